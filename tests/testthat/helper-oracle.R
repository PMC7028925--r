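# Exact collapsed-enumeration oracle for the K = 2 admixture model on a
# 2-locus, 2-allele toy: 3 wild references homozygous for allele A at both
# loci, 3 domestic references homozygous for allele B, one query genotype.
# Allele frequencies are integrated out via Dirichlet-multinomial terms,
# each individual's q via Beta integrals (alpha fixed), and all copy-origin
# configurations are enumerated, aggregating reference pools by
# exchangeability. The mirrored label mode is removed by conditioning on the
# wild references' copies being majority-wild, matching post-hoc anchoring.
#
# query: list of two length-2 vectors with entries 1 (allele A) or 2 (B),
# e.g. list(c(1, 2), c(1, 1)) = heterozygous at locus 1, homozygous A at 2.
# Returns the exact posterior mean wild membership of the query.
oracle_admixture_toy <- function(query, alpha = 1, lambda = 1,
                                 n_refs_per_pool = 3) {
  n_copies_ind <- 4L   # 2 loci x 2 copies
  beta_int <- function(nw) {
    beta(alpha + nw, alpha + n_copies_ind - nw) / beta(alpha, alpha)
  }
  # one reference individual: wild-copy counts (c1, c2) at the two loci,
  # weight = multiplicity x Beta integral
  ref_states <- expand.grid(c1 = 0:2, c2 = 0:2)
  ref_w <- choose(2, ref_states$c1) * choose(2, ref_states$c2) *
    beta_int(ref_states$c1 + ref_states$c2)
  # convolve n refs -> weight over pool totals (s1, s2), s in 0..2n
  pool_w <- matrix(1, 1, 1)  # delta at (0, 0)
  for (r in seq_len(n_refs_per_pool)) {
    newd <- nrow(pool_w) + 2L
    nw <- matrix(0, newd, newd)
    for (k in seq_len(nrow(ref_states))) {
      i <- ref_states$c1[k]
      j <- ref_states$c2[k]
      nw[seq_len(nrow(pool_w)) + i, seq_len(ncol(pool_w)) + j] <-
        nw[seq_len(nrow(pool_w)) + i, seq_len(ncol(pool_w)) + j] +
        pool_w * ref_w[k]
    }
    pool_w <- nw
  }
  smax <- 2L * n_refs_per_pool
  # query configurations: z (0 = wild) per copy
  qcfg <- expand.grid(z11 = 0:1, z12 = 0:1, z21 = 0:1, z22 = 0:1)
  dirmult <- function(nA, nB) {
    # integral of p^counts under Dirichlet(lambda) over 2 alleles
    exp(lgamma(2 * lambda) - lgamma(2 * lambda + nA + nB) +
          lgamma(lambda + nA) + lgamma(lambda + nB) - 2 * lgamma(lambda))
  }
  num <- 0
  den <- 0
  for (s1 in 0:smax) for (s2 in 0:smax) {
    if (s1 + s2 <= smax) next   # anchor: wild refs majority-wild
    w_wild <- pool_w[s1 + 1L, s2 + 1L]
    if (w_wild == 0) next
    for (u1 in 0:smax) for (u2 in 0:smax) {
      w_dog <- pool_w[u1 + 1L, u2 + 1L]   # same table by symmetry
      if (w_dog == 0) next
      for (k in seq_len(nrow(qcfg))) {
        z <- as.integer(qcfg[k, ])
        nw_q <- sum(z == 0L)
        # counts per locus x cluster x allele
        w <- w_wild * w_dog * beta_int(nw_q)
        for (l in 1:2) {
          zl <- z[c(2L * l - 1L, 2L * l)]
          al <- query[[l]]
          s_l <- if (l == 1L) s1 else s2
          u_l <- if (l == 1L) u1 else u2
          # wild cluster: A copies from wild refs + query; B from dog refs +
          # query; dog cluster is the complement
          nA_w <- s_l + sum(zl == 0L & al == 1L)
          nB_w <- (smax - u_l) + sum(zl == 0L & al == 2L)
          nA_d <- (smax - s_l) + sum(zl == 1L & al == 1L)
          nB_d <- u_l + sum(zl == 1L & al == 2L)
          w <- w * dirmult(nA_w, nB_w) * dirmult(nA_d, nB_d)
        }
        den <- den + w
        num <- num + w * (alpha + nw_q) / (2 * alpha + n_copies_ind)
      }
    }
  }
  num / den
}

# genotype_table matching the oracle's setup, with the query appended
oracle_toy_table <- function(query) {
  codes <- c(102L, 104L)  # A, B
  rows <- rbind(
    matrix(codes[1L], 3, 4),
    matrix(codes[2L], 3, 4)
  )
  qrow <- c(codes[query[[1L]]], codes[query[[2L]]])
  genotype_table(
    ids = c(paste0("W", 1:3), paste0("D", 1:3), "Q"),
    labels = c(rep("RW", 3), rep("RD", 3), "QUERY"),
    alleles = rbind(rows, qrow),
    panel = c("L01", "L02")
  )
}

# closed-form class posteriors at known allele frequencies (plug-in oracle):
# P(class | genotype) ~ prior * prod_l sum_w g_w(class) * GenoProb(a, b | w)
closed_form_class_posterior <- function(geno_pairs, p_wild, p_dom,
                                        prior = rep(1 / 5, 5)) {
  g <- class_g_vectors()
  ll <- rep(0, 5)
  for (l in seq_along(geno_pairs)) {
    a <- geno_pairs[[l]][1]
    b <- geno_pairs[[l]][2]
    p0a <- p_wild[[l]][a]; p0b <- p_wild[[l]][b]
    p1a <- p_dom[[l]][a];  p1b <- p_dom[[l]][b]
    if (a == b) {
      P <- c(p0a^2, p0a * p1a, p1a^2)
    } else {
      P <- c(2 * p0a * p0b, p0a * p1b + p0b * p1a, 2 * p1a * p1b)
    }
    ll <- ll + log(g %*% P)
  }
  w <- prior * exp(ll - max(ll))
  stats::setNames(as.vector(w / sum(w)), rownames(g))
}
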