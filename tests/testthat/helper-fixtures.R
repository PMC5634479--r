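# Shared fixtures, all built in code.

# XOR-style pure model at MAF 0.5: penetrance 1 on the cells with exactly one
# heterozygote among {(0,1),(1,0),(1,2),(2,1)}; prevalence 0.5, h2 = 1.
xor_model <- function() {
  pen <- matrix(0, 3, 3)
  pen[1, 2] <- pen[2, 1] <- pen[2, 3] <- pen[3, 2] <- 1
  penetrance_model(c(0.5, 0.5), pen)
}

# Small dataset in which SNP 1 perfectly separates cases (genotype 2) from
# controls (genotype 0); remaining SNPs are shuffled noise.
perfect_snp_data <- function(n_per_class = 30L, n_snps = 5L, seed = 42L) {
  set.seed(seed)
  n <- 2L * n_per_class
  g <- matrix(sample(0:2, n * n_snps, replace = TRUE), n, n_snps)
  phen <- rep(c(1L, 0L), each = n_per_class)
  g[, 1L] <- ifelse(phen == 1L, 2L, 0L)
  genotype_matrix(g, phen)
}

# A dataset with a planted perfect 2-locus XOR pattern at the given columns.
planted_pair_data <- function(n_per_class = 50L, n_snps = 20L,
                              pair = c(3L, 11L), seed = 7L) {
  set.seed(seed)
  n <- 2L * n_per_class
  g <- matrix(sample(0:2, n * n_snps, replace = TRUE), n, n_snps)
  phen <- rep(c(1L, 0L), each = n_per_class)
  a <- sample(0:2, n, replace = TRUE)
  b <- integer(n)
  # cases only on XOR-high cells, controls only elsewhere
  for (s in seq_len(n)) {
    repeat {
      bb <- sample(0:2, 1L)
      hi <- (a[s] == 0 && bb == 1) || (a[s] == 1 && bb == 0) ||
            (a[s] == 1 && bb == 2) || (a[s] == 2 && bb == 1)
      if (hi == (phen[s] == 1L)) { b[s] <- bb; break }
    }
  }
  g[, pair[1L]] <- a
  g[, pair[2L]] <- b
  genotype_matrix(g, phen)
}

# Random confusion-count tables for property tests.
random_confusion <- function(n_tables, max_count = 200L) {
  lapply(seq_len(n_tables), function(i) {
    v <- sample(0:max_count, 4L, replace = TRUE)
    list(TP = v[1L], FP = v[2L], FN = v[3L], TN = v[4L])
  })
}

# Entropy-composition NMI: the independent route through H(y), H(y|x).
nmi_by_entropies <- function(cc) {
  N <- cc$TP + cc$FP + cc$FN + cc$TN
  if (N == 0) return(0)
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  p_y <- c(cc$TP + cc$FN, cc$FP + cc$TN) / N
  hy <- h(p_y)
  if (hy == 0) return(0)
  p_hi <- (cc$TP + cc$FP) / N
  p_lo <- (cc$FN + cc$TN) / N
  hyx <- 0
  if (p_hi > 0) hyx <- hyx + p_hi * h(c(cc$TP, cc$FP) / (cc$TP + cc$FP))
  if (p_lo > 0) hyx <- hyx + p_lo * h(c(cc$FN, cc$TN) / (cc$FN + cc$TN))
  (hy - hyx) / hy
}
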