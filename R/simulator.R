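#' Hardy-Weinberg genotype frequencies
#'
#' Genotype probabilities for minor-allele counts 0, 1, 2 at a biallelic locus
#' under Hardy-Weinberg equilibrium: ((1-p)^2, 2p(1-p), p^2) for minor allele
#' frequency p.
#'
#' @param maf Minor allele frequency, in (0, 0.5].
#' @return Numeric probability 3-vector summing to 1.
#' @examples
#' hwe_genotype_frequencies(0.2) # 0.64 0.32 0.04
#' @export
hwe_genotype_frequencies <- function(maf) {
  if (!is.numeric(maf) || length(maf) != 1L || is.na(maf) ||
      maf <= 0 || maf > 0.5)
    stop("maf must be a single value in (0, 0.5]")
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

#' Construct a multilocus penetrance model
#'
#' A disease model over `d` biallelic loci: per-locus minor-allele frequencies
#' plus a `3^d`-cell penetrance table giving P(disease | genotype combination).
#' Genotype combinations index the table with the first locus varying fastest
#' (standard R array order), levels being minor-allele counts 0/1/2.
#'
#' @param mafs Numeric vector of per-locus MAFs, each in (0, 0.5].
#' @param penetrance Numeric array (or matrix/vector reshaped) of `3^d`
#'   penetrances in `[0, 1]`.
#' @return Object of class `penetrance_model` with fields `mafs`,
#'   `penetrance` (d-dimensional array) and `order`.
#' @export
penetrance_model <- function(mafs, penetrance) {
  d <- length(mafs)
  if (d < 1L) stop("at least one locus required")
  for (m in mafs) {
    if (is.na(m) || m <= 0 || m > 0.5)
      stop("every maf must lie in (0, 0.5]")
  }
  pen <- array(as.numeric(penetrance), dim = rep(3L, d))
  if (length(pen) != 3^d)
    stop("penetrance table must have 3^d = ", 3^d, " entries")
  if (anyNA(pen) || any(pen < 0) || any(pen > 1))
    stop("penetrance values must lie in [0, 1]")
  structure(list(mafs = as.numeric(mafs), penetrance = pen, order = d),
            class = "penetrance_model")
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat("penetrance_model: ", x$order, " loci, MAF = ",
      paste(signif(x$mafs, 4), collapse = ", "),
      ", K = ", signif(compute_prevalence(x), 4),
      ", h2 = ", signif(compute_heritability(x), 4), "\n", sep = "")
  invisible(x)
}

# Joint HWE probability over all genotype combinations, as an array matching
# the penetrance table layout.
hwe_cell_probabilities <- function(model) {
  probs <- lapply(model$mafs, hwe_genotype_frequencies)
  out <- Reduce(function(a, b) outer(a, b), probs)
  array(out, dim = rep(3L, model$order))
}

#' Disease prevalence of a penetrance model
#'
#' K = sum over genotype combinations of P_HWE(g) * f(g), with per-locus
#' independence under Hardy-Weinberg equilibrium.
#'
#' @param model A [penetrance_model()].
#' @return Prevalence K in `[0, 1]`.
#' @export
compute_prevalence <- function(model) {
  sum(hwe_cell_probabilities(model) * model$penetrance)
}

#' Broad-sense heritability of a penetrance model
#'
#' h2 = sum_g P_HWE(g) (f(g) - K)^2 / (K (1 - K)), the proportion of
#' phenotypic variance on the liability (probability) scale attributable to
#' genotype for a binary trait with prevalence K.
#'
#' @param model A [penetrance_model()].
#' @return Heritability in `[0, 1]`.
#' @export
compute_heritability <- function(model) {
  w <- hwe_cell_probabilities(model)
  K <- sum(w * model$penetrance)
  if (K <= 0 || K >= 1)
    stop("degenerate model: prevalence must lie strictly in (0, 1)")
  sum(w * (model$penetrance - K)^2) / (K * (1 - K))
}

#' Per-locus marginal penetrances
#'
#' For locus l and genotype a, the marginal penetrance is the HWE-weighted
#' average of f over the other loci. A model is "pure" (no marginal effects)
#' when every marginal penetrance equals the prevalence K: no single locus
#' carries any signal on its own.
#'
#' @param model A [penetrance_model()].
#' @return A `3 x d` matrix: rows are genotypes 0/1/2, columns loci.
#' @export
compute_marginal_penetrances <- function(model) {
  d <- model$order
  w <- hwe_cell_probabilities(model)
  wp <- w * model$penetrance
  out <- matrix(NA_real_, 3L, d)
  for (l in seq_len(d)) {
    num <- apply(wp, l, sum)
    den <- apply(w, l, sum)   # = HWE frequencies at locus l
    out[, l] <- num / den
  }
  rownames(out) <- c("0", "1", "2")
  out
}

#' Maximum deviation of the marginal penetrances from the prevalence
#'
#' Convenience purity diagnostic: 0 for a perfectly pure model.
#'
#' @param model A [penetrance_model()].
#' @return Largest absolute difference |m_l(a) - K| over loci and genotypes.
#' @export
marginal_deviation <- function(model) {
  K <- compute_prevalence(model)
  max(abs(compute_marginal_penetrances(model) - K))
}

#' Search for a pure two-locus epistatic penetrance model
#'
#' Random-restart stochastic search for a 2-locus penetrance table with both
#' MAFs equal to `maf`, heritability within `tol` of `h2_target`, and all
#' marginal penetrances within `tol` of the prevalence (no marginal effects).
#' Each restart proposes a random table, projects it toward zero marginal
#' deviation by alternating row/column additive adjustment under the HWE
#' weights, then rescales it about the prevalence, `f <- K + c (f - K)`
#' (clipped to `[0, 1]`), to move the heritability to the target; projection
#' and rescaling are iterated until both tolerances hold or the attempt is
#' abandoned.
#'
#' @param maf Minor allele frequency for both loci, in (0, 0.5].
#' @param h2_target Target heritability, in (0, 1).
#' @param seed Optional integer seed making the search deterministic.
#' @param tol Acceptance tolerance for both |h2 - target| and the maximum
#'   marginal deviation (default `1e-4`).
#' @param max_restarts Random restarts before giving up.
#' @return A [penetrance_model()] passing both self-checks.
#' @export
generate_pure_epistatic_model <- function(maf, h2_target, seed = NULL,
                                          tol = 1e-4, max_restarts = 500L) {
  if (h2_target <= 0 || h2_target >= 1)
    stop("h2_target must lie strictly in (0, 1)")
  w1 <- hwe_genotype_frequencies(maf)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  best_dev <- Inf
  for (restart in seq_len(max_restarts)) {
    f <- matrix(stats::runif(9L), 3L, 3L)
    ok <- FALSE
    for (outer_it in 1:200) {
      # project toward pure marginals (rows and columns weighted by HWE)
      for (it in 1:500) {
        K <- as.numeric(t(w1) %*% f %*% w1)
        rm_ <- as.numeric(f %*% w1)      # marginal over locus 2 per row
        f <- f - (rm_ - K)
        cm_ <- as.numeric(t(w1) %*% f)   # marginal over locus 1 per column
        f <- f - matrix(cm_ - as.numeric(t(w1) %*% f %*% w1),
                        3L, 3L, byrow = TRUE)
        f <- pmin(pmax(f, 0), 1)
        K <- as.numeric(t(w1) %*% f %*% w1)
        dev <- max(abs(c(as.numeric(f %*% w1), as.numeric(t(w1) %*% f)) - K))
        if (dev <= tol / 4) break
      }
      K <- as.numeric(t(w1) %*% f %*% w1)
      if (K <= 1e-6 || K >= 1 - 1e-6) break
      W <- outer(w1, w1)
      h2 <- sum(W * (f - K)^2) / (K * (1 - K))
      if (h2 <= 1e-12) break
      dev <- max(abs(c(as.numeric(f %*% w1), as.numeric(t(w1) %*% f)) - K))
      if (abs(h2 - h2_target) <= tol && dev <= tol) {
        ok <- TRUE
        break
      }
      # rescale about K toward the target heritability, then re-project
      f <- K + sqrt(h2_target / h2) * (f - K)
      f <- pmin(pmax(f, 0), 1)
      best_dev <- min(best_dev, abs(h2 - h2_target) + dev)
    }
    if (ok) {
      return(penetrance_model(c(maf, maf), f))
    }
  }
  stop("pure-model search failed after ", max_restarts,
       " restarts (best combined deviation ", signif(best_dev, 3),
       "); try a larger tol or different maf/h2_target")
}

#' Simulate a case-control dataset from a penetrance model
#'
#' Disease-locus genotypes are drawn per individual under HWE from the model
#' MAFs and disease status is Bernoulli in the corresponding penetrance; draws
#' are rejected until the case and control quotas are filled. Background SNPs
#' are pure null: independent of status, each with its own MAF drawn uniformly
#' from `maf_range`. The functional loci are hidden at random distinct column
#' positions, recorded in `functional_indices`.
#'
#' @param model A [penetrance_model()].
#' @param n_cases,n_controls Samples per class (> 0).
#' @param n_snps Total SNP columns, at least the model order.
#' @param maf_range Length-2 interval for the background MAF draw
#'   (default `c(0.05, 0.5)`, the upper end exclusive).
#' @param seed Optional integer seed; the dataset is then bit-reproducible.
#' @param draw_budget Maximum status draws before declaring the model
#'   degenerate; default `1000 * (n_cases + n_controls)`.
#' @return Object of class `simulated_dataset`: a list with `data`
#'   ([genotype_matrix()], cases first), `functional_indices` (columns of the
#'   disease loci, in model-locus order) and `model`.
#' @export
simulate_dataset <- function(model, n_cases, n_controls, n_snps,
                             maf_range = c(0.05, 0.5), seed = NULL,
                             draw_budget = NULL) {
  d <- model$order
  if (n_snps < d) stop("n_snps must be at least the model order")
  if (n_cases < 1L || n_controls < 1L) stop("both class quotas must be positive")
  if (is.null(draw_budget)) draw_budget <- 1000 * (n_cases + n_controls)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  n <- n_cases + n_controls
  geno_probs <- lapply(model$mafs, hwe_genotype_frequencies)

  func_case <- matrix(0L, 0L, d)
  func_ctrl <- matrix(0L, 0L, d)
  drawn <- 0L
  while ((nrow(func_case) < n_cases || nrow(func_ctrl) < n_controls) &&
         drawn < draw_budget) {
    chunk <- min(max(2L * n, 1000L), draw_budget - drawn)
    g <- vapply(seq_len(d), function(l) {
      sample.int(3L, chunk, replace = TRUE, prob = geno_probs[[l]]) - 1L
    }, integer(chunk))
    if (chunk == 1L) g <- matrix(g, 1L, d)
    cell <- 1L + as.integer(g %*% 3L^(seq_len(d) - 1L))
    status <- stats::rbinom(chunk, 1L, model$penetrance[cell])
    drawn <- drawn + chunk
    if (nrow(func_case) < n_cases) {
      add <- g[status == 1L, , drop = FALSE]
      func_case <- rbind(func_case, add)
    }
    if (nrow(func_ctrl) < n_controls) {
      add <- g[status == 0L, , drop = FALSE]
      func_ctrl <- rbind(func_ctrl, add)
    }
  }
  if (nrow(func_case) < n_cases || nrow(func_ctrl) < n_controls)
    stop("simulation budget exhausted (", drawn, " draws): model prevalence ",
         signif(compute_prevalence(model), 3),
         " too extreme to fill both quotas")
  func <- rbind(func_case[seq_len(n_cases), , drop = FALSE],
                func_ctrl[seq_len(n_controls), , drop = FALSE])
  phenotype <- c(rep(1L, n_cases), rep(0L, n_controls))

  geno <- matrix(0L, n, n_snps)
  n_bg <- n_snps - d
  if (n_bg > 0L) {
    bg_maf <- stats::runif(n_bg, maf_range[1L], maf_range[2L])
    bg <- vapply(bg_maf, function(p) {
      sample.int(3L, n, replace = TRUE, prob = hwe_genotype_frequencies(p)) - 1L
    }, integer(n))
    if (n == 1L) bg <- matrix(bg, 1L, n_bg)
  }
  functional_indices <- sort(sample.int(n_snps, d))
  geno[, functional_indices] <- func
  if (n_bg > 0L) geno[, -functional_indices] <- bg
  data <- genotype_matrix(geno, phenotype)
  structure(list(data = data, functional_indices = functional_indices,
                 model = model),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("simulated_dataset: functional loci at columns ",
      paste(x$functional_indices, collapse = ", "), "\n", sep = "")
  print(x$data)
  invisible(x)
}
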