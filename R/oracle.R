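#' Exhaustive Pareto front over all d-SNP combinations
#'
#' Brute-force reference: evaluates every d-combination of SNP columns with
#' the cross-validated MDR fitness and returns the full (uncapped)
#' nondominated set under the same dominance rule as the DE search. Intended
#' for small SNP counts; refuses to enumerate more than `max_combos`
#' combinations.
#'
#' @param data A [genotype_matrix()].
#' @param d Interaction order.
#' @param folds A [balanced_cv_split()] assignment.
#' @param objective,strict Dominance rule, as in [mode_config()].
#' @param max_combos Enumeration guard (default 1e6).
#' @return A `pareto_archive` with unlimited capacity, sorted by CCR
#'   descending, with attribute `n_evaluated` (number of combinations
#'   scored).
#' @export
exhaustive_pareto <- function(data, d, folds, objective = "both",
                              strict = TRUE, max_combos = 1e6) {
  n <- ncol(data$genotypes)
  n_combos <- choose(n, d)
  if (n_combos > max_combos)
    stop("refusing to enumerate ", n_combos, " combinations (guard ",
         max_combos, ")")
  combos <- utils::combn(n, d)
  fast <- d == 2L
  ctx <- if (fast) mdr_eval_context(data, folds)
  fit <- t(apply(combos, 2L, function(cmb) {
    if (fast) mdr_eval_pair(ctx, cmb[1L], cmb[2L])
    else {
      fp <- evaluate_combination(data, cmb, folds)
      c(fp$ccr, fp$nmi)
    }
  }))
  cfg <- list(objective = objective, strict = strict)
  arch <- new_archive(capacity = ncol(combos), d = d)
  arch <- update_archive(arch, t(combos), fit, cfg)
  ord <- order(-arch$fitness[, 1L], -arch$fitness[, 2L])
  arch$params <- arch$params[ord, , drop = FALSE]
  arch$fitness <- arch$fitness[ord, , drop = FALSE]
  arch$keys <- arch$keys[ord]
  attr(arch, "n_evaluated") <- ncol(combos)
  arch
}

# Training-data CCR per fold for one combination: cells are labeled from the
# training ratios and the training samples themselves are classified.
training_ccr_by_fold <- function(data, combo, folds) {
  k <- attr(folds, "k")
  if (is.null(k)) k <- max(folds)
  vapply(seq_len(k), function(f) {
    cells <- tabulate_cells(data, combo, folds, f)
    lab <- unclass(classify_cells(cells))
    hi <- lab == "high"; lo <- lab == "low"
    cc <- list(TP = sum(cells$train_cases[hi]),
               FP = sum(cells$train_controls[hi]),
               FN = sum(cells$train_cases[lo]),
               TN = sum(cells$train_controls[lo]))
    ccr(cc)
  }, numeric(1L))
}

#' Exhaustive MDR with cross-validation consistency
#'
#' Canonical MDR model selection: in each fold, the combination maximizing
#' the training-data CCR is recorded; the cross-validation consistency (CVC)
#' is the number of folds in which the modal combination wins. Returns the
#' modal combination, its CVC and its fold-averaged testing fitness.
#'
#' @inheritParams exhaustive_pareto
#' @return List with `combo` (integer vector), `cvc` (integer in `[1, k]`),
#'   `fitness` (the [evaluate_combination()] result for the modal combo) and
#'   `per_fold_best` (matrix of each fold's winning combination).
#' @export
exhaustive_best_by_cvc <- function(data, d, folds, max_combos = 1e6) {
  n <- ncol(data$genotypes)
  if (choose(n, d) > max_combos)
    stop("refusing to enumerate ", choose(n, d), " combinations (guard ",
         max_combos, ")")
  k <- attr(folds, "k")
  if (is.null(k)) k <- max(folds)
  combos <- utils::combn(n, d)
  train_ccr <- matrix(NA_real_, ncol(combos), k)
  if (d == 2L) {
    # vectorized training CCR over all pairs and folds
    ctx <- mdr_eval_context(data, folds)
    for (ci in seq_len(ncol(combos)))
      train_ccr[ci, ] <- fast_training_ccr_pair(ctx, combos[1L, ci],
                                                combos[2L, ci])
  } else {
    for (ci in seq_len(ncol(combos)))
      train_ccr[ci, ] <- training_ccr_by_fold(data, combos[, ci], folds)
  }
  best_per_fold <- apply(train_ccr, 2L, which.max)
  keys <- apply(combos[, best_per_fold, drop = FALSE], 2L, paste,
                collapse = ",")
  tabled <- sort(table(keys), decreasing = TRUE)
  modal_key <- names(tabled)[1L]
  combo <- as.integer(strsplit(modal_key, ",", fixed = TRUE)[[1L]])
  list(combo = combo,
       cvc = as.integer(tabled[[1L]]),
       fitness = evaluate_combination(data, combo, folds),
       per_fold_best = combos[, best_per_fold, drop = FALSE])
}

# Training CCR for a SNP pair in every fold at once (shares the binning
# trick of mdr_eval_pair).
fast_training_ccr_pair <- function(ctx, i, j) {
  g <- ctx$geno
  cell <- g[, i] * 3L + g[, j] + 1L
  cnt <- tabulate(cell + ctx$offset, nbins = ctx$nbins)
  M <- matrix(cnt, nrow = 18L)
  test_ctrl <- M[1:9, , drop = FALSE]
  test_case <- M[10:18, , drop = FALSE]
  train_ctrl <- rowSums(test_ctrl) - test_ctrl
  train_case <- rowSums(test_case) - test_case
  nplus0 <- colSums(train_ctrl)
  nplus1 <- colSums(train_case)
  hi <- (train_case + train_ctrl > 0L) &
    (train_case * rep(nplus0, each = 9L) >= train_ctrl * rep(nplus1, each = 9L))
  lo <- (train_case + train_ctrl > 0L) & !hi
  TP <- colSums(train_case * hi); FN <- colSums(train_case * lo)
  TN <- colSums(train_ctrl * lo); FP <- colSums(train_ctrl * hi)
  sens <- ifelse(TP + FN > 0, TP / (TP + FN), 0)
  spec <- ifelse(FP + TN > 0, TN / (FP + TN), 0)
  0.5 * (sens + spec)
}

#' Detection success rate over replicate simulated datasets
#'
#' Runs a search procedure on each replicate and scores it detected when the
#' planted functional SNP combination (as an unordered index set) appears
#' among the reported combinations.
#'
#' @param replicates List of [simulate_dataset()] results.
#' @param method Function taking a [genotype_matrix()] and returning either a
#'   `pareto_archive` or a matrix/vector of reported index combinations
#'   (rows).
#' @return The detected fraction in `[0, 1]`, with attribute `detail`: a
#'   logical vector per replicate.
#' @export
detection_success_rate <- function(replicates, method) {
  detected <- vapply(replicates, function(rep_i) {
    res <- method(rep_i$data)
    target <- combo_key(rep_i$functional_indices)
    keys <- if (inherits(res, "pareto_archive")) res$keys
            else {
              m <- if (is.matrix(res)) res else matrix(res, nrow = 1L)
              apply(m, 1L, function(r) combo_key(as.integer(r)))
            }
    target %in% keys
  }, logical(1L))
  structure(mean(detected), detail = detected)
}

#' Wilcoxon signed-rank comparison of paired detection rates
#'
#' Paired comparison of two methods across epistatic models: differences of
#' zero are counted as ties (R=), the remaining absolute differences are
#' ranked (average ranks for ties in magnitude), and the standard
#' normal-approximation z statistic is computed without continuity
#' correction. An exact p-value by enumeration of sign assignments is used
#' when fewer than `exact_below` non-tied pairs remain (and `exact = NULL`).
#'
#' @param rates_a,rates_b Equal-length numeric vectors (e.g. per-model
#'   detection rates of methods A and B).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact enumeration;
#'   `NULL` (default) decides by `exact_below`.
#' @param exact_below Threshold for the automatic exact rule (default 15).
#' @return List with `n_pos`, `n_neg`, `n_tie` (counts of a > b, a < b,
#'   ties), `rank_sum_pos`, `rank_sum_neg`, `z` and `p` (two-sided). All-tied
#'   input yields the degenerate result `p = 1`, `z = 0`.
#' @export
wilcoxon_signed_rank <- function(rates_a, rates_b, exact = NULL,
                                 exact_below = 15L) {
  if (length(rates_a) != length(rates_b))
    stop("paired vectors must have equal length")
  d <- rates_a - rates_b
  ties <- d == 0
  n_tie <- sum(ties)
  d <- d[!ties]
  n <- length(d)
  if (n == 0L)
    return(list(n_pos = 0L, n_neg = 0L, n_tie = n_tie,
                rank_sum_pos = 0, rank_sum_neg = 0, z = 0, p = 1))
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  mu <- n * (n + 1) / 4
  # variance with the standard correction for tied absolute ranks
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (w_pos - mu) / sqrt(sigma2)
  if (is.null(exact)) exact <- n < exact_below
  if (exact && length(unique(r)) == n) {
    # enumerate all 2^n sign assignments of the ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.numeric(signs %*% r)
    p <- mean(abs(w_all - mu) >= abs(w_pos - mu))
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(n_pos = sum(d > 0), n_neg = sum(d < 0), n_tie = n_tie,
       rank_sum_pos = w_pos, rank_sum_neg = w_neg, z = z, p = min(p, 1))
}

#' Detection-rate benchmark over a grid of epistatic model settings
#'
#' For each row of the settings grid, searches a pure epistatic model at the
#' requested MAF and heritability, simulates the replicate datasets, runs
#' each method, and tabulates detection success rates — the simulation-study
#' protocol at configurable scale.
#'
#' @param grid Data frame with columns `maf`, `h2`, `cases`, `controls`,
#'   `snps` (one row per setting).
#' @param n_replicates Replicate datasets per setting.
#' @param methods Named list of method functions (see
#'   [detection_success_rate()]); the default runs the multiobjective search
#'   with [mode_config()] defaults.
#' @param seed Integer master seed; every model search, dataset and method
#'   run derives its own sub-seed from it, so the full table is reproducible.
#' @param config Base [mode_config()] used by the default methods.
#' @return List with `rates` (data frame: setting x method x rate) and
#'   `detail` (one row per dataset x method with the detected flag).
#' @export
run_benchmark <- function(grid, n_replicates = 20L, methods = NULL,
                          seed = 1L, config = mode_config()) {
  stopifnot(all(c("maf", "h2", "cases", "controls", "snps") %in% names(grid)))
  if (is.null(methods)) {
    methods <- list(
      modemdr = function(data, run_seed) {
        cfg <- config
        cfg$seed <- run_seed
        mode_run(data, cfg)
      }
    )
  }
  rates <- list()
  detail <- list()
  for (s in seq_len(nrow(grid))) {
    st <- grid[s, ]
    model_seed <- seed + 7919L * s
    model <- generate_pure_epistatic_model(st$maf, st$h2, seed = model_seed)
    reps <- lapply(seq_len(n_replicates), function(r) {
      simulate_dataset(model, st$cases, st$controls, st$snps,
                       seed = model_seed + r)
    })
    for (mname in names(methods)) {
      fn <- methods[[mname]]
      det <- vapply(seq_along(reps), function(r) {
        res <- fn(reps[[r]]$data, model_seed + 104729L + r)
        target <- combo_key(reps[[r]]$functional_indices)
        keys <- if (inherits(res, "pareto_archive")) res$keys
                else apply(if (is.matrix(res)) res else
                           matrix(res, nrow = 1L), 1L,
                           function(x) combo_key(as.integer(x)))
        target %in% keys
      }, logical(1L))
      rates[[length(rates) + 1L]] <- data.frame(
        setting = s, maf = st$maf, h2 = st$h2, cases = st$cases,
        controls = st$controls, snps = st$snps, method = mname,
        rate = mean(det)
      )
      detail[[length(detail) + 1L]] <- data.frame(
        setting = s, method = mname, replicate = seq_along(det),
        detected = det
      )
    }
  }
  list(rates = do.call(rbind, rates), detail = do.call(rbind, detail))
}
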