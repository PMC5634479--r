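#' Tabulate multifactor contingency cells for one SNP combination
#'
#' For a d-SNP combination there are 3^d multifactor cells, one per genotype
#' combination (three genotype levels per SNP). This splits the samples into
#' training (all folds except `test_fold`) and testing (the `test_fold`) and
#' counts cases and controls per cell in each part.
#'
#' @param data A [genotype_matrix()].
#' @param combo Integer vector of d distinct SNP column indices.
#' @param folds A fold assignment from [balanced_cv_split()].
#' @param test_fold Which fold serves as the testing data.
#' @return Object of class `contingency_cells`: per-cell count vectors
#'   `train_cases`, `train_controls`, `test_cases`, `test_controls` (length
#'   3^d, first SNP varying fastest), plus the training totals `n_plus1`
#'   (cases) and `n_plus0` (controls).
#' @export
tabulate_cells <- function(data, combo, folds, test_fold) {
  combo <- as.integer(combo)
  if (anyDuplicated(combo) || any(combo < 1L | combo > ncol(data$genotypes)))
    stop("combo must be distinct SNP column indices within range")
  k <- attr(folds, "k")
  if (is.null(k)) k <- max(folds)
  if (test_fold < 1L || test_fold > k) stop("invalid test fold id: ", test_fold)
  d <- length(combo)
  ncell <- 3L^d
  g <- data$genotypes[, combo, drop = FALSE]
  cell <- 1L + as.integer(g %*% (3L^(seq_len(d) - 1L)))
  is_test <- folds == test_fold
  is_case <- data$phenotype == 1L
  cnt <- function(keep) tabulate(cell[keep], nbins = ncell)
  out <- list(
    train_cases    = cnt(!is_test & is_case),
    train_controls = cnt(!is_test & !is_case),
    test_cases     = cnt(is_test & is_case),
    test_controls  = cnt(is_test & !is_case)
  )
  out$n_plus1 <- sum(out$train_cases)
  out$n_plus0 <- sum(out$train_controls)
  structure(out, class = "contingency_cells")
}

#' Training-data risk ratios per cell
#'
#' The unbalanced-data-corrected case:control ratio of each multifactor cell
#' in the training data: theta_hat_a = (n_+0 * n_a1) / (n_+1 * n_a0). Scaling
#' by the training class totals makes 1 the natural high/low threshold even
#' when cases and controls are unbalanced. A cell with cases but no controls
#' is `Inf` (high risk); a cell with no training samples at all is `NaN`
#' (empty: no risk evidence).
#'
#' @param cells A [tabulate_cells()] result.
#' @return Numeric vector of ratios, one per cell.
#' @export
training_ratio <- function(cells) {
  num <- cells$n_plus0 * cells$train_cases
  den <- cells$n_plus1 * cells$train_controls
  r <- num / den
  r[cells$train_cases == 0L & cells$train_controls == 0L] <- NaN
  r[cells$train_cases > 0L & cells$train_controls == 0L] <- Inf
  r
}

#' Testing-data risk ratios per cell
#'
#' theta_a = (n_+0 * t_a1) / (n_+1 * t_a0), with the class totals n_+0 and
#' n_+1 still taken from the training data.
#'
#' @inheritParams training_ratio
#' @return Numeric vector of ratios, one per cell (`NaN` for cells without
#'   testing samples, `Inf` for testing cases without controls).
#' @export
testing_ratio <- function(cells) {
  num <- cells$n_plus0 * cells$test_cases
  den <- cells$n_plus1 * cells$test_controls
  r <- num / den
  r[cells$test_cases == 0L & cells$test_controls == 0L] <- NaN
  r[cells$test_cases > 0L & cells$test_controls == 0L] <- Inf
  r
}

#' Label multifactor cells high or low risk
#'
#' A cell is high risk when its training ratio is at least 1, low risk below
#' 1, and empty when the training data contain no samples for it. Risk is
#' determined by the training data only; testing samples are subsequently
#' classified against these labels.
#'
#' @inheritParams training_ratio
#' @return Character vector over cells with values `"high"`, `"low"`,
#'   `"empty"`; class `risk_labeling`.
#' @export
classify_cells <- function(cells) {
  r <- training_ratio(cells)
  lab <- ifelse(is.nan(r), "empty", ifelse(r >= 1, "high", "low"))
  structure(lab, class = "risk_labeling")
}

#' Confusion counts of the testing data against training risk labels
#'
#' TP/FN are testing cases in high/low cells; FP/TN are testing controls in
#' high/low cells. Testing samples that fall in empty-labeled cells carry no
#' risk evidence and are excluded (the default), or pooled into the low-risk
#' group with `empty_cells = "low"`.
#'
#' @param labels A [classify_cells()] labeling.
#' @param cells The matching [tabulate_cells()] result.
#' @param empty_cells Either `"exclude"` (default) or `"low"`.
#' @return List with integer fields `TP`, `FP`, `FN`, `TN`; class
#'   `confusion_counts`.
#' @export
confusion_counts <- function(labels, cells, empty_cells = c("exclude", "low")) {
  empty_cells <- match.arg(empty_cells)
  lab <- unclass(labels)
  if (length(lab) != length(cells$test_cases))
    stop("labels and cells disagree on the number of multifactor cells")
  if (empty_cells == "low") lab[lab == "empty"] <- "low"
  hi <- lab == "high"
  lo <- lab == "low"
  structure(list(
    TP = sum(cells$test_cases[hi]), FP = sum(cells$test_controls[hi]),
    FN = sum(cells$test_cases[lo]), TN = sum(cells$test_controls[lo])
  ), class = "confusion_counts")
}

#' Correct classification rate (balanced accuracy)
#'
#' CCR = 0.5 (TP/(TP+FN) + TN/(FP+TN)): the mean of sensitivity and
#' specificity, so chance level is 0.5 regardless of class balance. A term
#' with a zero denominator (no testing samples of that class in labeled
#' cells) contributes 0, keeping the measure bounded and comparisons total.
#'
#' @param counts A [confusion_counts()] result (or any list with TP, FP, FN,
#'   TN).
#' @return CCR in `[0, 1]`.
#' @export
ccr <- function(counts) {
  sens_den <- counts$TP + counts$FN
  spec_den <- counts$FP + counts$TN
  sens <- if (sens_den > 0) counts$TP / sens_den else 0
  spec <- if (spec_den > 0) counts$TN / spec_den else 0
  0.5 * (sens + spec)
}

# x log2 x with the 0 log 0 = 0 convention; vectorized.
xlogx <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log2(x[pos])
  out
}

#' Normalized mutual information of a confusion table
#'
#' NMI = (H(y) - H(y|x)) / H(y): the fraction of uncertainty about the true
#' class y removed by the high/low risk prediction x, computed from the 2x2
#' confusion table by the closed form in counts (with 0 log 0 = 0). Equals
#' the entropy-composition definition exactly. By the symmetry of mutual
#' information it is 1 for perfectly inverted as well as perfect
#' classification. Defined as 0 when the testing fold contains a single class
#' (H(y) = 0: no uncertainty to reduce) or is empty.
#'
#' @inheritParams ccr
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN; TN <- counts$TN
  N <- TP + FP + FN + TN
  num <- xlogx(N) + xlogx(TP) + xlogx(FN) + xlogx(TN) + xlogx(FP) -
    xlogx(TP + FP) - xlogx(TP + FN) - xlogx(TN + FP) - xlogx(TN + FN)
  den <- xlogx(N) - xlogx(TP + FN) - xlogx(TN + FP)
  if (den <= 0) return(0)
  min(max(num / den, 0), 1)
}

#' Cross-validated MDR fitness of a SNP combination
#'
#' Runs the full MDR evaluation: for each fold as testing data, tabulate the
#' multifactor cells, label them high/low risk from the training ratios,
#' classify the testing samples, and score the confusion table with CCR and
#' NMI; then average both measures over all folds.
#'
#' @param data A [genotype_matrix()].
#' @param combo Integer vector of distinct SNP column indices.
#' @param folds A [balanced_cv_split()] assignment.
#' @param rule `"training"` (default): risk labels come from the training
#'   ratios alone. `"joint"`: a testing sample only counts when the training
#'   and testing ratios agree on the side of 1 (the literal joint condition;
#'   kept for auditability).
#' @param empty_cells Passed to [confusion_counts()].
#' @return List with `ccr` and `nmi` (fold means) and matrices of the
#'   per-fold values in `per_fold`; class `fitness_pair`.
#' @export
evaluate_combination <- function(data, combo, folds,
                                 rule = c("training", "joint"),
                                 empty_cells = c("exclude", "low")) {
  rule <- match.arg(rule)
  empty_cells <- match.arg(empty_cells)
  k <- attr(folds, "k")
  if (is.null(k)) k <- max(folds)
  ccrs <- nmis <- numeric(k)
  for (f in seq_len(k)) {
    cells <- tabulate_cells(data, combo, folds, f)
    lab <- classify_cells(cells)
    if (rule == "joint") {
      test_r <- testing_ratio(cells)
      lab <- unclass(lab)
      agree_hi <- lab == "high" & !is.nan(test_r) & test_r >= 1
      agree_lo <- lab == "low" & !is.nan(test_r) & test_r < 1
      lab[!(agree_hi | agree_lo) & lab != "empty"] <- "empty"
      lab <- structure(lab, class = "risk_labeling")
    }
    cc <- confusion_counts(lab, cells, empty_cells)
    ccrs[f] <- ccr(cc)
    nmis[f] <- nmi(cc)
  }
  structure(list(ccr = mean(ccrs), nmi = mean(nmis),
                 per_fold = cbind(ccr = ccrs, nmi = nmis)),
            class = "fitness_pair")
}

# ---- fast evaluation path -------------------------------------------------
#
# The DE search evaluates tens of thousands of pairs per run, so the
# per-combination work must stay in a handful of vectorized operations. The
# context precomputes a per-sample bin offset combining phenotype and fold so
# that a single tabulate() call yields all 9 x 2 x k counts at once.

mdr_eval_context <- function(data, folds) {
  k <- attr(folds, "k")
  if (is.null(k)) k <- max(folds)
  list(
    geno = data$genotypes,
    k = k,
    offset = 9L * data$phenotype + 18L * (as.integer(folds) - 1L),
    nbins = 18L * k
  )
}

# Fold-averaged (ccr, nmi) for a pair of SNP columns under the training rule
# with empty cells excluded; numerically identical to evaluate_combination.
mdr_eval_pair <- function(ctx, i, j) {
  g <- ctx$geno
  cell <- g[, i] * 3L + g[, j] + 1L
  cnt <- tabulate(cell + ctx$offset, nbins = ctx$nbins)
  k <- ctx$k
  M <- matrix(cnt, nrow = 18L)          # rows 1:9 controls, 10:18 cases
  test_ctrl <- M[1:9, , drop = FALSE]
  test_case <- M[10:18, , drop = FALSE]
  tot_ctrl <- rowSums(test_ctrl)
  tot_case <- rowSums(test_case)
  train_ctrl <- tot_ctrl - test_ctrl    # 9 x k, recycled by column
  train_case <- tot_case - test_case
  nplus0 <- colSums(train_ctrl)
  nplus1 <- colSums(train_case)
  lhs <- train_case * rep(nplus0, each = 9L)
  rhs <- train_ctrl * rep(nplus1, each = 9L)
  nonempty <- (train_case + train_ctrl) > 0L
  hi <- nonempty & (lhs >= rhs)
  lo <- nonempty & !hi
  TP <- colSums(test_case * hi); FP <- colSums(test_ctrl * hi)
  FN <- colSums(test_case * lo); TN <- colSums(test_ctrl * lo)
  sens_den <- TP + FN
  spec_den <- FP + TN
  sens <- ifelse(sens_den > 0, TP / sens_den, 0)
  spec <- ifelse(spec_den > 0, TN / spec_den, 0)
  ccr_k <- 0.5 * (sens + spec)
  N <- TP + FP + FN + TN
  num <- xlogx(N) + xlogx(TP) + xlogx(FN) + xlogx(TN) + xlogx(FP) -
    xlogx(TP + FP) - xlogx(TP + FN) - xlogx(TN + FP) - xlogx(TN + FN)
  den <- xlogx(N) - xlogx(TP + FN) - xlogx(TN + FP)
  nmi_k <- ifelse(den > 0, pmin(pmax(num / den, 0), 1), 0)
  c(mean(ccr_k), mean(nmi_k))
}

#' Chi-square significance of a SNP combination
#'
#' Labels every multifactor cell high or low risk from the full dataset (no
#' cross-validation), pools the data into a 2x2 high/low-by-case/control
#' table, and returns the 1-df Pearson chi-square p-value (no continuity
#' correction by default).
#'
#' Because the high/low dichotomy is chosen from the same data it is then
#' tested on, the p-value is anti-conservative for null combinations; treat
#' it as a ranking aid for reported interactions, not a calibrated
#' significance test.
#'
#' @param data A [genotype_matrix()].
#' @param combo Integer vector of distinct SNP column indices.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return The p-value, with attributes `statistic` (the chi-square value),
#'   `table` (the pooled 2x2 table) and `degenerate` (`TRUE` when a margin is
#'   empty, in which case p = 1 and a warning is issued).
#' @export
chi2_significance <- function(data, combo, correct = FALSE) {
  combo <- as.integer(combo)
  d <- length(combo)
  if (anyDuplicated(combo) || any(combo < 1L | combo > ncol(data$genotypes)))
    stop("combo must be distinct SNP column indices within range")
  g <- data$genotypes[, combo, drop = FALSE]
  cell <- 1L + as.integer(g %*% (3L^(seq_len(d) - 1L)))
  ncell <- 3L^d
  is_case <- data$phenotype == 1L
  n_a1 <- tabulate(cell[is_case], nbins = ncell)
  n_a0 <- tabulate(cell[!is_case], nbins = ncell)
  np1 <- sum(n_a1); np0 <- sum(n_a0)
  nonempty <- (n_a1 + n_a0) > 0L
  hi <- nonempty & (np0 * n_a1 >= np1 * n_a0)
  lo <- nonempty & !hi
  tab <- matrix(c(sum(n_a1[hi]), sum(n_a0[hi]),
                  sum(n_a1[lo]), sum(n_a0[lo])),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("high", "low"), c("case", "control")))
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) {
    warning("degenerate 2x2 table (empty margin); returning p = 1")
    return(structure(1, statistic = 0, table = tab, degenerate = TRUE))
  }
  delta <- abs(tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])
  if (correct) delta <- max(delta - N / 2, 0)
  stat <- N * delta^2 / prod(c(rs, cs))
  p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  structure(p, statistic = stat, table = tab, degenerate = FALSE)
}
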