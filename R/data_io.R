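#' Construct a case-control genotype matrix
#'
#' The universal input container: an `n_samples x n_snps` integer matrix of
#' minor-allele counts (0/1/2) together with a binary phenotype (1 = case,
#' 0 = control) and unique SNP names.
#'
#' @param genotypes Integer matrix, samples in rows, SNPs in columns; values
#'   must be 0, 1 or 2 (minor-allele count).
#' @param phenotype Integer vector of length `nrow(genotypes)`; 1 for cases,
#'   0 for controls. Both classes must be present.
#' @param snp_names Character vector of unique SNP names, one per column.
#'   Defaults to existing column names or `SNP1..SNPn`.
#' @return An object of class `genotype_matrix` with elements `genotypes`,
#'   `phenotype` and `snp_names`.
#' @examples
#' g <- matrix(c(0L, 2L, 1L, 1L, 0L, 1L), nrow = 3)
#' gm <- genotype_matrix(g, c(1L, 0L, 1L))
#' gm
#' @export
genotype_matrix <- function(genotypes, phenotype, snp_names = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  phenotype <- as.integer(phenotype)
  if (is.null(snp_names)) {
    snp_names <- colnames(genotypes)
    if (is.null(snp_names)) snp_names <- paste0("SNP", seq_len(ncol(genotypes)))
  }
  obj <- structure(
    list(genotypes = genotypes, phenotype = phenotype,
         snp_names = as.character(snp_names)),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(obj)
}

validate_genotype_matrix <- function(x) {
  g <- x$genotypes
  if (nrow(g) < 1L) stop("genotype matrix must have at least one sample")
  if (ncol(g) < 2L) stop("genotype matrix must have at least two SNPs")
  if (anyNA(g) || !all(g %in% 0:2))
    stop("genotype values must all be 0, 1 or 2 (minor-allele counts)")
  ph <- x$phenotype
  if (length(ph) != nrow(g))
    stop("phenotype length (", length(ph), ") does not match sample count (",
         nrow(g), ")")
  if (anyNA(ph) || !all(ph %in% 0:1))
    stop("phenotype values must all be 0 (control) or 1 (case)")
  if (!any(ph == 1L) || !any(ph == 0L))
    stop("dataset must contain at least one case and one control")
  if (length(x$snp_names) != ncol(g))
    stop("snp_names length does not match SNP count")
  if (anyDuplicated(x$snp_names))
    stop("snp_names must be unique")
  x
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x$genotypes), " samples x ",
      ncol(x$genotypes), " SNPs (", sum(x$phenotype == 1L), " cases, ",
      sum(x$phenotype == 0L), " controls)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

#' Read a case-control genotype dataset from a tab-delimited file
#'
#' Reads the GAMETES-style dialect: one header row of SNP names followed by a
#' final `Class` column, then one tab-delimited row per sample with genotypes
#' coded 0/1/2 and class 0 (control) / 1 (case).
#'
#' @param path Path to an existing tab-delimited text file.
#' @return A validated [genotype_matrix()]; row order preserved.
#' @seealso [write_dataset()] for the inverse operation.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("parse error: file needs a header and body rows")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  p <- length(header)
  if (p < 3L)
    stop("parse error: header must list at least 2 SNP names plus a class column")
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(body) != p)
  if (length(bad))
    stop("parse error: line ", bad[[1L]] + 1L, " has ", lengths(body)[bad[[1L]]],
         " fields, expected ", p)
  vals <- suppressWarnings(as.integer(unlist(body, use.names = FALSE)))
  if (anyNA(vals))
    stop("parse error: non-integer field in body")
  m <- matrix(vals, nrow = length(body), ncol = p, byrow = TRUE)
  genotype_matrix(m[, -p, drop = FALSE], m[, p], header[-p])
}

#' Write a genotype dataset to the tab-delimited dialect read by read_dataset
#'
#' @param data A [genotype_matrix()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(data, path) {
  data <- validate_genotype_matrix(data)
  header <- paste(c(data$snp_names, "Class"), collapse = "\t")
  body <- apply(cbind(data$genotypes, data$phenotype), 1L, paste,
                collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Balanced k-fold cross-validation split
#'
#' Implements the balance strategy used before MDR evaluation: cases and
#' controls are shuffled independently, then each class is dealt round-robin
#' across the k folds, so every fold reproduces the global case:control ratio
#' to within one sample per class.
#'
#' @param data A [genotype_matrix()].
#' @param k Number of folds (>= 2); each class must have at least `k` members.
#' @param seed Optional integer seed; when supplied the split is a
#'   deterministic function of it (the global RNG state is restored on exit).
#' @return Integer vector of fold indices in `1..k`, one per sample, with
#'   attribute `k`; class `cv_fold_assignment`.
#' @export
balanced_cv_split <- function(data, k, seed = NULL) {
  data <- validate_genotype_matrix(data)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  idx_case <- which(data$phenotype == 1L)
  idx_ctrl <- which(data$phenotype == 0L)
  if (length(idx_case) < k || length(idx_ctrl) < k)
    stop("infeasible split: each class needs at least k = ", k, " samples ",
         "(have ", length(idx_case), " cases, ", length(idx_ctrl), " controls)")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  fold <- integer(nrow(data$genotypes))
  # deal each shuffled class round-robin over folds 1..k
  sh_case <- sample(idx_case)
  sh_ctrl <- sample(idx_ctrl)
  fold[sh_case] <- rep_len(seq_len(k), length(sh_case))
  fold[sh_ctrl] <- rep_len(seq_len(k), length(sh_ctrl))
  structure(fold, k = k, class = "cv_fold_assignment")
}

# Save / restore .Random.seed so seeded helpers do not clobber the caller's
# RNG stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
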