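#' Search configuration for the multiobjective DE engine
#'
#' Bundles the differential-evolution and evaluation parameters. Defaults are
#' the simulation-study settings: population 100, 300 generations,
#' F = CR = 0.5, 5-fold balanced cross-validation, pairwise (d = 2)
#' interactions, archive capacity 20% of the population.
#'
#' @param pop_size Number of target vectors in the population.
#' @param gen_size Number of generations.
#' @param F Mutation scale factor, in `[0, 2)`.
#' @param CR Crossover constant, in `[0, 1)`.
#' @param PV Probability that a mutation donor is drawn from the Pareto
#'   archive rather than the population, in `[0, 1)`. The defining equations
#'   leave its value open; 0.5 balances elite pull and population diversity.
#' @param d Interaction order (number of SNP indices per vector).
#' @param k Cross-validation fold count.
#' @param lower,upper Inclusive integer bounds of the SNP index space;
#'   `upper = NULL` is resolved to the SNP count of the dataset at run time.
#' @param seed Integer seed controlling the whole run.
#' @param capacity Archive capacity; default `ceiling(0.2 * pop_size)`.
#' @param objective `"both"` (CCR and NMI, the multiobjective method),
#'   `"ccr"` or `"nmi"` (single-measure DE-MDR comparators).
#' @param strict Use the strict dominance rule (better in every objective;
#'   the documented default). `FALSE` switches to the standard weak-Pareto
#'   rule (no worse in all, better in at least one).
#' @return A list of class `mode_config`.
#' @export
mode_config <- function(pop_size = 100L, gen_size = 300L, F = 0.5, CR = 0.5,
                        PV = 0.5, d = 2L, k = 5L, lower = 1L, upper = NULL,
                        seed = NULL, capacity = NULL,
                        objective = c("both", "ccr", "nmi"), strict = TRUE) {
  objective <- match.arg(objective)
  if (F < 0 || F >= 2) stop("F must lie in [0, 2)")
  if (CR < 0 || CR >= 1) stop("CR must lie in [0, 1)")
  if (PV < 0 || PV >= 1) stop("PV must lie in [0, 1)")
  if (pop_size < 4L) stop("pop_size must be at least 4 (three donors + target)")
  if (d < 1L) stop("d must be at least 1")
  if (is.null(capacity)) capacity <- as.integer(ceiling(0.2 * pop_size))
  structure(list(pop_size = as.integer(pop_size),
                 gen_size = as.integer(gen_size),
                 F = F, CR = CR, PV = PV, d = as.integer(d), k = as.integer(k),
                 lower = as.integer(lower),
                 upper = if (is.null(upper)) NULL else as.integer(upper),
                 seed = seed, capacity = as.integer(capacity),
                 objective = objective, strict = strict),
            class = "mode_config")
}

# Uniform integer index on {lower..upper}: the integer form of the
# initialization draw rand * (upper - lower) + lower.
rand_index <- function(n, lower, upper) {
  lower + as.integer(floor(stats::runif(n) * (upper - lower + 1L)))
}

#' Initialize the DE population
#'
#' Draws `pop_size` target vectors of `d` distinct SNP indices uniformly from
#' `{lower..upper}`; within-vector duplicates are repaired by redraw.
#' Fitness is left unevaluated.
#'
#' @param config A [mode_config()] with `upper` resolved.
#' @return Integer matrix `pop_size x d` of SNP indices.
#' @export
initialize_population <- function(config) {
  lower <- config$lower; upper <- config$upper
  if (is.null(upper)) stop("config$upper must be resolved before initialization")
  if (upper - lower + 1L < config$d)
    stop("index bounds span fewer than d distinct values")
  pop <- matrix(rand_index(config$pop_size * config$d, lower, upper),
                config$pop_size, config$d)
  for (i in seq_len(config$pop_size))
    pop[i, ] <- repair_vector(pop[i, ], lower, upper)
  pop
}

# Redraw out-of-range and duplicated components until the vector holds d
# distinct in-range indices; bounded retries, then exact sampling without
# replacement as a total fallback.
repair_vector <- function(u, lower, upper) {
  for (it in 1:100) {
    bad <- u < lower | u > upper | duplicated(u)
    if (!any(bad)) return(u)
    u[bad] <- rand_index(sum(bad), lower, upper)
  }
  sample(seq.int(lower, upper), length(u))
}

# Mutant vector arithmetic: round(x_r1 + F (x_r2 - x_r3)), componentwise.
de_combine <- function(x1, x2, x3, F) {
  as.integer(round(x1 + F * (x2 - x3)))
}

#' Differential mutation with archive-biased donors
#'
#' Builds the mutant vector `round(X_r1 + F (X_r2 - X_r3))` for target `i`.
#' The three donor indices r1, r2, r3 are distinct and different from `i`;
#' each donor is then independently replaced by a uniformly chosen archive
#' member with probability `PV` whenever the archive is nonempty.
#'
#' @param i Index of the target vector in the population.
#' @param population Integer matrix of target vectors (rows).
#' @param archive_params Integer matrix of archive member vectors (possibly
#'   zero rows).
#' @param config A [mode_config()].
#' @return Integer mutant vector of length `d` (not yet bound-feasible).
#' @export
de_mutate <- function(i, population, archive_params, config) {
  n <- nrow(population)
  if (n < 4L) stop("population must have at least 4 vectors")
  r <- sample(seq_len(n)[-i], 3L)
  donors <- population[r, , drop = FALSE]
  n_arch <- nrow(archive_params)
  if (n_arch > 0L) {
    use_arch <- stats::runif(3L) <= config$PV
    for (s in which(use_arch))
      donors[s, ] <- archive_params[sample.int(n_arch, 1L), ]
  }
  de_combine(donors[1L, ], donors[2L, ], donors[3L, ], config$F)
}

#' Binomial crossover of target and mutant
#'
#' Componentwise recombination: component j comes from the mutant when
#' `randb(j) <= CR` or when j equals the randomly chosen index `rnbr`, which
#' guarantees the trial inherits at least one mutant component.
#'
#' @param target,mutant Integer vectors of equal length `d`.
#' @param config A [mode_config()].
#' @return Integer trial vector of length `d`.
#' @export
de_recombine <- function(target, mutant, config) {
  d <- length(target)
  if (length(mutant) != d) stop("target and mutant must have equal dimension")
  take <- stats::runif(d) <= config$CR
  take[sample.int(d, 1L)] <- TRUE
  ifelse(take, mutant, target)
}

#' Boundary-constraint repair of a trial vector
#'
#' Every component outside `[lower, upper]` and every component involved in a
#' within-vector duplicate is redrawn uniformly on the index range until the
#' vector holds `d` distinct in-range indices (with an exact
#' sampling-without-replacement fallback, so the repair is total). A feasible
#' vector is returned unchanged.
#'
#' @param u Integer trial vector.
#' @param config A [mode_config()] with `upper` resolved.
#' @return A feasible integer vector of the same length.
#' @export
enforce_bounds <- function(u, config) {
  repair_vector(as.integer(u), config$lower, config$upper)
}

# Dominance on fitness rows c(ccr, nmi) under the configured objective.
# strict = TRUE: better in every objective (the documented rule); otherwise
# the weak-Pareto rule.
dominates_fit <- function(a, b, objective = "both", strict = TRUE) {
  switch(objective,
    ccr = a[1L] > b[1L],
    nmi = a[2L] > b[2L],
    both = if (strict) a[1L] > b[1L] && a[2L] > b[2L]
           else (a[1L] >= b[1L] && a[2L] >= b[2L]) &&
                (a[1L] > b[1L] || a[2L] > b[2L])
  )
}

#' Pareto dominance of fitness pairs
#'
#' Under the strict rule used by the search, `a` dominates `b` when it is
#' better in every objective (ties in any objective block dominance); the
#' relation is irreflexive.
#'
#' @param a,b Fitness pairs: lists or vectors with `ccr` and `nmi`.
#' @param objective,strict See [mode_config()].
#' @return Logical.
#' @export
dominates <- function(a, b, objective = "both", strict = TRUE) {
  fa <- c(a$ccr %||% a[[1L]], a$nmi %||% a[[2L]])
  fb <- c(b$ccr %||% b[[1L]], b$nmi %||% b[[2L]])
  dominates_fit(fa, fb, objective, strict)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Greedy DE selection
#'
#' The trial vector replaces the target only when it dominates it; otherwise
#' (including incomparable pairs and exact objective ties) the target is
#' retained.
#'
#' @param target,trial Lists with `params` and evaluated `fitness`
#'   (`c(ccr, nmi)`).
#' @param config A [mode_config()].
#' @return The surviving vector (one of the two inputs).
#' @export
de_select <- function(target, trial, config) {
  if (dominates_fit(trial$fitness, target$fitness, config$objective,
                    config$strict)) trial else target
}

# ---- Pareto archive -------------------------------------------------------

new_archive <- function(capacity, d) {
  structure(list(params = matrix(integer(), 0L, d),
                 fitness = matrix(numeric(), 0L, 2L),
                 keys = character(), capacity = as.integer(capacity)),
            class = "pareto_archive")
}

combo_key <- function(params) paste(sort.int(params), collapse = ",")

#' Update the Pareto archive with a set of candidates
#'
#' The Pareto filter: each candidate not dominated by any current member is
#' admitted (step 1), then members dominated by any other member are purged
#' (step 2). A combination already present (same unordered index set) is not
#' re-admitted. If the filtered archive exceeds its capacity, members with
#' the smallest objective-space crowding distance are dropped (extremes are
#' always kept), preserving the spread of the front deterministically.
#'
#' @param archive A `pareto_archive`.
#' @param cand_params Integer matrix of candidate vectors (rows).
#' @param cand_fitness Numeric matrix of matching `c(ccr, nmi)` rows.
#' @param config A [mode_config()].
#' @return The updated `pareto_archive`.
#' @export
update_archive <- function(archive, cand_params, cand_fitness, config) {
  obj <- config$objective
  strict <- config$strict
  P <- archive$params; Fm <- archive$fitness; keys <- archive$keys
  for (c_i in seq_len(nrow(cand_params))) {
    key <- combo_key(cand_params[c_i, ])
    if (key %in% keys) next
    f <- cand_fitness[c_i, ]
    dominated <- FALSE
    for (m in seq_len(nrow(Fm))) {
      if (dominates_fit(Fm[m, ], f, obj, strict)) { dominated <- TRUE; break }
    }
    if (!dominated) {
      P <- rbind(P, cand_params[c_i, ])
      Fm <- rbind(Fm, f)
      keys <- c(keys, key)
    }
  }
  m <- nrow(Fm)
  if (m > 1L) {
    keep <- rep(TRUE, m)
    for (a in seq_len(m)) {
      for (b in seq_len(m)) {
        if (a != b && keep[b] &&
            dominates_fit(Fm[b, ], Fm[a, ], obj, strict)) {
          keep[a] <- FALSE
          break
        }
      }
    }
    P <- P[keep, , drop = FALSE]
    Fm <- Fm[keep, , drop = FALSE]
    keys <- keys[keep]
  }
  while (nrow(Fm) > archive$capacity) {
    cd <- crowding_distance(Fm)
    drop <- order(cd, Fm[, 1L], Fm[, 2L])[1L]
    P <- P[-drop, , drop = FALSE]
    Fm <- Fm[-drop, , drop = FALSE]
    keys <- keys[-drop]
  }
  archive$params <- P
  archive$fitness <- Fm
  archive$keys <- keys
  archive
}

# NSGA-II style crowding distance over the two objectives; boundary members
# get Inf so the extremes of the front are never dropped.
crowding_distance <- function(fit) {
  m <- nrow(fit)
  cd <- numeric(m)
  for (o in 1:2) {
    v <- fit[, o]
    rng <- max(v) - min(v)
    ord <- order(v)
    if (rng > 0) {
      cd[ord[c(1L, m)]] <- Inf
      if (m > 2L)
        cd[ord[2:(m - 1L)]] <- cd[ord[2:(m - 1L)]] +
          (v[ord[3:m]] - v[ord[1:(m - 2L)]]) / rng
    }
  }
  cd
}

#' @export
print.pareto_archive <- function(x, ...) {
  cat("pareto_archive: ", nrow(x$params), " members (capacity ",
      x$capacity, ")\n", sep = "")
  if (nrow(x$params)) print(as.data.frame(x), ...)
  invisible(x)
}

#' Archive as a data frame
#'
#' @param x A `pareto_archive`.
#' @param ... Unused.
#' @return Data frame with one row per member: the SNP index columns, `ccr`
#'   and `nmi`.
#' @export
as.data.frame.pareto_archive <- function(x, ...) {
  d <- ncol(x$params)
  df <- as.data.frame(x$params)
  names(df) <- paste0("snp", seq_len(d))
  df$ccr <- x$fitness[, 1L]
  df$nmi <- x$fitness[, 2L]
  df
}

#' Run the multiobjective DE search for epistatic SNP combinations
#'
#' The full method: balanced cross-validation folds are drawn once, the
#' population of SNP-index vectors is initialized, and each generation
#' applies mutation (with archive-biased donors), binomial recombination,
#' boundary repair, MDR fitness evaluation (fold-averaged CCR and NMI) and
#' greedy dominance selection; the capacity-bounded Pareto archive is updated
#' from the population once per generation. Fitness values are cached on the
#' unordered index set, as the MDR evaluation is symmetric in the loci. The
#' whole run is a deterministic function of `config$seed`.
#'
#' @param data A [genotype_matrix()].
#' @param config A [mode_config()]; `upper = NULL` resolves to the SNP count.
#' @return The final `pareto_archive`, sorted by CCR (descending), with
#'   attributes `history` (per-generation archive size and best CCR/NMI),
#'   `folds`, `config`, `snp_names` (the member names, as a character
#'   matrix) and `n_evaluated` (distinct combinations scored).
#' @examples
#' sim <- simulate_dataset(
#'   generate_pure_epistatic_model(0.3, 0.2, seed = 7),
#'   n_cases = 100, n_controls = 100, n_snps = 20, seed = 7
#' )
#' arch <- mode_run(sim$data, mode_config(pop_size = 20, gen_size = 30,
#'                                        seed = 1))
#' as.data.frame(arch)
#' @export
mode_run <- function(data, config = mode_config()) {
  data <- validate_genotype_matrix(data)
  if (is.null(config$upper)) config$upper <- ncol(data$genotypes)
  if (config$upper - config$lower + 1L < config$d)
    stop("index bounds span fewer than d distinct values")
  if (!is.null(config$seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(config$seed)
  }
  folds <- balanced_cv_split(data, config$k)
  fast <- config$d == 2L
  ctx <- if (fast) mdr_eval_context(data, folds)
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  eval_combo <- function(params) {
    key <- combo_key(params)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    f <- if (fast) mdr_eval_pair(ctx, params[1L], params[2L])
         else {
           fp <- evaluate_combination(data, params, folds)
           c(fp$ccr, fp$nmi)
         }
    cache[[key]] <- f
    f
  }

  pop <- initialize_population(config)
  fit <- t(apply(pop, 1L, eval_combo))
  archive <- new_archive(config$capacity, config$d)
  archive <- update_archive(archive, pop, fit, config)

  hist_size <- integer(config$gen_size)
  hist_ccr <- hist_nmi <- numeric(config$gen_size)
  for (g in seq_len(config$gen_size)) {
    for (i in seq_len(config$pop_size)) {
      mutant <- de_mutate(i, pop, archive$params, config)
      trial <- de_recombine(pop[i, ], mutant, config)
      trial <- enforce_bounds(trial, config)
      tf <- eval_combo(trial)
      if (dominates_fit(tf, fit[i, ], config$objective, config$strict)) {
        pop[i, ] <- trial
        fit[i, ] <- tf
      }
    }
    archive <- update_archive(archive, pop, fit, config)
    hist_size[g] <- nrow(archive$params)
    hist_ccr[g] <- max(archive$fitness[, 1L])
    hist_nmi[g] <- max(archive$fitness[, 2L])
  }
  ord <- order(-archive$fitness[, 1L], -archive$fitness[, 2L])
  archive$params <- archive$params[ord, , drop = FALSE]
  archive$fitness <- archive$fitness[ord, , drop = FALSE]
  archive$keys <- archive$keys[ord]
  attr(archive, "history") <- data.frame(
    gen = seq_len(config$gen_size), archive_size = hist_size,
    best_ccr = hist_ccr, best_nmi = hist_nmi
  )
  attr(archive, "folds") <- folds
  attr(archive, "config") <- config
  attr(archive, "snp_names") <- matrix(data$snp_names[archive$params],
                                       nrow(archive$params), config$d)
  attr(archive, "n_evaluated") <- length(ls(cache))
  archive
}

#' Does the archive contain a given SNP combination?
#'
#' Membership is order-insensitive (a combination is an unordered index set).
#'
#' @param archive A `pareto_archive`.
#' @param combo Integer vector of SNP column indices.
#' @return Logical.
#' @export
archive_contains <- function(archive, combo) {
  combo_key(as.integer(combo)) %in% archive$keys
}
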