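test_that("mode_config validates parameter ranges", {
  cfg <- mode_config()
  expect_identical(cfg$pop_size, 100L)
  expect_identical(cfg$gen_size, 300L)
  expect_equal(cfg$F, 0.5)
  expect_equal(cfg$CR, 0.5)
  expect_identical(cfg$capacity, 20L)     # 20% of pop_size
  expect_identical(cfg$k, 5L)
  expect_error(mode_config(F = 2), "\\[0, 2\\)")
  expect_error(mode_config(CR = 1), "\\[0, 1\\)")
  expect_error(mode_config(pop_size = 3), "at least 4")
})

test_that("initialization draws distinct in-range indices, seed-stable", {
  cfg <- mode_config(pop_size = 100L, d = 2L, upper = 1000L)
  set.seed(1); pop1 <- initialize_population(cfg)
  set.seed(1); pop2 <- initialize_population(cfg)
  set.seed(2); pop3 <- initialize_population(cfg)
  expect_identical(pop1, pop2)
  expect_false(identical(pop1, pop3))
  expect_identical(dim(pop1), c(100L, 2L))
  expect_true(all(pop1 >= 1L & pop1 <= 1000L))
  expect_true(all(apply(pop1, 1L, anyDuplicated) == 0L))
  # bounds spanning exactly d values force the full permutation set
  cfg2 <- mode_config(pop_size = 10L, d = 2L, lower = 5L, upper = 6L)
  set.seed(3)
  pop <- initialize_population(cfg2)
  expect_true(all(apply(pop, 1L, sort)[1L, ] == 5L))
  expect_true(all(apply(pop, 1L, sort)[2L, ] == 6L))
  expect_error(initialize_population(mode_config(d = 3L, lower = 1L,
                                                 upper = 2L)),
               "fewer than d")
})

test_that("mutant arithmetic follows the weighted-difference rule", {
  expect_identical(modemdr:::de_combine(c(10L, 200L), c(40L, 300L),
                                        c(20L, 100L), 0.5),
                   c(20L, 300L))
  # F = 0: mutant is the first donor exactly
  expect_identical(modemdr:::de_combine(c(7L, 9L), c(1L, 2L), c(3L, 4L), 0),
                   c(7L, 9L))
})

test_that("mutation donors come from the population when the archive is empty
           and from the archive at rate PV otherwise", {
  pop <- matrix(rep(c(1L, 2L), each = 8L), 8L, 2L)
  pop <- pop + 10L * (seq_len(8L) - 1L)      # distinct rows
  empty <- matrix(integer(), 0L, 2L)
  cfg <- mode_config(pop_size = 8L, upper = 100L, F = 0, PV = 0.9)
  set.seed(5)
  for (r in 1:20) {
    v <- de_mutate(1L, pop, empty, cfg)
    # with F = 0 the mutant equals donor r1, necessarily a population row != 1
    expect_true(any(apply(pop[-1L, , drop = FALSE], 1L, identical, v)))
  }
  # archive present: with F = 0, P(mutant is the archive row) = PV
  arch <- matrix(c(999L, 998L), 1L)
  cfg$PV <- 0.5
  set.seed(6)
  hits <- mean(replicate(2000, identical(de_mutate(1L, pop, arch, cfg),
                                         c(999L, 998L))))
  expect_gt(hits, 0.45); expect_lt(hits, 0.55)
})

test_that("recombination inherits rnbr-forced and CR-gated components", {
  cfg0 <- mode_config(CR = 0)
  target <- c(1L, 2L); mutant <- c(100L, 200L)
  set.seed(7)
  for (r in 1:30) {
    u <- de_recombine(target, mutant, cfg0)
    expect_identical(sum(u %in% c(100L, 200L)), 1L)  # exactly the rnbr one
  }
  cfg9 <- mode_config(CR = 0.999)
  u <- de_recombine(target, mutant, cfg9)
  expect_identical(u, mutant)
  # expected mutant-inherited components at CR = 0.5, d = 2: one forced,
  # the other with probability 0.5 -> expectation 1.5
  cfg5 <- mode_config(CR = 0.5)
  set.seed(8)
  inherited <- replicate(10000, sum(de_recombine(target, mutant, cfg5)
                                    %in% mutant))
  expect_gt(mean(inherited), 1.4); expect_lt(mean(inherited), 1.6)
})

test_that("boundary repair redraws bad components and keeps feasible ones", {
  cfg <- mode_config(upper = 999L)
  set.seed(9)
  u <- enforce_bounds(c(-5L, 3L), cfg)
  expect_identical(u[2L], 3L)
  expect_true(u[1L] >= 1L && u[1L] <= 999L && u[1L] != 3L)
  # within-vector duplicate: exactly one component redrawn
  u2 <- enforce_bounds(c(7L, 7L), cfg)
  expect_identical(u2[1L], 7L)
  expect_true(u2[2L] != 7L)
  # feasible input returned unchanged
  expect_identical(enforce_bounds(c(4L, 2L), cfg), c(4L, 2L))
})

test_that("strict dominance is strict in every objective and irreflexive", {
  a <- list(ccr = 0.8, nmi = 0.4)
  b <- list(ccr = 0.7, nmi = 0.3)
  tie <- list(ccr = 0.8, nmi = 0.3)
  expect_true(dominates(a, b))
  expect_false(dominates(b, a))
  expect_false(dominates(tie, b))          # tie in one objective blocks
  expect_false(dominates(a, a))            # irreflexive
  # weak rule admits the single-objective improvement
  expect_true(dominates(tie, b, strict = FALSE))
  expect_false(dominates(a, a, strict = FALSE))
  # single-objective degenerations
  expect_true(dominates(tie, b, objective = "ccr"))
  expect_false(dominates(tie, b, objective = "nmi"))
})

test_that("selection keeps the target unless the trial dominates", {
  cfg <- mode_config()
  target <- list(params = c(1L, 2L), fitness = c(0.6, 0.2))
  better <- list(params = c(3L, 4L), fitness = c(0.7, 0.3))
  incomp <- list(params = c(5L, 6L), fitness = c(0.7, 0.1))
  equal <- list(params = c(7L, 8L), fitness = c(0.6, 0.2))
  expect_identical(de_select(target, better, cfg), better)
  expect_identical(de_select(target, incomp, cfg), target)
  expect_identical(de_select(target, equal, cfg), target)
})

test_that("archive update admits, purges and respects capacity", {
  cfg <- mode_config(pop_size = 10L)
  arch <- modemdr:::new_archive(5L, 2L)
  arch <- update_archive(arch, matrix(c(1L, 2L), 1L),
                         matrix(c(0.6, 0.6), 1L), cfg)
  expect_identical(nrow(arch$params), 1L)
  # dominated newcomer rejected; dominating newcomer purges the member
  arch <- update_archive(arch, matrix(c(3L, 4L), 1L),
                         matrix(c(0.5, 0.5), 1L), cfg)
  expect_identical(arch$keys, "1,2")
  arch <- update_archive(arch, matrix(c(5L, 6L), 1L),
                         matrix(c(0.7, 0.7), 1L), cfg)
  expect_identical(arch$keys, "5,6")
  # incomparable pair coexists
  arch <- update_archive(arch, matrix(c(7L, 8L), 1L),
                         matrix(c(0.2, 0.9), 1L), cfg)
  expect_identical(nrow(arch$params), 2L)
  # same combination is not re-admitted
  arch <- update_archive(arch, matrix(c(8L, 7L), 1L),
                         matrix(c(0.2, 0.9), 1L), cfg)
  expect_identical(nrow(arch$params), 2L)
  # capacity: 8 mutually nondominated members into capacity 5; the extremes
  # of the front must survive the crowding-distance drop
  front <- cbind(seq(0.1, 0.8, by = 0.1), seq(0.8, 0.1, by = -0.1))
  params <- cbind(11:18, 21:28)
  arch2 <- modemdr:::new_archive(5L, 2L)
  arch2 <- update_archive(arch2, params, front, cfg)
  expect_identical(nrow(arch2$params), 5L)
  expect_true("11,21" %in% arch2$keys)     # max nmi extreme
  expect_true("18,28" %in% arch2$keys)     # max ccr extreme
  # members are mutually nondominated
  for (i in seq_len(nrow(arch2$fitness)))
    for (j in seq_len(nrow(arch2$fitness)))
      if (i != j)
        expect_false(modemdr:::dominates_fit(arch2$fitness[i, ],
                                             arch2$fitness[j, ], "both", TRUE))
})

test_that("the search finds a planted perfect pair and is deterministic", {
  gm <- planted_pair_data(n_per_class = 50L, n_snps = 20L, pair = c(3L, 11L))
  cfg <- mode_config(pop_size = 50L, gen_size = 50L, seed = 123L)
  arch <- mode_run(gm, cfg)
  expect_true(archive_contains(arch, c(3L, 11L)))
  expect_true(archive_contains(arch, c(11L, 3L)))   # order-insensitive
  expect_equal(max(arch$fitness[, 1L]), 1.0)
  # the planted pair is Pareto-optimal per the exhaustive oracle
  front <- exhaustive_pareto(gm, 2L, attr(arch, "folds"))
  expect_true("3,11" %in% front$keys)
  # determinism
  arch2 <- mode_run(gm, cfg)
  expect_identical(arch$params, arch2$params)
  expect_identical(arch$fitness, arch2$fitness)
  # elitism: archive maxima never decrease across generations
  h <- attr(arch, "history")
  expect_true(all(diff(h$best_ccr) >= 0))
  expect_true(all(diff(h$best_nmi) >= 0))
  expect_true(all(h$archive_size <= cfg$capacity))
  # every reported member satisfies the distinct in-range contract
  expect_true(all(arch$params >= 1L & arch$params <= 20L))
  expect_true(all(apply(arch$params, 1L, anyDuplicated) == 0L))
})

test_that("gen_size = 0 reduces to the Pareto filter of the initial population", {
  gm <- planted_pair_data(n_per_class = 30L, n_snps = 10L, pair = c(2L, 9L))
  cfg <- mode_config(pop_size = 20L, gen_size = 0L, seed = 5L)
  arch <- mode_run(gm, cfg)
  expect_s3_class(arch, "pareto_archive")
  expect_gt(nrow(arch$params), 0L)
  # archive members are mutually nondominated draws from the initial pop
  fits <- arch$fitness
  for (i in seq_len(nrow(fits)))
    for (j in seq_len(nrow(fits)))
      if (i != j)
        expect_false(modemdr:::dominates_fit(fits[i, ], fits[j, ],
                                             "both", TRUE))
})

test_that("archive-donor frequency approaches PV once the archive fills", {
  pop <- cbind(seq(2L, 40L, by = 2L), seq(3L, 41L, by = 2L))
  arch_params <- cbind(c(100L, 110L, 120L), c(101L, 111L, 121L))
  cfg <- mode_config(pop_size = 20L, upper = 200L, F = 0, PV = 0.3)
  set.seed(10)
  from_arch <- replicate(3000, de_mutate(2L, pop, arch_params, cfg)[1L] >= 100L)
  expect_gt(mean(from_arch), 0.26); expect_lt(mean(from_arch), 0.34)
})
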