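test_that("initial population draws unique segment ids uniformly", {
  ga <- ga_config()
  set.seed(1)
  pop <- init_population(ga, 254)
  expect_length(pop, 20)
  for (ch in pop) expect_true(sersga:::check_chromosome(ch, 6, 254))

  set.seed(1)
  expect_identical(init_population(ga, 254), pop)

  full <- init_population(ga_config(k_segments = 10), 10)
  expect_true(all(vapply(full, identical, logical(1), y = 1:10)))

  expect_error(init_population(ga_config(k_segments = 7), 6), "exceeds")
})

test_that("elitist copy duplicates the best over the worst", {
  ga4 <- ga_config(population_size = 4, copy_fraction = 0.5)
  pop <- list(c(1L, 2L), c(3L, 4L), c(5L, 6L), c(7L, 8L))
  pool <- select_copy(pop, c(0.9, 0.8, 0.2, 0.1), ga4)
  # the two best overwrite the two worst
  expect_identical(pool, list(c(1L, 2L), c(3L, 4L), c(1L, 2L), c(3L, 4L)))

  # quartile copy at the default fraction: the 5 best land on the 5 worst
  ga20 <- ga_config()
  set.seed(10)
  pop20 <- replicate(20, sort(sample(254, 6)), simplify = FALSE)
  fit20 <- seq(0.5, 0.975, by = 0.025)  # ascending: worst are 1..5, best 16..20
  pool20 <- select_copy(pop20, fit20, ga20)
  expect_identical(pool20[1:5], pop20[16:20])
  expect_identical(pool20[6:20], pop20[6:20])

  # equal fitness: tie rule keeps the pool a copy of the population
  # (best and worst coincide under canonical ordering of identical members)
  same <- replicate(4, c(2L, 9L), simplify = FALSE)
  expect_identical(select_copy(same, rep(0.7, 4), ga4), same)
})

test_that("single-point crossover swaps tails and repairs duplicates", {
  a <- 1:6; b <- 7:12
  kids <- crossover(a, b, n_seg = 254, cut = 3)
  expect_identical(kids[[1]], c(1L, 2L, 3L, 10L, 11L, 12L))
  expect_identical(kids[[2]], c(4L, 5L, 6L, 7L, 8L, 9L))

  set.seed(2)
  same <- crossover(a, a, n_seg = 254)
  expect_identical(same[[1]], a)
  expect_identical(same[[2]], a)

  # property: children always valid whatever the overlap
  set.seed(3)
  for (r in 1:100) {
    pa <- sort(sample(40, 6)); pb <- sort(sample(40, 6))
    kids <- crossover(pa, pb, n_seg = 40)
    expect_true(sersga:::check_chromosome(kids[[1]], 6, 40))
    expect_true(sersga:::check_chromosome(kids[[2]], 6, 40))
  }
})

test_that("mutation flips at most one site to an unused id", {
  ch <- sort(sample(254, 6))
  expect_identical(mutate(ch, ga_config(mutation_prob = 0), 254), ch)

  full <- 1:6
  set.seed(4)
  expect_identical(mutate(full, ga_config(mutation_prob = 1, k_segments = 6), 6), full)

  set.seed(5)
  ga1 <- ga_config(mutation_prob = 1)
  for (r in 1:100) {
    out <- mutate(1:6, ga1, 254)
    expect_true(sersga:::check_chromosome(out, 6, 254))
    expect_length(setdiff(out, 1:6), 1)
    expect_length(setdiff(1:6, out), 1)
  }
})

test_that("fitness is LOOCV accuracy, memoized without changing values", {
  pp <- tiny_preprocessed(seed = 21)
  idx <- build_segment_index(200, 5, grid = pp$grid)
  fit <- make_fitness(pp, idx)

  planted <- planted_truth(tiny_config(seed = 21), idx)
  f1 <- fit(planted)
  f2 <- fit(planted)                                    # cached path
  f3 <- make_fitness(pp, idx)(planted)                  # fresh cache
  expect_identical(f1, f2)
  expect_identical(f1, f3)
  # the planted segments alone separate the classes well above chance
  expect_gte(f1, 0.75)

  # fitness equals the accuracy of loocv on the expanded variables
  cv <- loocv(pp, variables = expand_chromosome(planted, idx))
  expect_equal(f1, mean(cv$predicted == cv$label))
})

test_that("label-permuted fitness sits near the majority-class rate", {
  pp <- tiny_preprocessed(seed = 22, n_normal = 20, n_cancer = 20)
  idx <- build_segment_index(200, 5, grid = pp$grid)
  set.seed(99)
  accs <- replicate(50, {
    perm <- sersga::spectra_set(pp$grid, pp$spectra,
                                labels = sample(as.character(pp$labels)),
                                ids = pp$ids)
    make_fitness(perm, idx)(sort(sample(40, 6)))
  })
  # LOOCV under the null is centred at (or slightly below) the 0.5 base rate
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("a GA run keeps a non-decreasing best-fitness history", {
  pp <- tiny_preprocessed(seed = 23)
  idx <- build_segment_index(200, 5, grid = pp$grid)
  ga <- ga_config(generations = 15, population_size = 10, seed = 7)

  res <- run_ga(pp, ga, idx)
  expect_true(all(diff(res$history$best) >= 0))
  expect_equal(max(res$history$best), res$history$best[nrow(res$history)])
  expect_equal(res$best_fitness, max(res$history$best))
  expect_true(sersga:::check_chromosome(res$best_chromosome, 6, 40))
  expect_equal(nrow(res$history), 16)

  # zero generations: the best of the initial population
  res0 <- run_ga(pp, ga_config(generations = 0, population_size = 10, seed = 7), idx)
  fitf <- make_fitness(pp, idx)
  set.seed(7)
  pop <- init_population(ga_config(generations = 0, population_size = 10, seed = 7), 40)
  expect_equal(res0$best_fitness, max(vapply(pop, fitf, numeric(1))))
  expect_equal(nrow(res0$history), 1)

  # determinism: same seed, same result
  res2 <- run_ga(pp, ga, idx)
  expect_identical(res2$best_chromosome, res$best_chromosome)
  expect_identical(res2$history, res$history)
})

test_that("consensus counts sum to runs times chromosome size", {
  pp <- tiny_preprocessed(seed = 24)
  idx <- build_segment_index(200, 5, grid = pp$grid)
  ga <- ga_config(generations = 10, population_size = 10, n_runs = 1, seed = 11)

  one <- consensus_counts(pp, ga, idx)
  expect_equal(sum(one$counts), 6)
  expect_true(all(one$counts %in% 0:1))

  three <- consensus_counts(pp, ga, idx, n_runs = 3)
  expect_equal(sum(three$counts), 18)
  expect_equal(nrow(three$runs), 3)
})

test_that("permuted labels never out-count the planted signal", {
  # strong planted effects so the planted-label consensus concentrates
  pp <- tiny_preprocessed(seed = 25, n_normal = 14, n_cancer = 14,
                          effect = 0.5, noise_sd = 0.01)
  idx <- build_segment_index(200, 5, grid = pp$grid)
  ga <- ga_config(generations = 12, population_size = 10, n_runs = 5, seed = 31)

  planted <- consensus_counts(pp, ga, idx)
  set.seed(26)
  null_set <- spectra_set(pp$grid, pp$spectra,
                          labels = sample(as.character(pp$labels)), ids = pp$ids)
  permuted <- consensus_counts(null_set, ga, idx)
  expect_lte(max(permuted$counts), max(planted$counts))
})

test_that("top bands rank by count, merge adjacency, and break ties low", {
  idx <- build_segment_index(250, 5)
  cnt <- integer(50)
  cnt[c(10, 11, 40)] <- c(9, 7, 5)
  bands <- top_bands(cnt, idx, k = 2)
  expect_equal(bands$seg_lo, c(10, 40))
  expect_equal(bands$seg_hi, c(11, 40))
  expect_equal(bands$count, c(16, 5))

  cnt6 <- integer(50); cnt6[c(3, 9, 15, 21, 33, 47)] <- 4
  b6 <- top_bands(cnt6, idx, k = 6)
  expect_equal(nrow(b6), 6)
  expect_equal(b6$seg_lo, b6$seg_hi)

  # all counts equal: the tie rule (lowest ids first) makes the result
  # deterministic — the first segment alone forms the single requested band
  flat <- rep(2L, 50)
  bf <- top_bands(flat, idx, k = 1)
  expect_equal(bf$seg_lo, 1)
  expect_equal(bf$seg_hi, 1)
  expect_identical(top_bands(flat, idx, k = 1), bf)

  expect_error(top_bands(integer(50), idx, k = 1), "nonzero")
  expect_error(top_bands(cnt, idx, k = 4), "band")
})
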