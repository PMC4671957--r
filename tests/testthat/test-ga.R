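test_that("mutation schedule interpolates linearly between its endpoints", {
  cfg <- ga_config(generations = 100)
  expect_equal(mutation_rate(cfg, 1), 0.2)
  expect_equal(mutation_rate(cfg, 100), 0.01)
  expect_equal(mutation_rate(cfg, 50), 0.2 + (49 / 99) * (0.01 - 0.2))
  one <- ga_config(generations = 1)
  expect_equal(mutation_rate(one, 1), 0.2)
})

test_that("population seeding places components on feature points", {
  ctx <- cheap_ga_ctx(n = 3)
  pts <- point_set(rbind(c(0, 0, 0), c(12, 0, 0), c(0, 15, 0)))
  cfg <- ga_config(population_size = 160, quaternion_count = ctx$quats$size,
                   seed = 5)
  set.seed(5)
  pop <- seed_population(ctx, pts, cfg)
  expect_length(pop, 160)
  on_point <- vapply(pop, function(g) {
    pos <- sweep(g$trans, 2, ctx$map_center, "+")
    all(apply(pos, 1, function(p) {
      any(apply(pts$points, 1, function(q) isTRUE(all.equal(unname(p), unname(q)))))
    }))
  }, logical(1))
  expect_equal(sum(on_point), 80)       # undisplaced half sits exactly on points
  expect_true(all(which(on_point) == 1:80))
  # displaced half stays within twice the minimum pairwise distance
  dmax <- 2 * min_pairwise_distance(pts)
  for (g in pop[81:160]) {
    pos <- sweep(g$trans, 2, ctx$map_center, "+")
    d <- apply(pos, 1, function(p) min(sqrt(colSums((t(pts$points) - p)^2))))
    expect_true(all(d <= dmax + 1e-9))
  }
  rot <- unlist(lapply(pop, `[[`, "rot"))
  expect_true(all(rot >= 1 & rot <= ctx$quats$size))
  # seed-reproducible
  set.seed(5)
  pop2 <- seed_population(ctx, pts, cfg)
  expect_identical(lapply(pop, `[`, c("trans", "rot")),
                   lapply(pop2, `[`, c("trans", "rot")))

  single <- point_set(matrix(c(1, 1, 1), 1))
  expect_error(seed_population(ctx, single, cfg), "two points")
  expect_silent({
    p1 <- seed_population(ctx, single, cfg, min_dist = 10)
  })
  expect_length(p1, 160)
})

test_that("tournament selection picks the fitter genotype", {
  ctx <- cheap_ga_ctx(n = 2,
                      fitness_fun = function(g, ctx) {
                        fitness_breakdown(g$trans[1, 1], 0, ctx$n)
                      })
  mk <- function(f) {
    gafem:::evaluate_genotype(
      gafem:::new_genotype(matrix(f, 2, 3), c(1L, 1L)), ctx)
  }
  pop <- list(mk(5), mk(3))
  for (i in 1:20) {
    expect_equal(tournament_select(pop, 2)$trans[1, 1], 5)
  }
})

test_that("tournament-selection rank frequencies match the combinatorial law", {
  N <- 160
  ctx <- cheap_ga_ctx(n = 1,
                      fitness_fun = function(g, ctx) {
                        fitness_breakdown(g$trans[1, 1], 0, 1)
                      })
  pop <- lapply(seq_len(N), function(r) {       # rank r-1, fitness N - r
    gafem:::evaluate_genotype(
      gafem:::new_genotype(matrix(N - r, 1, 3), 1L), ctx)
  })
  set.seed(77)
  wins <- integer(N)
  n_tour <- 10000
  for (i in seq_len(n_tour)) {
    w <- tournament_select(pop, 2)
    r <- N - w$trans[1, 1]                      # 1-based rank
    wins[r] <- wins[r] + 1
  }
  # P(rank r, 0-based) = 2 (N - 1 - r) / (N (N - 1)); bin ranks so expected
  # counts stay large enough for a chi-squared goodness-of-fit test
  p_rank <- 2 * (N - seq_len(N)) / (N * (N - 1))
  bins <- rep(1:16, each = 10)
  obs <- tapply(wins, bins, sum)
  expp <- tapply(p_rank * n_tour, bins, sum)
  chi2 <- sum((obs - expp)^2 / expp)
  expect_gt(stats::pchisq(chi2, df = 15, lower.tail = FALSE), 0.001)
  # monotone: better ranks win more often (coarse deciles)
  expect_true(all(diff(as.numeric(obs)) < 0))
})

test_that("crossover respects its probability limits", {
  ctx <- cheap_ga_ctx(n = 3, fitness_fun = function(g, ctx) {
    fitness_breakdown(sum(g$trans), 0, ctx$n)
  })
  g1 <- gafem:::evaluate_genotype(
    gafem:::new_genotype(matrix(10, 3, 3), c(1L, 2L, 3L)), ctx)
  g2 <- gafem:::evaluate_genotype(
    gafem:::new_genotype(matrix(-10, 3, 3), c(4L, 5L, 6L)), ctx)

  cfg0 <- ga_config(crossover_prob = 0, mutation_initial = 0,
                    mutation_final = 0)
  ch <- crossover_child(g1, g2, cfg0, 1, ctx)
  expect_identical(ch$trans, g1$trans)          # copy of the fitter parent
  expect_identical(ch$rot, g1$rot)

  cfg1 <- ga_config(crossover_prob = 1, mutation_initial = 0,
                    mutation_final = 0)
  ch <- crossover_child(g1, g2, cfg1, 1, ctx)
  expect_identical(ch$trans, g2$trans)          # every gene exchanged
  expect_identical(ch$rot, g2$rot)

  expect_error(crossover_child(g1, gafem:::evaluate_genotype(
    gafem:::new_genotype(matrix(0, 2, 3), c(1L, 2L)), cheap_ga_ctx(2)),
    cfg1, 1, ctx), "gene counts")
})

test_that("gene mutations stay within their ranges", {
  ctx <- cheap_ga_ctx(n = 2)
  set.seed(3)
  for (i in 1:200) {
    v <- gafem:::mutate_translation(c(0, 0, 0), 7)
    expect_lte(sqrt(sum(v^2)), 7)
  }
  # rotation replacement is uniform over the library
  quats <- generate_quaternion_set(50, seed = 1)
  set.seed(8)
  draws <- replicate(10000, gafem:::mutate_rotation(quats))
  expect_true(all(draws >= 1 & draws <= 50))
  chi2 <- sum((tabulate(draws, 50) - 200)^2 / 200)
  expect_gt(stats::pchisq(chi2, df = 49, lower.tail = FALSE), 0.001)
})

test_that("diversity operator swaps a component pair and preserves the gene multiset", {
  ctx <- cheap_ga_ctx(n = 4, fitness_fun = function(g, ctx) {
    fitness_breakdown(0, 0, ctx$n)
  })
  g <- gafem:::evaluate_genotype(
    gafem:::new_genotype(matrix(seq_len(12), 4, 3), c(1L, 2L, 3L, 4L)), ctx)
  cfg <- ga_config(diversity_mutation_rate = 0)
  set.seed(21)
  ch <- diversity_child(g, cfg, ctx)
  key <- function(x) {
    sort(apply(cbind(x$trans, x$rot), 1, paste, collapse = ","))
  }
  expect_identical(key(ch), key(g))             # a permutation of gene pairs
  expect_false(identical(ch$trans, g$trans))    # but not the identity

  # n = 2: the only possible swap is deterministic
  ctx2 <- cheap_ga_ctx(n = 2, fitness_fun = function(g, ctx) {
    fitness_breakdown(0, 0, 2)
  })
  g2 <- gafem:::evaluate_genotype(
    gafem:::new_genotype(matrix(1:6, 2, 3), c(7L, 9L)), ctx2)
  ch2 <- diversity_child(g2, cfg, ctx2)
  expect_identical(ch2$trans, g2$trans[2:1, ])
  expect_identical(ch2$rot, g2$rot[2:1])
})

test_that("a generation builds 90/10 child mix and keeps the elitist top half", {
  ctx <- cheap_ga_ctx(n = 2, fitness_fun = function(g, ctx) {
    fitness_breakdown(sum(g$trans), 0, ctx$n)
  })
  cfg <- ga_config(population_size = 160, quaternion_count = ctx$quats$size)
  set.seed(10)
  pop <- lapply(1:160, function(i) random_genotype(ctx))
  ch <- gafem:::make_children(pop, cfg, 1, ctx)
  expect_length(ch$crossover, 144)
  expect_length(ch$diversity, 16)

  nxt <- next_generation(pop, cfg, 1, ctx)
  expect_length(nxt, 160)
  best0 <- max(vapply(pop, gafem:::genotype_fitness, numeric(1)))
  best1 <- max(vapply(nxt, gafem:::genotype_fitness, numeric(1)))
  expect_gte(best1, best0)
})

test_that("with crossover and mutation off, survivors are copies of parents", {
  ctx <- cheap_ga_ctx(n = 2, fitness_fun = function(g, ctx) {
    fitness_breakdown(sum(g$trans), 0, ctx$n)
  })
  cfg <- ga_config(population_size = 20, crossover_prob = 0,
                   mutation_initial = 0, mutation_final = 0,
                   diversity_fraction = 0, quaternion_count = ctx$quats$size)
  set.seed(31)
  pop <- lapply(1:20, function(i) random_genotype(ctx))
  nxt <- next_generation(pop, cfg, 1, ctx)
  keys <- vapply(pop, function(g) paste(c(g$trans, g$rot), collapse = ","),
                 character(1))
  for (g in nxt) {
    expect_true(paste(c(g$trans, g$rot), collapse = ",") %in% keys)
  }
  # no new gene values can appear, and the incumbent best survives exactly
  expect_equal(max(vapply(nxt, gafem:::genotype_fitness, numeric(1))),
               max(vapply(pop, gafem:::genotype_fitness, numeric(1))))
})

test_that("a GA run produces a monotone elitist trace of the configured length", {
  cfg <- ga_config(population_size = 14, generations = 8, n_runs = 1,
                   quaternion_count = 200, seed = 2)
  quats <- generate_quaternion_set(cfg$quaternion_count, seed = cfg$seed)
  ctx <- ga_context(fx3$map, fx3$components, quats)
  res <- run_ga(ctx, fx3$centroids, cfg, run_seed = 123)
  expect_equal(nrow(res$trace), 8)
  expect_true(all(diff(res$trace$best) >= 0))
  expect_equal(res$trace$best[8], gafem:::genotype_fitness(res$best))
  # selection pressure: the population improves on average
  expect_gte(res$trace$mean[8], res$trace$mean[1])
})

test_that("ensembles are seed-reproducible and ranked by fitness", {
  cfg <- ga_config(population_size = 10, generations = 3, n_runs = 3,
                   quaternion_count = 100, seed = 6)
  e1 <- run_ensemble(fx3$map, fx3$components, fx3$centroids, cfg,
                     reference = fx3$components)
  e2 <- run_ensemble(fx3$map, fx3$components, fx3$centroids, cfg,
                     reference = fx3$components)
  f1 <- vapply(e1$results, function(r) r$fit$f, numeric(1))
  f2 <- vapply(e2$results, function(r) r$fit$f, numeric(1))
  expect_identical(f1, f2)
  expect_true(all(diff(f1) <= 0))               # non-increasing fitness
  expect_equal(vapply(e1$results, `[[`, integer(1), "rank"), 1:3)
  for (i in 1:3) {
    expect_identical(
      component_coords(e1$results[[i]]$model[[1]]),
      component_coords(e2$results[[i]]$model[[1]]))
  }
  # BP definition: reference equal to one run's model puts BP at that rank
  ref <- e1$results[[2]]$model
  e3 <- run_ensemble(fx3$map, fx3$components, fx3$centroids, cfg,
                     reference = ref)
  expect_equal(e3$bp_rank, 2L)
})
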