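# Shared fixtures and independent oracles used across test files.

# one small 3-component assembly at 10 A resolution, reused by several suites
fx3 <- make_assembly(fixture_spec(seed = 42))

random_map <- function(dims = c(6, 6, 6), voxel = 2, seed = 1,
                       resolution = 10) {
  set.seed(seed)
  density_map(array(runif(prod(dims)), dims), voxel, resolution = resolution)
}

# brute-force mutual information: explicit 20x20 joint table and double loop
mi_bruteforce <- function(probe, target, bins = 20) {
  binv <- function(v) {
    mn <- min(v); mx <- max(v)
    if (mx <= mn) return(rep(1L, length(v)))
    pmin(bins, floor((v - mn) / (mx - mn) * bins) + 1L)
  }
  x <- binv(as.numeric(probe$grid))
  y <- binv(as.numeric(target$grid))
  tab <- matrix(0, bins, bins)
  for (i in seq_along(x)) tab[x[i], y[i]] <- tab[x[i], y[i]] + 1
  p <- tab / length(x)
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (a in seq_len(bins)) {
    for (b in seq_len(bins)) {
      if (p[a, b] > 0) mi <- mi + p[a, b] * log(p[a, b] / (px[a] * py[b]))
    }
  }
  mi
}

# brute-force Hausdorff distance: exhaustive double loop over all pairs
hausdorff_bruteforce <- function(A, B) {
  h <- function(P, Q) {
    worst <- 0
    for (i in seq_len(nrow(P))) {
      best <- Inf
      for (j in seq_len(nrow(Q))) {
        d <- sqrt(sum((P[i, ] - Q[j, ])^2))
        if (d < best) best <- d
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(h(A, B), h(B, A))
}

# lightweight GA context with an injectable fitness, for operator-level tests
cheap_ga_ctx <- function(n = 3, fitness_fun = NULL, quat_n = 100) {
  target <- random_map(c(6, 6, 6), voxel = 3.5, seed = 11)
  comps <- lapply(seq_len(n), function(i) {
    make_component(6, seed = i, id = LETTERS[i])
  })
  ctx <- ga_context(target, comps, generate_quaternion_set(quat_n, seed = 9))
  ctx$min_dist <- 5
  if (!is.null(fitness_fun)) ctx$fitness_fun <- fitness_fun
  ctx
}

random_genotype <- function(ctx, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- gafem:::new_genotype(matrix(runif(3 * ctx$n, -20, 20), ctx$n, 3),
                            sample.int(ctx$quats$size, ctx$n, replace = TRUE))
  gafem:::evaluate_genotype(g, ctx)
}
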