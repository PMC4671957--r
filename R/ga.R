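# Genetic-algorithm sampler: seeding from feature points, crossover /
# mutation / diversity operators, elitist merge selection, multi-run
# ensembles and convergence traces.

#' Genetic-algorithm configuration
#'
#' Defaults are the settings used throughout the benchmark of the method:
#' population of 160 evolved for 100 generations; per-gene crossover at
#' probability 0.8 with the mutation rate decaying linearly from 0.2 to 0.01
#' across generations; 90% crossover / 10% diversity children; tournament
#' selection of size 2; 20 independent runs; 5000 library rotations.
#'
#' @param population_size genotypes per generation.
#' @param generations number of generations per run.
#' @param crossover_prob per-gene probability of exchanging a gene with the
#'   second parent.
#' @param mutation_initial,mutation_final linear mutation-rate schedule
#'   endpoints (first and last generation).
#' @param diversity_fraction fraction of children built by the diversity
#'   operator.
#' @param diversity_mutation_rate constant per-gene mutation rate of
#'   diversity children.
#' @param tournament_size genotypes drawn per tournament.
#' @param n_runs independent GA runs in an ensemble.
#' @param quaternion_count size of the rotation library.
#' @param seed master seed; every source of randomness derives from it.
#' @export
ga_config <- function(population_size = 160, generations = 100,
                      crossover_prob = 0.8, mutation_initial = 0.2,
                      mutation_final = 0.01, diversity_fraction = 0.10,
                      diversity_mutation_rate = 0.10, tournament_size = 2,
                      n_runs = 20, quaternion_count = 5000, seed = 1) {
  stopifnot(population_size >= 1, generations >= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_initial >= mutation_final, mutation_final >= 0,
            mutation_initial <= 1,
            diversity_fraction >= 0, diversity_fraction <= 1,
            diversity_mutation_rate >= 0, diversity_mutation_rate <= 1,
            tournament_size >= 1, n_runs >= 1, quaternion_count >= 1)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_initial = mutation_initial,
                 mutation_final = mutation_final,
                 diversity_fraction = diversity_fraction,
                 diversity_mutation_rate = diversity_mutation_rate,
                 tournament_size = as.integer(tournament_size),
                 n_runs = as.integer(n_runs),
                 quaternion_count = as.integer(quaternion_count),
                 seed = as.integer(seed)),
            class = "GAConfig")
}

#' Mutation rate at a given generation (linear schedule)
#'
#' Interpolates linearly from `mutation_initial` at generation 1 to
#' `mutation_final` at the last generation.
#'
#' @param cfg a [ga_config()].
#' @param generation generation number in `1:cfg$generations`.
#' @export
mutation_rate <- function(cfg, generation) {
  if (cfg$generations == 1) return(cfg$mutation_initial)
  cfg$mutation_initial + (generation - 1) / (cfg$generations - 1) *
    (cfg$mutation_final - cfg$mutation_initial)
}

# ---- evaluation context ----------------------------------------------------

#' Build the evaluation context shared by all GA operations
#'
#' Precomputes centroid-centred coordinate sets for every component so that
#' decoding a genotype reduces to one rotation and one translation per
#' component. A genotype's gene `i` places component `i`'s centroid at
#' `map_center(target) + translation_i`, rotated by library quaternion
#' `rotation_index_i` about the centroid.
#'
#' @param target a `DensityMap` with nominal resolution set.
#' @param components list of `Component`s.
#' @param quats a `QuaternionSet` (built from the config if omitted).
#' @param bins mutual-information bins.
#' @param sigma_factor probe-simulation sigma factor.
#' @param clash_voxel clash-penalty voxel edge (Angstroms).
#' @return an environment-free list used by [run_ga()] and the operators.
#' @export
ga_context <- function(target, components, quats, bins = 20,
                       sigma_factor = 0.356, clash_voxel = 3.5) {
  if (inherits(components, "Component")) components <- list(components)
  if (length(components) < 1) stop("need at least one component")
  if (is.na(target$resolution)) stop("target map must carry a resolution")
  centered_atoms <- lapply(components, function(cm) {
    sweep(component_coords(cm), 2, cm$com)
  })
  centered_bb <- lapply(components, function(cm) {
    sweep(backbone_cb_coords(cm), 2, cm$com)
  })
  list(target = target, components = components, quats = quats,
       centered_atoms = centered_atoms, centered_bb = centered_bb,
       map_center = map_center(target),
       sigma = sigma_factor * target$resolution,
       sigma_factor = sigma_factor, bins = bins, clash_voxel = clash_voxel,
       n = length(components), fitness_fun = NULL)
}

new_genotype <- function(trans, rot) {
  structure(list(trans = trans, rot = as.integer(rot), fit = NULL),
            class = "Genotype")
}

#' Decode a genotype into placed components
#'
#' @param g a `Genotype`.
#' @param ctx a [ga_context()].
#' @return list of placed `Component`s (the assembly model).
#' @export
decode_genotype <- function(g, ctx) {
  lapply(seq_len(ctx$n), function(i) {
    q <- ctx$quats$quaternions[g$rot[i], ]
    pos <- ctx$map_center + g$trans[i, ]
    apply_transform(ctx$components[[i]],
                    rigid_transform(q, pos - ctx$components[[i]]$com))
  })
}

# fast fitness evaluation on raw coordinates (no Component rebuilding)
evaluate_genotype <- function(g, ctx) {
  if (!is.null(g$fit)) return(g)
  if (!is.null(ctx$fitness_fun)) {
    g$fit <- ctx$fitness_fun(g, ctx)
    return(g)
  }
  n <- ctx$n
  bb_list <- vector("list", n)
  atoms <- vector("list", n)
  for (i in seq_len(n)) {
    R <- quat_rotation_matrix(ctx$quats$quaternions[g$rot[i], ])
    pos <- ctx$map_center + g$trans[i, ]
    atoms[[i]] <- sweep(ctx$centered_atoms[[i]] %*% t(R), 2, pos, "+")
    bb_list[[i]] <- sweep(ctx$centered_bb[[i]] %*% t(R), 2, pos, "+")
  }
  target <- ctx$target
  grid <- cpp_blur_atoms(do.call(rbind, atoms), dim(target$grid),
                         target$origin, target$voxel_size,
                         ctx$sigma, 3 * ctx$sigma)
  probe <- density_map(grid, target$voxel_size, target$origin,
                       target$resolution)
  mi <- mutual_information(probe, target, ctx$bins)
  ps <- if (n >= 2) clash_penalty(bb_list, ctx$clash_voxel) else 0
  g$fit <- fitness_breakdown(mi, ps, n)
  g
}

genotype_fitness <- function(g) {
  if (is.null(g$fit)) stop("genotype has no evaluated fitness")
  g$fit$f
}

# ---- population operators --------------------------------------------------

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

#' Seed the initial population from feature points
#'
#' Every component of every genotype is placed on a uniformly chosen feature
#' point (with replacement) with a uniformly chosen library rotation. Half
#' the population is used as-is; the other half receives an extra random
#' displacement per component of length uniform in
#' `[0, 2 * min_pairwise_distance(points)]`.
#'
#' @param ctx a [ga_context()].
#' @param points a `PointSet` of feature points.
#' @param cfg a [ga_config()].
#' @param min_dist minimum pairwise feature-point distance; computed from
#'   `points` when there are at least two, otherwise a caller-supplied
#'   fallback (the map resolution by convention) must be given.
#' @return list of unevaluated `Genotype`s of length `cfg$population_size`.
#' @export
seed_population <- function(ctx, points, cfg,
                            min_dist = min_pairwise_distance(points)) {
  pts <- points$points
  npts <- nrow(pts)
  if (npts < 1) stop("feature-point set is empty")
  N <- cfg$population_size
  n <- ctx$n
  n_plain <- floor(N / 2)
  lapply(seq_len(N), function(j) {
    idx <- sample.int(npts, n, replace = TRUE)
    trans <- sweep(pts[idx, , drop = FALSE], 2, ctx$map_center)
    if (j > n_plain) {
      for (i in seq_len(n)) {
        trans[i, ] <- trans[i, ] +
          random_unit_vector() * runif(1, 0, 2 * min_dist)
      }
    }
    rot <- sample.int(ctx$quats$size, n, replace = TRUE)
    new_genotype(trans, rot)
  })
}

#' Tournament selection
#'
#' Draws `size` distinct genotypes uniformly and returns the fittest.
#'
#' @param pop list of evaluated `Genotype`s.
#' @param size tournament size (default 2).
#' @export
tournament_select <- function(pop, size = 2) {
  idx <- sample.int(length(pop), min(size, length(pop)))
  f <- vapply(pop[idx], genotype_fitness, numeric(1))
  pop[[idx[which.max(f)]]]
}

mutate_translation <- function(v, min_dist) {
  v + random_unit_vector() * runif(1, 0, min_dist)
}

mutate_rotation <- function(quats) {
  sample.int(quats$size, 1)
}

#' Crossover child of two parents
#'
#' The child starts as a copy of the fitter parent. Independently for each
#' gene (each per-component translation and each rotation), with probability
#' `crossover_prob` the gene is replaced by the other parent's value; every
#' gene that crossed over is then mutated with the generation's mutation
#' rate. Translation mutations add a uniformly oriented vector of length
#' uniform in `[0, min_dist]`; rotation mutations redraw the library index
#' uniformly.
#'
#' @param p1,p2 evaluated parent `Genotype`s with equal gene counts.
#' @param cfg a [ga_config()].
#' @param generation current generation (drives the mutation schedule).
#' @param ctx a [ga_context()] augmented with `min_dist` (see [run_ga()]).
#' @export
crossover_child <- function(p1, p2, cfg, generation, ctx) {
  if (nrow(p1$trans) != nrow(p2$trans)) stop("parents have mismatched gene counts")
  fitter_first <- genotype_fitness(p1) >= genotype_fitness(p2)
  fit_p <- if (fitter_first) p1 else p2
  oth_p <- if (fitter_first) p2 else p1
  child <- new_genotype(fit_p$trans, fit_p$rot)
  mr <- mutation_rate(cfg, generation)
  n <- nrow(child$trans)
  for (i in seq_len(n)) {
    if (runif(1) < cfg$crossover_prob) {
      child$trans[i, ] <- oth_p$trans[i, ]
      if (runif(1) < mr) {
        child$trans[i, ] <- mutate_translation(child$trans[i, ], ctx$min_dist)
      }
    }
    if (runif(1) < cfg$crossover_prob) {
      child$rot[i] <- oth_p$rot[i]
      if (runif(1) < mr) child$rot[i] <- mutate_rotation(ctx$quats)
    }
  }
  child
}

#' Diversity child of the fittest genotype
#'
#' Swaps the full gene pairs (translation and rotation together) of two
#' randomly chosen components of the fittest genotype, then mutates every
#' gene independently at the constant diversity mutation rate. With a single
#' component there is nothing to swap and the child is a pure mutation copy.
#'
#' @param fittest the fittest evaluated `Genotype` of the parent population.
#' @inheritParams crossover_child
#' @export
diversity_child <- function(fittest, cfg, ctx) {
  child <- new_genotype(fittest$trans, fittest$rot)
  n <- nrow(child$trans)
  if (n >= 2) {
    ij <- sample.int(n, 2)
    child$trans[ij, ] <- child$trans[rev(ij), ]
    child$rot[ij] <- child$rot[rev(ij)]
  }
  for (i in seq_len(n)) {
    if (runif(1) < cfg$diversity_mutation_rate) {
      child$trans[i, ] <- mutate_translation(child$trans[i, ], ctx$min_dist)
    }
    if (runif(1) < cfg$diversity_mutation_rate) {
      child$rot[i] <- mutate_rotation(ctx$quats)
    }
  }
  child
}

# child mix for a population of size N: crossover children first
make_children <- function(pop, cfg, generation, ctx) {
  N <- length(pop)
  n_cross <- round((1 - cfg$diversity_fraction) * N)
  n_div <- N - n_cross
  f <- vapply(pop, genotype_fitness, numeric(1))
  fittest <- pop[[which.max(f)]]
  cross <- lapply(seq_len(n_cross), function(j) {
    p1 <- tournament_select(pop, cfg$tournament_size)
    p2 <- tournament_select(pop, cfg$tournament_size)
    crossover_child(p1, p2, cfg, generation, ctx)
  })
  div <- lapply(seq_len(n_div), function(j) diversity_child(fittest, cfg, ctx))
  list(crossover = cross, diversity = div)
}

#' Advance the population by one generation (elitist merge selection)
#'
#' Builds `round((1 - diversity_fraction) * N)` crossover children and the
#' remainder by the diversity operator, evaluates them, merges children with
#' the N parents, and keeps the N fittest of the 2N pool (ties broken in
#' favour of parents, then creation order), so the best fitness can never
#' decrease.
#'
#' @param pop evaluated parent population.
#' @inheritParams crossover_child
#' @export
next_generation <- function(pop, cfg, generation, ctx) {
  ch <- make_children(pop, cfg, generation, ctx)
  children <- lapply(c(ch$crossover, ch$diversity), evaluate_genotype, ctx = ctx)
  merged <- c(pop, children)
  f <- vapply(merged, genotype_fitness, numeric(1))
  ord <- order(-f)                       # stable: parents first on ties
  merged[ord[seq_along(pop)]]
}

#' Run one genetic algorithm
#'
#' @param ctx a [ga_context()].
#' @param points feature-point `PointSet` used for seeding and mutation
#'   ranges.
#' @param cfg a [ga_config()].
#' @param run_seed integer seed for this run's randomness.
#' @return list with `best` (fittest final `Genotype`), `trace` (data frame
#'   of per-generation best/mean/sd fitness), `population` (final evaluated
#'   population) and `run_seed`.
#' @export
run_ga <- function(ctx, points, cfg, run_seed = cfg$seed) {
  set.seed(run_seed)
  if (nrow(points$points) >= 2) {
    ctx$min_dist <- min_pairwise_distance(points)
  } else {
    message("single feature point: using the map resolution (",
            ctx$target$resolution, " A) as the mutation range")
    ctx$min_dist <- ctx$target$resolution
  }
  pop <- seed_population(ctx, points, cfg, min_dist = ctx$min_dist)
  pop <- lapply(pop, evaluate_genotype, ctx = ctx)
  gens <- cfg$generations
  trace <- data.frame(generation = seq_len(gens), best = NA_real_,
                      mean = NA_real_, sd = NA_real_)
  for (g in seq_len(gens)) {
    pop <- next_generation(pop, cfg, g, ctx)
    f <- vapply(pop, genotype_fitness, numeric(1))
    trace$best[g] <- max(f)
    trace$mean[g] <- mean(f)
    trace$sd[g] <- sd(f)
  }
  f <- vapply(pop, genotype_fitness, numeric(1))
  list(best = pop[[which.max(f)]], trace = trace, population = pop,
       run_seed = run_seed)
}

#' Run an ensemble of independent GAs and rank the predictions
#'
#' Runs `cfg$n_runs` independent GAs (all from the same feature-point set,
#' with distinct seeds derived from `cfg$seed`) and ranks the resulting
#' models by fitness; rank 1 is the highest-scoring (HS) assembly. If a
#' reference assembly is supplied, the best-predicted (BP, lowest
#' permutation-aware C-alpha RMSD) model and its fitness rank are reported
#' as well.
#'
#' @param target a `DensityMap` with resolution set.
#' @param components list of `Component`s to fit.
#' @param points feature-point `PointSet`.
#' @param cfg a [ga_config()].
#' @param reference optional list of native `Component`s for BP
#'   identification.
#' @return object of class `ga_ensemble`: a list with `results` (one entry
#'   per rank: `model`, `fit`, `trace`, `run_seed`, and `rmsd` when a
#'   reference is given), `bp_rank`, and `config`.
#' @export
run_ensemble <- function(target, components, points, cfg, reference = NULL) {
  quats <- generate_quaternion_set(cfg$quaternion_count, seed = cfg$seed)
  ctx <- ga_context(target, components, quats)
  set.seed(cfg$seed)
  run_seeds <- sample.int(.Machine$integer.max, cfg$n_runs)
  runs <- lapply(run_seeds, function(s) run_ga(ctx, points, cfg, run_seed = s))
  fvals <- vapply(runs, function(r) genotype_fitness(r$best), numeric(1))
  ord <- order(-fvals)
  results <- lapply(seq_along(ord), function(rank) {
    r <- runs[[ord[rank]]]
    model <- decode_genotype(r$best, ctx)
    out <- list(rank = rank, model = model, fit = r$best$fit,
                trace = r$trace, run_seed = r$run_seed)
    if (!is.null(reference)) {
      out$rmsd <- assembly_rmsd(model, reference)$rmsd
    }
    out
  })
  bp_rank <- NA_integer_
  if (!is.null(reference)) {
    rmsds <- vapply(results, function(x) x$rmsd, numeric(1))
    bp_rank <- which.min(rmsds)
  }
  structure(list(results = results, bp_rank = bp_rank, config = cfg,
                 points = points),
            class = "ga_ensemble")
}

#' @export
print.ga_ensemble <- function(x, ...) {
  cat(sprintf("<GA ensemble: %d runs>\n", length(x$results)))
  for (r in x$results) {
    cat(sprintf("  rank %2d: F = %8.4f (MI = %.4f, PS = %.4f)%s\n",
                r$rank, r$fit$f, r$fit$mi, r$fit$ps,
                if (is.null(r$rmsd)) "" else sprintf(", RMSD = %.2f A", r$rmsd)))
  }
  if (!is.na(x$bp_rank)) cat("  best-predicted model at rank", x$bp_rank, "\n")
  invisible(x)
}
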