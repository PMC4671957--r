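# Fitness function: mutual-information goodness-of-fit, clash penalty,
# and their combination F = n * MI - PS.

bin_grid <- function(v, bins) {
  mn <- min(v); mx <- max(v)
  if (mx <= mn) return(list(idx = rep(1L, length(v)), nbins = 1L))
  idx <- as.integer(floor((v - mn) / (mx - mn) * bins)) + 1L
  idx[idx > bins] <- as.integer(bins)
  list(idx = idx, nbins = as.integer(bins))
}

#' Joint density histogram of two aligned maps
#'
#' Each map's densities are split into `bins` equal-width bins spanning that
#' map's own full range (a constant map collapses to a single bin); the joint
#' table counts aligned-voxel pairs over all voxels.
#'
#' @param probe,target `DensityMap`s on identical grid geometry.
#' @param bins number of density bins per axis (default 20).
#' @return list with `counts` (target-bins x probe-bins matrix), and marginal
#'   counts `probe_marginal`, `target_marginal`.
#' @export
joint_histogram <- function(probe, target, bins = 20) {
  if (!same_grid_geometry(probe, target)) {
    stop("probe and target must share grid dimensions, origin and voxel size")
  }
  bx <- bin_grid(as.numeric(probe$grid), bins)
  by <- bin_grid(as.numeric(target$grid), bins)
  counts <- tabulate((bx$idx - 1L) * by$nbins + by$idx,
                     nbins = bx$nbins * by$nbins)
  counts <- matrix(counts, nrow = by$nbins, ncol = bx$nbins)
  list(counts = counts,
       probe_marginal = colSums(counts),
       target_marginal = rowSums(counts),
       bins = c(probe = bx$nbins, target = by$nbins))
}

#' Mutual information between the binned densities of two aligned maps
#'
#' `MI = sum_xy p(x, y) log[ p(x, y) / (p(x) p(y)) ]` (natural log), where
#' `p(x, y)` is the fraction of aligned voxels falling in probe bin `x` and
#' target bin `y`. MI is non-negative, symmetric, and equals the entropy of
#' the binned density when probe and target are identical.
#'
#' @inheritParams joint_histogram
#' @return mutual information in nats.
#' @export
mutual_information <- function(probe, target, bins = 20) {
  jh <- joint_histogram(probe, target, bins)
  n <- sum(jh$counts)
  p <- jh$counts / n
  px <- jh$probe_marginal / n
  py <- jh$target_marginal / n
  op <- outer(py, px)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / op[nz]))
  max(mi, 0)
}

#' Entropy of a map's binned density distribution (nats)
#' @param m a `DensityMap`.
#' @param bins number of density bins (default 20).
#' @export
map_entropy <- function(m, bins = 20) {
  b <- bin_grid(as.numeric(m$grid), bins)
  p <- tabulate(b$idx, nbins = b$nbins)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

# occupied-voxel ids of backbone/C-beta coordinates on a shared lattice
occupied_voxel_ids <- function(coord_list, voxel_size) {
  all_min <- do.call(pmin, lapply(coord_list, function(x) apply(x, 2, min)))
  org <- floor(all_min / voxel_size) * voxel_size   # snap to lattice
  dims <- integer(3)
  iv <- lapply(coord_list, function(x) {
    floor(sweep(x, 2, org) / voxel_size)
  })
  kmax <- apply(do.call(rbind, lapply(iv, function(x) apply(x, 2, max))), 2, max)
  kx <- kmax[1] + 1; ky <- kmax[2] + 1
  lapply(iv, function(x) {
    unique((x[, 3] * ky + x[, 2]) * kx + x[, 1])
  })
}

#' Clash penalty between assembly components
#'
#' Each component occupies the set of voxels (edge `voxel_size`, shared
#' lattice) containing any of its backbone (N, CA, C, O) or C-beta atoms.
#' For each unordered pair the fractional overlap is
#' `|occ_i intersect occ_j| / (|occ_i| + |occ_j|)`; the penalty is the sum
#' over pairs. Mild clashes are tolerated (small fractions), severe overlap
#' is strongly penalized; a single component scores 0.
#'
#' @param components list of placed `Component`s (or list of coordinate
#'   matrices of their backbone/C-beta atoms).
#' @param voxel_size occupancy-grid voxel edge in Angstroms (default 3.5).
#' @return penalty (unitless, >= 0).
#' @export
clash_penalty <- function(components, voxel_size = 3.5) {
  if (inherits(components, "Component")) components <- list(components)
  coord_list <- lapply(components, function(cm) {
    x <- if (inherits(cm, "Component")) backbone_cb_coords(cm) else as.matrix(cm)
    if (nrow(x) == 0) stop("component has no backbone or C-beta atoms")
    x
  })
  n <- length(coord_list)
  if (n < 2) return(0)
  occ <- occupied_voxel_ids(coord_list, voxel_size)
  ps <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ov <- length(intersect(occ[[i]], occ[[j]]))
      if (ov > 0) ps <- ps + ov / (length(occ[[i]]) + length(occ[[j]]))
    }
  }
  ps
}

#' Fitness breakdown container
#'
#' The fitness of an assembly model with `n` components is
#' `F = n * MI - PS`, weighting the goodness of fit so it is not overwhelmed
#' by the clash penalty as assemblies grow.
#'
#' @param mi mutual information (nats).
#' @param ps clash penalty (unitless, >= 0).
#' @param n number of components.
#' @export
fitness_breakdown <- function(mi, ps, n) {
  if (ps < 0) stop("ps must be >= 0")
  structure(list(mi = mi, ps = ps, n = as.integer(n), f = n * mi - ps),
            class = "FitnessBreakdown")
}

#' @export
print.FitnessBreakdown <- function(x, ...) {
  cat(sprintf("<Fitness: F = %.4f (n = %d, MI = %.4f, PS = %.4f)>\n",
              x$f, x$n, x$mi, x$ps))
  invisible(x)
}

#' Fitness of a placed assembly model against a target map
#'
#' Simulates the probe density of the placed components on the target grid at
#' the target's nominal resolution, scores the mutual information against the
#' target, and subtracts the clash penalty.
#'
#' @param components list of placed `Component`s.
#' @param target a `DensityMap` with its `resolution` set.
#' @param sigma_factor Gaussian sigma factor for the probe simulation.
#' @param bins mutual-information density bins.
#' @param clash_voxel occupancy-grid voxel edge for the clash penalty.
#' @return a `FitnessBreakdown`.
#' @export
assembly_fitness <- function(components, target, sigma_factor = 0.356,
                             bins = 20, clash_voxel = 3.5) {
  if (inherits(components, "Component")) components <- list(components)
  if (length(components) < 1) stop("need at least one component")
  if (is.na(target$resolution)) {
    stop("target map must carry a nominal resolution")
  }
  probe <- simulate_map(components,
                        simulation_params(target$resolution,
                                          sigma_factor = sigma_factor,
                                          voxel_size = target$voxel_size),
                        grid_spec = target)
  mi <- mutual_information(probe, target, bins)
  ps <- clash_penalty(components, clash_voxel)
  fitness_breakdown(mi, ps, length(components))
}

#' Size of the rotational configuration space of an assembly
#'
#' With a 360-degree search range discretized at `step_deg` for each of the
#' three rotation angles of each component, the number of purely rotational
#' configurations is `(360 / step_deg)^(3 * n_components)` — about 1e14
#' already for three components at a 10-degree step, which motivates
#' heuristic rather than exhaustive search.
#'
#' @param n_components number of assembly components.
#' @param step_deg angular step in degrees (default 10).
#' @export
rotational_configurations <- function(n_components, step_deg = 10) {
  (360 / step_deg)^(3 * n_components)
}
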