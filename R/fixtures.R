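# Synthetic toy assemblies with known ground truth: compact pseudo-atomic
# chains, packed without overlap, plus a simulated target map. Every other
# module is testable against these fixtures without downloads.

#' Specification of a synthetic fixture assembly
#'
#' @param n_components number of components.
#' @param residues length-2 range of residues per component; sizes are spread
#'   evenly across the range (then shuffled), giving the heterogeneous
#'   component sizes typical of real assemblies.
#' @param packing minimum inter-centroid distance in Angstroms.
#' @param resolution simulated-map resolution in Angstroms.
#' @param voxel_size map voxel edge in Angstroms.
#' @param seed integer seed; fixtures are fully reproducible.
#' @param identical_pairs optional list of index pairs forced to be identical
#'   components (same sequence and internal coordinates).
#' @export
fixture_spec <- function(n_components = 3, residues = c(30, 70), packing = 25,
                         resolution = 10, voxel_size = 3.5, seed = 1,
                         identical_pairs = NULL) {
  stopifnot(n_components >= 1, packing > 0, length(residues) == 2,
            residues[1] >= 2, residues[2] >= residues[1],
            resolution > 0, voxel_size > 0)
  structure(list(n_components = as.integer(n_components),
                 residues = as.integer(residues), packing = packing,
                 resolution = resolution, voxel_size = voxel_size,
                 seed = as.integer(seed), identical_pairs = identical_pairs),
            class = "FixtureSpec")
}

#' Generate one compact pseudo-atomic component
#'
#' Builds a self-avoiding pseudo C-alpha chain (3.8 Angstrom consecutive
#' spacing; non-consecutive C-alphas at least 4 Angstroms apart) biased
#' towards its running centroid so the chain stays compact, then synthesizes
#' idealized backbone N, C, O and C-beta positions in a local frame at each
#' residue so that the occupancy grid of the clash penalty sees realistic
#' atom counts.
#'
#' @param n_residues chain length (>= 2).
#' @param seed integer seed.
#' @param id component label.
#' @return a `Component` with 5 atoms per residue (N, CA, C, O, CB).
#' @export
make_component <- function(n_residues, seed = 1, id = "A") {
  if (n_residues < 2) stop("n_residues must be >= 2")
  set.seed(seed)
  for (restart in 1:25) {
    ca <- matrix(NA_real_, n_residues, 3)
    ca[1, ] <- 0
    v <- rnorm(3); ca[2, ] <- 3.8 * v / sqrt(sum(v^2))
    ok <- TRUE
    if (n_residues > 2) {
      for (i in 3:n_residues) {
        cen <- colMeans(ca[1:(i - 1), , drop = FALSE])
        placed <- FALSE
        for (try in 1:300) {
          dir <- rnorm(3) + 0.08 * (cen - ca[i - 1, ])
          dir <- dir / sqrt(sum(dir^2))
          cand <- ca[i - 1, ] + 3.8 * dir
          prev <- ca[1:(i - 2), , drop = FALSE]
          if (min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= 4) {
            ca[i, ] <- cand
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
    }
    if (ok) break
    if (restart == 25) {
      stop("could not build a self-avoiding chain of ", n_residues,
           " residues; try fewer residues")
    }
  }
  # seeded random sequence so distinct components are distinguishable by
  # sequence identity (identical seeds give identical sequences)
  aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  seqn <- sample(aa3, n_residues, replace = TRUE)
  # idealized backbone/C-beta offsets in a local frame per residue
  atoms <- vector("list", n_residues)
  for (i in seq_len(n_residues)) {
    a <- if (i == 1) 1 else i - 1
    b <- if (i == n_residues) n_residues else i + 1
    u <- ca[b, ] - ca[a, ]
    u <- u / sqrt(sum(u^2))
    ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    vv <- c(u[2] * ref[3] - u[3] * ref[2],
            u[3] * ref[1] - u[1] * ref[3],
            u[1] * ref[2] - u[2] * ref[1])
    vv <- vv / sqrt(sum(vv^2))
    w <- c(u[2] * vv[3] - u[3] * vv[2],
           u[3] * vv[1] - u[1] * vv[3],
           u[1] * vv[2] - u[2] * vv[1])
    p_ca <- ca[i, ]
    pos <- rbind(N  = p_ca - 0.85 * u + 1.19 * vv,
                 CA = p_ca,
                 C  = p_ca + 0.85 * u + 1.26 * vv,
                 O  = p_ca + 0.85 * u + 1.26 * vv + 1.23 * w,
                 CB = p_ca - 1.53 * w)
    atoms[[i]] <- data.frame(
      name = rownames(pos), resno = i, resname = seqn[i],
      element = c("N", "C", "C", "O", "C"),
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, atoms)
  rownames(tab) <- NULL
  new_component(id, tab)
}

#' Generate a synthetic assembly, its simulated map, and ground truth
#'
#' Components are placed with random orientations at centroid positions
#' sampled with a minimum separation of `spec$packing`; placements with a
#' native clash penalty of 0.05 or more are rejected and re-drawn. The
#' target map is simulated from the placed assembly at the requested
#' resolution and voxel size with a 10 Angstrom margin.
#'
#' @param spec a [fixture_spec()].
#' @return list with `components` (the natively placed `Component`s, also
#'   the ground-truth model), `map` (simulated `DensityMap`), `centroids`
#'   (native-centroid `PointSet`), `transforms` (the native
#'   `RigidTransform`s applied to each as-built component) and `spec`.
#' @export
make_assembly <- function(spec) {
  if (!inherits(spec, "FixtureSpec")) stop("spec must be a fixture_spec()")
  set.seed(spec$seed)
  n <- spec$n_components
  sizes <- round(seq(spec$residues[1], spec$residues[2], length.out = n))
  sizes <- sample(sizes)
  comp_seeds <- sample.int(1e6, n)
  if (!is.null(spec$identical_pairs)) {
    for (pr in spec$identical_pairs) {
      comp_seeds[pr[2]] <- comp_seeds[pr[1]]
      sizes[pr[2]] <- sizes[pr[1]]
    }
  }
  comps <- lapply(seq_len(n), function(i) {
    make_component(sizes[i], seed = comp_seeds[i], id = LETTERS[i])
  })
  for (attempt in 1:50) {
    box <- spec$packing * (n^(1 / 3) + 0.8) * (1 + 0.05 * (attempt - 1))
    centers <- matrix(NA_real_, n, 3)
    feasible <- TRUE
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in 1:2000) {
        cand <- runif(3, 0, box)
        if (i == 1 ||
            min(sqrt(rowSums(sweep(centers[seq_len(i - 1), , drop = FALSE],
                                   2, cand)^2))) >= spec$packing) {
          centers[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { feasible <- FALSE; break }
    }
    if (!feasible) next
    transforms <- lapply(seq_len(n), function(i) {
      q <- quat_normalize(rnorm(4))
      rigid_transform(q, centers[i, ] - comps[[i]]$com)
    })
    placed <- Map(apply_transform, comps, transforms)
    if (clash_penalty(placed, spec$voxel_size) < 0.05) {
      map <- simulate_map(placed,
                          simulation_params(spec$resolution,
                                            voxel_size = spec$voxel_size,
                                            padding = 10))
      return(list(components = placed, map = map,
                  centroids = native_centroids(placed),
                  transforms = transforms, spec = spec))
    }
  }
  stop("could not pack ", n, " components at packing ", spec$packing,
       " A; reduce packing or component sizes")
}
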