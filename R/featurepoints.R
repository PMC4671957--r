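# Feature points: neural-gas vector quantization of density maps, native
# centroid extraction, and Hausdorff-distance comparison of point sets.

#' Construct an ordered 3D point set
#'
#' @param points n x 3 numeric matrix of coordinates in Angstroms.
#' @param label provenance: `"vq"`, `"centroid"` or `"external"`.
#' @return object of class `PointSet`.
#' @export
point_set <- function(points, label = c("external", "vq", "centroid")) {
  label <- match.arg(label)
  points <- as.matrix(points)
  if (nrow(points) < 1 || ncol(points) != 3) {
    stop("points must be a non-empty n x 3 matrix")
  }
  if (!all(is.finite(points))) stop("points must be finite")
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(list(points = points, label = label), class = "PointSet")
}

#' @export
print.PointSet <- function(x, ...) {
  cat(sprintf("<PointSet (%s): %d points>\n", x$label, nrow(x$points)))
  invisible(x)
}

#' Write a point set as whitespace-delimited text (one "x y z" per line)
#' @param ps a `PointSet`.
#' @param path output file.
#' @export
write_points <- function(ps, path) {
  writeLines(c(sprintf("# %s point set, %d points, Angstroms",
                       ps$label, nrow(ps$points)),
               apply(ps$points, 1, function(p) paste(format(p, digits = 10),
                                                     collapse = " "))),
             path)
  invisible(path)
}

#' Read a point set from whitespace-delimited text ('#' lines are comments)
#' @param path input file.
#' @param label provenance tag to attach.
#' @export
read_points <- function(path, label = "external") {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("no points in '", path, "'")
  vals <- lapply(strsplit(lines, "[[:space:]]+"), as.numeric)
  if (any(vapply(vals, length, 1L) != 3)) {
    stop("each line of '", path, "' must hold three coordinates")
  }
  point_set(do.call(rbind, vals), label)
}

#' Native component centroids as a point set
#' @param components list of `Component`s placed at their native positions.
#' @export
native_centroids <- function(components) {
  if (inherits(components, "Component")) components <- list(components)
  if (length(components) < 1) stop("need at least one component")
  point_set(do.call(rbind, lapply(components, function(cm) cm$com)),
            "centroid")
}

#' Hausdorff distance between two point sets
#'
#' `HD(A, B) = max(h(A, B), h(B, A))` with
#' `h(A, B) = max_a min_b d(a, b)` and `d` the Euclidean distance. Identical
#' sets have HD = 0 and the distance grows with dissimilarity.
#'
#' @param a,b `PointSet`s (or bare n x 3 matrices).
#' @return distance in Angstroms.
#' @export
hausdorff <- function(a, b) {
  pa <- if (inherits(a, "PointSet")) a$points else as.matrix(a)
  pb <- if (inherits(b, "PointSet")) b$points else as.matrix(b)
  if (nrow(pa) < 1 || nrow(pb) < 1) stop("point sets must be non-empty")
  h_dir <- function(P, Q) {
    worst <- 0
    for (i in seq_len(nrow(P))) {
      d2 <- min(rowSums(sweep(Q, 2, P[i, ])^2))
      if (d2 > worst) worst <- d2
    }
    sqrt(worst)
  }
  max(h_dir(pa, pb), h_dir(pb, pa))
}

#' Minimum pairwise distance within a point set
#' @param a a `PointSet` (or n x 3 matrix) with at least two points.
#' @return Angstroms.
#' @export
min_pairwise_distance <- function(a) {
  p <- if (inherits(a, "PointSet")) a$points else as.matrix(a)
  if (nrow(p) < 2) stop("need at least two points")
  min(dist(p))
}

#' Neural-gas parameters
#'
#' Defaults follow the standard neural-gas schedule for map quantization:
#' `steps = 10000 * k` density-proportional samples, learning rate decaying
#' exponentially from 0.1 to 0.001, and neighbourhood range decaying from
#' `k / 2` to 0.01.
#'
#' @param k number of codebook vectors (feature points).
#' @param steps total training samples.
#' @param eps_initial,eps_final learning-rate schedule endpoints.
#' @param lambda_initial,lambda_final neighbourhood-range schedule endpoints.
#' @param threshold_sigma density threshold in map-sigma units (default 2).
#' @param seed integer seed; a given seed fully determines the result.
#' @export
neural_gas_params <- function(k, steps = 10000 * k,
                              eps_initial = 0.1, eps_final = 0.001,
                              lambda_initial = max(k / 2, 0.01),
                              lambda_final = 0.01,
                              threshold_sigma = 2, seed = 1) {
  if (k < 1) stop("k must be >= 1")
  if (steps < 1) stop("steps must be >= 1")
  if (eps_initial <= 0 || eps_final <= 0 || eps_initial < eps_final) {
    stop("learning-rate schedule must be positive and decreasing")
  }
  if (lambda_initial <= 0 || lambda_final <= 0 ||
      lambda_initial < lambda_final) {
    stop("neighbourhood schedule must be positive and decreasing")
  }
  structure(list(k = as.integer(k), steps = as.integer(steps),
                 eps_initial = eps_initial, eps_final = eps_final,
                 lambda_initial = lambda_initial, lambda_final = lambda_final,
                 threshold_sigma = threshold_sigma, seed = seed),
            class = "NeuralGasParams")
}

#' Extract feature points from a density map by neural-gas vector quantization
#'
#' Voxel centres above the `mean + threshold_sigma * sigma` density threshold
#' are sampled with probability proportional to their density; each sample
#' updates all codebook vectors by the neural-gas rule
#' `w_j <- w_j + eps(t) * exp(-rank_j / lambda(t)) * (x - w_j)`, with
#' exponentially interpolated schedules. The converged codebook approximates
#' the centres of the density clusters (for `k` equal to the number of
#' assembly components, roughly the component centroids).
#'
#' @param m a `DensityMap`.
#' @param p a [neural_gas_params()] object (or an integer `k`, in which case
#'   defaults are used).
#' @return a `PointSet` labelled `"vq"` with `p$k` points.
#' @export
vector_quantize <- function(m, p) {
  if (is.numeric(p) && length(p) == 1) p <- neural_gas_params(p)
  if (!inherits(p, "NeuralGasParams")) stop("p must be neural_gas_params()")
  th <- threshold_mask(m, p$threshold_sigma)
  X <- th$coords
  if (nrow(X) < p$k) {
    stop("only ", nrow(X), " voxels above threshold but k = ", p$k,
         "; lower threshold_sigma")
  }
  w <- th$densities
  prob <- w / sum(w)
  set.seed(p$seed)
  k <- p$k
  W <- X[sample.int(nrow(X), k, prob = prob), , drop = FALSE]
  steps <- p$steps
  samp <- sample.int(nrow(X), steps, replace = TRUE, prob = prob)
  tfrac <- if (steps == 1) 0 else (seq_len(steps) - 1) / (steps - 1)
  eps_t <- p$eps_initial * (p$eps_final / p$eps_initial)^tfrac
  lam_t <- p$lambda_initial * (p$lambda_final / p$lambda_initial)^tfrac
  for (t in seq_len(steps)) {
    x <- X[samp[t], ]
    dx <- x[1] - W[, 1]; dy <- x[2] - W[, 2]; dz <- x[3] - W[, 3]
    d2 <- dx * dx + dy * dy + dz * dz
    r <- order(order(d2)) - 1            # neighbourhood rank, 0 = closest
    h <- eps_t[t] * exp(-r / lam_t[t])
    W[, 1] <- W[, 1] + h * dx
    W[, 2] <- W[, 2] + h * dy
    W[, 3] <- W[, 3] + h * dz
  }
  point_set(W, "vq")
}
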