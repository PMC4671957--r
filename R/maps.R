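# Density-map data model, MRC/CCP4 I/O, and map simulation by Gaussian blurring.

#' Construct a density map
#'
#' The grid is a 3D array indexed `[x, y, z]`; the centre of voxel `(1, 1, 1)`
#' sits at `origin` and voxel centres are spaced `voxel_size` Angstroms apart
#' along each axis.
#'
#' @param grid 3D numeric array of density values.
#' @param voxel_size isotropic voxel edge in Angstroms.
#' @param origin position (Angstroms) of the first voxel centre.
#' @param resolution nominal map resolution in Angstroms (metadata; required
#'   by operations that simulate a probe map).
#' @return object of class `DensityMap` with `stats = c(mean, sigma)` computed
#'   from the grid (sigma is the population standard deviation, matching the
#'   RMS-deviation convention of map headers).
#' @export
density_map <- function(grid, voxel_size, origin = c(0, 0, 0),
                        resolution = NA_real_) {
  if (length(dim(grid)) != 3) stop("grid must be a 3D array")
  if (any(dim(grid) < 1)) stop("grid dimensions must be >= 1")
  if (!is.numeric(voxel_size) || voxel_size <= 0) stop("voxel_size must be > 0")
  g <- as.numeric(grid)
  mu <- mean(g)
  sigma <- sqrt(mean((g - mu)^2))
  structure(list(grid = grid, voxel_size = voxel_size,
                 origin = as.numeric(origin), resolution = resolution,
                 stats = c(mean = mu, sigma = sigma)),
            class = "DensityMap")
}

#' @export
print.DensityMap <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<DensityMap %dx%dx%d, voxel %.3f A, origin (%.1f, %.1f, %.1f), mean %.4g, sigma %.4g%s>\n",
              d[1], d[2], d[3], x$voxel_size, x$origin[1], x$origin[2],
              x$origin[3], x$stats["mean"], x$stats["sigma"],
              if (is.na(x$resolution)) "" else sprintf(", res %.1f A", x$resolution)))
  invisible(x)
}

#' Geometric centre of a map (Angstroms)
#' @param m a `DensityMap`.
#' @export
map_center <- function(m) {
  m$origin + (dim(m$grid) - 1) * m$voxel_size / 2
}

same_grid_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$grid), dim(b$grid)) &&
    abs(a$voxel_size - b$voxel_size) <= tol &&
    all(abs(a$origin - b$origin) <= tol)
}

# ---- MRC/CCP4 I/O ----------------------------------------------------------

#' Read an MRC2014/CCP4 density map
#'
#' Data are returned in canonical axis order (columns = x fastest); axis
#' permutations recorded in the header are undone on read. Near-isotropic
#' voxel sizes (within 1%) are averaged; stronger anisotropy is rejected.
#'
#' @param path MRC/CCP4 file.
#' @param resolution optional nominal resolution (Angstroms) to attach; the
#'   MRC format itself does not carry one.
#' @return a `DensityMap`.
#' @export
read_map <- function(path, resolution = NA_real_) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 1024)
  if (length(hdr) < 1024) stop("corrupt MRC header in '", path, "' (short file)")
  ints <- readBin(hdr, "integer", 256, size = 4, endian = "little")
  flts <- readBin(hdr, "numeric", 256, size = 4, endian = "little")
  nc <- ints[1]; nr <- ints[2]; ns <- ints[3]; mode <- ints[4]
  if (any(c(nc, nr, ns) < 1) || any(c(nc, nr, ns) > 1e4)) {
    stop("corrupt MRC header in '", path, "' (implausible dimensions)")
  }
  if (!mode %in% c(0, 1, 2)) {
    stop("unsupported MRC mode ", mode, " in '", path, "'")
  }
  nstart <- ints[5:7]
  mgrid <- ints[8:10]
  cella <- flts[11:13]
  cms <- ints[17:19]                      # axis of columns, rows, sections
  if (!setequal(cms, 1:3)) cms <- 1:3     # tolerate broken headers
  orig <- flts[50:52]
  nsymbt <- ints[24]
  if (nsymbt > 0) invisible(readBin(con, "raw", nsymbt))
  nvox <- as.numeric(nc) * nr * ns
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", nvox, size = 1, endian = "little")),
    "1" = as.numeric(readBin(con, "integer", nvox, size = 2, endian = "little")),
    "2" = readBin(con, "numeric", nvox, size = 4, endian = "little"))
  if (length(vals) != nvox) stop("truncated MRC data in '", path, "'")
  arr <- array(vals, dim = c(nc, nr, ns))
  perm <- match(1:3, cms)
  arr <- aperm(arr, perm)
  nstart_xyz <- nstart[perm]
  mg <- ifelse(mgrid <= 0, dim(arr), mgrid)
  vsz <- cella / mg
  vsz <- vsz[is.finite(vsz) & vsz > 0]
  if (length(vsz) == 0) {
    voxel <- 1
  } else {
    if ((max(vsz) - min(vsz)) / mean(vsz) > 0.01) {
      stop("anisotropic voxel sizes in '", path, "' (",
           paste(sprintf("%.3f", vsz), collapse = ", "), " A)")
    }
    if (max(vsz) > min(vsz)) {
      message("averaging near-isotropic voxel sizes in '", path, "'")
    }
    voxel <- mean(vsz)
  }
  if (all(orig == 0)) orig <- nstart_xyz * voxel
  density_map(arr, voxel_size = voxel, origin = orig, resolution = resolution)
}

#' Write a density map as MRC2014 (mode 2, canonical axis order)
#' @param m a `DensityMap`.
#' @param path output file.
#' @export
write_map <- function(m, path) {
  if (!inherits(m, "DensityMap")) stop("m must be a DensityMap")
  d <- dim(m$grid)
  ints <- integer(256)
  flts <- numeric(256)
  use_f <- logical(256)
  ints[1:3] <- d
  ints[4] <- 2L
  ints[5:7] <- 0L
  ints[8:10] <- d
  flts[11:13] <- d * m$voxel_size; use_f[11:13] <- TRUE
  flts[14:16] <- 90; use_f[14:16] <- TRUE
  ints[17:19] <- 1:3
  g <- as.numeric(m$grid)
  flts[20] <- min(g); flts[21] <- max(g); flts[22] <- mean(g)
  use_f[20:22] <- TRUE
  ints[23] <- 1L                      # ispg
  ints[24] <- 0L                      # nsymbt
  flts[50:52] <- m$origin; use_f[50:52] <- TRUE
  flts[55] <- sqrt(mean((g - mean(g))^2)); use_f[55] <- TRUE
  ints[56] <- 0L                      # nlabl
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in 1:256) {
    if (i == 53) {
      writeBin(charToRaw("MAP "), con)
    } else if (i == 54) {
      writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)
    } else if (use_f[i]) {
      writeBin(flts[i], con, size = 4, endian = "little")
    } else {
      writeBin(ints[i], con, size = 4, endian = "little")
    }
  }
  writeBin(g, con, size = 4, endian = "little")
  invisible(path)
}

# ---- simulation ------------------------------------------------------------

#' Parameters for simulating a map from atomic coordinates
#'
#' Each atom is blurred by an isotropic Gaussian point-spread function with
#' standard deviation `sigma_factor * resolution`, truncated at 3 sigma.
#'
#' @param resolution nominal resolution in Angstroms.
#' @param sigma_factor unitless multiplier relating resolution to the Gaussian
#'   sigma (default 0.356).
#' @param voxel_size voxel edge in Angstroms (default 3.5).
#' @param padding margin (Angstroms) around the structure when no target
#'   geometry is given; default twice the resolution so the blurred density
#'   is not clipped.
#' @export
simulation_params <- function(resolution, sigma_factor = 0.356,
                              voxel_size = 3.5, padding = 2 * resolution) {
  if (!is.numeric(resolution) || resolution <= 0) stop("resolution must be > 0")
  if (sigma_factor <= 0) stop("sigma_factor must be > 0")
  if (voxel_size <= 0) stop("voxel_size must be > 0")
  structure(list(resolution = resolution, sigma_factor = sigma_factor,
                 voxel_size = voxel_size, padding = padding),
            class = "SimulationParams")
}

gather_atom_coords <- function(model) {
  if (is.matrix(model)) return(model)
  if (inherits(model, "Component")) return(component_coords(model))
  if (is.list(model)) {
    return(do.call(rbind, lapply(model, function(cm) {
      if (inherits(cm, "Component")) component_coords(cm) else as.matrix(cm)
    })))
  }
  stop("model must be a Component, a list of Components, or a coordinate matrix")
}

#' Simulate a density map from atomic coordinates
#'
#' Every atom contributes an identical isotropic 3D Gaussian of standard
#' deviation `sigma_factor * resolution`, truncated at a radius of 3 sigma
#' and normalized so each untruncated atom carries unit mass.
#'
#' @param model a `Component`, list of `Component`s, or an n x 3 coordinate
#'   matrix (Angstroms).
#' @param params a [simulation_params()] object.
#' @param grid_spec optional `DensityMap` (or list with `dim`, `origin`,
#'   `voxel_size`) fixing the output geometry, e.g. a target map so probe and
#'   target voxels align for the mutual-information score.
#' @return a `DensityMap` carrying `params$resolution`.
#' @export
simulate_map <- function(model, params, grid_spec = NULL) {
  if (!inherits(params, "SimulationParams")) stop("params must be simulation_params()")
  coords <- gather_atom_coords(model)
  if (is.null(coords) || nrow(coords) == 0) stop("no atoms to simulate")
  sigma <- params$sigma_factor * params$resolution
  if (is.null(grid_spec)) {
    pad <- params$padding
    lo <- apply(coords, 2, min) - pad
    hi <- apply(coords, 2, max) + pad
    origin <- lo
    dims <- pmax(1L, as.integer(ceiling((hi - lo) / params$voxel_size)) + 1L)
    voxel <- params$voxel_size
  } else {
    if (inherits(grid_spec, "DensityMap")) {
      dims <- dim(grid_spec$grid); origin <- grid_spec$origin
      voxel <- grid_spec$voxel_size
    } else {
      dims <- as.integer(grid_spec$dim); origin <- grid_spec$origin
      voxel <- grid_spec$voxel_size
    }
  }
  grid <- cpp_blur_atoms(coords, as.integer(dims), as.numeric(origin),
                         voxel, sigma, 3 * sigma)
  density_map(grid, voxel_size = voxel, origin = origin,
              resolution = params$resolution)
}

# ---- thresholding ----------------------------------------------------------

#' Voxels above a sigma threshold
#'
#' Selects voxels with density strictly above `mean + k_sigma * sigma`, the
#' map statistics being taken over the whole grid.
#'
#' @param m a `DensityMap`.
#' @param k_sigma threshold in map-sigma units (default 2).
#' @return list with `mask` (logical 3D array), `coords` (matrix of centres of
#'   selected voxels, Angstroms) and `densities` (their map values).
#' @export
threshold_mask <- function(m, k_sigma = 2) {
  thr <- m$stats[["mean"]] + k_sigma * m$stats[["sigma"]]
  mask <- m$grid > thr
  idx <- which(mask, arr.ind = TRUE)
  coords <- sweep((idx - 1) * m$voxel_size, 2, m$origin, "+")
  colnames(coords) <- c("x", "y", "z")
  if (nrow(coords) == 0) message("no voxels above threshold ", signif(thr, 4))
  list(mask = mask, coords = coords, densities = m$grid[mask],
       threshold = thr)
}
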