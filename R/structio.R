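# Rigid components, quaternion rotation library, and PDB input/output.

#' Construct a rigid assembly component
#'
#' A component is one rigid body of an assembly: an atom table plus derived
#' geometric quantities. The centre of mass (`com`) is the unweighted mean of
#' all atom coordinates and the radius of gyration (`rgyr`) is the root mean
#' squared distance of the atoms from `com`; both are used as purely geometric
#' quantities (sphere centre and radius) by the topology score.
#'
#' @param id character label (typically the chain identifier).
#' @param atoms data frame with columns `name` (atom name, e.g. `"CA"`),
#'   `resno` (residue number), `resname` (residue name), `element`,
#'   and coordinates `x`, `y`, `z` in Angstroms.
#' @return An object of class `Component`.
#' @export
new_component <- function(id, atoms) {
  needed <- c("name", "resno", "resname", "element", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) < 1) stop("component '", id, "' has no atoms")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("component '", id, "' has non-finite coordinates")
  com <- colMeans(xyz)
  rgyr <- sqrt(mean(rowSums(sweep(xyz, 2, com)^2)))
  bb <- which(atoms$name %in% c("N", "CA", "C", "O", "CB"))
  if (length(bb) == 0) {
    # generic (e.g. nucleic-acid) chain: fall back to all heavy atoms
    message("component '", id, "' has no protein backbone atoms; ",
            "using all atoms for the occupancy grid")
    bb <- seq_len(nrow(atoms))
  }
  structure(
    list(id = id, atoms = atoms, com = com, rgyr = rgyr,
         calpha_idx = which(atoms$name == "CA"), backbone_idx = bb),
    class = "Component")
}

#' @export
print.Component <- function(x, ...) {
  cat(sprintf("<Component %s: %d atoms, %d CA, rgyr %.2f A, com (%.1f, %.1f, %.1f)>\n",
              x$id, nrow(x$atoms), length(x$calpha_idx), x$rgyr,
              x$com[1], x$com[2], x$com[3]))
  invisible(x)
}

#' Atom coordinates of a component
#' @param comp a `Component`.
#' @return numeric matrix (n x 3) of coordinates in Angstroms.
#' @export
component_coords <- function(comp) {
  as.matrix(comp$atoms[, c("x", "y", "z")])
}

#' C-alpha coordinates of a component (in residue order)
#' @inheritParams component_coords
#' @export
calpha_coords <- function(comp) {
  component_coords(comp)[comp$calpha_idx, , drop = FALSE]
}

#' Backbone (N, CA, C, O) and C-beta coordinates of a component
#'
#' These are the atoms entering the clash-penalty occupancy grid.
#' @inheritParams component_coords
#' @export
backbone_cb_coords <- function(comp) {
  component_coords(comp)[comp$backbone_idx, , drop = FALSE]
}

# ---- quaternions -----------------------------------------------------------

quat_normalize <- function(q) q / sqrt(sum(q^2))

quat_conjugate <- function(q) c(q[1], -q[2:4])

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Rotation matrix of a unit quaternion
#' @param q unit quaternion `(w, x, y, z)`.
#' @return 3x3 rotation matrix `R`; row vectors rotate as `x %*% t(R)`.
#' @export
quat_rotation_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

#' Rotation angle (radians) represented by a unit quaternion
#' @param q unit quaternion.
#' @export
quat_angle <- function(q) 2 * acos(min(1, abs(q[1])))

# ---- rigid transforms ------------------------------------------------------

#' Rigid-body transform (rotation about the component centroid + translation)
#'
#' @param rotation unit quaternion `(w, x, y, z)`.
#' @param translation length-3 numeric vector, Angstroms.
#' @return object of class `RigidTransform`.
#' @export
rigid_transform <- function(rotation = c(1, 0, 0, 0), translation = c(0, 0, 0)) {
  rotation <- as.numeric(rotation)
  translation <- as.numeric(translation)
  if (length(rotation) != 4 || anyNA(rotation)) {
    stop("rotation must be a numeric quaternion (w, x, y, z)")
  }
  nrm <- sqrt(sum(rotation^2))
  if (abs(nrm - 1) > 1e-6) stop("rotation quaternion must have unit norm")
  if (length(translation) != 3 || anyNA(translation)) {
    stop("translation must be a length-3 numeric vector")
  }
  structure(list(rotation = rotation / nrm, translation = translation),
            class = "RigidTransform")
}

#' Inverse of a rigid transform
#' @param t a `RigidTransform`.
#' @export
transform_inverse <- function(t) {
  rigid_transform(quat_conjugate(t$rotation), -t$translation)
}

#' Apply a rigid transform to a component
#'
#' The rotation acts about the component centroid; the translation is applied
#' afterwards, so the centroid of the result equals `com + translation` and
#' the radius of gyration is unchanged.
#'
#' @param comp a `Component`.
#' @param t a `RigidTransform`.
#' @return a new `Component`.
#' @export
apply_transform <- function(comp, t) {
  if (!inherits(comp, "Component")) stop("comp must be a Component")
  if (!inherits(t, "RigidTransform")) stop("t must be a RigidTransform")
  xyz <- component_coords(comp)
  R <- quat_rotation_matrix(t$rotation)
  new_xyz <- sweep(sweep(xyz, 2, comp$com) %*% t(R), 2,
                   comp$com + t$translation, "+")
  atoms <- comp$atoms
  atoms$x <- new_xyz[, 1]; atoms$y <- new_xyz[, 2]; atoms$z <- new_xyz[, 3]
  # the backbone fallback (if any) was already reported at construction
  suppressMessages(new_component(comp$id, atoms))
}

# ---- quaternion library ----------------------------------------------------

#' Generate an approximately uniform library of rotations
#'
#' Quaternions are drawn uniformly on the unit 3-sphere (normalized 4D
#' Gaussians), which induces the uniform (Haar) distribution on the rotation
#' group. The library is indexed by the genetic algorithm's rotation genes.
#'
#' @param n number of quaternions (default 5000).
#' @param seed integer seed making the library reproducible.
#' @return object of class `QuaternionSet` with elements `quaternions`
#'   (n x 4 matrix, rows `(w, x, y, z)`) and `size`.
#' @export
generate_quaternion_set <- function(n = 5000, seed = 1) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  set.seed(seed)
  q <- matrix(rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  structure(list(quaternions = q, size = n, seed = seed),
            class = "QuaternionSet")
}

# ---- PDB I/O ---------------------------------------------------------------

#' Read assembly components from PDB files
#'
#' Hydrogens, HETATM records and alternate locations beyond the first are
#' dropped; only the first MODEL of a multi-model file is used.
#'
#' @param paths character vector of PDB file paths.
#' @param split_mode `"per-chain"` (one component per chain, ordered by file
#'   then chain ID) or `"per-file"` (one component per file).
#' @return list of `Component` objects.
#' @export
read_components <- function(paths, split_mode = c("per-chain", "per-file")) {
  split_mode <- match.arg(split_mode)
  comps <- list()
  for (path in paths) {
    pdb <- tryCatch(
      bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE, verbose = FALSE),
      error = function(e) stop("cannot read PDB file '", path, "': ",
                               conditionMessage(e), call. = FALSE))
    at <- pdb$atom
    at <- at[at$type == "ATOM", , drop = FALSE]
    elem <- at$elesy
    if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
      elem <- sub("^[0-9]*", "", at$elety)
      elem <- substr(elem, 1, 1)
    }
    keep <- !(toupper(trimws(elem)) %in% c("H", "D"))
    at <- at[keep, , drop = FALSE]
    elem <- trimws(elem[keep])
    if (nrow(at) == 0) stop("no heavy ATOM records in '", path, "'")
    tab <- data.frame(name = at$elety, resno = at$resno, resname = at$resid,
                      element = elem, x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
    base <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
    if (split_mode == "per-file") {
      if (!any(tab$name == "CA")) {
        stop("file '", path, "' contains no C-alpha atoms")
      }
      comps[[length(comps) + 1]] <- new_component(base, tab)
    } else {
      for (ch in sort(unique(at$chain))) {
        sub_tab <- tab[at$chain == ch, , drop = FALSE]
        if (!any(sub_tab$name == "CA")) {
          stop("chain '", ch, "' in '", path, "' contains no C-alpha atoms")
        }
        comps[[length(comps) + 1]] <- new_component(ch, sub_tab)
      }
    }
  }
  ids <- vapply(comps, function(x) x$id, character(1))
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids, sep = "_")
    comps <- Map(function(cmp, id) { cmp$id <- id; cmp }, comps, ids)
  }
  comps
}

#' Write an assembly model as a PDB file (one chain per component)
#'
#' @param components list of `Component` objects (with transforms applied).
#' @param path output PDB file.
#' @export
write_assembly_pdb <- function(components, path) {
  if (inherits(components, "Component")) components <- list(components)
  xyz <- NULL; resno <- c(); resid <- c(); elety <- c(); chain <- c(); elesy <- c()
  for (comp in components) {
    cc <- component_coords(comp)
    xyz <- rbind(xyz, cc)
    resno <- c(resno, comp$atoms$resno)
    resid <- c(resid, comp$atoms$resname)
    elety <- c(elety, comp$atoms$name)
    elesy <- c(elesy, comp$atoms$element)
    chain <- c(chain, rep(substr(comp$id, 1, 1), nrow(cc)))
  }
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)), resno = resno,
                   resid = resid, elety = elety, chain = chain, elesy = elesy,
                   eleno = seq_along(resno))
  invisible(path)
}
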