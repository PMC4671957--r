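# Accuracy metrics comparing a predicted assembly to its native reference:
# topology score, component/assembly placement scores, and permutation-aware
# C-alpha RMSD.

#' Topology score
#'
#' A predicted component counts as correctly placed when its centre of mass
#' lies within (inclusively) a sphere centred on the native component's
#' centre of mass with radius equal to the native radius of gyration. The
#' score is the fraction of correctly placed components.
#'
#' @param pred,native lists of `Component`s in corresponding order.
#' @return fraction in `[0, 1]`.
#' @export
topology_score <- function(pred, native) {
  if (inherits(pred, "Component")) pred <- list(pred)
  if (inherits(native, "Component")) native <- list(native)
  if (length(pred) != length(native)) {
    stop("predicted and native assemblies have different component counts")
  }
  ok <- mapply(function(p, n) {
    sqrt(sum((p$com - n$com)^2)) <= n$rgyr
  }, pred, native)
  mean(ok)
}

kabsch_rotation <- function(P, Q) {
  # optimal rotation R (P %*% t(R) ~ Q) for centred coordinate sets
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

rotation_angle_deg <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Component placement score (CPS)
#'
#' The translation (Angstroms) and rotation angle (degrees) needed to
#' superpose the predicted component onto its native counterpart: the
#' translation is the centre-of-mass displacement, and the rotation is the
#' angle of the optimal least-squares rotation aligning the centred
#' predicted C-alpha coordinates onto the centred native ones.
#'
#' @param pred_c,native_c `Component`s with identical C-alpha counts and
#'   ordering.
#' @return list with `translation` (Angstroms) and `rotation` (degrees,
#'   in `[0, 180]`).
#' @export
component_placement_score <- function(pred_c, native_c) {
  P <- calpha_coords(pred_c)
  Q <- calpha_coords(native_c)
  if (nrow(P) != nrow(Q) || nrow(P) == 0) {
    stop("components must have identical, non-empty C-alpha sets")
  }
  translation <- sqrt(sum((pred_c$com - native_c$com)^2))
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  R <- kabsch_rotation(Pc, Qc)
  list(translation = translation, rotation = rotation_angle_deg(R))
}

#' Assembly placement score (APS): average of the per-component CPS values
#' @param cps_list non-empty list of [component_placement_score()] results.
#' @export
assembly_placement_score <- function(cps_list) {
  if (length(cps_list) == 0) stop("empty placement-score list")
  list(translation = mean(vapply(cps_list, `[[`, numeric(1), "translation")),
       rotation = mean(vapply(cps_list, `[[`, numeric(1), "rotation")))
}

component_rmsd <- function(pred_c, native_c) {
  P <- calpha_coords(pred_c)
  Q <- calpha_coords(native_c)
  if (nrow(P) != nrow(Q)) stop("C-alpha count mismatch between components")
  sqrt(mean(rowSums((P - Q)^2)))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Detect groups of identical components (by C-alpha residue sequence)
#' @param components list of `Component`s.
#' @return list of integer index vectors partitioning the components.
#' @export
identical_component_groups <- function(components) {
  keys <- vapply(components, function(cm) {
    paste(cm$atoms$resname[cm$calpha_idx], collapse = "|")
  }, character(1))
  unname(split(seq_along(components), factor(keys, levels = unique(keys))))
}

#' Permutation-aware assembly RMSD
#'
#' Averages the per-component C-alpha RMSDs computed in the common map frame
#' (no re-superposition: for rigid components the RMSD measures placement
#' error, not conformational difference). For assemblies with identical
#' components, the correspondence between predicted and native copies is
#' chosen, by exhaustive enumeration within each identical group (group size
#' up to 8), to minimize the average RMSD.
#'
#' @param pred,native lists of `Component`s of equal length.
#' @param groups optional partition of component indices into groups of
#'   interchangeable (identical) components; detected from the C-alpha
#'   residue sequences when omitted.
#' @return list with `rmsd` (Angstroms), `correspondence` (integer vector:
#'   predicted component `i` is matched to native component
#'   `correspondence[i]`) and `per_component` RMSDs under that
#'   correspondence.
#' @export
assembly_rmsd <- function(pred, native, groups = NULL) {
  if (inherits(pred, "Component")) pred <- list(pred)
  if (inherits(native, "Component")) native <- list(native)
  n <- length(pred)
  if (length(native) != n) stop("component count mismatch")
  if (is.null(groups)) groups <- identical_component_groups(native)
  corr <- integer(n)
  for (grp in groups) {
    m <- length(grp)
    if (m == 1) { corr[grp] <- grp; next }
    if (m > 8) stop("identical groups larger than 8 are not supported")
    cost <- matrix(0, m, m)
    for (i in seq_len(m)) for (j in seq_len(m)) {
      cost[i, j] <- component_rmsd(pred[[grp[i]]], native[[grp[j]]])
    }
    perms <- all_permutations(m)
    totals <- apply(perms, 1, function(p) sum(cost[cbind(seq_len(m), p)]))
    corr[grp] <- grp[perms[which.min(totals), ]]
  }
  per <- vapply(seq_len(n), function(i) {
    component_rmsd(pred[[i]], native[[corr[i]]])
  }, numeric(1))
  list(rmsd = mean(per), correspondence = corr, per_component = per)
}

#' Full assessment of a predicted assembly against its native reference
#'
#' Resolves the component correspondence by minimizing the permutation-aware
#' RMSD first, then reports the topology score, per-component and assembly
#' placement scores and the RMSD under that correspondence.
#'
#' @inheritParams assembly_rmsd
#' @return object of class `assembly_assessment`.
#' @export
assess_assembly <- function(pred, native, groups = NULL) {
  ar <- assembly_rmsd(pred, native, groups)
  native_m <- native[ar$correspondence]
  cps <- Map(component_placement_score, pred, native_m)
  structure(list(
    ts = topology_score(pred, native_m),
    aps = assembly_placement_score(cps),
    per_component_cps = cps,
    rmsd = ar$rmsd,
    per_component_rmsd = ar$per_component,
    correspondence = ar$correspondence,
    component_ids = vapply(pred, function(x) x$id, character(1))),
    class = "assembly_assessment")
}

#' @export
print.assembly_assessment <- function(x, ...) {
  cat(sprintf("<Assessment: TS = %.2f, APS = (%.2f A, %.1f deg), RMSD = %.2f A>\n",
              x$ts, x$aps$translation, x$aps$rotation, x$rmsd))
  for (i in seq_along(x$per_component_cps)) {
    cps <- x$per_component_cps[[i]]
    cat(sprintf("  %s -> native %d: CPS (%.2f A, %.1f deg), RMSD %.2f A\n",
                x$component_ids[i], x$correspondence[i],
                cps$translation, cps$rotation, x$per_component_rmsd[i]))
  }
  invisible(x)
}
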