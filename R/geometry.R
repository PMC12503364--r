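## Core geometric computations on trajectories. All lengths in nm.

new_distance_trace <- function(label, times, values, equilibration_cutoff = 1.0) {
  stopifnot(length(times) == length(values))
  if (any(values < 0)) stop("distances cannot be negative")
  structure(list(label = label, times = times, values = values,
                 equilibration_cutoff = equilibration_cutoff),
            class = "DistanceTrace")
}

#' Analyzed view of a trace
#'
#' Frames at or after the equilibration cutoff (default 1 ns); all
#' event detection, averaging and maxima operate on this view.
#'
#' @param trace a `DistanceTrace`, `DisplacementTrace` or `SASATrace`.
#' @return list with `times` and `values`.
#' @export
analyzed_frames <- function(trace) {
  keep <- trace$times >= trace$equilibration_cutoff
  list(times = trace$times[keep], values = trace$values[keep])
}

#' @export
print.DistanceTrace <- function(x, ...) {
  cat("DistanceTrace", if (!is.null(x$label)) paste0("[", x$label, "]"), ":",
      length(x$times), "frames,",
      sprintf("mean %.3f nm (%.2f A)", mean(x$values), nm2ang(mean(x$values))),
      "\n")
  invisible(x)
}

#' Inter-atom distance trace
#'
#' Per-frame Euclidean distance between two atoms. No periodic-image
#' correction is applied unless an orthorhombic `box` is given:
#' intra-protein pairs in a typical solvated box never span an image,
#' so the plumbing stays simple and explicit.
#'
#' @param traj a `Trajectory`.
#' @param atom_a,atom_b atom indices (e.g. from [resolve_site()]).
#' @param label trace label for reports.
#' @param equilibration_cutoff ns excluded from analysis (default 1).
#' @param box optional length-3 orthorhombic box vector in nm enabling
#'   minimum-image distances.
#' @return A `DistanceTrace`.
#' @export
distance_trace <- function(traj, atom_a, atom_b, label = NULL,
                           equilibration_cutoff = 1.0, box = NULL) {
  stopifnot(inherits(traj, "Trajectory"))
  for (a in c(atom_a, atom_b))
    if (is.na(a) || a < 1L || a > traj$n_atoms)
      stop("unresolved atom index: ", a)
  d <- traj$xyz[, xyz_cols(atom_a), drop = FALSE] -
       traj$xyz[, xyz_cols(atom_b), drop = FALSE]
  if (!is.null(box)) {
    stopifnot(length(box) == 3L, all(box > 0))
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  }
  if (is.null(label)) {
    lab <- function(i) {
      at <- attributes(i)
      if (!is.null(at$chain)) paste0(at$chain, ":", at$resname, at$resno, ":", at$elety)
      else paste0("atom", as.integer(i))
    }
    label <- paste(lab(atom_a), "-", lab(atom_b))
  }
  new_distance_trace(label, traj$times, sqrt(rowSums(d^2)),
                     equilibration_cutoff)
}

#' Time-window mean of a distance trace
#'
#' Arithmetic mean over frames with `t_start <= t <= t_end`; the
#' default window 1-133 ns matches the analysis convention used for
#' per-replicate data points.
#'
#' @param trace a `DistanceTrace` (or any trace with times/values).
#' @param t_start,t_end window bounds, ns.
#' @return mean value (nm).
#' @export
mean_distance <- function(trace, t_start = 1, t_end = 133) {
  window_mean(trace$times, trace$values, t_start, t_end)
}

## ---- iron out-of-plane displacement -----------------------------------

## least-squares plane of a small point set: list(center, normal)
ls_plane <- function(pts) {
  ctr <- colMeans(pts)
  s <- svd(sweep(pts, 2, ctr))
  if (s$d[2] < 1e-8)
    stop("degenerate (collinear) point set; cannot fit a plane")
  list(center = ctr, normal = s$v[, 3])
}

#' Heme-iron out-of-plane displacement trace
#'
#' Per frame: the unweighted centroid C of the four pyrrole nitrogens
#' (all nitrogen, so mass weighting is a no-op), the point-to-point
#' distance |Fe - C| as the displacement magnitude, signed positive
#' when Fe lies on the proximal-histidine side of the least-squares
#' pyrrole-N plane. The perpendicular projection onto the plane normal
#' is also returned (`perpendicular`), but the reported `values` are
#' the signed |Fe - C| distance.
#'
#' @param traj a `Trajectory`.
#' @param heme a heme entry from the model (`model$hemes[[i]]`), or a
#'   chain id to look one up in `model`.
#' @param proximal_atom atom index of the proximal-side reference
#'   (typically HisF8 NE2) used to orient the sign.
#' @param model the `StructureModel` (required when `heme` is a chain id).
#' @param equilibration_cutoff ns excluded from analysis.
#' @return A `DisplacementTrace` with `values` (signed nm),
#'   `perpendicular` (signed nm) and `times`.
#' @export
iron_plane_displacement <- function(traj, heme, proximal_atom, model = NULL,
                                    equilibration_cutoff = 1.0) {
  if (is.character(heme)) {
    if (is.null(model)) stop("supply `model` when naming the heme by chain")
    heme <- heme_for_chain(model, heme)
  }
  stopifnot(length(heme$pyrrole) == 4L, length(heme$fe) == 1L)
  n <- traj$n_frames
  vals <- numeric(n); perp <- numeric(n)
  for (f in seq_len(n)) {
    npts <- frame_coords(traj, f, heme$pyrrole)
    fe <- frame_coords(traj, f, heme$fe)[1, ]
    prox <- frame_coords(traj, f, as.integer(proximal_atom))[1, ]
    pl <- ls_plane(npts)
    ctr <- colMeans(npts)
    side_fe <- sum((fe - pl$center) * pl$normal)
    side_prox <- sum((prox - pl$center) * pl$normal)
    sgn <- if (side_fe == 0) 0 else sign(side_fe) * sign(side_prox)
    if (sgn == 0) sgn <- 1
    vals[f] <- sgn * sqrt(sum((fe - ctr)^2))
    perp[f] <- side_fe * sign(side_prox)
  }
  structure(list(label = "Fe out-of-plane displacement",
                 times = traj$times, values = vals, perpendicular = perp,
                 equilibration_cutoff = equilibration_cutoff),
            class = "DisplacementTrace")
}

#' @export
print.DisplacementTrace <- function(x, ...) {
  cat("DisplacementTrace:", length(x$times), "frames,",
      sprintf("mean %+.4f nm", mean(x$values)), "\n")
  invisible(x)
}

## ---- Kabsch superposition RMSD ----------------------------------------

## optimal proper rotation R such that P %*% R best matches Q (both
## centered), via SVD of the covariance; reflection excluded
kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)              # 3x3
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' RMSD after optimal rigid superposition (Kabsch)
#'
#' Least-squares superposition (proper rotation + translation, no
#' reflection) of `frame` onto `reference` over `selection`, then the
#' root-mean-square deviation over that same selection.
#'
#' @param reference,frame n x 3 coordinate matrices (nm), or
#'   `Trajectory` frame blocks.
#' @param selection optional integer rows used both to fit and to
#'   score (default: all rows).
#' @return RMSD in nm.
#' @export
kabsch_rmsd <- function(reference, frame, selection = NULL) {
  R <- as.matrix(reference); Fm <- as.matrix(frame)
  if (!is.null(selection)) {
    R <- R[selection, , drop = FALSE]
    Fm <- Fm[selection, , drop = FALSE]
  }
  if (nrow(R) != nrow(Fm)) stop("mismatched atom sets")
  if (nrow(R) < 3L) stop("selection must contain at least 3 atoms")
  Rc <- sweep(R, 2, colMeans(R))
  Fc <- sweep(Fm, 2, colMeans(Fm))
  U <- kabsch_rotation(Fc, Rc)
  fit <- Fc %*% U
  sqrt(mean(rowSums((fit - Rc)^2)))
}

#' Per-frame RMSD trace against a reference frame
#'
#' [kabsch_rmsd()] of every frame against `reference_frame`, with the
#' superposition computed on the analysis selection itself (the local
#' interface convention), not the whole backbone.
#'
#' @param traj a `Trajectory`.
#' @param selection integer atom indices.
#' @param reference_frame frame index used as reference (default 1).
#' @param equilibration_cutoff ns excluded from analysis.
#' @return A `DistanceTrace` holding RMSD values (nm).
#' @export
rmsd_trace <- function(traj, selection, reference_frame = 1L,
                       equilibration_cutoff = 1.0) {
  if (reference_frame < 1L || reference_frame > traj$n_frames)
    stop("reference frame ", reference_frame, " does not exist")
  ref <- frame_coords(traj, reference_frame, selection)
  vals <- vapply(seq_len(traj$n_frames), function(f)
    kabsch_rmsd(ref, frame_coords(traj, f, selection)), numeric(1))
  new_distance_trace(sprintf("RMSD vs frame %d (%d atoms)",
                             reference_frame, length(selection)),
                     traj$times, vals, equilibration_cutoff)
}

## ---- aromatic stacking geometry ---------------------------------------

#' Ring-ring stacking geometry and classification
#'
#' Centroid distance, interplanar angle (folded to <= 90 deg) and
#' lateral centroid offset of two aromatic rings, classified as
#' parallel-displaced (angle < `pd_angle`, distance < `pd_dist`),
#' T-shaped (angle > `t_angle`, distance < `t_dist`) or none. Default
#' cutoffs 5.5 / 6.0 Angstrom and 30 / 60 degrees are package defaults
#' (configurable), in line with common stacking surveys.
#'
#' @param ring_a,ring_b >= 5 x 3 coordinate matrices (nm) of ring
#'   atoms; each ring must be approximately planar (RMS out-of-plane
#'   < 0.03 nm).
#' @param pd_dist,t_dist,pd_angle,t_angle classification cutoffs
#'   (nm, nm, degrees, degrees).
#' @return list of class `StackingGeometry`: `centroid_distance` (nm),
#'   `centroid_distance_ang`, `interplanar_angle` (deg), `offset` (nm),
#'   `offset_ang`, `class`.
#' @export
stacking_geometry <- function(ring_a, ring_b,
                              pd_dist = 0.55, t_dist = 0.60,
                              pd_angle = 30, t_angle = 60) {
  ring_a <- as.matrix(ring_a); ring_b <- as.matrix(ring_b)
  if (nrow(ring_a) < 5L || nrow(ring_b) < 5L)
    stop("each ring needs at least 5 atoms")
  pa <- ls_plane(ring_a); pb <- ls_plane(ring_b)
  for (nm_ in list(list(ring_a, pa), list(ring_b, pb))) {
    oop <- as.vector(sweep(nm_[[1]], 2, nm_[[2]]$center) %*% nm_[[2]]$normal)
    if (sqrt(mean(oop^2)) >= 0.03)
      stop("ring is not planar (RMS out-of-plane >= 0.03 nm)")
  }
  dvec <- pb$center - pa$center
  dist <- sqrt(sum(dvec^2))
  cosang <- abs(sum(pa$normal * pb$normal))
  angle <- acos(min(1, cosang)) * 180 / pi
  dz <- abs(sum(dvec * pa$normal))
  offset <- sqrt(max(0, dist^2 - dz^2))
  cls <- if (angle < pd_angle && dist < pd_dist) "parallel-displaced"
         else if (angle > t_angle && dist < t_dist) "T-shaped"
         else "none"
  structure(list(centroid_distance = dist,
                 centroid_distance_ang = nm2ang(dist),
                 interplanar_angle = angle,
                 offset = offset, offset_ang = nm2ang(offset),
                 class = cls),
            class = "StackingGeometry")
}

#' @export
print.StackingGeometry <- function(x, ...) {
  cat(sprintf("Stacking: %s  (d = %.2f A, angle = %.1f deg, offset = %.2f A)\n",
              x$class, x$centroid_distance_ang, x$interplanar_angle,
              x$offset_ang))
  invisible(x)
}
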