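## Shrake-Rupley solvent-accessible surface area. Lengths nm, areas nm^2.

## Bondi van der Waals radii (nm) keyed by element. Fe has no Bondi
## value; 0.200 nm is the conventional choice for heme iron in SASA
## work and is configurable via `custom`.
BONDI_RADII <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152,
                 S = 0.180, P = 0.180, FE = 0.200)

#' SASA parameters
#'
#' @param probe_radius solvent probe radius, nm (default 0.14, a water
#'   probe).
#' @param n_sphere_points quasi-uniform test points per atom sphere
#'   (default 960; >= 24).
#' @param radii_set name of the van der Waals radius table (only
#'   `"bondi"` ships; supply `custom` to override, e.g. with a GROMACS
#'   table).
#' @param custom optional named vector of radii (nm) by element,
#'   overriding/extending the table.
#' @return list of class `SASAParams`.
#' @export
sasa_params <- function(probe_radius = 0.14, n_sphere_points = 960L,
                        radii_set = "bondi", custom = NULL) {
  if (probe_radius <= 0) stop("probe_radius must be positive")
  if (n_sphere_points < 24L) stop("n_sphere_points must be >= 24")
  if (radii_set != "bondi") stop("unknown radii set: ", radii_set)
  radii <- BONDI_RADII
  if (!is.null(custom)) radii[names(custom)] <- custom
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 radii_set = radii_set, radii = radii),
            class = "SASAParams")
}

## Element guess from a PDB atom name: two-letter elements first (FE),
## else first alphabetic character.
atom_element <- function(elety) {
  up <- toupper(elety)
  el <- ifelse(substr(up, 1, 2) == "FE", "FE",
               substr(gsub("[^A-Z]", "", up), 1, 1))
  el[el == ""] <- NA_character_
  el
}

#' Van der Waals radii for atom names
#'
#' @param elety character vector of atom names.
#' @param params a `SASAParams`.
#' @return numeric vector of radii (nm); errors if any element lacks a
#'   tabulated radius.
#' @export
vdw_radii <- function(elety, params = sasa_params()) {
  el <- atom_element(elety)
  r <- params$radii[el]
  bad <- is.na(r)
  if (any(bad))
    stop("no van der Waals radius for atom(s): ",
         paste(unique(elety[bad]), collapse = ", "))
  unname(r)
}

## quasi-uniform unit-sphere points (golden-spiral / Fibonacci lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley per-atom solvent-accessible surface area
#'
#' For each target atom, the fraction of quasi-uniform points on its
#' expanded sphere (radius r_vdw + probe) not occluded by any other
#' atom's expanded sphere, times the expanded-sphere area.
#'
#' @param coords n x 3 coordinate matrix (nm).
#' @param radii per-atom van der Waals radii (nm), length n.
#' @param target integer indices of atoms whose area is wanted
#'   (default: all).
#' @param context integer indices of atoms that occlude (default: all).
#'   Target atoms always occlude each other.
#' @param params a `SASAParams`.
#' @return numeric vector, one area (nm^2) per target atom.
#' @export
shrake_rupley <- function(coords, radii, target = NULL, context = NULL,
                          params = sasa_params()) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(length(radii) == n)
  target <- if (is.null(target)) seq_len(n) else as.integer(target)
  context <- if (is.null(context)) seq_len(n) else
    unique(c(as.integer(context), target))
  w <- params$probe_radius
  pts <- sphere_points(params$n_sphere_points)
  exp_r <- radii + w
  out <- numeric(length(target))
  cxy <- coords[context, , drop = FALSE]
  crad <- exp_r[context]
  for (k in seq_along(target)) {
    i <- target[k]
    ri <- exp_r[i]
    dv <- sweep(cxy, 2, coords[i, ])
    d2 <- rowSums(dv^2)
    near <- which(d2 < (ri + crad)^2 & d2 > 1e-12)
    area1 <- 4 * pi * ri^2
    if (!length(near)) { out[k] <- area1; next }
    sp <- pts * ri                       # points relative to atom centre
    free <- rep(TRUE, nrow(sp))
    for (j in near) {
      if (!any(free)) break
      dd <- sweep(sp[free, , drop = FALSE], 2, dv[j, ])
      free[free] <- rowSums(dd^2) >= crad[j]^2
    }
    out[k] <- area1 * sum(free) / nrow(sp)
  }
  out
}

new_sasa_trace <- function(label, times, values, equilibration_cutoff, params) {
  structure(list(target_label = label, label = label, times = times,
                 values = values, equilibration_cutoff = equilibration_cutoff,
                 params = params),
            class = "SASATrace")
}

#' @export
print.SASATrace <- function(x, ...) {
  cat("SASATrace [", x$target_label, "]: ", length(x$times), " frames, mean ",
      sprintf("%.3f nm^2", mean(x$values)), "\n", sep = "")
  invisible(x)
}

## context = everything except solvent/ions: protein + heme (+ any
## synthetic occluders), mirroring an index of heme atoms with protein
## atoms.
sasa_context <- function(model) {
  which(!(model$atoms$resname %in% SOLVENT_RESNAMES))
}

sasa_trace_impl <- function(traj, model, target_idx, label, params,
                            equilibration_cutoff) {
  ctx <- sasa_context(model)
  radii <- vdw_radii(model$atoms$elety, params)
  vals <- vapply(seq_len(traj$n_frames), function(f) {
    co <- frame_coords(traj, f)
    sum(shrake_rupley(co, radii, target = target_idx, context = ctx,
                      params = params))
  }, numeric(1))
  new_sasa_trace(label, traj$times, vals, equilibration_cutoff, params)
}

#' Per-frame SASA trace of a mapped residue
#'
#' Sum of atomwise Shrake-Rupley areas over the residue's atoms,
#' computed in the context of all non-solvent atoms (protein + heme;
#' waters and ions excluded).
#'
#' @param traj a `Trajectory`.
#' @param model a `StructureModel`.
#' @param map a `SiteMap`.
#' @param subunit,site,chain residue addressed in helical notation
#'   (default site `"E11"`).
#' @param params a `SASAParams`.
#' @param equilibration_cutoff ns excluded from analysis.
#' @return A `SASATrace` (values nm^2).
#' @export
residue_sasa_trace <- function(traj, model, map, subunit = "alpha",
                               site = "E11", chain = NULL,
                               params = sasa_params(),
                               equilibration_cutoff = 1.0) {
  idx <- resolve_residue(model, map, subunit, site, chain)
  lab <- sprintf("SASA %s/%s chain %s", subunit, site,
                 model$atoms$chain[idx[1]])
  sasa_trace_impl(traj, model, idx, lab, params, equilibration_cutoff)
}

#' Per-frame SASA trace of a heme group
#'
#' @inheritParams residue_sasa_trace
#' @param chain chain id whose heme group is the target.
#' @return A `SASATrace` (values nm^2).
#' @export
heme_sasa_trace <- function(traj, model, chain, params = sasa_params(),
                            equilibration_cutoff = 1.0) {
  h <- heme_for_chain(model, chain)
  idx <- model$atoms$index[model$atoms$chain == chain &
                           model$atoms$resno == h$resno &
                           model$atoms$resname %in% c("HEM", "HEME")]
  sasa_trace_impl(traj, model, idx, sprintf("SASA heme chain %s", chain),
                  params, equilibration_cutoff)
}

#' Time-window mean SASA
#'
#' Same averaging contract as [mean_distance()]: arithmetic mean over
#' frames with `t_start <= t <= t_end` (default 1-133 ns).
#'
#' @param trace a `SASATrace`.
#' @param t_start,t_end window bounds, ns.
#' @return mean area (nm^2).
#' @export
mean_sasa <- function(trace, t_start = 1, t_end = 133) {
  window_mean(trace$times, trace$values, t_start, t_end)
}
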