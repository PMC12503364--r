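## alpha1-beta2 interface contact analysis: canonical site definitions,
## per-site distance traces and per-replicate maxima, local backbone
## RMSD of the interface residues, and its linear drift.

#' Canonical alpha1-beta2 interface contact sites
#'
#' The four atom-pair contacts tracked across the alpha1-beta2
#' interface. Sites A-C apply to both species; site D (the Thr
#' alpha1C6 hydroxyl to Arg beta2C6 guanidinium hydrogen bond) exists
#' in bovine only - trout substitutes Ala at alpha1C6, removing it.
#' `fig_site` gives the 3-site numbering used in interspecies
#' comparisons (the bovine-only pair is reported alongside site 2,
#' which shares the Arg beta2C6 guanidinium).
#'
#' @return data.frame with columns `site_id`, `fig_site`,
#'   `alpha_site`, `alpha_resname`, `alpha_atom`, `beta_site`,
#'   `beta_resname`, `beta_atom`, `interaction_class`, `species`.
#' @export
interface_sites <- function() {
  data.frame(
    site_id = c("A", "B", "C", "D"),
    fig_site = c(1L, 2L, 3L, 2L),
    alpha_site = c("G1", "C7", "FG4", "C6"),
    alpha_resname = c("ASP", "TYR", "ARG", "THR"),
    alpha_atom = c("CG", "CZ", "CD", "OG"),
    beta_site = c("G4", "C6", "C6", "C6"),
    beta_resname = c("ASN", "ARG", "ARG", "ARG"),
    beta_atom = c("ND2", "CZ", "CB", "CZ"),
    interaction_class = c("hydrogen-bond", "stacking", "stacking",
                          "hydrogen-bond"),
    species = c("both", "both", "both", "bovine-only"),
    stringsAsFactors = FALSE)
}

site_row <- function(site_id) {
  tbl <- interface_sites()
  row <- tbl[tbl$site_id == site_id, , drop = FALSE]
  if (!nrow(row)) stop("unknown interface site: ", site_id,
                       " (known: ", paste(tbl$site_id, collapse = ", "), ")")
  row
}

## does the map carry this site with the canonical residue identities?
site_applicable <- function(map, row) {
  a <- map$sites$alpha[[row$alpha_site]]
  b <- map$sites$beta[[row$beta_site]]
  !is.null(a) && !is.null(b) &&
    (is.null(a$resname) || a$resname == row$alpha_resname) &&
    (is.null(b$resname) || b$resname == row$beta_resname)
}

#' Interface sites applicable under a site map
#'
#' @param map a `SiteMap`.
#' @return character vector of applicable `site_id`s (4 for a
#'   bovine-style map, 3 for a trout-style map lacking Thr alpha1C6).
#' @export
applicable_sites <- function(map) {
  tbl <- interface_sites()
  tbl$site_id[vapply(seq_len(nrow(tbl)),
                     function(i) site_applicable(map, tbl[i, ]), logical(1))]
}

#' Distance trace of one interface contact site
#'
#' Per-frame distance between the two atoms of a canonical interface
#' site, for a given alpha1/beta2 chain pairing. A site that does not
#' exist for the mapped species (e.g. the bovine-only Thr/Arg hydrogen
#' bond under a trout-style map) is rejected with an applicability
#' error.
#'
#' @param traj a `Trajectory`.
#' @param model a `StructureModel`.
#' @param map a `SiteMap`.
#' @param site_id one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param alpha_chain,beta_chain the chain ids forming the alpha1-beta2
#'   pair under analysis.
#' @param equilibration_cutoff ns excluded from analysis.
#' @return A `DistanceTrace`.
#' @export
site_distance_trace <- function(traj, model, map, site_id,
                                alpha_chain = NULL, beta_chain = NULL,
                                equilibration_cutoff = 1.0) {
  row <- site_row(site_id)
  if (!site_applicable(map, row))
    stop("interface site ", site_id, " (", row$alpha_resname, " alpha1",
         row$alpha_site, " - ", row$beta_resname, " beta2", row$beta_site,
         ") is not applicable to species ", map$species)
  a <- resolve_site(model, map, "alpha", row$alpha_site, row$alpha_atom,
                    chain = alpha_chain)
  b <- resolve_site(model, map, "beta", row$beta_site, row$beta_atom,
                    chain = beta_chain)
  tr <- distance_trace(traj, a, b,
                       label = sprintf("site %s (fig site %d): %s - %s",
                                       row$site_id, row$fig_site,
                                       paste0("a1", row$alpha_site, ":", row$alpha_atom),
                                       paste0("b2", row$beta_site, ":", row$beta_atom)),
                       equilibration_cutoff = equilibration_cutoff)
  tr
}

#' Maximum interface-site distance over analyzed frames
#'
#' The per-replicate statistic for interface-site comparisons: the
#' maximum recorded distance over the analyzed portion of the
#' simulation (t >= equilibration cutoff).
#'
#' @param trace a `DistanceTrace`.
#' @return maximum distance, nm.
#' @export
max_site_distance <- function(trace) {
  av <- analyzed_frames(trace)
  if (!length(av$values)) stop("empty analyzed trace")
  max(av$values)
}

#' Backbone selection of the interface residues
#'
#' Atom indices of the backbone atoms (default N, CA, O) of the six
#' interface residues alpha1 C6/C7/FG4/G1 and beta2 C6/G4 for one
#' chain pairing. The selection defines both the superposition and the
#' scored atoms of the local interface RMSD.
#'
#' @param model a `StructureModel`.
#' @param map a `SiteMap`.
#' @param alpha_chain,beta_chain chain ids of the pairing.
#' @param backbone_atoms atom names included (default `N`, `CA`, `O`).
#' @param expected_n optional atom count to validate against (errors on
#'   mismatch).
#' @return integer vector of atom indices.
#' @export
interface_selection <- function(model, map, alpha_chain = NULL,
                                beta_chain = NULL,
                                backbone_atoms = c("N", "CA", "O"),
                                expected_n = NULL) {
  res <- list(alpha = c("C6", "C7", "FG4", "G1"), beta = c("C6", "G4"))
  chains <- list(alpha = alpha_chain, beta = beta_chain)
  idx <- integer(0)
  for (cls in names(res)) for (s in res[[cls]]) {
    if (is.null(map$sites[[cls]][[s]])) next
    ri <- resolve_residue(model, map, cls, s, chain = chains[[cls]])
    keep <- ri[model$atoms$elety[ri] %in% backbone_atoms]
    idx <- c(idx, keep)
  }
  if (!is.null(expected_n) && length(idx) != expected_n)
    stop("interface selection has ", length(idx), " atoms, expected ",
         expected_n)
  idx
}

#' Linear drift of the local interface RMSD
#'
#' Computes the per-frame interface RMSD against a reference frame
#' (superposed on the selection itself) and fits an ordinary
#' least-squares line over the analysis window (default 1-133 ns). The
#' slope is the interface's drift rate in nm/ns.
#'
#' @param traj a `Trajectory`.
#' @param selection atom indices (from [interface_selection()]).
#' @param reference_frame frame index of the reference (default 1).
#' @param t_start,t_end regression window, ns.
#' @return list with `slope` (nm/ns), `intercept` (nm), `r_squared`,
#'   `n_frames`, and the underlying `trace`.
#' @export
interface_rmsd_slope <- function(traj, selection, reference_frame = 1L,
                                 t_start = 1, t_end = 133) {
  tr <- rmsd_trace(traj, selection, reference_frame,
                   equilibration_cutoff = t_start)
  keep <- tr$times >= t_start & tr$times <= t_end
  if (sum(keep) < 3L) stop("fewer than 3 frames in the regression window")
  fit <- simple_linear_regression(tr$times[keep], tr$values[keep])
  list(slope = fit$slope, intercept = fit$intercept,
       r_squared = fit$r_squared, n_frames = sum(keep), trace = tr)
}
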