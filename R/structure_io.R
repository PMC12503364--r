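## Structure and trajectory I/O: PDB topologies, site maps in Perutz
## helical notation, DCD / multi-model-PDB trajectories, TSV export.

SOLVENT_RESNAMES <- c("HOH", "WAT", "SOL", "TIP3", "TIP4", "SPC",
                      "NA", "CL", "K", "MG", "ZN", "CA2", "SOD", "CLA", "POT")

#' Build a structure model from an atom table
#'
#' Assembles the package's structure container from a table of atoms,
#' detecting heme groups by residue name and identifying the iron and
#' the four pyrrole nitrogens by atom name. Used by [read_structure()]
#' and by the synthetic-system generator.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`,
#'   `elety` (atom name) and `x`, `y`, `z` coordinates in nm.
#' @param chain_classes named character vector mapping chain ids to
#'   `"alpha"` or `"beta"`; chains not named are left unclassified.
#' @param heme_resnames,fe_names,pyrrole_names residue/atom name sets
#'   used for heme detection; defaults cover the PDB and CHARMM
#'   dialects (`HEM`/`HEME`, `FE`, `NA`/`NB`/`NC`/`ND`).
#' @return An object of class `StructureModel`: list with `atoms`
#'   (the validated table plus an `index` column), `chains`
#'   (chain_id, subunit_class) and `hemes` (one entry per heme group
#'   holding the chain id, the Fe atom index and the 4 pyrrole-N
#'   indices).
#' @export
structure_model <- function(atoms, chain_classes = NULL,
                            heme_resnames = c("HEM", "HEME"),
                            fe_names = "FE",
                            pyrrole_names = c("NA", "NB", "NC", "ND")) {
  need <- c("chain", "resno", "resname", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$index <- seq_len(nrow(atoms))

  chain_ids <- unique(atoms$chain)
  classes <- rep(NA_character_, length(chain_ids))
  names(classes) <- chain_ids
  if (!is.null(chain_classes)) {
    bad <- setdiff(names(chain_classes), chain_ids)
    if (length(bad)) stop("chain_classes names chains absent from structure: ",
                          paste(bad, collapse = ", "))
    ok <- chain_classes %in% c("alpha", "beta")
    if (!all(ok)) stop("subunit classes must be 'alpha' or 'beta'")
    classes[names(chain_classes)] <- chain_classes
  }

  hemes <- list()
  hsel <- atoms$resname %in% heme_resnames
  if (any(hsel)) {
    key <- paste(atoms$chain[hsel], atoms$resno[hsel])
    for (k in unique(key)) {
      rows <- atoms[hsel, ][key == k, , drop = FALSE]
      ch <- rows$chain[1]
      fe <- rows$index[rows$elety %in% fe_names]
      pyr <- rows$index[rows$elety %in% pyrrole_names]
      if (length(fe) != 1L)
        stop("heme in chain ", ch, " has ", length(fe),
             " Fe atoms (expected exactly 1; atom names tried: ",
             paste(fe_names, collapse = ", "), ")")
      if (length(pyr) != 4L)
        stop("heme in chain ", ch, " has ", length(pyr),
             " pyrrole nitrogens (expected exactly 4)")
      hemes[[length(hemes) + 1L]] <- list(chain = ch, resno = rows$resno[1],
                                          fe = fe, pyrrole = pyr)
    }
  }

  structure(list(
    atoms = atoms,
    chains = data.frame(chain_id = chain_ids,
                        subunit_class = unname(classes[chain_ids]),
                        stringsAsFactors = FALSE),
    hemes = hemes
  ), class = "StructureModel")
}

#' Read a PDB structure into a StructureModel
#'
#' Parses a PDB file (via bio3d), converts coordinates to nm, and
#' auto-detects heme groups from HETATM residue names. Atom identity is
#' keyed on (chain, residue number, atom name); element columns are not
#' required.
#'
#' @param path PDB file.
#' @param chain_classes optional named vector of `"alpha"`/`"beta"`
#'   per chain id. Usually supplied implicitly by the site map at
#'   resolution time instead.
#' @inheritParams structure_model
#' @return A `StructureModel` (first MODEL only; use
#'   [read_trajectory()] for multi-model files).
#' @export
read_structure <- function(path, chain_classes = NULL,
                           heme_resnames = c("HEM", "HEME"),
                           fe_names = "FE",
                           pyrrole_names = c("NA", "NB", "NC", "ND")) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(chain = as.character(a$chain),
                      resno = as.integer(a$resno),
                      resname = as.character(a$resid),
                      elety = as.character(a$elety),
                      x = ang2nm(a$x), y = ang2nm(a$y), z = ang2nm(a$z),
                      stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "
  structure_model(atoms, chain_classes = chain_classes,
                  heme_resnames = heme_resnames, fe_names = fe_names,
                  pyrrole_names = pyrrole_names)
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel:", nrow(x$atoms), "atoms,",
      nrow(x$chains), "chains,", length(x$hemes), "heme group(s)\n")
  cls <- x$chains$subunit_class
  cat("  chains:", paste0(x$chains$chain_id,
      ifelse(is.na(cls), "", paste0(" (", cls, ")")), collapse = ", "), "\n")
  invisible(x)
}

## ---- site maps -------------------------------------------------------

#' Read a helical-notation site map
#'
#' A site map assigns Perutz helical sites (E7, F8, E11, CE4, C6, C7,
#' FG4, G1, G4, ...) to concrete residue numbers per subunit class, and
#' declares the subunit class (alpha/beta) of each chain. Supplied as a
#' YAML file with top-level keys `species`, `chains` (chain id ->
#' class) and `sites` (class -> site -> `{resid, resname}`).
#'
#' @param path YAML file.
#' @return An object of class `SiteMap`.
#' @export
read_site_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  site_map(species = y$species %||% "unknown",
           chains = unlist(y$chains),
           sites = y$sites)
}

#' Construct a site map in code
#'
#' @param species free-text species / model label.
#' @param chains named character vector: chain id -> "alpha"/"beta".
#' @param sites nested list: `sites$alpha$E7 = list(resid=, resname=)`
#'   etc. `resname` is optional but, when given, is validated against
#'   the structure at resolution time.
#' @return A `SiteMap`.
#' @export
site_map <- function(species, chains, sites) {
  if (!all(chains %in% c("alpha", "beta")))
    stop("chain classes must be 'alpha' or 'beta'")
  for (cls in names(sites)) {
    if (!cls %in% c("alpha", "beta"))
      stop("unknown subunit class in site map: ", cls)
    for (s in names(sites[[cls]])) {
      e <- sites[[cls]][[s]]
      if (is.null(e$resid)) stop("site ", cls, "/", s, " lacks a resid")
    }
  }
  structure(list(species = species, chains = chains, sites = sites),
            class = "SiteMap")
}

#' Write a site map to YAML
#' @param map a `SiteMap`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_site_map <- function(map, path) {
  stopifnot(inherits(map, "SiteMap"))
  yaml::write_yaml(list(species = map$species,
                        chains = as.list(map$chains),
                        sites = map$sites), path)
  invisible(path)
}

#' @export
print.SiteMap <- function(x, ...) {
  cat("SiteMap for", x$species, "\n")
  cat("  chains:", paste(names(x$chains), x$chains, sep = "=", collapse = ", "), "\n")
  for (cls in names(x$sites))
    cat("  ", cls, ": ", paste(names(x$sites[[cls]]), collapse = " "), "\n", sep = "")
  invisible(x)
}

## chains of a given subunit class according to the map, restricted to
## chains present in the model
map_chains <- function(model, map, subunit) {
  ch <- names(map$chains)[map$chains == subunit]
  ch[ch %in% model$chains$chain_id]
}

#' Resolve a helical site to a concrete atom
#'
#' Looks up `(subunit, site)` in the site map, finds that residue in
#' the requested chain, validates the residue name against the map's
#' expectation (failing loudly on mismatch, e.g. a map expecting
#' TrpCE4 applied to a structure with PheCE4), and returns the named
#' atom.
#'
#' @param model a `StructureModel`.
#' @param map a `SiteMap`.
#' @param subunit `"alpha"` or `"beta"`.
#' @param site helical site label, e.g. `"E7"`.
#' @param atom_name atom name within the residue, e.g. `"NE2"`.
#' @param chain chain id; may be omitted when exactly one chain of the
#'   class exists in the structure.
#' @return An integer atom index into `model$atoms` with attributes
#'   `chain`, `resno`, `resname`, `elety` (class `atom_ref`).
#' @export
resolve_site <- function(model, map, subunit, site, atom_name, chain = NULL) {
  stopifnot(inherits(model, "StructureModel"), inherits(map, "SiteMap"))
  entry <- map$sites[[subunit]][[site]]
  if (is.null(entry))
    stop("site ", subunit, "/", site, " is not mapped for species ", map$species)
  chains <- map_chains(model, map, subunit)
  if (is.null(chain)) {
    if (length(chains) != 1L)
      stop("structure has ", length(chains), " ", subunit,
           " chains; specify `chain` explicitly")
    chain <- chains
  } else if (!chain %in% chains) {
    stop("chain ", chain, " is not a ", subunit, " chain under this map")
  }
  rows <- model$atoms[model$atoms$chain == chain &
                      model$atoms$resno == entry$resid, , drop = FALSE]
  if (!nrow(rows))
    stop("residue ", entry$resid, " not found in chain ", chain)
  if (!is.null(entry$resname) && !all(rows$resname == entry$resname))
    stop("residue-name mismatch at ", subunit, "/", site, " chain ", chain,
         ": map expects ", entry$resname, " but structure has ",
         rows$resname[1])
  hit <- rows[rows$elety == atom_name, , drop = FALSE]
  if (nrow(hit) != 1L)
    stop("atom ", atom_name, " ", if (nrow(hit)) "not unique" else "absent",
         " in ", rows$resname[1], entry$resid, " of chain ", chain)
  structure(hit$index,
            chain = chain, resno = entry$resid, resname = hit$resname,
            elety = atom_name, class = "atom_ref")
}

#' Atom indices of a mapped residue
#'
#' All atoms of the residue that `(subunit, site)` maps to in `chain`.
#' @inheritParams resolve_site
#' @return Integer vector of atom indices.
#' @export
resolve_residue <- function(model, map, subunit, site, chain = NULL) {
  entry <- map$sites[[subunit]][[site]]
  if (is.null(entry))
    stop("site ", subunit, "/", site, " is not mapped for species ", map$species)
  chains <- map_chains(model, map, subunit)
  if (is.null(chain)) {
    if (length(chains) != 1L)
      stop("structure has ", length(chains), " ", subunit,
           " chains; specify `chain` explicitly")
    chain <- chains
  }
  rows <- model$atoms[model$atoms$chain == chain &
                      model$atoms$resno == entry$resid, , drop = FALSE]
  if (!nrow(rows)) stop("residue ", entry$resid, " not found in chain ", chain)
  if (!is.null(entry$resname) && !all(rows$resname == entry$resname))
    stop("residue-name mismatch at ", subunit, "/", site, " chain ", chain,
         ": map expects ", entry$resname, " but structure has ", rows$resname[1])
  rows$index
}

## heme entry for a chain
heme_for_chain <- function(model, chain) {
  for (h in model$hemes) if (h$chain == chain) return(h)
  stop("no heme group in chain ", chain)
}

## ---- trajectories ----------------------------------------------------

new_trajectory <- function(xyz, times, frame_spacing) {
  stopifnot(is.matrix(xyz), nrow(xyz) == length(times))
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(xyz = xyz, times = times,
                 n_frames = nrow(xyz), n_atoms = ncol(xyz) %/% 3L,
                 frame_spacing = frame_spacing),
            class = "Trajectory")
}

#' Read a coordinate trajectory
#'
#' Reads a DCD or multi-model PDB trajectory against a topology,
#' converting coordinates to nm. Frame times are synthesized from
#' `frame_spacing` starting at `t0` (trajectory formats here carry no
#' reliable physical clock).
#'
#' @param model the topology `StructureModel`; the frame atom count
#'   must match.
#' @param path trajectory file (`.dcd`, or `.pdb` with MODEL records).
#' @param frame_spacing ns between frames (default 0.2).
#' @param t0 time of the first frame, ns.
#' @return A `Trajectory`: frames x (3 x n_atoms) coordinate matrix in
#'   nm plus times.
#' @export
read_trajectory <- function(model, path, frame_spacing = 0.2, t0 = 0) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  xyz <- switch(ext,
    dcd = bio3d::read.dcd(path, verbose = FALSE),
    pdb = ,
    ent = {
      p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
      p$xyz
    },
    stop("unsupported trajectory format: .", ext,
         " (supported: DCD, multi-model PDB)")
  )
  xyz <- as.matrix(xyz) * NM_PER_ANGSTROM
  if (ncol(xyz) != 3L * nrow(model$atoms))
    stop("atom-count mismatch: trajectory has ", ncol(xyz) %/% 3L,
         " atoms, topology has ", nrow(model$atoms))
  times <- t0 + frame_spacing * (seq_len(nrow(xyz)) - 1L)
  new_trajectory(xyz, times, frame_spacing)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param model topology `StructureModel`.
#' @param traj a `Trajectory`, or a frames x 3N coordinate matrix (nm).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(model, traj, path) {
  xyz <- if (inherits(traj, "Trajectory")) traj$xyz else as.matrix(traj)
  if (ncol(xyz) != 3L * nrow(model$atoms))
    stop("atom-count mismatch between coordinates and topology")
  a <- model$atoms
  bio3d::write.pdb(file = path, xyz = nm2ang(xyz),
                   type = ifelse(a$resname %in% c("HEM", "HEME", "OCC"),
                                 "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resname,
                   elety = a$elety, chain = a$chain)
  invisible(path)
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", x$n_frames, "frames x", x$n_atoms, "atoms, t =",
      round(x$times[1], 3), "-", round(x$times[x$n_frames], 3),
      "ns (dt =", x$frame_spacing, "ns)\n")
  invisible(x)
}

## ---- TSV export ------------------------------------------------------

#' Write a trace (or any table) as TSV with a provenance header
#'
#' Mirrors the role of GROMACS .xvg files: a `#`-prefixed comment block
#' records the label, units and analysis parameters, followed by a
#' plain TSV table.
#'
#' @param x a trace object (`DistanceTrace`, `DisplacementTrace`,
#'   `SASATrace`) or a data.frame.
#' @param path output file.
#' @param header named list of parameter values recorded as comments.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(x, path, header = list()) {
  if (inherits(x, c("DistanceTrace", "DisplacementTrace", "SASATrace"))) {
    unit <- if (inherits(x, "SASATrace")) "nm^2" else "nm"
    header <- c(list(label = x$label %||% x$target_label,
                     unit = unit,
                     equilibration_cutoff_ns = x$equilibration_cutoff), header)
    df <- data.frame(time_ns = x$times, value = x$values)
    names(df)[2] <- if (unit == "nm^2") "sasa_nm2" else "value_nm"
  } else {
    df <- as.data.frame(x)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(header)) {
    v <- header[[k]]
    if (!is.null(v)) writeLines(sprintf("# %s: %s", k, paste(v, collapse = " ")), con)
  }
  utils::write.table(format(df, trim = TRUE, digits = 10), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
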