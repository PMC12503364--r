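## Synthetic-trajectory generator. Builds a chemically fake but
## structurally well-formed minimal hemoglobin tetramer (per chain: a
## heme [Fe + 4 pyrrole N], distal and proximal histidines, an E11
## residue, a CE4 aromatic, and the alpha1-beta2 interface residues),
## and writes trajectories whose planted distal-His gating, interface
## breathing and E11 burial are exactly recoverable by the analysis
## modules. It exists only to carry known ground truth through real
## file formats; it makes no claim of force-field validity.

#' Parameters of the two-state gating model
#'
#' The distal-histidine Nepsilon-Fe distance is modelled as a
#' continuous-time two-state Markov chain (down ~ 4-5 A, up ~ 8-10 A)
#' observed at fixed frame spacing, plus stationary Ornstein-Uhlenbeck
#' noise (mean-reverting, correlation time `ou_tau`) so traces have the
#' correlated fluctuations of real distance data rather than white
#' noise.
#'
#' @param k_up down->up switching rate, 1/ns.
#' @param k_down up->down switching rate, 1/ns.
#' @param mean_down,mean_up state means, nm (defaults 0.45 / 0.90; must
#'   straddle the 0.7 nm threshold).
#' @param ou_sd stationary noise SD, nm (default 0.03).
#' @param ou_tau noise correlation time, ns (default 0.5).
#' @param frame_spacing ns (default 0.2).
#' @param total_time trace length, ns.
#' @param seed integer seed or NULL.
#' @return list of class `GatingParams`.
#' @export
gating_params <- function(k_up, k_down, mean_down = 0.45, mean_up = 0.90,
                          ou_sd = 0.03, ou_tau = 0.5, frame_spacing = 0.2,
                          total_time = 133, seed = NULL) {
  if (!(mean_down < 0.7 && 0.7 < mean_up))
    stop("state means must straddle the 0.7 nm threshold")
  if (k_up < 0 || k_down < 0) stop("rates must be non-negative")
  if (any(c(ou_sd, ou_tau, frame_spacing, total_time) <= 0))
    stop("SDs and times must be positive")
  structure(list(k_up = k_up, k_down = k_down, mean_down = mean_down,
                 mean_up = mean_up, ou_sd = ou_sd, ou_tau = ou_tau,
                 frame_spacing = frame_spacing, total_time = total_time,
                 seed = seed),
            class = "GatingParams")
}

## stationary OU path sampled exactly at spacing dt
ou_series <- function(n, dt, sd, tau) {
  a <- exp(-dt / tau)
  innov_sd <- sd * sqrt(1 - a^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    z <- stats::rnorm(n - 1, 0, innov_sd)
    for (i in 2:n) x[i] <- a * x[i - 1] + z[i - 1]
  }
  x
}

## continuous-time two-state path: returns transition times (state
## toggles down->up->down-> ... starting from down at t = 0)
ctmc_transitions <- function(k_up, k_down, total_time) {
  t <- 0; up <- FALSE; trans <- numeric(0)
  repeat {
    rate <- if (up) k_down else k_up
    if (rate <= 0) break
    t <- t + stats::rexp(1, rate)
    if (t > total_time) break
    trans <- c(trans, t)
    up <- !up
  }
  trans
}

states_at <- function(times, transitions) {
  if (!length(transitions)) return(rep(FALSE, length(times)))
  findInterval(times, transitions) %% 2L == 1L
}

#' Generate one synthetic gating trace
#'
#' Samples the two-state Markov path (or uses an explicit planted
#' `schedule` of transition times), observes it at the frame spacing,
#' and adds stationary OU noise. Reproducible from the seed; the
#' caller's RNG state is restored afterwards.
#'
#' @param params a [gating_params()] object.
#' @param schedule optional numeric vector of planted transition times
#'   (ns), alternating down->up, up->down, ...; overrides the Markov
#'   sampler.
#' @param equilibration_cutoff ns, carried into the trace.
#' @return list of class `GatingTrace`: `trace` (a `DistanceTrace`),
#'   `states` (logical, up per frame), `transitions` (ns),
#'   `params`.
#' @export
generate_gating_trace <- function(params, schedule = NULL,
                                  equilibration_cutoff = 1.0) {
  stopifnot(inherits(params, "GatingParams"))
  with_seed(params$seed, {
    dt <- params$frame_spacing
    times <- seq(0, params$total_time, by = dt)
    trans <- schedule %||% ctmc_transitions(params$k_up, params$k_down,
                                            params$total_time)
    up <- states_at(times, trans)
    noise <- ou_series(length(times), dt, params$ou_sd, params$ou_tau)
    values <- ifelse(up, params$mean_up, params$mean_down) + noise
    values <- pmax(values, 0)
    structure(list(
      trace = new_distance_trace("HisE7 NE2 - heme Fe (synthetic)",
                                 times, values, equilibration_cutoff),
      states = up, transitions = trans, params = params),
      class = "GatingTrace")
  })
}

## ---- minimal tetramer topology -----------------------------------------

## residue templates: named atom offsets (nm) relative to an anchor
his_template <- function() {
  rbind(NE2 = c(0, 0, 0), CE1 = c(0.11, 0.08, 0), ND1 = c(0.21, 0.01, 0),
        CG = c(0.17, -0.12, 0), CD2 = c(0.04, -0.11, 0),
        CB = c(0.28, -0.22, 0.05), CA = c(0.40, -0.30, 0.02),
        N = c(0.50, -0.22, 0.05), C = c(0.46, -0.44, 0.03),
        O = c(0.56, -0.52, 0.06))
}

hexagon_ring <- function(r = 0.139) {
  ang <- (0:5) * pi / 3
  m <- cbind(r * cos(ang), r * sin(ang), 0)
  rownames(m) <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  m
}

trp_ring <- function() {
  ang <- (0:8) * 2 * pi / 9
  m <- cbind(0.16 * cos(ang), 0.16 * sin(ang), 0)
  rownames(m) <- c("CG", "CD1", "NE1", "CE2", "CD2", "CE3", "CZ2", "CZ3", "CH2")
  m
}

add_res <- function(atoms, chain, resno, resname, offsets, anchor) {
  for (nm_ in rownames(offsets)) {
    atoms[[length(atoms) + 1L]] <- data.frame(
      chain = chain, resno = resno, resname = resname, elety = nm_,
      x = anchor[1] + offsets[nm_, 1], y = anchor[2] + offsets[nm_, 2],
      z = anchor[3] + offsets[nm_, 3], stringsAsFactors = FALSE)
  }
  atoms
}

## per-species residue identities at the variable sites
species_idents <- function(species) {
  switch(species,
    bovine = list(ce4 = "PHE", c6 = "THR", e11 = "VAL"),
    trout = list(ce4 = "TRP", c6 = "ALA", e11 = "ILE"),
    stop("species must be 'bovine' or 'trout'"))
}

ALPHA_RES <- c(C6 = 38L, C7 = 39L, CE4 = 46L, E7 = 58L, E11 = 62L,
               F8 = 88L, FG4 = 92L, G1 = 94L)
BETA_RES <- c(C6 = 40L, E7 = 63L, F8 = 92L, G4 = 101L)
HEME_RESNO <- 201L

#' Build the minimal synthetic tetramer topology and its site map
#'
#' Two alpha chains (A, C) and two beta chains (B, D); alpha1-beta2
#' pairings A-D and C-B. Each chain carries a heme (Fe displaced
#' `fe_disp` nm toward the proximal side of the pyrrole-N plane), a
#' proximal HisF8 bonded at `fe_l1` nm, a distal HisE7 whose NE2 sits
#' `e7_down` nm from the Fe, an E11 residue, a CE4 aromatic stacked
#' against the distal-His ring, and (alpha) C6/C7/FG4/G1 or (beta)
#' C6/G4 interface residues at baseline contact distances of roughly
#' 0.5-0.55 nm across each pairing.
#'
#' @param species `"bovine"` (PheCE4, ThrC6, ValE11) or `"trout"`
#'   (TrpCE4, AlaC6, IleE11 - no bovine-only interface site).
#' @param fe_l1 proximal-bond length, nm.
#' @param fe_disp iron out-of-plane displacement, nm.
#' @param e7_down distal-His NE2 to Fe distance in the down state, nm.
#' @return list with `model` (a `StructureModel`), `map` (a `SiteMap`)
#'   and `movers` (bookkeeping of animatable atom groups used by
#'   [generate_synthetic_system()]).
#' @export
synthetic_topology <- function(species = "bovine", fe_l1 = 0.21,
                               fe_disp = 0.035, e7_down = 0.45) {
  id <- species_idents(species)
  origins <- list(A = c(0, 0, 0), B = c(7, 0, 0), C = c(0, 7, 0), D = c(7, 7, 0))
  classes <- c(A = "alpha", B = "beta", C = "alpha", D = "beta")
  pairs <- list(c(alpha = "A", beta = "D"), c(alpha = "C", beta = "B"))

  atoms <- list()
  his <- his_template()
  ring_ctr <- colMeans(his[c("NE2", "CE1", "ND1", "CG", "CD2"), ])

  for (ch in names(origins)) {
    o <- origins[[ch]]
    cls <- classes[[ch]]
    rn <- if (cls == "alpha") ALPHA_RES else BETA_RES
    ## heme: pyrrole N square in the z = 0 plane, Fe proximal (-z)
    hem <- rbind(FE = c(0, 0, -fe_disp), "NA" = c(0.1, 0, 0),
                 NB = c(0, 0.1, 0), NC = c(-0.1, 0, 0), ND = c(0, -0.1, 0))
    atoms <- add_res(atoms, ch, HEME_RESNO, "HEM", hem, o)
    ## proximal HisF8: NE2 bonded below the Fe, residue hanging -z
    prox <- his; prox[, 3] <- -prox[, 3] - 0.08; prox["NE2", 3] <- 0
    atoms <- add_res(atoms, ch, rn[["F8"]], "HIS", prox,
                     o + c(0, 0, -fe_disp - fe_l1))
    ## distal HisE7: NE2 a planted distance above the Fe
    atoms <- add_res(atoms, ch, rn[["E7"]], "HIS", his,
                     o + c(0, 0, -fe_disp + e7_down))
    ## E11 residue beside the pocket
    e11 <- rbind(CA = c(0, 0, 0), N = c(-0.12, 0.08, 0),
                 C = c(0.10, -0.10, 0.05), O = c(0.20, -0.05, 0.10),
                 CB = c(0.05, 0.12, -0.08), CG1 = c(0.18, 0.20, -0.05),
                 CG2 = c(-0.05, 0.25, -0.12))
    e11name <- if (cls == "alpha") id$e11 else "VAL"
    if (e11name == "ILE") e11 <- rbind(e11, CD1 = c(0.28, 0.28, 0))
    e11no <- if (cls == "alpha") rn[["E11"]] else 67L
    atoms <- add_res(atoms, ch, e11no, e11name, e11, o + c(0.45, 0.35, 0.10))
    if (cls == "alpha") {
      ## CE4 aromatic parallel-displaced above the distal-His ring
      ce4_ring <- if (id$ce4 == "PHE") hexagon_ring() else trp_ring()
      ce4 <- rbind(ce4_ring, CB = c(0.25, 0.05, 0.05), CA = c(0.36, 0.1, 0.08),
                   N = c(0.46, 0.03, 0.08), C = c(0.42, 0.24, 0.1),
                   O = c(0.52, 0.31, 0.12))
      ce4_anchor <- o + c(0, 0, -fe_disp + e7_down) + ring_ctr + c(0.15, 0, 0.35)
      atoms <- add_res(atoms, ch, rn[["CE4"]], id$ce4, ce4, ce4_anchor)
      ## interface residues, +x side of the chain origin
      if (id$c6 == "THR") {
        c6 <- rbind(OG = c(0, 0, 0), CB = c(-0.07, -0.08, 0),
                    CA = c(-0.15, -0.16, 0.02), N = c(-0.23, -0.08, 0.05),
                    C = c(-0.15, -0.30, 0), O = c(-0.07, -0.38, 0))
      } else {
        c6 <- rbind(CB = c(-0.07, -0.08, 0), CA = c(-0.15, -0.16, 0.02),
                    N = c(-0.23, -0.08, 0.05), C = c(-0.15, -0.30, 0),
                    O = c(-0.07, -0.38, 0))
      }
      atoms <- add_res(atoms, ch, rn[["C6"]], id$c6, c6, o + c(1.45, 0, 0))
      tyr <- rbind(CZ = c(0, 0, 0), CE1 = c(-0.06, 0.12, 0),
                   CE2 = c(-0.06, -0.12, 0), CD1 = c(-0.19, 0.12, 0),
                   CD2 = c(-0.19, -0.12, 0), CG = c(-0.25, 0, 0),
                   CB = c(-0.38, 0, 0.05), CA = c(-0.50, 0.05, 0),
                   N = c(-0.55, 0.15, 0), C = c(-0.55, -0.08, 0),
                   O = c(-0.65, -0.15, 0))
      atoms <- add_res(atoms, ch, rn[["C7"]], "TYR", tyr, o + c(1.5, 0, 0))
      arg <- rbind(CD = c(0, 0, 0), CG = c(-0.12, 0, 0.05),
                   CB = c(-0.22, -0.05, 0), CA = c(-0.32, 0, 0),
                   N = c(-0.40, -0.08, 0), C = c(-0.40, 0.10, 0),
                   O = c(-0.50, 0.18, 0), NE = c(0.12, 0.05, 0),
                   CZ = c(0.22, 0.10, 0))
      atoms <- add_res(atoms, ch, rn[["FG4"]], "ARG", arg, o + c(1.5, 0.5, 0))
      asp <- rbind(CG = c(0, 0, 0), CB = c(-0.12, 0, 0), CA = c(-0.24, 0, 0),
                   N = c(-0.32, -0.08, 0), C = c(-0.32, 0.10, 0),
                   O = c(-0.42, 0.18, 0))
      atoms <- add_res(atoms, ch, rn[["G1"]], "ASP", asp, o + c(1.5, 1.0, 0))
    }
  }

  ## beta-chain interface residues live across from their alpha partner
  base_d <- c(A = 0.50, B = 0.55, C = 0.52)   # site baselines, nm
  for (p in pairs) {
    ao <- origins[[p[["alpha"]]]]
    bc <- p[["beta"]]
    argb <- rbind(CZ = c(base_d[["B"]], 0, 0),           # pairs alpha C7 CZ
                  CB = c(base_d[["C"]], 0.5, 0),          # pairs alpha FG4 CD
                  NE = c(0.65, 0.1, 0), CG = c(0.60, 0.4, 0),
                  CD = c(0.70, 0.3, 0), CA = c(0.80, 0.25, 0),
                  N = c(0.88, 0.2, 0), C = c(0.80, 0.4, 0), O = c(0.88, 0.48, 0))
    atoms <- add_res(atoms, bc, BETA_RES[["C6"]], "ARG", argb, ao + c(1.5, 0, 0))
    asnb <- rbind(ND2 = c(base_d[["A"]], 0, 0),           # pairs alpha G1 CG
                  CG = c(0.60, 0.05, 0), CB = c(0.70, 0.10, 0),
                  CA = c(0.80, 0.10, 0), N = c(0.85, 0, 0),
                  C = c(0.85, 0.25, 0), O = c(0.95, 0.30, 0))
    atoms <- add_res(atoms, bc, BETA_RES[["G4"]], "ASN", asnb, ao + c(1.5, 1.0, 0))
  }

  tbl <- do.call(rbind, atoms)
  model <- structure_model(tbl, chain_classes = classes)

  sites <- list(
    alpha = list(
      C6 = list(resid = ALPHA_RES[["C6"]], resname = id$c6),
      C7 = list(resid = ALPHA_RES[["C7"]], resname = "TYR"),
      CE4 = list(resid = ALPHA_RES[["CE4"]], resname = id$ce4),
      E7 = list(resid = ALPHA_RES[["E7"]], resname = "HIS"),
      E11 = list(resid = ALPHA_RES[["E11"]], resname = id$e11),
      F8 = list(resid = ALPHA_RES[["F8"]], resname = "HIS"),
      FG4 = list(resid = ALPHA_RES[["FG4"]], resname = "ARG"),
      G1 = list(resid = ALPHA_RES[["G1"]], resname = "ASP")),
    beta = list(
      C6 = list(resid = BETA_RES[["C6"]], resname = "ARG"),
      E7 = list(resid = BETA_RES[["E7"]], resname = "HIS"),
      F8 = list(resid = BETA_RES[["F8"]], resname = "HIS"),
      G4 = list(resid = BETA_RES[["G4"]], resname = "ASN")))
  map <- site_map(paste0("synthetic-", species), classes, sites)

  ## bookkeeping for the animator
  at <- model$atoms
  movers <- list(origins = origins, pairs = pairs, base_d = base_d,
                 e7_down = e7_down, fe_disp = fe_disp,
                 e7_idx = lapply(c(A = "A", C = "C"), function(ch)
                   at$index[at$chain == ch & at$resno == ALPHA_RES[["E7"]]]),
                 pair_idx = lapply(pairs, function(p) {
                   bc <- p[["beta"]]
                   list(alpha = p[["alpha"]], beta = bc,
                        cz = at$index[at$chain == bc & at$resno == BETA_RES[["C6"]] & at$elety == "CZ"],
                        cb = at$index[at$chain == bc & at$resno == BETA_RES[["C6"]] & at$elety == "CB"],
                        nd2 = at$index[at$chain == bc & at$resno == BETA_RES[["G4"]] & at$elety == "ND2"],
                        c7ca = at$index[at$chain == p[["alpha"]] &
                                        at$resno == ALPHA_RES[["C7"]] &
                                        at$elety == "CA"])
                 }))
  list(model = model, map = map, movers = movers)
}

## ---- full synthetic study ----------------------------------------------

gaussian_bump <- function(times, t0, height, width) {
  height * exp(-(times - t0)^2 / (2 * width^2))
}

#' Generate a complete synthetic study (topology + replicate trajectories)
#'
#' Writes a topology PDB, a site-map YAML, one multi-model PDB
#' trajectory per replicate, and a ground-truth JSON manifest. The
#' distal-His NE2 of each alpha chain tracks a planted gating trace
#' (Markov-sampled or an explicit `swing_schedule`); the three (four
#' for bovine) interface atom pairs track planted breathing series with
#' optional large excursions (> 1 nm, mimicking the Arg beta2C6
#' guanidinium swinging toward solvent); an optional occluder shell
#' around the alpha1 E11 residue follows an open-fraction schedule so
#' its SASA varies with planted burial. Unequal replicate lengths are
#' supported to exercise the time normalizations.
#'
#' @param dir output directory (created if needed).
#' @param species `"bovine"` or `"trout"`.
#' @param n_replicates number of replicates (default 5).
#' @param replicate_times total time per replicate, ns (recycled;
#'   default 133 each).
#' @param gating a [gating_params()] (its `total_time`/`seed` fields are
#'   overridden per replicate).
#' @param swing_schedule optional planted transition times: a list with
#'   one element per replicate, each a named list of numeric vectors
#'   per alpha chain (e.g. `list(A = 25, C = numeric(0))`). Chains not
#'   named stay down.
#' @param interface_excursion optional `list(replicate=, site=, time=,
#'   peak=, width=)` planting one large excursion (peak in nm) on one
#'   interface site of one replicate (applied to the first chain
#'   pairing).
#' @param interface_noise_sd OU noise SD on interface series, nm.
#' @param backbone_drift planted linear drift (nm/ns) of one interface
#'   backbone atom (the alpha1 C7 CA) per pairing, giving the local
#'   interface RMSD a known slow upward trend like real interface
#'   loosening; 0 disables it.
#' @param e11_open_schedule optional function of time (ns) returning an
#'   open fraction in [0, 1]; drives the occluder shell around the
#'   alpha1 (chain A) E11 residue.
#' @param label treatment label recorded in the manifest.
#' @param seed master seed; every stochastic element derives from it.
#' @return list of class `SyntheticSystem`: paths, the `model` and
#'   `map`, the manifest (also written as JSON), and `planted` ground
#'   truth (full gating/interface series per replicate).
#' @export
generate_synthetic_system <- function(dir, species = "bovine",
                                      n_replicates = 5,
                                      replicate_times = rep(133, n_replicates),
                                      gating = gating_params(k_up = 0.02,
                                                             k_down = 0.002,
                                                             total_time = 133),
                                      swing_schedule = NULL,
                                      interface_excursion = NULL,
                                      interface_noise_sd = 0.02,
                                      backbone_drift = 5e-4,
                                      e11_open_schedule = NULL,
                                      label = paste0(species, "-native"),
                                      seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  replicate_times <- rep_len(replicate_times, n_replicates)
  topo <- synthetic_topology(species)
  model <- topo$model; map <- topo$map; mv <- topo$movers

  ## occluder shell around alpha1 (chain A) E11
  occ_dirs <- NULL
  if (!is.null(e11_open_schedule)) {
    e11_idx <- resolve_residue(model, map, "alpha", "E11", chain = "A")
    e11_ctr <- colMeans(as.matrix(model$atoms[e11_idx, c("x", "y", "z")]))
    occ_dirs <- sphere_points(64)
    occ <- data.frame(chain = "X", resno = 900L, resname = "OCC",
                      elety = sprintf("O%02d", seq_len(nrow(occ_dirs))),
                      x = e11_ctr[1] + 2.0 * occ_dirs[, 1],
                      y = e11_ctr[2] + 2.0 * occ_dirs[, 2],
                      z = e11_ctr[3] + 2.0 * occ_dirs[, 3],
                      stringsAsFactors = FALSE)
    model <- structure_model(rbind(model$atoms[, names(occ)], occ),
                             chain_classes = c(A = "alpha", B = "beta",
                                               C = "alpha", D = "beta"))
  }

  topo_path <- file.path(dir, "topology.pdb")
  map_path <- file.path(dir, "sitemap.yaml")
  write_trajectory_pdb(model, matrix(t(as.matrix(
    model$atoms[, c("x", "y", "z")])), nrow = 1), topo_path)
  write_site_map(map, map_path)

  base_xyz <- as.vector(t(as.matrix(model$atoms[, c("x", "y", "z")])))
  dt <- gating$frame_spacing
  alpha_chains <- c("A", "C")
  traj_paths <- character(n_replicates)
  planted <- list()
  manifest_reps <- list()

  for (r in seq_len(n_replicates)) {
    total <- replicate_times[r]
    times <- seq(0, total, by = dt)
    nf <- length(times)
    xyz <- matrix(base_xyz, nrow = nf, ncol = length(base_xyz), byrow = TRUE)

    rep_planted <- list(times = times, gating = list(), interface = list())
    rep_manifest <- list(replicate = r, total_time = total, chains = list())

    ## low-amplitude thermal jitter on the proximal His NE2, the
    ## pyrrole nitrogens and the E11 atoms of every chain, so Fe-L1,
    ## iron-displacement and SASA observables fluctuate like real data.
    ## The heme Fe and the distal-His/interface atoms stay on their
    ## planted series, which therefore remain exactly recoverable.
    at <- model$atoms
    for (ci in seq_along(mv$origins)) {
      ch <- names(mv$origins)[ci]
      cls <- if (ch %in% c("A", "C")) "alpha" else "beta"
      rn <- if (cls == "alpha") ALPHA_RES else BETA_RES
      set.seed(seed + 50000L * r + 200L * ci)
      jitter_atoms <- function(idx, sd) {
        for (i in idx) {
          cols <- xyz_cols(i)
          for (ax in 1:3)
            xyz[, cols[ax]] <<- xyz[, cols[ax]] + ou_series(nf, dt, sd, 0.5)
        }
      }
      f8_ne2 <- at$index[at$chain == ch & at$resno == rn[["F8"]] &
                         at$elety == "NE2"]
      jitter_atoms(f8_ne2, 0.004)
      jitter_atoms(heme_for_chain(model, ch)$pyrrole, 0.0025)
      e11no <- if (cls == "alpha") rn[["E11"]] else 67L
      jitter_atoms(at$index[at$chain == ch & at$resno == e11no &
                            at$resname != "HEM"], 0.002)
    }

    ## distal-His gating per alpha chain
    for (ci in seq_along(alpha_chains)) {
      ch <- alpha_chains[ci]
      p <- gating
      p$total_time <- total
      p$seed <- seed + 1000L * r + ci
      sched <- if (!is.null(swing_schedule)) {
        s <- swing_schedule[[r]][[ch]]
        if (is.null(s)) numeric(0) else s
      } else NULL
      gt <- generate_gating_trace(p, schedule = sched)
      d <- gt$trace$values
      idx <- mv$e7_idx[[ch]]
      zc <- xyz_cols(idx)[seq(3, 3 * length(idx), by = 3)]
      shift <- d - mv$e7_down
      for (k in seq_along(zc)) xyz[, zc[k]] <- xyz[1, zc[k]] + shift
      rep_planted$gating[[ch]] <- list(values = d, states = gt$states,
                                       transitions = gt$transitions)
      analyzed <- times >= 1.0
      up_frames <- which(gt$states & analyzed)
      rep_manifest$chains[[ch]] <- list(
        swung_out = length(up_frames) > 0,
        first_up_time = if (length(up_frames)) times[up_frames[1]] else NULL)
    }

    ## interface breathing series, first pairing only gets excursions
    for (pi in seq_along(mv$pair_idx)) {
      pr <- mv$pair_idx[[pi]]
      ser <- list()
      for (site in c("A", "B", "C")) {
        set.seed(seed + 10000L * r + 100L * pi +
                   match(site, c("A", "B", "C")))
        s <- mv$base_d[[site]] + ou_series(nf, dt, interface_noise_sd, 0.5)
        ex <- interface_excursion
        if (!is.null(ex) && pi == 1L && ex$replicate == r && ex$site == site)
          s <- s + gaussian_bump(times, ex$time, ex$peak - mv$base_d[[site]],
                                 ex$width %||% 2)
        s <- pmax(s, 0.05)
        ser[[site]] <- s
        col <- switch(site, A = pr$nd2, B = pr$cz, C = pr$cb)
        xc <- xyz_cols(col)[1]
        xyz[, xc] <- xyz[1, xc] - mv$base_d[[site]] + s
      }
      ## slow planted drift of one interface backbone atom
      if (backbone_drift != 0) {
        yc <- xyz_cols(pr$c7ca)[2]
        xyz[, yc] <- xyz[1, yc] + backbone_drift * times
      }
      rep_planted$interface[[pi]] <- list(alpha = pr$alpha, beta = pr$beta,
                                          series = ser)
      if (pi == 1L) {
        an <- times >= 1.0
        rep_manifest$interface_max <- lapply(ser, function(s) max(s[an]))
        ## bovine-only site D shares the beta CZ atom, offset 0.05 nm
        if ("D" %in% applicable_sites(map))
          rep_manifest$interface_max$D <- max(ser$B[an] + 0.05)
      }
    }

    ## E11 occluder shell follows the open-fraction schedule
    if (!is.null(e11_open_schedule)) {
      open_f <- pmin(1, pmax(0, e11_open_schedule(times)))
      occ_idx <- model$atoms$index[model$atoms$resname == "OCC"]
      occ_cols <- xyz_cols(occ_idx)
      e11_idx <- resolve_residue(model, map, "alpha", "E11", chain = "A")
      ctr <- colMeans(as.matrix(model$atoms[e11_idx, c("x", "y", "z")]))
      for (f in seq_len(nf))
        xyz[f, occ_cols] <- as.vector(t(
          occluder_coords(ctr, occ_dirs, open_f[f], 0.38, 2.0)))
      rep_planted$e11_open <- open_f
      rep_manifest$e11_open_range <- range(open_f)
    }

    traj_paths[r] <- file.path(dir, sprintf("replicate_%02d.pdb", r))
    write_trajectory_pdb(model, xyz, traj_paths[r])
    planted[[r]] <- rep_planted
    manifest_reps[[r]] <- rep_manifest
  }

  manifest <- list(label = label, species = species, seed = seed,
                   n_replicates = n_replicates,
                   replicate_times = replicate_times,
                   frame_spacing = dt,
                   raw_swing_count = sum(vapply(manifest_reps, function(m)
                     sum(vapply(m$chains, function(c) c$swung_out, logical(1))),
                     numeric(1))),
                   backbone_drift_nm_per_ns = backbone_drift,
                   gating = list(k_up = gating$k_up, k_down = gating$k_down,
                                 mean_down = gating$mean_down,
                                 mean_up = gating$mean_up,
                                 ou_sd = gating$ou_sd, ou_tau = gating$ou_tau),
                   replicates = manifest_reps,
                   topology = basename(topo_path),
                   site_map = basename(map_path),
                   trajectories = basename(traj_paths))
  manifest_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  structure(list(dir = dir, topology_path = topo_path, map_path = map_path,
                 trajectory_paths = traj_paths, manifest_path = manifest_path,
                 manifest = manifest, planted = planted,
                 model = model, map = map),
            class = "SyntheticSystem")
}

#' @export
print.SyntheticSystem <- function(x, ...) {
  cat("SyntheticSystem [", x$manifest$label, "]: ",
      x$manifest$n_replicates, " replicates in ", x$dir, "\n",
      "  planted raw swing-out count: ", x$manifest$raw_swing_count,
      "\n", sep = "")
  invisible(x)
}

## occluder-shell coordinates for one open fraction: the first
## floor(f * n) shell atoms are displaced beyond occlusion range (the
## golden-spiral ordering makes this a growing polar cap), and the
## remaining shell swells slightly with f so equal displaced counts
## still order correctly; SASA therefore increases monotonically with f
occluder_coords <- function(ctr, dirs, open_f, r_buried, r_open) {
  n <- nrow(dirs)
  n_far <- floor(open_f * n + 1e-9)
  r <- rep(r_buried + 0.15 * open_f, n)
  if (n_far > 0) r[seq_len(n_far)] <- r_open
  sweep(dirs * r, 2, ctr, "+")
}

#' Generate an E11 burial trajectory fragment
#'
#' A standalone E11-like residue surrounded by a spherical shell of
#' occluder pseudo-atoms driven by a planted open-fraction schedule: at
#' 0 the closed shell buries the residue completely, and as the
#' fraction grows a matching share of the shell is displaced out of
#' occlusion range, so the residue's SASA increases monotonically with
#' the schedule.
#'
#' @param open_fraction numeric vector in [0, 1], one value per frame.
#' @param frame_spacing ns between frames.
#' @param n_occluders shell size (default 64).
#' @param r_buried,r_open shell radii (nm) at open fractions 0 and 1.
#' @return list with `model`, `traj` (a `Trajectory`), `target`
#'   (atom indices of the residue) and `open_fraction`.
#' @export
generate_e11_burial_series <- function(open_fraction, frame_spacing = 0.2,
                                       n_occluders = 64L,
                                       r_buried = 0.38, r_open = 2.0) {
  if (any(open_fraction < 0 | open_fraction > 1))
    stop("open_fraction values must lie in [0, 1]")
  res <- rbind(CA = c(0, 0, 0), N = c(-0.12, 0.08, 0),
               C = c(0.10, -0.10, 0.05), O = c(0.20, -0.05, 0.10),
               CB = c(0.05, 0.12, -0.08), CG1 = c(0.18, 0.20, -0.05),
               CG2 = c(-0.05, 0.25, -0.12))
  dirs <- sphere_points(n_occluders)
  atoms <- rbind(
    data.frame(chain = "A", resno = 62L, resname = "VAL",
               elety = rownames(res), x = res[, 1], y = res[, 2], z = res[, 3],
               stringsAsFactors = FALSE),
    data.frame(chain = "X", resno = 900L, resname = "OCC",
               elety = sprintf("O%02d", seq_len(n_occluders)),
               x = r_open * dirs[, 1], y = r_open * dirs[, 2],
               z = r_open * dirs[, 3], stringsAsFactors = FALSE))
  model <- structure_model(atoms)
  ctr <- colMeans(res)
  nf <- length(open_fraction)
  xyz <- matrix(0, nf, 3L * nrow(atoms))
  base <- as.vector(t(as.matrix(atoms[, c("x", "y", "z")])))
  occ_idx <- which(atoms$resname == "OCC")
  occ_cols <- xyz_cols(occ_idx)
  for (f in seq_len(nf)) {
    v <- base
    oc <- occluder_coords(ctr, dirs, open_fraction[f], r_buried, r_open)
    v[occ_cols] <- as.vector(t(oc))
    xyz[f, ] <- v
  }
  traj <- new_trajectory(xyz, frame_spacing * (seq_len(nf) - 1L), frame_spacing)
  list(model = model, traj = traj, target = which(atoms$resname == "VAL"),
       open_fraction = open_fraction)
}
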