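## Config-driven end-to-end runner: per-treatment swing-event tables,
## normalized swing times, Fe-L1 and iron-displacement averages,
## interface maxima and RMSD slopes, SASA averages, cross-treatment
## statistics, and a provenance manifest.

#' Build an analysis configuration
#'
#' @param label treatment label (species x protonation state).
#' @param species `"bovine"` or `"trout"` (free text; used in reports).
#' @param topology path to the topology PDB.
#' @param site_map path to the site-map YAML.
#' @param trajectories character vector of replicate trajectory paths.
#' @param frame_spacing ns between frames (default 0.2).
#' @param swing_threshold swing-out threshold, nm (default 0.7 = 7 A).
#' @param equilibration_cutoff ns excluded from all analysis (default 1).
#' @param window averaging/regression window, ns (default `c(1, 133)`).
#' @param dwell_min return-to-down dwell requirement, ns.
#' @param sasa a [sasa_params()] object.
#' @param interface_pairs list of `c(alpha=, beta=)` chain pairings;
#'   defaults to pairing the i-th alpha with the opposite beta. Only
#'   the first pairing enters the per-replicate interface statistics
#'   (one value per replicate).
#' @return list of class `AnalysisConfig`.
#' @export
analysis_config <- function(label, species, topology, site_map, trajectories,
                            frame_spacing = 0.2, swing_threshold = 0.7,
                            equilibration_cutoff = 1.0, window = c(1, 133),
                            dwell_min = 5, sasa = sasa_params(),
                            interface_pairs = NULL) {
  for (p in c(topology, site_map, trajectories))
    if (!file.exists(p)) stop("config references a missing file: ", p)
  structure(list(label = label, species = species, topology = topology,
                 site_map = site_map, trajectories = trajectories,
                 frame_spacing = frame_spacing,
                 swing_threshold = swing_threshold,
                 equilibration_cutoff = equilibration_cutoff,
                 window = window, dwell_min = dwell_min, sasa = sasa,
                 interface_pairs = interface_pairs),
            class = "AnalysisConfig")
}

#' Read an analysis configuration from YAML
#'
#' Top-level keys mirror the [analysis_config()] arguments; `sasa` may
#' hold `probe_radius` / `n_sphere_points`. Relative paths are resolved
#' against the config file's directory.
#'
#' @param path YAML file.
#' @return An `AnalysisConfig`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) ifelse(startsWith(p, "/"), p, file.path(base, p))
  sp <- do.call(sasa_params, y$sasa %||% list())
  analysis_config(label = y$label, species = y$species,
                  topology = rel(y$topology), site_map = rel(y$site_map),
                  trajectories = rel(unlist(y$trajectories)),
                  frame_spacing = y$frame_spacing %||% 0.2,
                  swing_threshold = y$swing_threshold %||% 0.7,
                  equilibration_cutoff = y$equilibration_cutoff %||% 1.0,
                  window = unlist(y$window %||% c(1, 133)),
                  dwell_min = y$dwell_min %||% 5,
                  sasa = sp,
                  interface_pairs = y$interface_pairs)
}

default_pairs <- function(alphas, betas) {
  if (length(alphas) == 2L && length(betas) == 2L)
    list(c(alpha = alphas[1], beta = betas[2]),
         c(alpha = alphas[2], beta = betas[1]))
  else
    list(c(alpha = alphas[1], beta = betas[1]))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE))
}

analyze_treatment <- function(cfg) {
  model <- stage("read_structure", read_structure(cfg$topology))
  map <- stage("read_site_map", read_site_map(cfg$site_map))
  alphas <- map_chains(model, map, "alpha")
  betas <- map_chains(model, map, "beta")
  pairs <- cfg$interface_pairs %||% default_pairs(alphas, betas)
  w <- cfg$window
  eq <- cfg$equilibration_cutoff
  sites <- applicable_sites(map)

  swing_records <- list()
  fel1 <- list(); disp <- list(); imax <- list(); slopes <- list()
  sasa_rows <- list()

  ## interface backbone selection (static across replicates)
  sel <- stage("interface_selection",
               interface_selection(model, map,
                                   alpha_chain = pairs[[1]][["alpha"]],
                                   beta_chain = pairs[[1]][["beta"]]))

  for (r in seq_along(cfg$trajectories)) {
    traj <- stage("read_trajectory",
                  read_trajectory(model, cfg$trajectories[r],
                                  frame_spacing = cfg$frame_spacing))
    t_end <- min(w[2], max(traj$times))

    for (ch in alphas) {
      heme <- heme_for_chain(model, ch)
      e7 <- resolve_site(model, map, "alpha", "E7", "NE2", chain = ch)
      f8 <- resolve_site(model, map, "alpha", "F8", "NE2", chain = ch)
      tr_e7 <- distance_trace(traj, e7, heme$fe, equilibration_cutoff = eq)
      swing_records[[length(swing_records) + 1L]] <-
        detect_swing(tr_e7, threshold = cfg$swing_threshold,
                     dwell_min = cfg$dwell_min,
                     replicate_id = r, chain_id = ch)
      tr_f8 <- distance_trace(traj, f8, heme$fe, equilibration_cutoff = eq)
      fel1[[length(fel1) + 1L]] <- data.frame(
        replicate = r, chain = ch, chain_class = "alpha",
        mean_fel1_nm = mean_distance(tr_f8, w[1], t_end))
      dtr <- iron_plane_displacement(traj, heme, f8, equilibration_cutoff = eq)
      disp[[length(disp) + 1L]] <- data.frame(
        replicate = r, chain = ch,
        mean_displacement_nm = window_mean(dtr$times, dtr$values, w[1], t_end))
      e11_tr <- residue_sasa_trace(traj, model, map, "alpha", "E11",
                                   chain = ch, params = cfg$sasa,
                                   equilibration_cutoff = eq)
      heme_tr <- heme_sasa_trace(traj, model, ch, params = cfg$sasa,
                                 equilibration_cutoff = eq)
      sasa_rows[[length(sasa_rows) + 1L]] <- data.frame(
        replicate = r, chain = ch,
        mean_e11_sasa_nm2 = mean_sasa(e11_tr, w[1], t_end),
        mean_heme_sasa_nm2 = mean_sasa(heme_tr, w[1], t_end))
    }
    for (ch in betas) {
      heme <- heme_for_chain(model, ch)
      f8 <- resolve_site(model, map, "beta", "F8", "NE2", chain = ch)
      tr_f8 <- distance_trace(traj, f8, heme$fe, equilibration_cutoff = eq)
      fel1[[length(fel1) + 1L]] <- data.frame(
        replicate = r, chain = ch, chain_class = "beta",
        mean_fel1_nm = mean_distance(tr_f8, w[1], t_end))
    }

    p1 <- pairs[[1]]
    for (s in sites) {
      tr <- site_distance_trace(traj, model, map, s,
                                alpha_chain = p1[["alpha"]],
                                beta_chain = p1[["beta"]],
                                equilibration_cutoff = eq)
      imax[[length(imax) + 1L]] <- data.frame(
        site = s, fig_site = site_row(s)$fig_site, replicate = r,
        max_distance_nm = max_site_distance(tr))
    }
    fit <- interface_rmsd_slope(traj, sel, reference_frame = 1L,
                                t_start = w[1], t_end = t_end)
    slopes[[length(slopes) + 1L]] <- data.frame(
      replicate = r, slope_nm_per_ns = fit$slope,
      intercept_nm = fit$intercept, r_squared = fit$r_squared)
  }

  list(config = cfg, model = model, map = map,
       swing_records = swing_records,
       swing_table = records_table(swing_records),
       fel1 = do.call(rbind, fel1),
       displacement = do.call(rbind, disp),
       interface_max = do.call(rbind, imax),
       rmsd_slopes = do.call(rbind, slopes),
       sasa = do.call(rbind, sasa_rows),
       total_time = treatment_total_time(swing_records))
}

#' Run the full trajectory analysis for one or more treatments
#'
#' For every treatment: swing-out detection on the alpha-chain HisE7
#' Nepsilon-Fe traces (binary per chain-replicate, 2 alpha chains per
#' replicate), time-corrected event counts and normalized first-passage
#' times, mean Fe-L1 (HisF8 NE2 - Fe) distances per chain class with
#' alpha1/alpha2 (and beta1/beta2) pooled, iron out-of-plane
#' displacement averages, interface-site maxima and local backbone RMSD
#' drift for the first alpha1-beta2 pairing, and E11/heme SASA
#' averages. With more than one treatment, cross-treatment statistics
#' are added: one-way ANOVA with Tukey HSD on Fe-L1, displacement,
#' per-site interface maxima and heme SASA; unpaired t-tests on E11
#' SASA within species (E11 identity differs between species, so no
#' cross-species E11 comparison is made).
#'
#' @param configs an `AnalysisConfig` or list of them.
#' @param out_dir optional directory; when given, all tables are
#'   written as TSV plus a JSON run manifest recording parameters and
#'   input checksums.
#' @param reference_total_time ns used for count/time normalization;
#'   defaults to the largest treatment total.
#' @return list of class `AnalysisBundle`: per-treatment results,
#'   `event_summary`, `swing_times`, cross-treatment `stats`, and the
#'   `manifest`.
#' @export
run_analysis <- function(configs, out_dir = NULL,
                         reference_total_time = NULL) {
  if (inherits(configs, "AnalysisConfig")) configs <- list(configs)
  res <- lapply(configs, analyze_treatment)
  names(res) <- vapply(res, function(x) x$config$label, character(1))

  ref <- reference_total_time %||% max(vapply(res, `[[`, numeric(1),
                                              "total_time"))
  event_summary <- lapply(res, function(x)
    count_events(x$swing_records, ref, label = x$config$label))
  swing_times <- lapply(res, function(x)
    normalized_swing_times(x$swing_records,
                           reference_total_time = ref,
                           treatment_total_time = x$total_time))

  stats_out <- list()
  if (length(res) > 1L) {
    grp <- function(field, value, subset = TRUE) {
      lapply(res, function(x) {
        df <- x[[field]]
        df[[value]][eval(subset, df)]
      })
    }
    stats_out$fel1_alpha <- tukey_pairwise(grp("fel1", "mean_fel1_nm",
                                               quote(chain_class == "alpha")))
    stats_out$fel1_beta <- tukey_pairwise(grp("fel1", "mean_fel1_nm",
                                              quote(chain_class == "beta")))
    stats_out$displacement <- tukey_pairwise(grp("displacement",
                                                 "mean_displacement_nm"))
    shared <- Reduce(intersect, lapply(res, function(x)
      unique(x$interface_max$site)))
    stats_out$interface <- lapply(stats::setNames(shared, shared), function(s)
      tukey_pairwise(grp("interface_max", "max_distance_nm",
                         bquote(site == .(s)))))
    stats_out$heme_sasa <- tukey_pairwise(grp("sasa", "mean_heme_sasa_nm2"))
    ## E11 SASA: unpaired t-test within species only
    sp <- vapply(res, function(x) x$config$species, character(1))
    stats_out$e11_sasa <- list()
    for (s in unique(sp)) {
      ix <- which(sp == s)
      if (length(ix) == 2L)
        stats_out$e11_sasa[[s]] <- unpaired_t_test(
          res[[ix[1]]]$sasa$mean_e11_sasa_nm2,
          res[[ix[2]]]$sasa$mean_e11_sasa_nm2)
    }
  }

  manifest <- list(
    reference_total_time = ref,
    treatments = lapply(res, function(x) list(
      label = x$config$label, species = x$config$species,
      swing_threshold_nm = x$config$swing_threshold,
      swing_threshold_ang = nm2ang(x$config$swing_threshold),
      equilibration_cutoff_ns = x$config$equilibration_cutoff,
      window_ns = x$config$window, dwell_min_ns = x$config$dwell_min,
      sasa = x$config$sasa[c("probe_radius", "n_sphere_points", "radii_set")],
      total_time_ns = x$total_time,
      inputs = as.list(tools::md5sum(c(x$config$topology, x$config$site_map,
                                       x$config$trajectories))))))

  bundle <- structure(list(treatments = res,
                           event_summary = event_summary,
                           swing_times = swing_times,
                           stats = stats_out, manifest = manifest),
                      class = "AnalysisBundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (lab in names(bundle$treatments)) {
    x <- bundle$treatments[[lab]]
    pre <- file.path(out_dir, gsub("[^A-Za-z0-9_.-]", "_", lab))
    hdr <- list(treatment = lab,
                swing_threshold = sprintf("%.2f nm (%.1f A)",
                                          x$config$swing_threshold,
                                          nm2ang(x$config$swing_threshold)))
    write_trace_tsv(x$swing_table, paste0(pre, "_swing_events.tsv"), hdr)
    write_trace_tsv(bundle$swing_times[[lab]],
                    paste0(pre, "_swing_times.tsv"),
                    c(hdr, list(normalization = "t * longest/replicate * reference/treatment")))
    write_trace_tsv(x$fel1, paste0(pre, "_fel1.tsv"), hdr)
    write_trace_tsv(x$displacement, paste0(pre, "_iron_displacement.tsv"), hdr)
    write_trace_tsv(x$interface_max, paste0(pre, "_interface_max.tsv"), hdr)
    write_trace_tsv(x$rmsd_slopes, paste0(pre, "_interface_rmsd_slopes.tsv"), hdr)
    write_trace_tsv(x$sasa, paste0(pre, "_sasa.tsv"), hdr)
  }
  summ <- lapply(bundle$event_summary, function(s)
    s[c("label", "n_chain_replicates", "raw_event_count",
        "returned_down_count", "normalized_event_count", "time_correction",
        "total_time", "reference_total_time")])
  jsonlite::write_json(list(events = summ, manifest = bundle$manifest),
                       file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.AnalysisBundle <- function(x, ...) {
  cat("AnalysisBundle:", length(x$treatments), "treatment(s)\n")
  for (s in x$event_summary) print(s)
  invisible(x)
}

## single-frame Trajectory view of a static structure
model_trajectory <- function(model) {
  new_trajectory(matrix(t(as.matrix(model$atoms[, c("x", "y", "z")])),
                        nrow = 1), times = 0, frame_spacing = 0)
}

#' Compare Fe-L1 and iron displacement between two crystal structures
#'
#' Single-frame application of the distance and iron-displacement
#' measures to a low- and a high-affinity deoxyhemoglobin structure:
#' per alpha-chain Fe-L1 (HisF8 NE2 - Fe) distance and iron
#' out-of-plane displacement, and their low-minus-high differences
#' (mean over alpha chains), in nm.
#'
#' @param pdb_low,pdb_high paths to the two PDB structures (low / high
#'   oxygen affinity).
#' @param map_low,map_high their `SiteMap`s (objects or YAML paths).
#' @return list with `per_chain` (data.frame) and `differences`
#'   (named: `fel1_nm`, `displacement_nm`; low minus high).
#' @export
compare_crystal_structures <- function(pdb_low, pdb_high, map_low, map_high) {
  load1 <- function(pdb, map) {
    model <- read_structure(pdb)
    if (is.character(map)) map <- read_site_map(map)
    list(model = model, map = map, traj = model_trajectory(model))
  }
  sides <- list(low = load1(pdb_low, map_low),
                high = load1(pdb_high, map_high))
  rows <- list()
  for (nm_ in names(sides)) {
    s <- sides[[nm_]]
    for (ch in map_chains(s$model, s$map, "alpha")) {
      heme <- heme_for_chain(s$model, ch)
      f8 <- resolve_site(s$model, s$map, "alpha", "F8", "NE2", chain = ch)
      dtr <- iron_plane_displacement(s$traj, heme, f8,
                                     equilibration_cutoff = 0)
      d <- distance_trace(s$traj, f8, heme$fe, equilibration_cutoff = 0)
      rows[[length(rows) + 1L]] <- data.frame(
        structure = nm_, chain = ch, fel1_nm = d$values[1],
        displacement_nm = abs(dtr$values[1]))
    }
  }
  tab <- do.call(rbind, rows)
  m <- function(st, col) mean(tab[[col]][tab$structure == st])
  list(per_chain = tab,
       differences = c(fel1_nm = m("low", "fel1_nm") - m("high", "fel1_nm"),
                       displacement_nm = m("low", "displacement_nm") -
                         m("high", "displacement_nm")))
}
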