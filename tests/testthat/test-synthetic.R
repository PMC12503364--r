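test_that("gating parameters are validated", {
  expect_error(gating_params(0.02, 0.002, mean_down = 0.8), "straddle")
  expect_error(gating_params(0.02, 0.002, mean_up = 0.6), "straddle")
  expect_error(gating_params(-1, 0.002), "non-negative")
  expect_error(gating_params(0.02, 0.002, ou_sd = 0), "positive")
})

test_that("rate-zero traces never cross and seeds are reproducible", {
  p <- gating_params(k_up = 0, k_down = 0, total_time = 200, seed = 5)
  g <- generate_gating_trace(p)
  expect_false(any(g$trace$values > 0.7))   # 8 sigma from the threshold
  expect_false(any(g$states))
  g2 <- generate_gating_trace(p)
  expect_identical(g$trace$values, g2$trace$values)
  ## different seed, different noise
  p3 <- gating_params(k_up = 0, k_down = 0, total_time = 200, seed = 6)
  expect_false(identical(generate_gating_trace(p3)$trace$values,
                         g$trace$values))
  ## generator does not disturb the caller's RNG stream
  set.seed(1); before <- stats::rnorm(1)
  set.seed(1); invisible(generate_gating_trace(p)); after <- stats::rnorm(1)
  expect_identical(before, after)
})

test_that("planted schedules override the Markov sampler exactly", {
  p <- gating_params(k_up = 0.02, k_down = 0.002, total_time = 50, seed = 8)
  g <- generate_gating_trace(p, schedule = c(10, 20, 35))
  expect_identical(g$transitions, c(10, 20, 35))
  expect_true(all(g$states[g$trace$times >= 10 & g$trace$times < 20]))
  expect_false(any(g$states[g$trace$times < 10]))
  expect_true(all(g$states[g$trace$times >= 35]))
})

test_that("first-passage statistics match two-state Markov theory", {
  ## moderate-n version of the calibration check (the acceptance suite
  ## runs the full 500-trace version)
  k_up <- 0.03; T <- 120
  p0 <- 1 - exp(-k_up * T)
  firsts <- numeric(200); swung <- logical(200)
  for (i in 1:200) {
    p <- gating_params(k_up = k_up, k_down = 0, total_time = T,
                       seed = 4000 + i)
    g <- generate_gating_trace(p, equilibration_cutoff = 0)
    r <- detect_swing(g$trace)
    swung[i] <- r$swung_out
    firsts[i] <- ifelse(r$swung_out, r$first_exceed_time, NA)
  }
  phat <- mean(swung)
  expect_lt(abs(phat - p0), 1.96 * sqrt(p0 * (1 - p0) / 200) + 0.01)
  ## truncated-exponential mean first passage
  m <- 1 / k_up - T * exp(-k_up * T) / (1 - exp(-k_up * T))
  e2 <- (2 / k_up^2 - exp(-k_up * T) * (T^2 + 2 * T / k_up + 2 / k_up^2)) /
    (1 - exp(-k_up * T))
  sd_t <- sqrt(e2 - m^2)
  obs <- mean(firsts[swung])
  expect_lt(abs(obs - m), 1.96 * sd_t / sqrt(sum(swung)) + 0.2)
})

test_that("the synthetic system plants its manifest truth", {
  sys <- tiny_study()
  expect_equal(sys$manifest$raw_swing_count, 2)
  expect_equal(sys$manifest$replicate_times, c(16, 20, 18))
  expect_true(file.exists(sys$manifest_path))
  js <- jsonlite::read_json(sys$manifest_path)
  expect_equal(js$raw_swing_count, 2)
  expect_equal(length(js$replicates), 3L)
  ## pipeline raw count equals planted truth
  model <- read_structure(sys$topology_path)
  map <- read_site_map(sys$map_path)
  recs <- list()
  for (r in seq_along(sys$trajectory_paths)) {
    traj <- read_trajectory(model, sys$trajectory_paths[r])
    for (ch in c("A", "C")) {
      e7 <- resolve_site(model, map, "alpha", "E7", "NE2", chain = ch)
      fe <- hemegating:::heme_for_chain(model, ch)$fe
      recs[[length(recs) + 1L]] <- detect_swing(
        distance_trace(traj, e7, fe), replicate_id = r, chain_id = ch)
    }
  }
  s <- count_events(recs, reference_total_time = sum(c(16, 20, 18)))
  expect_equal(s$raw_event_count, 2L)
  ## detected first-passage times match the planted schedule to one frame
  tab <- hemegating:::records_table(recs)
  expect_equal(tab$first_exceed_time[tab$replicate_id == 1 &
                                     tab$chain_id == "A"], 5, tolerance = 0.2)
  expect_equal(tab$first_exceed_time[tab$replicate_id == 3 &
                                     tab$chain_id == "C"], 8, tolerance = 0.2)
  ## replicate 3 chain C was planted to come back down at 12 ns,
  ## leaving a 6 ns dwell below threshold (>= the 5 ns requirement)
  expect_true(tab$returned_down[tab$replicate_id == 3 & tab$chain_id == "C"])
  expect_false(tab$returned_down[tab$replicate_id == 1 & tab$chain_id == "A"])
})

test_that("seed determinism gives byte-identical trajectory files", {
  d1 <- tempfile("det1"); d2 <- tempfile("det2")
  args <- list(species = "trout", n_replicates = 1, replicate_times = 6,
               swing_schedule = list(list(A = 2)), seed = 42)
  s1 <- do.call(generate_synthetic_system, c(list(d1), args))
  s2 <- do.call(generate_synthetic_system, c(list(d2), args))
  expect_identical(readLines(s1$trajectory_paths[1]),
                   readLines(s2$trajectory_paths[1]))
  expect_identical(readLines(s1$topology_path), readLines(s2$topology_path))
})

test_that("E11 burial series drives SASA monotonically", {
  expect_error(generate_e11_burial_series(c(0.2, 1.4)), "\\[0, 1\\]")
  p <- sasa_params(n_sphere_points = 240)
  ## monotone schedule: strongly monotone SASA
  open_f <- seq(0, 1, length.out = 30)
  bb <- generate_e11_burial_series(open_f)
  radii <- vdw_radii(bb$model$atoms$elety)
  vals <- vapply(seq_len(bb$traj$n_frames), function(f)
    sum(shrake_rupley(hemegating:::frame_coords(bb$traj, f), radii,
                      target = bb$target, params = p)), numeric(1))
  expect_lt(vals[1], 0.02 * vals[30])        # closed ~ buried
  expect_gt(stats::cor(vals, open_f, method = "spearman"), 0.95)
  ## constant schedule: constant SASA
  bbc <- generate_e11_burial_series(rep(0.5, 6))
  valsc <- vapply(1:6, function(f)
    sum(shrake_rupley(hemegating:::frame_coords(bbc$traj, f), radii,
                      target = bbc$target, params = p)), numeric(1))
  expect_equal(diff(range(valsc)), 0)
})
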