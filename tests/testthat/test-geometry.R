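make_traj <- function(frames) {
  ## frames: list of n x 3 matrices
  xyz <- do.call(rbind, lapply(frames, function(m) as.vector(t(m))))
  hemegating:::new_trajectory(xyz, 0.2 * (seq_along(frames) - 1), 0.2)
}

test_that("distance traces reproduce fixed and planted geometry", {
  ## two static atoms 0.45 nm apart
  fr <- matrix(c(0, 0, 0, 0.45, 0, 0), 2, 3, byrow = TRUE)
  tr <- distance_trace(make_traj(rep(list(fr), 5)), 1, 2,
                       equilibration_cutoff = 0)
  expect_equal(tr$values, rep(0.45, 5))
  ## atom with itself: all-zero
  tr0 <- distance_trace(make_traj(rep(list(fr), 5)), 2, 2,
                        equilibration_cutoff = 0)
  expect_equal(tr0$values, rep(0, 5))
  ## exact agreement with a naive per-frame recomputation
  set.seed(5)
  frames <- replicate(20, matrix(stats::rnorm(12), 4, 3), simplify = FALSE)
  traj <- make_traj(frames)
  tr2 <- distance_trace(traj, 1, 3, equilibration_cutoff = 0)
  naive <- vapply(frames, function(m) sqrt(sum((m[1, ] - m[3, ])^2)),
                  numeric(1))
  expect_identical(tr2$values, naive)
  expect_error(distance_trace(traj, 1, 99), "unresolved")
})

test_that("planted gating series is recovered from emitted coordinates", {
  sys <- tiny_study()
  model <- read_structure(sys$topology_path)
  map <- read_site_map(sys$map_path)
  traj <- read_trajectory(model, sys$trajectory_paths[3])
  e7 <- resolve_site(model, map, "alpha", "E7", "NE2", chain = "C")
  fe <- hemegating:::heme_for_chain(model, "C")$fe
  tr <- distance_trace(traj, e7, fe)
  expect_lt(max(abs(tr$values - sys$planted[[3]]$gating$C$values)), 1e-3)
})

test_that("mean_distance follows the shared averaging contract", {
  expect_equal(mean_distance(const_trace(0.21, n = 50), 1, 8), 0.21)
  alt <- make_trace(rep(c(0.2, 0.3), 20), cutoff = 0)
  expect_equal(mean_distance(alt, 0, 8), 0.25)
  ## planted OU mean recovered within 3 standard errors
  p <- gating_params(k_up = 0, k_down = 0, mean_down = 0.213,
                     total_time = 133, seed = 99)
  g <- generate_gating_trace(p)
  v <- g$trace$values[g$trace$times >= 1]
  ## effective n for an OU process: n * (1-a)/(1+a), a = exp(-dt/tau)
  a <- exp(-0.2 / 0.5)
  se <- 0.03 / sqrt(length(v) * (1 - a) / (1 + a))
  expect_lt(abs(mean_distance(g$trace, 1, 133) - 0.213), 3 * se)
  expect_error(mean_distance(const_trace(0.2), 5, 5), "empty")
})

test_that("iron displacement matches the analytic planted case", {
  ## N at (+-1,0,0),(0,+-1,0) A; Fe at (0,0,0.4) A; proximal ref at +z
  base <- rbind(c(0, 0, 0.04),                       # Fe
                c(0.1, 0, 0), c(0, 0.1, 0), c(-0.1, 0, 0), c(0, -0.1, 0),
                c(0, 0, 0.5))                         # proximal ref
  heme <- list(chain = "A", fe = 1L, pyrrole = 2:5)
  traj <- make_traj(list(base))
  d <- iron_plane_displacement(traj, heme, 6L, equilibration_cutoff = 0)
  expect_equal(d$values, 0.04, tolerance = 1e-12)
  ## Fe at the centroid: zero
  base0 <- base; base0[1, ] <- c(0, 0, 0)
  d0 <- iron_plane_displacement(make_traj(list(base0)), heme, 6L,
                                equilibration_cutoff = 0)
  expect_equal(d0$values, 0, tolerance = 1e-12)
  ## invariance under global rigid motion (independent centroid check)
  set.seed(7)
  for (k in 1:20) {
    R <- random_rotation(); t <- stats::rnorm(3)
    moved <- rigid_move(base, R, t)
    dm <- iron_plane_displacement(make_traj(list(moved)), heme, 6L,
                                  equilibration_cutoff = 0)
    expect_equal(dm$values, 0.04, tolerance = 1e-10)
    ## independent computation: |Fe - centroid| is rotation invariant
    expect_equal(sqrt(sum((moved[1, ] - colMeans(moved[2:5, ]))^2)),
                 0.04, tolerance = 1e-12)
  }
  ## sign is equivariant under proximal-reference reflection
  flipped <- base; flipped[6, 3] <- -0.5
  df <- iron_plane_displacement(make_traj(list(flipped)), heme, 6L,
                                equilibration_cutoff = 0)
  expect_equal(df$values, -0.04, tolerance = 1e-12)
  ## |signed| never exceeds |Fe - centroid|; perpendicular never
  ## exceeds the point-to-point value
  set.seed(8)
  for (k in 1:10) {
    m <- base
    m[1, ] <- stats::rnorm(3, sd = 0.05)
    m[2:5, 3] <- m[2:5, 3] + stats::rnorm(4, sd = 0.01)  # pucker the plane
    dd <- iron_plane_displacement(make_traj(list(m)), heme, 6L,
                                  equilibration_cutoff = 0)
    fe_c <- sqrt(sum((m[1, ] - colMeans(m[2:5, ]))^2))
    expect_lte(abs(dd$values), fe_c + 1e-12)
    expect_lte(abs(dd$perpendicular), abs(dd$values) + 1e-12)
  }
  ## collinear pyrrole nitrogens are degenerate
  bad <- base; bad[2:5, ] <- cbind(seq(0.1, 0.4, 0.1), 0, 0)
  expect_error(iron_plane_displacement(make_traj(list(bad)), heme, 6L),
               "degenerate|collinear")
})

test_that("kabsch_rmsd removes rigid motion and matches a brute-force oracle", {
  set.seed(21)
  x <- matrix(stats::rnorm(36), 12, 3)
  expect_equal(kabsch_rmsd(x, x), 0)
  for (k in 1:25)
    expect_lt(kabsch_rmsd(x, rigid_move(x)), 1e-10)
  ## one atom displaced: compare against grid + refinement minimization
  y <- x; y[4, ] <- y[4, ] + c(0.3, -0.2, 0.1)
  expect_equal(kabsch_rmsd(x, y), brute_force_rmsd(x, y), tolerance = 1e-6)
  ## and against an arbitrary deformation
  set.seed(22)
  z <- x + matrix(stats::rnorm(36, sd = 0.1), 12, 3)
  expect_equal(kabsch_rmsd(x, z), brute_force_rmsd(x, z), tolerance = 1e-6)
  expect_error(kabsch_rmsd(x[1:2, ], z[1:2, ]), "at least 3")
  expect_error(kabsch_rmsd(x, z[1:5, ]), "mismatched")
})

test_that("rmsd_trace is zero for static or rigid-body trajectories", {
  set.seed(30)
  ref <- matrix(stats::rnorm(30), 10, 3)
  static <- make_traj(rep(list(ref), 6))
  expect_equal(rmsd_trace(static, 1:10, equilibration_cutoff = 0)$values,
               rep(0, 6))
  rigid <- make_traj(c(list(ref), replicate(5, rigid_move(ref),
                                            simplify = FALSE)))
  expect_lt(max(rmsd_trace(rigid, 1:10, equilibration_cutoff = 0)$values),
            1e-10)
  ## planted deformation of known magnitude matches the oracle per frame
  frames <- list(ref)
  for (k in 1:4) {
    f <- ref + matrix(stats::rnorm(30, sd = 0.02 * k), 10, 3)
    frames[[k + 1]] <- rigid_move(f)
  }
  traj <- make_traj(frames)
  tr <- rmsd_trace(traj, 1:10, equilibration_cutoff = 0)
  for (k in 2:5) {
    fk <- matrix(traj$xyz[k, ], ncol = 3, byrow = TRUE)
    expect_equal(tr$values[k], brute_force_rmsd(ref, fk), tolerance = 1e-6)
  }
  expect_error(rmsd_trace(traj, 1:10, reference_frame = 99), "does not exist")
})

test_that("stacking geometry classifies constructed ring pairs", {
  hex <- function() cbind(0.139 * cos((0:5) * pi / 3),
                          0.139 * sin((0:5) * pi / 3), 0)
  a <- hex()
  ## parallel rings 3.8 A apart with 1.5 A lateral offset
  b <- sweep(hex(), 2, c(0.15, 0, 0.38), "+")
  g <- stacking_geometry(a, b)
  expect_equal(g$class, "parallel-displaced")
  expect_equal(g$centroid_distance_ang, sqrt(1.5^2 + 3.8^2), tolerance = 1e-6)
  expect_equal(g$offset_ang, 1.5, tolerance = 1e-6)
  expect_lt(g$interplanar_angle, 1)
  ## perpendicular rings, centroids 5.0 A apart
  c_ring <- cbind(0.139 * cos((0:5) * pi / 3), 0,
                  0.139 * sin((0:5) * pi / 3))
  g2 <- stacking_geometry(a, sweep(c_ring, 2, c(0, 0, 0.5), "+"))
  expect_equal(g2$class, "T-shaped")
  expect_equal(g2$interplanar_angle, 90, tolerance = 1e-6)
  ## parallel rings 8 A apart: outside every cutoff
  g3 <- stacking_geometry(a, sweep(hex(), 2, c(0, 0, 0.8), "+"))
  expect_equal(g3$class, "none")
  ## non-planar ring is rejected
  bad <- a; bad[, 3] <- c(0, 0.08, -0.08, 0.08, -0.08, 0)
  expect_error(stacking_geometry(bad, b), "planar")
})
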