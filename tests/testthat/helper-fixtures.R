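## Shared fixtures, built in code at test time.

## uniformly random proper rotation matrix (quaternion method)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

rigid_move <- function(coords, R = random_rotation(), t = stats::rnorm(3)) {
  sweep(coords %*% t(R), 2, t, "+")
}

## independent RMSD oracle: minimize over rotations by coarse Euler
## grid + Nelder-Mead refinement (translation optimum = centroids)
brute_force_rmsd <- function(reference, frame) {
  A <- sweep(frame, 2, colMeans(frame))
  B <- sweep(reference, 2, colMeans(reference))
  rot <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    Rz1 <- matrix(c(ca[1], -sa[1], 0, sa[1], ca[1], 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(ca[2], 0, sa[2], 0, 1, 0, -sa[2], 0, ca[2]), 3, byrow = TRUE)
    Rz2 <- matrix(c(ca[3], -sa[3], 0, sa[3], ca[3], 0, 0, 0, 1), 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(ang) sqrt(mean(rowSums((A %*% t(rot(ang)) - B)^2)))
  grid <- expand.grid(a = seq(0, 2 * pi, by = pi / 4),
                      b = seq(0, pi, by = pi / 4),
                      c = seq(0, 2 * pi, by = pi / 4))
  vals <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.min(vals), ])
  fit <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  fit$value
}

## brute-force oracle for swing detection on a numeric trace
brute_swing_scan <- function(times, values, cutoff = 1, threshold = 0.7) {
  keep <- times >= cutoff
  t <- times[keep]; v <- values[keep]
  hit <- v > threshold
  list(swung = any(hit),
       first = if (any(hit)) t[which(hit)[1]] else NA_real_)
}

## small synthetic study shared by interface/pipeline tests; cached per
## test run
tiny_study <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    dir <- file.path(tempdir(), "hg-tiny-study")
    cache <<- generate_synthetic_system(
      dir, species = "bovine", n_replicates = 3,
      replicate_times = c(16, 20, 18),
      swing_schedule = list(list(A = 5), list(), list(C = c(8, 12))),
      interface_excursion = list(replicate = 2, site = "B", time = 10,
                                 peak = 1.15, width = 1.5),
      seed = 11)
    cache
  }
})

## constant-value DistanceTrace helper
const_trace <- function(value, n = 30, dt = 0.2, cutoff = 1) {
  hemegating:::new_distance_trace("const", dt * (seq_len(n) - 1),
                                  rep(value, n), cutoff)
}

make_trace <- function(values, dt = 0.2, cutoff = 1) {
  hemegating:::new_distance_trace("t", dt * (seq_along(values) - 1),
                                  values, cutoff)
}
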