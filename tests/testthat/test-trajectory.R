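make_static_traj <- function(F = 3, N = 5, seed = 1) {
  set.seed(seed)
  base <- matrix(rnorm(N * 3, sd = 4), N, 3)
  arr <- array(NA_real_, c(F, N, 3))
  for (f in seq_len(F)) arr[f, , ] <- base
  trajectory(arr)
}

rot3 <- function(a, b) {
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(b), sin(b), 0, -sin(b), cos(b)), 3, 3)
  Rz %*% Rx
}

test_that("trajectory construction validates shape and content", {
  expect_error(trajectory(array(0, c(1, 5, 3))), "at least 2 frames")
  expect_error(trajectory(array(0, c(3, 1, 3))), "at least 2 residues")
  arr <- array(0, c(2, 3, 3)); arr[1, 1, 1] <- NaN
  expect_error(trajectory(arr), "non-finite")
})

test_that("trajectories round-trip through XYZ and CSV dialects", {
  tj <- make_coupled_trajectory(n_residues = 6, n_frames = 5, seed = 3)
  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(tj, xyz)
  back <- read_trajectory(xyz)
  expect_equal(back$coords, tj$coords, tolerance = 1e-6)
  expect_identical(n_frames(back), 5L)
  expect_identical(n_residues(back), 6L)
  csv <- withr::local_tempfile(fileext = ".csv")
  df <- expand.grid(residue = 1:6, frame = 1:5)
  df <- df[order(df$frame, df$residue), ]
  df$x <- as.vector(t(tj$coords[, , 1]))
  df$y <- as.vector(t(tj$coords[, , 2]))
  df$z <- as.vector(t(tj$coords[, , 3]))
  readr::write_csv(df, csv)
  back2 <- read_trajectory(csv)
  expect_equal(back2$coords, tj$coords, tolerance = 1e-9)
})

test_that("malformed trajectory files are rejected", {
  f <- withr::local_tempfile(fileext = ".xyz")
  # single frame
  readr::write_lines(c("2", "only frame", "R1 0 0 0", "R2 1 0 0"), f)
  expect_error(read_trajectory(f), "at least 2 frames")
  # non-numeric coordinate
  readr::write_lines(c("2", "f1", "R1 0 0 0", "R2 1 0 0",
                       "2", "f2", "R1 0 0 x", "R2 1 0 0"), f)
  expect_error(read_trajectory(f), "non-numeric")
  # ragged frames
  readr::write_lines(c("2", "f1", "R1 0 0 0", "R2 1 0 0",
                       "1", "f2", "R1 0 0 0"), f)
  expect_error(read_trajectory(f), "ragged")
})

test_that("replica concatenation drops equilibration frames with exact
          frame accounting", {
  reps <- lapply(1:3, function(s)
    make_coupled_trajectory(n_residues = 6, n_frames = 48, seed = s))
  macro <- discard_and_concatenate(reps, discard = 8)
  expect_identical(n_frames(macro), 120L)
  expect_equal(macro$coords[1, , ], reps[[1]]$coords[9, , ],
               tolerance = 1e-12)
  plain <- discard_and_concatenate(reps, discard = 0)
  expect_identical(n_frames(plain), 144L)
  expect_error(discard_and_concatenate(reps, discard = 48), "exceeds")
  reps[[2]] <- make_coupled_trajectory(n_residues = 7, n_frames = 48,
                                       seed = 2)
  expect_error(discard_and_concatenate(reps, 0), "residue count")
})

test_that("RMSD and RMSF vanish for static or rigidly moving
          trajectories", {
  st <- make_static_traj()
  expect_equal(rmsd_series(st)$rmsd, rep(0, 3), tolerance = 1e-10)
  expect_equal(rmsf_profile(st)$rmsf, rep(0, 5), tolerance = 1e-10)
  # per-frame rigid rotation + translation is removed by superposition
  tj <- make_static_traj(F = 4, N = 8, seed = 2)
  for (f in 2:4) {
    tj$coords[f, , ] <- sweep(tj$coords[f, , ] %*% rot3(0.3 * f, 0.5),
                              2, c(f, -f, 2 * f), "+")
  }
  expect_lt(max(rmsd_series(tj)$rmsd), 1e-8)
  expect_lt(max(rmsf_profile(tj)$rmsf), 1e-8)
})

test_that("the two-point RMSD equals the hand-computed half separation
          difference", {
  # two residues 2 A apart, then 4 A apart: optimal overlay leaves
  # |a - b| / 2 deviation per residue
  arr <- array(0, c(2, 2, 3))
  arr[1, 2, 1] <- 2
  arr[2, 2, 1] <- 4
  expect_equal(rmsd_series(trajectory(arr))$rmsd[2], 1,
               tolerance = 1e-10)
})

test_that("RMSD/RMSF are invariant under a global rigid transform of
          every frame", {
  tj <- make_coupled_trajectory(n_residues = 8, n_frames = 30, seed = 5)
  r0 <- rmsd_series(tj)$rmsd
  f0 <- rmsf_profile(tj)$rmsf
  R <- rot3(1.1, 0.4)
  tj2 <- tj
  for (f in seq_len(n_frames(tj))) {
    tj2$coords[f, , ] <- sweep(tj$coords[f, , ] %*% R, 2,
                               c(10, 20, -5), "+")
  }
  expect_equal(rmsd_series(tj2)$rmsd, r0, tolerance = 1e-6)
  expect_equal(rmsf_profile(tj2)$rmsf, f0, tolerance = 1e-6)
})

test_that("covariance modes recover a constructed one-dimensional
          oscillation", {
  F <- 200; N <- 5
  sig <- sin(seq(0, 6 * pi, length.out = F)) * 2
  arr <- array(0, c(F, N, 3))
  for (f in seq_len(F)) {
    arr[f, , 1] <- seq_len(N) * 4 + sig[f]
    arr[f, , 3] <- seq_len(N)  # static offsets
  }
  md <- covariance_modes(trajectory(arr), k = 3)
  expect_equal(md$eigenvalue[1], N * var(sig), tolerance = 1e-9)
  v <- md$vectors[[1]]
  expect_lt(max(abs(v[, 2:3])), 1e-9)
  expect_true(all(v[, 1] > 0))  # sign convention
  expect_true(all(diff(md$eigenvalue) <= 1e-12))
  expect_true(all(md$eigenvalue >= 0))
  expect_error(covariance_modes(trajectory(arr), k = 16), "3N")
})

test_that("isotropic white noise gives a flat eigenvalue spectrum", {
  set.seed(21)
  F <- 4000; N <- 4
  arr <- array(rnorm(F * N * 3), c(F, N, 3))
  md <- covariance_modes(trajectory(arr), k = 12)
  expect_lt(md$eigenvalue[1] / md$eigenvalue[12], 1.5)
})
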