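# Calpha trajectory container, I/O (multi-frame XYZ and long CSV),
# replica concatenation, Kabsch superposition, RMSD/RMSF, and principal
# modes of the displacement covariance.

#' Construct a trajectory
#'
#' @param coords Numeric array `F x N x 3` of Calpha coordinates in
#'   Angstrom (F frames, N residues).
#' @param labels Optional residue labels (length N).
#' @param domains Optional domain map tibble (`domain`, `start`, `end`).
#' @param dt Optional frame spacing (metadata only; no unit conversion is
#'   attempted).
#' @return A `trajectory` object.
#' @export
trajectory <- function(coords, labels = NULL, domains = NULL, dt = NULL) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    abort("coords must be an F x N x 3 array")
  }
  if (dim(coords)[1] < 2) abort("a trajectory needs at least 2 frames")
  if (dim(coords)[2] < 2) abort("a trajectory needs at least 2 residues")
  if (!all(is.finite(coords))) abort("non-finite coordinates")
  labels <- labels %||% paste0("R", seq_len(dim(coords)[2]))
  stopifnot(length(labels) == dim(coords)[2])
  structure(list(coords = coords, labels = labels,
                 domains = domains, dt = dt),
            class = "trajectory")
}

#' Number of frames / residues in a trajectory
#' @param traj A `trajectory`.
#' @return Integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname n_frames
#' @export
n_residues <- function(traj) dim(traj$coords)[2]

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d residues\n",
              n_frames(x), n_residues(x)))
  invisible(x)
}

#' Read a trajectory from multi-frame XYZ or long CSV
#'
#' XYZ dialect: per frame, a line with the atom count, a comment line,
#' then `N` lines `label x y z`. CSV dialect: columns `frame`, `residue`,
#' `x`, `y`, `z`. Ragged frames or non-numeric coordinates are errors.
#'
#' @param path Input path.
#' @param format "auto" (by extension), "xyz" or "csv".
#' @return A `trajectory`.
#' @export
read_trajectory <- function(path, format = c("auto", "xyz", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
              else "xyz"
  }
  if (format == "csv") {
    df <- readr::read_csv(path, show_col_types = FALSE)
    stopifnot(all(c("frame", "residue", "x", "y", "z") %in% names(df)))
    frames <- sort(unique(df$frame))
    resn <- sort(unique(df$residue))
    counts <- table(df$frame)
    if (length(unique(counts)) != 1) abort("ragged frames")
    arr <- array(NA_real_, c(length(frames), length(resn), 3))
    fi <- match(df$frame, frames)
    ri <- match(df$residue, resn)
    arr[cbind(fi, ri, 1)] <- df$x
    arr[cbind(fi, ri, 2)] <- df$y
    arr[cbind(fi, ri, 3)] <- df$z
    if (anyNA(arr)) abort("ragged frames or non-numeric coordinates")
    return(trajectory(arr, labels = as.character(resn)))
  }
  lines <- readr::read_lines(path)
  frames <- list()
  labels <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) abort(sprintf("bad atom-count line at %d", i))
    block <- lines[(i + 2):(i + 1 + nat)]
    if (length(block) < nat || anyNA(block)) abort("ragged frames")
    parts <- strsplit(trimws(block), "\\s+")
    if (any(lengths(parts) != 4)) abort("malformed coordinate line")
    m <- matrix(suppressWarnings(
      as.numeric(unlist(lapply(parts, `[`, 2:4)))), ncol = 3,
      byrow = TRUE)
    if (anyNA(m)) abort("non-numeric coordinates")
    labels <- vapply(parts, `[`, "", 1)
    frames[[length(frames) + 1]] <- m
    i <- i + 2 + nat
  }
  if (length(unique(vapply(frames, nrow, 1L))) != 1) {
    abort("ragged frames")
  }
  arr <- aperm(simplify2array(frames), c(3, 1, 2))
  trajectory(arr, labels = labels)
}

#' Write a trajectory as multi-frame XYZ
#' @param traj A `trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  N <- n_residues(traj)
  out <- unlist(lapply(seq_len(n_frames(traj)), function(f) {
    m <- traj$coords[f, , , drop = TRUE]
    c(as.character(N), sprintf("frame %d", f),
      sprintf("%s %.6f %.6f %.6f", traj$labels, m[, 1], m[, 2], m[, 3]))
  }))
  readr::write_lines(out, path)
  invisible(path)
}

#' Discard equilibration frames and concatenate replicas
#'
#' Drops the first `discard` frames of each replica (the equilibration
#' portion) and concatenates the remainder in order, e.g. three 48-frame
#' replicas with 8 discarded each yield a 120-frame macro-trajectory.
#'
#' @param replicas List of `trajectory` objects sharing a residue count.
#' @param discard Leading frame count to drop, scalar or per-replica.
#' @return A concatenated `trajectory`.
#' @export
discard_and_concatenate <- function(replicas, discard = 0) {
  stopifnot(length(replicas) >= 1)
  Ns <- vapply(replicas, n_residues, 1L)
  if (length(unique(Ns)) != 1) abort("replicas differ in residue count")
  discard <- rep(as.integer(discard), length.out = length(replicas))
  kept <- purrr::map2(replicas, discard, function(tr, d) {
    if (d >= n_frames(tr)) abort("discard exceeds replica length")
    tr$coords[(d + 1):n_frames(tr), , , drop = FALSE]
  })
  arr <- do.call(abind_frames, kept)
  trajectory(arr, labels = replicas[[1]]$labels,
             domains = replicas[[1]]$domains, dt = replicas[[1]]$dt)
}

abind_frames <- function(...) {
  parts <- list(...)
  N <- dim(parts[[1]])[2]
  arr <- array(NA_real_, c(sum(vapply(parts, function(p) dim(p)[1], 1L)),
                           N, 3))
  at <- 1
  for (p in parts) {
    arr[at:(at + dim(p)[1] - 1), , ] <- p
    at <- at + dim(p)[1]
  }
  arr
}

# optimal rotation (Kabsch, via SVD) aligning mobile onto target;
# both N x 3, returns the superposed mobile coordinates
kabsch_align <- function(mobile, target) {
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  Xc <- sweep(mobile, 2, cm)
  Yc <- sweep(target, 2, ct)
  s <- svd(t(Xc) %*% Yc)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(Xc %*% R, 2, ct, "+")
}

#' Superpose every frame onto a common reference
#'
#' Each frame is rigidly fitted (rotation + translation, Kabsch) onto the
#' reference. With `reference = "mean"` the reference is the mean
#' structure refined by iterative fitting (default 2 passes), which
#' stabilizes downstream covariances for short trajectories.
#'
#' @param traj A `trajectory`.
#' @param reference "mean" or "frame".
#' @param frame Reference frame index when `reference = "frame"`.
#' @param passes Mean-structure refinement passes.
#' @return A superposed `trajectory`.
#' @export
superpose_trajectory <- function(traj, reference = c("mean", "frame"),
                                 frame = 1, passes = 2) {
  reference <- match.arg(reference)
  arr <- traj$coords
  align_all <- function(arr, ref) {
    for (f in seq_len(dim(arr)[1])) {
      arr[f, , ] <- kabsch_align(arr[f, , , drop = TRUE], ref)
    }
    arr
  }
  if (reference == "frame") {
    arr <- align_all(arr, arr[frame, , , drop = TRUE])
  } else {
    ref <- arr[1, , , drop = TRUE]
    for (p in seq_len(passes)) {
      arr <- align_all(arr, ref)
      ref <- apply(arr, c(2, 3), mean)
    }
    arr <- align_all(arr, ref)
  }
  out <- traj
  out$coords <- arr
  out
}

#' Per-frame RMSD against a reference frame
#'
#' Each frame is optimally superposed onto the reference frame before the
#' deviation is computed, so rigid-body motion contributes nothing.
#'
#' @param traj A `trajectory`.
#' @param reference Reference frame index, default 1.
#' @return Tibble `frame`, `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, reference = 1) {
  ref <- traj$coords[reference, , , drop = TRUE]
  rmsd <- vapply(seq_len(n_frames(traj)), function(f) {
    al <- kabsch_align(traj$coords[f, , , drop = TRUE], ref)
    sqrt(mean(rowSums((al - ref)^2)))
  }, numeric(1))
  tibble(frame = seq_len(n_frames(traj)), rmsd = rmsd)
}

#' Per-residue RMSF about the mean structure
#'
#' Frames are superposed onto the iteratively refined mean structure; the
#' fluctuation of residue `i` is the root mean square distance from its
#' mean position.
#'
#' @param traj A `trajectory`.
#' @return Tibble `residue`, `label`, `rmsf` (Angstrom).
#' @export
rmsf_profile <- function(traj) {
  sp <- superpose_trajectory(traj, "mean")
  mu <- apply(sp$coords, c(2, 3), mean)
  dev2 <- vapply(seq_len(n_residues(traj)), function(i) {
    mean(rowSums(sweep(sp$coords[, i, , drop = TRUE], 2, mu[i, ])^2))
  }, numeric(1))
  tibble(residue = seq_len(n_residues(traj)), label = traj$labels,
         rmsf = sqrt(dev2))
}

#' Principal modes of the displacement covariance
#'
#' Eigen-decomposition of the `3N x 3N` covariance of mean-centered
#' Calpha coordinates. The input is expected to be superposed already
#' (use [superpose_trajectory()]); rigid-body motion left in the
#' trajectory will appear as modes. Eigenvector sign is fixed so the
#' largest-magnitude component is positive.
#'
#' @param traj A (superposed) `trajectory`.
#' @param k Number of modes to return.
#' @return Tibble of class `mode_projections`: `mode`, `eigenvalue`
#'   (A^2), and list-column `vectors` of `N x 3` per-residue
#'   displacement matrices.
#' @export
covariance_modes <- function(traj, k = 1) {
  F <- n_frames(traj)
  N <- n_residues(traj)
  if (k > 3 * N) abort("k exceeds 3N")
  # F x 3N with residue-major layout (x1,y1,z1,x2,...)
  X <- do.call(cbind, lapply(seq_len(N), function(i) {
    traj$coords[, i, , drop = TRUE]
  }))
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / (F - 1)
  e <- eigen(C, symmetric = TRUE)
  rows <- map(seq_len(k), function(m) {
    v <- e$vectors[, m]
    if (v[which.max(abs(v))] < 0) v <- -v
    tibble(mode = m, eigenvalue = max(e$values[m], 0),
           vectors = list(matrix(v, ncol = 3, byrow = TRUE)))
  }) |> list_rbind()
  class(rows) <- c("mode_projections", class(rows))
  rows
}

#' Export the first mode as a porcupine pseudo-atom PDB
#'
#' Writes, for each residue, a pseudo-atom at the mean Calpha position
#' and a second at the tip of the (scaled) mode-1 displacement vector, so
#' standard viewers can draw the principal-motion spikes.
#'
#' @param modes A `mode_projections` from [covariance_modes()].
#' @param traj The trajectory the modes came from.
#' @param path Output PDB path.
#' @param scale Arrow scale factor.
#' @return `path`, invisibly.
#' @export
write_porcupine_pdb <- function(modes, traj, path, scale = 10) {
  mu <- apply(traj$coords, c(2, 3), mean)
  v <- modes$vectors[[1]]
  tips <- mu + scale * v
  N <- nrow(mu)
  # interleave base/tip per residue
  coords <- matrix(NA_real_, 2 * N, 3)
  coords[seq(1, 2 * N, 2), ] <- mu
  coords[seq(2, 2 * N, 2), ] <- tips
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = c(t(coords)),
    resno = rep(seq_len(N), each = 2),
    resid = rep("GLY", 2 * N),
    elety = rep(c("CA", "TIP"), N),
    chain = rep("A", 2 * N))
  invisible(path)
}
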