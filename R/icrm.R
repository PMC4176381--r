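# Distance-gated correlated-motion matrix (ICRM) and its first-eigenvalue
# coordination score. The matrix is the absolute normalized displacement
# covariance between residue pairs, with entries zeroed for pairs whose
# mean Calpha-Calpha distance exceeds the gating threshold. Only relative
# orderings of scores across systems are meaningful on this definition;
# the absolute scale depends on the normalization chosen.

#' Internal coordination matrix of a trajectory
#'
#' Entry `(i, j)` is `|<d_i . d_j>| / sqrt(<|d_i|^2> <|d_j|^2>)`, where
#' `d` are mean-centered per-residue Calpha displacement 3-vectors, so
#' entries lie in `[0, 1]` with a unit diagonal. Pairs whose mean
#' distance exceeds `distance_threshold` (default 30 Angstrom) are set to
#' exactly 0. Residues with zero displacement variance are flagged with a
#' warning and their rows/columns zeroed. The trajectory is used as
#' given; superpose first (see [superpose_trajectory()]) when rigid-body
#' motion should be removed.
#'
#' @param traj A `trajectory`.
#' @param distance_threshold Gating distance, Angstrom; `Inf` disables
#'   gating.
#' @return An `icrm_matrix`: `N x N` matrix with attributes `threshold`,
#'   `gate_mask` (TRUE where gated out), `n_frames`.
#' @export
icrm <- function(traj, distance_threshold = 30) {
  arr <- traj$coords
  F <- dim(arr)[1]
  N <- dim(arr)[2]
  mu <- apply(arr, c(2, 3), mean)
  # displacement matrices per axis: F x N
  dx <- sweep(arr[, , 1, drop = TRUE], 2, mu[, 1])
  dy <- sweep(arr[, , 2, drop = TRUE], 2, mu[, 2])
  dz <- sweep(arr[, , 3, drop = TRUE], 2, mu[, 3])
  cov <- (crossprod(dx) + crossprod(dy) + crossprod(dz)) / F
  v <- diag(cov)
  zero_var <- v < 1e-12
  if (any(zero_var)) {
    warn(sprintf("%d residue(s) with zero displacement variance zeroed",
                 sum(zero_var)))
  }
  denom <- sqrt(outer(pmax(v, 1e-300), pmax(v, 1e-300)))
  m <- abs(cov) / denom
  m[zero_var, ] <- 0
  m[, zero_var] <- 0
  diag(m)[!zero_var] <- 1

  # mean pairwise distance over frames
  dsum <- matrix(0, N, N)
  for (f in seq_len(F)) {
    dsum <- dsum + .pdist(arr[f, , , drop = TRUE],
                          arr[f, , , drop = TRUE])
  }
  mask <- (dsum / F) > distance_threshold
  m[mask] <- 0
  m <- (m + t(m)) / 2  # enforce exact symmetry
  structure(m, threshold = distance_threshold, gate_mask = mask,
            n_frames = F, class = c("icrm_matrix", "matrix"))
}

#' First-eigenvalue coordination score
#'
#' The largest eigenvalue of the gated correlation matrix summarizes how
#' globally coordinated the motion is: 1 for fully uncorrelated residues
#' (identity matrix), `N` for perfectly coherent motion (all-ones
#' matrix).
#'
#' @param m An `icrm_matrix`.
#' @param system Optional system label.
#' @return One-row tibble: `system`, `first_eigenvalue`.
#' @export
coordination_score <- function(m, system = NA_character_) {
  ev <- eigen(unclass(m), symmetric = TRUE, only.values = TRUE)$values
  tibble(system = system, first_eigenvalue = ev[1])
}

#' Mean correlation per domain block
#'
#' Averages the off-diagonal entries of the gated matrix within and
#' between named domains, the block-level view of inter-domain
#' coordination.
#'
#' @param m An `icrm_matrix`.
#' @param domains Domain map tibble: `domain`, `start`, `end` (residue
#'   index ranges covering matrix indices).
#' @return Tibble: `domain_i`, `domain_j`, `mean_correlation`, `n_pairs`.
#' @export
domain_block_summary <- function(m, domains) {
  N <- nrow(m)
  if (any(domains$start < 1) || any(domains$end > N)) {
    abort("domain indices out of matrix range")
  }
  dn <- domains$domain
  idx <- lapply(seq_len(nrow(domains)), function(k) {
    domains$start[k]:domains$end[k]
  })
  grid <- expand.grid(ki = seq_along(dn), kj = seq_along(dn))
  grid <- grid[grid$ki <= grid$kj, ]
  pmap(grid, function(ki, kj) {
    block <- unclass(m)[idx[[ki]], idx[[kj]], drop = FALSE]
    if (ki == kj) {
      vals <- block[upper.tri(block)]
    } else {
      vals <- as.vector(block)
    }
    tibble(domain_i = dn[ki], domain_j = dn[kj],
           mean_correlation = if (length(vals)) mean(abs(vals)) else
             NA_real_,
           n_pairs = length(vals))
  }) |> list_rbind()
}

#' @export
tidy.icrm_matrix <- function(x, ...) {
  N <- nrow(x)
  g <- expand.grid(i = seq_len(N), j = seq_len(N))
  tibble(i = g$i, j = g$j,
         correlation = as.vector(unclass(x)),
         gated = as.vector(attr(x, "gate_mask")))
}

#' Write a correlation matrix as tab-separated text
#'
#' A header comment records the gating threshold and a scale disclaimer.
#'
#' @param m An `icrm_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_icrm <- function(m, path) {
  hdr <- c(
    sprintf("# ICRM: absolute normalized displacement covariance"),
    sprintf("# gate_angstrom\t%g", attr(m, "threshold")),
    "# NOTE: entries are normalized to [0,1]; only relative orderings",
    "# of eigenvalues across systems are comparable on this scale")
  readr::write_lines(hdr, path)
  readr::write_tsv(as.data.frame(unclass(m)), path, append = TRUE)
  invisible(path)
}
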