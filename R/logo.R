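# Sequence-logo statistics over a bound set: Boltzmann weights, weighted
# and unweighted frequency matrices, per-position information content,
# threshold sweeps, and pairwise conditional-probability tables.

#' Boltzmann weights from relative binding energies
#'
#' `w_i` proportional to `exp(-ddG_i / kT)`, normalized to sum 1. Weights
#' are invariant under a uniform shift of the energies, and converge to
#' uniform as `kT -> Inf`.
#'
#' @param ddG Numeric vector of relative energies, kcal/mol.
#' @param kT Thermal energy in kcal/mol; default 0.593 (298 K).
#' @return Numeric weight vector summing to 1.
#' @export
boltzmann_weights <- function(ddG, kT = 0.593) {
  if (length(ddG) == 0) abort("empty energy list")
  if (!is.numeric(kT) || kT <= 0) abort("kT must be positive")
  w <- exp(-(ddG - min(ddG)) / kT)
  w / sum(w)
}

.motif_char_matrix <- function(motifs) {
  L <- unique(nchar(motifs))
  if (length(L) != 1) abort("motifs must share a common length")
  matrix(unlist(strsplit(motifs, "")), nrow = length(motifs),
         ncol = L, byrow = TRUE)
}

#' Position frequency matrix of a motif set
#'
#' Column `j` gives the (optionally weighted) probability of each base at
#' position `j`; every column sums to 1. Base order is fixed A, C, G, T.
#'
#' @param motifs Character vector of equal-length motifs.
#' @param weights Optional weight vector aligned with `motifs` (defaults
#'   to uniform); normalized internally.
#' @return A 4 x L matrix of class `frequency_matrix` (rows A,C,G,T).
#' @export
frequency_matrix <- function(motifs, weights = NULL) {
  M <- .motif_char_matrix(motifs)
  L <- ncol(M)
  if (is.null(weights)) weights <- rep(1, nrow(M))
  if (length(weights) != nrow(M)) {
    abort("weights must align with motifs")
  }
  w <- weights / sum(weights)
  fm <- vapply(seq_len(L), function(j) {
    vapply(.BASES, function(b) sum(w[M[, j] == b]), numeric(1))
  }, numeric(4))
  dimnames(fm) <- list(.BASES, paste0("pos", seq_len(L)))
  structure(fm, class = c("frequency_matrix", "matrix"))
}

#' Per-position information content
#'
#' `IC_j = 2 + sum_b p_bj log2 p_bj` bits, with `0 log 0 := 0`; bounded in
#' `[0, 2]` (0 for a uniform column, 2 for a single-base column).
#'
#' @param fm A [frequency_matrix()].
#' @return Tibble with `position` and `bits`.
#' @export
information_profile <- function(fm) {
  plogp <- function(p) ifelse(p > 0, p * log2(p), 0)
  tibble(position = seq_len(ncol(fm)),
         bits = 2 + colSums(plogp(unclass(fm))))
}

#' Frequency matrices across a threshold sweep
#'
#' For each threshold, takes the bound set at that cutoff and compiles the
#' uniform-weight frequency matrix, showing how the logo composition
#' changes as lower-ranked motifs are admitted.
#'
#' @param table A `scan_table`.
#' @param thresholds Ascending numeric vector of cutoffs, kcal/mol.
#' @return Tibble with `threshold`, `n_bound`, and a list-column `fm` of
#'   frequency matrices.
#' @export
frequency_vs_threshold <- function(table, thresholds) {
  if (is.unsorted(thresholds)) abort("thresholds must be ascending")
  map(thresholds, function(t) {
    bs <- select_bound(table, t)
    tibble(threshold = t, n_bound = nrow(bs$bound),
           fm = list(frequency_matrix(bs$bound$motif)))
  }) |> list_rbind()
}

#' Pairwise conditional probabilities between motif positions
#'
#' For every ordered pair of distinct positions `(i, j)` and bases
#' `(a, b)`, computes `P(b at j | a at i)` under the given weights,
#' together with the marginal `P(b at j)` and their difference `delta`
#' (the interaction signal). Entries whose conditioning event has zero
#' weight are reported with `defined = FALSE` and `p = NA`, never as 0.
#'
#' @inheritParams frequency_matrix
#' @param flag_threshold Report threshold on `|delta|` for the `flagged`
#'   column; default 0.1.
#' @return Long tibble of class `cond_prob`: `i`, `a`, `j`, `b`,
#'   `p_joint`, `p_cond`, `p_marginal`, `delta`, `defined`, `flagged`.
#' @export
conditional_probabilities <- function(motifs, weights = NULL,
                                      flag_threshold = 0.1) {
  M <- .motif_char_matrix(motifs)
  L <- ncol(M)
  if (L < 2) abort("need at least two positions")
  if (is.null(weights)) weights <- rep(1, nrow(M))
  w <- weights / sum(weights)
  marg <- frequency_matrix(motifs, w)
  grid <- expand.grid(i = seq_len(L), a = .BASES, j = seq_len(L),
                      b = .BASES, stringsAsFactors = FALSE)
  grid <- grid[grid$i != grid$j, ]
  rows <- pmap(grid, function(i, a, j, b) {
    wa <- sum(w[M[, i] == a])
    joint <- sum(w[M[, i] == a & M[, j] == b])
    defined <- wa > 0
    pc <- if (defined) joint / wa else NA_real_
    tibble(i = i, a = a, j = j, b = b,
           p_joint = joint, p_cond = pc,
           p_marginal = marg[b, j],
           delta = pc - marg[b, j], defined = defined)
  }) |> list_rbind()
  rows$flagged <- rows$defined & abs(rows$delta) > flag_threshold
  class(rows) <- c("cond_prob", class(rows))
  rows
}

#' @export
tidy.frequency_matrix <- function(x, ...) {
  as_tibble(as.data.frame.table(unclass(x), responseName = "p")) |>
    rename(base = "Var1", position = "Var2") |>
    mutate(base = as.character(.data$base),
           position = as.integer(sub("pos", "", .data$position)))
}

#' Write a frequency matrix as tab-separated text
#' @param fm A [frequency_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_matrix <- function(fm, path) {
  df <- as.data.frame(unclass(fm))
  df <- cbind(base = rownames(fm), df)
  readr::write_tsv(df, path)
  invisible(path)
}
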