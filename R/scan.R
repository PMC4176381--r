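# Exhaustive motif-space scan: enumerate all 4^L sequences, thread each
# onto the fixed backbone, score with the energy function, rank by ddG
# relative to the best-scoring motif, and partition at a threshold.

#' Enumerate all DNA motifs of a given length
#'
#' Yields the full 4^L motif space in lexicographic order (A < C < G < T).
#'
#' @param L Motif length, 1-12 (the upper bound guards against explosion;
#'   4^12 ~ 1.7e7).
#' @return Character vector of 4^L distinct motifs.
#' @examples
#' enumerate_motifs(1)  # "A" "C" "G" "T"
#' length(enumerate_motifs(8))  # 65536
#' @export
enumerate_motifs <- function(L) {
  if (!is.numeric(L) || length(L) != 1 || L < 1 || L > 12 || L != round(L)) {
    abort("L must be an integer in 1..12")
  }
  g <- expand.grid(rep(list(.BASES), L), stringsAsFactors = FALSE)
  do.call(paste0, rev(unname(as.list(g))))
}

#' Scan the full motif space against a complex
#'
#' Threads every motif of length `L = duplex_length(complex)` (or a
#' supplied subset) onto the fixed backbone, evaluates the four-term
#' binding energy, and ranks records by `ddG = total - min(total)` with
#' lexicographic tie-breaking. The scan is deterministic: repeated runs on
#' the same inputs give identical tables.
#'
#' @param complex A `protein_dna_complex`.
#' @param params An [energy_params()] list.
#' @param motifs Optional character vector of motifs to score (defaults to
#'   the full enumeration).
#' @return A tibble of class `scan_table`: `motif`, `ddG`, `rank`, the four
#'   energy terms and `total`, sorted ascending by `ddG`. Attributes:
#'   `reference` (the input complex's sequence), `L`, `params`.
#' @export
scan_motifs <- function(complex, params = energy_params(), motifs = NULL) {
  L <- duplex_length(complex)
  motifs <- motifs %||% enumerate_motifs(L)
  if (any(nchar(motifs) != L)) {
    abort("all motifs must match the duplex length")
  }
  rows <- map(motifs, function(m) {
    bd <- tryCatch(
      binding_energy(thread_sequence(complex, m), params),
      error = function(e) {
        abort(sprintf("scoring failed for motif %s: %s", m,
                      conditionMessage(e)))
      })
    mutate(as_tibble(bd), motif = m, .before = 1)
  }) |> list_rbind()
  rows <- rows |>
    mutate(ddG = .data$total - min(.data$total)) |>
    arrange(.data$ddG, .data$motif) |>
    mutate(rank = row_number()) |>
    select("motif", "ddG", "rank", "clash_dna", "clash_protein",
           "interaction_energy", "sidechain_hbond", "total")
  attr(rows, "reference") <- complex$reference_sequence
  attr(rows, "L") <- L
  attr(rows, "params") <- params
  class(rows) <- c("scan_table", class(rows))
  rows
}

#' Partition a scan table into bound and residual motifs
#'
#' The bound set contains every record with `ddG <= threshold` (inclusive,
#' measured from the top-ranked motif); counts are conserved exactly:
#' `nrow(bound) + residual_count == nrow(table)`.
#'
#' @param table A `scan_table`.
#' @param threshold Energy cutoff in kcal/mol (>= 0), default 3.
#' @return A `bound_set` list: `threshold`, `bound` (tibble of records),
#'   `residual_count`, `L`, `reference`.
#' @export
select_bound <- function(table, threshold = 3.0) {
  stopifnot(threshold >= 0)
  bound <- filter(as_tibble(table), .data$ddG <= threshold)
  structure(list(
    threshold = threshold,
    bound = bound,
    residual_count = nrow(table) - nrow(bound),
    L = attr(table, "L"),
    reference = attr(table, "reference")),
    class = "bound_set")
}

#' @export
print.bound_set <- function(x, ...) {
  cat(sprintf(
    "<bound_set> threshold %.2f kcal/mol: %d bound / %d residual\n",
    x$threshold, nrow(x$bound), x$residual_count))
  invisible(x)
}

#' @export
glance.scan_table <- function(x, ...) {
  tibble(n_motifs = nrow(x), L = attr(x, "L"),
         reference = attr(x, "reference"),
         best_motif = x$motif[1], ddG_max = max(x$ddG))
}

#' Write a scan table as tab-separated text
#' @param table A `scan_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(table, path) {
  readr::write_tsv(as_tibble(table), path)
  invisible(path)
}
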