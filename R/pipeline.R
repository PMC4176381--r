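# End-to-end orchestration: scan -> bound set -> logo statistics with a
# run manifest, and multi-system trajectory comparison.

#' Run the full motif-scan pipeline
#'
#' Scans the motif space of the complex, partitions at the threshold,
#' builds Boltzmann-weighted and unweighted frequency matrices,
#' information profiles, and the conditional-probability table, and
#' returns everything with a manifest of counts and parameters. When
#' `out_dir` is given, all stage outputs are written there as
#' tab-separated text.
#'
#' @param complex A `protein_dna_complex`.
#' @param params An [energy_params()] list.
#' @param threshold Bound-set cutoff, kcal/mol (default 3).
#' @param kT Boltzmann temperature, kcal/mol (default 0.593).
#' @param out_dir Optional output directory.
#' @return A `scan_pipeline_result` list: `scan`, `bound`, `weights`,
#'   `fm_weighted`, `fm_unweighted`, `information`, `conditional`,
#'   `manifest`.
#' @export
run_scan_pipeline <- function(complex, params = energy_params(),
                              threshold = 3.0, kT = 0.593,
                              out_dir = NULL) {
  tab <- scan_motifs(complex, params)
  bs <- select_bound(tab, threshold)
  w <- boltzmann_weights(bs$bound$ddG, kT)
  fmw <- frequency_matrix(bs$bound$motif, w)
  fmu <- frequency_matrix(bs$bound$motif)
  info <- information_profile(fmw)
  cp <- conditional_probabilities(bs$bound$motif, w)
  manifest <- tibble(
    key = c("reference", "L", "n_motifs", "n_bound", "n_residual",
            "threshold_kcal_mol", "kT_kcal_mol"),
    value = as.character(c(
      attr(tab, "reference"), attr(tab, "L"), nrow(tab),
      nrow(bs$bound), bs$residual_count, threshold, kT)))
  out <- structure(list(
    scan = tab, bound = bs, weights = w, fm_weighted = fmw,
    fm_unweighted = fmu, information = info, conditional = cp,
    manifest = manifest), class = "scan_pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_scan_table(tab, file.path(out_dir, "scan.tsv"))
    readr::write_tsv(bs$bound, file.path(out_dir, "bound.tsv"))
    write_frequency_matrix(fmw,
                           file.path(out_dir, "frequency_weighted.tsv"))
    write_frequency_matrix(fmu,
                           file.path(out_dir, "frequency_unweighted.tsv"))
    readr::write_tsv(info, file.path(out_dir, "information.tsv"))
    readr::write_tsv(as_tibble(cp),
                     file.path(out_dir, "conditional.tsv"))
    readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  }
  out
}

#' @export
print.scan_pipeline_result <- function(x, ...) {
  cat("<scan_pipeline_result>\n")
  print(x$manifest, n = nrow(x$manifest))
  invisible(x)
}

#' Compare coordination across trajectory systems
#'
#' Computes the distance-gated correlation matrix and its first
#' eigenvalue for each named trajectory, ranks the systems by score
#' (descending), and summarizes inter-domain blocks where a domain map
#' is available.
#'
#' @param trajectories Named list of `trajectory` objects sharing a
#'   residue count.
#' @param gate Gating distance, Angstrom (default 30).
#' @param domains Optional shared domain map (falls back to each
#'   trajectory's own).
#' @return A `dynamics_comparison` list: `ranking` (tibble `system`,
#'   `first_eigenvalue`, `rank`), `matrices` (named list), `blocks`
#'   (tibble or NULL).
#' @export
run_dynamics_comparison <- function(trajectories, gate = 30,
                                    domains = NULL) {
  stopifnot(length(trajectories) >= 1)
  nm <- names(trajectories) %||%
    paste0("system", seq_along(trajectories))
  Ns <- vapply(trajectories, n_residues, 1L)
  if (length(unique(Ns)) != 1) {
    abort("trajectories differ in residue count")
  }
  mats <- purrr::map(trajectories, icrm, distance_threshold = gate)
  names(mats) <- nm
  ranking <- purrr::imap(mats, function(m, s) coordination_score(m, s)) |>
    list_rbind() |>
    arrange(desc(.data$first_eigenvalue)) |>
    mutate(rank = row_number())
  blocks <- purrr::imap(mats, function(m, s) {
    dm <- domains %||% trajectories[[s]]$domains
    if (is.null(dm)) return(NULL)
    mutate(domain_block_summary(m, dm), system = s, .before = 1)
  }) |> purrr::compact()
  blocks <- if (length(blocks)) list_rbind(blocks) else NULL
  structure(list(ranking = ranking, matrices = mats, blocks = blocks),
            class = "dynamics_comparison")
}

#' @export
print.dynamics_comparison <- function(x, ...) {
  cat("<dynamics_comparison>\n")
  print(x$ranking)
  invisible(x)
}
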