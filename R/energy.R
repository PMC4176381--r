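# Term-decomposed empirical binding energy: steric clash (DNA-internal and
# protein-DNA), a distance-weighted favorable interaction term, and
# geometric side-chain-to-base hydrogen bonds. All terms depend only on
# interatomic distances and angles, so every term is invariant under
# rigid-body transforms of the whole complex.

#' Energy function parameters
#'
#' Defaults: hydrogen bonds accepted at donor-acceptor distance
#' 2.5-3.5 A and donor angle >= 120 degrees, worth -1 kcal/mol at ideal
#' geometry with linear distance/angle attenuation; soft quadratic clash
#' penalty below 0.9 x the sum of van der Waals radii; favorable
#' interaction well truncated at 6 A. All values are configurable; only
#' relative energies between threaded variants are meaningful.
#'
#' @param hbond_dist_min,hbond_dist_max Donor-acceptor distance window, A.
#' @param hbond_angle_min Minimum donor angle, degrees.
#' @param hbond_well_depth Energy of an ideal bond, kcal/mol (positive
#'   number; contributes negatively).
#' @param clash_radius_scale Fraction of summed van der Waals radii below
#'   which the clash penalty turns on.
#' @param clash_penalty_scale Clash prefactor, kcal/mol.
#' @param interaction_cutoff Interaction term cutoff, A.
#' @param interaction_depth Per-pair well depth at contact, kcal/mol.
#' @return An `energy_params` list.
#' @export
energy_params <- function(hbond_dist_min = 2.5, hbond_dist_max = 3.5,
                          hbond_angle_min = 120, hbond_well_depth = 1.0,
                          clash_radius_scale = 0.9,
                          clash_penalty_scale = 10,
                          interaction_cutoff = 6.0,
                          interaction_depth = 0.2) {
  stopifnot(hbond_dist_min < hbond_dist_max,
            hbond_well_depth > 0, clash_radius_scale > 0,
            clash_penalty_scale > 0, interaction_cutoff > 0,
            interaction_depth > 0)
  structure(list(
    hbond_dist_min = hbond_dist_min, hbond_dist_max = hbond_dist_max,
    hbond_angle_min = hbond_angle_min,
    hbond_well_depth = hbond_well_depth,
    clash_radius_scale = clash_radius_scale,
    clash_penalty_scale = clash_penalty_scale,
    interaction_cutoff = interaction_cutoff,
    interaction_depth = interaction_depth), class = "energy_params")
}

.coords <- function(df) as.matrix(df[, c("x", "y", "z")])

# full pairwise distance matrix between two coordinate sets
.pdist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

.angle_deg <- function(p, v, a) {
  u1 <- p - v
  u2 <- a - v
  cosang <- sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

# protein side-chain H-bond site atoms with coordinates and parents
.protein_sites <- function(protein) {
  st <- dplyr::inner_join(protein, .PROTEIN_HB_SITES,
                          by = c("resname", "atom"),
                          relationship = "many-to-many")
  if (nrow(st) == 0) return(st)
  par <- protein |>
    select("residue", parent = "atom", px = "x", py = "y", pz = "z")
  left_join(st, par, by = c("residue", "parent"))
}

# DNA groove site atoms (donor/acceptor) with parent coordinates
.dna_sites <- function(bases) {
  st <- filter(bases, .data$role %in% c("donor", "acceptor"),
               !is.na(.data$groove))
  if (nrow(st) == 0) return(st)
  par <- bases |>
    select("strand", "position", parent = "atom",
           px = "x", py = "y", pz = "z")
  left_join(st, par, by = c("strand", "position", "parent"))
}

#' Detect protein-DNA hydrogen bonds
#'
#' Finds geometric donor-acceptor pairs between protein side-chain sites
#' and base groove sites: distance within the configured window and, when
#' the donor's parent atom is present, donor angle above the minimum.
#' A single base may contribute two or more contacts to one side chain
#' (a bidentate interaction, as a minor-groove guanine can make through
#' its N2 amino group and aromatic N3).
#'
#' @param complex A threaded `protein_dna_complex`.
#' @param params An [energy_params()] list.
#' @return Tibble of contacts: donor/acceptor descriptors, `distance` (A),
#'   `angle` (degrees, `NA` when no parent atom), `energy` (kcal/mol,
#'   always <= 0).
#' @export
detect_hbonds <- function(complex, params = energy_params()) {
  ps <- .protein_sites(complex$protein)
  ds <- .dna_sites(complex$bases)
  empty <- tibble(
    donor = character(), donor_atom = character(),
    acceptor = character(), acceptor_atom = character(),
    position = integer(), distance = numeric(), angle = numeric(),
    energy = numeric())
  if (nrow(ps) == 0 || nrow(ds) == 0) return(empty)

  pairings <- list(
    list(don = filter(ps, .data$role == "donor"),
         acc = filter(ds, .data$role == "acceptor"), protein_donor = TRUE),
    list(don = filter(ds, .data$role == "donor"),
         acc = filter(ps, .data$role == "acceptor"), protein_donor = FALSE))

  out <- map(pairings, function(pr) {
    don <- pr$don; acc <- pr$acc
    if (nrow(don) == 0 || nrow(acc) == 0) return(NULL)
    D <- .pdist(.coords(don), .coords(acc))
    hits <- which(D >= params$hbond_dist_min &
                    D <= params$hbond_dist_max, arr.ind = TRUE)
    if (nrow(hits) == 0) return(NULL)
    map(seq_len(nrow(hits)), function(k) {
      i <- hits[k, 1]; j <- hits[k, 2]
      d <- D[i, j]
      dn <- don[i, ]; ac <- acc[j, ]
      ang <- NA_real_
      if (!is.na(dn$px)) {
        ang <- .angle_deg(c(dn$px, dn$py, dn$pz),
                          c(dn$x, dn$y, dn$z), c(ac$x, ac$y, ac$z))
        if (ang < params$hbond_angle_min) return(NULL)
      }
      d0 <- (params$hbond_dist_min + params$hbond_dist_max) / 2
      fd <- max(0, 1 - abs(d - d0) / (params$hbond_dist_max - d0))
      fa <- if (is.na(ang)) 1 else {
        (ang - params$hbond_angle_min) / (180 - params$hbond_angle_min)
      }
      lab <- function(s, is_prot) {
        if (is_prot) sprintf("%s%d:%s", s$resname, s$residue, s$atom)
        else sprintf("%s(strand %d, pos %d):%s", s$base, s$strand,
                     s$position, s$atom)
      }
      tibble(
        donor = lab(dn, pr$protein_donor),
        donor_atom = dn$atom,
        acceptor = lab(ac, !pr$protein_donor),
        acceptor_atom = ac$atom,
        position = as.integer(if (pr$protein_donor) ac$position
                              else dn$position),
        distance = d, angle = ang,
        energy = -params$hbond_well_depth * fd * fa)
    }) |> list_rbind()
  }) |> list_rbind()
  if (is.null(out) || nrow(out) == 0) empty else out
}

# soft quadratic penalty for pairs below the scaled vdW contact distance
.clash_sum <- function(A, B, rA, rB, params, same_set = FALSE,
                       exclude = NULL) {
  if (nrow(A) == 0 || nrow(B) == 0) return(0)
  D <- .pdist(A, B)
  lim <- params$clash_radius_scale * outer(rA, rB, "+")
  if (same_set) D[upper.tri(D, diag = TRUE)] <- Inf
  if (!is.null(exclude)) D[exclude] <- Inf
  ov <- which(D < lim, arr.ind = TRUE)
  if (nrow(ov) == 0) return(0)
  sum(params$clash_penalty_scale *
        (1 - D[ov] / lim[ov])^2)
}

#' Steric clash terms
#'
#' Soft quadratic overlap penalties below `clash_radius_scale` x the sum
#' of van der Waals radii, partitioned into DNA-internal overlap
#' (`clash_dna`, atom pairs from different nucleotides) and protein-DNA
#' overlap (`clash_protein`). Both are non-negative.
#'
#' @inheritParams detect_hbonds
#' @return Named numeric vector `c(clash_dna=, clash_protein=)`, kcal/mol.
#' @export
clash_terms <- function(complex, params = energy_params()) {
  b <- complex$bases
  Bc <- .coords(b)
  rB <- vdw_radius(b$element)
  nuc <- paste(b$strand, b$position)
  same_nuc <- outer(nuc, nuc, "==")
  cd <- .clash_sum(Bc, Bc, rB, rB, params, same_set = TRUE,
                   exclude = same_nuc)
  Pc <- .coords(complex$protein)
  rP <- vdw_radius(complex$protein$element)
  cp <- .clash_sum(Pc, Bc, rP, rB, params)
  c(clash_dna = cd, clash_protein = cp)
}

#' Favorable protein-DNA interaction term
#'
#' Pairwise-additive attractive well over protein-DNA atom pairs within
#' the cutoff: each pair contributes
#' `-depth * (1 - (d/cutoff)^2)^2`, so the term is always <= 0 and adding
#' a contacting atom can only make it more negative. Electrostatics are
#' folded into this single distance-weighted term; no explicit charges.
#'
#' @inheritParams detect_hbonds
#' @return Scalar kcal/mol, <= 0.
#' @export
interaction_energy <- function(complex, params = energy_params()) {
  D <- .pdist(.coords(complex$protein), .coords(complex$bases))
  w <- D < params$interaction_cutoff
  if (!any(w)) return(0)
  -params$interaction_depth *
    sum((1 - (D[w] / params$interaction_cutoff)^2)^2)
}

#' Four-term binding energy breakdown
#'
#' Evaluates the full decomposition for a threaded complex: `clash_dna`,
#' `clash_protein`, `interaction_energy`, `sidechain_hbond`, and their
#' exact sum `total`. Absolute values are on the energy function's own
#' scale; only differences between threaded variants are interpreted.
#'
#' @inheritParams detect_hbonds
#' @return One-row tibble of class `energy_breakdown` with the four terms
#'   and `total`; the parameter set is attached as attribute `params`.
#' @export
binding_energy <- function(complex, params = energy_params()) {
  cl <- clash_terms(complex, params)
  ie <- interaction_energy(complex, params)
  hb <- sum(detect_hbonds(complex, params)$energy)
  out <- tibble(
    clash_dna = unname(cl["clash_dna"]),
    clash_protein = unname(cl["clash_protein"]),
    interaction_energy = ie,
    sidechain_hbond = hb)
  out$total <- out$clash_dna + out$clash_protein +
    out$interaction_energy + out$sidechain_hbond
  attr(out, "params") <- params
  class(out) <- c("energy_breakdown", class(out))
  out
}

#' Relative binding energy between two breakdowns
#'
#' `ddG = variant$total - reference$total`, defined only for breakdowns
#' computed with identical parameters.
#'
#' @param reference,variant `energy_breakdown` rows from
#'   [binding_energy()] (or fixture rows with a `total` column and a
#'   `params` attribute).
#' @return Scalar kcal/mol.
#' @export
relative_binding_energy <- function(reference, variant) {
  if (!identical(attr(reference, "params"), attr(variant, "params"))) {
    abort("breakdowns were computed with different parameters")
  }
  variant$total - reference$total
}
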