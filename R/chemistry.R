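# Base chemistry tables: idealized planar templates for the four canonical
# bases, their groove-facing hydrogen-bond sites, and the donor/acceptor
# atoms of protein side chains. Local template coordinates are in the base
# plane (z = 0): x runs from the C1' anchor toward the helix axis, +y faces
# the major groove, -y the minor groove.

.BASES <- c("A", "C", "G", "T")

.BASE_TEMPLATES <- list(
  G = data.frame(
    atom    = c("N9", "C4", "N7", "C6", "O6", "C2", "N2", "N3"),
    element = c("N", "C", "N", "C", "O", "C", "N", "N"),
    x       = c(1.5, 2.9, 3.4, 5.0, 5.3, 4.4, 5.1, 3.2),
    y       = c(0.0, 0.0, 1.3, 0.4, 1.6, -1.7, -2.9, -1.6),
    role    = c("ring", "ring", "acceptor", "ring", "acceptor",
                "ring", "donor", "acceptor"),
    groove  = c(NA, NA, "major", NA, "major", NA, "minor", "minor"),
    parent  = c(NA, NA, "C4", NA, "C6", NA, "C2", "C2"),
    stringsAsFactors = FALSE
  ),
  A = data.frame(
    atom    = c("N9", "C4", "N7", "C6", "N6", "C2", "N3"),
    element = c("N", "C", "N", "C", "N", "C", "N"),
    x       = c(1.5, 2.9, 3.4, 5.0, 5.3, 4.4, 3.2),
    y       = c(0.0, 0.0, 1.3, 0.4, 1.6, -1.7, -1.6),
    role    = c("ring", "ring", "acceptor", "ring", "donor", "ring",
                "acceptor"),
    groove  = c(NA, NA, "major", NA, "major", NA, "minor"),
    parent  = c(NA, NA, "C4", NA, "C6", NA, "C2"),
    stringsAsFactors = FALSE
  ),
  C = data.frame(
    atom    = c("N1", "C2", "O2", "C4", "N4"),
    element = c("N", "C", "O", "C", "N"),
    x       = c(1.5, 2.7, 2.9, 4.5, 4.8),
    y       = c(0.0, -0.8, -2.0, 0.7, 1.9),
    role    = c("ring", "ring", "acceptor", "ring", "donor"),
    groove  = c(NA, NA, "minor", NA, "major"),
    parent  = c(NA, NA, "C2", NA, "C4"),
    stringsAsFactors = FALSE
  ),
  T = data.frame(
    atom    = c("N1", "C2", "O2", "C4", "O4", "C7"),
    element = c("N", "C", "O", "C", "O", "C"),
    x       = c(1.5, 2.7, 2.9, 4.5, 4.8, 5.2),
    y       = c(0.0, -0.8, -2.0, 0.7, 1.9, -0.9),
    role    = c("ring", "ring", "acceptor", "ring", "acceptor",
                "hydrophobic"),
    groove  = c(NA, NA, "minor", NA, "major", "major"),
    parent  = c(NA, NA, "C2", NA, "C4", "C4"),
    stringsAsFactors = FALSE
  )
)

# glycosidic nitrogen and the in-plane atom used to recover the base frame
.GLYCOSIDIC <- c(A = "N9", G = "N9", C = "N1", T = "N1")
.PLANE_ATOM <- c(A = "N3", G = "N3", C = "O2", T = "O2")

# side-chain hydrogen-bond sites by residue type; parent anchors the
# donor-angle computation
.PROTEIN_HB_SITES <- data.frame(
  resname = c("GLN", "GLN", "ASN", "ASN", "SER", "SER", "THR", "THR",
              "TYR", "TYR", "LYS", "ARG", "ARG", "ARG", "HIS", "HIS",
              "TRP", "ASP", "ASP", "GLU", "GLU"),
  atom    = c("NE2", "OE1", "ND2", "OD1", "OG", "OG", "OG1", "OG1",
              "OH", "OH", "NZ", "NE", "NH1", "NH2", "ND1", "NE2",
              "NE1", "OD1", "OD2", "OE1", "OE2"),
  role    = c("donor", "acceptor", "donor", "acceptor", "donor",
              "acceptor", "donor", "acceptor", "donor", "acceptor",
              "donor", "donor", "donor", "donor", "acceptor", "donor",
              "donor", "acceptor", "acceptor", "acceptor", "acceptor"),
  parent  = c("CD", "CD", "CG", "CG", "CB", "CB", "CB", "CB",
              "CZ", "CZ", "CE", "CD", "CZ", "CZ", "CG", "CD2",
              "CD1", "CG", "CG", "CD", "CD"),
  stringsAsFactors = FALSE
)

.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80, H = 1.20)
.VDW_DEFAULT <- 1.60

vdw_radius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  r[is.na(r)] <- .VDW_DEFAULT
  unname(r)
}

#' Watson-Crick complement of canonical bases
#'
#' Maps each canonical base to its pairing partner (A-T, C-G). The map is an
#' involution: `dna_complement(dna_complement(x))` returns `x`.
#'
#' @param base Character vector of single-letter bases in `A`, `C`, `G`, `T`.
#' @return Character vector of complementary bases.
#' @examples
#' dna_complement(c("C", "T"))  # "G" "A"
#' @export
dna_complement <- function(base) {
  map <- c(A = "T", T = "A", C = "G", G = "C")
  out <- map[base]
  if (anyNA(out)) {
    abort(paste0("non-canonical base symbol(s): ",
                 paste(unique(base[is.na(out)]), collapse = ", ")))
  }
  unname(out)
}

#' Groove-facing chemistry of the canonical bases
#'
#' Lists the hydrogen-bond donor, acceptor and hydrophobic sites each base
#' presents in the major and minor grooves, as used by the threading
#' templates and the hydrogen-bond detector. Guanine presents two minor
#' groove sites (the N2 amino donor and the aromatic N3 acceptor) and can
#' therefore accept a bidentate side-chain contact; adenine presents only
#' the aromatic N3 on that edge.
#'
#' @param base Optional single base to restrict the table to.
#' @return A tibble with columns `base`, `atom`, `element`, `role`,
#'   `groove`.
#' @export
base_chemistry <- function(base = NULL) {
  tb <- purrr::imap(.BASE_TEMPLATES, function(df, b) {
    tibble(base = b, atom = df$atom, element = df$element,
           role = df$role, groove = df$groove)
  }) |> list_rbind() |> filter(.data$role != "ring")
  if (!is.null(base)) {
    if (!base %in% .BASES) abort("base must be one of A, C, G, T")
    tb <- filter(tb, .data$base == !!base)
  }
  tb
}
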