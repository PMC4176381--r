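# Protein-DNA complex container and sequence threading.
#
# A complex holds a protein atom table, a DNA duplex atom table indexed by
# (strand, position) where position counts 1..L along the reference strand
# 5'->3' and strand 2 entries are the pairing partners, and per-position
# backbone anchor frames onto which idealized base templates are placed.

.unit <- function(v) v / sqrt(sum(v^2))
.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

new_protein_dna_complex <- function(protein, bases, anchors,
                                    reference_sequence,
                                    numbering_offset = 52L,
                                    domain_map = NULL) {
  x <- structure(
    list(protein = protein, bases = bases, anchors = anchors,
         reference_sequence = reference_sequence,
         numbering_offset = as.integer(numbering_offset),
         domain_map = domain_map),
    class = "protein_dna_complex")
  validate_complex(x)
  x
}

validate_complex <- function(x) {
  if (nrow(x$protein) == 0) abort("protein is empty")
  if (nrow(x$bases) == 0) abort("not a protein-DNA complex: no DNA present")
  L <- nchar(x$reference_sequence)
  if (!all(sort(unique(x$anchors$position)) == seq_len(L)) ||
      !all(sort(unique(x$anchors$strand)) == 1:2)) {
    abort("anchor frames must cover both strands at every position")
  }
  coords <- c(x$protein$x, x$protein$y, x$protein$z,
              x$bases$x, x$bases$y, x$bases$z)
  if (!all(is.finite(coords))) abort("non-finite coordinates")
  invisible(x)
}

#' Duplex length of a complex
#' @param complex A `protein_dna_complex`.
#' @return Integer motif length L.
#' @export
duplex_length <- function(complex) nchar(complex$reference_sequence)

#' Reference and complementary strand sequences
#'
#' The reference sequence is read 5'->3' at positions 1..L; the
#' complementary sequence is its reverse complement, i.e. the partner
#' strand read 5'->3'.
#'
#' @param complex A `protein_dna_complex`.
#' @return Named character vector with `reference` and `complementary`.
#' @export
duplex_sequences <- function(complex) {
  ref <- complex$reference_sequence
  comp <- paste(rev(dna_complement(strsplit(ref, "")[[1]])), collapse = "")
  c(reference = ref, complementary = comp)
}

# place a base template onto an anchor frame; returns atom tibble rows
place_base <- function(base, anchor, strand, position) {
  tmpl <- .BASE_TEMPLATES[[base]]
  o <- c(anchor$ox, anchor$oy, anchor$oz)
  ex <- c(anchor$ex1, anchor$ex2, anchor$ex3)
  ey <- c(anchor$ey1, anchor$ey2, anchor$ey3)
  pos <- t(vapply(seq_len(nrow(tmpl)), function(i) {
    o + tmpl$x[i] * ex + tmpl$y[i] * ey
  }, numeric(3)))
  tibble(strand = strand, position = position, base = base,
         atom = tmpl$atom, element = tmpl$element,
         x = pos[, 1], y = pos[, 2], z = pos[, 3],
         role = tmpl$role, groove = tmpl$groove, parent = tmpl$parent)
}

#' Thread a DNA motif onto the fixed duplex backbone
#'
#' Replaces the base identities of the duplex on both strands (the partner
#' strand always carries the Watson-Crick complement), rebuilding base atoms
#' from idealized planar templates oriented on the per-position backbone
#' anchor frames. Protein atoms and backbone anchors are never moved, so a
#' threaded variant differs from the input only in base atoms. Side chains
#' are kept rigid; no repacking is attempted.
#'
#' @param complex A `protein_dna_complex`.
#' @param motif Character scalar over `A`,`C`,`G`,`T` of length
#'   `duplex_length(complex)`.
#' @return A new `protein_dna_complex` carrying `motif` as its reference
#'   sequence.
#' @export
thread_sequence <- function(complex, motif) {
  L <- duplex_length(complex)
  if (!is.character(motif) || length(motif) != 1 || nchar(motif) != L) {
    abort(sprintf("motif must be a single string of length %d", L))
  }
  chars <- strsplit(motif, "")[[1]]
  if (!all(chars %in% .BASES)) {
    abort("motif contains non-canonical base codes")
  }
  backbone <- filter(complex$bases, .data$role == "backbone") |>
    mutate(base = ifelse(.data$strand == 1, chars[.data$position],
                         dna_complement(chars)[.data$position]))
  placed <- map(seq_len(L), function(p) {
    a1 <- filter(complex$anchors, .data$strand == 1, .data$position == p)
    a2 <- filter(complex$anchors, .data$strand == 2, .data$position == p)
    bind_rows(
      place_base(chars[p], a1, 1L, p),
      place_base(dna_complement(chars[p]), a2, 2L, p))
  }) |> list_rbind()
  out <- complex
  out$bases <- bind_rows(backbone, placed) |>
    arrange(.data$strand, .data$position)
  out$reference_sequence <- motif
  out
}

#' Attach a named domain map to a complex
#'
#' @param complex A `protein_dna_complex`.
#' @param domains Tibble with columns `domain`, `start`, `end` giving
#'   non-overlapping 1-based file-order residue index ranges (e.g. NTD,
#'   BTD, CTD). `NULL` or an empty tibble labels every residue "linker".
#' @return The complex with `domain_map` set.
#' @export
assign_domains <- function(complex, domains) {
  complex$domain_map <- check_domain_map(domains,
                                         max(complex$protein$residue))
  complex
}

check_domain_map <- function(domains, n_max) {
  if (is.null(domains) || nrow(domains) == 0) return(NULL)
  stopifnot(all(c("domain", "start", "end") %in% names(domains)))
  if (any(domains$start > domains$end)) abort("empty domain range")
  if (any(domains$start < 1) || any(domains$end > n_max)) {
    abort("domain range outside residue index span")
  }
  d <- arrange(domains, .data$start)
  if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)])) {
    abort("overlapping domain ranges")
  }
  d
}

#' Per-residue domain labels
#'
#' @param complex A `protein_dna_complex` (or the residue count via
#'   `n`) with an attached domain map.
#' @return Tibble with `residue` and `domain` ("linker" outside all
#'   ranges).
#' @export
residue_domains <- function(complex) {
  res <- sort(unique(complex$protein$residue))
  lab <- rep("linker", length(res))
  dm <- complex$domain_map
  if (!is.null(dm)) {
    for (i in seq_len(nrow(dm))) {
      lab[res >= dm$start[i] & res <= dm$end[i]] <- dm$domain[i]
    }
  }
  tibble(residue = res, domain = lab)
}

#' @export
print.protein_dna_complex <- function(x, ...) {
  sq <- duplex_sequences(x)
  cat("<protein_dna_complex>\n")
  cat(sprintf("  duplex   : 5'-%s-3' / 5'-%s-3'  (L = %d)\n",
              sq["reference"], sq["complementary"], duplex_length(x)))
  cat(sprintf("  protein  : %d residues, %d atoms (numbering offset %d)\n",
              length(unique(x$protein$residue)), nrow(x$protein),
              x$numbering_offset))
  if (!is.null(x$domain_map)) {
    cat(sprintf("  domains  : %s\n",
                paste(x$domain_map$domain, collapse = ", ")))
  }
  invisible(x)
}

.DNA_RESID <- c(DA = "A", DC = "C", DG = "G", DT = "T",
                A = "A", C = "C", G = "G", T = "T")

# element symbol: PDB column 77-78 when present, else first letter of name
.element_of <- function(elesy, elety) {
  es <- trimws(as.character(elesy))
  es[is.na(es) | !nzchar(es)] <- NA_character_
  ifelse(is.na(es), substr(gsub("[^A-Za-z].*", "", elety), 1, 1), es)
}

# recover the anchor frame of one nucleotide from its atom coordinates
anchor_from_atoms <- function(atoms, base) {
  need <- c("C1'", .GLYCOSIDIC[[base]], .PLANE_ATOM[[base]])
  nm <- gsub("\\*", "'", atoms$atom)
  idx <- match(need, nm)
  if (anyNA(idx)) {
    abort(sprintf("cannot build anchor frame: missing atom(s) %s",
                  paste(need[is.na(idx)], collapse = ", ")))
  }
  p <- as.matrix(atoms[idx, c("x", "y", "z")])
  o <- p[1, ]
  ex <- .unit(p[2, ] - o)
  w <- p[3, ] - o
  wp <- w - sum(w * ex) * ex
  tmpl <- .BASE_TEMPLATES[[base]]
  yq <- tmpl$y[tmpl$atom == .PLANE_ATOM[[base]]]
  ey <- .unit(wp) * sign(yq)
  list(ox = o[1], oy = o[2], oz = o[3],
       ex1 = ex[1], ex2 = ex[2], ex3 = ex[3],
       ey1 = ey[1], ey2 = ey[2], ey3 = ey[3])
}

#' Read a protein-DNA complex from a PDB file
#'
#' Parses a PDB-dialect file (via \pkg{bio3d}), separates protein and DNA
#' chains, establishes duplex base pairing by complementarity of the two
#' DNA strands, and records backbone anchor frames for threading. Exactly
#' two DNA chains of equal length are expected, each written 5'->3'.
#'
#' @param path Path to a PDB file.
#' @param config Optional list: `reference_sequence` selects which strand
#'   is the reference by sequence match; `numbering_offset` (default 52)
#'   records the offset between file-order indices and the numbering of
#'   the parent construct.
#' @return A `protein_dna_complex`.
#' @export
read_complex <- function(path, config = list()) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), ]
  if ("alt" %in% names(at)) {
    at <- at[is.na(at$alt) | at$alt %in% c("", "A"), ]
  }
  is_dna <- at$resid %in% names(.DNA_RESID)
  aa3 <- suppressWarnings(bio3d::aa321(at$resid))
  is_protein <- !is_dna & aa3 != "X"
  unknown <- !is_dna & !is_protein
  if (any(unknown)) {
    bad <- unique(at$resno[unknown])
    abort(sprintf("unknown residue code(s) at residue index %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  if (!any(is_dna)) abort("not a protein-DNA complex: no DNA chain found")
  if (!any(is_protein)) abort("no protein chain found")

  prot <- at[is_protein, ]
  rid <- paste(prot$chain, prot$resno)
  ridx <- as.integer(factor(rid, levels = unique(rid)))
  protein <- tibble(
    residue = ridx, resname = prot$resid, chain = prot$chain,
    atom = gsub("\\*", "'", prot$elety),
    element = .element_of(prot$elesy, prot$elety),
    x = prot$x, y = prot$y, z = prot$z)

  dna <- at[is_dna, ]
  chains <- unique(dna$chain)
  if (length(chains) != 2) {
    abort(sprintf("pairing error: expected 2 DNA chains, found %d",
                  length(chains)))
  }
  strand_atoms <- lapply(chains, function(ch) dna[dna$chain == ch, ])
  seqs <- lapply(strand_atoms, function(d) {
    .DNA_RESID[d$resid[!duplicated(d$resno)]]
  })
  if (length(seqs[[1]]) != length(seqs[[2]])) {
    abort("pairing error: mismatched strand lengths")
  }
  L <- length(seqs[[1]])
  ref_strand <- 1L
  if (!is.null(config$reference_sequence)) {
    hint <- config$reference_sequence
    if (paste(seqs[[2]], collapse = "") == hint) ref_strand <- 2L
  }
  if (ref_strand == 2L) {
    strand_atoms <- rev(strand_atoms)
    seqs <- rev(seqs)
  }
  if (!all(rev(dna_complement(seqs[[1]])) == seqs[[2]])) {
    abort("pairing error: strands are not reverse complements")
  }

  build_strand <- function(d, strand, positions) {
    resnos <- unique(d$resno)
    purrr::map2(resnos, positions, function(rn, p) {
      a <- d[d$resno == rn, ]
      base <- .DNA_RESID[[a$resid[1]]]
      nm <- gsub("\\*", "'", a$elety)
      tmpl <- .BASE_TEMPLATES[[base]]
      mi <- match(nm, tmpl$atom)
      tibble(strand = strand, position = p, base = base, atom = nm,
             element = .element_of(a$elesy, nm),
             x = a$x, y = a$y, z = a$z,
             role = ifelse(grepl("'|P", nm), "backbone",
                           ifelse(is.na(mi), "other", tmpl$role[mi])),
             groove = ifelse(is.na(mi), NA_character_, tmpl$groove[mi]),
             parent = ifelse(is.na(mi), NA_character_, tmpl$parent[mi]))
    }) |> list_rbind()
  }
  bases1 <- build_strand(strand_atoms[[1]], 1L, seq_len(L))
  bases2 <- build_strand(strand_atoms[[2]], 2L, rev(seq_len(L)))
  bases <- bind_rows(bases1, bases2) |>
    arrange(.data$strand, .data$position)

  anchors <- purrr::pmap(
    expand.grid(strand = 1:2, position = seq_len(L)),
    function(strand, position) {
      a <- filter(bases, .data$strand == !!strand,
                  .data$position == !!position)
      fr <- anchor_from_atoms(a, a$base[1])
      c(list(strand = strand, position = position), fr)
    }) |> purrr::map(as_tibble) |> list_rbind()

  new_protein_dna_complex(
    protein = protein, bases = bases, anchors = anchors,
    reference_sequence = paste(seqs[[1]], collapse = ""),
    numbering_offset = config$numbering_offset %||% 52L)
}

#' Write a complex to a PDB file
#'
#' Protein chains keep their chain identifiers; the reference strand is
#' written as chain "D" (5'->3') and the partner strand as chain "E"
#' (5'->3', i.e. positions L..1).
#'
#' @param complex A `protein_dna_complex`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_complex <- function(complex, path) {
  p <- complex$protein
  b1 <- filter(complex$bases, .data$strand == 1) |>
    arrange(.data$position)
  b2 <- filter(complex$bases, .data$strand == 2) |>
    arrange(desc(.data$position))
  nres_p <- max(p$residue)
  resid_dna <- function(b) paste0("D", b$base)
  xyz <- c(t(as.matrix(rbind(p[, c("x", "y", "z")],
                             b1[, c("x", "y", "z")],
                             b2[, c("x", "y", "z")]))))
  resno <- c(p$residue, nres_p + b1$position,
             nres_p + duplex_length(complex) +
               (duplex_length(complex) - b2$position + 1L))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    resno = resno,
    resid = c(p$resname, resid_dna(b1), resid_dna(b2)),
    elety = c(p$atom, b1$atom, b2$atom),
    chain = c(p$chain, rep("D", nrow(b1)), rep("E", nrow(b2))),
    elesy = c(p$element, b1$element, b2$element))
  invisible(path)
}
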