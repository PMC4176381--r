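# Seeded synthetic substrates: a toy protein-DNA complex whose probe and
# pocket exercise every branch of the energy function, coupled-domain
# trajectories with a known inter-domain correlation, simulated ITC
# titrations, and packaged fixture tables.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# idealized duplex anchor frames: rise/twist helix, strands antiparallel,
# base x-axes pointing at the helix axis
.helix_anchors <- function(L, rise = 3.4, twist = 36, radius = 9.0,
                           delta = 60) {
  rows <- list()
  for (p in seq_len(L)) {
    phi <- (twist * (p - 1)) * pi / 180
    z <- rise * (p - 1)
    for (s in 1:2) {
      th <- phi + (if (s == 1) delta else -delta) * pi / 180
      o <- c(radius * cos(th), radius * sin(th), z)
      ex <- .unit(c(-o[1], -o[2], 0))
      ez <- if (s == 1) c(0, 0, 1) else c(0, 0, -1)
      ey <- .cross(ez, ex)
      rows[[length(rows) + 1]] <- tibble(
        strand = s, position = p,
        ox = o[1], oy = o[2], oz = o[3],
        ex1 = ex[1], ex2 = ex[2], ex3 = ex[3],
        ey1 = ey[1], ey2 = ey[2], ey3 = ey[3])
    }
  }
  list_rbind(rows)
}

.anchor_row <- function(anchors, strand, position) {
  filter(anchors, .data$strand == !!strand, .data$position == !!position)
}

#' Build a toy protein-DNA complex
#'
#' A small, fully synthetic scan substrate: an idealized duplex of length
#' `L` on helix-like backbone anchors, a glutamine-like probe whose amide
#' donor/acceptor pair sits at bidentate geometry against the minor
#' groove edge of the base complementary to position 1 (two hydrogen
#' bonds when position 1 is C, one when it is T), per-position groove
#' reader atoms whose contact distances depend on base size, a pocket
#' atom that clashes more with bulky bases at position 2, and a sparse
#' shell. The geometry is idealized, not biophysically accurate; its
#' contract is to exercise the energy operators reproducibly.
#'
#' @param L Duplex length, 2-8.
#' @param reference Reference motif (default: the leading `L` bases of
#'   CGTGGGAA).
#' @param seed Seed for the small shell jitter.
#' @param probe Place the glutamine-like probe?
#' @param probe_offset Extra displacement of the probe away from the base
#'   edge, Angstrom (push beyond ~0.7 to break the contacts).
#' @param pocket Place the pocket atom at position 2?
#' @return A `protein_dna_complex`.
#' @export
make_toy_complex <- function(L = 4, reference = NULL, seed = 1,
                             probe = TRUE, probe_offset = 0,
                             pocket = TRUE) {
  stopifnot(L >= 2, L <= 8)
  reference <- reference %||% substr("CGTGGGAA", 1, L)
  stopifnot(nchar(reference) == L)
  anchors <- .helix_anchors(L)

  backbone <- pmap(anchors[, c("strand", "position")],
                   function(strand, position) {
    a <- .anchor_row(anchors, strand, position)
    tibble(strand = strand, position = position, base = "A",
           atom = "C1'", element = "C", x = a$ox, y = a$oy, z = a$oz,
           role = "backbone", groove = NA_character_,
           parent = NA_character_)
  }) |> list_rbind()

  # world position of a template atom for a hypothetical base at a slot
  tmpl_world <- function(strand, position, base, atom) {
    a <- .anchor_row(anchors, strand, position)
    t <- .BASE_TEMPLATES[[base]]
    i <- match(atom, t$atom)
    c(a$ox, a$oy, a$oz) +
      t$x[i] * c(a$ex1, a$ex2, a$ex3) +
      t$y[i] * c(a$ey1, a$ey2, a$ey3)
  }

  prot <- list()
  res_i <- 0L
  add_res <- function(resname, atoms) {
    res_i <<- res_i + 1L
    prot[[length(prot) + 1]] <<- tibble(
      residue = res_i, resname = resname, chain = "A",
      atom = names(atoms),
      element = substr(names(atoms), 1, 1),
      x = unname(vapply(atoms, `[`, 0, 1)),
      y = unname(vapply(atoms, `[`, 0, 2)),
      z = unname(vapply(atoms, `[`, 0, 3)))
  }

  if (probe) {
    # bidentate geometry against the minor edge of a hypothetical G
    # paired with position 1 (present when position 1 is C)
    ring <- c("N9", "C4", "C6", "C2")
    ctr <- colMeans(do.call(rbind, lapply(ring, function(a)
      tmpl_world(2, 1, "G", a))))
    N3 <- tmpl_world(2, 1, "G", "N3")
    N2 <- tmpl_world(2, 1, "G", "N2")
    u3 <- .unit(N3 - ctr)
    u2 <- .unit(N2 - ctr)
    NE2 <- N3 + (2.9 + probe_offset) * u3
    OE1 <- N2 + (2.9 + probe_offset) * u2
    CD <- NE2 + 1.33 * u3
    add_res("GLN", list(CD = CD, OE1 = OE1, NE2 = NE2))
  }

  # groove readers: one carbon per position off the major-groove edge
  for (p in seq_len(L)) {
    a <- .anchor_row(anchors, 1, p)
    pos <- c(a$ox, a$oy, a$oz) +
      7.5 * c(a$ex1, a$ex2, a$ex3) + 3.0 * c(a$ey1, a$ey2, a$ey3)
    add_res("GLY", list(CA = pos))
  }

  if (pocket && L >= 2) {
    a <- .anchor_row(anchors, 1, 2)
    cb <- c(a$ox, a$oy, a$oz) +
      5.6 * c(a$ex1, a$ex2, a$ex3) - 2.2 * c(a$ey1, a$ey2, a$ey3)
    ca <- cb - 1.5 * c(a$ex1, a$ex2, a$ex3)
    add_res("ALA", list(CA = ca, CB = cb))
  }

  shell <- .with_seed(seed, {
    lapply(1:2, function(k) {
      th <- c(2.4, 4.4)[k]
      c(13 * cos(th), 13 * sin(th), 1.7 * (L - 1) + rnorm(1, 0, 0.2))
    })
  })
  for (s in shell) add_res("GLY", list(CA = s))

  protein <- list_rbind(prot)
  cx <- new_protein_dna_complex(
    protein = protein,
    bases = backbone,  # placeholder; threading fills base atoms
    anchors = anchors,
    reference_sequence = reference,
    numbering_offset = 52L)
  thread_sequence(cx, reference)
}

#' Simulate a coupled-domain Calpha trajectory
#'
#' Residues are grouped into domains placed as spatial clusters; each
#' domain moves with a shared latent 3-vector per frame, built as
#' `sqrt(coupling) * g + sqrt(1 - coupling) * e_d` from a global latent
#' `g` and independent per-domain latents, so the latent inter-domain
#' correlation equals `coupling` exactly in expectation. Independent
#' Gaussian noise is added per residue.
#'
#' @param n_residues Total residues (split as evenly as possible).
#' @param n_domains Number of domains (named NTD, BTD, CTD, D4, ...).
#' @param coupling Inter-domain latent correlation in `[0, 1]`.
#' @param n_frames Frames to simulate.
#' @param seed RNG seed.
#' @param latent_sd Domain motion amplitude, Angstrom.
#' @param noise_sd Per-residue noise, Angstrom (0 gives perfectly
#'   coherent domains).
#' @param domain_separation Distance between cluster centers, Angstrom.
#' @return A `trajectory` with its domain map attached.
#' @export
make_coupled_trajectory <- function(n_residues = 45, n_domains = 3,
                                    coupling = 0.5, n_frames = 300,
                                    seed = 1, latent_sd = 1.0,
                                    noise_sd = 0.3,
                                    domain_separation = 14) {
  stopifnot(coupling >= 0, coupling <= 1, n_domains >= 1)
  sizes <- diff(round(seq(0, n_residues, length.out = n_domains + 1)))
  dn <- c("NTD", "BTD", "CTD", paste0("D", seq_len(max(0, n_domains))))
  dn <- dn[seq_len(n_domains)]
  ends <- cumsum(sizes)
  domains <- tibble(domain = dn, start = c(1, head(ends, -1) + 1),
                    end = ends)
  centers <- cbind(
    domain_separation * (seq_len(n_domains) - 1) %% 2 +
      domain_separation * ((seq_len(n_domains) - 1) %/% 2) * 0.5,
    domain_separation * 0.87 * ((seq_len(n_domains) - 1) %/% 2),
    0)
  .with_seed(seed, {
    base <- do.call(rbind, lapply(seq_len(n_domains), function(d) {
      sweep(matrix(rnorm(sizes[d] * 3, 0, 2.0), ncol = 3), 2,
            centers[d, ], "+")
    }))
    g <- matrix(rnorm(n_frames * 3, 0, latent_sd), ncol = 3)
    arr <- array(NA_real_, c(n_frames, n_residues, 3))
    for (d in seq_len(n_domains)) {
      e <- matrix(rnorm(n_frames * 3, 0, latent_sd), ncol = 3)
      l <- sqrt(coupling) * g + sqrt(1 - coupling) * e
      for (i in domains$start[d]:domains$end[d]) {
        arr[, i, ] <- sweep(
          l + matrix(rnorm(n_frames * 3, 0, noise_sd), ncol = 3),
          2, base[i, ], "+")
      }
    }
    trajectory(arr, domains = domains)
  })
}

#' Simulate an ITC titration
#'
#' [predict_heats()] plus seeded Gaussian noise on the injection heats.
#'
#' @inheritParams predict_heats
#' @param noise_sd Noise standard deviation, ucal (0 reproduces the
#'   noiseless model exactly).
#' @param seed RNG seed.
#' @return A `thermogram`.
#' @export
make_itc_titration <- function(n = 1, K = 2e6, dH = 8.8,
                               protocol = titration_protocol(),
                               noise_sd = 0, seed = 1) {
  tg <- predict_heats(protocol, n, K, dH)
  if (noise_sd > 0) {
    tg$heat <- tg$heat +
      .with_seed(seed, rnorm(nrow(tg), 0, noise_sd))
  }
  tg
}

#' Counter-ion count for a physiological salt concentration
#'
#' `N(ions) = round(N(water) * 0.15 / 55.555)`, the conversion from a
#' water count to the number of ion pairs giving 0.15 M salt.
#'
#' @param n_water Number of water molecules (>= 0).
#' @return Integer ion count; linear in `n_water` before rounding.
#' @export
ion_count <- function(n_water) {
  if (any(n_water < 0)) abort("n_water must be non-negative")
  round(n_water * 0.15 / 55.555)
}

#' Load a packaged fixture table
#'
#' Exact transcriptions of the published reference tables shipped with
#' the package: `"table1"` is the four-term energy decomposition of the
#' position-1 C/T motif pair (a computed `total` column, defined as the
#' four-term sum, is appended); `"table2"` the calorimetric summary for
#' five DNA duplexes, including the weak-binding (Kd above 50 uM) and
#' no-binding-detected (NBD) outcomes as explicit flags rather than
#' numbers.
#'
#' @param name "table1" or "table2".
#' @return A tibble.
#' @export
load_fixture <- function(name = c("table1", "table2")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"),
                      package = "groovescan", mustWork = TRUE)
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  if (name == "table1") {
    tb$total <- tb$clash_dna + tb$clash_protein +
      tb$interaction_energy + tb$sidechain_hbond
  }
  tb
}
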