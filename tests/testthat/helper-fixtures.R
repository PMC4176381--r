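# Shared small fixtures, built in code at test time.

toy2 <- make_toy_complex(2)
toy4 <- make_toy_complex(4)

# apply a rigid-body transform (rotation + translation) to a complex
rigid_transform_complex <- function(cx, angles = c(0.3, 0.7, 1.1),
                                    shift = c(5, -3, 2)) {
  Rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a),
                             0, -sin(a), cos(a)), 3, 3)
  Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a),
                             cos(a), 0, 0, 0, 1), 3, 3)
  R <- Rx(angles[1]) %*% Rz(angles[2]) %*% Rx(angles[3])
  tf_df <- function(df) {
    m <- as.matrix(df[, c("x", "y", "z")]) %*% R
    df$x <- m[, 1] + shift[1]
    df$y <- m[, 2] + shift[2]
    df$z <- m[, 3] + shift[3]
    df
  }
  cx$protein <- tf_df(cx$protein)
  cx$bases <- tf_df(cx$bases)
  a <- cx$anchors
  o <- as.matrix(a[, c("ox", "oy", "oz")]) %*% R
  a[, c("ox", "oy", "oz")] <- sweep(o, 2, shift, "+")
  a[, c("ex1", "ex2", "ex3")] <-
    as.matrix(a[, c("ex1", "ex2", "ex3")]) %*% R
  a[, c("ey1", "ey2", "ey3")] <-
    as.matrix(a[, c("ey1", "ey2", "ey3")]) %*% R
  cx$anchors <- a
  cx
}

# minimal hand-built complex: a few free-floating atoms around a 2-bp
# duplex far from the protein, for clash/interaction edge cases
sparse_complex <- function(protein_xyz = matrix(c(100, 100, 100), 1, 3),
                           resname = "GLY", atom = "CA") {
  cx <- make_toy_complex(2, probe = FALSE, pocket = FALSE)
  cx$protein <- tibble::tibble(
    residue = seq_len(nrow(protein_xyz)),
    resname = resname, chain = "A", atom = atom, element = "C",
    x = protein_xyz[, 1], y = protein_xyz[, 2], z = protein_xyz[, 3])
  cx
}

# a hand-rolled scan_table for select_bound unit tests
fake_scan_table <- function(ddG) {
  motifs <- enumerate_motifs(1)[seq_along(ddG)]
  tb <- tibble::tibble(
    motif = motifs, ddG = sort(ddG), rank = seq_along(ddG),
    clash_dna = 0, clash_protein = 0, interaction_energy = 0,
    sidechain_hbond = 0, total = sort(ddG))
  attr(tb, "reference") <- motifs[1]
  attr(tb, "L") <- 1L
  class(tb) <- c("scan_table", class(tb))
  tb
}
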