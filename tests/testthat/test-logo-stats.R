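test_that("Boltzmann weights follow the closed form and its
          invariances", {
  expect_equal(boltzmann_weights(c(1, 1, 1)), rep(1 / 3, 3))
  kT <- 0.593
  w <- boltzmann_weights(c(0, kT * log(2)), kT)
  expect_equal(w[1] / w[2], 2, tolerance = 1e-12)
  expect_equal(boltzmann_weights(c(0, 1, 2) + 57, kT),
               boltzmann_weights(c(0, 1, 2), kT), tolerance = 1e-12)
  expect_equal(sum(boltzmann_weights(rnorm(20))), 1, tolerance = 1e-12)
  # high-temperature limit recovers the uniform logo
  expect_equal(boltzmann_weights(c(0, 1, 3), kT = 1e6), rep(1 / 3, 3),
               tolerance = 1e-5)
  expect_error(boltzmann_weights(numeric(0)), "empty")
  expect_error(boltzmann_weights(c(0, 1), kT = 0), "positive")
})

test_that("frequency matrices accumulate weights per position", {
  fm1 <- frequency_matrix("CG")
  expect_equal(unclass(fm1),
               matrix(c(0, 1, 0, 0, 0, 0, 1, 0), 4, 2,
                      dimnames = list(c("A", "C", "G", "T"),
                                      c("pos1", "pos2"))))
  fm2 <- frequency_matrix(c("AA", "CC"))
  expect_equal(unname(fm2["A", ]), c(0.5, 0.5))
  expect_equal(unname(fm2["C", ]), c(0.5, 0.5))
  # weighted accumulation vs brute-force loop over all 64 motifs
  motifs <- enumerate_motifs(3)
  set.seed(11)
  w <- boltzmann_weights(runif(64, 0, 5))
  fm <- frequency_matrix(motifs, w)
  oracle <- matrix(0, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (k in seq_along(motifs)) {
    for (j in 1:3) {
      b <- substr(motifs[k], j, j)
      oracle[b, j] <- oracle[b, j] + w[k]
    }
  }
  expect_equal(unname(unclass(fm)), unname(oracle), tolerance = 1e-12)
  expect_equal(colSums(fm), c(pos1 = 1, pos2 = 1, pos3 = 1),
               tolerance = 1e-9)
  expect_error(frequency_matrix(c("AA", "CC"), weights = 1), "align")
})

test_that("information content hits its closed-form anchors and
          bounds", {
  fm <- structure(matrix(c(0.25, 0.25, 0.25, 0.25,
                           1, 0, 0, 0,
                           0.5, 0.5, 0, 0), 4, 3,
                         dimnames = list(c("A", "C", "G", "T"), NULL)),
                  class = c("frequency_matrix", "matrix"))
  ip <- information_profile(fm)
  expect_equal(ip$bits, c(0, 2, 1), tolerance = 1e-12)
  # bounds on an arbitrary scan-derived logo
  st <- scan_motifs(toy2)
  bs <- select_bound(st, 3)
  ip2 <- information_profile(frequency_matrix(bs$bound$motif))
  expect_true(all(ip2$bits >= 0 & ip2$bits <= 2))
})

test_that("threshold sweep matrices equal per-threshold recomputation", {
  st <- scan_motifs(toy2)
  thr <- c(0, 1, 2, 100)
  sw <- frequency_vs_threshold(st, thr)
  for (k in seq_along(thr)) {
    bs <- select_bound(st, thr[k])
    expect_identical(sw$n_bound[k], nrow(bs$bound))
    expect_equal(sw$fm[[k]], frequency_matrix(bs$bound$motif),
                 tolerance = 1e-12)
  }
  # widest threshold equals the full-table composition
  expect_equal(sw$fm[[4]], frequency_matrix(st$motif), tolerance = 1e-12)
  expect_error(frequency_vs_threshold(st, c(2, 1)), "ascending")
})

test_that("conditional probabilities renormalize the joint weights and
          obey the chain rule", {
  cp <- conditional_probabilities(c("AC", "AG"))
  expect_equal(
    cp$p_cond[cp$i == 1 & cp$a == "A" & cp$j == 2 & cp$b == "C"], 0.5)
  # normalization over b for every defined (i, a, j) slice
  sums <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(cp, defined), i, a, j),
    s = sum(p_cond), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
  # undefined slices are flagged, never zero-filled
  expect_true(all(is.na(cp$p_cond[!cp$defined])))
  expect_gt(sum(!cp$defined), 0)  # no T anywhere at position 1
  # chain rule on a Boltzmann-weighted ensemble
  motifs <- enumerate_motifs(3)
  set.seed(4)
  w <- boltzmann_weights(runif(64, 0, 4))
  cpw <- conditional_probabilities(motifs, w)
  fm <- frequency_matrix(motifs, w)
  marg <- vapply(seq_len(nrow(cpw)), function(r)
    fm[cpw$a[r], cpw$i[r]], numeric(1))
  ok <- cpw$defined
  expect_equal(cpw$p_joint[ok], (marg * cpw$p_cond)[ok],
               tolerance = 1e-12)
})

test_that("an independent ensemble shows vanishing positional coupling
          as the sample grows", {
  draw <- function(n, seed) {
    set.seed(seed)
    p <- list(c(0.4, 0.3, 0.2, 0.1), c(0.1, 0.2, 0.3, 0.4),
              c(0.25, 0.25, 0.25, 0.25))
    apply(vapply(p, function(pp)
      sample(c("A", "C", "G", "T"), n, TRUE, pp), character(n)),
      1, paste0, collapse = "")
  }
  dev <- function(n) {
    cp <- conditional_probabilities(draw(n, seed = 99))
    mean(abs(cp$delta[cp$defined]))
  }
  d_small <- dev(250)
  d_large <- dev(4000)
  expect_lt(d_large, d_small)
  expect_lt(d_large, 0.05)
})
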