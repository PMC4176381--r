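test_that("the minor-groove probe distinguishes bidentate guanine from
          monodentate adenine", {
  # C at position 1 pairs a G: amide donor + acceptor both engaged
  hb_G <- detect_hbonds(toy4)
  expect_identical(nrow(hb_G), 2L)
  expect_true(all(hb_G$energy <= 0))
  expect_true(all(hb_G$position == 1L))
  # T at position 1 pairs an A: only the aromatic N3 acceptor remains
  hb_A <- detect_hbonds(thread_sequence(toy4, "TGTG"))
  expect_identical(nrow(hb_A), 1L)
  # displaced probe: no contacts at all
  far <- make_toy_complex(4, probe_offset = 1.5)
  expect_identical(nrow(detect_hbonds(far)), 0L)
  # the G pairing is strictly more favorable than the A pairing
  expect_lt(sum(hb_G$energy), sum(hb_A$energy))
})

test_that("hydrogen bond detection matches a brute-force all-pairs
          geometric filter", {
  params <- energy_params()
  for (motif in c("CGTG", "TGTG", "AGCA")) {
    cx <- thread_sequence(toy4, motif)
    got <- detect_hbonds(cx, params)
    # independent filter: loop every protein site x DNA site pair
    psites <- merge(cx$protein,
                    groovescan:::.PROTEIN_HB_SITES,
                    by = c("resname", "atom"))
    dsites <- as.data.frame(
      cx$bases[cx$bases$role %in% c("donor", "acceptor") &
                 !is.na(cx$bases$groove), ])
    n_expected <- 0L
    for (i in seq_len(nrow(psites))) {
      for (j in seq_len(nrow(dsites))) {
        if (psites$role[i] == dsites$role[j]) next
        don <- if (psites$role[i] == "donor") psites[i, ] else dsites[j, ]
        acc <- if (psites$role[i] == "donor") dsites[j, ] else psites[i, ]
        d <- sqrt((don$x - acc$x)^2 + (don$y - acc$y)^2 +
                    (don$z - acc$z)^2)
        if (d < params$hbond_dist_min || d > params$hbond_dist_max) next
        # donor angle via its parent atom
        if (don$role == "donor" && "position" %in% names(don)) {
          par <- cx$bases[cx$bases$strand == don$strand &
                            cx$bases$position == don$position &
                            cx$bases$atom == don$parent, ]
        } else {
          par <- cx$protein[cx$protein$residue == don$residue &
                              cx$protein$atom == don$parent, ]
        }
        if (nrow(par) == 1) {
          v1 <- c(par$x - don$x, par$y - don$y, par$z - don$z)
          v2 <- c(acc$x - don$x, acc$y - don$y, acc$z - don$z)
          ang <- acos(sum(v1 * v2) /
                        sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
          if (ang < params$hbond_angle_min) next
        }
        n_expected <- n_expected + 1L
      }
    }
    expect_identical(nrow(got), n_expected)
  }
})

test_that("clash terms are zero for well-separated atoms and grow
          monotonically with overlap", {
  cx <- sparse_complex()
  cl <- clash_terms(cx)
  expect_identical(unname(cl["clash_protein"]), 0)
  params <- energy_params()
  # bring one carbon down toward the top base plane from above: every
  # pair distance shrinks together, so the total penalty must grow
  target <- dplyr::filter(cx$bases, atom == "N3", strand == 1,
                          position == 2)
  contact <- params$clash_radius_scale * (1.70 + 1.55)
  pen <- vapply(c(0.9, 0.5, 0.25), function(fr) {
    cxx <- sparse_complex(matrix(
      c(target$x, target$y, target$z + fr * contact), 1, 3))
    unname(clash_terms(cxx, params)["clash_protein"])
  }, numeric(1))
  expect_identical(pen[1] > 0, TRUE)
  expect_true(all(diff(pen) > 0))
})

test_that("a bulky purine threaded into the pocket clashes more than a
          pyrimidine, matching a brute-force pair sum", {
  params <- energy_params()
  bulky <- clash_terms(thread_sequence(toy4, "CGTG"), params)
  small <- clash_terms(thread_sequence(toy4, "CCTG"), params)
  expect_gt(bulky[["clash_protein"]], small[["clash_protein"]])
  # brute-force oracle: direct double loop over protein x DNA atoms
  cx <- thread_sequence(toy4, "CGTG")
  expected <- 0
  for (i in seq_len(nrow(cx$protein))) {
    for (j in seq_len(nrow(cx$bases))) {
      d <- sqrt((cx$protein$x[i] - cx$bases$x[j])^2 +
                  (cx$protein$y[i] - cx$bases$y[j])^2 +
                  (cx$protein$z[i] - cx$bases$z[j])^2)
      lim <- params$clash_radius_scale *
        (groovescan:::vdw_radius(cx$protein$element[i]) +
           groovescan:::vdw_radius(cx$bases$element[j]))
      if (d < lim) {
        expected <- expected +
          params$clash_penalty_scale * (1 - d / lim)^2
      }
    }
  }
  expect_equal(bulky[["clash_protein"]], expected, tolerance = 1e-12)
})

test_that("interaction term is a non-positive sum of pair wells", {
  params <- energy_params()
  expect_identical(interaction_energy(sparse_complex(), params), 0)
  # 3-atom interface equals the hand-summed pair terms
  cx <- sparse_complex()
  b <- cx$bases[1:3, ]
  probe <- c(b$x[1] + 3, b$y[1], b$z[1])
  cxx <- sparse_complex(matrix(probe, 1, 3))
  got <- interaction_energy(cxx, params)
  d <- sqrt((cxx$bases$x - probe[1])^2 + (cxx$bases$y - probe[2])^2 +
              (cxx$bases$z - probe[3])^2)
  d <- d[d < params$interaction_cutoff]
  expected <- -params$interaction_depth *
    sum((1 - (d / params$interaction_cutoff)^2)^2)
  expect_equal(got, expected, tolerance = 1e-12)
  # adding a contacting atom never makes the term less negative
  cx2 <- sparse_complex(rbind(probe, probe + c(0.5, 0, 0)))
  expect_lte(interaction_energy(cx2, params), got)
})

test_that("the breakdown total is the exact four-term sum and is rigid-
          transform invariant", {
  be <- binding_energy(toy4)
  expect_identical(be$total,
                   be$clash_dna + be$clash_protein +
                     be$interaction_energy + be$sidechain_hbond)
  expect_gte(be$clash_dna, 0)
  expect_gte(be$clash_protein, 0)
  expect_lte(be$sidechain_hbond, 0)
  expect_lte(be$interaction_energy, 0)
  for (seed in 1:3) {
    set.seed(seed)
    be2 <- binding_energy(rigid_transform_complex(
      toy4, angles = runif(3, 0, 2 * pi), shift = rnorm(3, 0, 10)))
    expect_equal(unlist(be2), unlist(be), tolerance = 1e-6)
  }
})

test_that("published energy decomposition fixture reproduces its printed
          arithmetic", {
  t1 <- load_fixture("table1")
  cgt <- t1[t1$sequence == "CGTGGGAA", ]
  expect_equal(cgt$total, 11.16 + 37.67 - 12.94 - 16.75)
  expect_equal(cgt$total, 19.14, tolerance = 1e-9)
  # position-1 thymine penalty carried by the side-chain H-bond term
  tgt <- t1[t1$sequence == "TGTGGGAA", ]
  expect_equal(tgt$sidechain_hbond - cgt$sidechain_hbond, 1.99)
})

test_that("relative binding energy is antisymmetric and parameter-
          checked", {
  a <- binding_energy(toy4)
  b <- binding_energy(thread_sequence(toy4, "TGTG"))
  expect_identical(relative_binding_energy(a, a), 0)
  expect_equal(relative_binding_energy(a, b),
               -relative_binding_energy(b, a))
  c2 <- binding_energy(toy4, energy_params(interaction_depth = 0.5))
  expect_error(relative_binding_energy(a, c2), "different parameters")
})
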