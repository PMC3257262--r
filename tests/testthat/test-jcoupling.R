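test_that("doublet splittings convert to Hz through the field", {
  expect_equal(j_from_doublet(8.00, 8.01, 800), 8.0)
  expect_equal(j_from_doublet(8.000, 8.005, 800), 4.0)
  expect_equal(j_from_doublet(8.0, 8.0, 800), 0.0)
  expect_error(j_from_doublet(8.0, 8.01, -1), "field_mhz")
  # linear in field
  set.seed(3)
  for (i in 1:20) {
    lo <- runif(1, 7, 9); d <- runif(1, 0, 0.02); f <- runif(1, 300, 1200)
    expect_equal(j_from_doublet(lo, lo + d, 2 * f),
                 2 * j_from_doublet(lo, lo + d, f))
  }
})

test_that("band classification is total, deterministic and matches the limits", {
  expect_equal(classify_band(4.0), "helix")
  expect_equal(classify_band(9.5), "sheet")
  expect_equal(classify_band(5.5), "unresolved")
  expect_equal(classify_band(7.0), "coil")
  # closed/open boundaries: 3 and 5 helix; 6 and 8 coil; just above 8 sheet
  expect_equal(classify_band(c(3, 5, 6, 8, 8.0001, 11, 11.5, 2.9, 0, NA)),
               c("helix", "helix", "coil", "coil", "sheet", "sheet",
                 "unresolved", "unresolved", "unresolved", "unresolved"))
  expect_error(classify_band(-1), ">= 0")
  # no coupling maps to two bands: classification is a pure function
  set.seed(8)
  j <- runif(200, 0, 13)
  expect_identical(classify_band(j), classify_band(j))
})

test_that("random-coil J takes the predecessor correction", {
  seq <- toy_sequence()  # F at 8, so 9 is aromatic-preceded
  base <- toy_jrandom(7)
  expect_equal(j_random_for(seq, 3, base), 7)
  expect_equal(j_random_for(seq, 9, base, aromatic_correction_hz = -0.5), 6.5)
  expect_true(is.na(j_random_for(seq, 1, base)))  # chain start: unresolved
  expect_error(j_random_for(seq, 5, base), "proline")
})

test_that("deviation profiles match element-wise computation", {
  seq <- toy_sequence()
  cond <- condition(0.9, field_mhz = 800)
  base <- toy_jrandom(7)
  set.seed(21)
  pos <- setdiff(2:20, prolines(seq))
  pos <- sample(pos, 12)
  j_true <- runif(12, 3.5, 9.5)
  h0 <- runif(12, 7.5, 8.5)
  dt <- doublet_table(cond, data.frame(
    position = pos,
    h_ppm_low = h0 - j_true / 800 / 2,
    h_ppm_high = h0 + j_true / 800 / 2,
    n_ppm = 120))
  prof <- deviation_profile(dt, seq, base_table = base)
  for (i in seq_along(pos)) {
    row <- prof[prof$position == pos[i], ]
    expect_equal(row$j_obs, j_true[i])
    expect_equal(row$j_random, j_random_for(seq, pos[i], base))
    expect_equal(row$deviation, row$j_obs - row$j_random)
    expect_equal(row$band, classify_band(j_true[i]))
  }
  # residues without a doublet are unresolved, not zero
  missing <- setdiff(setdiff(seq$positions, prolines(seq)), pos)
  expect_true(all(prof$band[prof$position %in% missing] == "unresolved"))
  expect_true(all(is.na(prof$j_obs[prof$position %in% missing])))
})

test_that("observed J equal to random coil gives zero deviation", {
  seq <- toy_sequence()
  cond <- condition(0.9)
  base <- toy_jrandom(7)
  pos <- c(3, 9, 15)
  jr <- j_random_for(seq, pos, base)
  dt <- doublet_table(cond, data.frame(
    position = pos, h_ppm_low = 8 - jr / 800 / 2,
    h_ppm_high = 8 + jr / 800 / 2, n_ppm = 120))
  prof <- deviation_profile(dt, seq, base_table = base)
  expect_equal(prof$deviation[match(pos, prof$position)], c(0, 0, 0))
})

test_that("a planted deviation range is reported back exactly", {
  # fixture spanning deviations from +2.5 down to -4.9 Hz
  seq <- protein_sequence(rep("A", 30))
  base <- toy_jrandom(7)
  devs <- seq(2.5, -4.9, length.out = 20)
  pos <- 2:21
  dt <- doublet_table(condition(0.9), data.frame(
    position = pos,
    h_ppm_low = 8 - (7 + devs) / 800 / 2,
    h_ppm_high = 8 + (7 + devs) / 800 / 2,
    n_ppm = 118))
  prof <- deviation_profile(dt, seq, base_table = base)
  expect_equal(range(prof$deviation, na.rm = TRUE), c(-4.9, 2.5))
})
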