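test_that("solvent weights default to the volume fractions", {
  expect_equal(solvent_weights(condition(1.0)), c(p1 = 1.0, p2 = 0.0))
  expect_equal(solvent_weights(condition(0.0)), c(p1 = 0.0, p2 = 1.0))
  expect_equal(solvent_weights(condition(0.9)), c(p1 = 0.9, p2 = 0.1))
})

test_that("delta_ca applies the blended random-coil baseline", {
  seq <- toy_sequence()
  rc <- toy_rc_tables()
  # hand arithmetic: C_obs 55, rc_dmso 52, rc_aq 53, f = 0.8 -> 2.8
  rc_d <- random_coil_table(setNames(rep(52, 20), names(rc$dmso)), "dmso")
  rc_a <- random_coil_table(setNames(rep(53, 20), names(rc$aqueous)), "aqueous")
  st <- ca_table(c("2" = 55.0), seq, condition(0.8))
  prof <- delta_ca(st, rc_d, rc_a)
  expect_equal(prof$delta_ca, 55.0 - (0.8 * 52 + 0.2 * 53))
  expect_equal(attr(prof, "p1"), 0.8)

  # p1 = 1 collapses to the single DMSO baseline
  st1 <- ca_table(c("2" = 55.0), seq, condition(1.0))
  prof1 <- delta_ca(st1, rc_d, rc_a)
  expect_equal(prof1$delta_ca, 55.0 - 52)

  # observed shift equal to the blend gives exactly zero
  st0 <- ca_table(c("2" = 0.8 * 52 + 0.2 * 53), seq, condition(0.8))
  expect_equal(delta_ca(st0, rc_d, rc_a)$delta_ca, 0.0)
})

test_that("identical solvent tables make delta_ca independent of the weights", {
  seq <- toy_sequence()
  same <- toy_rc_tables(offset = 0)
  set.seed(5)
  shifts <- setNames(runif(6, 50, 60), c(1, 2, 3, 4, 6, 7))
  profs <- lapply(c(1.0, 0.6, 0.3, 0.0), function(f) {
    delta_ca(ca_table(shifts, seq, condition(f)), same$dmso, same$aqueous)
  })
  for (p in profs[-1]) expect_equal(p$delta_ca, profs[[1]]$delta_ca)
})

test_that("residues without a CA record are absent, never zero-filled", {
  seq <- toy_sequence()
  rc <- toy_rc_tables()
  prof <- delta_ca(ca_table(c("2" = 55, "7" = 56), seq), rc$dmso, rc$aqueous)
  expect_equal(prof$position, c(2, 7))
})

test_that("an amino acid missing from a random-coil table names the residue", {
  seq <- toy_sequence()
  rc <- toy_rc_tables()
  partial <- rc$dmso
  crippled <- unclass(partial)
  crippled <- crippled[names(crippled) != "S"]
  fake <- structure(crippled, class = "random_coil_table", medium = "dmso")
  expect_error(delta_ca(ca_table(c("2" = 55), seq), fake, rc$aqueous),
               "'S' \\(position 2\\)")
})

test_that("propensity segments match the worked examples", {
  prof <- data.frame(position = c(100, 101, 102, 103),
                     delta_ca = c(1.2, 1.5, 0.9, 0.2))
  seg <- call_propensity_segments(prof, threshold_ppm = 0.7, min_len = 3)
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$start, seg$end), c(100, 102))
  expect_equal(seg$label, "helix-propensity")

  # all zero -> nothing
  flat <- data.frame(position = 1:10, delta_ca = rep(0, 10))
  expect_equal(nrow(call_propensity_segments(flat)), 0)

  # one sub-threshold residue splits a run
  split <- data.frame(position = 1:7,
                      delta_ca = c(1, 1, 1, 0.1, 1, 1, 1))
  seg3 <- call_propensity_segments(split, min_len = 3)
  expect_equal(seg3$start, c(1, 5))
  expect_equal(seg3$end, c(3, 7))
  expect_equal(nrow(call_propensity_segments(split, min_len = 4)), 0)

  # a residue exactly at the threshold is not significant
  edge <- data.frame(position = 1:3, delta_ca = c(0.7, 0.7, 0.7))
  expect_equal(nrow(call_propensity_segments(edge, threshold_ppm = 0.7,
                                             min_len = 1)), 0)
  expect_error(call_propensity_segments(edge, threshold_ppm = -1), "non-negative")
})

test_that("segment calls equal brute-force maximal-run enumeration", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(8:40, 1)
    pos <- sort(sample(1:60, n))
    deltas <- rnorm(n, 0, 1)
    thr <- sample(c(0.3, 0.7), 1)
    ml <- sample(1:3, 1)
    prof <- data.frame(position = pos, delta_ca = deltas)
    got <- call_propensity_segments(prof, threshold_ppm = thr, min_len = ml)
    want <- oracle_propensity_segments(pos, deltas, thr, ml)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$label, want$label)
  }
})

test_that("raising the threshold never lengthens any called segment", {
  set.seed(7)
  for (i in 1:20) {
    prof <- data.frame(position = 1:40, delta_ca = rnorm(40, 0, 1.2))
    lo <- call_propensity_segments(prof, threshold_ppm = 0.5, min_len = 1)
    hi <- call_propensity_segments(prof, threshold_ppm = 1.0, min_len = 1)
    for (j in seq_len(nrow(hi))) {
      container <- lo[lo$start <= hi$start[j] & lo$end >= hi$end[j] &
                        lo$label == hi$label[j], ]
      expect_gte(nrow(container), 1)
    }
  }
})

test_that("a planted helix is recovered with <= 1 residue boundary error", {
  seq <- fixture_sequence()
  rc <- toy_rc_tables()
  base <- as.numeric(rc$dmso[seq$aa])
  names(base) <- seq$positions
  set.seed(31)
  for (rep in 1:10) {
    helix <- c(75, 95)  # avoids the fixture prolines: a missing residue breaks runs
    shifts <- base + rnorm(137, 0, 0.2)
    idx <- seq$positions >= helix[1] & seq$positions <= helix[2]
    shifts[idx] <- shifts[idx] + 2.5
    st <- ca_table(shifts[seq$aa != "P"], seq, condition(1.0))
    prof <- delta_ca(st, rc$dmso, rc$aqueous)
    seg <- call_propensity_segments(prof, threshold_ppm = 0.7, min_len = 3)
    seg <- seg[seg$label == "helix-propensity", ]
    # the planted interval is recovered by one segment with <= 1 residue slack
    hit <- seg[abs(seg$start - helix[1]) <= 1 & abs(seg$end - helix[2]) <= 1, ]
    expect_equal(nrow(hit), 1)
  }
})
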