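test_that("ground truth is deterministic and validates its geometry", {
  t1 <- make_ground_truth(seed = 6)
  t2 <- make_ground_truth(seed = 6)
  expect_identical(t1, t2)
  expect_equal(t1$nucleation, c(109L, 116L))
  expect_equal(unname(t1$stage[109:116]), rep(1, 8))
  # nucleation at a terminus is rejected
  expect_error(make_ground_truth(ground_truth_config(nucleation = c(1, 8))),
               "terminus")
  expect_error(make_ground_truth(ground_truth_config(nucleation = c(130, 137))),
               "terminus")
})

test_that("custom nucleation radiates monotone stages in both directions", {
  cfg <- ground_truth_config(nucleation = c(50, 55), flexible = NULL,
                             stage_plan = NULL)
  truth <- make_ground_truth(cfg, seed = 1)
  s <- truth$stage
  pos <- truth$seq$positions
  expect_equal(unname(s[50:55]), rep(1, 6))
  # stages never decrease moving away from the nucleation segment
  n_arm <- s[pos < 50 & pos > 1]
  expect_true(all(diff(rev(unname(n_arm))) >= 0 |
                    is.infinite(rev(unname(n_arm))[-1])))
  c_arm <- unname(s[pos > 55])
  c_arm[is.infinite(c_arm)] <- 999
  expect_true(all(diff(c_arm) >= 0))
})

test_that("emission is byte-identical for identical seed and config", {
  o1 <- emit_observables(make_ground_truth(seed = 13))
  o2 <- emit_observables(make_ground_truth(seed = 13))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_observables(o1, d1)
  write_observables(o2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
  # and different seeds perturb the noise
  o3 <- emit_observables(make_ground_truth(seed = 14))
  expect_false(identical(o1$shift_tables[[1]]$records,
                         o3$shift_tables[[1]]$records))
})

test_that("the folded fraction is monotone in the denaturant ladder", {
  truth <- make_ground_truth(seed = 5)
  f_prev <- fold_fraction(truth, 1)
  for (k in 2:6) {
    f_k <- fold_fraction(truth, k)
    expect_true(all(f_k >= f_prev - 1e-12))
    f_prev <- f_k
  }
  # flexible residues never fold
  flex <- as.character(2:32)
  expect_true(all(fold_fraction(truth, 6)[flex] == 0))
})

test_that("zero noise and zero propensity give identically zero delta_ca", {
  cfg <- ground_truth_config(helix_propensity = 0, shift_sigma_ppm = 0,
                             intensity_sigma_frac = 0, j_sigma_hz = 0)
  obs <- emit_observables(make_ground_truth(cfg, seed = 1))
  for (st in obs$shift_tables) {
    prof <- delta_ca(st)
    expect_equal(max(abs(prof$delta_ca)), 0)
  }
})

test_that("the default fixture reproduces the expected presence ladder", {
  obs <- emit_observables(make_ground_truth(seed = 20))
  seq <- obs$seq
  # at the final 50% DMSO condition exactly the non-proline N-terminal
  # tail [2, 32] remains observable
  pp <- present_positions(obs$presence, 6)
  expect_equal(pp, setdiff(2:32, 12))
  expect_equal(length(pp), 30)
  # at 100% DMSO the nucleation segment (and the alpha-amino first residue)
  # are the only non-proline absences
  p1 <- present_positions(obs$presence, 1)
  expect_equal(setdiff(setdiff(seq$positions, prolines(seq)), p1),
               c(1, 109:116))
  # presence built from the emitted shift tables equals the planted matrix
  rebuilt <- build_presence(obs$shift_tables, seq)
  expect_equal(rebuilt$states, obs$presence$states)
})

test_that("emitted couplings shrink toward the helix value as folding grows", {
  cfg <- ground_truth_config(j_sigma_hz = 0, shift_sigma_ppm = 0)
  truth <- make_ground_truth(cfg, seed = 1)
  obs <- emit_observables(truth)
  j_at <- function(k, p) {
    dt <- obs$doublets[[k]]
    r <- dt$records[dt$records$position == p, ]
    if (!nrow(r)) return(NA_real_)
    j_from_doublet(r$h_ppm_low, r$h_ppm_high, dt$condition$field_mhz)
  }
  # residue 100 (stage 2, propensity 1): coil-like at 100%, folding at 90%
  expect_equal(j_at(1, 100), 7 - 3 * 0.5)  # fold_fraction 0.5 at k=1
  # flexible tail residue stays at coil J throughout
  expect_equal(j_at(1, 20), 7)
  expect_equal(j_at(6, 20), 7)
})

test_that("generated observables satisfy the container invariants on re-read", {
  obs <- emit_observables(make_ground_truth(seed = 8))
  d <- withr::local_tempdir()
  write_observables(obs, d)
  expect_no_error(read_observables(d))
})
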