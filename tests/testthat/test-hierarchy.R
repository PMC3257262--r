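test_that("presence follows major-state amide assignments", {
  seq <- toy_sequence()
  cond <- condition(1.0)
  pos <- setdiff(seq$positions, prolines(seq))
  st <- shift_table(cond, data.frame(position = pos, nucleus = "H",
                                     shift_ppm = 8.1, state = "major"),
                    seq = seq)
  pm <- build_presence(list(dmso100 = st), seq)
  expect_equal(present_positions(pm, 1), pos)
  expect_true(all(pm$states[match(prolines(seq), pm$positions), ] == "absent"))
})

test_that("minor-state duplicates are recorded separately but count as present", {
  seq <- toy_sequence()
  cond <- condition(1.0)
  rec <- rbind(
    data.frame(position = c(2L, 3L, 4L), nucleus = "H", shift_ppm = 8.1,
               state = "major"),
    data.frame(position = 3L, nucleus = "H", shift_ppm = 8.15,
               state = "minor"))
  pm <- build_presence(list(dmso100 = shift_table(cond, rec, seq = seq)), seq)
  expect_equal(unname(pm$states[match(3, pm$positions), 1]), "minor_duplicate")
  expect_true(3 %in% present_positions(pm, 1))
})

test_that("non-monotone presence is flagged, not silently fixed", {
  seq <- protein_sequence(rep("A", 12))
  pm <- presence_from_lists(list(2:10, c(2:5, 8:10), 2:10), seq,
                            fractions = c(1, 0.9, 0.8))
  audit <- presence_consistency(pm)
  expect_setequal(audit$position, 6:7)  # reappear at 0.8 after vanishing
  # the matrix itself is untouched
  expect_true(all(6:7 %in% present_positions(pm, 3)))
})

test_that("disappearance events reconstruct a planted stage map", {
  truth <- make_ground_truth(seed = 2)
  obs <- emit_observables(truth)
  ev <- disappearance_events(obs$presence)
  lab <- nmrtitr:::ladder_labels(truth$conditions)
  fr <- conditions_table(truth$conditions)$dmso_fraction
  want <- oracle_events_from_stages(truth$stage, truth$seq$positions,
                                    prolines(truth$seq),
                                    length(truth$conditions), lab, fr)
  expect_equal(ev$condition_index, want$condition_index)
  expect_equal(ev$start, want$start)
  expect_equal(ev$end, want$end)
  expect_equal(ev$length, want$length)
})

test_that("no change between conditions yields no events; single residues do", {
  seq <- protein_sequence(rep("A", 10))
  same <- presence_from_lists(list(2:9, 2:9), seq)
  expect_equal(nrow(disappearance_events(same)), 0)
  one <- presence_from_lists(list(2:9, c(2:5, 7:9)), seq)
  ev <- disappearance_events(one)
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$start, ev$end, ev$length), c(6, 6, 1))
  expect_error(disappearance_events(presence_from_lists(list(2:9), seq)),
               "at least 2")
})

test_that("each residue vanishes in at most one event on a clean titration", {
  obs <- emit_observables(make_ground_truth(seed = 9))
  ev <- disappearance_events(obs$presence)
  covered <- unlist(lapply(seq_len(nrow(ev)), function(i) ev$start[i]:ev$end[i]))
  covered <- setdiff(covered, prolines(obs$seq))
  expect_equal(anyDuplicated(covered), 0)
})

test_that("nucleation requires exchange flanks on both sides", {
  seq <- protein_sequence(rep("A", 137))
  present <- setdiff(2:137, 109:116)
  pm <- presence_from_lists(list(present, present), seq)
  ex <- data.frame(start = c(97, 117), end = c(108, 120))
  nuc <- find_nucleation(pm, ex, flank_window = 3)
  expect_equal(nrow(nuc), 1)
  expect_equal(c(nuc$start, nuc$end), c(109, 116))
  expect_equal(c(nuc$left_flank_start, nuc$left_flank_end), c(97, 108))
  expect_equal(c(nuc$right_flank_start, nuc$right_flank_end), c(117, 120))
  # one-sided exchange: excluded
  expect_equal(nrow(find_nucleation(pm, ex[1, , drop = FALSE])), 0)
  # flank farther than the window: excluded
  far <- data.frame(start = c(90, 125), end = c(100, 130))
  expect_equal(nrow(find_nucleation(pm, far, flank_window = 3)), 0)
  expect_equal(nrow(find_nucleation(pm, far, flank_window = 10)), 1)
  # terminal absent runs are never nucleation candidates
  pm2 <- presence_from_lists(list(setdiff(2:130, 109:116),
                                  setdiff(2:130, 109:116)), seq)
  nuc2 <- find_nucleation(pm2, ex)
  expect_equal(nrow(nuc2), 1)  # the [131,137] terminal run is not reported
  expect_equal(nuc2$start, 109)
})

test_that("nucleation depends only on the DMSO ordering, not the labels", {
  seq <- protein_sequence(rep("A", 137))
  present <- setdiff(2:137, 60:66)
  ex <- data.frame(start = c(50, 67), end = c(59, 75))
  mk <- function(labels) {
    ladder <- condition_ladder(c(1, 0.9), labels = labels)
    states <- matrix("absent", 137, 2,
                     dimnames = list(1:137, nmrtitr:::ladder_labels(ladder)))
    states[match(present, 1:137), ] <- "present"
    presence_matrix(ladder, states)
  }
  n1 <- find_nucleation(mk(NULL), ex)
  n2 <- find_nucleation(mk(c("zz_top", "aa_bottom")), ex)
  expect_equal(n1[names(n1) != "condition_label"],
               n2[names(n2) != "condition_label"])
})

test_that("the hierarchy report summarises a full synthetic study", {
  truth <- make_ground_truth(seed = 4)
  obs <- emit_observables(truth)
  res <- run_pipeline(obs, fit_relaxation = 1L)
  rep <- res$report
  # incorporation order equals the planted stage order
  expect_equal(rep$incorporation_order$condition_index,
               sort(rep$incorporation_order$condition_index))
  lab <- nmrtitr:::ladder_labels(truth$conditions)
  fr <- conditions_table(truth$conditions)$dmso_fraction
  want <- oracle_events_from_stages(truth$stage, truth$seq$positions,
                                    prolines(truth$seq), 6, lab, fr)
  expect_equal(rep$incorporation_order$start, want$start)
  # the final flexible segment is the N-terminal tail [2, 32]
  final <- rep$per_condition[[6]]$flexible_segments
  expect_equal(nrow(final), 1)
  expect_equal(c(final$start, final$end), c(2, 32))
  # nucleation call propagated
  expect_equal(c(rep$nucleation$start, rep$nucleation$end), c(109, 116))
  # C-half packs before the N-half
  f90 <- rep$per_condition[[2]]
  expect_gt(f90$fraction_incorporated_c_half,
            f90$fraction_incorporated_n_half)
  # report serialises and prints
  f <- withr::local_tempfile(fileext = ".json")
  write_hierarchy_report(rep, f)
  expect_true(file.size(f) > 100)
  expect_output(print(rep), "nucleation")
})

test_that("empty inputs produce an empty report cleanly", {
  seq <- protein_sequence(rep("A", 10))
  pm <- presence_from_lists(list(integer(0), integer(0)), seq)
  rep <- hierarchy_report(pm)
  expect_equal(nrow(rep$incorporation_order), 0)
  expect_null(rep$nucleation)
  expect_output(print(rep), "none")
})
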