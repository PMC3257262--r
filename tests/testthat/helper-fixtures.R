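# Shared fixtures: everything is generated in code at test time.

fixture_sequence <- function() {
  make_ground_truth(seed = 1)$seq
}

# a small hand-controllable sequence: positions 1..20, prolines at 5 and 12,
# aromatic F at 8 (so position 9 takes the predecessor correction)
toy_sequence <- function() {
  aa <- rep("A", 20)
  aa[c(5, 12)] <- "P"
  aa[8] <- "F"
  aa[2] <- "S"
  protein_sequence(aa, name = "toy")
}

toy_condition <- function(frac = 0.9) condition(frac)

# synthetic random-coil tables decoupled from the shipped literature-style
# defaults, so correctness tests do not depend on the packaged values
toy_rc_tables <- function(offset = 2) {
  aq <- setNames(50 + seq_along(nmrtitr:::AA_STANDARD), nmrtitr:::AA_STANDARD)
  list(dmso = random_coil_table(aq - offset, medium = "dmso"),
       aqueous = random_coil_table(aq, medium = "aqueous"))
}

toy_jrandom <- function(base = 7) {
  setNames(rep(base, 20), nmrtitr:::AA_STANDARD)
}

# build a shift_table carrying only CA major records from a position->shift map
ca_table <- function(shifts, seq, cond = toy_condition()) {
  shift_table(cond,
              data.frame(position = as.integer(names(shifts)),
                         nucleus = "CA", shift_ppm = as.numeric(shifts),
                         state = "major", stringsAsFactors = FALSE),
              seq = seq)
}

# presence matrix from a list of present-position vectors (one per condition)
presence_from_lists <- function(present_by_condition, seq,
                                fractions = NULL) {
  K <- length(present_by_condition)
  fractions <- fractions %||% seq(1, by = -0.1, length.out = K)
  ladder <- condition_ladder(fractions)
  pos <- seq$positions
  states <- matrix("absent", nrow = length(pos), ncol = K,
                   dimnames = list(pos, nmrtitr:::ladder_labels(ladder)))
  for (k in seq_len(K)) {
    states[match(present_by_condition[[k]], pos), k] <- "present"
  }
  presence_matrix(ladder, states, proline_mask = prolines(seq))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
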