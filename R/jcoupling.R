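#' 3J(HN-HA) coupling from a resolved doublet splitting
#'
#' The two proton components of a resolved amide doublet are separated by
#' the coupling constant; a ppm splitting converts to Hz through the proton
#' spectrometer frequency: `J = (h_ppm_high - h_ppm_low) * field_mhz`.
#'
#' @param h_ppm_low,h_ppm_high Proton ppm of the two doublet components
#'   (`h_ppm_high >= h_ppm_low`); vectorised.
#' @param field_mhz Proton frequency in MHz (> 0).
#' @return Coupling(s) in Hz.
#' @examples
#' j_from_doublet(8.00, 8.01, 800)  # 8 Hz
#' @export
j_from_doublet <- function(h_ppm_low, h_ppm_high, field_mhz) {
  if (!is.finite(field_mhz) || field_mhz <= 0) {
    stop("field_mhz must be > 0", call. = FALSE)
  }
  if (any(h_ppm_high < h_ppm_low)) {
    stop("h_ppm_high must be >= h_ppm_low", call. = FALSE)
  }
  (h_ppm_high - h_ppm_low) * field_mhz
}

#' Default random-coil 3J(HN-HA) base values
#'
#' Per-residue random-coil couplings near 7 Hz, shipped as an editable
#' default (the literature per-residue corrections are not hard-coded; a
#' lab's preferred table can be read with [read_jrandom_table()]). Proline
#' has no amide proton and carries NA.
#'
#' @return Named numeric vector (one-letter code -> Hz).
#' @export
default_jrandom_table <- function() {
  read_jrandom_table(system.file("extdata", "jrandom_base_hn_ha.tsv",
                                 package = "nmrtitr", mustWork = TRUE))
}

#' Read a random-coil J base table from TSV (columns `aa`, `j_hz`)
#' @param path TSV path.
#' @return Named numeric vector (one-letter code -> Hz).
#' @export
read_jrandom_table <- function(path) {
  df <- read_checked_tsv(path, numeric_cols = "j_hz",
                         character_cols = "aa")
  missing <- setdiff(AA_STANDARD, df$aa)
  if (length(missing)) {
    stop(sprintf("J base table is missing amino acid(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  setNames(df$j_hz, df$aa)[AA_STANDARD]
}

#' Random-coil 3J(HN-HA) for residues, corrected by the preceding residue
#'
#' Returns the base random-coil coupling of each residue, shifted by a
#' configurable correction when the preceding residue carries an aromatic
#' side chain (F, Y, W, H), whose ring current perturbs the reference value.
#' The first residue of the chain has no predecessor and returns `NA`
#' (unresolved downstream); querying a proline is an error (no amide
#' proton).
#'
#' @param seq A [protein_sequence()].
#' @param positions Residue numbers (vectorised).
#' @param base_table Named numeric vector as from [default_jrandom_table()].
#' @param aromatic_correction_hz Correction added when the predecessor is
#'   aromatic (default -0.5 Hz; an assumption shipped as a parameter, not a
#'   literature constant).
#' @return Numeric vector of random-coil couplings in Hz (`NA` at the chain
#'   start).
#' @export
j_random_for <- function(seq, positions, base_table = default_jrandom_table(),
                         aromatic_correction_hz = -0.5) {
  stopifnot(inherits(seq, "protein_sequence"))
  positions <- as.integer(positions)
  aa <- aa_at(seq, positions)
  if (any(aa == "P")) {
    stop(sprintf("position %d is a proline: no amide proton, no 3J(HN-HA)",
                 positions[aa == "P"][1]), call. = FALSE)
  }
  first <- min(seq$positions)
  out <- as.numeric(base_table[aa])
  at_start <- positions == first
  prev_aa <- rep(NA_character_, length(positions))
  prev_aa[!at_start] <- aa_at(seq, positions[!at_start] - 1L)
  out[!at_start & prev_aa %in% AROMATIC_AA] <-
    out[!at_start & prev_aa %in% AROMATIC_AA] + aromatic_correction_hz
  out[at_start] <- NA_real_
  out
}

#' Classify a 3J(HN-HA) coupling into a secondary-structure band
#'
#' Band limits: 3-5 Hz alpha-helix, 6-8 Hz random coil, 8-11 Hz beta sheet.
#' Couplings in the gaps (below 3, between 5 and 6, above 11) are
#' `"unresolved"`. The coil and sheet bands share the value 8 Hz; the
#' boundary is assigned to coil so that the classification is total and
#' deterministic (configurable through `bands`).
#'
#' @param j_obs Coupling(s) in Hz (>= 0); `NA` maps to `"unresolved"`.
#' @param bands List with elements `helix`, `coil`, `sheet`, each
#'   `c(lo, hi)`. Helix and coil bands are closed; the sheet band is open at
#'   its lower edge (`lo < J <= hi`).
#' @return Character vector in `{"helix", "coil", "sheet", "unresolved"}`.
#' @examples
#' classify_band(c(4, 9.5, 5.5, 8))  # helix, sheet, unresolved, coil
#' @export
classify_band <- function(j_obs,
                          bands = list(helix = c(3, 5), coil = c(6, 8),
                                       sheet = c(8, 11))) {
  if (any(j_obs < 0, na.rm = TRUE)) {
    stop("couplings must be >= 0", call. = FALSE)
  }
  out <- rep("unresolved", length(j_obs))
  ok <- !is.na(j_obs)
  out[ok & j_obs >= bands$helix[1] & j_obs <= bands$helix[2]] <- "helix"
  out[ok & j_obs >= bands$coil[1] & j_obs <= bands$coil[2]] <- "coil"
  out[ok & j_obs > bands$sheet[1] & j_obs <= bands$sheet[2]] <- "sheet"
  out
}

#' Per-residue 3J(HN-HA) deviation profile
#'
#' Converts a doublet list into observed couplings, attaches the
#' predecessor-corrected random-coil reference, and reports the deviation
#' `j_obs - j_random` together with the band classification of `j_obs`.
#' Negative deviations flag helical propensity (this is ambiguous with PPII
#' structure, which shares the low-J regime); positive deviations flag beta
#' propensity. Non-proline residues of the sequence without a resolved
#' doublet are included with band `"unresolved"` -- in a titration an
#' unmeasurable splitting is itself evidence of helical structure, so it is
#' kept distinct from `J = 0`.
#'
#' @param doublets A [doublet_table()].
#' @param seq A [protein_sequence()].
#' @param base_table,aromatic_correction_hz See [j_random_for()].
#' @param bands See [classify_band()].
#' @return data.frame of class `jcoupling_profile` with columns `position`,
#'   `aa`, `j_obs`, `j_random`, `deviation`, `band` and attributes
#'   `condition` and `note` (the PPII ambiguity statement).
#' @export
deviation_profile <- function(doublets, seq,
                              base_table = default_jrandom_table(),
                              aromatic_correction_hz = -0.5,
                              bands = list(helix = c(3, 5), coil = c(6, 8),
                                           sheet = c(8, 11))) {
  stopifnot(inherits(doublets, "doublet_table"),
            inherits(seq, "protein_sequence"))
  field <- doublets$condition$field_mhz
  rec <- doublets$records
  check_positions_in_sequence(rec$position, seq, "doublet list")
  all_pos <- seq$positions[seq$aa != "P"]
  out <- data.frame(position = all_pos, aa = aa_at(seq, all_pos),
                    j_obs = NA_real_, j_random = NA_real_,
                    deviation = NA_real_, band = "unresolved",
                    stringsAsFactors = FALSE)
  if (nrow(rec)) {
    j_obs <- j_from_doublet(rec$h_ppm_low, rec$h_ppm_high, field)
    idx <- match(rec$position, out$position)
    if (anyNA(idx)) {
      stop(sprintf("doublet recorded for proline position %d",
                   rec$position[is.na(idx)][1]), call. = FALSE)
    }
    out$j_obs[idx] <- j_obs
    out$j_random[idx] <- j_random_for(seq, rec$position, base_table,
                                      aromatic_correction_hz)
    out$deviation[idx] <- out$j_obs[idx] - out$j_random[idx]
    out$band[idx] <- classify_band(j_obs, bands)
  }
  structure(out, condition = doublets$condition,
            note = paste("negative deviations indicate helical propensity",
                         "(ambiguous with PPII); unresolved splittings may",
                         "themselves reflect helical structure"),
            class = c("jcoupling_profile", "data.frame"))
}
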