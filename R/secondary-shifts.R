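#' Solvent weights for the blended random-coil baseline
#'
#' In a mixed DMSO-water sample the random-coil baseline is taken as a
#' weighted blend of the two single-solvent reference tables,
#' `p1 * C_ran,dmso + p2 * C_ran,aq` with `p1 + p2 = 1`. The default policy
#' equates the weights with the solvent volume fractions; the true relative
#' exposure of the chain to each solvent is generally unknown, so the policy
#' is pluggable (pass any function of the condition returning `c(p1, p2)`).
#'
#' @param condition An [condition()] object.
#' @return Named numeric vector `c(p1 = ..., p2 = ...)`.
#' @examples
#' solvent_weights(condition(0.9))  # c(p1 = 0.9, p2 = 0.1)
#' @export
solvent_weights <- function(condition) {
  stopifnot(inherits(condition, "nmr_condition"))
  c(p1 = condition$dmso_fraction, p2 = 1 - condition$dmso_fraction)
}

check_weights <- function(w) {
  if (length(w) != 2L || any(!is.finite(w)) || any(w < 0) || any(w > 1) ||
      abs(sum(w) - 1) > 1e-9) {
    stop("solvent weights must be two values in [0,1] summing to 1", call. = FALSE)
  }
  invisible(w)
}

#' Secondary Calpha chemical shifts against a blended baseline
#'
#' For every residue with a major-state Calpha assignment, computes
#' `delta_ca(i) = ca_obs(i) - (p1 * rc_dmso(aa_i) + p2 * rc_aq(aa_i))`.
#' Positive runs of `delta_ca` indicate alpha-helical propensity, negative
#' runs beta propensity. Residues without a Calpha record are absent from
#' the profile (never zero-filled).
#'
#' @param shifts A [shift_table()]; only major-state CA records are used.
#' @param rc_dmso,rc_aq [random_coil_table()] objects (default: the shipped
#'   tables).
#' @param weights Length-2 numeric `c(p1, p2)`; defaults to
#'   `weight_policy(shifts$condition)`.
#' @param weight_policy Function mapping a condition to weights; default
#'   [solvent_weights()].
#' @return A data.frame of class `secondary_shift_profile` with columns
#'   `position`, `aa`, `ca_obs`, `baseline`, `delta_ca` and attributes
#'   `condition`, `p1`, `p2`.
#' @export
delta_ca <- function(shifts, rc_dmso = NULL, rc_aq = NULL, weights = NULL,
                     weight_policy = solvent_weights) {
  stopifnot(inherits(shifts, "shift_table"))
  if (is.null(rc_dmso) || is.null(rc_aq)) {
    defaults <- default_random_coil_tables()
    rc_dmso <- rc_dmso %||% defaults$dmso
    rc_aq <- rc_aq %||% defaults$aqueous
  }
  if (is.null(weights)) weights <- weight_policy(shifts$condition)
  check_weights(weights)
  ca <- major_records(shifts, "CA")
  if (nrow(ca) && anyNA(ca$aa)) {
    stop("CA records lack amino-acid identities; supply a sequence when building the shift table",
         call. = FALSE)
  }
  known <- names(rc_dmso)
  bad <- which(!(ca$aa %in% known) | !(ca$aa %in% names(rc_aq)))
  if (length(bad)) {
    stop(sprintf("amino acid '%s' (position %d) missing from a random-coil table",
                 ca$aa[bad[1]], ca$position[bad[1]]), call. = FALSE)
  }
  baseline <- weights[1] * as.numeric(rc_dmso[ca$aa]) +
    weights[2] * as.numeric(rc_aq[ca$aa])
  out <- data.frame(position = ca$position, aa = ca$aa,
                    ca_obs = ca$shift_ppm, baseline = baseline,
                    delta_ca = ca$shift_ppm - baseline,
                    stringsAsFactors = FALSE)
  out <- out[order(out$position), ]
  rownames(out) <- NULL
  structure(out,
            condition = shifts$condition,
            p1 = unname(weights[1]), p2 = unname(weights[2]),
            class = c("secondary_shift_profile", "data.frame"))
}

#' Call contiguous structural-propensity segments from a delta-Calpha profile
#'
#' Flags residues whose secondary shift exceeds the significance threshold
#' (strictly: a residue sitting exactly at the threshold is not significant,
#' because the threshold is drawn at the uncertainty level of the shift
#' spread itself) and returns the maximal contiguous runs of consistently
#' signed significant residues. Missing residues and sub-threshold residues
#' break runs; runs shorter than `min_len` are dropped.
#'
#' @param profile A profile from [delta_ca()], or any data.frame with
#'   integer `position` and numeric `delta_ca` columns.
#' @param threshold_ppm Significance threshold in ppm (default 0.7, the
#'   typical uncertainty in the spread of Calpha shifts). Must be >= 0.
#' @param min_len Minimum run length (default 3: the shortest stretch that
#'   is more than a point).
#' @return data.frame of segment calls: `start`, `end`, `length`, `label`
#'   (`"helix-propensity"` or `"sheet-propensity"`), `mean_delta`.
#' @export
call_propensity_segments <- function(profile, threshold_ppm = 0.7,
                                     min_len = 3L) {
  if (!is.numeric(threshold_ppm) || is.na(threshold_ppm) || threshold_ppm < 0) {
    stop("threshold_ppm must be a non-negative number", call. = FALSE)
  }
  min_len <- max(1L, as.integer(min_len))
  pos <- as.integer(profile$position)
  d <- as.numeric(profile$delta_ca)
  cls <- integer(length(d))
  cls[d > threshold_ppm] <- 1L
  cls[d < -threshold_ppm] <- -1L
  runs <- classified_runs(pos, cls, min_len = min_len)
  if (!nrow(runs)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), label = character(0),
                      mean_delta = numeric(0), stringsAsFactors = FALSE))
  }
  runs$label <- ifelse(runs$class > 0, "helix-propensity", "sheet-propensity")
  runs$mean_delta <- vapply(seq_len(nrow(runs)), function(i) {
    mean(d[pos >= runs$start[i] & pos <= runs$end[i]])
  }, numeric(1))
  runs[, c("start", "end", "length", "label", "mean_delta")]
}
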