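#' Parameters shared by the full analysis pipeline
#'
#' One declarative bundle holding every stage's tunable, with the
#' documented defaults: the 0.7 ppm secondary-shift significance threshold,
#' minimum run lengths of 3 residues, a robust z-score of 1 for exchange
#' flagging, a 3-residue flank window for nucleation calls, and the
#' 7 +/- 1 ppm proline decision band.
#'
#' @param threshold_ppm Secondary-shift significance threshold (ppm).
#' @param min_len Minimum propensity-segment length (residues).
#' @param k_sigma Robust z-score multiplier for exchange flagging.
#' @param exchange_min_len Minimum exchange-segment length (residues).
#' @param flank_window Maximum flank gap for nucleation calls (residues).
#' @param boundary_ppm,margin_ppm Proline isomer decision band (ppm).
#' @param aromatic_correction_hz Predecessor correction for random-coil J.
#' @param weight_policy Function mapping a condition to solvent weights.
#' @return Named list of class `pipeline_params`. Unknown arguments are an
#'   error (there are no silently ignored knobs).
#' @export
pipeline_params <- function(threshold_ppm = 0.7, min_len = 3L, k_sigma = 1,
                            exchange_min_len = 3L, flank_window = 3L,
                            boundary_ppm = 7, margin_ppm = 1,
                            aromatic_correction_hz = -0.5,
                            weight_policy = solvent_weights) {
  structure(as.list(environment()), class = "pipeline_params")
}

#' Run the full titration analysis pipeline
#'
#' Wires every stage over a shared sequence and condition ladder: presence
#' bookkeeping from the assigned shift tables, per-condition secondary
#' Calpha shifts and propensity segments, J-coupling deviation profiles
#' where doublets exist, per-condition R2 fits and exchange segments,
#' proline isomer calls at the most denaturing condition, disappearance
#' events, the nucleation call, and the combined hierarchy report.
#' Deterministic for deterministic inputs.
#'
#' @param obs A list with elements `seq`, `conditions`, `shift_tables`,
#'   and optionally `doublets` and `relaxation` (e.g. from
#'   [emit_observables()] or [read_observables()]).
#' @param params A [pipeline_params()] bundle.
#' @param rc_tables List with `dmso` and `aqueous` [random_coil_table()]s.
#' @param jrandom_table Named base-J vector (see [default_jrandom_table()]).
#' @param fit_relaxation Conditions (indices into the ladder) at which to
#'   fit R2 profiles; default all conditions with relaxation data. The
#'   first condition is always fitted when data exist, since the
#'   nucleation call needs its exchange segments.
#' @return A list of class `titration_analysis` with elements `presence`,
#'   `secondary` (per-condition profiles and segments), `jcoupling`, `r2`,
#'   `exchange`, `proline`, `events`, `nucleation`, `report`, `params`.
#' @export
run_pipeline <- function(obs, params = pipeline_params(),
                         rc_tables = default_random_coil_tables(),
                         jrandom_table = default_jrandom_table(),
                         fit_relaxation = NULL) {
  stopifnot(inherits(params, "pipeline_params"))
  seq <- obs$seq
  ladder <- obs$conditions
  labels <- ladder_labels(ladder)
  presence <- build_presence(obs$shift_tables, seq)
  # secondary shifts + propensity segments, per condition
  secondary <- lapply(obs$shift_tables, function(st) {
    profile <- delta_ca(st, rc_tables$dmso, rc_tables$aqueous,
                        weight_policy = params$weight_policy)
    list(profile = profile,
         segments = call_propensity_segments(profile,
                                             threshold_ppm = params$threshold_ppm,
                                             min_len = params$min_len))
  })
  # J couplings where doublet lists exist
  jcoupling <- lapply(obs$doublets %||% list(), function(dt) {
    deviation_profile(dt, seq, base_table = jrandom_table,
                      aromatic_correction_hz = params$aromatic_correction_hz)
  })
  # R2 fits + exchange segments
  r2 <- list(); exchange <- list()
  relax <- obs$relaxation %||% list()
  if (length(relax)) {
    fit_idx <- fit_relaxation %||% seq_along(relax)
    fit_idx <- sort(unique(c(1L, fit_idx)))
    fit_idx <- fit_idx[fit_idx <= length(relax)]
    for (i in fit_idx) {
      prof <- fit_r2_profile(relax[[i]])
      r2[[names(relax)[i]]] <- prof
      if (sum(prof$status == "ok") >= 5L) {
        exchange[[names(relax)[i]]] <-
          detect_exchange_segments(prof, k_sigma = params$k_sigma,
                                   min_len = params$exchange_min_len,
                                   transparent = prolines(seq))
      }
    }
  }
  # proline isomers at the most denaturing condition
  proline <- if (length(obs$shift_tables)) {
    proline_calls(obs$shift_tables[[1]], seq,
                  boundary_ppm = params$boundary_ppm,
                  margin_ppm = params$margin_ppm)
  } else NULL
  events <- if (ncol(presence$states) >= 2L) disappearance_events(presence)
            else NULL
  first_label <- labels[1]
  nucleation <- if (!is.null(exchange[[first_label]])) {
    find_nucleation(presence, exchange[[first_label]],
                    flank_window = params$flank_window)
  } else NULL
  report <- hierarchy_report(presence, events = events,
                             nucleation = nucleation,
                             propensity = lapply(secondary, `[[`, "segments"),
                             exchange = exchange)
  structure(list(presence = presence, secondary = secondary,
                 jcoupling = jcoupling, r2 = r2, exchange = exchange,
                 proline = proline, events = events, nucleation = nucleation,
                 report = report, params = params),
            class = "titration_analysis")
}

#' @export
print.titration_analysis <- function(x, ...) {
  cat("<titration_analysis>\n")
  print(x$report)
  invisible(x)
}
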