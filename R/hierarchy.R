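#' Build a presence matrix from per-condition shift tables
#'
#' A residue is present at a condition iff it carries a major-state amide
#' proton (H) assignment there; a residue that additionally carries a
#' minor-state H record is marked `"minor_duplicate"` (present, with a
#' slow-exchange duplicate peak). Prolines are always `"absent"`.
#'
#' @param shift_tables Named list of [shift_table()] objects, one per
#'   condition, ordered by strictly decreasing DMSO fraction.
#' @param seq A [protein_sequence()].
#' @return A [presence_matrix()] covering every residue of `seq`.
#' @export
build_presence <- function(shift_tables, seq) {
  stopifnot(inherits(seq, "protein_sequence"), length(shift_tables) >= 1L)
  conds <- lapply(shift_tables, function(st) {
    stopifnot(inherits(st, "shift_table"))
    st$condition
  })
  fr <- vapply(conds, function(c) c$dmso_fraction, numeric(1))
  if (length(fr) > 1L && any(diff(fr) >= 0)) {
    stop("shift tables must be ordered by strictly decreasing dmso_fraction",
         call. = FALSE)
  }
  ladder <- condition_ladder(
    dmso_fractions = fr,
    temperature_c = vapply(conds, function(c) c$temperature_c, numeric(1)),
    field_mhz = vapply(conds, function(c) c$field_mhz, numeric(1)),
    labels = vapply(conds, function(c) c$label, character(1))
  )
  pos <- seq$positions
  pro <- prolines(seq)
  states <- matrix("absent", nrow = length(pos), ncol = length(ladder),
                   dimnames = list(pos, ladder_labels(ladder)))
  for (k in seq_along(shift_tables)) {
    rec <- shift_tables[[k]]$records
    check_positions_in_sequence(rec$position, seq, "shift table")
    major_h <- unique(rec$position[rec$nucleus == "H" & rec$state == "major"])
    minor_h <- unique(rec$position[rec$nucleus == "H" & rec$state == "minor"])
    if (length(bad <- intersect(major_h, pro))) {
      stop(sprintf("amide record for proline position %d", bad[1]),
           call. = FALSE)
    }
    states[match(major_h, pos), k] <- "present"
    dup <- intersect(major_h, minor_h)
    states[match(dup, pos), k] <- "minor_duplicate"
  }
  presence_matrix(ladder, states, proline_mask = pro)
}

#' Audit a presence matrix for non-monotone observability
#'
#' In a clean titration a residue is present at high denaturant, vanishes
#' once when its segment joins the assembly, and stays absent. Residues
#' that reappear at a lower denaturant after an absence are physically
#' admissible (transient exposure, assignment gaps) but worth surfacing;
#' they are flagged here and retained everywhere else.
#'
#' @param pm A [presence_matrix()].
#' @return data.frame with columns `position` and `pattern` (the
#'   present/absent string across conditions), one row per flagged residue.
#' @export
presence_consistency <- function(pm) {
  stopifnot(inherits(pm, "presence_matrix"))
  present <- is_present_state(pm$states)
  flagged <- apply(present, 1, function(row) {
    any(diff(as.integer(row)) > 0)  # absent -> present at lower DMSO
  })
  flagged[pm$positions %in% pm$proline_mask] <- FALSE
  data.frame(
    position = pm$positions[flagged],
    pattern = apply(pm$states[flagged, , drop = FALSE], 1, paste,
                    collapse = ";"),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Segment-wise peak-disappearance events across the titration
#'
#' For each adjacent condition pair of the ladder, finds the maximal
#' contiguous runs of residues newly absent at the lower DMSO fraction.
#' Each run is one incorporation event: a chain segment whose peaks vanish
#' because it joined the NMR-invisible assembly. Prolines are transparent
#' for run contiguity. Events are ordered by condition, then start
#' position.
#'
#' @param pm A [presence_matrix()] over at least 2 conditions.
#' @return data.frame with columns `condition_index`, `condition_label`,
#'   `dmso_fraction`, `start`, `end`, `length` (non-proline residues in the
#'   run).
#' @export
disappearance_events <- function(pm) {
  stopifnot(inherits(pm, "presence_matrix"))
  K <- ncol(pm$states)
  if (K < 2L) stop("at least 2 conditions are required", call. = FALSE)
  present <- is_present_state(pm$states)
  tab <- conditions_table(pm$conditions)
  out <- list()
  for (k in 2:K) {
    newly <- present[, k - 1L] & !present[, k]
    runs <- flagged_runs(pm$positions, newly, min_len = 1L,
                         transparent = pm$proline_mask)
    if (nrow(runs)) {
      runs$condition_index <- k
      runs$condition_label <- tab$label[k]
      runs$dmso_fraction <- tab$dmso_fraction[k]
      out[[length(out) + 1L]] <- runs
    }
  }
  if (!length(out)) {
    return(data.frame(condition_index = integer(0),
                      condition_label = character(0),
                      dmso_fraction = numeric(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  out <- out[order(out$condition_index, out$start),
             c("condition_index", "condition_label", "dmso_fraction",
               "start", "end", "length")]
  rownames(out) <- NULL
  out
}

# maximal runs of absent non-proline residues at one condition
absent_runs_at <- function(pm, condition_index = 1L) {
  observable <- !(pm$positions %in% pm$proline_mask)
  absent <- !is_present_state(pm$states[, condition_index]) & observable
  flagged_runs(pm$positions[observable], absent[observable],
               min_len = 1L, transparent = pm$proline_mask)
}

#' Locate nucleation candidates at the most denaturing condition
#'
#' A segment already missing from the spectra at the highest denaturant
#' concentration, flanked on both sides by detected conformational-exchange
#' segments, is the signature of a folding/association nucleation site: its
#' neighbours exchange slowly because the segment between them is already
#' committed to the assembly. Every maximal absent run with an exchange
#' segment within `flank_window` residues on both sides is returned; runs
#' touching a chain terminus are excluded (one flank is impossible there).
#'
#' @param pm A [presence_matrix()].
#' @param exchange Segment calls from [detect_exchange_segments()] computed
#'   at the same highest-denaturant condition (data.frame with `start`,
#'   `end`).
#' @param flank_window Maximum residue gap between the absent run and each
#'   flanking exchange segment (default 3; directly adjacent flanks have
#'   gap 1).
#' @return data.frame with columns `start`, `end`, `length`,
#'   `left_flank_start`, `left_flank_end`, `right_flank_start`,
#'   `right_flank_end`, `condition_label`.
#' @export
find_nucleation <- function(pm, exchange, flank_window = 3L) {
  stopifnot(inherits(pm, "presence_matrix"))
  flank_window <- as.integer(flank_window)
  runs <- absent_runs_at(pm, 1L)
  label <- colnames(pm$states)[1]
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0),
                      left_flank_start = integer(0),
                      left_flank_end = integer(0),
                      right_flank_start = integer(0),
                      right_flank_end = integer(0),
                      condition_label = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(runs) || is.null(exchange) || !nrow(exchange)) return(empty)
  observable <- pm$positions[!(pm$positions %in% pm$proline_mask)]
  first_obs <- min(observable)
  last_obs <- max(observable)
  out <- list()
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]; e <- runs$end[i]
    if (s <= first_obs || e >= last_obs) next  # terminal run: one flank impossible
    left <- exchange[exchange$end < s & s - exchange$end <= flank_window, ,
                     drop = FALSE]
    right <- exchange[exchange$start > e & exchange$start - e <= flank_window, ,
                      drop = FALSE]
    if (!nrow(left) || !nrow(right)) next
    lf <- left[which.max(left$end), ]
    rf <- right[which.min(right$start), ]
    out[[length(out) + 1L]] <- data.frame(
      start = s, end = e, length = runs$length[i],
      left_flank_start = lf$start, left_flank_end = lf$end,
      right_flank_start = rf$start, right_flank_end = rf$end,
      condition_label = label, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Assemble the full titration hierarchy report
#'
#' Combines the presence matrix, disappearance events, nucleation calls and
#' any per-condition propensity/exchange segment calls into one structured
#' report: per condition, the newly incorporated segments, the segments
#' still flexible (observable) and the structural annotations; globally,
#' the nucleation call, the incorporation order and an N-half/C-half
#' packing summary (fraction of each chain half already incorporated at
#' each condition).
#'
#' @param pm A [presence_matrix()].
#' @param events Result of [disappearance_events()] (computed if `NULL`).
#' @param nucleation Result of [find_nucleation()] (may be `NULL`).
#' @param propensity Optional named list (by condition label) of
#'   [call_propensity_segments()] results.
#' @param exchange Optional named list (by condition label) of
#'   [detect_exchange_segments()] results.
#' @return A list of class `hierarchy_report`.
#' @export
hierarchy_report <- function(pm, events = NULL, nucleation = NULL,
                             propensity = NULL, exchange = NULL) {
  stopifnot(inherits(pm, "presence_matrix"))
  if (is.null(events) && ncol(pm$states) >= 2L) events <- disappearance_events(pm)
  tab <- conditions_table(pm$conditions)
  observable <- pm$positions[!(pm$positions %in% pm$proline_mask)]
  mid <- floor((min(pm$positions) + max(pm$positions)) / 2)
  n_half <- observable[observable <= mid]
  c_half <- observable[observable > mid]
  per_condition <- lapply(seq_len(nrow(tab)), function(k) {
    present <- is_present_state(pm$states[, k])
    flex <- flagged_runs(pm$positions, present, min_len = 1L,
                         transparent = pm$proline_mask)
    absent_n <- sum(!present[match(n_half, pm$positions)])
    absent_c <- sum(!present[match(c_half, pm$positions)])
    list(
      condition_label = tab$label[k],
      dmso_fraction = tab$dmso_fraction[k],
      n_present = sum(present),
      newly_incorporated = if (!is.null(events))
        events[events$condition_index == k, , drop = FALSE]
        else NULL,
      flexible_segments = flex,
      propensity_segments = propensity[[tab$label[k]]],
      exchange_segments = exchange[[tab$label[k]]],
      fraction_incorporated_n_half = absent_n / length(n_half),
      fraction_incorporated_c_half = absent_c / length(c_half)
    )
  })
  names(per_condition) <- tab$label
  structure(list(
    conditions = tab,
    per_condition = per_condition,
    incorporation_order = events,
    nucleation = nucleation,
    consistency = presence_consistency(pm)
  ), class = "hierarchy_report")
}

#' @export
print.hierarchy_report <- function(x, ...) {
  cat("<hierarchy_report>\n")
  for (pc in x$per_condition) {
    seg <- pc$newly_incorporated
    segs <- if (!is.null(seg) && nrow(seg)) {
      paste(sprintf("[%d-%d]", seg$start, seg$end), collapse = " ")
    } else "-"
    cat(sprintf("  %s (%.0f%% DMSO): %3d present; newly incorporated: %s\n",
                pc$condition_label, 100 * pc$dmso_fraction, pc$n_present, segs))
  }
  if (!is.null(x$nucleation) && nrow(x$nucleation)) {
    cat(sprintf("  nucleation candidate(s): %s\n",
                paste(sprintf("[%d-%d]", x$nucleation$start,
                              x$nucleation$end), collapse = " ")))
  } else {
    cat("  nucleation candidate(s): none\n")
  }
  if (nrow(x$consistency)) {
    cat(sprintf("  non-monotone presence flagged at %d residue(s): %s\n",
                nrow(x$consistency),
                paste(x$consistency$position, collapse = ", ")))
  }
  invisible(x)
}

#' Serialise a hierarchy report to JSON
#' @param report A [hierarchy_report()].
#' @param path Output path.
#' @export
write_hierarchy_report <- function(report, path) {
  stopifnot(inherits(report, "hierarchy_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
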