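#' Cis/trans classification of X-Pro peptide bonds
#'
#' The proline Cbeta-Cgamma chemical-shift difference separates the two
#' peptide-bond isomers: around 5 ppm for trans, markedly larger (about
#' 9-10 ppm) for cis. The decision boundary defaults to 7 ppm with a
#' +/- 1 ppm ambiguity band: `trans` when `delta < boundary - margin`,
#' `cis` when `delta > boundary + margin`, `ambiguous` inside the closed
#' band. Both the boundary and the margin are configurable.
#'
#' @param cb_ppm,cg_ppm Proline Cbeta and Cgamma shifts in ppm (vectorised).
#' @param boundary_ppm Centre of the decision band (default 7).
#' @param margin_ppm Half-width of the ambiguity band (default 1, >= 0).
#' @return data.frame with columns `delta_bg_ppm` and `isomer`
#'   (`"trans"`, `"cis"` or `"ambiguous"`).
#' @examples
#' classify_proline(31.8, 26.8)$isomer  # "trans" (delta = 5 ppm)
#' @export
classify_proline <- function(cb_ppm, cg_ppm, boundary_ppm = 7,
                             margin_ppm = 1) {
  if (!is.finite(boundary_ppm) || boundary_ppm <= 0) {
    stop("boundary_ppm must be > 0", call. = FALSE)
  }
  if (!is.finite(margin_ppm) || margin_ppm < 0) {
    stop("margin_ppm must be >= 0", call. = FALSE)
  }
  delta <- as.numeric(cb_ppm) - as.numeric(cg_ppm)
  isomer <- rep("ambiguous", length(delta))
  isomer[delta < boundary_ppm - margin_ppm] <- "trans"
  isomer[delta > boundary_ppm + margin_ppm] <- "cis"
  data.frame(delta_bg_ppm = delta, isomer = isomer, stringsAsFactors = FALSE)
}

#' Isomer calls for every proline in a shift table
#'
#' Looks up Cbeta and Cgamma records (major and minor state separately) for
#' each proline of the sequence and classifies the peptide bond. A proline
#' with one of the two carbons assigned but not the other is an error
#' naming the position and missing nucleus; prolines with neither are
#' skipped.
#'
#' @param shifts A [shift_table()].
#' @param seq A [protein_sequence()].
#' @param boundary_ppm,margin_ppm See [classify_proline()].
#' @return data.frame with columns `position`, `state`, `cb_ppm`, `cg_ppm`,
#'   `delta_bg_ppm`, `isomer`.
#' @export
proline_calls <- function(shifts, seq, boundary_ppm = 7, margin_ppm = 1) {
  stopifnot(inherits(shifts, "shift_table"), inherits(seq, "protein_sequence"))
  pro <- prolines(seq)
  rec <- shifts$records
  rows <- list()
  for (p in pro) {
    for (st in c("major", "minor")) {
      cb <- rec$shift_ppm[rec$position == p & rec$nucleus == "CB" &
                            rec$state == st]
      cg <- rec$shift_ppm[rec$position == p & rec$nucleus == "CG" &
                            rec$state == st]
      if (!length(cb) && !length(cg)) next
      if (!length(cb)) {
        stop(sprintf("proline %d (%s state): CB record missing", p, st),
             call. = FALSE)
      }
      if (!length(cg)) {
        stop(sprintf("proline %d (%s state): CG record missing", p, st),
             call. = FALSE)
      }
      cls <- classify_proline(cb, cg, boundary_ppm, margin_ppm)
      rows[[length(rows) + 1L]] <-
        data.frame(position = p, state = st, cb_ppm = cb, cg_ppm = cg,
                   delta_bg_ppm = cls$delta_bg_ppm, isomer = cls$isomer,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(position = integer(0), state = character(0),
                      cb_ppm = numeric(0), cg_ppm = numeric(0),
                      delta_bg_ppm = numeric(0), isomer = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
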