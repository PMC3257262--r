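#' CPMG intensity decay series for one condition
#'
#' Per-residue peak intensities as a function of the CPMG relaxation delay.
#' Delays are stored in seconds.
#'
#' @param condition An [condition()] object.
#' @param delays_s Numeric vector of at least 3 positive, strictly
#'   increasing delays in seconds.
#' @param intensities Numeric matrix with one row per residue (rownames are
#'   residue numbers) and one column per delay, or a named list of numeric
#'   vectors.
#' @param intensity_errors Optional matrix/list of per-point errors with the
#'   same shape.
#' @return An object of class `relaxation_series`.
#' @export
relaxation_series <- function(condition, delays_s, intensities,
                              intensity_errors = NULL) {
  stopifnot(inherits(condition, "nmr_condition"))
  delays_s <- as.numeric(delays_s)
  if (length(delays_s) < 3L) {
    stop("at least 3 CPMG delays are required", call. = FALSE)
  }
  if (any(delays_s <= 0) || any(diff(delays_s) <= 0)) {
    stop("delays must be positive and strictly increasing", call. = FALSE)
  }
  to_matrix <- function(x, what) {
    if (is.list(x)) {
      lens <- lengths(x)
      if (any(lens != length(delays_s))) {
        stop(sprintf("%s length mismatch with delays at position %s",
                     what, names(x)[lens != length(delays_s)][1]),
             call. = FALSE)
      }
      x <- do.call(rbind, x)
    }
    x <- as.matrix(x)
    if (ncol(x) != length(delays_s)) {
      stop(sprintf("%s must have one column per delay", what), call. = FALSE)
    }
    if (is.null(rownames(x))) {
      stop(sprintf("%s must carry residue numbers as rownames/names", what),
           call. = FALSE)
    }
    x[order(as.integer(rownames(x))), , drop = FALSE]
  }
  intensities <- to_matrix(intensities, "intensities")
  if (!is.null(intensity_errors)) {
    intensity_errors <- to_matrix(intensity_errors, "intensity_errors")
    if (!identical(dim(intensity_errors), dim(intensities))) {
      stop("intensity_errors shape must match intensities", call. = FALSE)
    }
  }
  structure(list(condition = condition, delays_s = delays_s,
                 intensities = intensities,
                 intensity_errors = intensity_errors),
            class = "relaxation_series")
}

#' @export
print.relaxation_series <- function(x, ...) {
  cat(sprintf("<relaxation_series> %s: %d residues x %d delays (%.0f-%.0f ms)\n",
              x$condition$label, nrow(x$intensities), length(x$delays_s),
              1000 * min(x$delays_s), 1000 * max(x$delays_s)))
  invisible(x)
}

series_positions <- function(series) as.integer(rownames(series$intensities))

#' The standard 10-point CPMG delay schedule
#'
#' Delays of 10, 30, 50, ..., 190 ms, returned in seconds. Storing the
#' canonical schedule once, already converted, avoids ms/s unit mistakes.
#'
#' @return Numeric vector of 10 delays in seconds.
#' @export
default_cpmg_delays <- function() {
  seq(10, 190, by = 20) / 1000
}

#' Write relaxation series to one long TSV
#'
#' Columns: `condition_label`, `position`, `delay_s`, `intensity`,
#' `intensity_err` (NA when no errors were recorded).
#'
#' @param series_list List of [relaxation_series()] objects.
#' @param path Output path.
#' @export
write_relaxation_tables <- function(series_list, path) {
  if (inherits(series_list, "relaxation_series")) series_list <- list(series_list)
  rows <- do.call(rbind, lapply(series_list, function(s) {
    pos <- series_positions(s)
    err <- s$intensity_errors
    do.call(rbind, lapply(seq_along(pos), function(i) {
      data.frame(condition_label = s$condition$label,
                 position = pos[i],
                 delay_s = s$delays_s,
                 intensity = as.numeric(s$intensities[i, ]),
                 intensity_err = if (is.null(err)) NA_real_
                                 else as.numeric(err[i, ]),
                 stringsAsFactors = FALSE)
    }))
  }))
  write_tsv_raw(rows, path)
}

#' Read relaxation series from one long TSV
#' @param path TSV written by [write_relaxation_tables()].
#' @param ladder A [condition_ladder()].
#' @param seq Optional [protein_sequence()] for position validation.
#' @return Named list of [relaxation_series()] objects in ladder order.
#' @export
read_relaxation_tables <- function(path, ladder, seq = NULL) {
  df <- read_checked_tsv(path,
                         numeric_cols = c("delay_s", "intensity",
                                          "intensity_err"),
                         integer_cols = "position",
                         character_cols = "condition_label")
  check_positions_in_sequence(df$position, seq, "relaxation table", path)
  parts <- split_by_condition(df, ladder, path)
  labels <- ladder_labels(ladder)
  out <- lapply(names(parts), function(l) {
    d <- parts[[l]]
    delays <- sort(unique(d$delay_s))
    pos <- sort(unique(d$position))
    mat <- matrix(NA_real_, nrow = length(pos), ncol = length(delays),
                  dimnames = list(pos, NULL))
    emat <- mat
    for (i in seq_along(pos)) {
      di <- d[d$position == pos[i], , drop = FALSE]
      if (nrow(di) != length(delays) ||
          !isTRUE(all.equal(sort(di$delay_s), delays))) {
        stop(sprintf("position %d lacks intensities for every delay in '%s'",
                     pos[i], path), call. = FALSE)
      }
      di <- di[order(di$delay_s), , drop = FALSE]
      mat[i, ] <- di$intensity
      emat[i, ] <- di$intensity_err
    }
    if (all(is.na(emat))) emat <- NULL
    relaxation_series(ladder[[match(l, labels)]], delays, mat, emat)
  })
  names(out) <- names(parts)
  out
}
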