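#' Assigned chemical-shift table for one condition
#'
#' One record per (residue, nucleus, state). Minor-state records are
#' first-class duplicates from slow-exchange conformers and are never merged
#' with the major state.
#'
#' @param condition An [condition()] object.
#' @param records data.frame with columns `position` (integer), `aa`
#'   (one-letter code, optional when `seq` is given), `nucleus` (one of CA,
#'   CB, CG, N, H, HA, C), `shift_ppm` (finite numeric) and `state`
#'   (`"major"` or `"minor"`, default major).
#' @param seq Optional [protein_sequence()] used to validate positions and
#'   fill in missing `aa`.
#' @return An object of class `shift_table` with fields `condition` and
#'   `records`.
#' @export
shift_table <- function(condition, records, seq = NULL) {
  stopifnot(inherits(condition, "nmr_condition"))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(records$state)) records$state <- "major"
  needed <- c("position", "nucleus", "shift_ppm", "state")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop(sprintf("shift records lack column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  records$position <- as.integer(records$position)
  records$nucleus <- as.character(records$nucleus)
  records$state <- as.character(records$state)
  bad_nuc <- setdiff(unique(records$nucleus), SHIFT_NUCLEI)
  if (length(bad_nuc)) {
    stop(sprintf("unknown nucleus code(s): %s", paste(bad_nuc, collapse = ", ")),
         call. = FALSE)
  }
  bad_state <- setdiff(unique(records$state), c("major", "minor"))
  if (length(bad_state)) {
    stop(sprintf("state must be 'major' or 'minor', got: %s",
                 paste(bad_state, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(records$shift_ppm))) {
    stop("all shift_ppm values must be finite", call. = FALSE)
  }
  key <- paste(records$position, records$nucleus, records$state)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop(sprintf("duplicate shift record for (position, nucleus, state) = (%s)",
                 gsub(" ", ", ", d)), call. = FALSE)
  }
  check_positions_in_sequence(records$position, seq, "shift table")
  if (!is.null(seq)) {
    filled <- aa_at(seq, records$position)
    if (is.null(records$aa)) {
      records$aa <- filled
    } else if (any(records$aa != filled)) {
      bad <- records$position[records$aa != filled][1]
      stop(sprintf("aa column disagrees with sequence at position %d", bad),
           call. = FALSE)
    }
  }
  if (is.null(records$aa)) records$aa <- NA_character_
  records <- records[order(records$position, records$nucleus, records$state),
                     c("position", "aa", "nucleus", "shift_ppm", "state")]
  rownames(records) <- NULL
  structure(list(condition = condition, records = records),
            class = "shift_table")
}

#' @export
print.shift_table <- function(x, ...) {
  cat(sprintf("<shift_table> %s: %d records, %d residues (%d minor-state)\n",
              x$condition$label, nrow(x$records),
              length(unique(x$records$position)),
              sum(x$records$state == "minor")))
  invisible(x)
}

#' Write per-condition shift tables to one TSV
#'
#' Columns: `condition_label`, `position`, `aa`, `nucleus`, `shift_ppm`,
#' `state`.
#'
#' @param tables A list of [shift_table()] objects.
#' @param path Output path.
#' @export
write_shift_tables <- function(tables, path) {
  if (inherits(tables, "shift_table")) tables <- list(tables)
  rows <- do.call(rbind, lapply(tables, function(st) {
    cbind(data.frame(condition_label = st$condition$label,
                     stringsAsFactors = FALSE),
          st$records)
  }))
  write_tsv_raw(rows, path)
}

#' Read per-condition shift tables from one TSV
#'
#' @param path TSV written by [write_shift_tables()].
#' @param ladder A [condition_ladder()] providing condition metadata; only
#'   labels appearing in the file are returned, in ladder order.
#' @param seq Optional [protein_sequence()]; rows referencing positions
#'   outside it are rejected.
#' @return Named list of [shift_table()] objects.
#' @export
read_shift_tables <- function(path, ladder, seq = NULL) {
  df <- read_checked_tsv(path,
                         numeric_cols = "shift_ppm",
                         integer_cols = "position",
                         character_cols = c("condition_label", "aa",
                                            "nucleus", "state"))
  parts <- split_by_condition(df, ladder, path)
  labels <- ladder_labels(ladder)
  out <- lapply(names(parts), function(l) {
    cond <- ladder[[match(l, labels)]]
    rec <- parts[[l]][, c("position", "aa", "nucleus", "shift_ppm", "state")]
    shift_table(cond, rec, seq = seq)
  })
  names(out) <- names(parts)
  out
}

# major-state records for one nucleus, as position -> shift
major_records <- function(st, nucleus) {
  r <- st$records
  r[r$nucleus == nucleus & r$state == "major", , drop = FALSE]
}
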