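#' Resolved HSQC doublet peak list for one condition
#'
#' Each row records the two resolved proton components of an amide cross
#' peak; their separation in ppm times the proton frequency gives the
#' 3J(HN-HA) coupling in Hz.
#'
#' @param condition An [condition()] object.
#' @param records data.frame with columns `position`, `h_ppm_low`,
#'   `h_ppm_high` (with `h_ppm_high >= h_ppm_low`) and `n_ppm`.
#' @return An object of class `doublet_table`.
#' @export
doublet_table <- function(condition, records) {
  stopifnot(inherits(condition, "nmr_condition"))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  needed <- c("position", "h_ppm_low", "h_ppm_high", "n_ppm")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop(sprintf("doublet records lack column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  records$position <- as.integer(records$position)
  if (any(records$h_ppm_high < records$h_ppm_low)) {
    bad <- records$position[records$h_ppm_high < records$h_ppm_low][1]
    stop(sprintf("h_ppm_high < h_ppm_low at position %d", bad), call. = FALSE)
  }
  if (anyDuplicated(records$position)) {
    stop("duplicate doublet for a position", call. = FALSE)
  }
  records <- records[order(records$position), needed]
  rownames(records) <- NULL
  structure(list(condition = condition, records = records),
            class = "doublet_table")
}

#' @export
print.doublet_table <- function(x, ...) {
  cat(sprintf("<doublet_table> %s: %d resolved doublets\n",
              x$condition$label, nrow(x$records)))
  invisible(x)
}

#' Write doublet lists to one TSV
#' @param tables List of [doublet_table()] objects.
#' @param path Output path.
#' @export
write_doublet_tables <- function(tables, path) {
  if (inherits(tables, "doublet_table")) tables <- list(tables)
  rows <- do.call(rbind, lapply(tables, function(dt) {
    cbind(data.frame(condition_label = dt$condition$label,
                     stringsAsFactors = FALSE),
          dt$records)
  }))
  write_tsv_raw(rows, path)
}

#' Read doublet lists from one TSV
#' @param path TSV written by [write_doublet_tables()].
#' @param ladder A [condition_ladder()].
#' @param seq Optional [protein_sequence()] for position validation.
#' @return Named list of [doublet_table()] objects in ladder order.
#' @export
read_doublet_tables <- function(path, ladder, seq = NULL) {
  df <- read_checked_tsv(path,
                         numeric_cols = c("h_ppm_low", "h_ppm_high", "n_ppm"),
                         integer_cols = "position",
                         character_cols = "condition_label")
  check_positions_in_sequence(df$position, seq, "doublet list", path)
  parts <- split_by_condition(df, ladder, path)
  labels <- ladder_labels(ladder)
  out <- lapply(names(parts), function(l) {
    doublet_table(ladder[[match(l, labels)]],
                  parts[[l]][, c("position", "h_ppm_low", "h_ppm_high", "n_ppm")])
  })
  names(out) <- names(parts)
  out
}
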