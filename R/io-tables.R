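# Delimited-text table plumbing. All tabular observables travel as TSV with a
# documented header; numeric cells are written with 17 significant digits so a
# write -> read -> write cycle is lossless and byte-stable.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_tsv_raw <- function(df, path, append = FALSE) {
  df <- as.data.frame(df)
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- fmt_num(df[[nm]])
  }
  write.table(df, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = !append, append = append)
  invisible(path)
}

# Read a TSV, check the header, and convert columns with row-numbered errors.
read_checked_tsv <- function(path, numeric_cols = character(0),
                             integer_cols = character(0),
                             character_cols = character(0),
                             optional_cols = character(0)) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: '%s'", path), call. = FALSE)
  }
  raw <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = character(0))
  required <- setdiff(c(numeric_cols, integer_cols, character_cols),
                      optional_cols)
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop(sprintf("'%s' is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  convert <- function(col, as_int) {
    v <- raw[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & v != "NA" & v != "")
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column '%s' of '%s' (data row %d)",
                   v[bad[1]], col, path, bad[1]), call. = FALSE)
    }
    num[v == ""] <- NA_real_
    if (as_int) as.integer(round(num)) else num
  }
  for (col in intersect(numeric_cols, names(raw))) raw[[col]] <- convert(col, FALSE)
  for (col in intersect(integer_cols, names(raw))) raw[[col]] <- convert(col, TRUE)
  raw
}

check_positions_in_sequence <- function(positions, seq, what, path = NULL) {
  if (is.null(seq)) return(invisible(TRUE))
  bad <- setdiff(unique(as.integer(positions)), seq$positions)
  if (length(bad)) {
    stop(sprintf("%s references position(s) outside the sequence: %s%s",
                 what, paste(sort(bad), collapse = ", "),
                 if (is.null(path)) "" else sprintf(" (in '%s')", path)),
         call. = FALSE)
  }
  invisible(TRUE)
}

# resolve condition labels in a long table against a ladder, preserving
# ladder order; unknown labels are an error
split_by_condition <- function(df, ladder, path) {
  labels <- ladder_labels(ladder)
  unknown <- setdiff(unique(df$condition_label), labels)
  if (length(unknown)) {
    stop(sprintf("'%s' contains condition label(s) not in the ladder: %s",
                 path, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  present <- labels[labels %in% df$condition_label]
  out <- lapply(present, function(l) df[df$condition_label == l, , drop = FALSE])
  names(out) <- present
  out
}
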