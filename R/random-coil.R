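#' Random-coil Calpha reference table
#'
#' A medium-specific lookup of random-coil Calpha chemical shifts for the 20
#' standard amino acids. The shipped defaults (see
#' [default_random_coil_tables()]) are editable starting points: the aqueous
#' values follow the classic short-peptide reference compilations
#' (Richarz-style), while the DMSO table is an approximate default (the
#' aprotic-solvent reference values differ systematically from water and
#' should be replaced by a lab's preferred compilation for quantitative
#' work). All segment-calling logic is validated against synthetic tables,
#' so no result in this package's test suite depends on these defaults.
#'
#' @param values Named numeric vector (names are one-letter codes) or a
#'   data.frame with columns `aa` and `shift_ppm`.
#' @param medium `"dmso"` or `"aqueous"`.
#' @param source Free-text provenance note.
#' @return Named numeric vector of class `random_coil_table` with
#'   attributes `medium` and `source`.
#' @export
random_coil_table <- function(values, medium = c("dmso", "aqueous"),
                              source = "") {
  medium <- match.arg(medium)
  if (is.data.frame(values)) {
    values <- setNames(as.numeric(values$shift_ppm), as.character(values$aa))
  }
  missing <- setdiff(AA_STANDARD, names(values))
  if (length(missing)) {
    stop(sprintf("random-coil table (%s) is missing amino acid(s): %s",
                 medium, paste(missing, collapse = ", ")), call. = FALSE)
  }
  values <- values[AA_STANDARD]
  if (any(!is.finite(values))) {
    stop("random-coil shifts must all be finite", call. = FALSE)
  }
  structure(values, medium = medium, source = source,
            class = "random_coil_table")
}

#' Read a random-coil table from TSV
#'
#' Expects columns `aa`, `shift_ppm` and optionally `medium`.
#'
#' @param path TSV path.
#' @param medium Overrides the file's `medium` column if given.
#' @return A [random_coil_table()].
#' @export
read_random_coil_table <- function(path, medium = NULL) {
  df <- read_checked_tsv(path,
                         numeric_cols = "shift_ppm",
                         character_cols = c("aa", "medium"),
                         optional_cols = "medium")
  if (is.null(medium)) {
    medium <- unique(df$medium)
    if (length(medium) != 1L) {
      stop(sprintf("'%s' must state a single medium", path), call. = FALSE)
    }
  }
  random_coil_table(df, medium = medium, source = path)
}

#' Default random-coil Calpha tables for DMSO and water
#'
#' @return List with elements `dmso` and `aqueous`, each a
#'   [random_coil_table()]. See [random_coil_table()] for the provenance
#'   caveats of the shipped defaults.
#' @export
default_random_coil_tables <- function() {
  list(
    dmso = read_random_coil_table(
      system.file("extdata", "random_coil_ca_dmso.tsv", package = "nmrtitr",
                  mustWork = TRUE), medium = "dmso"),
    aqueous = read_random_coil_table(
      system.file("extdata", "random_coil_ca_aqueous.tsv", package = "nmrtitr",
                  mustWork = TRUE), medium = "aqueous")
  )
}
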