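#' Numbered protein sequence
#'
#' The coordinate frame for every per-residue result: an ordered run of
#' one-letter amino-acid codes with strictly increasing, contiguous residue
#' numbers starting at `first_position`.
#'
#' @param residues A single string (e.g. `"MSP"`) or a character vector of
#'   one-letter codes drawn from the 20 standard amino acids.
#' @param name Optional construct name.
#' @param first_position Residue number of the first residue (default 1).
#' @return An object of class `protein_sequence` with fields `positions`,
#'   `aa` and `name`.
#' @examples
#' seq <- protein_sequence("MSPAG", name = "toy")
#' prolines(seq)
#' @export
protein_sequence <- function(residues, name = "", first_position = 1L) {
  if (length(residues) == 1L && nchar(residues[1]) > 1L) {
    residues <- strsplit(residues[1], "")[[1]]
  }
  residues <- toupper(as.character(residues))
  if (length(residues) == 0L || identical(residues, "")) {
    stop("empty sequence: at least one residue is required", call. = FALSE)
  }
  bad <- setdiff(unique(residues), AA_STANDARD)
  if (length(bad)) {
    stop(sprintf("non-standard amino-acid letter(s): %s",
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }
  first_position <- as.integer(first_position)
  structure(
    list(positions = seq.int(first_position, length.out = length(residues)),
         aa = residues,
         name = as.character(name)[1]),
    class = "protein_sequence"
  )
}

#' @export
length.protein_sequence <- function(x) length(x$aa)

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s: %d residues (%d-%d), %d proline(s)\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              length(x$aa), min(x$positions), max(x$positions),
              sum(x$aa == "P")))
  invisible(x)
}

#' @export
as.character.protein_sequence <- function(x, ...) paste(x$aa, collapse = "")

#' Read a single-record FASTA file into a numbered sequence
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @param first_position Residue number assigned to the first residue.
#' @return A [protein_sequence()].
#' @export
read_fasta_sequence <- function(path, first_position = 1L) {
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop(sprintf("cannot parse FASTA file '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  if (length(set) == 0L) {
    stop(sprintf("empty FASTA file: no record found in '%s'", path), call. = FALSE)
  }
  if (length(set) > 1L) {
    stop(sprintf("expected exactly one FASTA record in '%s', found %d",
                 path, length(set)), call. = FALSE)
  }
  chars <- strsplit(as.character(set[[1]]), "")[[1]]
  protein_sequence(chars, name = names(set)[1] %||% "",
                   first_position = first_position)
}

#' Write a numbered sequence as FASTA
#'
#' @param seq A [protein_sequence()].
#' @param path Output path.
#' @export
write_fasta_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "protein_sequence"))
  x <- Biostrings::AAStringSet(as.character(seq))
  names(x) <- if (nzchar(seq$name)) seq$name else "sequence"
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Proline positions of a sequence
#' @param seq A [protein_sequence()].
#' @return Integer vector of residue numbers carrying proline.
#' @export
prolines <- function(seq) {
  stopifnot(inherits(seq, "protein_sequence"))
  seq$positions[seq$aa == "P"]
}

#' Amino acids at given positions
#' @param seq A [protein_sequence()].
#' @param positions Residue numbers (must exist in `seq`).
#' @return Character vector of one-letter codes.
#' @export
aa_at <- function(seq, positions) {
  idx <- match(as.integer(positions), seq$positions)
  if (anyNA(idx)) {
    stop(sprintf("position(s) not in sequence: %s",
                 paste(positions[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  seq$aa[idx]
}

#' Expected number of HSQC-observable residues
#'
#' Prolines lack the backbone amide proton, so a folded, tumbling protein of
#' `n` residues with `p` prolines gives at most `n - p` amide cross peaks.
#'
#' @param seq A [protein_sequence()].
#' @return Integer count of non-proline residues.
#' @examples
#' count_observable(protein_sequence("ACD"))  # 3
#' @export
count_observable <- function(seq) {
  stopifnot(inherits(seq, "protein_sequence"))
  sum(seq$aa != "P")
}

#' Count residues inside a closed interval
#'
#' Intervals are closed (inclusive) on both ends throughout this package,
#' matching the conventional "Ser2-Phe32" style of naming chain segments.
#'
#' @param seq A [protein_sequence()].
#' @param start,end Residue numbers bounding the interval (inclusive).
#' @param exclude_proline If `TRUE`, prolines inside the interval are not
#'   counted (e.g. when predicting amide peak counts).
#' @return Integer count.
#' @export
residues_in_segment <- function(seq, start, end, exclude_proline = FALSE) {
  stopifnot(inherits(seq, "protein_sequence"))
  start <- as.integer(start); end <- as.integer(end)
  if (start > end) stop("start must be <= end", call. = FALSE)
  rng <- range(seq$positions)
  if (start < rng[1] || end > rng[2]) {
    stop(sprintf("interval [%d, %d] outside sequence positions [%d, %d]",
                 start, end, rng[1], rng[2]), call. = FALSE)
  }
  inside <- seq$positions >= start & seq$positions <= end
  if (exclude_proline) inside <- inside & seq$aa != "P"
  sum(inside)
}
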