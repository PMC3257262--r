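#' Residue-by-condition observability matrix
#'
#' The substrate of the hierarchy inference: for every residue and every
#' titration condition, one of `"present"`, `"absent"` or
#' `"minor_duplicate"` (present with an additional slow-exchange duplicate
#' cross peak). Prolines carry no amide proton and are never present.
#'
#' @param ladder A [condition_ladder()] (decreasing DMSO fraction).
#' @param states Character matrix, one row per residue (rownames are residue
#'   numbers) and one column per condition (colnames are ladder labels).
#' @param proline_mask Integer vector of proline positions.
#' @return An object of class `presence_matrix`.
#' @export
presence_matrix <- function(ladder, states, proline_mask = integer(0)) {
  stopifnot(inherits(ladder, "condition_ladder"))
  states <- as.matrix(states)
  labels <- ladder_labels(ladder)
  if (is.null(colnames(states)) || !identical(colnames(states), labels)) {
    stop("states columns must match the ladder labels, in order", call. = FALSE)
  }
  if (is.null(rownames(states))) {
    stop("states must carry residue numbers as rownames", call. = FALSE)
  }
  allowed <- c("present", "absent", "minor_duplicate")
  bad <- setdiff(unique(as.vector(states)), allowed)
  if (length(bad)) {
    stop(sprintf("unknown presence state(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  positions <- as.integer(rownames(states))
  states <- states[order(positions), , drop = FALSE]
  positions <- sort(positions)
  proline_mask <- sort(as.integer(proline_mask))
  pro_rows <- positions %in% proline_mask
  if (any(states[pro_rows, ] != "absent")) {
    stop("prolines can never be 'present' (no amide proton)", call. = FALSE)
  }
  structure(list(conditions = ladder, states = states,
                 positions = positions, proline_mask = proline_mask),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  np <- colSums(is_present_state(x$states))
  cat(sprintf("<presence_matrix> %d residues x %d conditions (%d proline)\n",
              length(x$positions), ncol(x$states), length(x$proline_mask)))
  cat("  present per condition: ",
      paste(sprintf("%s=%d", colnames(x$states), np), collapse = ", "), "\n")
  invisible(x)
}

is_present_state <- function(x) {
  m <- x %in% c("present", "minor_duplicate")
  if (is.matrix(x)) m <- matrix(m, nrow = nrow(x), dimnames = dimnames(x))
  m
}

#' Residues observable at one condition
#' @param pm A [presence_matrix()].
#' @param condition_index Column index into the ladder (1 = most denaturing).
#' @return Integer vector of present residue numbers.
#' @export
present_positions <- function(pm, condition_index = 1L) {
  stopifnot(inherits(pm, "presence_matrix"))
  pm$positions[is_present_state(pm$states[, condition_index])]
}

#' Write a presence matrix to one long TSV
#'
#' Columns: `condition_label`, `position`, `state`.
#'
#' @param pm A [presence_matrix()].
#' @param path Output path.
#' @export
write_presence_table <- function(pm, path) {
  stopifnot(inherits(pm, "presence_matrix"))
  labels <- colnames(pm$states)
  rows <- do.call(rbind, lapply(seq_along(labels), function(k) {
    data.frame(condition_label = labels[k],
               position = pm$positions,
               state = as.character(pm$states[, k]),
               stringsAsFactors = FALSE)
  }))
  write_tsv_raw(rows, path)
}

#' Read a presence matrix from one long TSV
#' @param path TSV written by [write_presence_table()].
#' @param ladder A [condition_ladder()].
#' @param proline_mask Integer proline positions (or a [protein_sequence()]
#'   from which they are taken).
#' @return A [presence_matrix()].
#' @export
read_presence_table <- function(path, ladder, proline_mask = integer(0)) {
  if (inherits(proline_mask, "protein_sequence")) {
    proline_mask <- prolines(proline_mask)
  }
  df <- read_checked_tsv(path,
                         integer_cols = "position",
                         character_cols = c("condition_label", "state"))
  labels <- ladder_labels(ladder)
  unknown <- setdiff(unique(df$condition_label), labels)
  if (length(unknown)) {
    stop(sprintf("'%s' contains condition label(s) not in the ladder: %s",
                 path, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  pos <- sort(unique(df$position))
  states <- matrix(NA_character_, nrow = length(pos), ncol = length(labels),
                   dimnames = list(pos, labels))
  for (k in seq_along(labels)) {
    d <- df[df$condition_label == labels[k], , drop = FALSE]
    states[match(d$position, pos), k] <- d$state
  }
  if (anyNA(states)) {
    stop(sprintf("'%s' does not state every residue at every condition", path),
         call. = FALSE)
  }
  presence_matrix(ladder, states, proline_mask)
}
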