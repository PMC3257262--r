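# Internal run-finding helpers shared by the segment callers.

# Maximal runs of TRUE over integer residue positions. Positions that are not
# consecutive integers break a run (a missing residue interrupts contiguity),
# unless the only intervening positions belong to `transparent` (e.g. prolines,
# which can never carry an amide cross peak and therefore neither extend nor
# break a run).
flagged_runs <- function(positions, flagged, min_len = 1L, transparent = integer(0)) {
  stopifnot(length(positions) == length(flagged))
  o <- order(positions)
  positions <- as.integer(positions[o])
  flagged <- flagged[o] %in% TRUE
  pos <- positions[flagged]
  empty <- data.frame(start = integer(0), end = integer(0), length = integer(0))
  if (!length(pos)) {
    return(empty)
  }
  # gap between consecutive flagged positions is bridged when every
  # intervening integer is transparent
  bridged <- function(a, b) {
    if (b - a == 1L) return(TRUE)
    between <- seq.int(a + 1L, b - 1L)
    all(between %in% transparent)
  }
  grp <- integer(length(pos))
  grp[1] <- 1L
  if (length(pos) > 1L) {
    for (i in 2:length(pos)) {
      grp[i] <- if (bridged(pos[i - 1L], pos[i])) grp[i - 1L] else grp[i - 1L] + 1L
    }
  }
  starts <- tapply(pos, grp, min)
  ends <- tapply(pos, grp, max)
  out <- data.frame(start = as.integer(starts), end = as.integer(ends))
  # length counts non-transparent positions actually inside the run
  out$length <- vapply(seq_len(nrow(out)), function(i) {
    sum(pos >= out$start[i] & pos <= out$end[i])
  }, integer(1))
  out <- out[out$length >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Maximal runs of identical non-zero class labels over integer positions.
# `class` is an integer vector (0 breaks a run); contiguity as in flagged_runs.
classified_runs <- function(positions, class, min_len = 1L, transparent = integer(0)) {
  stopifnot(length(positions) == length(class))
  o <- order(positions)
  positions <- as.integer(positions[o])
  class <- class[o]
  keep <- !is.na(class) & class != 0L
  pos <- positions[keep]
  cls <- class[keep]
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), class = integer(0))
  if (!length(pos)) {
    return(empty)
  }
  bridged <- function(a, b) {
    if (b - a == 1L) return(TRUE)
    all(seq.int(a + 1L, b - 1L) %in% transparent)
  }
  grp <- integer(length(pos))
  grp[1] <- 1L
  if (length(pos) > 1L) {
    for (i in 2:length(pos)) {
      same <- cls[i] == cls[i - 1L] && bridged(pos[i - 1L], pos[i])
      grp[i] <- if (same) grp[i - 1L] else grp[i - 1L] + 1L
    }
  }
  starts <- as.integer(tapply(pos, grp, min))
  ends <- as.integer(tapply(pos, grp, max))
  classes <- as.integer(tapply(cls, grp, function(x) x[1]))
  out <- data.frame(start = starts, end = ends, class = classes)
  out$length <- vapply(seq_len(nrow(out)), function(i) {
    sum(pos >= out$start[i] & pos <= out$end[i])
  }, integer(1))
  out <- out[out$length >= min_len, c("start", "end", "length", "class"), drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
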