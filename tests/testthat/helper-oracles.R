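# Independent brute-force oracles. These deliberately avoid the package's
# run-finding helpers: they enumerate every candidate interval and check the
# qualifying conditions directly.

# all maximal contiguous runs of same-signed significant residues
oracle_propensity_segments <- function(positions, deltas, threshold, min_len) {
  sig <- function(p) {
    i <- match(p, positions)
    if (is.na(i)) return(0L)
    d <- deltas[i]
    if (d > threshold) 1L else if (d < -threshold) -1L else 0L
  }
  found <- list()
  for (a in positions) {
    for (b in positions[positions >= a]) {
      span <- a:b
      if (!all(span %in% positions)) next          # missing residues break runs
      s <- sig(a)
      if (s == 0L) next
      if (!all(vapply(span, sig, integer(1)) == s)) next
      if (length(span) < min_len) next
      # maximality
      if ((a - 1) %in% positions && sig(a - 1) == s) next
      if ((b + 1) %in% positions && sig(b + 1) == s) next
      found[[length(found) + 1L]] <-
        data.frame(start = a, end = b,
                   label = if (s > 0) "helix-propensity" else "sheet-propensity",
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(found)) {
    return(data.frame(start = integer(0), end = integer(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, found)
  out[order(out$start), ]
}

# maximal contiguous runs of residues whose R2 exceeds median + k * mad
oracle_exchange_segments <- function(positions, r2, k_sigma, min_len) {
  thr <- median(r2) + k_sigma * mad(r2)
  flag <- function(p) {
    i <- match(p, positions)
    !is.na(i) && r2[i] > thr
  }
  found <- list()
  for (a in positions) {
    for (b in positions[positions >= a]) {
      span <- a:b
      if (!all(span %in% positions)) next
      if (!all(vapply(span, flag, logical(1)))) next
      if (length(span) < min_len) next
      if ((a - 1) %in% positions && flag(a - 1)) next
      if ((b + 1) %in% positions && flag(b + 1)) next
      found[[length(found) + 1L]] <- data.frame(start = a, end = b)
    }
  }
  if (!length(found)) return(data.frame(start = integer(0), end = integer(0)))
  out <- do.call(rbind, found)
  out[order(out$start), ]
}

# expected disappearance events recomputed directly from a planted stage map
oracle_events_from_stages <- function(stage, positions, prolines, n_conditions,
                                      labels, fractions) {
  out <- list()
  for (k in 2:n_conditions) {
    newly <- positions[stage == k & !(positions %in% prolines)]
    if (!length(newly)) next
    newly <- sort(newly)
    # group, treating prolines as transparent
    grp <- cumsum(c(1, vapply(seq_along(newly)[-1], function(i) {
      gap <- setdiff(seq(newly[i - 1] + 1, newly[i] - 1),
                     prolines)
      if (newly[i] - newly[i - 1] == 1 || length(gap) == 0) 0 else 1
    }, numeric(1))))
    for (g in unique(grp)) {
      out[[length(out) + 1L]] <- data.frame(
        condition_index = k, condition_label = labels[k],
        dmso_fraction = fractions[k],
        start = min(newly[grp == g]), end = max(newly[grp == g]),
        length = sum(grp == g), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(condition_index = integer(0)))
  }
  out <- do.call(rbind, out)
  out <- out[order(out$condition_index, out$start), ]
  rownames(out) <- NULL
  out
}
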