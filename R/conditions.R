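#' Solvent condition of one titration point
#'
#' @param dmso_fraction DMSO volume fraction in `[0, 1]`.
#' @param temperature_c Sample temperature in degrees Celsius.
#' @param field_mhz Proton spectrometer frequency in MHz (must be > 0).
#' @param label Short text label; defaults to e.g. `"dmso090"` for 0.90.
#' @return An object of class `nmr_condition`.
#' @export
condition <- function(dmso_fraction, temperature_c = 45, field_mhz = 800,
                      label = NULL) {
  dmso_fraction <- as.numeric(dmso_fraction)
  if (is.na(dmso_fraction) || dmso_fraction < 0 || dmso_fraction > 1) {
    stop("dmso_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(field_mhz) || field_mhz <= 0) {
    stop("field_mhz must be > 0", call. = FALSE)
  }
  if (is.null(label)) {
    label <- sprintf("dmso%03d", as.integer(round(100 * dmso_fraction)))
  }
  structure(
    list(dmso_fraction = dmso_fraction,
         temperature_c = as.numeric(temperature_c),
         field_mhz = as.numeric(field_mhz),
         label = as.character(label)[1]),
    class = "nmr_condition"
  )
}

#' @export
print.nmr_condition <- function(x, ...) {
  cat(sprintf("<nmr_condition> %s: %.0f%% DMSO, %.0f degC, %.0f MHz\n",
              x$label, 100 * x$dmso_fraction, x$temperature_c, x$field_mhz))
  invisible(x)
}

#' Ordered ladder of titration conditions
#'
#' Conditions are kept in strictly decreasing order of DMSO fraction (most
#' denaturing first); this ordering defines the condition index used by the
#' disappearance bookkeeping.
#'
#' @param dmso_fractions Numeric vector, strictly decreasing.
#' @param temperature_c,field_mhz Shared across the ladder (or vectors).
#' @param labels Optional character vector of labels.
#' @return A list of [condition()] objects with class `condition_ladder`.
#' @examples
#' ladder <- condition_ladder()  # 100/90/85/80/70/50% DMSO
#' @export
condition_ladder <- function(dmso_fractions = c(1, 0.9, 0.85, 0.8, 0.7, 0.5),
                             temperature_c = 45, field_mhz = 800,
                             labels = NULL) {
  n <- length(dmso_fractions)
  if (n < 1L) stop("at least one condition is required", call. = FALSE)
  if (n > 1L && any(diff(dmso_fractions) >= 0)) {
    stop("dmso_fractions must be strictly decreasing", call. = FALSE)
  }
  temperature_c <- rep_len(temperature_c, n)
  field_mhz <- rep_len(field_mhz, n)
  out <- lapply(seq_len(n), function(i) {
    condition(dmso_fractions[i], temperature_c[i], field_mhz[i],
              label = if (is.null(labels)) NULL else labels[i])
  })
  lbl <- vapply(out, function(c) c$label, character(1))
  if (anyDuplicated(lbl)) stop("condition labels must be unique", call. = FALSE)
  structure(out, class = "condition_ladder")
}

#' @export
print.condition_ladder <- function(x, ...) {
  cat(sprintf("<condition_ladder> %d conditions: %s\n", length(x),
              paste(vapply(x, function(c) c$label, character(1)),
                    collapse = " > ")))
  invisible(x)
}

#' Tabulate a condition ladder
#' @param ladder A [condition_ladder()].
#' @return data.frame with one row per condition.
#' @export
conditions_table <- function(ladder) {
  stopifnot(inherits(ladder, "condition_ladder"))
  data.frame(
    label = vapply(ladder, function(c) c$label, character(1)),
    dmso_fraction = vapply(ladder, function(c) c$dmso_fraction, numeric(1)),
    temperature_c = vapply(ladder, function(c) c$temperature_c, numeric(1)),
    field_mhz = vapply(ladder, function(c) c$field_mhz, numeric(1)),
    stringsAsFactors = FALSE
  )
}

ladder_labels <- function(ladder) vapply(ladder, function(c) c$label, character(1))

ladder_from_table <- function(df) {
  condition_ladder(dmso_fractions = df$dmso_fraction,
                   temperature_c = df$temperature_c,
                   field_mhz = df$field_mhz,
                   labels = df$label)
}
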