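#' Fit a monoexponential R2 decay to one residue's CPMG intensities
#'
#' Nonlinear least squares on `I(t) = I0 * exp(-R2 * t)`
#' (Levenberg-Marquardt), initialised from a log-linear regression of the
#' positive intensities; the standard error of R2 comes from the fit
#' covariance. A failed or non-decaying fit produces a failure record (not
#' an exception), so batch fitting over a chain never aborts.
#'
#' @param delays_s Delays in seconds.
#' @param intensities Intensities at those delays.
#' @return A list with `r2` (1/s), `r2_err` (covariance SE; `NA` when there
#'   are no residual degrees of freedom), `i0`, `sigma` (residual SD),
#'   `status` (`"ok"`/`"failed"`) and `reason`.
#' @examples
#' t <- default_cpmg_delays()
#' fit_r2(t, 10 * exp(-5 * t))$r2  # 5
#' @export
fit_r2 <- function(delays_s, intensities) {
  fail <- function(reason) {
    list(r2 = NA_real_, r2_err = NA_real_, i0 = NA_real_, sigma = NA_real_,
         status = "failed", reason = reason)
  }
  delays_s <- as.numeric(delays_s)
  intensities <- as.numeric(intensities)
  ok <- is.finite(intensities) & intensities > 0 & is.finite(delays_s)
  if (sum(ok) < 2L) return(fail("fewer than 2 positive intensities"))
  t <- delays_s[ok]
  y <- intensities[ok]
  # log-linear initial guess
  ll <- lm(log(y) ~ t)
  r2_0 <- -unname(coef(ll)[2])
  i0_0 <- exp(unname(coef(ll)[1]))
  if (!is.finite(r2_0) || r2_0 <= 0) return(fail("non-decaying intensities"))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ i0 * exp(-r2 * t),
                      start = list(i0 = i0_0, r2 = r2_0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(fail("nonlinear fit did not converge"))
  est <- coef(fit)
  if (!is.finite(est["r2"]) || est["r2"] <= 0) {
    return(fail("fitted rate not positive"))
  }
  s <- summary(fit)
  se <- tryCatch(s$coefficients["r2", "Std. Error"], error = function(e) NA_real_)
  dof <- length(y) - 2L
  list(r2 = unname(est["r2"]),
       r2_err = if (dof > 0L) unname(se) else NA_real_,
       i0 = unname(est["i0"]),
       sigma = if (dof > 0L) s$sigma else 0,
       status = "ok", reason = NA_character_)
}

#' Fit R2 for every residue of a relaxation series
#'
#' @param series A [relaxation_series()].
#' @return data.frame of class `r2_profile` with columns `position`, `r2`,
#'   `r2_err`, `i0`, `sigma`, `status`, `reason` and attribute `condition`.
#' @export
fit_r2_profile <- function(series) {
  stopifnot(inherits(series, "relaxation_series"))
  pos <- series_positions(series)
  fits <- lapply(seq_along(pos), function(i) {
    fit_r2(series$delays_s, series$intensities[i, ])
  })
  out <- data.frame(
    position = pos,
    r2 = vapply(fits, `[[`, numeric(1), "r2"),
    r2_err = vapply(fits, `[[`, numeric(1), "r2_err"),
    i0 = vapply(fits, `[[`, numeric(1), "i0"),
    sigma = vapply(fits, `[[`, numeric(1), "sigma"),
    status = vapply(fits, `[[`, character(1), "status"),
    reason = vapply(fits, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE
  )
  structure(out, condition = series$condition,
            class = c("r2_profile", "data.frame"))
}

#' Summary statistics of a fitted R2 profile
#' @param profile An [fit_r2_profile()] result (or any data.frame with `r2`
#'   and `status`).
#' @return List with `n`, `min`, `max`, `mean` over converged fits.
#' @export
r2_summary <- function(profile) {
  r2 <- profile$r2[profile$status == "ok"]
  list(n = length(r2), min = min(r2), max = max(r2), mean = mean(r2))
}

#' Detect conformational-exchange segments from an R2 profile
#'
#' Operationalises the visual "trend of the spread" reading of an R2
#' profile as a robust outlier rule: residues with
#' `R2 > median + k_sigma * (scaled MAD)` are flagged, and maximal
#' contiguous flagged runs of at least `min_len` residues are returned as
#' `"exchange"` segments. Prolines (and other never-observable residues)
#' are transparent for contiguity.
#'
#' @param profile An [fit_r2_profile()] result.
#' @param k_sigma Multiplier on the robust spread (default 1).
#' @param min_len Minimum run length (default 3).
#' @param transparent Integer positions bridged silently (e.g. prolines).
#' @return data.frame of segment calls (`start`, `end`, `length`, `label`,
#'   `mean_r2`) with attribute `summary` = [r2_summary()] of the profile.
#' @export
detect_exchange_segments <- function(profile, k_sigma = 1, min_len = 3L,
                                     transparent = integer(0)) {
  ok <- profile$status == "ok"
  if (sum(ok) < 5L) {
    stop("at least 5 fitted residues are required to define the R2 spread",
         call. = FALSE)
  }
  pos <- as.integer(profile$position[ok])
  r2 <- as.numeric(profile$r2[ok])
  med <- median(r2)
  spread <- mad(r2)  # scaled MAD (consistent with a normal SD)
  thr <- med + k_sigma * spread
  runs <- flagged_runs(pos, r2 > thr, min_len = max(1L, as.integer(min_len)),
                       transparent = transparent)
  if (nrow(runs)) {
    runs$label <- "exchange"
    runs$mean_r2 <- vapply(seq_len(nrow(runs)), function(i) {
      mean(r2[pos >= runs$start[i] & pos <= runs$end[i]])
    }, numeric(1))
  } else {
    runs$label <- character(0)
    runs$mean_r2 <- numeric(0)
  }
  structure(runs, summary = r2_summary(profile), threshold = thr,
            class = c("exchange_segments", "data.frame"))
}
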