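#' Score wells of a limiting-dilution assay
#'
#' Converts per-well colony sizes into negative-well counts per seeding
#' density. A well is negative when its largest colony is below `threshold`
#' (a colony of exactly `threshold` cells makes the well positive); empty
#' wells (no colony rows, `colony_size_cells` = NA) are negative.
#'
#' @param per_well long-format data frame with columns
#'   `dose_cells_per_well`, `well_id` and `colony_size_cells` (NA for a
#'   well listed without colonies); every well must be listed.
#' @param threshold scoring threshold in cells (default 50).
#' @param expected_wells optional wells per density for validation; a
#'   mismatch signals malformed input.
#' @return A data frame of class `ld_plate` (columns `dose_cells_per_well`,
#'   `wells_total`, `wells_negative`).
#' @export
score_wells <- function(per_well, threshold = 50, expected_wells = NULL) {
  req <- c("dose_cells_per_well", "well_id", "colony_size_cells")
  if (!all(req %in% names(per_well)))
    stop_config("per-well table needs columns: ", paste(req, collapse = ", "))
  key <- interaction(per_well$dose_cells_per_well, per_well$well_id,
                     drop = TRUE)
  biggest <- tapply(per_well$colony_size_cells, key,
                    function(s) if (all(is.na(s))) 0 else max(s, na.rm = TRUE))
  dose_of <- tapply(per_well$dose_cells_per_well, key, `[`, 1)
  neg <- biggest < threshold
  out <- data.frame(
    dose_cells_per_well = sort(unique(per_well$dose_cells_per_well),
                               decreasing = TRUE))
  out$wells_total <- vapply(out$dose_cells_per_well,
                            function(d) sum(dose_of == d), integer(1))
  out$wells_negative <- vapply(out$dose_cells_per_well,
                               function(d) sum(neg[dose_of == d]), integer(1))
  if (!is.null(expected_wells) && any(out$wells_total != expected_wells))
    stop_config("missing well records: found ",
                paste(out$wells_total, collapse = "/"), " wells, expected ",
                paste(expected_wells, collapse = "/"))
  class(out) <- c("ld_plate", "data.frame")
  out
}

#' Fit the single-hit limiting-dilution model
#'
#' Fits the natural log of the fraction of negative wells linearly against
#' the seeded cell number. Under single-hit kinetics
#' ln(frac negative) = slope * dose with slope = ln(1 - f), f the per-cell
#' frequency of resistance-initiating cells, so the regression runs through
#' the origin by default; a free-intercept variant is available, and when
#' the two slopes disagree by more than 10% both are reported in a warning.
#' Dose levels with zero negative wells have no defined log fraction and
#' are dropped with a warning (or continuity-corrected with +0.5 wells via
#' `continuity_correction`).
#'
#' The slope's standard error defaults to `se_method = "binomial"`: the
#' binomial sampling variance of each log proportion,
#' var(ln p-hat) ~ (1 - p-hat) / (p-hat * wells), propagated through the
#' least-squares weights. The conventional residual-based error
#' (`se_method = "residual"`) is also available but understates the slope's
#' sampling variability because the scatter of the log fractions grows
#' strongly with dose while the fit weights high doses most.
#'
#' @param plate an `ld_plate` data frame (columns `dose_cells_per_well`,
#'   `wells_total`, `wells_negative`).
#' @param intercept `"zero"` (single-hit default) or `"free"`.
#' @param se_method `"binomial"` (default, see above) or `"residual"`.
#' @param continuity_correction add 0.5 to zero negative-well counts
#'   instead of dropping those levels.
#' @return An object of class `ld_fit`: list with `slope`, `slope_se`,
#'   `intercept` (type), `n_levels_used`, `dropped_doses`, `data`.
#' @export
fit_limiting_dilution <- function(plate, intercept = c("zero", "free"),
                                  se_method = c("binomial", "residual"),
                                  continuity_correction = FALSE) {
  intercept <- match.arg(intercept)
  se_method <- match.arg(se_method)
  req <- c("dose_cells_per_well", "wells_total", "wells_negative")
  stopifnot(all(req %in% names(plate)))
  stopifnot(all(plate$wells_negative >= 0),
            all(plate$wells_negative <= plate$wells_total),
            all(plate$dose_cells_per_well > 0))
  neg <- plate$wells_negative
  dropped <- numeric(0)
  if (continuity_correction) {
    neg <- ifelse(neg == 0, 0.5, neg)
    use <- rep(TRUE, nrow(plate))
  } else {
    use <- neg > 0
    dropped <- plate$dose_cells_per_well[!use]
    if (length(dropped))
      warning(sprintf(
        "dropping %d dose level(s) with zero negative wells: %s",
        length(dropped), paste(signif(dropped, 4), collapse = ", ")))
  }
  if (sum(use) < 2)
    stop_config("fewer than 2 usable dose levels: frequency inestimable")
  x <- plate$dose_cells_per_well[use]
  nw <- plate$wells_total[use]
  phat <- neg[use] / nw
  y <- log(phat)
  # per-level binomial variance of ln(p-hat); fractions of exactly 1 get a
  # half-well correction so their variance is small but non-zero
  pv <- ifelse(phat >= 1, (nw - 0.5) / nw, phat)
  vbin <- (1 - pv) / (pv * nw)

  fit_zero <- function() {
    sxx <- sum(x^2)
    slope <- sum(x * y) / sxx
    se <- if (se_method == "binomial") {
      sqrt(sum(x^2 * vbin)) / sxx
    } else {
      df <- length(x) - 1
      if (df > 0) sqrt(sum((y - slope * x)^2) / df / sxx) else NA_real_
    }
    c(slope, se)
  }
  fit_free <- function() {
    m <- lm(y ~ x)
    se <- if (se_method == "binomial") {
      X <- cbind(1, x)
      xtx_inv <- solve(crossprod(X))
      sqrt((xtx_inv %*% t(X) %*% diag(vbin, length(x)) %*% X %*%
              xtx_inv)[2, 2])
    } else summary(m)$coefficients["x", "Std. Error"]
    c(coef(m)[["x"]], se)
  }
  est <- if (intercept == "zero") fit_zero() else fit_free()
  if (est[1] >= 0)
    stop_config("fitted slope >= 0: negative-well fraction does not decay ",
                "with dose; frequency inestimable")
  if (intercept == "zero" && sum(use) >= 3) {
    alt <- fit_free()
    if (is.finite(alt[1]) && alt[1] < 0 &&
        abs(alt[1] - est[1]) > 0.1 * abs(est[1]))
      warning(sprintf(
        "zero-intercept slope %.4g and free-intercept slope %.4g disagree by >10%%",
        est[1], alt[1]))
  }
  structure(list(slope = est[1], slope_se = est[2], intercept = intercept,
                 n_levels_used = sum(use), dropped_doses = dropped,
                 data = data.frame(dose = x, log_frac_negative = y)),
            class = "ld_fit")
}

#' @export
print.ld_fit <- function(x, ...) {
  cat("Limiting-dilution fit (single-hit model)\n")
  cat(sprintf("  slope = %.6g per cell (se %.3g), %s intercept, %d levels\n",
              x$slope, x$slope_se, x$intercept, x$n_levels_used))
  if (length(x$dropped_doses))
    cat("  dropped zero-negative doses:",
        paste(signif(x$dropped_doses, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.ld_fit <- function(object, ...) c(slope = object$slope)

#' Frequency of resistance-initiating cells
#'
#' Converts the fitted single-hit slope into the frequency estimate:
#' cells per resistance-initiating cell = 1 / (1 - e^slope), its
#' delta-method standard error = se_slope * e^slope / (1 - e^slope)^2, and
#' the per-cell frequency 1 - e^slope.
#'
#' @param slope fitted slope (< 0), or an [fit_limiting_dilution()] result.
#' @param slope_se standard error of the slope (ignored when `slope` is an
#'   `ld_fit`).
#' @return An object of class `ric_estimate`: list with `slope`,
#'   `slope_se`, `per_cell_frequency`, `cells_per_ric`,
#'   `cells_per_ric_error`.
#' @export
ric_frequency <- function(slope, slope_se = NA_real_) {
  if (inherits(slope, "ld_fit")) {
    slope_se <- slope$slope_se
    slope <- slope$slope
  }
  if (!is.finite(slope) || slope >= 0)
    stop_config("slope must be finite and < 0")
  f <- 1 - exp(slope)
  structure(list(slope = slope, slope_se = slope_se,
                 per_cell_frequency = f,
                 cells_per_ric = 1 / f,
                 cells_per_ric_error = slope_se * exp(slope) / f^2),
            class = "ric_estimate")
}

#' @export
print.ric_estimate <- function(x, ...) {
  cat("Resistance-initiating cell frequency\n")
  cat(sprintf("  1 RIC per %.4g cells (+/- %.3g)\n", x$cells_per_ric,
              x$cells_per_ric_error))
  cat(sprintf("  per-cell frequency %.4g (slope %.4g, se %.3g)\n",
              x$per_cell_frequency, x$slope, x$slope_se))
  invisible(x)
}
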