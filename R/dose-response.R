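#' Normalize plate luminescence to percent viability
#'
#' Viability is `100 * (signal - mean(empty)) / (mean(DMSO) - mean(empty))`:
#' empty-well background is subtracted and the result scaled so DMSO
#' (zero-dose) wells average 100% by construction.
#'
#' @param plate a `luminescence_plate` data frame (columns `role`,
#'   `concentration`, `replicate`, `signal`), or any numeric vector of
#'   signals if `empty` and `dmso` are given.
#' @param empty,dmso numeric vectors of empty-well and DMSO-well signals;
#'   taken from `plate$role` when `plate` is a plate table.
#' @return For a plate table, the non-empty rows with a `viability` column
#'   appended; for a signal vector, the viability vector.
#' @export
normalize_viability <- function(plate, empty = NULL, dmso = NULL) {
  is_table <- is.data.frame(plate)
  if (is_table) {
    stopifnot(all(c("role", "signal") %in% names(plate)))
    empty <- plate$signal[plate$role == "empty"]
    dmso <- plate$signal[plate$role == "dmso"]
    signal <- plate$signal
  } else signal <- plate
  if (!length(empty) || !length(dmso))
    stop_config("need at least one empty and one DMSO well")
  m_empty <- mean(empty)
  m_dmso <- mean(dmso)
  if (m_dmso <= m_empty)
    stop_config("mean DMSO signal <= mean empty signal: unusable plate")
  v <- 100 * (signal - m_empty) / (m_dmso - m_empty)
  if (!is_table) return(v)
  out <- plate[plate$role != "empty", , drop = FALSE]
  out$viability <- v[plate$role != "empty"]
  rownames(out) <- NULL
  out
}

#' Fit the four-parameter dose-response curve
#'
#' Nonlinear least squares of y = b + (100 - b) / (1 + (x / IC50)^k) on
#' linear concentration, exactly the form used to summarize short-term
#' viability assays: `b` is the bottom plateau (viability as x grows
#' without bound), `k` the hill slope and IC50 the half-maximal inhibitory
#' concentration. Initialization is deterministic (b0 = smallest observed
#' viability clamped to [0, 100]; IC50_0 = the concentration whose mean
#' viability is nearest (100 + b0)/2; k0 = 1) with bounds b in [0, 100],
#' k in (0, 10], IC50 in (0, 1e4 * max dose], so the fit is reproducible
#' given the data. Non-convergence is reported via `converged = FALSE`
#' with the best parameters found, never silently.
#'
#' @param conc drug concentrations (>= 0; at least 4 distinct positive
#'   values, zero-dose anchors allowed).
#' @param viability percent viability per well (same length).
#' @return An object of class `dose_response_fit` with elements `b`, `k`,
#'   `ic50`, `residual_sse`, `converged` and `flags` (e.g.
#'   `"ic50_at_bound"` when the plateau is unidentifiable).
#' @export
fit_dose_response <- function(conc, viability) {
  stopifnot(length(conc) == length(viability), all(is.finite(viability)),
            all(conc >= 0))
  if (length(unique(conc[conc > 0])) < 4)
    stop_config("need >= 4 distinct positive concentrations")
  b0 <- min(max(min(viability), 0), 100)
  mid <- (100 + b0) / 2
  pos <- sort(unique(conc[conc > 0]))
  mean_v <- vapply(pos, function(cc) mean(viability[conc == cc]), numeric(1))
  ic50_0 <- pos[which.min(abs(mean_v - mid))]
  start <- list(b = b0, k = 1, ic50 = ic50_0)
  lower <- c(b = 0, k = 1e-3, ic50 = 1e-9 * max(pos))
  upper <- c(b = 100, k = 10, ic50 = 1e4 * max(pos))
  df <- data.frame(x = conc, y = viability)

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ b + (100 - b) / (1 + (x / ic50)^k), data = df,
                      start = start, lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) e)

  if (inherits(fit, "error")) {
    # fall back to bounded quasi-Newton on the same least-squares objective
    sse <- function(par) {
      sum((viability - dr_curve(conc, par[1], par[2], par[3]))^2)
    }
    op <- stats::optim(unlist(start), sse, method = "L-BFGS-B",
                       lower = lower, upper = upper)
    est <- op$par
    converged <- FALSE
    rss <- op$value
  } else {
    est <- coef(fit)
    converged <- isTRUE(fit$convInfo$isConv)
    rss <- sum(stats::residuals(fit)^2)
  }
  flags <- character(0)
  if (est[["ic50"]] >= 0.99 * upper[["ic50"]] ||
      est[["ic50"]] <= 1.01 * lower[["ic50"]])
    flags <- c(flags, "ic50_at_bound")
  if (est[["k"]] >= 0.99 * upper[["k"]]) flags <- c(flags, "k_at_bound")
  structure(list(b = est[["b"]], k = est[["k"]], ic50 = est[["ic50"]],
                 residual_sse = rss, converged = converged, flags = flags,
                 data = df),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Four-parameter dose-response fit\n")
  cat(sprintf("  IC50 = %.4g, hill slope k = %.3g, bottom b = %.3g%%\n",
              x$ic50, x$k, x$b))
  cat(sprintf("  residual SSE = %.4g over %d wells%s\n", x$residual_sse,
              nrow(x$data),
              if (x$converged) "" else "  [did not converge]"))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.dose_response_fit <- function(object, ...) {
  c(b = object$b, k = object$k, ic50 = object$ic50)
}

#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
       else if (is.data.frame(newdata)) newdata$x else newdata
  dr_curve(x, object$b, object$k, object$ic50)
}

#' @export
residuals.dose_response_fit <- function(object, ...) {
  object$data$y - predict(object)
}

#' @export
plot.dose_response_fit <- function(x, ...) {
  d <- x$data
  xx <- d$x
  xx[xx == 0] <- min(xx[xx > 0]) / 10  # plot zero-dose wells at left edge
  graphics::plot(xx, d$y, log = "x", xlab = "concentration",
                 ylab = "viability (%)", ...)
  grid_x <- exp(seq(log(min(xx)), log(max(xx)), length.out = 200))
  lines(grid_x, predict(x, grid_x), col = "firebrick", lwd = 2)
  invisible(x)
}
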