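#' Map division probability to expected colony size
#'
#' Runs mutation-free (`mu = 0`) colony simulations of fixed duration over a
#' grid of division probabilities and records the mean final size at each,
#' smoothed by isotonic regression so the map is monotone and invertible.
#' This is the bridge between observable colony sizes and the model's
#' division probabilities: tolerant and resistant colony-size data are
#' converted into `p_init` and per-colony `p_max` through its inverse.
#'
#' @param duration_updates number of update rounds each calibration colony
#'   is grown for (e.g. `clonogenic_days * updates_per_day`).
#' @param p_grid sorted division probabilities in `[0, 1]`.
#' @param reps colonies simulated per grid point.
#' @param params a [simulation_params()] supplying the neighbourhood; its
#'   mutation and death settings are ignored (the map is defined mutation-
#'   and death-free).
#' @param seed optional integer seed.
#' @return An object of class `rate_size_map`: data frame with columns `p`,
#'   `mean_size` (raw Monte-Carlo mean) and `expected_size` (isotonic).
#' @export
build_rate_size_map <- function(duration_updates, p_grid = seq(0, 1, 0.05),
                                reps = 200, params = simulation_params(),
                                seed = NULL) {
  stopifnot(duration_updates >= 0, reps >= 1, !is.unsorted(p_grid),
            all(p_grid >= 0 & p_grid <= 1))
  side <- auto_lattice_side(duration_updates, Inf)
  moore <- params$neighborhood == "moore"
  with_seed(seed, {
    means <- vapply(p_grid, function(p) {
      if (p == 0) return(1)  # no division: every colony stays a single cell
      par <- list(p_init = p, p_max = p, n_steps = 1L, mu = 0,
                  death_prob = 0, bidirectional = FALSE, effect_sd = 0,
                  moore = moore)
      sizes <- abm_simulate_cohort_cpp(integer(reps), rep(p, reps), par,
                                       as.integer(duration_updates), side)
      mean(sizes)
    }, numeric(1))
    iso <- isoreg(p_grid, means)$yf
    out <- data.frame(p = p_grid, mean_size = means, expected_size = iso)
    attr(out, "duration_updates") <- duration_updates
    attr(out, "reps") <- reps
    class(out) <- c("rate_size_map", "data.frame")
    out
  })
}

#' @export
print.rate_size_map <- function(x, ...) {
  cat(sprintf(
    "rate_size_map: %d grid points over p in [%g, %g], %d updates, %d reps/point\n",
    nrow(x), min(x$p), max(x$p), attr(x, "duration_updates"), attr(x, "reps")))
  cat(sprintf("  expected size range: %.3g .. %.3g cells\n",
              min(x$expected_size), max(x$expected_size)))
  invisible(x)
}

#' @export
plot.rate_size_map <- function(x, ...) {
  graphics::plot(x$p, x$mean_size, xlab = "division probability per update",
                 ylab = "expected final colony size (cells)",
                 log = "y", ...)
  lines(x$p, x$expected_size, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Invert a rate-size map
#'
#' Linear interpolation of the monotone map to convert an observed colony
#' size into the division probability expected to produce it. Targets above
#' the map's maximum are clamped to the largest grid probability with a
#' warning; ties on flat stretches resolve to the smallest admissible
#' probability.
#'
#' @param map a [build_rate_size_map()] result.
#' @param target_size colony size(s) in cells (>= 1).
#' @return Division probabilities, one per target.
#' @export
invert_size_to_rate <- function(map, target_size) {
  stopifnot(inherits(map, "rate_size_map"))
  if (any(target_size < 1)) stop_config("target_size must be >= 1")
  hi <- max(map$expected_size)
  if (any(target_size > hi)) {
    warning(sprintf(
      "target size above map maximum (%.3g); clamped to largest grid p", hi))
    target_size <- pmin(target_size, hi)
  }
  out <- approx(x = map$expected_size, y = map$p, xout = target_size,
                ties = min, rule = 2)$y
  unname(out)
}

#' Calibrate the model from tolerant and resistant colony sizes
#'
#' Sets the initial division probability from the median tolerant colony
#' size (tolerant cells are assumed to vary little in proliferation rate)
#' and builds a per-colony maximal-probability sampler by inverting sizes
#' drawn uniformly with replacement from the resistant sample (capturing
#' the observed between-colony variability of resistant growth).
#'
#' @param tolerant_sizes,resistant_sizes non-empty integer vectors of
#'   per-colony sizes (cells).
#' @param map a [build_rate_size_map()] result.
#' @return An object of class `cohort_calibration`: list with `p_init`,
#'   `p_max_ref` (inverse of the resistant median, used for the shared
#'   pre-incubation phase) and `p_max_sampler(n)`. Sampled values below
#'   `p_init` are clamped up with a warning.
#' @export
calibrate_cohort <- function(tolerant_sizes, resistant_sizes, map) {
  if (length(tolerant_sizes) == 0 || length(resistant_sizes) == 0)
    stop_config("tolerant and resistant samples must be non-empty")
  stopifnot(inherits(map, "rate_size_map"))
  p_init <- invert_size_to_rate(map, median(tolerant_sizes))
  p_max_ref <- max(p_init, invert_size_to_rate(map, median(resistant_sizes)))
  resistant_sizes <- as.numeric(resistant_sizes)
  sampler <- function(n) {
    s <- sample(resistant_sizes, n, replace = TRUE)
    p <- invert_size_to_rate(map, s)
    if (any(p < p_init)) {
      warning("sampled p_max below p_init; clamped up to p_init")
      p <- pmax(p, p_init)
    }
    p
  }
  structure(list(p_init = p_init, p_max_ref = p_max_ref,
                 p_max_sampler = sampler,
                 tolerant_median = median(tolerant_sizes),
                 resistant_median = median(resistant_sizes)),
            class = "cohort_calibration")
}

#' @export
print.cohort_calibration <- function(x, ...) {
  cat("cohort_calibration\n")
  cat(sprintf("  p_init = %.4g (tolerant median %g cells)\n", x$p_init,
              x$tolerant_median))
  cat(sprintf("  reference p_max = %.4g (resistant median %g cells)\n",
              x$p_max_ref, x$resistant_median))
  cat("  per-colony p_max: empirical resample of resistant sizes\n")
  invisible(x)
}

#' Apply a calibration to simulation parameters
#'
#' @param params a [simulation_params()] template.
#' @param calibration a [calibrate_cohort()] result.
#' @return `params` with `p_init` and `p_max` replaced by the calibrated
#'   values.
#' @export
apply_calibration <- function(params, calibration) {
  stopifnot(inherits(params, "simulation_params"),
            inherits(calibration, "cohort_calibration"))
  simulation_params(p_init = calibration$p_init,
                    p_max = calibration$p_max_ref,
                    n_steps = params$n_steps, mu = params$mu,
                    death_prob = params$death_prob,
                    bidirectional = params$bidirectional,
                    effect_sd = params$effect_sd,
                    updates_per_day = params$updates_per_day,
                    neighborhood = params$neighborhood)
}
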