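#' Histogram of colony sizes on log2-spaced bins
#'
#' Colony sizes span orders of magnitude, so histograms are built on
#' doubling bins (0.5, 1], (1, 2], (2, 4], ... A Laplace pseudocount is
#' added to every bin before normalization so that divergences between two
#' histograms on shared edges are always finite.
#'
#' @param sizes non-empty vector of colony sizes (cells, >= 1).
#' @param edges optional bin edges (strictly increasing, spanning the data);
#'   defaults to log2-spaced edges spanning `sizes` and `other`.
#' @param other optional second sample the bins must also span (the sample
#'   this histogram will be compared against).
#' @param pseudocount Laplace pseudocount per bin (default 1).
#' @return An object of class `size_histogram`: list with `bin_edges`,
#'   `counts` and `probs` (sums to 1; all entries > 0).
#' @export
size_histogram <- function(sizes, edges = NULL, other = NULL,
                           pseudocount = 1) {
  if (length(sizes) == 0) stop_config("sizes must be non-empty")
  stopifnot(all(sizes >= 1), pseudocount >= 0)
  if (is.null(edges)) edges <- log2_bin_edges(c(sizes, other))
  if (is.unsorted(edges, strictly = TRUE))
    stop_config("bin edges must be strictly increasing")
  if (min(sizes) <= edges[1] || max(sizes) > edges[length(edges)])
    stop_config("bin edges must span the data")
  counts <- tabulate(findInterval(sizes, edges, left.open = TRUE),
                     nbins = length(edges) - 1)
  probs <- (counts + pseudocount) / (sum(counts) + pseudocount * length(counts))
  stopifnot(abs(sum(probs) - 1) < 1e-9)
  structure(list(bin_edges = edges, counts = counts, probs = probs),
            class = "size_histogram")
}

# doubling-scale edges 0.5, 1, 2, 4, ... spanning all values (>= 1)
log2_bin_edges <- function(values) {
  k <- max(1, ceiling(log2(max(values))))
  c(0.5, 2^(0:k))
}

#' @export
print.size_histogram <- function(x, ...) {
  cat(sprintf("size_histogram: %d colonies over %d log2 bins [%g, %g]\n",
              sum(x$counts), length(x$counts), x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)]))
  invisible(x)
}

#' Kullback-Leibler divergence between two size histograms
#'
#' Computes D(P || Q) = sum_i P_i log(P_i / Q_i) in nats, with P the
#' observed and Q the simulated histogram (this direction penalizes models
#' that assign little probability where data actually fall). Both
#' histograms must share identical bin edges.
#'
#' @param P,Q [size_histogram()] objects on identical bin edges.
#' @return Divergence in nats (>= 0; 0 iff the histograms are identical).
#' @export
kl_divergence <- function(P, Q) {
  stopifnot(inherits(P, "size_histogram"), inherits(Q, "size_histogram"))
  if (length(P$bin_edges) != length(Q$bin_edges) ||
      any(P$bin_edges != Q$bin_edges))
    stop_config("histograms must share identical bin edges")
  d <- sum(P$probs * log(P$probs / Q$probs))
  stopifnot(d > -1e-12)  # non-negativity up to rounding
  max(d, 0)
}

#' Sweep the (mutation probability x step number) grid
#'
#' The model-selection core: for every grid cell (mu, n) a colony cohort is
#' simulated through the full two-phase assay ([run_colony_cohort()]) for
#' each observed timepoint, and the Kullback-Leibler divergence
#' D(observed || simulated) is recorded on shared log2 bins; multi-timepoint
#' fits are aggregated as the unweighted mean divergence across timepoints.
#'
#' @param observed a numeric vector of observed colony sizes, or a list of
#'   such vectors (one per timepoint).
#' @param timepoint_weeks pre-incubation weeks for each element of
#'   `observed`.
#' @param mu_values,n_values grid of mutation probabilities and step counts.
#' @param calibration a [calibrate_cohort()] result fixing `p_init`, the
#'   reference `p_max` and the per-colony `p_max` sampler.
#' @param base_params a [simulation_params()] supplying the remaining model
#'   settings (death, bidirectionality, effect variability, neighbourhood,
#'   update rate).
#' @param reps simulated colonies per grid cell and timepoint.
#' @param clonogenic_days clonogenic growth duration (default 7).
#' @param seed optional integer seed.
#' @return An object of class `kl_grid`: list with `mu_values`, `n_values`,
#'   `divergence` (matrix, mu x n, nats) and `reps`.
#' @export
sweep_parameter_grid <- function(observed, timepoint_weeks, mu_values,
                                 n_values, calibration,
                                 base_params = simulation_params(),
                                 reps = 2000, clonogenic_days = 7,
                                 seed = NULL) {
  if (!is.list(observed)) observed <- list(observed)
  stopifnot(length(observed) == length(timepoint_weeks),
            all(lengths(observed) > 0), reps >= 1,
            all(mu_values >= 0 & mu_values <= 1), all(n_values >= 1),
            inherits(calibration, "cohort_calibration"))
  with_seed(seed, {
    D <- matrix(NA_real_, length(mu_values), length(n_values),
                dimnames = list(mu = mu_values, n = n_values))
    for (i in seq_along(mu_values)) {
      for (j in seq_along(n_values)) {
        par_ij <- simulation_params(
          p_init = calibration$p_init, p_max = calibration$p_max_ref,
          n_steps = n_values[j], mu = mu_values[i],
          death_prob = base_params$death_prob,
          bidirectional = base_params$bidirectional,
          effect_sd = base_params$effect_sd,
          updates_per_day = base_params$updates_per_day,
          neighborhood = base_params$neighborhood)
        kl_t <- vapply(seq_along(observed), function(t) {
          sim <- run_colony_cohort(par_ij, timepoint_weeks[t], reps,
                                   calibration$p_max_sampler,
                                   clonogenic_days = clonogenic_days)
          edges <- log2_bin_edges(c(observed[[t]], sim))
          kl_divergence(size_histogram(observed[[t]], edges),
                        size_histogram(sim, edges))
        }, numeric(1))
        D[i, j] <- mean(kl_t)
      }
    }
    structure(list(mu_values = mu_values, n_values = n_values,
                   divergence = D, reps = reps,
                   timepoint_weeks = timepoint_weeks),
              class = "kl_grid")
  })
}

#' @export
print.kl_grid <- function(x, ...) {
  cat(sprintf("kl_grid: %d mu x %d n cells, %d simulated colonies/cell\n",
              length(x$mu_values), length(x$n_values), x$reps))
  print(round(x$divergence, 4))
  best <- arrayInd(which.min(x$divergence), dim(x$divergence))
  cat(sprintf("minimum %.4f nats at mu = %g, n = %g\n", min(x$divergence),
              x$mu_values[best[1]], x$n_values[best[2]]))
  invisible(x)
}

#' @export
plot.kl_grid <- function(x, ...) {
  image(x = seq_along(x$mu_values), y = seq_along(x$n_values),
        z = log10(x$divergence), axes = FALSE,
        xlab = "mutation probability", ylab = "steps n",
        col = hcl.colors(64, "viridis", rev = TRUE),
        main = "log10 KL divergence (obs || sim)", ...)
  axis(1, at = seq_along(x$mu_values), labels = x$mu_values)
  axis(2, at = seq_along(x$n_values), labels = x$n_values)
  invisible(x)
}

#' Best-fitting region of a divergence grid
#'
#' @param grid a [sweep_parameter_grid()] result.
#' @param tolerance relative tolerance: cells within
#'   `(1 + tolerance) * min(divergence)` belong to the region.
#' @return Data frame with columns `mu`, `n`, `divergence`, ordered by
#'   divergence; the argmin cell is row 1 and also in
#'   `attr(, "argmin")`.
#' @export
best_fit_region <- function(grid, tolerance = 0.1) {
  stopifnot(inherits(grid, "kl_grid"), tolerance >= 0)
  d <- grid$divergence
  cells <- expand.grid(mu = grid$mu_values, n = grid$n_values)
  cells$divergence <- as.vector(d)
  keep <- cells$divergence <= (1 + tolerance) * min(cells$divergence)
  out <- cells[keep, , drop = FALSE]
  out <- out[order(out$divergence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "argmin") <- out[1, c("mu", "n")]
  out
}

# exact empirical CDF values of `sample` at the points `at`
ecdf_at <- function(sample, at) {
  findInterval(at, sort(sample)) / length(sample)
}

# KS distance profile over the alpha grid: for each alpha, the sup over the
# discrete support of |F_sample - (alpha F_tol + (1 - alpha) F_res)|
ks_profile <- function(F_s, F_t, F_r, alphas) {
  a <- F_s - F_r
  b <- F_t - F_r
  vapply(alphas, function(al) max(abs(a - al * b)), numeric(1))
}

#' Mixture-null test of a colony-size sample
#'
#' Tests the single-hit explanation that an observed colony-size sample is
#' a mixture of the tolerant and fully resistant reference distributions:
#' the mixing fraction alpha is fitted by minimizing the Kolmogorov-Smirnov
#' distance between the observed sample and the empirical mixture
#' alpha * F_tol + (1 - alpha) * F_res over a fine alpha grid, and the
#' p-value is obtained by parametric bootstrap from the fitted mixture
#' (each bootstrap sample refits alpha). Small p-values indicate colony
#' sizes that no tolerant/resistant mixture can produce -- the signature of
#' a gradually shifting population.
#'
#' @param observed observed colony sizes (non-empty).
#' @param tolerant_ref,resistant_ref reference samples of tolerant and fully
#'   resistant colony sizes.
#' @param n_boot number of parametric bootstrap replicates (>= 100).
#' @param alpha_step grid step for the mixing fraction (default 0.01).
#' @param seed optional integer seed.
#' @return An object of class `ks_mixture_test`: list with `alpha_hat`,
#'   `ks_stat`, `p_value`, `n_boot`.
#' @export
ks_mixture_test <- function(observed, tolerant_ref, resistant_ref,
                            n_boot = 1000, alpha_step = 0.01, seed = NULL) {
  if (!length(observed) || !length(tolerant_ref) || !length(resistant_ref))
    stop_config("all three samples must be non-empty")
  if (n_boot < 100) stop_config("n_boot must be >= 100")
  refs <- c(tolerant_ref, resistant_ref)
  if (length(unique(refs)) == 1)
    stop_config("degenerate references: all reference sizes identical")
  alphas <- seq(0, 1, by = alpha_step)
  support <- sort(unique(c(observed, refs)))
  F_t <- ecdf_at(tolerant_ref, support)
  F_r <- ecdf_at(resistant_ref, support)
  fit <- function(x) {
    prof <- ks_profile(ecdf_at(x, support), F_t, F_r, alphas)
    i <- which.min(prof)
    c(alpha = alphas[i], ks = prof[i])
  }
  obs_fit <- fit(observed)
  n_obs <- length(observed)
  tol_s <- as.numeric(tolerant_ref)
  res_s <- as.numeric(resistant_ref)
  with_seed(seed, {
    boot_ks <- vapply(seq_len(n_boot), function(b) {
      from_tol <- runif(n_obs) < obs_fit[["alpha"]]
      x <- numeric(n_obs)
      if (any(from_tol))
        x[from_tol] <- sample(tol_s, sum(from_tol), replace = TRUE)
      if (any(!from_tol))
        x[!from_tol] <- sample(res_s, sum(!from_tol), replace = TRUE)
      fit(x)[["ks"]]
    }, numeric(1))
    p <- (1 + sum(boot_ks >= obs_fit[["ks"]] - 1e-12)) / (1 + n_boot)
    structure(list(alpha_hat = obs_fit[["alpha"]],
                   ks_stat = obs_fit[["ks"]],
                   p_value = p, n_boot = n_boot,
                   n_observed = n_obs),
              class = "ks_mixture_test")
  })
}

#' @export
print.ks_mixture_test <- function(x, ...) {
  cat("Kolmogorov-Smirnov test of the tolerant/resistant mixture null\n")
  cat(sprintf("  fitted tolerant fraction alpha = %.2f\n", x$alpha_hat))
  cat(sprintf("  KS distance D = %.4f (n = %d)\n", x$ks_stat, x$n_observed))
  cat(sprintf("  bootstrap p-value = %.4g (%d replicates)\n", x$p_value,
              x$n_boot))
  if (x$p_value < 0.05)
    cat("  -> mixture null rejected: sizes not explainable by mixed\n",
        "    sampling from the tolerant and resistant references\n")
  invisible(x)
}

#' Normalized clonogenic fraction
#'
#' Fraction of seeded cells forming colonies at or above the scoring
#' threshold, normalized to the vehicle (DMSO) control:
#' `(#treated >= min_size / seeded_treated) / (#dmso >= min_size / seeded_dmso)`.
#' The default threshold of 5 cells corresponds to the macroscopic-colony
#' cutoff used when scoring fluorescent colony area.
#'
#' @param treated_sizes,dmso_sizes per-colony sizes (cells) in the treated
#'   and control wells.
#' @param seeded_treated,seeded_dmso cells seeded (> 0).
#' @param min_size scoring threshold in cells (colonies of exactly
#'   `min_size` count).
#' @return Normalized clonogenic survival (dimensionless).
#' @export
clonogenic_fraction <- function(treated_sizes, seeded_treated, dmso_sizes,
                                seeded_dmso, min_size = 5) {
  if (seeded_treated <= 0 || seeded_dmso <= 0)
    stop_config("seeded counts must be > 0")
  n_dmso <- sum(dmso_sizes >= min_size)
  if (n_dmso == 0)
    stop_config("no DMSO colonies above threshold: normalization undefined")
  (sum(treated_sizes >= min_size) / seeded_treated) / (n_dmso / seeded_dmso)
}
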