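#' Specify a synthetic colony-size population
#'
#' Describes the distribution of per-colony sizes (in cells) for one
#' condition/timepoint as a lognormal or a finite mixture of lognormals.
#' A mixture with well-separated components emulates the bimodal
#' tolerant/resistant picture expected under a single-hit transition; a
#' single component with drifting `meanlog` emulates a gradually shifting
#' population.
#'
#' @param name label for the population (condition/timepoint).
#' @param meanlog,sdlog numeric vectors (one entry per mixture component)
#'   of lognormal parameters on the log-cells scale.
#' @param weights mixture weights, one per component; must sum to 1.
#'   Defaults to a single component.
#' @param min_size smallest admissible colony size in cells (>= 1); draws
#'   below it are clipped up.
#' @return An object of class `colony_population_spec`.
#' @seealso [generate_colony_sizes()]
#' @export
colony_population_spec <- function(name, meanlog, sdlog, weights = NULL,
                                   min_size = 1) {
  if (is.null(weights)) weights <- rep(1 / length(meanlog), length(meanlog))
  if (length(meanlog) != length(sdlog) || length(meanlog) != length(weights))
    stop_config("meanlog, sdlog and weights must have equal length")
  if (abs(sum(weights) - 1) > 1e-9)
    stop_config("mixture weights must sum to 1")
  if (any(weights < 0)) stop_config("mixture weights must be non-negative")
  if (any(sdlog < 0)) stop_config("sdlog must be >= 0")
  if (min_size < 1) stop_config("min_size must be >= 1")
  structure(list(name = as.character(name), meanlog = as.numeric(meanlog),
                 sdlog = as.numeric(sdlog), weights = as.numeric(weights),
                 min_size = min_size),
            class = "colony_population_spec")
}

#' Generate per-colony sizes
#'
#' Draws `n` colony sizes from the (mixture of) lognormal distribution(s) in
#' `spec`, rounds half-up to whole cells and clips at `spec$min_size`.
#'
#' @param spec a [colony_population_spec()].
#' @param n number of colonies (>= 0).
#' @param seed optional integer seed; identical `(spec, n, seed)` gives
#'   identical output.
#' @return Integer vector of colony sizes (cells).
#' @export
generate_colony_sizes <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "colony_population_spec"), n >= 0)
  with_seed(seed, {
    if (n == 0) return(integer(0))
    comp <- sample.int(length(spec$weights), n, replace = TRUE,
                       prob = spec$weights)
    x <- rlnorm(n, meanlog = spec$meanlog[comp], sdlog = spec$sdlog[comp])
    as.integer(pmax(spec$min_size, round_half_up(x)))
  })
}

#' Simulate limiting-dilution plates under single-hit kinetics
#'
#' For each seeding density d (each top density followed by `n_twofold_dilutions`
#' two-fold dilutions, `wells_per_density` wells each) the number of negative
#' wells is Binomial(wells, (1 - per_cell_freq)^d): a well stays negative only
#' if none of its d seeded cells initiates a resistant colony.
#'
#' The defaults reproduce the assay layout used for frequency estimation:
#' one top density of 400 cells/well plus five two-fold dilutions, 10 wells
#' per density.
#'
#' @param per_cell_freq per-cell probability of being a resistance-initiating
#'   cell, in (0, 1].
#' @param top_densities vector of top seeding densities (cells/well).
#' @param n_twofold_dilutions number of additional two-fold dilutions.
#' @param wells_per_density wells at each density.
#' @param seed optional integer seed.
#' @return A data frame of class `ld_plate` with columns
#'   `dose_cells_per_well`, `wells_total`, `wells_negative`.
#' @export
generate_limiting_dilution_plates <- function(per_cell_freq,
                                              top_densities = 400,
                                              n_twofold_dilutions = 5,
                                              wells_per_density = 10,
                                              seed = NULL) {
  if (!is.numeric(per_cell_freq) || per_cell_freq <= 0 || per_cell_freq > 1)
    stop_config("per_cell_freq must be in (0, 1]")
  stopifnot(all(top_densities > 0), n_twofold_dilutions >= 0,
            wells_per_density >= 1)
  doses <- unlist(lapply(top_densities,
                         function(d0) d0 / 2^(0:n_twofold_dilutions)))
  with_seed(seed, {
    p_neg <- (1 - per_cell_freq)^doses
    neg <- rbinom(length(doses), size = wells_per_density, prob = p_neg)
    out <- data.frame(dose_cells_per_well = doses,
                      wells_total = wells_per_density,
                      wells_negative = neg)
    attr(out, "per_cell_freq") <- per_cell_freq
    class(out) <- c("ld_plate", "data.frame")
    out
  })
}

#' Specify a synthetic clone-tracing (barcode) experiment
#'
#' Emulates a lentiviral-barcode experiment: a barcoded population is split
#' into baseline aliquots and replicate cultures per drug condition; within
#' each condition a fixed set of pre-existing clones expands (clone identity
#' fixed before treatment, growth factors resampled per replicate), and each
#' sample is sequenced to a fixed read depth. Defaults mirror a quadruplicate
#' design with two baseline aliquots.
#'
#' @param n_barcodes number of distinct barcodes in the library.
#' @param baseline_meanlog,baseline_sdlog lognormal parameters for baseline
#'   clone abundances.
#' @param n_conditions number of drug conditions.
#' @param n_replicates_per_condition replicate cultures per condition.
#' @param expanded_fraction fraction of barcodes under positive selection
#'   per condition (0-1).
#' @param selection_overlap fraction of each condition's expanded set shared
#'   across all conditions (0-1).
#' @param growth_meanlog,growth_sdlog lognormal parameters of the clone
#'   expansion factor.
#' @param sequencing_depth reads per sample (> 0).
#' @return An object of class `barcode_sim_spec`.
#' @export
barcode_sim_spec <- function(n_barcodes = 5000,
                             baseline_meanlog = 0, baseline_sdlog = 0.4,
                             n_conditions = 3,
                             n_replicates_per_condition = 4,
                             expanded_fraction = 0.01,
                             selection_overlap = 0,
                             growth_meanlog = 3, growth_sdlog = 0.5,
                             sequencing_depth = 5e5) {
  if (expanded_fraction < 0 || expanded_fraction > 1)
    stop_config("expanded_fraction must be in [0, 1]")
  if (selection_overlap < 0 || selection_overlap > 1)
    stop_config("selection_overlap must be in [0, 1]")
  if (sequencing_depth <= 0) stop_config("sequencing_depth must be > 0")
  stopifnot(n_barcodes >= 1, n_conditions >= 1,
            n_replicates_per_condition >= 1, baseline_sdlog >= 0,
            growth_sdlog >= 0)
  structure(as.list(environment()), class = "barcode_sim_spec")
}

#' Generate a synthetic barcode count table
#'
#' @param spec a [barcode_sim_spec()].
#' @param seed optional integer seed.
#' @return A `barcode_table`: integer count matrix (barcodes x samples) with
#'   two baseline samples plus one column per condition x replicate; sample
#'   roles in `attr(, "roles")` and the planted expanded barcode sets per
#'   condition in `attr(, "truth")`.
#' @export
generate_barcode_experiment <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "barcode_sim_spec"))
  with_seed(seed, {
    nb <- spec$n_barcodes
    ids <- sprintf("bc%05d", seq_len(nb))
    w0 <- rlnorm(nb, spec$baseline_meanlog, spec$baseline_sdlog)
    m <- max(0L, round(spec$expanded_fraction * nb))
    n_shared <- round(spec$selection_overlap * m)
    shared <- if (n_shared > 0) sample.int(nb, n_shared) else integer(0)
    pool <- setdiff(seq_len(nb), shared)
    expanded <- lapply(seq_len(spec$n_conditions), function(j) {
      extra <- if (m - n_shared > 0) sample(pool, m - n_shared) else integer(0)
      sort(c(shared, extra))
    })
    names(expanded) <- sprintf("cond%d", seq_len(spec$n_conditions))

    draw_sample <- function(w) {
      as.integer(rmultinom(1, size = spec$sequencing_depth, prob = w / sum(w)))
    }
    cols <- list(baseline_1 = draw_sample(w0), baseline_2 = draw_sample(w0))
    roles <- c("baseline", "baseline")
    for (j in seq_len(spec$n_conditions)) {
      for (r in seq_len(spec$n_replicates_per_condition)) {
        w <- w0
        idx <- expanded[[j]]
        if (length(idx))
          w[idx] <- w[idx] * rlnorm(length(idx), spec$growth_meanlog,
                                    spec$growth_sdlog)
        cols[[sprintf("cond%d_rep%d", j, r)]] <- draw_sample(w)
        roles <- c(roles, sprintf("cond%d", j))
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- ids
    barcode_table(counts, roles = roles, truth = expanded)
  })
}

#' Ground truth for a synthetic viability plate
#'
#' Parameters of the four-parameter dose-response curve
#' y(x) = b + (100 - b) / (1 + (x / IC50)^k) used to generate luminescence
#' signal, plus plate nuisance parameters.
#'
#' @param b bottom-plateau viability in percent (0-100), the viability as
#'   drug concentration grows without bound.
#' @param k hill slope.
#' @param ic50 half-maximal inhibitory concentration (> 0), same units as
#'   the dose series.
#' @param noise_cv multiplicative noise coefficient of variation (>= 0).
#' @param background empty-well luminescence (arbitrary units).
#' @param scale luminescence corresponding to 100% viability, above
#'   background.
#' @return An object of class `dose_response_truth`.
#' @export
dose_response_truth <- function(b = 20, k = 1.5, ic50 = 100, noise_cv = 0.1,
                                background = 500, scale = 1e4) {
  if (ic50 <= 0) stop_config("ic50 must be > 0")
  if (noise_cv < 0) stop_config("noise_cv must be >= 0")
  if (b < 0 || b > 100) stop_config("b must be in [0, 100]")
  stopifnot(scale > 0, background >= 0)
  structure(as.list(environment()), class = "dose_response_truth")
}

# the four-parameter logistic viability curve (percent)
dr_curve <- function(x, b, k, ic50) b + (100 - b) / (1 + (x / ic50)^k)

#' Generate a synthetic luminescence viability plate
#'
#' Simulates raw luminescence: drug wells read
#' `background + scale * y(x)/100 * (1 + eps)` with
#' `eps ~ Normal(0, noise_cv)`; DMSO (zero-dose) wells sit at 100% viability
#' and empty wells at `background * (1 + eps)`. A zero-dose column and empty
#' wells are always included.
#'
#' @param truth a [dose_response_truth()].
#' @param concentrations positive drug concentrations.
#' @param n_replicates replicate wells per concentration (and per control).
#' @param seed optional integer seed.
#' @return A data frame of class `luminescence_plate` with columns `role`
#'   ("drug", "dmso", "empty"), `concentration`, `replicate`, `signal`.
#' @export
generate_dose_response_plate <- function(truth,
                                         concentrations = 10^seq(0, 3.5,
                                                                 length.out = 8),
                                         n_replicates = 3, seed = NULL) {
  stopifnot(inherits(truth, "dose_response_truth"), all(concentrations > 0),
            n_replicates >= 1)
  with_seed(seed, {
    conc <- rep(c(0, concentrations), each = n_replicates)
    role <- rep(c("dmso", rep("drug", length(concentrations))),
                each = n_replicates)
    y <- dr_curve(conc, truth$b, truth$k, truth$ic50)  # x = 0 gives 100
    eps <- if (truth$noise_cv > 0) rnorm(length(y), 0, truth$noise_cv) else 0
    signal <- truth$background + truth$scale * y / 100 * (1 + eps)
    eps_e <- if (truth$noise_cv > 0) rnorm(n_replicates, 0, truth$noise_cv)
             else rep(0, n_replicates)
    out <- data.frame(
      role = c(role, rep("empty", n_replicates)),
      concentration = c(conc, rep(NA_real_, n_replicates)),
      replicate = c(rep(seq_len(n_replicates), length(concentrations) + 1),
                    seq_len(n_replicates)),
      signal = c(signal, truth$background * (1 + eps_e)))
    class(out) <- c("luminescence_plate", "data.frame")
    out
  })
}
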