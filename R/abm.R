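#' Parameters of the lattice colony-growth model
#'
#' Bundles the agent-based model parameters. Cells carry a step index
#' k in 0..n_steps; a cell at step k divides per update with probability
#' p(k) = p_init + k * (p_max - p_init) / n_steps, so p(0) = p_init and
#' p(n_steps) = p_max exactly, each (epi)mutational step contributing a
#' fractional increment of the single tolerant-to-resistant transition.
#' At every division each daughter independently gains one step with
#' probability `mu` (capped at `n_steps`; with `bidirectional = TRUE` the
#' change is +1 or -1 with equal odds, floored at 0).
#'
#' @param p_init division probability per update of an unmutated (step-0)
#'   cell, in `[0, 1]`.
#' @param p_max division probability per update of a fully resistant cell;
#'   must satisfy `p_init <= p_max <= 1`.
#' @param n_steps number of (epi)mutational steps separating tolerance from
#'   full resistance (1-300 is the grid explored by the model selection).
#' @param mu per-daughter, per-division probability of gaining one step.
#' @param death_prob per-update death probability (default 0).
#' @param bidirectional if `TRUE`, mutational steps may also decrement.
#' @param effect_sd relative spread of per-step fitness increments; 0 means
#'   deterministic equal increments.
#' @param updates_per_day lattice update rounds per day of wall-clock
#'   culture time (default 2, so p = 1 approximates a ~12 h minimum cycle).
#' @param neighborhood `"moore"` (8 neighbours, default) or `"vonneumann"`
#'   (4 neighbours).
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(p_init = 0.3, p_max = 0.9, n_steps = 30,
                              mu = 0.05, death_prob = 0,
                              bidirectional = FALSE, effect_sd = 0,
                              updates_per_day = 2,
                              neighborhood = c("moore", "vonneumann")) {
  neighborhood <- match.arg(neighborhood)
  if (p_init < 0 || p_max > 1 || p_init > p_max)
    stop_config("need 0 <= p_init <= p_max <= 1")
  if (n_steps < 1) stop_config("n_steps must be >= 1")
  if (mu < 0 || mu > 1) stop_config("mu must be in [0, 1]")
  if (death_prob < 0 || death_prob >= 1)
    stop_config("death_prob must be in [0, 1)")
  stopifnot(effect_sd >= 0, updates_per_day >= 1)
  structure(list(p_init = p_init, p_max = p_max, n_steps = as.integer(n_steps),
                 mu = mu, death_prob = death_prob,
                 bidirectional = bidirectional, effect_sd = effect_sd,
                 updates_per_day = as.integer(updates_per_day),
                 neighborhood = neighborhood),
            class = "simulation_params")
}

#' @export
print.simulation_params <- function(x, ...) {
  cat("Lattice colony-growth parameters\n")
  cat(sprintf("  division probability: %.3g (step 0) -> %.3g (step %d)\n",
              x$p_init, x$p_max, x$n_steps))
  cat(sprintf("  mutation probability per daughter: %.3g%s\n", x$mu,
              if (x$bidirectional) " (bidirectional)" else ""))
  if (x$death_prob > 0)
    cat(sprintf("  death probability per update: %.3g\n", x$death_prob))
  if (x$effect_sd > 0)
    cat(sprintf("  per-step effect variability (relative sd): %.3g\n",
                x$effect_sd))
  cat(sprintf("  %s neighbourhood, %d updates/day\n", x$neighborhood,
              x$updates_per_day))
  invisible(x)
}

# parameter list consumed by the C++ engine
cpp_params <- function(params, p_max = NULL) {
  list(p_init = params$p_init,
       p_max = if (is.null(p_max)) params$p_max else p_max,
       n_steps = params$n_steps, mu = params$mu,
       death_prob = params$death_prob, bidirectional = params$bidirectional,
       effect_sd = params$effect_sd, moore = params$neighborhood == "moore")
}

# smallest safe odd lattice side for t updates from a central founder:
# the bounding box grows by at most 4 sites per update (invariant), so
# 4t + 5 leaves a one-site safety margin to the absorbing boundary
auto_lattice_side <- function(n_updates, cap = 401) {
  as.integer(min(cap, 4 * n_updates + 5))
}

#' Create a lattice state
#'
#' An explicit lattice holding at most one cell per site; empty sites are
#' `NA`, occupied sites hold the cell's step index. Used with
#' [step_lattice()] for inspecting the update rule directly;
#' [simulate_colony()] manages its own lattice.
#'
#' @param width,height lattice dimensions in sites.
#' @param cells optional data frame with columns `x`, `y` (1-based site
#'   coordinates) and `step` giving initial occupants.
#' @param periodic wrap around the boundary instead of treating it as a
#'   wall.
#' @return An object of class `lattice_state`.
#' @export
lattice_state <- function(width = 401, height = 401, cells = NULL,
                          periodic = FALSE) {
  steps <- matrix(NA_integer_, nrow = width, ncol = height)
  if (!is.null(cells)) {
    stopifnot(all(c("x", "y", "step") %in% names(cells)),
              all(cells$x >= 1 & cells$x <= width),
              all(cells$y >= 1 & cells$y <= height))
    ij <- cbind(cells$x, cells$y)
    if (anyDuplicated(ij)) stop_config("one cell per site")
    steps[ij] <- as.integer(cells$step)
  }
  structure(list(steps = steps, periodic = periodic), class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("lattice_state: %d x %d sites, %d cells%s\n", nrow(x$steps),
              ncol(x$steps), sum(!is.na(x$steps)),
              if (x$periodic) ", periodic" else ""))
  invisible(x)
}

#' Advance a lattice state by update rounds
#'
#' Applies the asynchronous update rule: each living cell, visited in a
#' freshly randomized order each round, first survives a death check, then
#' with probability p(k) attempts division. Division succeeds if an empty
#' site lies among the cell's neighbours, or among neighbours-of-neighbours
#' reachable by pushing exactly one intervening cell one site outward; the
#' daughter site and any displacement direction are chosen uniformly among
#' the admissible options. Each daughter then mutates independently with
#' probability `mu`. A fully enclosed cell simply does not divide.
#'
#' @param state a [lattice_state()].
#' @param params a [simulation_params()].
#' @param n_rounds number of update rounds.
#' @param seed optional integer seed.
#' @return The updated `lattice_state`.
#' @export
step_lattice <- function(state, params, n_rounds = 1, seed = NULL) {
  stopifnot(inherits(state, "lattice_state"),
            inherits(params, "simulation_params"), n_rounds >= 0)
  if (n_rounds == 0) return(state)
  steps <- state$steps
  stopifnot(all(steps >= 0 & steps <= params$n_steps, na.rm = TRUE))
  state$steps <- with_seed(seed,
    abm_step_matrix_cpp(steps, cpp_params(params), as.integer(n_rounds),
                        state$periodic))
  state
}

#' Simulate a single colony
#'
#' Grows one colony from a central founder for `n_updates` rounds on a
#' lattice sized so the colony cannot reach the boundary (boundary contact
#' raises an error when `lattice_size` is forced too small).
#'
#' @param params a [simulation_params()].
#' @param n_updates number of update rounds.
#' @param founder_step step index of the founding cell (0..n_steps).
#' @param lattice_size side of the square lattice; `NULL` (default) sizes it
#'   automatically from the geometric growth bound.
#' @param seed optional integer seed.
#' @return An object of class `colony_sim`: list with `final_size`,
#'   `size_trajectory` (size after each update, starting at 1),
#'   `step_index_histogram` (named counts for k = 0..n_steps) and
#'   `bbox_side` (bounding-box side, always <= 1 + 4 * n_updates).
#' @export
simulate_colony <- function(params, n_updates, founder_step = 0,
                            lattice_size = NULL, seed = NULL) {
  stopifnot(inherits(params, "simulation_params"), n_updates >= 0,
            founder_step >= 0, founder_step <= params$n_steps)
  side <- if (is.null(lattice_size)) auto_lattice_side(n_updates, Inf)
          else as.integer(lattice_size)
  res <- with_seed(seed,
    abm_simulate_colony_cpp(as.integer(founder_step), cpp_params(params),
                            as.integer(n_updates), side, TRUE))
  names(res$step_index_histogram) <- 0:params$n_steps
  res$n_updates <- n_updates
  res$params <- params
  structure(res, class = "colony_sim")
}

#' @export
print.colony_sim <- function(x, ...) {
  cat(sprintf("colony_sim: %d cells after %d updates (bounding box %d)\n",
              x$final_size, x$n_updates, x$bbox_side))
  invisible(x)
}

#' Naive reference simulator for one colony (validation aid)
#'
#' An intentionally simple, structurally independent implementation of the
#' same growth rules (fixed division probability, no mutation, no death),
#' used to validate [simulate_colony()] distributionally. Not meant for
#' production-scale runs.
#'
#' @param p fixed division probability per update.
#' @param n_updates number of update rounds.
#' @param lattice_size side of the square lattice (`NULL` = automatic).
#' @param seed optional integer seed.
#' @return Final colony size (cells).
#' @export
simulate_colony_reference <- function(p, n_updates, lattice_size = NULL,
                                      seed = NULL) {
  stopifnot(p >= 0, p <= 1, n_updates >= 0)
  side <- if (is.null(lattice_size)) auto_lattice_side(n_updates, Inf)
          else as.integer(lattice_size)
  with_seed(seed, oracle_colony_cpp(p, as.integer(n_updates), side))
}

#' Simulate a mutation-free cohort at fixed division rates
#'
#' Grows one colony per entry of `p`, each at a constant division
#' probability (no mutation, no death), for `n_updates` rounds. This is how
#' reference colony populations are produced: tolerant references at a
#' single low rate, resistant references at per-colony rates sampled from
#' the resistant growth distribution.
#'
#' @param p vector of division probabilities, one colony each.
#' @param n_updates number of update rounds.
#' @param neighborhood `"moore"` or `"vonneumann"`.
#' @param seed optional integer seed.
#' @return Integer vector of final colony sizes.
#' @export
simulate_fixed_rate_cohort <- function(p, n_updates,
                                       neighborhood = c("moore", "vonneumann"),
                                       seed = NULL) {
  neighborhood <- match.arg(neighborhood)
  stopifnot(all(p >= 0 & p <= 1), n_updates >= 0)
  par <- list(p_init = 0, p_max = 1, n_steps = 1L, mu = 0, death_prob = 0,
              bidirectional = FALSE, effect_sd = 0,
              moore = neighborhood == "moore")
  with_seed(seed,
    abm_simulate_cohort_cpp(rep(1L, length(p)), as.numeric(p), par,
                            as.integer(n_updates),
                            auto_lattice_side(n_updates, Inf)))
}

#' Simulate the pre-incubation phase (well-mixed)
#'
#' Models the drug-exposure phase preceding the clonogenic assay as a
#' well-mixed branching population: per update each cell dies with
#' `death_prob`, else divides with p(k); both daughters of a division
#' independently mutate with probability `mu`. Whenever the population
#' exceeds `ceiling` it is randomly down-sampled to `n_cells`, mimicking
#' re-plating. Spatial structure is deliberately ignored for this phase
#' (the culture is dense and repeatedly re-plated); colony-level spatial
#' competition is modelled in the clonogenic phase.
#'
#' @param params a [simulation_params()].
#' @param duration_days duration of exposure in days (>= 0); update rounds
#'   are `duration_days * params$updates_per_day`.
#' @param n_cells starting population size, and the size re-plated to when
#'   the ceiling is exceeded.
#' @param ceiling population ceiling that triggers down-sampling.
#' @param seed optional integer seed.
#' @return Named numeric vector of proportions over step indices 0..n_steps.
#' @export
simulate_preincubation <- function(params, duration_days, n_cells = 1e4,
                                   ceiling = 1e5, seed = NULL) {
  stopifnot(inherits(params, "simulation_params"), duration_days >= 0,
            n_cells >= 1, ceiling >= n_cells)
  ns <- params$n_steps
  p_k <- params$p_init + (0:ns) * (params$p_max - params$p_init) / ns
  with_seed(seed, {
    counts <- c(n_cells, rep(0, ns))  # all cells start unmutated
    n_updates <- round(duration_days * params$updates_per_day)
    for (t in seq_len(n_updates)) {
      if (params$death_prob > 0) {
        dead <- rbinom(ns + 1, counts, params$death_prob)
        counts <- counts - dead
      }
      div <- rbinom(ns + 1, counts, p_k)
      daughters <- 2 * div
      mut <- rbinom(ns + 1, daughters, params$mu)
      if (params$bidirectional) {
        up <- rbinom(ns + 1, mut, 0.5)
        down <- mut - up
      } else {
        up <- mut
        down <- rep(0, ns + 1)
      }
      # cap at n_steps, floor at 0: boundary moves stay in place
      up[ns + 1] <- 0
      down[1] <- 0
      stay <- counts - div + daughters - up - down
      counts <- stay
      counts[-1] <- counts[-1] + up[-(ns + 1)]
      counts[-(ns + 1)] <- counts[-(ns + 1)] + down[-1]
      if (sum(counts) > ceiling) {
        counts <- as.numeric(rmultinom(1, n_cells, counts / sum(counts)))
      }
    }
    total <- sum(counts)
    if (total == 0) stop("population went extinct during pre-incubation")
    setNames(counts / total, 0:ns)
  })
}

#' Simulate a cohort of clonogenic colonies
#'
#' Reproduces the full two-phase assay in silico: founder step indices are
#' drawn from the population distribution after `preincubation_weeks` of
#' well-mixed growth under drug ([simulate_preincubation()]), each colony
#' receives its own maximal division probability from `p_max_sampler`
#' (reflecting between-colony variability of fully resistant growth), and
#' each founder is then grown on its own lattice for
#' `clonogenic_days * updates_per_day` rounds.
#'
#' @param params a [simulation_params()]; `params$p_max` is the reference
#'   maximal probability used for the shared pre-incubation phase.
#' @param preincubation_weeks weeks of drug exposure before plating (0 gives
#'   all founders at step 0).
#' @param n_colonies number of colonies to simulate.
#' @param p_max_sampler function of `n` returning per-colony maximal division
#'   probabilities in `[p_init, 1]`; defaults to the constant `params$p_max`.
#'   Values below `p_init` are clamped up with a warning.
#' @param clonogenic_days duration of the clonogenic growth phase (default 7).
#' @param preincubation_cells population size for the well-mixed phase.
#' @param seed optional integer seed.
#' @return Integer vector of per-colony final sizes, with the founder step
#'   indices in `attr(, "founder_steps")`.
#' @export
run_colony_cohort <- function(params, preincubation_weeks, n_colonies,
                              p_max_sampler = NULL, clonogenic_days = 7,
                              preincubation_cells = 1e4, seed = NULL) {
  stopifnot(inherits(params, "simulation_params"), preincubation_weeks >= 0,
            n_colonies >= 0)
  if (n_colonies == 0) return(integer(0))
  if (is.null(p_max_sampler))
    p_max_sampler <- function(n) rep(params$p_max, n)
  with_seed(seed, {
    dist <- simulate_preincubation(params, preincubation_weeks * 7,
                                   n_cells = preincubation_cells)
    founder <- sample(0:params$n_steps, n_colonies, replace = TRUE,
                      prob = dist)
    p_max <- p_max_sampler(n_colonies)
    if (any(p_max > 1)) stop_config("p_max_sampler returned values > 1")
    if (any(p_max < params$p_init)) {
      warning("p_max draws below p_init clamped up to p_init")
      p_max <- pmax(p_max, params$p_init)
    }
    n_updates <- as.integer(clonogenic_days * params$updates_per_day)
    sizes <- abm_simulate_cohort_cpp(as.integer(founder), as.numeric(p_max),
                                     cpp_params(params), n_updates,
                                     auto_lattice_side(n_updates, Inf))
    attr(sizes, "founder_steps") <- founder
    sizes
  })
}
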