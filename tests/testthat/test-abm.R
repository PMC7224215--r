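test_that("parameter constructor enforces invariants", {
  expect_error(simulation_params(p_init = 0.5, p_max = 0.4), "p_init")
  expect_error(simulation_params(n_steps = 0), "n_steps")
  expect_error(simulation_params(mu = 1.5), "mu")
  expect_error(simulation_params(death_prob = 1), "death_prob")
  p <- simulation_params(p_init = 0.2, p_max = 0.8, n_steps = 4)
  # endpoint exactness of the step -> probability interpolation
  pk <- p$p_init + (0:4) * (p$p_max - p$p_init) / 4
  expect_identical(pk[1], 0.2)
  expect_identical(pk[5], 0.8)
  expect_true(all(diff(pk) > 0))
})

test_that("single update round follows the division rule", {
  # forced division with space: one cell becomes two
  st <- lattice_state(9, 9, cells = data.frame(x = 5, y = 5, step = 0))
  p1 <- simulation_params(p_init = 1, p_max = 1, n_steps = 1, mu = 0)
  out <- step_lattice(st, p1, seed = 1)
  expect_equal(sum(!is.na(out$steps)), 2)

  # zero division probability: state unchanged
  p0 <- simulation_params(p_init = 0, p_max = 0, n_steps = 1, mu = 0)
  out0 <- step_lattice(st, p0, seed = 1)
  expect_identical(out0$steps, st$steps)

  # fully occupied periodic lattice: nowhere to go, no divisions
  full <- expand.grid(x = 1:6, y = 1:6)
  full$step <- 0
  stf <- lattice_state(6, 6, cells = full, periodic = TRUE)
  outf <- step_lattice(stf, p1, seed = 2)
  expect_equal(sum(!is.na(outf$steps)), 36)
})

test_that("colony simulation honours growth bounds and determinism", {
  p1 <- simulation_params(p_init = 1, p_max = 1, n_steps = 1, mu = 0)
  expect_equal(simulate_colony(p1, 0, seed = 1)$final_size, 1)

  # with at most 8 cells a divider always has a reachable empty site, so
  # three forced-division rounds give exactly 8 cells
  for (s in 1:12)
    expect_equal(simulate_colony(p1, 3, seed = s)$final_size, 8)

  p <- simulation_params(p_init = 0.55, p_max = 0.9, n_steps = 5, mu = 0.1)
  a <- simulate_colony(p, 12, seed = 33)
  b <- simulate_colony(p, 12, seed = 33)
  expect_identical(a$size_trajectory, b$size_trajectory)
  expect_identical(a$step_index_histogram, b$step_index_histogram)
  # geometric and population bounds
  expect_lte(a$bbox_side, 1 + 4 * 12)
  expect_lte(a$final_size, 2^12)
  expect_true(all(diff(a$size_trajectory) >= 0))  # no deaths configured
  # step indices stay inside [0, n_steps]
  expect_equal(sum(a$step_index_histogram), a$final_size)
  expect_named(a$step_index_histogram, as.character(0:5))

  # a lattice forced too small errors out on boundary contact
  expect_error(simulate_colony(p1, 4, lattice_size = 5, seed = 1),
               "boundary")
})

test_that("main simulator matches the naive reference implementation", {
  set.seed(101)
  n <- 300
  main <- simulate_fixed_rate_cohort(rep(0.6, n), 10)
  ref <- vapply(seq_len(n), function(i) simulate_colony_reference(0.6, 10),
                integer(1))
  expect_gt(suppressWarnings(stats::ks.test(main, ref)$p.value), 0.01)
})

test_that("well-mixed pre-incubation matches exhaustive lineage logic", {
  p <- simulation_params(p_init = 0.4, p_max = 0.9, n_steps = 10, mu = 0.05)
  d0 <- simulate_preincubation(p, 0, seed = 1)
  expect_equal(unname(d0[1]), 1)  # week 0: everything at step 0

  pmu0 <- simulation_params(p_init = 0.4, p_max = 0.9, n_steps = 10, mu = 0)
  d <- simulate_preincubation(pmu0, 14, seed = 2)
  expect_equal(unname(d[1]), 1)  # no mutation: nothing ever advances

  # mu = 1, p = 1: every cell divides every update and every daughter
  # mutates, so after t updates every lineage tip sits at step min(t, 3)
  pfast <- simulation_params(p_init = 1, p_max = 1, n_steps = 3, mu = 1)
  for (t in 1:4) {
    dt <- simulate_preincubation(pfast, t / 2, n_cells = 64, seed = 3)
    expect_equal(unname(dt[as.character(min(t, 3))]), 1)
  }
})

test_that("cohorts reflect pre-incubation history", {
  expect_identical(run_colony_cohort(simulation_params(), 0, 0), integer(0))

  # without mutation, pre-incubation cannot matter: week-0 cohort is
  # indistinguishable from direct growth at p_init
  pmu0 <- simulation_params(p_init = 0.45, p_max = 0.9, n_steps = 5, mu = 0)
  ok <- vapply(1:10, function(s) {
    coh <- run_colony_cohort(pmu0, 0, 400, seed = s)
    ref <- simulate_fixed_rate_cohort(rep(0.45, 400), 14, seed = s + 1000)
    suppressWarnings(stats::ks.test(coh, ref)$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.8)

  # with mutation, longer drug exposure yields larger colonies
  p <- simulation_params(p_init = 0.3, p_max = 0.9, n_steps = 10, mu = 0.05)
  m0 <- median(run_colony_cohort(p, 0, 500, seed = 7))
  m3 <- median(run_colony_cohort(p, 3, 500, seed = 8))
  expect_gt(m3, m0)
})

test_that("cohort seeding is reproducible and p_max draws are validated", {
  p <- simulation_params()
  a <- run_colony_cohort(p, 1, 50, seed = 5)
  b <- run_colony_cohort(p, 1, 50, seed = 5)
  expect_identical(as.integer(a), as.integer(b))
  expect_identical(attr(a, "founder_steps"), attr(b, "founder_steps"))
  expect_warning(
    run_colony_cohort(p, 0, 10, p_max_sampler = function(n) rep(0.1, n),
                      seed = 1),
    "clamped")
  expect_error(
    run_colony_cohort(p, 0, 10, p_max_sampler = function(n) rep(1.2, n),
                      seed = 1),
    "> 1")
})

test_that("death and bidirectional variants stay within model bounds", {
  p <- simulation_params(p_init = 0.6, p_max = 0.9, n_steps = 4, mu = 0.3,
                         death_prob = 0.1, bidirectional = TRUE)
  sim <- simulate_colony(p, 10, seed = 21)
  expect_true(all(sim$step_index_histogram >= 0))
  expect_equal(sum(sim$step_index_histogram), sim$final_size)
  expect_lte(sim$bbox_side, 1 + 4 * 10)
  # effect-size variability runs and respects the same structural bounds
  pv <- simulation_params(p_init = 0.4, p_max = 0.9, n_steps = 5, mu = 0.2,
                          effect_sd = 0.5)
  simv <- simulate_colony(pv, 8, seed = 22)
  expect_lte(simv$final_size, 2^8)
})
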