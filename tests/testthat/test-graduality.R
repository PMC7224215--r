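test_that("size histograms normalize and cover the data", {
  h <- size_histogram(rep(8L, 50))
  expect_equal(sum(h$probs), 1)
  expect_equal(max(h$counts), 50)   # all mass in one bin
  expect_equal(sum(h$counts), 50)
  expect_true(all(h$probs > 0))     # pseudocount everywhere
  expect_error(size_histogram(integer(0)), "non-empty")
  expect_error(size_histogram(c(1, 5), edges = c(2, 4)), "span")
})

test_that("histogram frequencies match known cell probabilities", {
  # discretized distribution on sizes 1, 2, 4, 8 landing in distinct bins
  probs <- c(0.4, 0.3, 0.2, 0.1)
  set.seed(1)
  x <- sample(c(1L, 2L, 4L, 8L), 1e5, replace = TRUE, prob = probs)
  h <- size_histogram(x, edges = c(0.5, 1, 2, 4, 8), pseudocount = 0)
  se <- sqrt(probs * (1 - probs) / 1e5)
  expect_true(all(abs(h$probs - probs) < 3 * se))
})

test_that("KL divergence has the right identity, value and asymmetry", {
  x <- c(rep(1L, 30), rep(4L, 20))
  h <- size_histogram(x)
  expect_identical(kl_divergence(h, h), 0)

  # closed form: P = (1, 0), Q = (0.5, 0.5) gives ln 2 as pseudocount -> 0
  edges <- c(0.5, 1, 2)
  P <- size_histogram(rep(1L, 1000), edges = edges, pseudocount = 1e-9)
  Q <- size_histogram(c(rep(1L, 500), rep(2L, 500)), edges = edges,
                      pseudocount = 1e-9)
  expect_equal(kl_divergence(P, Q), log(2), tolerance = 1e-4)
  expect_false(isTRUE(all.equal(kl_divergence(P, Q), kl_divergence(Q, P))))

  mis <- size_histogram(x, edges = c(0.5, 2, 8))
  expect_error(kl_divergence(h, mis), "identical bin edges")
})

test_that("grid sweep identifies its own generating cell", {
  map <- build_rate_size_map(14, p_grid = seq(0, 1, 0.05), reps = 150,
                             seed = 31)
  tol <- simulate_fixed_rate_cohort(rep(0.3, 200), 14, seed = 32)
  set.seed(33)
  res <- simulate_fixed_rate_cohort(runif(200, 0.8, 0.97), 14)
  cal <- calibrate_cohort(tol, res, map)
  par_true <- simulation_params(p_init = cal$p_init, p_max = cal$p_max_ref,
                                n_steps = 30, mu = 0.05)
  target <- run_colony_cohort(par_true, 3, 500, cal$p_max_sampler,
                              seed = 34)
  grid <- sweep_parameter_grid(target, 3, mu_values = c(0.01, 0.05),
                               n_values = c(1, 30), calibration = cal,
                               reps = 500, seed = 35)
  expect_true(all(grid$divergence >= 0))
  # the generating cell wins and the single-step model fits worst
  best <- arrayInd(which.min(grid$divergence), dim(grid$divergence))
  expect_equal(grid$n_values[best[2]], 30)
  expect_true(all(grid$divergence[, 1] > grid$divergence[, 2]))

  region <- best_fit_region(grid, tolerance = 0.5)
  expect_true(30 %in% region$n)
  expect_false(1 %in% region$n)

  # multi-timepoint sweep aggregates and stays reproducible
  target2 <- run_colony_cohort(par_true, 1, 200, cal$p_max_sampler,
                               seed = 36)
  g2a <- sweep_parameter_grid(list(target2, target), c(1, 3),
                              mu_values = 0.05, n_values = c(1, 30),
                              calibration = cal, reps = 200, seed = 37)
  g2b <- sweep_parameter_grid(list(target2, target), c(1, 3),
                              mu_values = 0.05, n_values = c(1, 30),
                              calibration = cal, reps = 200, seed = 37)
  expect_identical(g2a$divergence, g2b$divergence)
})

test_that("best-fit region reduces to argmin at zero tolerance", {
  g <- structure(list(mu_values = 0.05, n_values = 10,
                      divergence = matrix(0.2, 1, 1), reps = 1),
                 class = "kl_grid")
  expect_equal(nrow(best_fit_region(g)), 1)
  g2 <- structure(list(mu_values = c(0.01, 0.05), n_values = c(1, 30),
                       divergence = matrix(c(0.5, 0.1, 0.1, 0.9), 2, 2),
                       reps = 1),
                  class = "kl_grid")
  r0 <- best_fit_region(g2, tolerance = 0)
  expect_equal(nrow(r0), 2)  # ties all returned
  expect_equal(r0$divergence, c(0.1, 0.1))
})

test_that("mixture test recognises pure components and rescaling", {
  set.seed(41)
  tolr <- generate_colony_sizes(tol_spec, 200)
  resr <- generate_colony_sizes(res_spec, 200)
  obs <- sample(tolr, 200, replace = TRUE)
  fit <- ks_mixture_test(obs, tolr, resr, n_boot = 100, seed = 42)
  expect_gte(fit$alpha_hat, 0.9)
  expect_true(fit$p_value >= 0 && fit$p_value <= 1)

  # KS is rank-based: a common monotone rescaling changes nothing
  fit2 <- ks_mixture_test(obs^2, tolr^2, resr^2, n_boot = 100, seed = 42)
  expect_identical(fit$alpha_hat, fit2$alpha_hat)
  expect_identical(fit$ks_stat, fit2$ks_stat)
  expect_identical(fit$p_value, fit2$p_value)

  expect_error(ks_mixture_test(obs, rep(5, 10), rep(5, 10), n_boot = 100),
               "degenerate")
  expect_error(ks_mixture_test(obs, tolr, resr, n_boot = 10), "n_boot")
  expect_error(ks_mixture_test(numeric(0), tolr, resr), "non-empty")
})

test_that("mixture test rejects a unimodal intermediate population", {
  set.seed(43)
  tolr <- generate_colony_sizes(tol_spec, 200)
  resr <- generate_colony_sizes(res_spec, 200)
  rej <- vapply(1:20, function(s) {
    obs <- generate_colony_sizes(mid_spec, 200, seed = 4300 + s)
    ks_mixture_test(obs, tolr, resr, n_boot = 100)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})

test_that("clonogenic fraction arithmetic and threshold semantics", {
  treated <- rep(10L, 10)   # 10 colonies, all >= 5 cells
  dmso <- rep(20L, 250)
  expect_equal(clonogenic_fraction(treated, 500, dmso, 500), 0.04)
  expect_equal(clonogenic_fraction(dmso, 500, dmso, 500), 1)
  # colonies of size 4: excluded at threshold 5, included at threshold 4
  sizes <- c(rep(4L, 3), rep(10L, 7))
  n5 <- sum(sizes >= 5)
  f5 <- clonogenic_fraction(sizes, 100, dmso, 500, min_size = 5)
  f4 <- clonogenic_fraction(sizes, 100, dmso, 500, min_size = 4)
  expect_equal(f4 / f5, (n5 + 3) / n5)
  expect_error(clonogenic_fraction(treated, 0, dmso, 500), "seeded")
  expect_error(clonogenic_fraction(treated, 500, rep(1L, 10), 500),
               "DMSO")
})
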