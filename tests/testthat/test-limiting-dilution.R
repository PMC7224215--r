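test_that("well scoring applies the colony-size threshold strictly", {
  # all wells empty: everything negative
  tab <- data.frame(dose_cells_per_well = rep(c(100, 50), each = 3),
                    well_id = rep(1:3, 2),
                    colony_size_cells = NA_real_)
  pl <- score_wells(tab)
  expect_equal(pl$wells_negative, pl$wells_total)

  # a colony of exactly 50 cells makes its well positive at threshold 50
  tab$colony_size_cells[1] <- 50
  tab$colony_size_cells[4] <- 49
  pl <- score_wells(tab, threshold = 50)
  expect_equal(pl$wells_negative[pl$dose_cells_per_well == 100], 2)
  expect_equal(pl$wells_negative[pl$dose_cells_per_well == 50], 3)

  expect_error(score_wells(tab[, 1:2]), "columns")
  expect_error(score_wells(tab, expected_wells = 10), "missing well")
})

test_that("scored plates agree with the generator's counts", {
  gen <- generate_limiting_dilution_plates(1 / 300, seed = 2)
  # expand to per-well records: negatives empty, positives one 60-cell colony
  rows <- do.call(rbind, lapply(seq_len(nrow(gen)), function(i) {
    n <- gen$wells_total[i]
    neg <- gen$wells_negative[i]
    data.frame(dose_cells_per_well = gen$dose_cells_per_well[i],
               well_id = seq_len(n),
               colony_size_cells = c(rep(NA_real_, neg),
                                     rep(60, n - neg)))
  }))
  scored <- score_wells(rows, threshold = 50)
  expect_equal(scored$wells_negative,
               gen$wells_negative[order(gen$dose_cells_per_well,
                                        decreasing = TRUE)])
})

test_that("noiseless log-linear data recover slope exactly", {
  d <- 400 / 2^(0:5)
  pl <- data.frame(dose_cells_per_well = d, wells_total = 10,
                   wells_negative = 10 * exp(-0.002 * d))
  f <- suppressWarnings(
    fit_limiting_dilution(pl, se_method = "residual"))
  expect_equal(f$slope, -0.002, tolerance = 1e-12)
  expect_equal(f$slope_se, 0, tolerance = 1e-12)
  # free intercept agrees on an exact line
  ff <- suppressWarnings(
    fit_limiting_dilution(pl, intercept = "free", se_method = "residual"))
  expect_equal(ff$slope, -0.002, tolerance = 1e-9)
})

test_that("uninformative or rising plates are rejected", {
  d <- 400 / 2^(0:5)
  # all wells positive everywhere: no usable levels
  pl <- data.frame(dose_cells_per_well = d, wells_total = 10,
                   wells_negative = 0)
  expect_warning(expect_error(fit_limiting_dilution(pl), "usable"),
                 "zero negative")
  # negatives increasing with dose: the free-intercept slope is >= 0
  pl2 <- data.frame(dose_cells_per_well = d, wells_total = 10,
                    wells_negative = c(10, 8, 6, 4, 2, 1))
  expect_error(fit_limiting_dilution(pl2, intercept = "free"), "slope")
  # every well negative everywhere: flat at zero, slope 0, inestimable
  pl2b <- data.frame(dose_cells_per_well = d, wells_total = 10,
                     wells_negative = 10)
  expect_error(fit_limiting_dilution(pl2b), "slope")
  # zero-negative levels are dropped with a warning
  pl3 <- data.frame(dose_cells_per_well = d, wells_total = 10,
                    wells_negative = c(0, 2, 5, 8, 9, 10))
  w <- capture_warnings(fit_limiting_dilution(pl3))
  expect_true(any(grepl("dropping", w)))
})

test_that("frequency formulas are exact inversions", {
  expect_equal(ric_frequency(log(0.5), 0)$cells_per_ric, 2)
  expect_equal(ric_frequency(log(1 - 1 / 500), 0)$cells_per_ric, 500)
  expect_error(ric_frequency(0, 0), "slope")
  expect_error(ric_frequency(0.1, 0), "slope")

  # round trip over the full frequency range, to machine precision
  q <- seq(0.001, 0.989, by = 0.004)
  back <- vapply(q, function(qi) ric_frequency(log(1 - qi))$per_cell_frequency,
                 numeric(1))
  expect_equal(back, q, tolerance = 1e-12)

  # cells_per_ric strictly decreasing in |slope|
  slopes <- -seq(0.0005, 0.05, length.out = 20)
  cpr <- vapply(slopes, function(s) ric_frequency(s)$cells_per_ric,
                numeric(1))
  expect_true(all(diff(cpr) < 0))

  # delta-method error equals |d/ds 1/(1-e^s)| * se numerically
  s <- -0.002; se <- 3e-4; h <- 1e-7
  num_deriv <- (1 / (1 - exp(s + h)) - 1 / (1 - exp(s - h))) / (2 * h)
  expect_equal(ric_frequency(s, se)$cells_per_ric_error,
               abs(num_deriv) * se, tolerance = 1e-6)
})

test_that("simulated plates recover the planted frequency", {
  set.seed(61)
  est <- replicate(60, {
    pl <- generate_limiting_dilution_plates(1 / 500)
    r <- ric_frequency(suppressWarnings(fit_limiting_dilution(pl)))
    c(r$cells_per_ric, r$cells_per_ric_error)
  })
  expect_lt(abs(mean(est[1, ]) - 500) / 500, 0.25)
  ratio <- sd(est[1, ]) / mean(est[2, ])
  expect_gt(ratio, 1 / 2)
  expect_lt(ratio, 2)
})
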