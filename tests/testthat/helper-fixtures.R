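# shared fixtures: small synthetic populations used across test files

tol_spec <- colony_population_spec("tolerant", meanlog = 2.2, sdlog = 0.6)
res_spec <- colony_population_spec("resistant", meanlog = 5.5, sdlog = 0.6)
# unimodal population midway (log scale) between the two reference modes
mid_spec <- colony_population_spec("intermediate", meanlog = 3.85, sdlog = 0.6)

# mutation-free parameters at a fixed division probability
mu0_params <- function(p, ...) {
  simulation_params(p_init = p, p_max = p, n_steps = 1, mu = 0, ...)
}

# recovery statistics of planted expanded clones in a synthetic barcode
# experiment: sensitivity, false-call rate and the within- vs
# between-condition Spearman correlation means over enriched barcodes
barcode_recovery_stats <- function(tb) {
  res <- analyze_barcodes(tb)
  truth <- attr(tb, "truth")
  called <- res$enrichment$enriched
  sens <- fpr <- numeric(0)
  for (s in names(called)) {
    planted <- rownames(tb)[truth[[sub("_rep.*", "", s)]]]
    sens <- c(sens, mean(planted %in% called[[s]]))
    fpr <- c(fpr, if (length(called[[s]]))
      mean(!(called[[s]] %in% planted)) else 0)
  }
  samples <- names(called)
  within <- between <- numeric(0)
  if (!is.null(res$correlation)) {
    for (i in seq_along(samples)) {
      for (j in seq_along(samples)) {
        if (i < j) {
          v <- res$correlation[samples[i], samples[j]]
          if (sub("_rep.*", "", samples[i]) == sub("_rep.*", "", samples[j]))
            within <- c(within, v)
          else between <- c(between, v)
        }
      }
    }
  }
  c(sensitivity = mean(sens), false_call = mean(fpr),
    within = mean(within), between = mean(between))
}
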