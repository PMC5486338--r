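# shared fixtures for the test suite (all data generated in code)

default_roles <- function() {
  list(response = "hb",
       fixed = c("sex", "fever", "cough", "wasting", "underweight",
                 "mother_anemia", "mother_literacy", "vitamin_a",
                 "mother_bmi", "wealth"),
       smooth = c("child_age", "mother_age", "breastfeed"),
       spatial = "district")
}

# small, quick MCMC settings for unit tests
quick_mcmc <- list(iters = 2000, burnin = 600, thin = 2)

# correlation between a fitted smooth curve and the generator truth,
# matched on the observed grid
smooth_truth_cor <- function(fit, sim, term) {
  cv <- smooth_curves(fit, term)
  tr <- sim$truth[[paste0("f_", term)]]
  stats::cor(cv$mean, tr$value[match(cv$grid, tr$grid)])
}

# proportion of true fixed effects covered by the per-term credible
# intervals of an effects_table
fixed_effect_coverage <- function(et, truth, col_tag) {
  nm <- sub("=", "", names(truth$beta_true))
  hits <- vapply(seq_along(nm), function(i) {
    j <- match(nm[i], et$term)
    !is.na(j) &&
      et[[paste0("lower_", col_tag)]][j] <= truth$beta_true[i] &&
      truth$beta_true[i] <= et[[paste0("upper_", col_tag)]][j]
  }, TRUE)
  mean(hits)
}
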