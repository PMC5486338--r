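test_that("the cross-quantile effects table lines up per-theta summaries", {
  sim <- generate_dataset(sim_config(n_children = 900, seed = 31))
  fits <- lapply(c(`0.21` = 0.21, `0.37` = 0.37), function(th) {
    staqr(hb ~ sex + fever, sim$data, theta = th, iters = 1500,
          burnin = 500, thin = 2, seed = 6)
  })
  et <- effects_table(fits)
  expect_equal(et$term, c("(Intercept)", "sexmale", "feveryes"))
  expect_true(all(c("mean_0.21", "sd_0.21", "mean_0.37", "sig_0.37")
                  %in% names(et)))
  # per-theta columns come from the corresponding fit
  expect_equal(et$mean_0.37, unname(colMeans(fits[[2]]$draws$beta)))
  # intercepts order with theta (conditional quantiles are monotone)
  expect_lt(et$mean_0.21[1], et$mean_0.37[1])

  # single fit gives a single summary column set
  et1 <- effects_table(fits[[2]])
  expect_equal(sum(grepl("^mean_", names(et1))), 1)

  # mismatched fixed-effect structure (different reference coding) errors
  d2 <- sim$data
  d2$sex <- stats::relevel(d2$sex, "male")
  f_swapped <- staqr(hb ~ sex + fever, d2, theta = 0.37, iters = 1500,
                     burnin = 500, thin = 2, seed = 6)
  expect_error(effects_table(list(fits[[1]], f_swapped)),
               "reference coding|structure")
})

test_that("smooth curves live on the observed grid with credible bands", {
  sim <- generate_dataset(sim_config(n_children = 1000, seed = 32))
  fit <- staqr(hb ~ sex + s(child_age), sim$data, theta = 0.37,
               iters = 1500, burnin = 500, thin = 2, seed = 7)
  cv <- smooth_curves(fit, "child_age")
  expect_equal(cv$grid, sort(unique(sim$data$child_age)))
  expect_true(all(cv$lower <= cv$mean & cv$mean <= cv$upper))
  expect_error(smooth_curves(fit, "sex"), "not a smooth term")
})

test_that("null data keeps smooth bands around zero", {
  sim <- generate_dataset(sim_config(n_children = 1500, seed = 33,
                                     effect_scale = 0))
  fit <- staqr(hb ~ sex + s(child_age) + s(breastfeed), sim$data,
               theta = 0.37, iters = 2500, burnin = 800, thin = 2, seed = 8)
  for (nm in c("child_age", "breastfeed")) {
    cv <- smooth_curves(fit, nm)
    cover0 <- mean(cv$lower <= 0 & 0 <= cv$upper)
    expect_gte(cover0, 0.9)
  }
})

test_that("the spatial table covers every district once, centred, with risk
          flags that track the true clusters", {
  sim <- generate_dataset(sim_config(n_children = 3000, seed = 34,
                                     noise = "asymmetric-laplace"))
  fit <- staqr(hb ~ sex + fever + mrf(district), sim$data, theta = 0.37,
               graph = sim$graph, iters = 2500, burnin = 800, thin = 2,
               seed = 9)
  st <- spatial_table(fit)
  expect_setequal(st$district, sim$graph$labels)
  expect_equal(anyDuplicated(st$district), 0L)
  expect_lt(abs(mean(st$mean)), 1e-8)
  expect_true(all(st$risk %in% c("lower-risk", "higher-risk")))
  # the districts with the largest true positive effects read as lower risk
  tr <- sort(sim$truth$spatial_true, decreasing = TRUE)
  top <- names(tr)[1:5]
  expect_true(all(st$risk[match(top, st$district)] == "lower-risk"))
  bottom <- names(tr)[(length(tr) - 4):length(tr)]
  expect_true(all(st$risk[match(bottom, st$district)] == "higher-risk"))
  expect_error(spatial_table(staqr(hb ~ sex, sim$data, theta = 0.37,
                                   iters = 1200, burnin = 400, thin = 2,
                                   seed = 1)),
               "no spatial")
})

test_that("report CSVs are written and reproducible", {
  sim <- generate_dataset(sim_config(n_children = 600, seed = 35))
  fit <- staqr(hb ~ sex + s(child_age) + mrf(district), sim$data,
               theta = 0.37, graph = sim$graph, iters = 1200, burnin = 400,
               thin = 2, seed = 10)
  out1 <- tempfile(); out2 <- tempfile()
  p1 <- write_report(fit, out1)
  expect_true(all(file.exists(file.path(out1, c("fixed_effects.csv",
                                                "smooth_child_age.csv",
                                                "spatial_effects.csv")))))
  write_report(fit, out2)
  for (f in basename(p1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})

test_that("plotting runs headless on a null device", {
  sim <- generate_dataset(sim_config(n_children = 500, seed = 36))
  fit <- staqr(hb ~ sex + s(child_age) + mrf(district), sim$data,
               theta = 0.37, graph = sim$graph, iters = 1000, burnin = 300,
               thin = 2, seed = 11)
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})
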