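test_that("the default generator matches its marginal calibration targets", {
  sim <- generate_dataset(sim_config(n_children = 3248, seed = 1))
  expect_equal(nrow(sim$data), 3248)
  expect_lt(abs(mean(sim$data$hb) - 11.25), 0.1)
  expect_lt(abs(sd(sim$data$hb) - 1.41), 0.1)
})

test_that("the 0.37 empirical quantile of simulated hemoglobin sits near the
          anemia cut-off across seeds", {
  qs <- vapply(1:20, function(s) {
    sim <- generate_dataset(sim_config(n_children = 3248, seed = s))
    unname(quantile(sim$data$hb, 0.37))
  }, 0)
  expect_true(all(qs >= 10.8 & qs <= 11.2))
})

test_that("identical configurations reproduce identical datasets", {
  a <- generate_dataset(sim_config(n_children = 5000, seed = 7))
  b <- generate_dataset(sim_config(n_children = 5000, seed = 7))
  expect_identical(a$data, b$data)
  expect_identical(a$truth, b$truth)
  c <- generate_dataset(sim_config(n_children = 5000, seed = 8))
  expect_false(identical(a$data$hb, c$data$hb))
})

test_that("effect_scale = 0 collapses hemoglobin to intercept plus noise", {
  sim <- generate_dataset(sim_config(n_children = 800, seed = 3,
                                     effect_scale = 0, noise = "gaussian",
                                     noise_sd = 1))
  expect_true(all(sim$truth$beta_true == 0))
  expect_true(all(sim$truth$f_child_age$value == 0))
  expect_true(all(sim$truth$spatial_true == 0))
  expect_equal(sim$truth$intercept, 11.25)
  expect_lt(abs(mean(sim$data$hb) - 11.25), 0.12)
  expect_lt(abs(sd(sim$data$hb) - 1), 0.08)
})

test_that("ground-truth smooths and spatial effects are centred", {
  sim <- generate_dataset(sim_config(n_children = 100, seed = 2))
  expect_lt(abs(mean(sim$truth$f_child_age$value)), 1e-10)
  expect_lt(abs(mean(sim$truth$f_mother_age$value)), 1e-10)
  expect_lt(abs(mean(sim$truth$f_breastfeed$value)), 1e-10)
  expect_lt(abs(sum(sim$truth$spatial_true)), 1e-10)
})

test_that("smooth truths have the documented qualitative shapes", {
  sim <- generate_dataset(sim_config(n_children = 100, seed = 2))
  fa <- sim$truth$f_child_age
  expect_true(all(diff(fa$value) > 0))              # increasing
  expect_true(all(diff(diff(fa$value)) < 1e-9))     # concave
  fm <- sim$truth$f_mother_age
  expect_lt(fm$value[fm$grid == 16], 0)             # early births harmful
  expect_gt(fm$value[fm$grid == 25], fm$value[fm$grid == 35])  # dip near 35
  fb <- sim$truth$f_breastfeed
  expect_gt(fb$value[fb$grid == 0], fb$value[fb$grid == 10])   # early decline
  peak <- fb$grid[which.max(fb$value)]
  expect_true(peak >= 20 && peak <= 30)             # inverse-U peak near 25
})

test_that("covariates follow their declared supports and frequencies", {
  sim <- generate_dataset(sim_config(n_children = 6000, seed = 10))
  d <- sim$data
  expect_true(all(d$child_age %in% 0:59))
  expect_true(all(d$mother_age %in% 15:49))
  expect_true(all(d$breastfeed %in% 0:36))
  expect_lt(abs(mean(d$sex == "male") - 0.506), 0.03)
  expect_lt(abs(mean(d$fever == "yes") - 0.207), 0.03)
  expect_equal(sort(unique(as.character(d$district))),
               sort(sim$graph$labels))
})

test_that("AL noise places the design quantile on the structural predictor", {
  sim <- generate_dataset(sim_config(n_children = 30000, seed = 5,
                                     noise = "asymmetric-laplace",
                                     effect_scale = 0))
  # theta_design-quantile of Hb should be the intercept itself
  expect_lt(abs(quantile(sim$data$hb, 0.37) - sim$truth$intercept), 0.03)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_children = 0), "at least 1")
  expect_error(sim_config(n_districts = 1), "at least 2")
  expect_error(sim_config(graph_kind = "file"), "adjacency_graph")
})

test_that("child datasets round-trip through CSV", {
  sim <- generate_dataset(sim_config(n_children = 50, seed = 4))
  p <- tempfile(fileext = ".csv")
  write_children(sim$data, p)
  d2 <- read_children(p)
  expect_equal(nrow(d2), 50)
  expect_equal(d2$hb, sim$data$hb)
  expect_true(is.factor(d2$district))
  expect_equal(as.character(d2$district), as.character(sim$data$district))
})
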