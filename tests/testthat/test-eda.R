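test_that("anemia categories follow the cut-offs with closed lower bounds", {
  expect_equal(as.character(classify_anemia(c(6.9, 11.0, 10.0, 9.95))),
               c("severe", "non-anemic", "mild", "moderate"))
  expect_equal(as.character(classify_anemia(c(0, 7.0, 9.9, 10.9, 25))),
               c("severe", "moderate", "moderate", "mild", "non-anemic"))
  expect_error(classify_anemia(-0.1), "negative")
  # monotone: higher hemoglobin never maps to a more severe category
  grid <- seq(0, 20, by = 0.1)
  cats <- classify_anemia(grid)
  expect_true(all(diff(as.integer(cats)) >= 0))
})

test_that("the fixture reproduces every published cross-tabulation count", {
  fx <- table1_fixture()
  for (nm in names(staqr:::table1_counts)) {
    spec <- staqr:::table1_counts[[nm]]
    tab <- anemia_crosstab(fx, nm)
    expect_equal(unname(tab$counts[, "anemic"]), spec$anemic, label = nm)
    expect_equal(unname(tab$counts[, "non_anemic"]), spec$non_anemic,
                 label = nm)
    expect_equal(tab$df, length(spec$levels) - 1L)
  }
  expect_equal(anemia_crosstab(fx, "sex")$n, 3248)
})

test_that("published row percentages consistent with their counts match", {
  fx <- table1_fixture()
  expect_equal(anemia_crosstab(fx, "sex")$row_pct["male", "anemic"], 36.9)
  expect_equal(anemia_crosstab(fx, "sex")$row_pct["female", "anemic"], 36.4)
  expect_equal(anemia_crosstab(fx, "underweight")$row_pct["yes", "anemic"],
               58.6)
  expect_equal(anemia_crosstab(fx, "mother_anemia")$row_pct["anemic", "anemic"],
               47.8)
  expect_equal(anemia_crosstab(fx, "fever")$row_pct["yes", "anemic"], 44.4)
  expect_equal(anemia_crosstab(fx, "vitamin_a")$row_pct["no", "anemic"], 45.9)
  expect_equal(anemia_crosstab(fx, "wasting")$row_pct["yes", "anemic"], 47.5)
  expect_equal(anemia_crosstab(fx, "deworming")$row_pct["no", "anemic"], 52.1)
})

test_that("crosstab percentages sum to 100 and chi-square is label-invariant", {
  fx <- table1_fixture()
  tab <- anemia_crosstab(fx, "wealth")
  expect_true(all(abs(rowSums(tab$row_pct) - 100) <= 0.1))
  expect_equal(sum(tab$counts), tab$n)
  # swapping the level order leaves the statistic unchanged
  fx2 <- fx
  fx2$wealth <- factor(fx2$wealth, levels = rev(levels(fx$wealth)))
  expect_equal(anemia_crosstab(fx2, "wealth")$chi2, tab$chi2)
})

test_that("identical rows give a zero chi-square and weights are honoured", {
  d <- data.frame(anemic = factor(rep(c("yes", "no"), each = 20)),
                  g = factor(rep(c("a", "b"), times = 20)))
  tab <- anemia_crosstab(d, "g")
  expect_equal(tab$chi2, 0)
  expect_equal(tab$p, 1)
  # doubling one level's weight doubles its counts
  w <- ifelse(d$g == "a", 2, 1)
  tw <- anemia_crosstab(d, "g", weights = w)
  expect_equal(unname(tw$counts["a", ]), unname(2 * tab$counts["a", ]))
  expect_error(anemia_crosstab(d, "missing_var"), "unknown variable")
})

test_that("hb column drives the anemia flag when no indicator is present", {
  d <- data.frame(hb = c(9, 10.9, 11, 12.5), g = factor(c("a", "a", "b", "b")))
  tab <- anemia_crosstab(d, "g")
  expect_equal(unname(tab$counts[, "anemic"]), c(2, 0))
})

test_that("screening keeps variables below the threshold, in order", {
  fake <- function(v, p) structure(list(variable = v, p = p),
                                   class = "anemia_crosstab")
  tabs <- list(fake("a", 0.05), fake("b", 0.19), fake("c", 0.21))
  expect_equal(screen_variables(tabs), c("a", "b"))
  expect_equal(screen_variables(tabs, alpha = 1), c("a", "b", "c"))
  expect_error(screen_variables(list()), "empty")
  # fever's published counts give an overwhelming association
  fx <- table1_fixture()
  tabs2 <- lapply(c("sex", "fever"), function(v) anemia_crosstab(fx, v))
  expect_true("fever" %in% screen_variables(tabs2))
  expect_lt(anemia_crosstab(fx, "fever")$p, 0.001)
})

test_that("prevalence maps to quantile levels through the empirical CDF", {
  expect_equal(prevalence_to_theta(c(6, 8, 10.5, 11.5), 11), 0.75)
  expect_equal(prevalence_to_theta(c(12, 13), 11), 0)
  expect_error(prevalence_to_theta(numeric(0), 11), "empty")
  # non-decreasing in the cutoff, and complements sum to one
  set.seed(2)
  hb <- rnorm(500, 11, 1.4)
  cuts <- seq(8, 14, by = 0.5)
  prev <- vapply(cuts, function(c) prevalence_to_theta(hb, c), 0)
  expect_true(all(diff(prev) >= 0))
  expect_equal(prevalence_to_theta(hb, 11) + mean(hb >= 11), 1)
  # generator calibration: about 37% of children below 11 g/dL
  sim <- generate_dataset(sim_config(n_children = 3248, seed = 6))
  expect_lt(abs(prevalence_to_theta(sim$data$hb, 11) - 0.37), 0.03)
})

test_that("eda_tables writes one CSV per variable plus the screening list", {
  fx <- table1_fixture()
  out <- tempfile()
  tabs <- eda_tables(fx, c("sex", "fever", "wealth"), out)
  expect_length(tabs, 3)
  expect_true(file.exists(file.path(out, "fever.csv")))
  screened <- readLines(file.path(out, "screened_variables.csv"))
  expect_true("fever" %in% screened)
  expect_false("sex" %in% screened)
  got <- read.csv(file.path(out, "sex.csv"))
  expect_equal(got$anemic, c(607, 583))
})
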