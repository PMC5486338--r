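# staqr — structured additive Bayesian quantile regression for childhood anemia

`staqr` models conditional **quantiles** of childhood hemoglobin
concentration (g/dL) rather than its mean, for epidemiologists analysing
DHS-style child health surveys.  Because anemia is defined by Hb falling
below a cut-off (11 g/dL in under-fives), the quantile level of interest
is tied to prevalence: with 37% of children anemic, the
θ = 0.37 conditional quantile describes the marginal anemic child, and
θ = 0.15 or 0.21 the more severely affected.

The core model is the structured additive quantile regression

$$Q_{y_i}(\theta\mid\cdot) = x_i'\beta_\theta + \sum_k f_{\theta k}(u_{ki}) + f_\theta^{(sp)}(d_i),$$

combining categorical fixed effects (child sex, fever, cough,
malnutrition indicators, maternal anemia/literacy/BMI, wealth, vitamin A),
second-order random-walk (RW2) smooths of child age, mother's age at
birth and breastfeeding duration, and an intrinsic CAR (Besag) spatial
effect over districts.  Estimation is fully Bayesian: minimising the
check loss $\rho_\theta(u) = u\{\theta - I(u<0)\}$ is equivalent to
maximising an asymmetric Laplace (AL) likelihood, whose
normal–exponential scale mixture yields closed-form Gibbs updates for
every block (implemented in C++).  Models along the classical ladder —
Gaussian mean model, linear QR, additive QR, spatial QR, structured
spatial additive QR — are compared by DIC.  An exact
linear-programming-type frequentist QR solver is included as an
independent validation oracle, together with a calibrated synthetic
survey generator with known ground truth, and the exploratory stage
(anemia classification, cross-tabulation with chi-square screening).

## Worked example

```r
library(staqr)

## synthetic DHS-like survey: 3248 children, 30 districts on a 5x6 lattice
sim <- generate_dataset(sim_config(n_children = 3248, seed = 1))
round(c(mean = mean(sim$data$hb), sd = sd(sim$data$hb),
        prevalence = prevalence_to_theta(sim$data$hb, 11)), 3)
#>       mean         sd prevalence
#>     11.277      1.417      0.364

## exploratory stage: cross-tabulation with Pearson chi-square
anemia_crosstab(sim$data, "fever")
#> Anemia cross-tabulation: fever
#>     anemic      non-anemic
#> no  854 (33.7%) 1678 (66.3%)
#> yes 328 (45.8%) 388 (54.2%)
#> Pearson chi-square = 35.197, df = 1, p = 2.98e-09

## structured additive quantile fit at theta = 0.37
fit <- staqr(hb ~ sex + fever + wealth + s(child_age) + mrf(district),
             data = sim$data, theta = 0.37, graph = sim$graph,
             iters = 6000, burnin = 2000, thin = 2, seed = 1)
fit
#> Structured additive quantile regression (theta = 0.37)
#> Formula: hb ~ sex + fever + wealth + s(child_age) + mrf(district)
#> n = 3248, 2000 stored draws (6000 iters, burn-in 2000, thin 2)
#> Structured terms: rw2(child_age), icar(district)
#> DIC = 11312.60 (pD = 32.76, Dbar = 11279.84)

round(coef(fit), 3)
#>  (Intercept)      sexmale     feveryes wealthmiddle   wealthrich
#>       11.028        0.075       -0.382       -0.007        0.178

head(spatial_table(fit), 3)
#>   district       mean         sd       lower     upper       risk significant
#> 1     R1C1 0.23917757 0.09776254  0.04434367 0.4263996 lower-risk        TRUE
#> 2     R1C2 0.21922053 0.08183414  0.06724283 0.3914790 lower-risk        TRUE
#> 3     R1C3 0.06444432 0.08757103 -0.11935020 0.2281964 lower-risk       FALSE
```

Reading the output: fixed effects are in g/dL of hemoglobin at the
fitted quantile — a positive coefficient (male sex, rich household)
raises Hb and so lowers anemia risk; fever lowers Hb by ~0.38 g/dL at
θ = 0.37.  `spatial_table()` gives per-district effects under a
sum-to-zero constraint with a two-class risk flag; `smooth_curves(fit,
"child_age")` returns the centred posterior smooth with credible bands;
`plot(fit)` draws both.  The five-model ladder is run with
`fit_ladder()` and compared with `compare_models()`, which flags the
smallest-DIC model.

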