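test_that("convergence diagnostics calibrate on i.i.d. and broken chains", {
  set.seed(1)
  arr <- array(rnorm(1000 * 4), dim = c(1000, 4, 2),
               dimnames = list(NULL, NULL, c("a", "b")))
  d <- compute_diagnostics(arr)
  expect_true(all(d$rhat < 1.01))
  expect_true(all(d$ess_bulk > 0.8 * 4000))
  expect_true(all(d$ess_tail > 0.5 * 4000))
  expect_equal(d$mcse, rep(1 / sqrt(4000), 2), tolerance = 0.3)

  # chains with shifted means are flagged hard
  shifted <- arr
  shifted[, 1, 1] <- shifted[, 1, 1] + 5
  d2 <- compute_diagnostics(shifted)
  expect_gt(d2$rhat[d2$parameter == "a"], 1.5)

  # constant parameters have undefined diagnostics
  const <- arr
  const[, , 2] <- 7
  d3 <- compute_diagnostics(const)
  expect_true(is.na(d3$rhat[d3$parameter == "b"]))

  expect_error(compute_diagnostics(arr[, 1, , drop = FALSE]), "2 chains")
})

test_that("posterior summaries use interpolated equal-tailed quantiles", {
  s <- summarize_posterior(as.numeric(1:100))
  expect_equal(s$median, 50.5)
  expect_equal(c(s$l95, s$u95), c(3.475, 97.525))

  sym <- summarize_posterior(c(-3, -1, 0, 1, 3))
  expect_equal(sym$l66 + sym$u66, 0)
  expect_equal(sym$median, 0)

  degen <- summarize_posterior(rep(2, 50))
  expect_true(all(degen == 2))
})

test_that("posterior probabilities count draws and resolve contrasts", {
  expect_equal(posterior_probability(NULL, c(-1, 2, 3, 4)), 0.75)
  expect_equal(posterior_probability(NULL, c(1, 2, 3)), 1)
  set.seed(2)
  expect_equal(posterior_probability(NULL, rnorm(20000)), 0.5, tolerance = 0.02)

  arr <- array(rnorm(200 * 2 * 2), dim = c(200, 2, 2),
               dimnames = list(NULL, NULL, c("beta[1]", "beta[2]")))
  fit <- structure(list(draws = arr), class = "posterior_draws")
  p1 <- posterior_probability(fit, "beta[1]")
  expect_true(p1 >= 0 && p1 <= 1)
  pd <- posterior_probability(fit, "`beta[2]` - `beta[1]`")
  dm <- draws_matrix(fit)
  expect_equal(pd, mean(dm[, 2] > dm[, 1]))
  expect_error(posterior_probability(fit, "nope"), "unknown parameter")
  # invariance under monotone reparameterization of the contrast
  expect_equal(posterior_probability(fit, exp(dm[, 1]) - 1),
               posterior_probability(fit, "beta[1]"))
})

test_that("prior draws stay finite at the configured scales", {
  set.seed(3)
  pc <- prior_config()
  beta <- rnorm(2000, 0, pc$beta_sd)
  sds <- abs(pc$sd_scale * rt(2000, 1))           # half-Cauchy
  nu <- rgamma(2000, pc$df_shape, pc$df_rate)
  y <- rnorm(2000, beta, pmin(sds, 1e6))
  expect_true(all(is.finite(y)))
  expect_true(all(nu > 0))
  expect_error(prior_config(sd_scale = -1), "positive")
})

test_that("single-level regression matches least squares under weak priors", {
  set.seed(4)
  n <- 150
  X <- cbind(intercept = 1, x = rnorm(n))
  y <- as.numeric(X %*% c(2, -1) + rnorm(n, 0, 0.5))
  fit <- fit_single_level_model(y, X, chains = 2, warmup = 500, draws = 500,
                                seed = 5)
  ols <- unname(coef(lm(y ~ 0 + X)))
  td <- tidy(fit)
  est <- td$estimate[match(c("beta[1]", "beta[2]"), td$term)]
  mcse <- td$mcse[match(c("beta[1]", "beta[2]"), td$term)]
  expect_lt(max(abs(est - ols) / (mcse + 0.01)), 5)

  # intercept-only model recovers the sample mean
  fit0 <- fit_single_level_model(y, matrix(1, n, 1), chains = 2,
                                 warmup = 300, draws = 300, seed = 6)
  expect_equal(tidy(fit0)$estimate[1], mean(y), tolerance = 0.05)

  expect_error(fit_single_level_model(y[1:2], X[1:2, ]), "more observations")
  expect_error(fit_single_level_model(y, cbind(X, X[, 2])), "rank deficient")
})

test_that("the two-level model recovers its own generative coefficients", {
  covered <- 0L
  n_rep <- 6
  for (s in seq_len(n_rep)) {
    g <- gen_two_level(seed = 60 + s)
    fit <- fit_two_level_model(g$spec, chains = 2, warmup = 500, draws = 500,
                               seed = 70 + s)
    td <- tidy(fit)
    for (k in 1:2) {
      row <- td[td$term == sprintf("beta[%d]", k), ]
      covered <- covered + (g$beta[k] >= row$conf.low && g$beta[k] <= row$conf.high)
    }
  }
  expect_gte(covered, 0.75 * 2 * n_rep)   # ~95% nominal, small-sample slack
})

test_that("a null design concentrates every contrast at zero", {
  set.seed(7)
  J <- 10; nb <- 30
  pid <- rep(1:J, each = nb)
  grp <- rep(rep(0:1, each = nb / 2), J)
  y <- rnorm(J * nb, 5, 1) + rep(rnorm(J, 0, 0.3), each = nb)
  X <- cbind(intercept = 1, g = grp)
  spec <- model_spec(y, X, pid, resid_structure = "single")
  fit <- fit_two_level_model(spec, chains = 2, warmup = 500, draws = 500,
                             seed = 8)
  s <- summarize_posterior(fit, "beta[2]")
  expect_lt(abs(s$median), 0.2)
  expect_true(s$l95 < 0 && s$u95 > 0)
})

test_that("centered and non-centered forms agree on a well-identified fit", {
  g <- gen_two_level(seed = 90, J = 10, nb = 30)
  f1 <- suppressMessages(
    fit_two_level_model(g$spec, chains = 2, warmup = 1500, draws = 1500,
                        seed = 91, parameterization = "noncentered"))
  f2 <- suppressMessages(
    fit_two_level_model(g$spec, chains = 2, warmup = 1500, draws = 1500,
                        seed = 92, parameterization = "centered"))
  for (par in c("beta[1]", "beta[2]", "sigma_m")) {
    # thin the Gibbs draws toward independence before the distribution test
    a <- draws_matrix(f1)[, par]
    b <- draws_matrix(f2)[, par]
    keep <- seq(1, length(a), by = 15)
    ks <- suppressWarnings(stats::ks.test(a[keep], b[keep]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("pooled residual structure shrinks participant SDs toward method SDs", {
  set.seed(10)
  J <- 8; nt <- 30
  pid <- rep(1:J, each = nt)
  side <- rep(rep(0:1, nt / 2), J)
  # homogeneous residual SD in truth
  y <- 1 + 0.5 * side + rnorm(J * nt, 0, 1)
  spec <- model_spec(y, cbind(intercept = 1, side = side), pid,
                     method = rep("m1", J * nt),
                     resid_structure = "per_method_per_participant_pooled")
  fit <- fit_effect_size_model(spec, "side", chains = 2, warmup = 600,
                               draws = 600, seed = 11)
  dm <- draws_matrix(fit)
  sd_cols <- grep("^sigma_pm", colnames(dm), value = TRUE)
  # posterior spread of participant SDs around the method SD is small
  per_draw_spread <- apply(dm[, sd_cols], 1, sd)
  expect_lt(median(per_draw_spread), 0.3)

  # the standardized group-average effect covers the injected 0.5
  es <- fit$effect_size[, "m1"]
  q <- quantile(es, c(0.025, 0.975))
  expect_true(q[1] < 0.5 && q[2] > 0.5)

  # contra == ipsi: effect size posterior centres at 0
  y0 <- 1 + rnorm(J * nt, 0, 1)
  spec0 <- model_spec(y0, cbind(intercept = 1, side = side), pid,
                      method = rep("m1", J * nt),
                      resid_structure = "per_method_per_participant_pooled")
  fit0 <- fit_effect_size_model(spec0, "side", chains = 2, warmup = 600,
                                draws = 600, seed = 12)
  q0 <- quantile(fit0$effect_size[, "m1"], c(0.025, 0.975))
  expect_true(q0[1] < 0 && q0[2] > 0)
})

test_that("robust correlation resists outliers and matches Pearson when clean", {
  set.seed(13)
  n <- 120
  x <- rnorm(n)
  y <- 0.7 * x + sqrt(1 - 0.49) * rnorm(n)
  fit <- robust_correlation(x, y, chains = 2, warmup = 500, draws = 500,
                            seed = 14)
  expect_lt(abs(summarize_posterior(fit, "rho")$median - cor(x, y)), 0.05)

  # y essentially identical to x: posterior mass piles at 1
  fitxx <- robust_correlation(x, x + 0.05 * rnorm(n), chains = 2,
                              warmup = 500, draws = 500, seed = 15)
  expect_gt(summarize_posterior(fitxx, "rho")$median, 0.99)

  expect_error(robust_correlation(x, rep(1, n)), "constant")
  expect_error(robust_correlation(x[1:5], y[1:5]), "at least 10")
})
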