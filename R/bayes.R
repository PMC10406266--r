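#' Weakly informative prior configuration
#'
#' Priors shared by all evaluation models: normal(0, 10) on regression
#' coefficients, half-Cauchy(0, 2.5) on standard deviations, and for the
#' robust-correlation model a vague normal(0, 100) on the means, a
#' gamma(2, 0.1) prior on the Student-t degrees of freedom and a uniform
#' prior on the correlation. The coefficient-correlation prior is LKJ-shaped
#' with shape `lkj_eta` (implemented exactly for two coefficients, where
#' LKJ(eta) is `2*Beta(eta, eta) - 1` on the single correlation).
#'
#' @param beta_sd SD of the normal prior on regression coefficients.
#' @param sd_scale Scale of the half-Cauchy prior on standard deviations.
#' @param cor_mean_sd SD of the normal prior on robust-correlation means.
#' @param df_shape,df_rate Gamma prior on the Student-t degrees of freedom.
#' @param lkj_eta Shape of the coefficient-correlation prior.
#' @return A list of class `prior_config`.
#' @export
prior_config <- function(beta_sd = 10, sd_scale = 2.5, cor_mean_sd = 100,
                         df_shape = 2, df_rate = 0.1, lkj_eta = 2) {
  if (any(c(beta_sd, sd_scale, cor_mean_sd, df_shape, df_rate, lkj_eta) <= 0)) {
    abort("all prior scales must be positive.")
  }
  structure(list(beta_sd = beta_sd, sd_scale = sd_scale,
                 cor_mean_sd = cor_mean_sd, df_shape = df_shape,
                 df_rate = df_rate, lkj_eta = lkj_eta),
            class = "prior_config")
}

#' Model specification for the hierarchical evaluation models
#'
#' @param y Outcome vector (band power, power difference, log-SNR or
#'   amplitude).
#' @param X Design matrix with named columns (variant indicators, condition
#'   indicator, ...); must have full column rank.
#' @param participant Participant identifier per row (factor/character/
#'   integer); converted to contiguous indices.
#' @param method Optional method identifier per row, defining the residual
#'   variance groups. Required for the per-method residual structures.
#' @param resid_structure `"per_method"` (one residual SD per method,
#'   default), `"single"`, or `"per_method_per_participant_pooled"` (one SD
#'   per participant and method, partially pooled on the log scale toward its
#'   method-level SD).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(y, X, participant, method = NULL,
                       resid_structure = c("per_method", "single",
                                           "per_method_per_participant_pooled")) {
  resid_structure <- match.arg(resid_structure)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(y) != nrow(X)) abort("y and X disagree in length.")
  if (qr(X)$rank < ncol(X)) abort("design matrix X is rank deficient.")
  pid <- as.integer(factor(participant))
  if (resid_structure == "single") {
    mid <- rep(1L, length(y)); methods <- "all"
  } else {
    if (is.null(method)) abort("`method` is required for per-method residuals.")
    mf <- factor(method)
    mid <- as.integer(mf); methods <- levels(mf)
  }
  if (min(table(pid)) < 2) abort("each participant needs at least 2 rows.")
  if (length(unique(pid)) < 2) abort("at least 2 participants are required.")
  structure(list(y = as.numeric(y), X = X, pid = pid, mid = mid,
                 methods = methods, participants = levels(factor(participant)),
                 resid_structure = resid_structure),
            class = "model_spec")
}

# --- JAGS model code ---------------------------------------------------------

jags_two_level_code <- function(p, parameterization, pooled_sd) {
  sd_prior <- "dt(0, invlam, 1) T(0,)"
  resid <- if (pooled_sd) "
  for (g in 1:G) {
    sigma_m[g] ~ %SD%
    tau_sig[g] ~ %SD%
    prec_sig[g] <- pow(tau_sig[g], -2)
    for (j in 1:J) {
      log_sigma_pm[j, g] ~ dnorm(log(sigma_m[g]), prec_sig[g])
      sigma_pm[j, g] <- exp(log_sigma_pm[j, g])
    }
  }
  for (i in 1:N) { prec_y[i] <- pow(sigma_pm[pid[i], mid[i]], -2) }
" else "
  for (g in 1:G) {
    sigma_m[g] ~ %SD%
    prec_m[g] <- pow(sigma_m[g], -2)
  }
  for (i in 1:N) { prec_y[i] <- prec_m[mid[i]] }
"
  cov2 <- if (parameterization == "noncentered") "
  for (j in 1:J) {
    z[j, 1] ~ dnorm(0, 1)
    z[j, 2] ~ dnorm(0, 1)
    beta_p[j, 1] <- beta[1] + tau[1] * z[j, 1]
    beta_p[j, 2] <- beta[2] + tau[2] * (rho * z[j, 1] + sqrt(1 - rho * rho) * z[j, 2])
  }
  rho_raw ~ dbeta(eta, eta)
  rho <- 2 * rho_raw - 1
  for (k in 1:P) { tau[k] ~ %SD% }
" else "
  for (j in 1:J) { beta_p[j, 1:P] ~ dmnorm(beta[1:P], OmegaP[1:P, 1:P]) }
  rho_raw ~ dbeta(eta, eta)
  rho <- 2 * rho_raw - 1
  for (k in 1:P) { tau[k] ~ %SD% }
  Sig[1, 1] <- tau[1] * tau[1]
  Sig[2, 2] <- tau[2] * tau[2]
  Sig[1, 2] <- rho * tau[1] * tau[2]
  Sig[2, 1] <- Sig[1, 2]
  OmegaP[1:2, 1:2] <- inverse(Sig[1:2, 1:2])
"
  covp <- "
  PrecU[1:P, 1:P] ~ dwish(S0[1:P, 1:P], Pplus)
  SigU[1:P, 1:P] <- inverse(PrecU[1:P, 1:P])
  for (j in 1:J) {
    u[j, 1:P] ~ dmnorm(zeros[1:P], PrecU[1:P, 1:P])
    for (k in 1:P) { beta_p[j, k] <- beta[k] + u[j, k] }
  }
  for (k in 1:P) { tau[k] <- sqrt(SigU[k, k]) }
"
  conjugate <- !(p == 2 && parameterization %in% c("noncentered", "centered"))
  cov <- if (conjugate) covp else cov2
  mu <- if (conjugate) {
    "mu[i] <- inprod(X[i, 1:P], beta[1:P]) + inprod(X[i, 1:P], u[pid[i], 1:P])"
  } else {
    "mu[i] <- inprod(X[i, 1:P], beta_p[pid[i], 1:P])"
  }
  code <- paste0("model {
  for (i in 1:N) {
    ", mu, "
    y[i] ~ dnorm(mu[i], prec_y[i])
  }
  for (k in 1:P) { beta[k] ~ dnorm(0, prec_beta) }
", cov, resid, "}\n")
  gsub("%SD%", sd_prior, code, fixed = TRUE)
}

jags_single_level_code <- "model {
  for (i in 1:N) {
    mu[i] <- inprod(X[i, 1:P], beta[1:P])
    y[i] ~ dnorm(mu[i], prec)
  }
  for (k in 1:P) { beta[k] ~ dnorm(0, prec_beta) }
  sigma ~ dt(0, invlam, 1) T(0,)
  prec <- pow(sigma, -2)
}"

jags_robust_cor_code <- "model {
  for (i in 1:N) { xy[i, 1:2] ~ dmt(mu[1:2], Tau[1:2, 1:2], nu) }
  mu[1] ~ dnorm(0, prec_mu)
  mu[2] ~ dnorm(0, prec_mu)
  s[1] ~ dt(0, invlam, 1) T(0,)
  s[2] ~ dt(0, invlam, 1) T(0,)
  rho ~ dunif(-1, 1)
  Sig[1, 1] <- s[1] * s[1]
  Sig[2, 2] <- s[2] * s[2]
  Sig[1, 2] <- rho * s[1] * s[2]
  Sig[2, 1] <- Sig[1, 2]
  Tau[1:2, 1:2] <- inverse(Sig[1:2, 1:2])
  nu ~ dgamma(df_shape, df_rate) T(2,)
}"

run_jags <- function(code, data, variables, chains, warmup, draws, seed,
                     inits_extra = NULL) {
  rngs <- rep(c("base::Wichmann-Hill", "base::Marsaglia-Multicarry",
                "base::Super-Duper", "base::Mersenne-Twister"),
              length.out = chains)
  inits <- lapply(seq_len(chains), function(i) {
    ini <- list(.RNG.name = rngs[i],
                .RNG.seed = child_seed(seed, 7000 + i))
    c(ini, inits_extra %||% list())
  })
  adapt <- min(1000L, max(100L, floor(warmup / 2)))
  m <- rjags::jags.model(textConnection(code), data = data, inits = inits,
                         n.chains = chains, n.adapt = adapt, quiet = TRUE)
  stats::update(m, n.iter = max(0L, warmup - adapt), progress.bar = "none")
  samp <- rjags::coda.samples(m, variable.names = variables, n.iter = draws,
                              progress.bar = "none")
  mcmc_to_array(samp)
}

mcmc_to_array <- function(mcmc_list) {
  mats <- lapply(mcmc_list, as.matrix)
  pars <- colnames(mats[[1]])
  arr <- array(NA_real_, dim = c(nrow(mats[[1]]), length(mats), length(pars)),
               dimnames = list(NULL, NULL, pars))
  for (i in seq_along(mats)) arr[, i, ] <- mats[[i]]
  arr
}

new_posterior_draws <- function(arr, model, spec = NULL, priors = NULL) {
  d <- structure(list(draws = arr, model = model, spec = spec, priors = priors),
                 class = "posterior_draws")
  d$diagnostics <- compute_diagnostics(d)
  worst <- suppressWarnings(max(d$diagnostics$rhat, na.rm = TRUE))
  d$converged <- is.finite(worst) && worst <= 1.01
  if (!d$converged) {
    log_msg("warning", sprintf("fit flagged non-converged (max rhat = %.3f)", worst))
  }
  d
}

#' @export
print.posterior_draws <- function(x, ...) {
  dm <- dim(x$draws)
  cat(sprintf("<posterior_draws: %s> %d draws x %d chains x %d parameters; %s\n",
              x$model, dm[1], dm[2], dm[3],
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

# --- fitting front-ends ------------------------------------------------------

#' Fit the two-level varying-intercept / varying-slope model
#'
#' The core evaluation model: `y ~ Normal(X beta_participant, sigma_method)`,
#' with participant coefficient vectors drawn from a multivariate normal
#' around the group coefficients. For two coefficients the covariance is
#' parameterized as SD vector x correlation (LKJ-shaped prior) and sampled in
#' non-centered form by default; wider designs use a scaled inverse-Wishart
#' covariance. Residual SDs follow the structure declared in the
#' [model_spec()]. Convergence is assessed with [compute_diagnostics()]; a
#' fit with max R-hat > 1.01 is returned flagged, not discarded.
#'
#' @param spec A [model_spec()].
#' @param priors A [prior_config()].
#' @param chains Number of MCMC chains (default 4).
#' @param warmup,draws Warmup and retained draws per chain (default 1000 each).
#' @param seed Integer seed.
#' @param parameterization Covariance parameterization. `"conjugate"`
#'   (default) separates group coefficients from zero-centered participant
#'   deviations with an inverse-Wishart covariance prior - the non-centered
#'   form whose fully conjugate block updates mix best under Gibbs sampling,
#'   and the only form available for designs wider than two coefficients.
#'   `"noncentered"` and `"centered"` expose the SD-vector x correlation
#'   covariance exactly (half-Cauchy SDs, LKJ-shaped correlation prior;
#'   two-coefficient designs only).
#' @return A `posterior_draws` object with `diagnostics` and `converged`
#'   fields. Group coefficients are named `beta[k]`, participant coefficients
#'   `beta_p[j,k]`, residual SDs `sigma_m[g]`, coefficient SDs `tau[k]`.
#' @export
fit_two_level_model <- function(spec, priors = prior_config(), chains = 4,
                                warmup = 1000, draws = 1000, seed = 1L,
                                parameterization = c("conjugate", "noncentered",
                                                     "centered")) {
  stopifnot(inherits(spec, "model_spec"))
  parameterization <- match.arg(parameterization)
  p <- ncol(spec$X)
  pooled <- spec$resid_structure == "per_method_per_participant_pooled"
  code <- jags_two_level_code(p, parameterization, pooled)
  data <- list(
    y = spec$y, X = spec$X, pid = spec$pid, mid = spec$mid,
    N = length(spec$y), P = p, J = max(spec$pid), G = max(spec$mid),
    prec_beta = 1 / priors$beta_sd^2, invlam = 1 / priors$sd_scale^2
  )
  use_iw <- !(p == 2 && parameterization %in% c("noncentered", "centered"))
  if (!use_iw) data$eta <- priors$lkj_eta
  if (use_iw) {
    data$S0 <- diag(p) * priors$sd_scale^2
    data$Pplus <- p + 1
    data$zeros <- numeric(p)
  }
  vars <- c("beta", "beta_p", "tau", "sigma_m")
  if (!use_iw) vars <- c(vars, "rho")
  if (pooled) vars <- c(vars, "sigma_pm", "tau_sig")
  arr <- run_jags(code, data, vars, chains, warmup, draws, seed)
  out <- new_posterior_draws(arr, "two_level", spec, priors)
  out$coef_names <- colnames(spec$X)
  out
}

#' Fit a single-level Bayesian linear regression
#'
#' `y ~ Normal(X beta, sigma)` with the shared weakly informative priors;
#' used for across-participant effect sizes and participant-average SNR.
#'
#' @param y Outcome vector.
#' @param X Design matrix (named columns), `nrow(X) > ncol(X)`.
#' @inheritParams fit_two_level_model
#' @return A `posterior_draws` object.
#' @export
fit_single_level_model <- function(y, X, priors = prior_config(), chains = 4,
                                   warmup = 1000, draws = 1000, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(y) <= ncol(X)) abort("need more observations than coefficients.")
  if (qr(X)$rank < ncol(X)) abort("design matrix X is rank deficient.")
  data <- list(y = as.numeric(y), X = X, N = length(y), P = ncol(X),
               prec_beta = 1 / priors$beta_sd^2, invlam = 1 / priors$sd_scale^2)
  arr <- run_jags(jags_single_level_code, data, c("beta", "sigma"),
                  chains, warmup, draws, seed)
  out <- new_posterior_draws(arr, "single_level", priors = priors)
  out$coef_names <- colnames(X)
  out
}

#' Fit the within-participant effect-size model
#'
#' The two-level model with trial-level amplitudes and a two-level residual
#' structure: one residual SD per participant and method, partially pooled on
#' the log scale toward its method-level SD. The group-average
#' within-participant effect size for a coefficient is the posterior of that
#' coefficient's participant-level draws divided by the participant-method
#' residual SD, averaged over participants; draws are attached under
#' `effect_size` (one column per method).
#'
#' @param spec A [model_spec()] with
#'   `resid_structure = "per_method_per_participant_pooled"` and trial-level
#'   rows carrying a stimulus-side indicator column in `X`.
#' @param es_coefficient Name of the `X` column whose standardized effect is
#'   wanted (e.g. the contralateral-minus-ipsilateral indicator).
#' @inheritParams fit_two_level_model
#' @return A `posterior_draws` object with an `effect_size` draws matrix.
#' @export
fit_effect_size_model <- function(spec, es_coefficient,
                                  priors = prior_config(), chains = 4,
                                  warmup = 1000, draws = 1000, seed = 1L) {
  if (spec$resid_structure != "per_method_per_participant_pooled") {
    abort("effect-size model requires the pooled per-participant residual structure.")
  }
  fit <- fit_two_level_model(spec, priors, chains, warmup, draws, seed)
  fit$model <- "effect_size"
  ci <- match(es_coefficient, colnames(spec$X))
  if (is.na(ci)) abort(sprintf("unknown coefficient '%s'", es_coefficient))
  dm <- draws_matrix(fit)
  J <- max(spec$pid); G <- max(spec$mid)
  es <- matrix(0, nrow(dm), G)
  colnames(es) <- spec$methods
  for (g in seq_len(G)) {
    acc <- 0
    for (j in seq_len(J)) {
      bj <- dm[, sprintf("beta_p[%d,%d]", j, ci)]
      sj <- dm[, sprintf("sigma_pm[%d,%d]", j, g)]
      acc <- acc + bj / sj
    }
    es[, g] <- acc / J
  }
  fit$effect_size <- es
  fit
}

#' Robust correlation via the bivariate Student-t distribution
#'
#' Estimates the correlation as the scale-matrix correlation of a bivariate
#' Student-t likelihood with vague normal(0, 100) means, half-Cauchy(2.5)
#' scales, uniform(-1, 1) correlation and gamma(2, 0.1) degrees of freedom -
#' robust to outliers relative to the Pearson estimator.
#'
#' @param x,y Equal-length numeric vectors (n >= 10), neither constant.
#' @inheritParams fit_two_level_model
#' @return A `posterior_draws` object; the correlation parameter is `rho`.
#' @export
robust_correlation <- function(x, y, priors = prior_config(), chains = 4,
                               warmup = 1000, draws = 1000, seed = 1L) {
  if (length(x) != length(y)) abort("x and y lengths differ.")
  if (length(x) < 10) abort("robust correlation needs at least 10 pairs.")
  if (sd(x) < 1e-12 || sd(y) < 1e-12) abort("constant input vector.")
  data <- list(xy = cbind(x, y), N = length(x),
               prec_mu = 1 / priors$cor_mean_sd^2,
               invlam = 1 / priors$sd_scale^2,
               df_shape = priors$df_shape, df_rate = priors$df_rate)
  arr <- run_jags(jags_robust_cor_code, data, c("rho", "mu", "s", "nu"),
                  chains, warmup, draws, seed)
  new_posterior_draws(arr, "robust_correlation", priors = priors)
}
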