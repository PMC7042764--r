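# R-side joint log-posterior of the integrated population model. Mirrors the
# BUGS model exactly (same likelihood components, priors and covariate
# conventions); used for testing, diagnostics and likelihood evaluation at
# arbitrary parameter points.

# derived vital-rate arrays from a parameter list
derive_rates <- function(arr, par) {
  M <- arr$M; T <- arr$T
  phi <- matrix(0, M, T - 1)
  RI <- piM <- matrix(0, M, T)
  for (m in seq_len(M)) {
    phi[m, ] <- survival_linpred(par$phi0[m], par$beta_cmd[m], arr$cmdz[m, 2:T],
                                 par$beta_tw[m], arr$twz[m, 2:T], par$nu[m, ])
    RI[m, ] <- reproductive_index(par$alpha0[m], par$alpha_cmd[m], arr$cmdz[m, ],
                                  par$alpha_temp[m], arr$tempz[m, ], par$yr[m, ])
    piM[m, ] <- stats::plogis(stats::qlogis(par$pi0[m]) + par$upi[m, ])
  }
  p <- stats::plogis(stats::qlogis(par$p0[arr$sta_m]) + par$psta)
  list(phi = phi, RI = RI, pi = piM, p = p)
}

ipm_loglik_counts <- function(arr, par) {
  n <- par$s + par$g
  if (any(n <= 0)) return(-Inf)
  log_n <- log(n)[cbind(arr$cnt$m, arr$cnt$t)]
  sum(count_loglik(arr$cnt$y, log_n, par$om[arr$cnt$ro], par$eta,
                   arr$cnt$novice, par$eps))
}

ipm_loglik_process <- function(arr, par, rates) {
  M <- arr$M; T <- arr$T
  n <- par$s + par$g
  if (any(par$s < 0) || any(par$g < 0)) return(-Inf)
  ll <- sum(trunc_normal_logpdf(par$s[, 1], arr$init_mean, arr$init_sd)) +
    sum(trunc_normal_logpdf(par$g[, 1], arr$init_mean, arr$init_sd))
  for (t in 2:T) {
    gam <- rates$RI[, t - 1] * par$iota[, t - 1]
    ll <- ll + sum(survivor_logdensity(par$s[, t], n[, t - 1], rates$phi[, t - 1])) +
      sum(recruit_logdensity(par$g[, t], n[, t - 1], gam))
  }
  ll
}

# closed-form group likelihoods; algebraically identical to the forward
# recursion in transient_cjs_joint_loglik()
ipm_loglik_cjs <- function(arr, par, rates) {
  T <- arr$T
  chi <- matrix(1, arr$Nsta, T)
  for (t in (T - 1):1) {
    ph <- rates$phi[arr$sta_m, t]
    chi[, t] <- (1 - ph) + ph * (1 - rates$p) * chi[, t + 1]
  }
  clphi <- cbind(0, t(apply(log(rates$phi), 1, cumsum)))  # [M, T]
  gr <- arr$groups
  lres <- clphi[cbind(gr$m, gr$last)] - clphi[cbind(gr$m, gr$first)] +
    gr$d * log(rates$p[gr$sta]) +
    (gr$last - gr$first - gr$d) * log(1 - rates$p[gr$sta])
  Lres <- exp(lres) * chi[cbind(gr$sta, gr$last)]
  pi_g <- rates$pi[cbind(gr$m, gr$first)]
  L <- ifelse(gr$r == 1, pi_g * par$rho[gr$m] * Lres,
              (1 - pi_g) * (gr$d == 0) + pi_g * (1 - par$rho[gr$m]) * Lres)
  sum(gr$mult * log(L))
}

ipm_loglik_prod <- function(arr, par, rates) {
  pc <- arr$prod_cells
  lp <- par$alpha0[pc$m] + par$alpha_ef * pc$leff +
    par$alpha_cmd[pc$m] * arr$cmdz[cbind(pc$m, pc$t)] +
    par$alpha_temp[pc$m] * arr$tempz[cbind(pc$m, pc$t)] +
    par$yr[cbind(pc$m, pc$t)] + par$sta[pc$sta]
  sum(productivity_loglik(pc$hy, pc$tot, lp))
}

ipm_log_hyperprior <- function(arr, par, priors) {
  in01 <- function(x) all(x > 0 & x < 1)
  sds <- c(par$sig_om, par$sig_eps, par$sig_sta, par$sig_psta,
           par$sig_nu, par$sig_pi, par$sig_yr)
  if (!in01(par$phi0) || !in01(par$pi0) || !in01(par$p0) || !in01(par$rho) ||
      !in01(stats::plogis(par$alpha0))) return(-Inf)
  if (any(sds <= 0) || any(sds >= priors$sd_upper)) return(-Inf)
  if (any(par$iota < 0)) return(-Inf)
  coefs <- c(par$beta_cmd, par$beta_tw, par$alpha_cmd, par$alpha_temp,
             par$alpha_ef, par$eta)
  # uniform(0,1) intercept priors contribute 0 on the probability scale; the
  # alpha0 intercept prior is uniform on plogis(alpha0), hence the Jacobian
  jac_alpha0 <- sum(log(stats::plogis(par$alpha0)) +
                      log(1 - stats::plogis(par$alpha0)))
  sum(stats::dnorm(coefs, 0, priors$coef_sd, log = TRUE)) +
    jac_alpha0 - length(sds) * log(priors$sd_upper) +
    sum(trunc_normal_logpdf(par$iota, priors$iota_mean, priors$iota_sd)) +
    sum(stats::dnorm(par$om, 0, par$sig_om, log = TRUE)) +
    sum(stats::dnorm(par$eps, 0, par$sig_eps, log = TRUE)) +
    sum(stats::dnorm(par$nu, 0, par$sig_nu[row(par$nu)], log = TRUE)) +
    sum(stats::dnorm(par$upi, 0, par$sig_pi[row(par$upi)], log = TRUE)) +
    sum(stats::dnorm(par$yr, 0, par$sig_yr[row(par$yr)], log = TRUE)) +
    sum(stats::dnorm(par$sta, 0, par$sig_sta, log = TRUE)) +
    sum(stats::dnorm(par$psta, 0, par$sig_psta, log = TRUE))
}

#' Build the joint log-posterior of the integrated population model
#'
#' Assembles a callable joint log-posterior: the sum of the state-space count
#' likelihood (observation + process), the marginalized transient-CJS
#' likelihood, the binomial productivity likelihood, and the priors, with
#' adult survival and the reproductive index shared across components.
#' Parameter points outside the prior support return `-Inf`.
#'
#' @param dataset A `model_dataset` from [assemble_dataset()].
#' @param priors A [prior_spec()].
#' @return An `ipm_joint_model` list with elements `log_posterior(par)`,
#'   `components(par)` (named vector: counts, process, cjs, productivity,
#'   hyper), `example_params()` (a valid point to start from), and `arrays`.
#' @export
build_joint_model <- function(dataset, priors = prior_spec()) {
  arr <- build_model_arrays(dataset)
  components <- function(par) {
    hyper <- ipm_log_hyperprior(arr, par, priors)
    if (!is.finite(hyper)) {
      return(c(counts = -Inf, process = -Inf, cjs = -Inf,
               productivity = -Inf, hyper = -Inf))
    }
    rates <- derive_rates(arr, par)
    c(counts = ipm_loglik_counts(arr, par),
      process = ipm_loglik_process(arr, par, rates),
      cjs = ipm_loglik_cjs(arr, par, rates),
      productivity = ipm_loglik_prod(arr, par, rates),
      hyper = hyper)
  }
  example_params <- function() {
    M <- arr$M; T <- arr$T
    mean_y <- vapply(seq_len(M), function(m) {
      max(mean(arr$cnt$y[arr$cnt$m == m]), 0.5)
    }, numeric(1))
    list(phi0 = rep(0.5, M), beta_cmd = rep(0, M), beta_tw = rep(0, M),
         nu = matrix(0, M, T - 1),
         pi0 = rep(0.5, M), upi = matrix(0, M, T),
         p0 = rep(0.3, M), psta = rep(0, arr$Nsta), rho = rep(0.5, M),
         alpha0 = rep(stats::qlogis(0.2), M), alpha_cmd = rep(0, M),
         alpha_temp = rep(0, M), alpha_ef = 0,
         yr = matrix(0, M, T), sta = rep(0, arr$Nasta),
         iota = matrix(1, M, T - 1),
         s = matrix(rep(0.55 * mean_y, T), M, T),
         g = matrix(rep(0.45 * mean_y, T), M, T),
         eta = 0, om = rep(0, arr$Nro), eps = rep(0, length(arr$cnt$y)),
         sig_om = 0.5, sig_eps = 0.3, sig_nu = rep(0.2, M),
         sig_pi = rep(0.2, M), sig_yr = rep(0.3, M),
         sig_sta = 0.3, sig_psta = 0.5)
  }
  structure(list(log_posterior = function(par) sum(components(par)),
                 components = components,
                 example_params = example_params,
                 arrays = arr, priors = priors),
            class = "ipm_joint_model")
}
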