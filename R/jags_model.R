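# The joint model as BUGS code, plus the dense-array preparation shared by
# the JAGS backend and the R-side joint log-posterior.
#
# The transient-CJS component enters in marginalized form: with recapture
# probability constant over years within a station, each collapsed history
# group has closed-form likelihood
#   L_res = prod(phi over first..last-1) * p^d * (1-p)^(last-first-d) * chi[last]
# where chi[t] is the probability of never being seen after t given alive at
# t (backward recursion), and the residency mixture is
#   r = 1:  pi * rho * L_res
#   r = 0:  (1-pi) * I(no recaptures) + pi * (1-rho) * L_res.
# This is identical to the forward-recursion likelihood in
# `cjs_marginal_loglik()` / `transient_cjs_joint_loglik()` and enters JAGS
# through the zeros trick.

#' Dense model arrays from an assembled dataset
#'
#' Internal plumbing shared by [build_joint_model()] and
#' [sample_posterior()]: long count vectors with dense indices, standardized
#' covariate matrices, collapsed capture-history groups, productivity cells
#' with centered log-effort, initial-state priors and route weights.
#'
#' @param dataset A `model_dataset` from [assemble_dataset()].
#' @return A list of arrays (see source).
#' @keywords internal
build_model_arrays <- function(dataset) {
  M <- dataset$counts$M
  T <- dataset$T
  strata <- dataset$strata
  covz <- dataset$covariates
  getmat <- function(col) {
    out <- matrix(NA_real_, M, T)
    for (m in seq_len(M)) {
      rows <- covz[covz$stratum == strata[m], ]
      out[m, rows$year - dataset$year0 + 1] <- rows[[col]]
    }
    if (anyNA(out)) stop("covariate series incomplete for some stratum-year")
    out
  }
  rec <- dataset$counts$records
  cnt <- list(y = rec$count,
              m = unname(dataset$m_index[as.character(rec$stratum)]),
              t = rec$year - dataset$year0 + 1L,
              ro = unname(dataset$ro_index[as.character(rec$route_observer)]),
              novice = rec$novice)

  groups <- dataset$groups
  gsta_ids <- sort(unique(groups$station))
  gsta_index <- stats::setNames(seq_along(gsta_ids), gsta_ids)
  sta_m <- unname(dataset$m_index[as.character(
    groups$stratum[match(gsta_ids, groups$station)])])

  ages <- dataset$ages
  ages <- ages[ages$n_hy + ages$n_adult > 0, , drop = FALSE]
  asta_ids <- sort(unique(ages$station))
  asta_index <- stats::setNames(seq_along(asta_ids), asta_ids)
  leff <- log(ages$effort_net_hours)
  prod_cells <- list(hy = ages$n_hy, tot = ages$n_hy + ages$n_adult,
                     m = unname(dataset$m_index[as.character(ages$stratum)]),
                     t = ages$year - dataset$year0 + 1L,
                     sta = unname(asta_index[as.character(ages$station)]),
                     leff = leff - mean(leff))

  init <- lapply(strata, function(m) {
    y1 <- rec$count[rec$stratum == m & rec$year == dataset$year0]
    if (length(y1) == 0) list(mean = 1, sd = 10) else initial_state_prior(y1)
  })

  list(M = M, T = T, strata = strata,
       cmdz = getmat("cmd_z"), twz = getmat("tw_z"), tempz = getmat("temp_z"),
       cnt = cnt, Nro = length(dataset$ro_index),
       groups = data.frame(sta = unname(gsta_index[as.character(groups$station)]),
                           m = unname(dataset$m_index[as.character(groups$stratum)]),
                           first = groups$first, last = groups$last,
                           d = groups$n_recap, r = groups$r, mult = groups$mult),
       Nsta = length(gsta_ids), sta_m = sta_m,
       prod_cells = prod_cells, Nasta = length(asta_ids),
       init_mean = vapply(init, `[[`, numeric(1), "mean"),
       init_sd = vapply(init, `[[`, numeric(1), "sd"),
       w = dataset$meta$route_weight,
       area_weight = dataset$meta$area_weight,
       standardization = attr(dataset$covariates, "standardization"))
}

#' BUGS code of the joint integrated population model
#'
#' The three-component joint model: overdispersed-Poisson counts over the
#' truncated-Gaussian survivor/recruit process, the marginalized transient
#' CJS likelihood (zeros trick over collapsed history groups), and the
#' binomial age-ratio productivity model. Survival over interval t uses the
#' winter/spring covariates labelled year t+1; productivity in year t uses
#' year t covariates.
#'
#' @return A single character string of BUGS code.
#' @export
ipm_bugs_model <- function() {
'model {
  # ---- priors ----
  for (m in 1:M) {
    phi0[m] ~ dunif(0, 1)
    pi0[m] ~ dunif(0, 1)
    p0[m] ~ dunif(0, 1)
    rho[m] ~ dunif(0, 1)
    ri0[m] ~ dunif(0, 1)
    alpha0[m] <- logit(ri0[m])
    beta_cmd[m] ~ dnorm(0, coef_prec)
    beta_tw[m] ~ dnorm(0, coef_prec)
    alpha_cmd[m] ~ dnorm(0, coef_prec)
    alpha_temp[m] ~ dnorm(0, coef_prec)
    sig_nu[m] ~ dunif(0, sd_upper);  tau_nu[m] <- pow(sig_nu[m], -2)
    sig_pi[m] ~ dunif(0, sd_upper);  tau_pi[m] <- pow(sig_pi[m], -2)
    sig_yr[m] ~ dunif(0, sd_upper);  tau_yr[m] <- pow(sig_yr[m], -2)
  }
  eta ~ dnorm(0, coef_prec)
  alpha_ef ~ dnorm(0, coef_prec)
  sig_om ~ dunif(0, sd_upper);   tau_om <- pow(sig_om, -2)
  sig_eps ~ dunif(0, sd_upper);  tau_eps <- pow(sig_eps, -2)
  sig_sta ~ dunif(0, sd_upper);  tau_sta <- pow(sig_sta, -2)
  sig_psta ~ dunif(0, sd_upper); tau_psta <- pow(sig_psta, -2)

  # ---- vital rates ----
  for (m in 1:M) {
    for (t in 1:T) {
      upi[m,t] ~ dnorm(0, tau_pi[m])
      logit(pi[m,t]) <- logit(pi0[m]) + upi[m,t]
      yr[m,t] ~ dnorm(0, tau_yr[m])
      logit(RI[m,t]) <- alpha0[m] + alpha_cmd[m]*cmdz[m,t]
                        + alpha_temp[m]*tempz[m,t] + yr[m,t]
    }
    for (t in 1:(T-1)) {
      nu[m,t] ~ dnorm(0, tau_nu[m])
      logit(phi[m,t]) <- logit(phi0[m]) + beta_cmd[m]*cmdz[m,t+1]
                         + beta_tw[m]*twz[m,t+1] + nu[m,t]
      iota[m,t] ~ dnorm(iota_pr_mean, iota_pr_prec) T(0,)
      gam[m,t] <- RI[m,t] * iota[m,t]
    }
  }

  # ---- population process (truncated-Gaussian approximations) ----
  for (m in 1:M) {
    s[m,1] ~ dnorm(init_mean[m], init_prec[m]) T(0,)
    g[m,1] ~ dnorm(init_mean[m], init_prec[m]) T(0,)
    n[m,1] <- s[m,1] + g[m,1]
    for (t in 2:T) {
      mu_s[m,t] <- n[m,t-1] * phi[m,t-1]
      tau_s[m,t] <- 1 / (mu_s[m,t] * (1 - phi[m,t-1]))
      s[m,t] ~ dnorm(mu_s[m,t], tau_s[m,t]) T(0,)
      mu_g[m,t] <- n[m,t-1] * gam[m,t-1]
      tau_g[m,t] <- 1 / mu_g[m,t]
      g[m,t] ~ dnorm(mu_g[m,t], tau_g[m,t]) T(0,)
      n[m,t] <- s[m,t] + g[m,t]
    }
  }

  # ---- count observation model ----
  for (i in 1:Nro) { om[i] ~ dnorm(0, tau_om) }
  for (c in 1:Ncnt) {
    eps[c] ~ dnorm(0, tau_eps)
    log(lam[c]) <- log(n[cnt_m[c], cnt_t[c]]) + om[cnt_ro[c]]
                   + eta * novice[c] + eps[c]
    y[c] ~ dpois(lam[c])
  }

  # ---- marginalized transient CJS (zeros trick on history groups) ----
  for (k in 1:Nsta) {
    psta[k] ~ dnorm(0, tau_psta)
    logit(p[k]) <- logit(p0[sta_m[k]]) + psta[k]
    chi[k,T] <- 1
    for (t in 1:(T-1)) {
      chi[k,T-t] <- (1 - phi[sta_m[k],T-t])
                    + phi[sta_m[k],T-t] * (1 - p[k]) * chi[k,T-t+1]
    }
  }
  for (m in 1:M) {
    clphi[m,1] <- 0
    for (t in 2:T) { clphi[m,t] <- clphi[m,t-1] + log(phi[m,t-1]) }
  }
  for (q in 1:G) {
    lres[q] <- clphi[g_m[q], g_last[q]] - clphi[g_m[q], g_first[q]]
               + g_d[q] * log(p[g_sta[q]])
               + (g_last[q] - g_first[q] - g_d[q]) * log(1 - p[g_sta[q]])
    Lres[q] <- exp(lres[q]) * chi[g_sta[q], g_last[q]]
    L[q] <- g_r[q] * pi[g_m[q], g_first[q]] * rho[g_m[q]] * Lres[q]
            + (1 - g_r[q]) * ((1 - pi[g_m[q], g_first[q]]) * g_eq0[q]
                              + pi[g_m[q], g_first[q]] * (1 - rho[g_m[q]]) * Lres[q])
    zeros[q] ~ dpois(-g_mult[q] * log(max(L[q], 1.0E-300)))
  }

  # ---- binomial age-ratio productivity ----
  for (k in 1:Nasta) { sta[k] ~ dnorm(0, tau_sta) }
  for (c in 1:Npc) {
    logit(qhy[c]) <- alpha0[pc_m[c]] + alpha_ef * pc_leff[c]
                     + alpha_cmd[pc_m[c]] * cmdz[pc_m[c], pc_t[c]]
                     + alpha_temp[pc_m[c]] * tempz[pc_m[c], pc_t[c]]
                     + yr[pc_m[c], pc_t[c]] + sta[pc_sta[c]]
    pc_hy[c] ~ dbin(qhy[c], pc_tot[c])
  }
}'
}

# JAGS data list from model arrays + priors
build_jags_data <- function(arr, priors) {
  list(M = arr$M, T = arr$T,
       cmdz = arr$cmdz, twz = arr$twz, tempz = arr$tempz,
       coef_prec = 1 / priors$coef_sd^2, sd_upper = priors$sd_upper,
       iota_pr_mean = priors$iota_mean, iota_pr_prec = 1 / priors$iota_sd^2,
       init_mean = arr$init_mean, init_prec = 1 / arr$init_sd^2,
       Ncnt = length(arr$cnt$y), y = arr$cnt$y, cnt_m = arr$cnt$m,
       cnt_t = arr$cnt$t, cnt_ro = arr$cnt$ro, novice = arr$cnt$novice,
       Nro = arr$Nro,
       Nsta = arr$Nsta, sta_m = arr$sta_m,
       G = nrow(arr$groups), g_sta = arr$groups$sta, g_m = arr$groups$m,
       g_first = arr$groups$first, g_last = arr$groups$last,
       g_d = arr$groups$d, g_r = arr$groups$r,
       g_eq0 = as.numeric(arr$groups$d == 0), g_mult = arr$groups$mult,
       zeros = rep(0, nrow(arr$groups)),
       Npc = length(arr$prod_cells$hy), pc_hy = arr$prod_cells$hy,
       pc_tot = arr$prod_cells$tot, pc_m = arr$prod_cells$m,
       pc_t = arr$prod_cells$t, pc_sta = arr$prod_cells$sta,
       pc_leff = arr$prod_cells$leff, Nasta = arr$Nasta)
}

# moderate starting values; latent states seeded from stratum mean counts
build_jags_inits <- function(arr, seed, chain) {
  T <- arr$T; M <- arr$M
  mean_y <- matrix(1, M, T)
  for (m in seq_len(M)) {
    for (t in seq_len(T)) {
      ym <- arr$cnt$y[arr$cnt$m == m & arr$cnt$t == t]
      mean_y[m, t] <- max(mean(ym), 0.5)
      if (length(ym) == 0) mean_y[m, t] <- 1
    }
  }
  list(phi0 = rep(0.5, M), pi0 = rep(0.5, M), p0 = rep(0.3, M),
       rho = rep(0.5, M), ri0 = rep(0.2, M),
       beta_cmd = rep(0, M), beta_tw = rep(0, M),
       alpha_cmd = rep(0, M), alpha_temp = rep(0, M),
       eta = 0, alpha_ef = 0,
       sig_nu = rep(0.2, M), sig_pi = rep(0.2, M), sig_yr = rep(0.3, M),
       sig_om = 0.5, sig_eps = 0.3, sig_sta = 0.3, sig_psta = 0.5,
       s = 0.55 * mean_y, g = 0.45 * mean_y,
       iota = matrix(1, M, T - 1),
       .RNG.name = "base::Mersenne-Twister",
       .RNG.seed = (seed + 1000L * chain) %% 2147483647L)
}
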