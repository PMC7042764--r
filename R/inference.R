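# Fitting the joint model by MCMC (JAGS backend), convergence checking, and
# posterior summarization with derived abundance/trend/LTRE quantities.

#' Prior specification
#'
#' Probability-scale intercepts (mean survival, residency, recapture,
#' observed-residency, mean productivity) get Uniform(0, 1) priors; fixed
#' regression coefficients get Normal(0, sd `coef_sd`) priors (default
#' variance 1000); sd hyperparameters get Uniform(0, `sd_upper`); the
#' first-year-survival/immigration multiplier `iota` gets a Normal(`iota_mean`,
#' sd `iota_sd`) prior truncated to `[0, Inf)` - weakly informative, centered
#' at 1 with a wide sd so only a plausible range is enforced. Set
#' `iota_sd = 0.1` for the tight-prior sensitivity variant.
#'
#' @param coef_sd Sd of coefficient priors.
#' @param sd_upper Upper bound of sd-hyperparameter priors.
#' @param iota_mean,iota_sd Truncated-normal prior for `iota`.
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(coef_sd = sqrt(1000), sd_upper = 10,
                       iota_mean = 1, iota_sd = 10) {
  stopifnot(coef_sd > 0, sd_upper > 0, iota_sd > 0)
  structure(list(coef_sd = coef_sd, sd_upper = sd_upper,
                 iota_mean = iota_mean, iota_sd = iota_sd),
            class = "prior_spec")
}

#' MCMC settings
#'
#' The `"paper"` preset reproduces the original fitting protocol: 4 chains,
#' 40,000 adaptation iterations, 20,000 burn-in, 80,000 retained draws total
#' after thinning by 4. The `"reduced"` preset (2 chains, 1,000/1,000, 2,000
#' retained draws) is sized for validation runs on synthetic data.
#'
#' @param preset `"reduced"` or `"paper"`.
#' @param chains,adapt,burn,draws,thin Override individual settings; `draws`
#'   is the total retained across chains (the authoritative quantity).
#' @return An `mcmc_settings` list.
#' @export
mcmc_settings <- function(preset = c("reduced", "paper"), chains = NULL,
                          adapt = NULL, burn = NULL, draws = NULL, thin = NULL) {
  preset <- match.arg(preset)
  def <- if (preset == "paper") {
    list(chains = 4L, adapt = 40000L, burn = 20000L, draws = 80000L, thin = 4L)
  } else {
    list(chains = 2L, adapt = 1000L, burn = 1000L, draws = 2000L, thin = 1L)
  }
  for (nm in c("chains", "adapt", "burn", "draws", "thin")) {
    v <- get(nm)
    if (!is.null(v)) def[[nm]] <- as.integer(v)
  }
  stopifnot(all(unlist(def) > 0), def$draws %% def$chains == 0)
  structure(c(def, list(preset = preset)), class = "mcmc_settings")
}

#' Default monitored nodes
#'
#' All top-level parameters plus the latent abundance index `n` and the
#' vital-rate series (`phi`, `RI`, `iota`) needed for trends and the LTRE.
#' @return Character vector of node names.
#' @export
default_monitors <- function() {
  c("phi0", "beta_cmd", "beta_tw", "alpha0", "alpha_cmd", "alpha_temp",
    "alpha_ef", "eta", "pi0", "p0", "rho", "sig_om", "sig_eps", "sig_nu",
    "sig_pi", "sig_yr", "sig_sta", "sig_psta", "n", "phi", "RI", "iota")
}

#' Sample the joint posterior
#'
#' Compiles the BUGS model (see [ipm_bugs_model()]) with the assembled data
#' and runs JAGS: adaptation, burn-in, then `draws` retained samples total
#' across chains after thinning. Reproducible given `seed` (per-chain RNG
#' seeds are derived from it).
#'
#' @param dataset A `model_dataset`.
#' @param settings An [mcmc_settings()].
#' @param priors A [prior_spec()].
#' @param seed Integer seed.
#' @param monitors Character vector of nodes to monitor (default covers all
#'   parameters plus the latent abundance and vital-rate series).
#' @param quiet Suppress JAGS progress output.
#' @return An `ipm_fit`: list with `samples` (a `coda::mcmc.list`), `meta`
#'   (strata, years, weights, covariate standardization), `settings`,
#'   `priors`, and a run `manifest`.
#' @export
sample_posterior <- function(dataset, settings = mcmc_settings("reduced"),
                             priors = prior_spec(), seed = 1,
                             monitors = default_monitors(), quiet = TRUE) {
  arr <- build_model_arrays(dataset)
  jdata <- build_jags_data(arr, priors)
  inits <- lapply(seq_len(settings$chains), function(ch) {
    build_jags_inits(arr, as.integer(seed), ch)
  })
  jm <- rjags::jags.model(textConnection(ipm_bugs_model()), data = jdata,
                          inits = inits, n.chains = settings$chains,
                          n.adapt = settings$adapt, quiet = quiet)
  update(jm, settings$burn, progress.bar = "none")
  per_chain <- settings$draws %/% settings$chains
  samples <- rjags::coda.samples(jm, monitors, per_chain * settings$thin,
                                 thin = settings$thin, progress.bar = "none")
  meta <- list(strata = arr$strata, M = arr$M, T = arr$T,
               year0 = dataset$year0, w = arr$w,
               area_weight = arr$area_weight,
               standardization = arr$standardization)
  manifest <- list(seed = as.integer(seed),
                   settings = unclass(settings)[c("chains", "adapt", "burn",
                                                 "draws", "thin", "preset")],
                   priors = unclass(priors),
                   n_count_records = length(arr$cnt$y),
                   n_history_groups = nrow(arr$groups),
                   n_productivity_cells = length(arr$prod_cells$hy),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  structure(list(samples = samples, meta = meta, settings = settings,
                 priors = priors, manifest = manifest),
            class = "ipm_fit")
}

#' Write the JSON run manifest
#' @param fit An `ipm_fit`.
#' @param path Output path.
#' @export
write_run_manifest <- function(fit, path) {
  manifest <- fit$manifest
  conv <- convergence_check(fit)
  manifest$converged <- attr(conv, "pass")
  manifest$max_rhat <- max(conv$rhat, na.rm = TRUE)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# draws matrix (all chains stacked) from an ipm_fit or mcmc.list
draws_matrix <- function(fit) {
  samples <- if (inherits(fit, "ipm_fit")) fit$samples else fit
  do.call(rbind, lapply(samples, as.matrix))
}

# pull a monitored array: name "phi" with dims c(M, T-1) -> [draw, M, T-1]
draws_array <- function(X, name, dims) {
  if (prod(dims) == 1 && name %in% colnames(X)) {
    idx <- name
  } else {
    grid <- expand.grid(lapply(dims, seq_len))
    idx <- paste0(name, "[", apply(grid, 1, paste, collapse = ","), "]")
  }
  missing <- setdiff(idx, colnames(X))
  if (length(missing) > 0) stop("monitored node(s) not found: ", missing[1])
  array(X[, idx], dim = c(nrow(X), dims))
}

#' Split-chain potential scale reduction (R-hat)
#'
#' Each chain is split in half; R-hat is
#' `sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean within-sequence variance
#' and `B` the between-sequence variance of the 2C half-chains.
#'
#' @param fit An `ipm_fit` or `coda::mcmc.list` (>= 2 chains).
#' @param threshold Pass threshold (default 1.1).
#' @return Data frame (`parameter`, `rhat`) with attribute `pass`
#'   (`TRUE` iff all finite R-hat < threshold).
#' @export
convergence_check <- function(fit, threshold = 1.1) {
  samples <- if (inherits(fit, "ipm_fit")) fit$samples else fit
  if (length(samples) < 2) stop("R-hat needs at least 2 chains")
  mats <- lapply(samples, as.matrix)
  n2 <- floor(nrow(mats[[1]]) / 2)
  halves <- list()
  for (m in mats) {
    halves <- c(halves, list(m[1:n2, , drop = FALSE],
                             m[(nrow(m) - n2 + 1):nrow(m), , drop = FALSE]))
  }
  rhat <- vapply(seq_len(ncol(mats[[1]])), function(j) {
    means <- vapply(halves, function(h) mean(h[, j]), numeric(1))
    vars <- vapply(halves, function(h) stats::var(h[, j]), numeric(1))
    W <- mean(vars)
    B <- n2 * stats::var(means)
    if (!is.finite(W) || W == 0) return(1)
    sqrt(((n2 - 1) / n2 * W + B / n2) / W)
  }, numeric(1))
  out <- data.frame(parameter = colnames(mats[[1]]), rhat = rhat)
  attr(out, "pass") <- all(out$rhat < threshold, na.rm = TRUE)
  out
}

#' Summarize the posterior and derive abundance, trends and LTRE inputs
#'
#' Produces the parameter summary table (mean, sd, 2.5/50/97.5 percentiles),
#' per-draw abundance indices `N_{m,t} = w_m * exp(log n_{m,t} +
#' 0.5*sigma_omega^2 + 0.5*sigma_eps^2)`, the area-weighted composite series,
#' per-draw trends (geometric-mean growth, %/year), and the per-draw
#' vital-rate series (`phi`, `RI`, `iota`) that feed the LTRE.
#'
#' @param fit An `ipm_fit`.
#' @return List with `params` (summary data frame), `N` (`[draw, M, T]`),
#'   `N_composite` (`[draw, T]`), `trend_draws` (`[draw, M+1]`, last column
#'   composite), `trend` (summary data frame), `rates` (list of per-draw
#'   `phi`, `RI`, `iota` arrays), `years`, `strata`.
#' @export
summarize_posterior <- function(fit) {
  X <- draws_matrix(fit)
  meta <- fit$meta
  M <- meta$M; T <- meta$T
  qs <- function(v) stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
  params <- data.frame(parameter = colnames(X),
                       mean = colMeans(X),
                       sd = apply(X, 2, stats::sd),
                       q2.5 = apply(X, 2, function(v) qs(v)[1]),
                       q50 = apply(X, 2, function(v) qs(v)[2]),
                       q97.5 = apply(X, 2, function(v) qs(v)[3]),
                       row.names = NULL)
  n_arr <- draws_array(X, "n", c(M, T))
  sig_om <- as.numeric(X[, "sig_om"])
  sig_eps <- as.numeric(X[, "sig_eps"])
  corr <- exp(0.5 * sig_om^2 + 0.5 * sig_eps^2)
  N <- n_arr
  for (m in seq_len(M)) N[, m, ] <- n_arr[, m, ] * meta$w[m] * corr
  Nc <- matrix(0, nrow(X), T)
  for (m in seq_len(M)) Nc <- Nc + meta$area_weight[m] * N[, m, ]
  trend_draws <- matrix(0, nrow(X), M + 1)
  for (m in seq_len(M)) trend_draws[, m] <- apply(N[, m, , drop = FALSE], 1,
                                                  function(v) trend(as.numeric(v)))
  trend_draws[, M + 1] <- apply(Nc, 1, trend)
  colnames(trend_draws) <- c(meta$strata, "composite")
  trend_sum <- data.frame(stratum = colnames(trend_draws),
                          mean = colMeans(trend_draws),
                          q2.5 = apply(trend_draws, 2, function(v) qs(v)[1]),
                          q50 = apply(trend_draws, 2, function(v) qs(v)[2]),
                          q97.5 = apply(trend_draws, 2, function(v) qs(v)[3]),
                          row.names = NULL)
  rates <- list(phi = draws_array(X, "phi", c(M, T - 1)),
                RI = draws_array(X, "RI", c(M, T)),
                iota = draws_array(X, "iota", c(M, T - 1)))
  list(params = params, N = N, N_composite = Nc, trend_draws = trend_draws,
       trend = trend_sum, rates = rates,
       years = meta$year0 + seq_len(T) - 1L, strata = meta$strata)
}

#' Write posterior summaries as CSV
#'
#' Long-format summary (`parameter, stratum, year, mean, sd, q2.5, q50,
#' q97.5`): indexed parameters are expanded with stratum labels and calendar
#' years where applicable.
#'
#' @param summary Output of [summarize_posterior()].
#' @param path Output CSV path.
#' @export
write_posterior_csv <- function(summary, path) {
  df <- summary$params
  idx <- regmatches(df$parameter, regexec("^([a-zA-Z_0-9]+)\\[([0-9]+)(,([0-9]+))?\\]$",
                                          df$parameter))
  base <- vapply(seq_along(idx), function(i) {
    if (length(idx[[i]]) > 0) idx[[i]][2] else df$parameter[i]
  }, character(1))
  i1 <- vapply(seq_along(idx), function(i) {
    if (length(idx[[i]]) > 0) as.integer(idx[[i]][3]) else NA_integer_
  }, integer(1))
  i2 <- vapply(seq_along(idx), function(i) {
    if (length(idx[[i]]) > 0 && idx[[i]][5] != "") as.integer(idx[[i]][5]) else NA_integer_
  }, integer(1))
  out <- data.frame(parameter = base,
                    stratum = ifelse(is.na(i1), NA, summary$strata[i1]),
                    year = ifelse(is.na(i2), NA, summary$years[1] + i2 - 1L),
                    df[, c("mean", "sd", "q2.5", "q50", "q97.5")])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
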