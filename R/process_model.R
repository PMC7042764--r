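# State-space count model: overdispersed-Poisson observation layer over a
# continuous population process in which survivors and recruits follow
# truncated-Gaussian approximations of binomial and Poisson demography.

#' Overdispersed Poisson count log-likelihood
#'
#' Log-density of one route-by-observer-by-year count under the observation
#' model: `y ~ Poisson(lambda)` with
#' `log lambda = log(n) + omega + eta * novice + eps`, where `n` is the
#' stratum-year population index, `omega` a route-by-observer random effect,
#' `eta` a novice (start-up-year) observer effect, and `eps` an
#' overdispersion effect.
#'
#' @param y Non-negative integer count.
#' @param log_n Log population index for the stratum-year.
#' @param omega,eta,novice,eps Observation effects; `novice` is the 0/1
#'   start-up-year indicator.
#' @return Log-density. Vectorized.
#' @export
count_loglik <- function(y, log_n, omega = 0, eta = 0, novice = 0, eps = 0) {
  if (any(y < 0) || any(y != round(y))) stop("`y` must be non-negative integers")
  lp <- log_n + omega + eta * novice + eps
  if (any(!is.finite(lp))) stop("non-finite linear predictor in count model")
  stats::dpois(y, exp(lp), log = TRUE)
}

# log-density of Normal(mean, sd) truncated to [0, Inf), with normalizing
# constant; -Inf below the support.
trunc_normal_logpdf <- function(x, mean, sd) {
  if (any(sd <= 0)) stop("truncated-normal sd must be positive")
  out <- stats::dnorm(x, mean, sd, log = TRUE) -
    stats::pnorm(0, mean, sd, lower.tail = FALSE, log.p = TRUE)
  out[x < 0] <- -Inf
  out
}

#' Survivor process log-density (truncated-Gaussian binomial approximation)
#'
#' Survivors from year t-1 to t are modelled as
#' `s ~ Normal(n_prev * phi, n_prev * phi * (1 - phi))` truncated to
#' `[0, Inf)` - the moment-matched Gaussian approximation of
#' `Binomial(n_prev, phi)`, which keeps the process continuous so regional
#' indices need not be integers.
#'
#' @param s Number of survivors (non-negative real).
#' @param n_prev Previous-year population index (> 0).
#' @param phi Adult apparent survival probability in (0, 1).
#' @return Log-density including the truncation normalizing constant.
#' @export
survivor_logdensity <- function(s, n_prev, phi) {
  if (any(n_prev <= 0)) stop("`n_prev` must be positive")
  if (any(phi <= 0 | phi >= 1)) stop("`phi` must be in (0, 1)")
  v <- n_prev * phi * (1 - phi)
  if (any(v <= 0)) stop("zero process variance in survivor model")
  trunc_normal_logpdf(s, n_prev * phi, sqrt(v))
}

#' Recruit process log-density (truncated-Gaussian Poisson approximation)
#'
#' Recruits entering between years are modelled as
#' `g ~ Normal(n_prev * gamma, n_prev * gamma)` truncated to `[0, Inf)` - the
#' moment-matched Gaussian approximation of `Poisson(n_prev * gamma)`, where
#' recruitment decomposes as `gamma = RI * iota` (productivity index times
#' first-year-survival/immigration).
#'
#' @param g Number of recruits (non-negative real).
#' @param n_prev Previous-year population index (> 0).
#' @param gamma Per-capita recruitment rate (> 0).
#' @return Log-density including the truncation normalizing constant.
#' @export
recruit_logdensity <- function(g, n_prev, gamma) {
  if (any(n_prev <= 0)) stop("`n_prev` must be positive")
  if (any(gamma <= 0)) stop("`gamma` must be positive")
  trunc_normal_logpdf(g, n_prev * gamma, sqrt(n_prev * gamma))
}

#' Logit-linear adult survival model
#'
#' `logit(phi) = logit(phi0) + beta_cmd * cmd + beta_tw * tw + nu`, where
#' `cmd` is the winter drought (climate-moisture-deficit) anomaly, `tw` the
#' mean spring-migration tailwind, and `nu` a mean-zero stratum-specific year
#' effect.
#'
#' @param phi0 Stratum mean survival on the probability scale, in (0, 1).
#' @param beta_cmd,cmd Winter-drought coefficient and covariate value.
#' @param beta_tw,tw Tailwind coefficient and covariate value.
#' @param nu Random year effect.
#' @return Survival probability in (0, 1). Vectorized.
#' @export
survival_linpred <- function(phi0, beta_cmd = 0, cmd = 0, beta_tw = 0, tw = 0, nu = 0) {
  if (any(phi0 <= 0 | phi0 >= 1)) stop("`phi0` must be in (0, 1)")
  stats::plogis(stats::qlogis(phi0) + beta_cmd * cmd + beta_tw * tw + nu)
}

#' Route-level abundance index with lognormal mean correction
#'
#' `N = w * exp(log(n) + 0.5 * sigma_omega^2 + 0.5 * sigma_eps^2)`: the
#' population index rescaled by the lognormal means of the route-by-observer
#' and overdispersion effect distributions, times the stratum route weight
#' `w` (proportion of routes on which the species was encountered).
#'
#' @param n Population index (> 0).
#' @param sigma_omega Sd of route-by-observer effects.
#' @param sigma_eps Sd of overdispersion effects.
#' @param w Stratum route weight in (0, 1].
#' @return Abundance index. Vectorized.
#' @export
abundance_index <- function(n, sigma_omega, sigma_eps, w = 1) {
  if (any(n <= 0)) stop("`n` must be positive")
  if (any(sigma_omega < 0) || any(sigma_eps < 0)) stop("sds must be non-negative")
  w * exp(log(n) + 0.5 * sigma_omega^2 + 0.5 * sigma_eps^2)
}

#' Population trend as geometric mean growth
#'
#' Trend (%/year) is `100 * (geometric mean of lambda_t - 1)` where
#' `lambda_t = N_{t+1} / N_t` are realized annual growth rates.
#'
#' @param N Positive abundance series (length >= 2, chronological).
#' @return Trend in percent per year.
#' @export
trend <- function(N) {
  if (length(N) < 2) stop("need at least 2 years to compute a trend")
  if (any(N <= 0)) stop("`N` must be positive")
  100 * (exp(mean(diff(log(N)))) - 1)
}

#' Composite (area-weighted) abundance and trend across strata
#'
#' Composite abundance is `N_t = sum_m a_m * N_{m,t}` with area weights
#' `a_m`; the composite trend is [trend()] of that series.
#'
#' @param N_mat Matrix of abundance indices, strata in rows, years in columns.
#' @param area_weights Per-stratum area proportions summing to 1.
#' @return List with `N` (composite series) and `trend_pct` (%/year).
#' @export
composite_trend <- function(N_mat, area_weights) {
  if (!is.matrix(N_mat)) N_mat <- rbind(N_mat)
  if (length(area_weights) != nrow(N_mat)) stop("one area weight per stratum required")
  if (abs(sum(area_weights) - 1) > 1e-8) stop("area weights must sum to 1")
  Ns <- as.numeric(crossprod(area_weights, N_mat))
  list(N = Ns, trend_pct = trend(Ns))
}

#' Weakly informative initial-state prior from first-year counts
#'
#' First-year survivors and recruits each get an independent truncated-Normal
#' `[0, Inf)` prior centered at half the stratum's mean first-year count with
#' sd equal to 10 times that mean count - diffuse enough that the initial
#' state is determined mainly by the count data.
#'
#' @param y_first First-year counts observed in the stratum.
#' @return List with `mean` and `sd` of the (shared) survivor and recruit
#'   priors.
#' @export
initial_state_prior <- function(y_first) {
  if (length(y_first) == 0) stop("no first-year counts supplied")
  m <- mean(y_first)
  if (m <= 0) return(list(mean = 1, sd = 10))
  list(mean = m / 2, sd = 10 * m)
}

# integer-bin probability mass of Normal(mean, sd) truncated to [0, Inf)
trunc_normal_bin_mass <- function(k, mean, sd) {
  lo <- pmax(k - 0.5, 0)
  hi <- k + 0.5
  z <- stats::pnorm(0, mean, sd, lower.tail = FALSE)
  (stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd)) / z
}

#' Total variation distance between the Gaussian survivor approximation and
#' the exact binomial
#'
#' Compares the truncated-Normal(n*phi, n*phi*(1-phi)) survivor model against
#' Binomial(n, phi) on integer bins (bin k spans `[k - 0.5, k + 0.5]`,
#' clipped at 0): `TV = 0.5 * sum_k |approx mass - pmf|`.
#'
#' @param n Binomial size.
#' @param phi Success probability.
#' @return Total variation distance in `[0, 1]`.
#' @export
gaussian_binomial_tv <- function(n, phi) {
  mu <- n * phi
  sd <- sqrt(n * phi * (1 - phi))
  kmax <- max(n, ceiling(mu + 12 * sd))
  k <- 0:kmax
  approx <- trunc_normal_bin_mass(k, mu, sd)
  exact <- ifelse(k <= n, stats::dbinom(pmin(k, n), n, phi), 0)
  0.5 * sum(abs(approx - exact))
}

#' Total variation distance between the Gaussian recruit approximation and
#' the exact Poisson
#'
#' Compares truncated-Normal(n*gamma, n*gamma) against Poisson(n*gamma) on
#' integer bins.
#'
#' @param n Previous population size.
#' @param gamma Per-capita recruitment rate.
#' @return Total variation distance in `[0, 1]`.
#' @export
gaussian_poisson_tv <- function(n, gamma) {
  mu <- n * gamma
  sd <- sqrt(mu)
  kmax <- ceiling(mu + 12 * sd)
  k <- 0:kmax
  approx <- trunc_normal_bin_mass(k, mu, sd)
  exact <- stats::dpois(k, mu)
  0.5 * sum(abs(approx - exact))
}
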