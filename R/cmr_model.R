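# Transient Cormack-Jolly-Seber likelihood for adult capture histories, the
# residency observation model, and the binomial age-ratio productivity model.
#
# Latent structure per individual: residency state R ~ Bern(pi) fixed at
# marking (transients, R = 0, are never available for recapture again), and
# an alive state z that survives each interval with probability phi and is
# absorbing on death. Both are marginalized out analytically (forward
# recursion over z, mixture over R) so the likelihood is a smooth function of
# (pi, phi, p, rho) and can be checked against brute-force enumeration.

# forward recursion for the standard CJS likelihood of one history,
# conditional on residency (R = 1) and release at occasion 1 of `history`
cjs_forward <- function(history, phi_seq, p_seq) {
  len <- length(history)
  if (len == 1) return(1)
  f_alive <- 1
  f_dead <- 0
  for (t in 2:len) {
    a <- f_alive * phi_seq[t - 1]
    d <- f_dead + f_alive * (1 - phi_seq[t - 1])
    if (history[t] == 1) {
      f_alive <- a * p_seq[t - 1]
      f_dead <- 0
    } else {
      f_alive <- a * (1 - p_seq[t - 1])
      f_dead <- d
    }
  }
  f_alive + f_dead
}

#' Marginalized transient-CJS log-likelihood of one capture history
#'
#' Likelihood of a capture history (starting at the marking occasion, where
#' `history[1] == 1`) with the residency and alive states marginalized out:
#' `L = (1 - pi) * I(no recaptures) + pi * L_CJS(history | phi, p)`, where
#' `L_CJS` is the standard Cormack-Jolly-Seber likelihood computed by forward
#' recursion over the alive state with absorbing death. Transients (residency
#' state 0) have zero probability of recapture after marking.
#'
#' @param history 0/1 detection vector from the marking year onward;
#'   `history[1]` must be 1.
#' @param pi Residency probability at marking, in `[0, 1]`.
#' @param phi_seq Survival probabilities for the `length(history) - 1`
#'   intervals following marking.
#' @param p_seq Recapture probabilities for occasions `2..length(history)`.
#' @return Log-likelihood (scalar).
#' @export
cjs_marginal_loglik <- function(history, pi, phi_seq, p_seq) {
  len <- length(history)
  if (history[1] != 1) stop("`history[1]` must be 1 (the marking occasion)")
  if (len > 1 && (length(phi_seq) != len - 1 || length(p_seq) != len - 1)) {
    stop("`phi_seq` and `p_seq` must have length(history) - 1 elements")
  }
  any_recap <- len > 1 && any(history[-1] == 1)
  if (any_recap && pi <= 1e-12) {
    warning("recapture observed but residency probability ~ 0; likelihood is 0")
    return(-Inf)
  }
  l_cjs <- cjs_forward(history, phi_seq, p_seq)
  log((1 - pi) * as.numeric(!any_recap) + pi * l_cjs)
}

#' Residency observation log-likelihood
#'
#' A newly marked bird is scored as an observed resident (`r = 1`) only if it
#' is a true resident (probability `pi`) and its residency is detected
#' (probability `rho`); transients can never be observed as residents.
#' Marginally, `P(r = 1) = pi * rho`.
#'
#' @param r Observed-residency indicator (0/1).
#' @param pi Residency probability.
#' @param rho Probability a true resident is observed as resident.
#' @return Log-likelihood contribution. Vectorized.
#' @export
residency_obs_loglik <- function(r, pi, rho) {
  if (any(r != 0 & r != 1)) stop("`r` must be 0 or 1")
  ifelse(r == 1, log(pi * rho), log1p(-pi * rho))
}

#' Joint log-likelihood of a capture history and its residency observation
#'
#' The joint marginal over (R, z) of a history and the marking-year residency
#' flag. An observed resident (`r = 1`) implies `R = 1`, so the transient
#' branch is zeroed; with `r = 0` the history may come from a transient (only
#' if it has no recaptures) or from an undetected resident:
#' \deqn{L(h, r=1) = \pi \rho \, L_{CJS}(h)}
#' \deqn{L(h, r=0) = (1-\pi) I(\text{no recaptures}) + \pi (1-\rho) L_{CJS}(h)}
#'
#' @inheritParams cjs_marginal_loglik
#' @param r Observed-residency indicator at marking (0/1).
#' @param rho Probability a true resident is observed as resident.
#' @return Log-likelihood (scalar).
#' @export
transient_cjs_joint_loglik <- function(history, r, pi, phi_seq, p_seq, rho) {
  len <- length(history)
  if (history[1] != 1) stop("`history[1]` must be 1 (the marking occasion)")
  any_recap <- len > 1 && any(history[-1] == 1)
  l_cjs <- cjs_forward(history, phi_seq, p_seq)
  if (r == 1) {
    log(pi * rho * l_cjs)
  } else {
    log((1 - pi) * as.numeric(!any_recap) + pi * (1 - rho) * l_cjs)
  }
}

#' Binomial age-ratio productivity log-likelihood
#'
#' One station-year cell of age-specific capture totals: the number of
#' hatch-year (HY) captures out of all captures is binomial with success
#' probability `plogis(linpred)`, where the linear predictor is
#' `alpha0_m + alpha_ef * log-effort (centered) + alpha_cmd * cmd +
#' alpha_temp * temp + yr_{m,t} + sta_k`.
#'
#' @param n_hy Hatch-year captures (0..`n_total`).
#' @param n_total Total captures in the cell; cells with `n_total = 0`
#'   contribute 0.
#' @param linpred Logit-scale linear predictor.
#' @return Log-likelihood. Vectorized.
#' @export
productivity_loglik <- function(n_hy, n_total, linpred) {
  if (any(n_hy > n_total)) stop("`n_hy` cannot exceed `n_total`")
  if (any(n_hy < 0) || any(n_total < 0)) stop("counts must be non-negative")
  out <- stats::dbinom(n_hy, n_total, stats::plogis(linpred), log = TRUE)
  out[n_total == 0] <- 0
  out
}

#' Reproductive index (expected HY proportion at reference effort)
#'
#' The productivity index entering recruitment, `RI = plogis(alpha0 +
#' alpha_cmd * cmd + alpha_temp * temp + yr)`: the expected proportion of
#' hatch-year birds among captures at reference (centered-zero) effort with
#' the station effect at 0.
#'
#' @param alpha0 Stratum intercept (logit scale).
#' @param alpha_cmd,cmd Winter-drought (carry-over) coefficient and value.
#' @param alpha_temp,temp Spring-temperature coefficient and value.
#' @param yr Random year effect.
#' @return Productivity index in (0, 1). Vectorized.
#' @export
reproductive_index <- function(alpha0, alpha_cmd = 0, cmd = 0,
                               alpha_temp = 0, temp = 0, yr = 0) {
  stats::plogis(alpha0 + alpha_cmd * cmd + alpha_temp * temp + yr)
}

#' Collapse capture histories to sufficient-statistic groups
#'
#' With recapture probability constant over years within a station, the
#' transient-CJS likelihood of a history depends only on (station, marking
#' year, last detection year, number of recaptures, residency flag). This
#' groups individuals accordingly, with multiplicities, which is what the
#' MCMC backend consumes.
#'
#' @param captures A `capture_data` object (see [load_captures()]).
#' @return Data frame with columns `station`, `stratum`, `first`, `last`,
#'   `n_recap`, `r`, `mult` (years as 1-based indices).
#' @export
collapse_histories <- function(captures) {
  ind <- captures$individuals
  det <- captures$detections
  Tn <- ncol(det)
  first <- ind$first
  last <- integer(nrow(det))
  n_recap <- integer(nrow(det))
  for (j in seq_len(nrow(det))) {
    hits <- which(det[j, ] == 1)
    last[j] <- max(hits)
    n_recap[j] <- length(hits) - 1L
  }
  key <- data.frame(station = ind$station, stratum = ind$stratum,
                    first = first, last = last, n_recap = n_recap,
                    r = ind$resident_observed)
  agg <- stats::aggregate(list(mult = rep(1L, nrow(key))),
                          by = key, FUN = sum)
  agg[order(agg$stratum, agg$station, agg$first, agg$last), , drop = FALSE]
}
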