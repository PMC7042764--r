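# Independent oracles used across tests.

# Exhaustive enumeration of the transient-CJS likelihood over all latent
# configurations: residency state R in {0, 1} and every monotone alive-state
# path (parameterized by the last occasion alive). Deliberately independent
# of the package's forward recursion.
#
# If `r` is NULL the residency observation is marginalized out (history-only
# likelihood); otherwise the joint of (history, r) is returned.
enum_transient_cjs <- function(history, r = NULL, pi, phi_seq, p_seq, rho = NULL) {
  len <- length(history)
  no_recap <- len == 1 || all(history[-1] == 0)
  l0 <- as.numeric(no_recap)                     # transient branch
  if (!is.null(r) && r == 1) l0 <- 0             # transients never scored resident
  l1 <- 0                                        # resident branch
  for (k in seq_len(len)) {                      # k = last occasion alive
    pr_alive <- if (k > 1) prod(phi_seq[seq_len(k - 1)]) else 1
    pr_death <- if (k < len) 1 - phi_seq[k] else 1
    det <- 1
    ok <- TRUE
    if (len > 1) {
      for (t in 2:len) {
        if (t <= k) {
          det <- det * (if (history[t] == 1) p_seq[t - 1] else 1 - p_seq[t - 1])
        } else if (history[t] == 1) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) l1 <- l1 + pr_alive * pr_death * det
  }
  robs <- if (is.null(r)) 1 else if (r == 1) rho else 1 - rho
  if (is.null(r)) {
    (1 - pi) * l0 + pi * l1
  } else {
    (1 - pi) * l0 + pi * robs * l1
  }
}

# all 0/1 continuation histories of a given length after the marking occasion
all_histories <- function(len) {
  if (len == 1) return(matrix(1, 1, 1))
  cont <- as.matrix(expand.grid(rep(list(0:1), len - 1)))
  unname(cbind(1, cont))
}

# a small joint dataset for fit-level tests (kept tiny on purpose)
micro_dataset <- function(seed = 5) {
  sc <- simulation_scenario(strata = "s1", T = 6, n_routes = 8, n_stations = 5,
                            n0 = 400, birds_per_route = 6, new_inds_rate = 3,
                            age_rate = 5)
  simulate_dataset(sc, seed = seed)
}
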