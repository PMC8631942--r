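# Independent oracles used across tests. These deliberately avoid the code
# paths they check: direct arithmetic, exhaustive enumeration, RK4.

RT298 <- 1.987e-3 * 298

# Langmuir curve, direct evaluation
oracle_langmuir <- function(kd, rmax, conc) rmax * conc / (kd + conc)

# six binding-mode free energies by hand arithmetic from four Kd's (uM)
oracle_mode_dgs <- function(kd_n_itim, kd_n_itsm, kd_c_itim, kd_c_itsm,
                            c_eff = 1e-3, temperature = 298) {
  rt <- 1.987e-3 * temperature
  dg <- function(kd_uM) rt * log(kd_uM * 1e-6)
  c(MONO_nSH2_ITIM = dg(kd_n_itim),
    MONO_nSH2_ITSM = dg(kd_n_itsm),
    MONO_cSH2_ITIM = dg(kd_c_itim),
    MONO_cSH2_ITSM = dg(kd_c_itsm),
    BIVALENT_PARALLEL = dg(kd_n_itim) + dg(kd_c_itsm) - rt * log(c_eff),
    BIVALENT_ANTIPARALLEL = dg(kd_n_itsm) + dg(kd_c_itim) - rt * log(c_eff))
}

# exhaustive Viterbi: enumerate all 2^T paths of a 2-state Gaussian HMM
oracle_viterbi_exhaustive <- function(y, mu, sigma, A, pi0) {
  T_ <- length(y)
  best_lp <- -Inf; best_path <- NULL
  for (code in 0:(2^T_ - 1)) {
    path <- as.integer(intToBits(code))[1:T_] + 1L
    lp <- log(pi0[path[1]]) + dnorm(y[1], mu[path[1]], sigma[path[1]], log = TRUE)
    for (t in 2:T_) {
      lp <- lp + log(A[path[t - 1], path[t]]) +
        dnorm(y[t], mu[path[t]], sigma[path[t]], log = TRUE)
    }
    if (lp > best_lp) { best_lp <- lp; best_path <- path }
  }
  list(path = best_path, logprob = best_lp)
}

# RK4 integration of dR/dt = kon*C*(Rmax - R) - koff*R
oracle_sensorgram_ode <- function(k_on, k_off, C, r_max, times) {
  f <- function(R) k_on * C * (r_max - R) - k_off * R
  R <- numeric(length(times)); R[1] <- 0
  for (i in 2:length(times)) {
    h <- times[i] - times[i - 1]
    k1 <- f(R[i - 1]); k2 <- f(R[i - 1] + h / 2 * k1)
    k3 <- f(R[i - 1] + h / 2 * k2); k4 <- f(R[i - 1] + h * k3)
    R[i] <- R[i - 1] + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  R
}

# discrete-chain probability that a receptor is bound in at least one of
# n frames, starting from stationarity (instantaneous-sampling approx.)
oracle_p_bound_once <- function(k_on, k_off, n_frames, dt) {
  lam <- k_on + k_off
  pi_u <- k_off / lam
  p_uu <- (k_off + k_on * exp(-lam * dt)) / lam
  1 - pi_u * p_uu^(n_frames - 1)
}

# shared small helpers
make_step_trace <- function(levels, lengths, sd, seed) {
  set.seed(seed)
  rep(levels, lengths) + rnorm(sum(lengths), 0, sd)
}
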