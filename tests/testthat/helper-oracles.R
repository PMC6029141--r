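# Independent oracles and small fixture builders used across the suite.

# RK4 integration of the one-compartment infusion ODE
#   dA/dt = rate_in(t) - (CL/V) A,  C = A/V
# integrated piecewise between dose on/off boundaries so the forcing is
# smooth within every segment.
ode_concentration <- function(params, doses, times, h = 0.005) {
  ke <- params$CL / params$V
  rate_in <- function(t) {
    r <- 0
    for (d in seq_len(nrow(doses))) {
      t0 <- doses$start[d]
      te <- t0 + doses$duration[d]
      if (t >= t0 && t < te) r <- r + doses$amount[d] / doses$duration[d]
    }
    r
  }
  breaks <- sort(unique(c(0, doses$start, doses$start + doses$duration,
                          times)))
  breaks <- breaks[breaks <= max(times)]
  A <- 0
  out <- numeric(length(times))
  t <- 0
  if (any(times == 0)) out[times == 0] <- 0
  for (b in breaks[breaks > 0]) {
    seg_len <- b - t
    n_step <- max(1L, ceiling(seg_len / h))
    hh <- seg_len / n_step
    rmid <- rate_in(t + seg_len / 2) # constant within segment
    f <- function(a) rmid - ke * a
    for (s in seq_len(n_step)) {
      k1 <- f(A)
      k2 <- f(A + hh / 2 * k1)
      k3 <- f(A + hh / 2 * k2)
      k4 <- f(A + hh * k3)
      A <- A + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    t <- b
    hit <- which(abs(times - b) < 1e-12)
    if (length(hit)) out[hit] <- A / params$V
  }
  out
}

# brute-force trapezoid marginal -2LL for a single subject, independent of
# the adaptive Gauss-Hermite path
trapezoid_neg2ll <- function(y, times, tvcl, tvv, doses, omega2, s2p, s2a,
                             grid_n = 20001, width = 8) {
  w <- sqrt(omega2)
  etas <- seq(-width * w, width * w, length.out = grid_n)
  ll <- vapply(etas, function(eta) {
    f <- vapply(seq_along(times), function(j) {
      predict_concentration(list(CL = tvcl[j] * exp(eta), V = tvv[j]),
                            doses, times[j])
    }, numeric(1))
    v <- pmax(s2p * f^2 + s2a, 1e-12)
    sum(dnorm(y, f, sqrt(v), log = TRUE)) + dnorm(eta, 0, w, log = TRUE)
  }, numeric(1))
  m <- max(ll)
  step <- etas[2] - etas[1]
  -2 * (m + log(sum(exp(ll - m)) * step))
}

# one-subject dataset with explicit values, for contract tests
make_subject_dataset <- function(id = "S001",
                                 doses = data.frame(start = c(0, 8, 16, 24, 32),
                                                    amount = 40,
                                                    duration = 2),
                                 obs_times = c(35, 39.5),
                                 obs_values = c(20, 8),
                                 kinds = c("peak", "trough"),
                                 wt = 2.9, scr = 23.3, ga = 36, pna = 21) {
  covs <- data.frame(time = 0, WT = wt, SCR = scr, GA = ga, PNA = pna,
                     PMA = ga + pna / 7, SEX = 0, BUN = 4, ALB = 32,
                     AST = 20, ALT = 40, CEF = 0, MER = 0, GEN = 0,
                     FUR = 0, IBU = 0, DEX = 0)
  obs <- data.frame(time = obs_times, value = obs_values, kind = kinds,
                    below_detection = obs_values < 1,
                    below_calibration = obs_values < 3,
                    stringsAsFactors = FALSE)
  subject_record(id, covs, doses, obs)
}

make_tiny_dataset <- function(n = 3, seed = 1) {
  set.seed(seed)
  subs <- lapply(seq_len(n), function(i) {
    wt <- runif(1, 2, 4)
    scr <- runif(1, 10, 40)
    doses <- data.frame(start = seq(0, 48, by = 8), amount = 12 * wt,
                        duration = 2)
    pars <- individual_params(fixed_effects(), rnorm(1, 0, 0.3), wt, scr)
    times <- c(35, 39.5)
    f <- predict_concentration(pars, doses, times)
    make_subject_dataset(sprintf("S%03d", i), doses, times,
                         f * exp(rnorm(2, 0, 0.2)),
                         c("peak", "trough"), wt, scr)
  })
  population_dataset(subs, provenance = list(fixture = "make_tiny_dataset"))
}
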