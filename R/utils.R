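`%||%` <- function(a, b) if (is.null(a)) b else a

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @noRd
stop_domain <- function(msg) stop(msg, call. = FALSE)

# rolling 31-hash of a string, reported as hex; a run fingerprint for logs,
# not a cryptographic digest
config_hash <- function(x) {
  if (!is.character(x)) {
    x <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  b <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (v in b) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", h)
}

# vectorized rejection sampler for truncated draws
rtrunc <- function(n, sampler, lo, hi, max_tries = 1000L) {
  out <- sampler(n)
  bad <- which(out < lo | out > hi)
  tries <- 0L
  while (length(bad) > 0L && tries < max_tries) {
    out[bad] <- sampler(length(bad))
    bad <- which(out < lo | out > hi)
    tries <- tries + 1L
  }
  if (length(bad) > 0L) out[bad] <- pmin(pmax(out[bad], lo), hi)
  out
}

# central finite-difference Hessian; f is scalar-valued
fd_hessian <- function(f, x, rel_step = 1e-4) {
  p <- length(x)
  h <- rel_step * pmax(1, abs(x))
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    fpi <- f(x + ei)
    fmi <- f(x - ei)
    H[i, i] <- (fpi - 2 * f0 + fmi) / h[i]^2
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        ej <- replace(numeric(p), j, h[j])
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
          (4 * h[i] * h[j])
      }
    }
  }
  H
}

# Gauss-Hermite nodes/weights (physicists' convention, weight exp(-x^2))
# by the Golub-Welsch eigen decomposition of the Jacobi matrix
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  b <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- b
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}
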