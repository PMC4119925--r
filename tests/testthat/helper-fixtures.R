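# Shared fixtures and independent oracles used across the test files.

# Small deterministic two-strain dataset (no randomness; 8 distinct doses
# so the default basis dimension needs no reduction).
make_counts <- function() {
  tibble::tibble(
    strain = rep(c("A", "B"), each = 16),
    experiment = rep(rep(c("e1", "e2"), each = 8), 2),
    dose = rep(c(0, 1, 2, 5, 10, 20, 40, 80), 4),
    count = c(200, 190, 175, 150, 110, 60, 18, 3,
              220, 205, 180, 160, 120, 70, 22, 5,
              300, 280, 240, 180, 100, 35, 8, 1,
              280, 270, 250, 170, 110, 40, 10, 2)
  )
}

# Flat dataset: identical counts at every dose (no dose effect).
make_flat_counts <- function(value = 100) {
  tibble::tibble(
    strain = rep(c("A", "B"), each = 12),
    experiment = rep(rep(c("e1", "e2"), each = 6), 2),
    dose = rep(c(0, 2, 5, 10, 20, 40), 4),
    count = value
  )
}

# Independent penalized-Poisson IRLS oracle on a prebuilt design
# (same objective as the package fit with theta -> infinity).
poisson_penalized_fit <- function(X, y, Slist, lambda, max_iter = 400,
                                  tol = 1e-12) {
  p <- ncol(X)
  P <- matrix(0, p, p)
  for (j in seq_along(Slist)) P <- P + lambda[j] * Slist[[j]]
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    w <- mu
    z <- eta + (y - mu) / mu
    A <- crossprod(X * w, X) + P + 1e-10 * diag(p)
    beta_new <- solve(A, crossprod(X * w, z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
    eta <- pmin(pmax(drop(X %*% beta), -40), 40)
    mu <- exp(eta)
  }
  drop(beta)
}

# Exhaustive-scan MIC oracle: smallest tested concentration c_i such that
# every call at c_i and above is no-growth; censored when none qualifies.
mic_oracle <- function(conc, growth) {
  o <- order(conc)
  conc <- conc[o]
  growth <- growth[o]
  k <- length(conc)
  for (i in seq_len(k)) {
    if (!any(growth[i:k])) {
      return(list(mic = conc[i], censored = FALSE))
    }
  }
  list(mic = conc[k], censored = TRUE)
}
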