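# Independent oracles and small fixture builders used across the tests.
# These deliberately avoid the package's pattern-grouped likelihood path.

# Multivariate normal log-density of one observed (sub)vector, via solve()
# and determinant() -- not chol/chol2inv, so it is an independent route.
dmvn_log <- function(y, mu, sigma) {
  k <- length(y)
  d <- y - mu
  -0.5 * (k * log(2 * pi) +
            as.numeric(determinant(sigma, logarithm = TRUE)$modulus) +
            sum(d * solve(sigma, d)))
}

# Brute-force row-by-row FIML log-likelihood.
rowwise_fiml <- function(Y, mu, sigma) {
  ll <- 0
  for (i in seq_len(nrow(Y))) {
    v <- which(!is.na(Y[i, ]))
    if (length(v) == 0) next
    ll <- ll + dmvn_log(Y[i, v], mu[v], sigma[v, v, drop = FALSE])
  }
  ll
}

# Complete-data Gaussian log-likelihood from per-row densities.
complete_loglik <- function(Y, mu, sigma) rowwise_fiml(Y, mu, sigma)

# A tiny deterministic wide panel: ids 1..n, both constructs, T waves.
tiny_panel <- function(n = 6, T = 3, labels = c("dep", "cm")) {
  ages <- list(seq(10, by = 2, length.out = T),
               seq(9.5, by = 2, length.out = T))
  names(ages) <- labels
  sch <- wave_schedule(ages)
  set.seed(99)
  data <- data.frame(id = seq_len(n))
  for (lab in labels) {
    for (w in seq_len(T)) {
      data[[paste0(lab, "_", w)]] <- round(runif(n, 1, 9), 3)
    }
  }
  raw_panel(data, sch)
}

# Truth whose raw-scale links are identity: simulated panels are exact
# draws from the model class (multivariate normal with the implied moments).
identity_truth <- function() {
  tr <- default_truth()
  tr$links <- list(dep = list(kind = "identity"),
                   cm = list(kind = "identity"))
  tr
}

riclpm_paths <- function(x) grep("^AR_|^CL_", names(x), value = TRUE)
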