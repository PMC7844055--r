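# shared fixtures, built in code at test time

# a coarse template: few neurons, fast to simulate
toy_template <- function(resolution = 35) {
  brain_template(resolution = resolution)
}

# small synthetic session for integration tests
small_session <- function(seed = 11, n_trials = 6) {
  generate_session(synth_config(n_trials = n_trials, seed = seed))
}

# default STDP parameter set used across reservoir tests
stdp_pars <- function() {
  list(A_plus = 0.01, A_minus = 0.012, tau_plus = 20, tau_minus = 25,
       enabled = TRUE)
}

# independent brute-force oracle for the STDP double sum: explicit loops,
# window written out inline (kept independent of stdp_window)
stdp_oracle <- function(pre, post, p) {
  acc <- 0
  for (tf in pre) for (tn in post) {
    x <- tn - tf
    acc <- acc + if (x > 0) p$A_plus * exp(-x / p$tau_plus)
    else if (x < 0) -p$A_minus * exp(x / p$tau_minus)
    else 0
  }
  acc
}

# independent shift-and-Pearson oracle for the lagged cross-correlation
xcorr_oracle <- function(a, b, L) {
  n <- length(a)
  vapply(-L:L, function(l) {
    if (l >= 0) { x <- a[1:(n - l)]; y <- b[(1 + l):n] }
    else { x <- a[(1 - l):n]; y <- b[1:(n + l)] }
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }, numeric(1))
}

# cached end-to-end fit on the default synthetic conditions, shared by the
# slower acceptance checks so the expensive fit runs once
default_fit_cache <- new.env(parent = emptyenv())
default_fit <- function(seed = 1) {
  key <- as.character(seed)
  if (is.null(default_fit_cache[[key]])) {
    ses <- generate_session(synth_config(seed = seed))
    default_fit_cache[[key]] <-
      list(session = ses,
           result = decode_session(ses, train_trials = 20, seed = seed))
  }
  default_fit_cache[[key]]
}
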