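# Shared fixtures: all tables are generated in code, none stored on disk.

# deterministic 2-year x 2-interval relative-survival toy table
toy_table <- function() {
  survtable(data.frame(
    year = c(2000L, 2000L, 2001L, 2001L),
    interval = c(1L, 2L, 1L, 2L),
    n_at_risk = c(100L, 80L, 120L, 100L),
    n_lost = c(10L, 8L, 10L, 6L),
    n_died = c(10L, 6L, 10L, 8L),
    e_exp = 0.95), mode = "relative")
}

toy_csv <- function(path = tempfile(fileext = ".csv")) {
  write_survival_table(toy_table(), path)
  path
}

# small simulated cohort used across tests: 20 diagnosis years, 5 intervals,
# one joinpoint mid-range (the standard recovery design)
quick_config <- function(seed, n = 2000, beta = -0.02, deltas = -0.08,
                         taus = NULL, years = 1981:2000, J = 5,
                         mode = "relative", ...) {
  if (is.null(taus)) taus <- round(mean(range(years)))   # mid-range joinpoint
  sim_config(year_range = years, J = J, cohort_size = n,
             beta = beta, deltas = deltas, taus = taus,
             mode = mode, seed = seed, ...)
}

quick_table <- function(seed, ...) simulate_table(quick_config(seed, ...))

# central finite differences of a scalar function, for derivative oracles
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    hi <- h * max(abs(x[i]), 1)
    up <- x; up[i] <- up[i] + hi
    dn <- x; dn[i] <- dn[i] - hi
    (f(up) - f(dn)) / (2 * hi)
  }, numeric(1))
}

fd_hessian <- function(f, x, h = 1e-5) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    hi <- h * max(abs(x[i]), 1)
    up <- x; up[i] <- up[i] + hi
    dn <- x; dn[i] <- dn[i] - hi
    H[i, ] <- (fd_gradient(f, up, h) - fd_gradient(f, dn, h)) / (2 * hi)
  }
  (H + t(H)) / 2
}

# rebuild a jp_params with a new free-parameter vector (taus fixed)
theta_to_params <- function(theta, ref) {
  J <- length(ref$alphas)
  K <- length(ref$taus)
  jp_params(theta[seq_len(J)], theta[J + 1L],
            if (K) theta[J + 1L + seq_len(K)] else numeric(),
            ref$taus, ref$anchor)
}
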