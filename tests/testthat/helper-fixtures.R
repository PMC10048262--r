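# Shared fixtures, all generated in code.

# Reduced simulation: 2 groups x 6 samples, short axis, few shots — fast
# enough for unit tests while keeping the full generative structure.
small_sim_config <- function(...) {
  defaults <- list(
    n_groups = 2, n_per_group = 6,
    group_means = rbind(Cd = c(1, 60), Cu = c(3, 100), Pb = c(1, 80)),
    group_sds = rbind(Cd = c(0.3, 10), Cu = c(1, 15), Pb = c(0.3, 12)),
    wl_start = 200, wl_stop = 700, wl_step = 1,
    n_shots = 3
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Noise-free variant (constant baseline channels exercise degenerate paths).
noiseless_sim_config <- function(...) {
  small_sim_config(noise_additive_sd = 0, noise_shot_sd = 0, ...)
}

# Low-dimensional regression fixture: y linear in a few columns plus noise.
linear_fixture <- function(n = 30, p = 8, seed = 42, noise_sd = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- c(3, -2, 1, rep(0, p - 3))
  list(X = X, y = as.numeric(X %*% beta) + rnorm(n, sd = noise_sd),
       beta = beta)
}

# Normal-equations OLS oracle (independent of the PLS path).
ols_oracle <- function(X, y) {
  Z <- cbind(1, X)
  as.numeric(solve(crossprod(Z), crossprod(Z, y)))
}

# Trapezoid integration oracle.
trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

cd_lines <- c(214.44, 226.50, 441.56, 467.90, 573.80, 643.85)

covers_lines <- function(selected, wavelengths, lines, tol_channels = 1) {
  step <- stats::median(diff(wavelengths))
  all(vapply(lines, function(L) {
    any(abs(wavelengths[selected] - L) <= tol_channels * step + 1e-9)
  }, logical(1)))
}
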