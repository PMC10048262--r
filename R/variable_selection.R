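#' Selection result container
#'
#' Uniform return type of the three wavelength selectors: the method name,
#' the sorted unique 1-based channel indices retained, and per-method
#' diagnostics (CARS: subset-size schedule and RMSECV trace; random frog:
#' per-variable counts and selection probabilities; UVE: stability values
#' and cutoff).
#'
#' @param method character method name.
#' @param selected integer indices into the wavelength axis (1-based).
#' @param diagnostics list of per-method diagnostics.
#' @param p total number of channels.
#' @return object of class `selection_result`.
#' @export
selection_result <- function(method, selected, diagnostics = list(), p = NA) {
  selected <- sort(unique(as.integer(selected)))
  if (!is.na(p) && length(selected) &&
      (min(selected) < 1 || max(selected) > p)) {
    stop("selected indices out of range")
  }
  structure(list(method = method, selected = selected,
                 diagnostics = diagnostics, p = p),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result [", x$method, "]:", length(x$selected), "of",
      x$p, "channels selected\n")
  invisible(x)
}

#' Exponentially decreasing retention schedule (EDF)
#'
#' The fraction of wavelengths forcibly retained at CARS sampling run i is
#' `r_i = a * exp(-k * i)` with `a = (p/2)^(1/(N-1))` and
#' `k = log(p/2)/(N-1)`, so that `r_1 = 1` (all p channels survive run 1)
#' and `r_N = 2/p` (exactly 2 channels survive the last run).
#'
#' @param p number of variables (>= 3; for p < 3 the endpoint 2/p would not
#'   be below 1 and the schedule could not decrease).
#' @param n_runs number of sampling runs N (>= 2).
#' @return numeric vector of length `n_runs`, strictly decreasing.
#' @export
edf_schedule <- function(p, n_runs) {
  if (p < 3) stop("p must be >= 3 (2/p >= 1 breaks monotonicity)")
  if (n_runs < 2) stop("n_runs must be >= 2")
  a <- (p / 2)^(1 / (n_runs - 1))
  k <- log(p / 2) / (n_runs - 1)
  a * exp(-k * seq_len(n_runs))
}

#' CARS configuration
#'
#' @param n_runs number of Monte Carlo sampling runs (default 50).
#' @param mc_fraction fraction of calibration rows drawn per run
#'   (default 0.8, the convention of the CARS literature).
#' @param folds cross-validation folds for the per-run RMSECV (default 5).
#' @param max_components PLS component cap (default 10).
#' @param seed RNG seed.
#' @return list of class `cars_config`.
#' @export
cars_config <- function(n_runs = 50, mc_fraction = 0.8, folds = 5,
                        max_components = 10, seed = NULL) {
  stopifnot(n_runs >= 2, mc_fraction > 0, mc_fraction <= 1, folds >= 2)
  structure(list(n_runs = n_runs, mc_fraction = mc_fraction, folds = folds,
                 max_components = max_components, seed = seed),
            class = "cars_config")
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Wavelength selection by survival of the fittest. Each sampling run i
#' (i = 1..N): (a) fits a PLS model on a Monte Carlo row subsample of the
#' calibration set restricted to the currently surviving channels; (b)
#' ranks channels by the absolute PLS regression coefficient |b| and
#' enforces the exponentially decreasing schedule by keeping only the top
#' `ceiling(r_i * p)`; (c) applies adaptive reweighted sampling — a
#' weighted draw with replacement (weights proportional to |b|,
#' `ceiling(r_i * p)` draws, unique hits kept) — as the competitive step;
#' (d) records the K-fold RMSECV of the run's subset on the full
#' calibration set (fold assignment fixed once and shared across runs).
#' The subset with the lowest RMSECV over all runs is returned.
#'
#' @param X_cal calibration spectra matrix (rows = samples), normalized.
#' @param y_cal calibration concentrations for a single element (mg/kg).
#' @param config a [cars_config()].
#' @return a [selection_result()] with diagnostics `schedule` (r_i),
#'   `subset_size` (per run), `rmsecv` (per run), `best_run`, `subsets`.
#' @export
cars_select <- function(X_cal, y_cal, config = cars_config()) {
  X_cal <- as.matrix(X_cal)
  n <- nrow(X_cal)
  p <- ncol(X_cal)
  if (!is.null(config$seed)) set.seed(config$seed)
  r <- edf_schedule(p, config$n_runs)
  fold_id <- sample(rep_len(seq_len(config$folds), n))
  n_mc <- max(2L, ceiling(config$mc_fraction * n))

  surviving <- seq_len(p)
  subsets <- vector("list", config$n_runs)
  rmsecv_trace <- rep(NA_real_, config$n_runs)
  sizes <- rep(NA_integer_, config$n_runs)
  n_runs_done <- 0L
  for (i in seq_len(config$n_runs)) {
    rows <- sample.int(n, n_mc)
    a_i <- min(config$max_components, length(surviving), n_mc - 1L)
    fit <- fit_pls(X_cal[rows, surviving, drop = FALSE], y_cal[rows],
                   ncomp = a_i)
    b <- abs(fit$coef)
    n_keep <- min(ceiling(r[i] * p), length(surviving))
    ord <- order(b, decreasing = TRUE)
    forced <- ord[seq_len(n_keep)]
    wts <- b[forced]
    if (sum(wts) <= 0) wts <- rep(1, length(forced))
    draws <- forced[sample.int(length(forced), n_keep, replace = TRUE,
                               prob = wts)]
    new_surv <- surviving[sort(unique(draws))]
    if (length(new_surv) < 2L) {
      message("CARS: surviving variable count fell below 2 at run ", i,
              "; schedule truncated")
      break
    }
    surviving <- new_surv
    cv <- kfold_rmsecv(X_cal[, surviving, drop = FALSE], y_cal,
                       config$max_components, fold_id)
    subsets[[i]] <- surviving
    rmsecv_trace[i] <- cv$best
    sizes[i] <- length(surviving)
    n_runs_done <- i
  }
  if (n_runs_done == 0L) stop("CARS failed before completing a single run")
  keep <- seq_len(n_runs_done)
  best_run <- which.min(rmsecv_trace[keep])
  selection_result(
    method = "CARS",
    selected = subsets[[best_run]],
    diagnostics = list(schedule = r[keep], subset_size = sizes[keep],
                       rmsecv = rmsecv_trace[keep], best_run = best_run,
                       best_rmsecv = rmsecv_trace[best_run],
                       subsets = subsets[keep]),
    p = p
  )
}

#' Random frog configuration
#'
#' @param n_iterations number of iterations N (default 1000).
#' @param q0 initial subset size (default `round(p/10)`, computed at run
#'   time when `NULL`).
#' @param theta relative spread of the candidate subset size (default 0.3).
#' @param eta acceptance factor for inferior candidates (default 0.1).
#' @param folds RMSECV folds (default 5).
#' @param max_components PLS component cap (default 10).
#' @param k_grid candidate counts for the final top-k rule (default
#'   `seq(5, min(p, 300), by = 5)`, computed at run time when `NULL`;
#'   the cap comfortably exceeds the subset sizes informative emission
#'   spectra need at p of a few thousand channels).
#' @param seed RNG seed.
#' @return list of class `frog_config`.
#' @export
frog_config <- function(n_iterations = 1000, q0 = NULL, theta = 0.3,
                        eta = 0.1, folds = 5, max_components = 10,
                        k_grid = NULL, seed = NULL) {
  stopifnot(n_iterations >= 1, theta > 0, eta > 0, eta <= 1)
  if (!is.null(q0)) stopifnot(q0 >= 1)
  structure(list(n_iterations = n_iterations, q0 = q0, theta = theta,
                 eta = eta, folds = folds, max_components = max_components,
                 k_grid = k_grid, seed = seed),
            class = "frog_config")
}

#' Random frog wavelength selection
#'
#' Iterative subset proposal: starting from a random subset of size Q0, each
#' iteration draws a candidate size `Q* = |round(Normal(Q, theta * Q))|`
#' (at least 1, at most p). A candidate subset of that size is formed by
#' ranking channels with |b| from a PLS fit — dropping the bottom-ranked
#' members when shrinking, or pooling the current subset with a random
#' batch of outside channels and keeping the top Q* when growing. The
#' candidate replaces the current subset if its RMSECV is no worse;
#' otherwise it is accepted with probability
#' `eta * RMSECV(current) / RMSECV(candidate)`. After N iterations the
#' selection probability of channel j is `P_j = N_j / N`, where `N_j`
#' counts the iterations whose retained subset contained j. The final
#' selection takes the smallest k in `k_grid` whose top-k channels by
#' `P_j` minimize RMSECV.
#'
#' @inheritParams cars_select
#' @param config a [frog_config()].
#' @return a [selection_result()] with diagnostics `counts` (N_j),
#'   `probability` (P_j), `n_iterations`, `accepted`, `rejected_nonfinite`,
#'   `k_grid`, `k_rmsecv`, `best_k`.
#' @export
random_frog_select <- function(X_cal, y_cal, config = frog_config()) {
  X_cal <- as.matrix(X_cal)
  n <- nrow(X_cal)
  p <- ncol(X_cal)
  if (!is.null(config$seed)) set.seed(config$seed)
  q0 <- config$q0 %||% max(1L, round(p / 10))
  q0 <- min(q0, p)
  k_grid <- config$k_grid %||% seq(5L, max(5L, min(p, 300L)), by = 5L)
  k_grid <- unique(pmin(as.integer(k_grid), p))
  fold_id <- sample(rep_len(seq_len(config$folds), n))
  amax <- config$max_components

  cv_subset <- function(idx) {
    kfold_rmsecv(X_cal[, idx, drop = FALSE], y_cal, amax, fold_id)$best
  }
  rank_by_b <- function(idx) {
    a <- min(amax, length(idx), n - 1L)
    fit <- fit_pls(X_cal[, idx, drop = FALSE], y_cal, ncomp = a)
    idx[order(abs(fit$coef), decreasing = TRUE)]
  }

  current <- sort(sample.int(p, q0))
  rmse_cur <- cv_subset(current)
  counts <- integer(p)
  size_trace <- integer(config$n_iterations)
  accepted <- 0L
  rejected_nonfinite <- 0L
  for (it in seq_len(config$n_iterations)) {
    q_cur <- length(current)
    q_star <- abs(round(rnorm(1, q_cur, config$theta * q_cur)))
    q_star <- max(1L, min(p, as.integer(q_star)))
    if (q_star <= q_cur) {
      cand <- if (q_star == q_cur) current else
        sort(head(rank_by_b(current), q_star))
    } else {
      outside <- setdiff(seq_len(p), current)
      # exploration pool: omega = 3 random outside channels per slot, the
      # convention of the random-frog literature
      pool_extra <- outside[sample.int(length(outside),
                                       min(length(outside),
                                           3L * (q_star - q_cur)))]
      pool <- c(current, pool_extra)
      cand <- sort(head(rank_by_b(pool), min(q_star, length(pool))))
    }
    rmse_cand <- cv_subset(cand)
    if (!is.finite(rmse_cand)) {
      rejected_nonfinite <- rejected_nonfinite + 1L
    } else if (rmse_cand <= rmse_cur ||
               runif(1) < config$eta * rmse_cur / rmse_cand) {
      current <- cand
      rmse_cur <- rmse_cand
      accepted <- accepted + 1L
    }
    counts[current] <- counts[current] + 1L
    size_trace[it] <- length(current)
  }
  prob <- counts / config$n_iterations

  ord <- order(prob, decreasing = TRUE)
  k_rmsecv <- vapply(k_grid, function(k) cv_subset(ord[seq_len(k)]),
                     numeric(1))
  best_k <- k_grid[which.min(k_rmsecv)]
  selected <- ord[seq_len(best_k)]
  selection_result(
    method = "RF",
    selected = selected,
    diagnostics = list(counts = counts, probability = prob,
                       n_iterations = config$n_iterations,
                       size_trace = size_trace,
                       accepted = accepted,
                       rejected_nonfinite = rejected_nonfinite,
                       k_grid = k_grid, k_rmsecv = k_rmsecv,
                       best_k = best_k),
    p = p
  )
}

#' UVE configuration
#'
#' @param n_noise number of appended noise columns (default p, computed at
#'   run time when `NULL`).
#' @param noise_amplitude amplitude of the uniform noise block (default
#'   1e-10, negligible relative to unit-area spectra; the stability
#'   statistic is scale-free in the noise block).
#' @param quantile cutoff quantile of the absolute noise stabilities
#'   (default 0.99; the maximum is unstable with many noise columns).
#' @param ncomp PLS components used in the jackknife fits (default 5).
#' @param seed RNG seed.
#' @param exact_refit force brute-force refitting for every leave-one-out
#'   replicate instead of the algebraically equivalent sample-space
#'   (wide-kernel) computation; only useful for verification.
#' @return list of class `uve_config`.
#' @export
uve_config <- function(n_noise = NULL, noise_amplitude = 1e-10,
                       quantile = 0.99, ncomp = 5, seed = NULL,
                       exact_refit = FALSE) {
  stopifnot(noise_amplitude > 0, quantile > 0, quantile <= 1, ncomp >= 1)
  structure(list(n_noise = n_noise, noise_amplitude = noise_amplitude,
                 quantile = quantile, ncomp = ncomp, seed = seed,
                 exact_refit = exact_refit),
            class = "uve_config")
}

# Leave-one-out jackknife of PLS1 regression coefficients, computed in
# sample space (wide-kernel form). For p >> n every NIPALS quantity can be
# expressed through the Gram matrix K = Z Z': weights and loadings have
# dual representations w_a = Xc' v_a, p_a = Xc' u_a with n-vectors v_a,
# u_a, so each leave-one-out coefficient vector is b_i = Xc' m_i for an
# n-vector m_i, and all p-dimensional work collapses into one final
# crossproduct. Algebraically identical to refitting fit_pls() on every
# leave-one-out subset (verified in the test suite); the row-space route
# just avoids 173 passes over a samples x 2p matrix.
loo_pls_coefficients <- function(Z, y, ncomp, tol = 1e-24) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  K <- tcrossprod(Z)
  cs <- colSums(Z)
  M <- matrix(0, n, n)
  sigma <- numeric(n)
  for (i in seq_len(n)) {
    idx <- seq_len(n)[-i]
    m <- n - 1L
    Ki <- K[idx, idx]
    rm_i <- rowMeans(Ki)
    Kc <- Ki - rep(rm_i, times = m) - rep(rm_i, each = m) + mean(rm_i)
    dim(Kc) <- c(m, m)
    yc <- y[idx] - mean(y[idx])
    a_max <- min(ncomp, m - 1L)
    Tm <- matrix(0, m, a_max)
    Yd <- matrix(0, m, a_max)
    tts <- nws <- q <- numeric(a_max)
    Kc_cur <- Kc
    y_cur <- yc
    a_done <- 0L
    for (a in seq_len(a_max)) {
      ky <- Kc_cur %*% y_cur
      nw2 <- sum(y_cur * ky)
      if (!is.finite(nw2) || nw2 < tol) break
      t_a <- as.numeric(ky) / sqrt(nw2)
      tt <- sum(t_a^2)
      if (tt < tol) break
      q_a <- sum(y_cur * t_a) / tt
      Yd[, a] <- y_cur
      Tm[, a] <- t_a
      tts[a] <- tt
      nws[a] <- sqrt(nw2)
      q[a] <- q_a
      g <- as.numeric(Kc_cur %*% t_a)
      Kc_cur <- Kc_cur - tcrossprod(t_a, g) / tt - tcrossprod(g, t_a) / tt +
        tcrossprod(t_a) * (sum(t_a * g) / tt^2)
      y_cur <- y_cur - t_a * q_a
      a_done <- a
    }
    if (a_done == 0L) stop("degenerate leave-one-out PLS fit (replicate ",
                           i, ")")
    V <- matrix(0, m, a_done)
    U <- matrix(0, m, a_done)
    for (a in seq_len(a_done)) {
      v <- Yd[, a]
      u <- Tm[, a]
      if (a > 1L) for (j in seq(a - 1L, 1L)) {
        tj <- Tm[, j]
        v <- v - tj * (sum(tj * v) / tts[j])
        u <- u - tj * (sum(tj * u) / tts[j])
      }
      V[, a] <- v / nws[a]
      U[, a] <- u / tts[a]
    }
    pw <- crossprod(U, Kc %*% V)
    m_i <- as.numeric(V %*% solve(pw, q[seq_len(a_done)]))
    M[idx, i] <- m_i
    sigma[i] <- sum(m_i)
  }
  # b_i = Z_{-i}' m_i - mu_i * sum(m_i); assemble all replicates at once
  B <- crossprod(Z, M) - (outer(cs, sigma) - t(Z * sigma)) / (n - 1)
  t(B)
}

#' Uninformative variable elimination (UVE)
#'
#' Appends a block of uniform random noise columns to the calibration
#' spectra, then jackknifes the PLS regression coefficients leave-one-out:
#' for each left-out sample a PLS model is fitted on the remaining rows of
#' the augmented matrix and its coefficient vector recorded. The stability
#' of variable j is `c_j = mean(b_j) / sd(b_j)` over the jackknife
#' replicates. Real channels whose |c_j| exceeds the configured quantile of
#' the absolute noise-column stabilities are retained; everything a random
#' column can match is deemed uninformative.
#'
#' @inheritParams cars_select
#' @param config a [uve_config()].
#' @return a [selection_result()] with diagnostics `stability` (real
#'   channels), `noise_stability`, `cutoff`, `ncomp`.
#' @export
uve_select <- function(X_cal, y_cal, config = uve_config()) {
  X_cal <- as.matrix(X_cal)
  n <- nrow(X_cal)
  p <- ncol(X_cal)
  if (!is.null(config$seed)) set.seed(config$seed)
  n_noise <- config$n_noise %||% p
  noise <- matrix(runif(n * n_noise), n, n_noise) * config$noise_amplitude
  Z <- cbind(X_cal, noise)
  a <- min(config$ncomp, n - 2L, ncol(Z))
  B <- if (isTRUE(config$exact_refit)) {
    Bf <- matrix(0, n, ncol(Z))
    for (i in seq_len(n)) {
      Bf[i, ] <- fit_pls(Z[-i, , drop = FALSE], y_cal[-i], ncomp = a)$coef
    }
    Bf
  } else {
    loo_pls_coefficients(Z, y_cal, ncomp = a)
  }
  b_mean <- unname(colMeans(B))
  b_sd <- unname(apply(B, 2, sd))
  stability <- b_mean / b_sd
  degen <- b_sd == 0
  if (any(degen)) {
    stability[degen] <- sign(b_mean[degen]) * Inf
    message("UVE: ", sum(degen), " variable(s) with zero jackknife sd; ",
            "stability set to signed infinity")
  }
  real_stab <- stability[seq_len(p)]
  noise_stab <- stability[p + seq_len(n_noise)]
  cutoff <- as.numeric(quantile(abs(noise_stab), config$quantile,
                                na.rm = TRUE))
  selected <- which(abs(real_stab) > cutoff)
  selection_result(
    method = "UVE",
    selected = selected,
    diagnostics = list(stability = real_stab, noise_stability = noise_stab,
                       cutoff = cutoff, ncomp = a),
    p = p
  )
}

#' Serialize a selection result to JSON
#'
#' Writes method, indices, wavelengths (nm) and scalar diagnostics.
#'
#' @param result a [selection_result()].
#' @param wavelengths wavelength axis indexed by the selection.
#' @param path output path.
#' @export
write_selection <- function(result, wavelengths, path) {
  diag_small <- result$diagnostics[
    vapply(result$diagnostics,
           function(d) is.atomic(d) && length(d) <= 10000, logical(1))]
  out <- list(method = result$method,
              n_selected = length(result$selected),
              selected_indices = result$selected,
              selected_wavelengths_nm = wavelengths[result$selected],
              diagnostics = diag_small)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-channel selector scores as a flat table
#'
#' One row per channel: wavelength plus the selector's per-channel score
#' (selection probability for random frog, stability for UVE, selection
#' indicator for CARS), ready for plotting selection distributions.
#'
#' @param result a [selection_result()].
#' @param wavelengths wavelength axis.
#' @return data.frame with columns `wavelength`, `score`, `selected`.
#' @export
selection_scores <- function(result, wavelengths) {
  p <- length(wavelengths)
  score <- switch(result$method,
    RF = result$diagnostics$probability,
    UVE = abs(result$diagnostics$stability),
    as.numeric(seq_len(p) %in% result$selected))
  data.frame(wavelength = wavelengths, score = score,
             selected = seq_len(p) %in% result$selected)
}
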