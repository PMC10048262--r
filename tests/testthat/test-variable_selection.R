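# Small spectral fixture for selector unit tests: ~300 channels, six Cd
# lines plus one Cu and one Pb line, generated by the synthetic module.
selector_fixture <- function(seed) {
  cfg <- sim_config(
    n_groups = 4, n_per_group = 18,
    group_means = rbind(Cd = c(0.5, 20, 50, 90), Cu = c(2, 40, 80, 160),
                        Pb = c(0.3, 25, 60, 140)),
    group_sds = rbind(Cd = c(0.3, 3, 8, 9), Cu = c(1, 5, 8, 16),
                      Pb = c(0.2, 4, 7, 14)),
    wl_start = 200, wl_stop = 500, wl_step = 1,
    lines = line_library(
      element = c(rep("Cd", 6), "Cu", "Pb"),
      wavelength = c(220, 260, 300, 340, 380, 420, 450, 480),
      strength = c(1, 0.9, 0.7, 0.6, 0.5, 0.4, 1, 1)),
    matrix_lines = data.frame(species = "Ca", wavelength = 393.37,
                              intensity = 150),
    sigma = 0.6, n_shots = 5
  )
  ds <- generate_dataset(cfg, seed = seed)
  norm <- area_normalize(ds$spectra)
  list(X = norm$intensities, y = ds$concentrations$Cd_mgkg,
       wl = norm$wavelengths,
       cd_lines = c(220, 260, 300, 340, 380, 420))
}

test_that("the EDF schedule matches its closed form and decreases", {
  r <- edf_schedule(200, 50)
  expect_lt(abs(r[1] - 1), 1e-12)
  expect_lt(abs(r[50] - 0.01), 1e-12)
  expect_true(all(diff(r) < 0))
  expect_equal(edf_schedule(4, 2), c(1, 0.5), tolerance = 1e-12)
  expect_error(edf_schedule(2, 10), "p must be")
  expect_error(edf_schedule(100, 1), "n_runs")
})

test_that("CARS honors the EDF bound and the argmin contract", {
  fx <- selector_fixture(31)
  res <- suppressMessages(
    cars_select(fx$X, fx$y, cars_config(n_runs = 30, seed = 5)))
  d <- res$diagnostics
  p <- ncol(fx$X)
  expect_true(all(diff(d$subset_size) <= 0))
  expect_true(all(d$subset_size <= ceiling(d$schedule * p)))
  expect_equal(d$rmsecv[d$best_run], min(d$rmsecv))
  expect_equal(d$best_rmsecv, min(d$rmsecv))
  expect_lte(d$rmsecv[d$best_run], d$rmsecv[1])
  expect_identical(res$selected, sort(d$subsets[[d$best_run]]))
  # recovery sanity on one seed: selected channels near most true lines
  expect_gte(sum(vapply(fx$cd_lines, function(L)
    any(abs(fx$wl[res$selected] - L) <= 1), logical(1))), 5)
})

test_that("CARS is a deterministic function of its seed", {
  fx <- selector_fixture(32)
  r1 <- suppressMessages(cars_select(fx$X, fx$y,
                                     cars_config(n_runs = 20, seed = 8)))
  r2 <- suppressMessages(cars_select(fx$X, fx$y,
                                     cars_config(n_runs = 20, seed = 8)))
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$diagnostics$rmsecv, r2$diagnostics$rmsecv)
})

test_that("random frog counting identities hold on every run", {
  fx <- selector_fixture(33)
  res <- random_frog_select(fx$X, fx$y,
                            frog_config(n_iterations = 150, seed = 6))
  d <- res$diagnostics
  expect_true(all(d$probability >= 0 & d$probability <= 1))
  expect_equal(d$probability, d$counts / d$n_iterations)
  expect_equal(sum(d$counts), sum(d$size_trace))
})

test_that("random frog attains the probability bounds in forced cases", {
  set.seed(4)
  X <- matrix(rnorm(60), 30, 2)
  y <- X[, 1] + rnorm(30, sd = 0.05)
  # theta so small every proposal keeps both variables: P = 1 for both
  res <- random_frog_select(X, y, frog_config(n_iterations = 50, q0 = 2,
                                              theta = 1e-6, folds = 3,
                                              k_grid = 2, seed = 1))
  expect_equal(res$diagnostics$probability, c(1, 1))
  # a larger pool leaves never-visited variables at exactly zero
  fx <- selector_fixture(34)
  res2 <- random_frog_select(fx$X, fx$y,
                             frog_config(n_iterations = 100, q0 = 5,
                                         seed = 2))
  expect_true(any(res2$diagnostics$probability == 0))
})

test_that("random frog ranks true lines above pure-noise channels", {
  hits <- 0
  for (s in 1:3) {
    fx <- selector_fixture(40 + s)
    res <- random_frog_select(fx$X, fx$y,
                              frog_config(n_iterations = 400, seed = s))
    p <- res$diagnostics$probability
    line_ch <- unlist(lapply(fx$cd_lines, function(L)
      which(abs(fx$wl - L) <= 1)))
    noise_ch <- setdiff(seq_along(fx$wl),
                        unlist(lapply(c(fx$cd_lines, 450, 480, 393.37),
                                      function(L)
                                        which(abs(fx$wl - L) <= 5))))
    hits <- hits + (mean(p[line_ch]) > mean(p[noise_ch]))
  }
  expect_gte(hits, 3)
})

test_that("UVE keeps only channels beating the noise cutoff", {
  fx <- selector_fixture(35)
  res <- suppressMessages(uve_select(fx$X, fx$y, uve_config(seed = 3)))
  d <- res$diagnostics
  expect_true(all(res$selected <= ncol(fx$X)))
  expect_true(all(abs(d$stability[res$selected]) > d$cutoff))
  expect_true(all(abs(d$stability[-res$selected]) <= d$cutoff))
})

test_that("UVE retains a directly informative column across seeds", {
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(40 * 12), 40, 12)
    y <- X[, 3] + rnorm(40, sd = 0.01)
    res <- uve_select(X, y, uve_config(ncomp = 3, seed = s))
    expect_true(3 %in% res$selected)
  }
})

test_that("sample-space jackknife equals brute-force leave-one-out refits", {
  set.seed(17)
  Z <- matrix(rnorm(25 * 60), 25, 60)
  y <- as.numeric(Z[, 1:3] %*% c(2, -1, 1)) + rnorm(25, sd = 0.2)
  Bk <- libsvarsel:::loo_pls_coefficients(Z, y, 4)
  for (i in c(1, 7, 25)) {
    expect_lt(max(abs(Bk[i, ] - fit_pls(Z[-i, ], y[-i], 4)$coef)), 1e-8)
  }
  # and the full UVE op agrees between the two routes
  fx <- selector_fixture(38)
  r_fast <- uve_select(fx$X, fx$y, uve_config(ncomp = 3, seed = 19))
  r_slow <- uve_select(fx$X, fx$y, uve_config(ncomp = 3, seed = 19,
                                              exact_refit = TRUE))
  expect_identical(r_fast$selected, r_slow$selected)
  expect_equal(r_fast$diagnostics$stability, r_slow$diagnostics$stability,
               tolerance = 1e-8)
})

test_that("UVE selection is invariant to the noise amplitude scale", {
  fx <- selector_fixture(36)
  r1 <- uve_select(fx$X, fx$y, uve_config(noise_amplitude = 1e-10,
                                          seed = 11))
  r2 <- uve_select(fx$X, fx$y, uve_config(noise_amplitude = 2e-10,
                                          seed = 11))
  expect_identical(r1$selected, r2$selected)
})

test_that("selectors are deterministic and write valid diagnostics", {
  fx <- selector_fixture(37)
  res <- suppressMessages(uve_select(fx$X, fx$y, uve_config(seed = 13)))
  path <- tempfile(fileext = ".json")
  write_selection(res, fx$wl, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$method, "UVE")
  expect_equal(back$n_selected, length(res$selected))
  expect_equal(back$selected_wavelengths_nm, fx$wl[res$selected])
  scores <- selection_scores(res, fx$wl)
  expect_equal(nrow(scores), length(fx$wl))
  expect_equal(sum(scores$selected), length(res$selected))
})
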