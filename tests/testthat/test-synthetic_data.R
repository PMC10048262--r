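test_that("the default design is 288 samples in 8 groups of 36", {
  design <- generate_design(sim_config(), seed = 1)
  expect_equal(nrow(design), 288)
  expect_equal(as.numeric(table(design$group)), rep(36, 8))
  expect_equal(length(unique(design$variety)), 12)
  conc <- concentration_matrix(design)
  expect_true(all(conc >= 0))
  # control group sits below every treatment mean
  ck <- design$group == "CK"
  for (el in colnames(conc)) {
    trt_means <- tapply(conc[!ck, el], droplevels(design$group[!ck]), mean)
    expect_true(all(mean(conc[ck, el]) < trt_means))
  }
})

test_that("group sample means track the configured targets", {
  cfg <- sim_config()
  mu <- cfg$group_means["Cd", ]
  sds <- cfg$group_sds["Cd", ]
  n_seeds <- 20
  acc <- matrix(0, n_seeds, length(mu))
  for (s in seq_len(n_seeds)) {
    d <- generate_design(cfg, seed = s)
    acc[s, ] <- tapply(d$Cd_mgkg, d$group, mean)
  }
  pooled <- colMeans(acc)
  se_pooled <- sds / sqrt(cfg$n_per_group * n_seeds)
  expect_true(all(abs(pooled - mu) <= 3 * se_pooled + 1e-12))
})

test_that("zero sds collapse each group onto its mean", {
  cfg <- small_sim_config()
  cfg$group_sds[] <- 0
  d <- generate_design(cfg, seed = 3)
  conc <- concentration_matrix(d)
  for (el in rownames(cfg$group_means)) {
    expect_equal(as.numeric(tapply(conc[, el], d$group, function(v)
      length(unique(v)))), rep(1, cfg$n_groups))
    expect_equal(sort(unique(conc[, el])), sort(cfg$group_means[el, ]))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_per_group = 0), "group size")
  expect_error(sim_config(wl_step = 0), "wl_step")
  expect_error(sim_config(n_shots = 0), "n_shots")
  cfg <- sim_config()
  cfg$group_sds[1, 1] <- -1
  expect_error(validate_sim_config(cfg), "negative")
  expect_error(sim_config(lines = line_library("Cd", 150, 1)),
               "inside the wavelength axis")
})

test_that("a null sample with no noise is the flat baseline", {
  cfg <- noiseless_sim_config(matrix_lines = default_matrix_lines()[0, ])
  sp <- synthesize_spectrum(c(Cd = 0, Cu = 0, Pb = 0), cfg)
  expect_equal(sp, rep(cfg$baseline, length(wavelength_axis(cfg))))
})

test_that("noise-free spectra peak at the channels nearest each Cd line", {
  cfg <- sim_config(noise_additive_sd = 0, noise_shot_sd = 0,
                    matrix_lines = default_matrix_lines()[0, ])
  wl <- wavelength_axis(cfg)
  sp <- synthesize_spectrum(c(Cd = 50, Cu = 0, Pb = 0), cfg)
  maxima <- wl[which(diff(sign(diff(sp))) == -2) + 1]
  nearest <- wl[vapply(cd_lines, function(L) which.min(abs(wl - L)),
                       integer(1))]
  expect_setequal(maxima, nearest)
})

test_that("baseline-subtracted peak area is linear in concentration", {
  cfg <- noiseless_sim_config(matrix_lines = default_matrix_lines()[0, ])
  wl <- wavelength_axis(cfg)
  area_of <- function(conc) {
    sp <- synthesize_spectrum(c(Cd = conc, Cu = 0, Pb = 0), cfg)
    win <- abs(wl - 214.44) <= 5 # isolated Cd peak
    trapz(wl[win], (sp - cfg$baseline)[win])
  }
  a1 <- area_of(30)
  a2 <- area_of(60)
  expect_lt(abs(a2 / a1 - 2), 1e-6)
})

test_that("identical seeds reproduce bit-identical datasets", {
  cfg <- small_sim_config()
  d1 <- generate_dataset(cfg, seed = 77)
  d2 <- generate_dataset(cfg, seed = 77)
  expect_identical(d1$spectra$intensities, d2$spectra$intensities)
  expect_identical(d1$concentrations, d2$concentrations)
  d3 <- generate_dataset(cfg, seed = 78)
  expect_false(identical(d1$spectra$intensities, d3$spectra$intensities))
})

test_that("shot averaging shrinks channel noise like 1/sqrt(k)", {
  cfg <- small_sim_config(
    wl_start = 200, wl_stop = 260, wl_step = 1,
    lines = line_library(c("Cd", "Cd", "Cu", "Pb"),
                         c(214.44, 226.50, 230.50, 240.00),
                         c(1, 0.9, 1, 1)))
  conc <- c(Cd = 20, Cu = 30, Pb = 20)
  reps <- 120
  sd_for <- function(k, seed0) {
    set.seed(seed0)
    mats <- replicate(reps, synthesize_spectrum(conc, cfg, n_shots = k))
    apply(mats, 1, sd)
  }
  s1 <- sd_for(1, 1)
  s80 <- sd_for(80, 2)
  ratio <- median(s80 / s1)
  expect_gt(ratio, 1 / sqrt(80) * 0.8)
  expect_lt(ratio, 1 / sqrt(80) * 1.25)
})

test_that("dataset dimensions honor the configured axis and design", {
  cfg <- small_sim_config()
  ds <- generate_dataset(cfg, seed = 5)
  expect_equal(dim(ds$spectra$intensities),
               c(cfg$n_groups * cfg$n_per_group,
                 length(wavelength_axis(cfg))))
  expect_identical(ds$spectra$sample_ids, ds$concentrations$sample_id)
})

test_that("spectrum_set enforces its invariants", {
  expect_error(spectrum_set(c(2, 1), matrix(0, 1, 2), "a"), "increase")
  expect_error(spectrum_set(1:3, matrix(0, 1, 2), "a"), "column count")
  expect_error(spectrum_set(1:2, matrix(0, 2, 2), c("a", "a")), "unique")
  expect_error(spectrum_set(1:2, matrix(NA_real_, 1, 2), "a"), "missing")
})
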