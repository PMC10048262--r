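#' Emission line library
#'
#' A small table of analyte emission lines: element label, line center in nm
#' and a dimensionless relative strength (> 0). The default library carries
#' the Cd, Cu and Pb lines used for quantification in this pipeline, with
#' relative strengths decreasing from the most persistent line of each
#' element.
#'
#' @param element character vector of element labels.
#' @param wavelength numeric vector of line centers (nm).
#' @param strength numeric vector of relative strengths (> 0).
#' @return data.frame of class `line_library`.
#' @export
line_library <- function(element, wavelength, strength) {
  stopifnot(length(element) == length(wavelength),
            length(element) == length(strength))
  if (any(strength <= 0)) stop("line strengths must be > 0")
  lib <- data.frame(element = as.character(element),
                    wavelength = as.numeric(wavelength),
                    strength = as.numeric(strength),
                    stringsAsFactors = FALSE)
  class(lib) <- c("line_library", "data.frame")
  lib
}

#' @rdname line_library
#' @export
default_line_library <- function() {
  line_library(
    element = c(rep("Cd", 6), rep("Cu", 2), rep("Pb", 3)),
    wavelength = c(214.44, 226.50, 441.56, 467.90, 573.80, 643.85,
                   324.09, 324.79,
                   280.00, 404.00, 405.70),
    strength = c(1.0, 0.9, 0.7, 0.6, 0.5, 0.4,
                 0.7, 1.0,
                 0.5, 0.7, 1.0)
  )
}

#' Default matrix (non-analyte) emission lines
#'
#' Concentration-independent decoy lines from the plant matrix (Ca, Na, K,
#' Mg are dominant emitters in dried plant material). After area
#' normalization these channels become correlated with total analyte content
#' without carrying analyte information, which is exactly the trap a
#' wavelength selector must not fall into.
#'
#' @return data.frame with columns `species`, `wavelength` (nm),
#'   `intensity` (arbitrary units, area of the line profile).
#' @export
default_matrix_lines <- function() {
  data.frame(
    species = c("Ca", "Ca", "Ca", "Mg", "Na", "K", "K"),
    wavelength = c(393.37, 396.85, 422.67, 285.21, 589.00, 766.49, 769.90),
    intensity = c(250, 200, 150, 100, 150, 200, 120),
    stringsAsFactors = FALSE
  )
}

#' Default concentration design
#'
#' Per-group mean and standard deviation (mg/kg) of each element for the
#' built-in 8-group contamination design (control + 7 treatments, 36
#' samples per group): elements x groups matrices with element rownames.
#'
#' @return numeric matrix (elements x groups).
#' @export
default_group_means <- function() {
  rbind(
    Cd = c(0.43, 5.86, 10.64, 22.87, 26.39, 60.32, 82.48, 93.91),
    Cu = c(2.50, 20.06, 37.31, 52.48, 65.95, 79.66, 172.57, 215.06),
    Pb = c(0.29, 6.06, 22.75, 51.58, 65.62, 85.00, 112.26, 199.24)
  )
}

#' @rdname default_group_means
#' @export
default_group_sds <- function() {
  rbind(
    Cd = c(0.28, 0.46, 0.56, 1.53, 1.31, 19.85, 13.24, 5.94),
    Cu = c(1.09, 3.62, 6.05, 6.13, 4.10, 4.50, 22.74, 27.82),
    Pb = c(0.19, 0.74, 0.80, 16.29, 3.81, 7.71, 7.99, 24.58)
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic LIBS experiment. Defaults emulate the study
#' design this pipeline targets: 8 sample groups (one control, seven
#' spiked treatments) of 36 pellets each, concentration design per element
#' and group in mg/kg, spectra over 200-1000 nm, and 80 accumulated
#' laser shots averaged per sample (a 4 x 4 crater array with 5 pulses per
#' crater).
#'
#' @param n_groups number of groups (default 8; group 1 is the control).
#' @param n_per_group samples per group (default 36).
#' @param group_means elements x groups matrix of mean concentrations
#'   (mg/kg); rownames are element labels.
#' @param group_sds matching matrix of standard deviations (mg/kg).
#' @param wl_start,wl_stop,wl_step wavelength axis in nm (default 200-1000
#'   at 0.5 nm, 1601 channels).
#' @param sigma Gaussian line profile standard deviation in nm (default
#'   0.3, so the Cu doublet at 324.09/324.79 nm partially overlaps).
#' @param sensitivity named per-element sensitivity (integrated intensity
#'   per mg/kg per unit line strength).
#' @param lines a [line_library()].
#' @param matrix_lines data.frame of decoy lines (see
#'   [default_matrix_lines()]); may have zero rows.
#' @param baseline flat continuum level (arbitrary units).
#' @param noise_additive_sd additive (detector) noise sd per shot, same
#'   units as intensities.
#' @param noise_shot_sd relative multiplicative shot-to-shot fluctuation sd.
#' @param n_shots shots averaged per sample (default 80).
#' @param varieties labels cycled over samples (default 12 varieties).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_groups = 8,
                       n_per_group = 36,
                       group_means = default_group_means(),
                       group_sds = default_group_sds(),
                       wl_start = 200, wl_stop = 1000, wl_step = 0.5,
                       sigma = 0.3,
                       sensitivity = c(Cd = 1, Cu = 1, Pb = 1),
                       lines = default_line_library(),
                       matrix_lines = default_matrix_lines(),
                       baseline = 100,
                       noise_additive_sd = 5,
                       noise_shot_sd = 0.2,
                       n_shots = 80,
                       varieties = sprintf("V%02d", 1:12)) {
  cfg <- list(n_groups = n_groups, n_per_group = n_per_group,
              group_means = group_means, group_sds = group_sds,
              wl_start = wl_start, wl_stop = wl_stop, wl_step = wl_step,
              sigma = sigma, sensitivity = sensitivity, lines = lines,
              matrix_lines = matrix_lines, baseline = baseline,
              noise_additive_sd = noise_additive_sd,
              noise_shot_sd = noise_shot_sd, n_shots = n_shots,
              varieties = varieties)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the invariants of a [sim_config()] (positive axis step,
#' non-negative noise, line centers inside the axis, complete per-element
#' design and sensitivities). Called by every generator entry point;
#' exported so hand-edited configurations can be checked early.
#'
#' @param cfg a [sim_config()].
#' @return invisibly TRUE, or an error describing the violation.
#' @export
validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_groups < 1 || n_per_group < 1) stop("non-positive group size")
    if (wl_step <= 0) stop("wl_step must be > 0")
    if (wl_stop <= wl_start) stop("wl_stop must exceed wl_start")
    if (sigma <= 0) stop("sigma must be > 0")
    if (n_shots < 1) stop("n_shots must be >= 1")
    if (noise_additive_sd < 0 || noise_shot_sd < 0) stop("negative noise sd")
    if (any(group_sds < 0)) stop("negative concentration sd")
    if (!identical(dim(group_means), dim(group_sds)))
      stop("group_means and group_sds dimensions differ")
    if (ncol(group_means) != n_groups)
      stop("group_means must have n_groups columns")
    if (is.null(rownames(group_means)))
      stop("group_means must carry element rownames")
    els <- unique(lines$element)
    if (!all(els %in% rownames(group_means)))
      stop("every line-library element needs a concentration design row")
    if (!all(els %in% names(sensitivity)))
      stop("every line-library element needs a sensitivity")
    if (any(lines$wavelength <= wl_start) || any(lines$wavelength >= wl_stop))
      stop("analyte line centers must lie strictly inside the wavelength axis")
    invisible(TRUE)
  })
}

#' Wavelength axis of a simulation configuration
#' @param config a [sim_config()].
#' @return numeric vector of channel centers in nm.
#' @export
wavelength_axis <- function(config) {
  seq(config$wl_start, config$wl_stop, by = config$wl_step)
}

#' Generate a concentration design table
#'
#' Draws per-sample concentrations for each element from a normal
#' distribution with the configured group mean and sd, truncated at zero
#' (negative draws are set to 0). With all sds equal to zero every sample
#' in a group sits exactly on the group mean. Varieties are assigned
#' cyclically over the configured labels.
#'
#' @param config a [sim_config()].
#' @param seed optional RNG seed; if `NULL` the current RNG state is used.
#' @return data.frame of class `concentration_table` with columns
#'   `sample_id`, `group`, `variety` and one `<element>_mgkg` column per
#'   element.
#' @export
generate_design <- function(config = sim_config(), seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  ng <- config$n_groups
  npg <- config$n_per_group
  n <- ng * npg
  elements <- rownames(config$group_means)
  group_labels <- c("CK", paste0("T", seq_len(ng - 1L)))[seq_len(ng)]
  group <- rep(group_labels, each = npg)
  tab <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    group = factor(group, levels = group_labels),
    variety = rep_len(config$varieties, n),
    stringsAsFactors = FALSE
  )
  for (el in elements) {
    mu <- rep(config$group_means[el, ], each = npg)
    sdv <- rep(config$group_sds[el, ], each = npg)
    tab[[paste0(el, "_mgkg")]] <- pmax(0, rnorm(n, mu, sdv))
  }
  class(tab) <- c("concentration_table", "data.frame")
  tab
}

#' Extract the concentration matrix from a concentration table
#' @param concentrations a [generate_design()] table.
#' @return numeric matrix samples x elements (mg/kg), element colnames.
#' @export
concentration_matrix <- function(concentrations) {
  cols <- grep("_mgkg$", names(concentrations), value = TRUE)
  m <- as.matrix(concentrations[, cols, drop = FALSE])
  colnames(m) <- sub("_mgkg$", "", cols)
  rownames(m) <- concentrations$sample_id
  m
}

# Line profile matrix: one row per emission line (analyte lines first, then
# in-axis matrix lines), one column per channel; rows integrate to ~1 over
# the axis. Analyte lines outside the axis are an error; matrix decoys
# outside it are simply irrelevant and dropped.
line_profiles <- function(config) {
  wl <- wavelength_axis(config)
  if (any(config$lines$wavelength <= config$wl_start) ||
      any(config$lines$wavelength >= config$wl_stop)) {
    stop("line center outside the wavelength axis")
  }
  centers <- c(config$lines$wavelength, active_matrix_lines(config)$wavelength)
  t(vapply(centers, function(mu) dnorm(wl, mu, config$sigma),
           numeric(length(wl))))
}

active_matrix_lines <- function(config) {
  ml <- config$matrix_lines
  ml[ml$wavelength > config$wl_start & ml$wavelength < config$wl_stop, ,
     drop = FALSE]
}

# Noise-free signal for one sample: baseline + analyte lines + matrix lines.
signal_vector <- function(concentrations, config, profiles = NULL) {
  if (is.null(profiles)) profiles <- line_profiles(config)
  lines <- config$lines
  missing_el <- setdiff(unique(lines$element), names(concentrations))
  if (length(missing_el)) {
    stop("concentrations missing for element(s): ",
         paste(missing_el, collapse = ", "))
  }
  areas <- lines$strength * config$sensitivity[lines$element] *
    as.numeric(concentrations[lines$element])
  ml <- active_matrix_lines(config)
  if (nrow(ml)) areas <- c(areas, ml$intensity)
  config$baseline + as.numeric(crossprod(profiles, areas))
}

#' Synthesize one LIBS-like spectrum
#'
#' The noise-free signal is a flat baseline plus one unit-area Gaussian
#' profile per emission line, scaled by `strength x sensitivity x
#' concentration` for analyte lines and by a fixed intensity for matrix
#' lines. Each of `n_shots` simulated shots multiplies the signal by
#' `(1 + shot noise)` and adds detector noise, clips at zero, and the
#' shots are averaged.
#'
#' @param concentrations named vector of analyte concentrations (mg/kg)
#'   covering every element in the line library.
#' @param config a [sim_config()] (supplies lines, axis, noise levels).
#' @param n_shots number of shots to average (default from `config`).
#' @return numeric intensity vector over the wavelength axis.
#' @export
synthesize_spectrum <- function(concentrations, config = sim_config(),
                                n_shots = config$n_shots) {
  sig <- signal_vector(concentrations, config)
  average_shots(sig, config, n_shots)
}

# Average n_shots noisy realizations of a signal vector.
average_shots <- function(sig, config, n_shots) {
  p <- length(sig)
  if (config$noise_shot_sd == 0 && config$noise_additive_sd == 0) {
    return(pmax(0, sig))
  }
  shot <- matrix(rnorm(n_shots * p, sd = config$noise_shot_sd),
                 n_shots, p, byrow = FALSE)
  addn <- matrix(rnorm(n_shots * p, sd = config$noise_additive_sd),
                 n_shots, p, byrow = FALSE)
  shots <- rep(sig, each = n_shots) * (1 + shot) + addn
  shots[shots < 0] <- 0
  colMeans(matrix(shots, n_shots, p))
}

#' Spectrum set container
#'
#' The pipeline currency: a strictly increasing wavelength axis, an
#' n x p intensity matrix and aligned sample ids.
#'
#' @param wavelengths numeric vector, strictly increasing (nm).
#' @param intensities numeric matrix, one row per sample.
#' @param sample_ids unique character ids, length nrow(intensities).
#' @return object of class `spectrum_set`.
#' @export
spectrum_set <- function(wavelengths, intensities, sample_ids) {
  intensities <- as.matrix(intensities)
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must strictly increase")
  if (ncol(intensities) != length(wavelengths))
    stop("column count must equal wavelength axis length")
  if (length(sample_ids) != nrow(intensities))
    stop("sample_ids length must equal row count")
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (anyNA(intensities)) stop("missing values in intensities")
  dimnames(intensities) <- list(sample_ids,
                                format(wavelengths, trim = TRUE))
  structure(list(wavelengths = as.numeric(wavelengths),
                 intensities = intensities,
                 sample_ids = as.character(sample_ids)),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("spectrum_set:", nrow(x$intensities), "samples x",
      length(x$wavelengths), "channels (",
      min(x$wavelengths), "-", max(x$wavelengths), "nm )\n")
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$intensities)

#' Generate a full synthetic dataset
#'
#' Draws a concentration design, then synthesizes and shot-averages one
#' spectrum per sample. The whole dataset is a deterministic function of
#' `(config, seed)`: the same seed reproduces bit-identical output.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed.
#' @return list with `spectra` (a [spectrum_set()]) and `concentrations`
#'   (a [generate_design()] table).
#' @export
generate_dataset <- function(config = sim_config(), seed = 1) {
  validate_sim_config(config)
  set.seed(seed)
  design <- generate_design(config)
  conc <- concentration_matrix(design)
  profiles <- line_profiles(config)
  wl <- wavelength_axis(config)
  n <- nrow(design)
  intens <- matrix(0, n, length(wl))
  for (i in seq_len(n)) {
    sig <- signal_vector(conc[i, ], config, profiles)
    intens[i, ] <- average_shots(sig, config, config$n_shots)
  }
  list(spectra = spectrum_set(wl, intens, design$sample_id),
       concentrations = design)
}
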