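#' Area normalization of spectra
#'
#' Divides each spectrum by its trapezoidal integral over the wavelength
#' axis, so every normalized row has unit area. Normalization w.r.t. the
#' axis (not the plain channel sum) keeps results stable under changes of
#' channel spacing. The operation is per-spectrum (no training-set
#' statistics), hence free of train/test leakage, scale-invariant and
#' idempotent.
#'
#' @param spectra a [spectrum_set()].
#' @return a [spectrum_set()] with unit-area rows.
#' @export
area_normalize <- function(spectra) {
  stopifnot(inherits(spectra, "spectrum_set"))
  w <- trapezoid_weights(spectra$wavelengths)
  areas <- as.numeric(spectra$intensities %*% w)
  bad <- which(areas <= 0)
  if (length(bad)) {
    stop("non-positive spectral area for sample(s): ",
         paste(spectra$sample_ids[bad], collapse = ", "))
  }
  spectrum_set(spectra$wavelengths, spectra$intensities / areas,
               spectra$sample_ids)
}

# Quadrature weights such that sum(w * f) equals the trapezoidal integral
# of f over the (possibly non-uniform) axis x.
trapezoid_weights <- function(x) {
  d <- diff(x)
  p <- length(x)
  w <- numeric(p)
  w[1] <- d[1] / 2
  w[p] <- d[p - 1] / 2
  if (p > 2) w[2:(p - 1)] <- (d[-length(d)] + d[-1]) / 2
  w
}

#' Trapezoidal area of each spectrum
#' @param spectra a [spectrum_set()].
#' @return numeric vector of row areas.
#' @export
spectral_areas <- function(spectra) {
  as.numeric(spectra$intensities %*% trapezoid_weights(spectra$wavelengths))
}

# Largest-remainder apportionment of n items over fractions.
largest_remainder <- function(n, fractions) {
  quota <- n * fractions
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    # ties broken by subset order (calibration first)
    add <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Split samples into calibration / validation / prediction sets
#'
#' Random partition of `n` samples into three disjoint, covering subsets
#' with sizes given by largest-remainder apportionment of the fractions
#' (default 60% / 28% / 12%). When `group_labels` is supplied the split is
#' stratified: apportionment and random assignment happen within each
#' group, so extreme-concentration groups appear in all three subsets.
#'
#' @param n sample count (>= 3).
#' @param fractions length-3 positive fractions summing to 1 (tolerance
#'   1e-9), in the order calibration, validation, prediction.
#' @param seed optional RNG seed.
#' @param group_labels optional length-n vector of group labels enabling
#'   stratification.
#' @return object of class `split_indices`: list with sorted integer index
#'   vectors `calibration`, `validation`, `prediction`.
#' @export
split_dataset <- function(n, fractions = c(0.60, 0.28, 0.12), seed = NULL,
                          group_labels = NULL) {
  if (n < 3) stop("n must be >= 3")
  if (length(fractions) != 3 || any(fractions <= 0))
    stop("fractions must be 3 positive numbers")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  assign_one <- function(idx) {
    sizes <- largest_remainder(length(idx), fractions)
    perm <- sample(idx)
    list(calibration = perm[seq_len(sizes[1])],
         validation = perm[sizes[1] + seq_len(sizes[2])],
         prediction = perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
  }
  if (is.null(group_labels)) {
    parts <- assign_one(seq_len(n))
  } else {
    if (length(group_labels) != n) stop("group_labels must have length n")
    parts <- list(calibration = integer(), validation = integer(),
                  prediction = integer())
    for (g in unique(group_labels)) {
      sub <- assign_one(which(group_labels == g))
      parts <- Map(c, parts, sub)
    }
  }
  structure(lapply(parts, function(v) sort(as.integer(v))),
            class = "split_indices")
}

#' @export
print.split_indices <- function(x, ...) {
  cat("split_indices: calibration", length(x$calibration),
      "/ validation", length(x$validation),
      "/ prediction", length(x$prediction), "\n")
  invisible(x)
}

#' Serialize split indices to a CSV of (sample_id, subset)
#' @param split a [split_dataset()] result.
#' @param sample_ids character ids indexed by the split.
#' @param path output CSV path.
#' @export
write_split <- function(split, sample_ids, path) {
  rows <- do.call(rbind, lapply(names(split), function(s) {
    data.frame(sample_id = sample_ids[split[[s]]], subset = s,
               stringsAsFactors = FALSE)
  }))
  data.table::fwrite(rows, path)
  invisible(path)
}
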