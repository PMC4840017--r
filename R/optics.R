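#' @title Modified Beer-Lambert law conversion
#' @description Functions converting between dual-wavelength optical-density
#'   changes and oxy/deoxy-hemoglobin concentration changes.
#' @name optics
NULL

#' Default molar absorption coefficients for HbO and HbR
#'
#' Approximate base-10 molar absorption (extinction) coefficients of
#' oxygenated (HbO) and deoxygenated (HbR) hemoglobin at near-infrared
#' wavelengths, in mM^-1 cm^-1, compiled from standard spectrophotometric
#' tabulations. Values at intermediate wavelengths are linearly
#' interpolated. These defaults are adequate for differential (change)
#' analysis; for quantitative work supply your own table via
#' [mbll_coefficients()].
#'
#' @return A data.frame with columns `wavelength` (nm), `alpha_hbo`,
#'   `alpha_hbr` (mM^-1 cm^-1).
#' @export
extinction_defaults <- function() {
  data.frame(
    wavelength = c(690, 695, 750, 780, 808, 830, 850),
    alpha_hbo  = c(0.276, 0.312, 0.518, 0.710, 0.856, 0.974, 1.058),
    alpha_hbr  = c(2.052, 1.922, 1.405, 1.059, 0.762, 0.693, 0.691)
  )
}

lookup_extinction <- function(wavelength, table = extinction_defaults()) {
  rng <- range(table$wavelength)
  if (wavelength < rng[1] || wavelength > rng[2])
    stop("wavelength ", wavelength, " nm outside extinction table range [",
         rng[1], ", ", rng[2], "] nm", call. = FALSE)
  c(alpha_hbo = stats::approx(table$wavelength, table$alpha_hbo, wavelength)$y,
    alpha_hbr = stats::approx(table$wavelength, table$alpha_hbr, wavelength)$y)
}

#' Differential pathlength factor models
#'
#' The differential pathlength factor (DPF) scales the geometric
#' source-detector separation to the effective optical pathlength through
#' scattering tissue; it depends on wavelength and on subject age.
#'
#' `dpf_model_general()` returns the general empirical DPF equation
#' (polynomial in wavelength, power law in age) fitted across published
#' frontal-lobe measurements; it is valid for wavelengths 690-832 nm and
#' increases monotonically with age. `dpf_model_table()` wraps a fixed
#' lookup table (age-independent), e.g. instrument-vendor constants.
#'
#' @param table Named numeric vector mapping wavelength (nm, as names) to
#'   DPF values.
#' @return An object of class `dpf_model`: a list with a `value(wavelength,
#'   age)` function and a `range` of valid wavelengths.
#' @seealso [get_dpf()]
#' @export
dpf_model_general <- function() {
  structure(list(
    name = "general",
    range = c(690, 832),
    value = function(wavelength, age) {
      223.3 + 0.05624 * age^0.8493 - 5.723e-7 * wavelength^3 +
        0.001245 * wavelength^2 - 0.9025 * wavelength
    }
  ), class = "dpf_model")
}

#' @rdname dpf_model_general
#' @export
dpf_model_table <- function(table) {
  stopifnot(is.numeric(table), !is.null(names(table)), all(table > 0))
  wl <- as.numeric(names(table))
  structure(list(
    name = "table",
    range = range(wl),
    value = function(wavelength, age) {
      i <- match(wavelength, wl)
      if (is.na(i)) stop("wavelength ", wavelength,
                         " nm not in DPF table (", paste(wl, collapse = ", "),
                         ")", call. = FALSE)
      unname(table[i])
    }
  ), class = "dpf_model")
}

#' Evaluate a differential pathlength factor
#'
#' @param wavelength Wavelength in nm; must lie in the model's validity
#'   range.
#' @param age Subject age in years (ignored by table models).
#' @param model A `dpf_model`, by default the general age-dependent
#'   equation.
#' @return DPF value (dimensionless, > 0).
#' @export
get_dpf <- function(wavelength, age = 25, model = dpf_model_general()) {
  stopifnot(inherits(model, "dpf_model"), age >= 0)
  if (wavelength < model$range[1] || wavelength > model$range[2])
    stop("wavelength ", wavelength, " nm outside model validity range [",
         model$range[1], ", ", model$range[2], "] nm", call. = FALSE)
  d <- model$value(wavelength, age)
  stopifnot(d > 0)
  d
}

#' Coefficients of the modified Beer-Lambert law
#'
#' Bundles everything needed to convert dual-wavelength optical-density
#' changes into hemoglobin concentration changes: molar absorption
#' coefficients of HbO and HbR at each wavelength (mM^-1 cm^-1),
#' differential pathlength factors, and the source-detector separation
#' (cm). The 2x2 conversion is singular when the wavelength pair carries
#' no independent information, i.e. when the determinant
#' `alpha_hbo(l1)*alpha_hbr(l2) - alpha_hbo(l2)*alpha_hbr(l1)` vanishes.
#'
#' @param wavelengths Length-2 numeric, wavelengths in nm.
#' @param distance Source-detector separation in cm (> 0).
#' @param age Subject age in years, passed to the DPF model.
#' @param alpha_hbo,alpha_hbr Length-2 absorption coefficients per
#'   wavelength (mM^-1 cm^-1); defaults interpolated from
#'   [extinction_defaults()].
#' @param dpf Length-2 DPF values; default evaluated from `dpf_model`.
#' @param dpf_model DPF model used when `dpf` is not given.
#' @return An object of class `mbll_coefficients`.
#' @export
mbll_coefficients <- function(wavelengths = c(695, 830), distance = 3,
                              age = 25,
                              alpha_hbo = NULL, alpha_hbr = NULL,
                              dpf = NULL, dpf_model = dpf_model_general()) {
  stopifnot(length(wavelengths) == 2, distance > 0)
  if (is.null(alpha_hbo) || is.null(alpha_hbr)) {
    ext <- vapply(wavelengths, lookup_extinction, numeric(2))
    if (is.null(alpha_hbo)) alpha_hbo <- ext["alpha_hbo", ]
    if (is.null(alpha_hbr)) alpha_hbr <- ext["alpha_hbr", ]
  }
  if (is.null(dpf))
    dpf <- vapply(wavelengths, get_dpf, numeric(1), age = age,
                  model = dpf_model)
  stopifnot(length(alpha_hbo) == 2, length(alpha_hbr) == 2,
            length(dpf) == 2, all(dpf > 0))
  det_c <- alpha_hbo[1] * alpha_hbr[2] - alpha_hbo[2] * alpha_hbr[1]
  tol <- 1e-12 * max(abs(c(alpha_hbo[1] * alpha_hbr[2],
                           alpha_hbo[2] * alpha_hbr[1])))
  if (abs(det_c) <= tol)
    stop("singular MBLL coefficients: wavelength pair determinant ",
         format(det_c), " is numerically zero", call. = FALSE)
  structure(list(wavelengths = as.numeric(wavelengths),
                 alpha_hbo = as.numeric(alpha_hbo),
                 alpha_hbr = as.numeric(alpha_hbr),
                 dpf = as.numeric(dpf),
                 distance = distance,
                 det = det_c),
            class = "mbll_coefficients")
}

#' @export
print.mbll_coefficients <- function(x, ...) {
  cat("MBLL coefficients\n")
  cat(sprintf("  wavelengths: %g / %g nm, separation %g cm\n",
              x$wavelengths[1], x$wavelengths[2], x$distance))
  cat(sprintf("  alpha_HbO: %.4g / %.4g, alpha_HbR: %.4g / %.4g mM^-1 cm^-1\n",
              x$alpha_hbo[1], x$alpha_hbo[2], x$alpha_hbr[1], x$alpha_hbr[2]))
  cat(sprintf("  DPF: %.3f / %.3f, determinant %.4g\n",
              x$dpf[1], x$dpf[2], x$det))
  invisible(x)
}

#' Optical recording container
#'
#' Dual-wavelength optical-density change time series: an M x J x 2 array
#' (observations x channels x wavelengths).
#'
#' @param od Numeric array `[M, J, 2]` of optical-density changes, or a
#'   list of two M x J matrices (one per wavelength).
#' @param fs Sampling frequency, Hz.
#' @param channel_ids Optional channel labels (default CH1..CHJ); must be
#'   unique.
#' @param wavelengths Length-2 wavelengths in nm.
#' @param layout Optional [probe_layout()].
#' @return Object of class `optical_recording`.
#' @export
optical_recording <- function(od, fs, channel_ids = NULL,
                              wavelengths = c(695, 830), layout = NULL) {
  if (is.list(od) && !is.array(od)) {
    stopifnot(length(od) == 2, all(dim(od[[1]]) == dim(od[[2]])))
    od <- array(c(od[[1]], od[[2]]), dim = c(dim(od[[1]]), 2))
  }
  stopifnot(is.array(od), length(dim(od)) == 3, dim(od)[3] == 2, fs > 0)
  J <- dim(od)[2]
  if (is.null(channel_ids)) channel_ids <- paste0("CH", seq_len(J))
  stopifnot(length(channel_ids) == J)
  if (anyDuplicated(channel_ids))
    stop("duplicated channel labels: ",
         paste(unique(channel_ids[duplicated(channel_ids)]), collapse = ", "),
         call. = FALSE)
  structure(list(od = od, fs = fs, channel_ids = as.character(channel_ids),
                 wavelengths = wavelengths, layout = layout),
            class = "optical_recording")
}

#' Hemoglobin concentration-change time series
#'
#' @param hbo,hbr M x J matrices of HbO / HbR concentration changes (mM).
#' @param fs Sampling frequency, Hz.
#' @param channel_ids Optional channel labels.
#' @return Object of class `hb_series`.
#' @export
hb_series <- function(hbo, hbr, fs, channel_ids = NULL) {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  stopifnot(all(dim(hbo) == dim(hbr)), fs > 0)
  if (is.null(channel_ids)) channel_ids <- paste0("CH", seq_len(ncol(hbo)))
  structure(list(hbo = hbo, hbr = hbr, fs = fs,
                 channel_ids = as.character(channel_ids)),
            class = "hb_series")
}

#' @export
print.hb_series <- function(x, ...) {
  cat(sprintf("hb_series: %d samples x %d channels at %g Hz (%.1f s)\n",
              nrow(x$hbo), ncol(x$hbo), x$fs, nrow(x$hbo) / x$fs))
  invisible(x)
}

#' Convert optical-density changes to hemoglobin changes
#'
#' Inverts the modified Beer-Lambert law per sample and channel: the
#' optical-density change at each wavelength is divided by pathlength
#' (DPF x separation), and the resulting 2x2 linear system in
#' (dHbO, dHbR) is solved in closed form.
#'
#' @param rec An [optical_recording()].
#' @param coeffs An [mbll_coefficients()]; its wavelength order must match
#'   the recording's.
#' @return An [hb_series()] in mM.
#' @export
od_to_hb <- function(rec, coeffs) {
  stopifnot(inherits(rec, "optical_recording"),
            inherits(coeffs, "mbll_coefficients"))
  l <- coeffs$distance
  a1 <- rec$od[, , 1] / (coeffs$dpf[1] * l)   # attenuation per unit path
  a2 <- rec$od[, , 2] / (coeffs$dpf[2] * l)
  cdet <- coeffs$det
  hbo <- (coeffs$alpha_hbr[2] * a1 - coeffs$alpha_hbr[1] * a2) / cdet
  hbr <- (coeffs$alpha_hbo[1] * a2 - coeffs$alpha_hbo[2] * a1) / cdet
  hb_series(hbo, hbr, rec$fs, rec$channel_ids)
}

#' Convert hemoglobin changes to optical-density changes
#'
#' Forward modified Beer-Lambert law: at each wavelength the
#' optical-density change is
#' `(alpha_hbo * dHbO + alpha_hbr * dHbR) * dpf * distance`.
#' Exact inverse of [od_to_hb()].
#'
#' @param hb An [hb_series()].
#' @param coeffs An [mbll_coefficients()].
#' @param layout Optional [probe_layout()] attached to the result.
#' @return An [optical_recording()].
#' @export
hb_to_od <- function(hb, coeffs, layout = NULL) {
  stopifnot(inherits(hb, "hb_series"), inherits(coeffs, "mbll_coefficients"))
  if (!all(dim(hb$hbo) == dim(hb$hbr))) stop("hbo/hbr shape mismatch")
  l <- coeffs$distance
  od1 <- (coeffs$alpha_hbo[1] * hb$hbo + coeffs$alpha_hbr[1] * hb$hbr) *
    coeffs$dpf[1] * l
  od2 <- (coeffs$alpha_hbo[2] * hb$hbo + coeffs$alpha_hbr[2] * hb$hbr) *
    coeffs$dpf[2] * l
  optical_recording(array(c(od1, od2), dim = c(dim(od1), 2)), hb$fs,
                    hb$channel_ids, coeffs$wavelengths, layout)
}
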