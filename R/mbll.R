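# Modified Beer-Lambert law: forward projection and inversion, and the
# age-dependent differential pathlength factor.

# Coefficients of the general DPF equation (polynomial in wavelength, power
# law in age), transcribed from the published general-equation compilation
# for continuous-wave NIRS (Scholkmann & Wolf 2013, J Biomed Opt 18:105004):
# DPF(lambda, A) = a + b*A^c + d*lambda^3 + e*lambda^2 + f*lambda
DPF_COEF <- c(a = 223.3, b = 0.05624, c = 0.8493,
              d = -5.723e-7, e = 0.001245, f = -0.9025)

#' Age-dependent differential pathlength factor
#'
#' Evaluates the general DPF equation for continuous-wave NIRS: a cubic
#' polynomial in wavelength plus a power law in age. The DPF converts the
#' geometric source-detector distance into an effective photon pathlength and
#' is strictly increasing in age at a fixed wavelength.
#'
#' @param age_years Subject age in years, within \[0, 100\].
#' @param wavelength_nm Wavelength in nm, within \[690, 950\] (vectorised).
#' @return Dimensionless pathlength factor(s).
#' @examples
#' compute_dpf(30, 760)
#' compute_dpf(30, c(760, 850))
#' @export
compute_dpf <- function(age_years, wavelength_nm) {
  if (age_years < 0 || age_years > 100) stop("age_years must be within [0, 100]")
  if (any(wavelength_nm < 690 | wavelength_nm > 950))
    stop("wavelength_nm must be within [690, 950]")
  k <- DPF_COEF
  k[["a"]] + k[["b"]] * age_years^k[["c"]] +
    k[["d"]] * wavelength_nm^3 + k[["e"]] * wavelength_nm^2 +
    k[["f"]] * wavelength_nm
}

#' Hemoglobin extinction coefficients
#'
#' Decadic molar extinction coefficients of oxy- and deoxyhemoglobin at the
#' acquisition wavelengths, shipped as package data (see the file header in
#' `extdata/extinction_hb.tsv` for provenance).
#'
#' @param path Optional path to an alternative table (TSV with columns
#'   `wavelength_nm`, `eps_o2hb`, `eps_hhb`).
#' @return Data frame with one row per wavelength; units cm^-1/(mol/L).
#' @export
extinction_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "extinction_hb.tsv", package = "nirspine",
                        mustWork = TRUE)
  utils::read.delim(path, comment.char = "#")
}

# Per-channel 2x2 MBLL matrix M such that OD[wl] = M %*% conc[chromophore],
# conc in umol/L, separation in mm (converted to cm), decadic extinction.
mbll_matrix <- function(separation_mm, dpf_by_wavelength, ext) {
  d_cm <- separation_mm / 10
  sapply(seq_along(WAVELENGTHS_NM), function(i) {
    wl <- WAVELENGTHS_NM[i]
    row <- ext[ext$wavelength_nm == wl, ]
    if (nrow(row) != 1) stop("missing extinction coefficients for ", wl, " nm")
    c(row$eps_o2hb, row$eps_hhb) * 1e-6 * d_cm * dpf_by_wavelength[[as.character(wl)]]
  }) |> t()
}

#' Project chromophore concentration changes to optical density
#'
#' The forward modified Beer-Lambert law: per channel and sample,
#' `dOD(lambda) = [eps_O2Hb(lambda) dO2Hb + eps_HHb(lambda) dHHb] * d * DPF(lambda)`
#' with concentrations in umol/L, separation `d` in cm and decadic extinction
#' coefficients. Exactly linear; algebraic inverse of [mbll_invert()].
#'
#' @param chromophores `channel_ts` of kind `"chromophore"` with layers
#'   `O2Hb`, `HHb` (umol/L).
#' @param layout A `probe_layout` (provides per-channel separations).
#' @param dpf_by_wavelength Named list/vector of DPFs, names `"760"`, `"850"`.
#' @param ext Extinction table, as from [extinction_table()].
#' @return `channel_ts` of kind `"optical_density"`, layers `"760"`, `"850"`.
#' @export
forward_mbll <- function(chromophores, layout,
                         dpf_by_wavelength = NULL, ext = extinction_table()) {
  stopifnot(inherits(chromophores, "channel_ts"),
            chromophores$kind == "chromophore")
  if (is.null(dpf_by_wavelength))
    dpf_by_wavelength <- default_dpf()
  X <- chromophores$values
  nch <- dim(X)[1]; ns <- dim(X)[2]
  od <- array(0, dim = c(nch, ns, 2),
              dimnames = list(NULL, NULL, as.character(WAVELENGTHS_NM)))
  # per-channel matrices differ only by the separation scale factor
  M1 <- mbll_matrix(1, dpf_by_wavelength, ext)   # at 1 mm
  d_mm <- layout$channels$separation_mm
  for (w in 1:2)
    od[, , w] <- d_mm * (M1[w, 1] * X[, , "O2Hb"] + M1[w, 2] * X[, , "HHb"])
  channel_ts(od, fs = chromophores$fs, t0 = chromophores$t0,
             kind = "optical_density")
}

#' Convert optical density to chromophore concentration changes
#'
#' Inverts the modified Beer-Lambert law: per channel and sample solves the
#' 2x2 linear system relating the two-wavelength OD changes to
#' (dO2Hb, dHHb). Output is in umol/L.
#'
#' @param od `channel_ts` of kind `"optical_density"` with layers at the two
#'   acquisition wavelengths.
#' @inheritParams forward_mbll
#' @return `channel_ts` of kind `"chromophore"`, layers `O2Hb`, `HHb`.
#' @export
mbll_invert <- function(od, layout, dpf_by_wavelength = NULL,
                        ext = extinction_table()) {
  stopifnot(inherits(od, "channel_ts"), od$kind == "optical_density")
  if (is.null(dpf_by_wavelength))
    dpf_by_wavelength <- default_dpf()
  X <- od$values
  nch <- dim(X)[1]; ns <- dim(X)[2]
  conc <- array(0, dim = c(nch, ns, 2),
                dimnames = list(NULL, NULL, CHROMOPHORES))
  M1 <- mbll_matrix(1, dpf_by_wavelength, ext)   # at 1 mm
  if (abs(det(M1)) < .Machine$double.eps * 100)
    stop("singular extinction matrix (collinear wavelengths)")
  Minv <- solve(M1)
  inv_d <- 1 / layout$channels$separation_mm
  for (cr in 1:2)
    conc[, , cr] <- inv_d * (Minv[cr, 1] * X[, , "760"] + Minv[cr, 2] * X[, , "850"])
  channel_ts(conc, fs = od$fs, t0 = od$t0, kind = "chromophore")
}

#' DPF pair for a subject age
#'
#' @param age_years Subject age (default 33.5, the study group's mean age).
#' @return Named vector of DPFs at 760 and 850 nm.
#' @export
default_dpf <- function(age_years = 33.5) {
  stats::setNames(compute_dpf(age_years, WAVELENGTHS_NM),
                  as.character(WAVELENGTHS_NM))
}
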