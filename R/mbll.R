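#' Hemoglobin extinction coefficients
#'
#' Molar extinction coefficients (cm^-1 M^-1) of oxygenated and deoxygenated
#' hemoglobin at the instrument wavelengths, from the standard published
#' compilation of in-vitro hemoglobin spectra used throughout the fNIRS
#' literature.
#'
#' @return Data frame with `wavelength_nm`, `eps_hbo`, `eps_hbr`.
#' @export
extinction_coefficients <- function() {
  data.frame(wavelength_nm = c(730, 808, 850),
             eps_hbo = c(446.0, 856.0, 1058.0),
             eps_hbr = c(1102.2, 717.1, 691.3))
}

#' Invert optical density to hemoglobin concentration changes
#'
#' Modified Beer-Lambert law: at each wavelength,
#' `dOD(lambda) = (eps_HbO(lambda) * dHbO + eps_HbR(lambda) * dHbR) * d * DPF`,
#' with source-detector separation `d` (cm) and differential pathlength
#' factor `DPF`. With three wavelengths the 3x2 system is solved per channel
#' and sample by ordinary least squares; concentrations come out in
#' micromolar.
#'
#' @param rec An od-stage [optical_recording()].
#' @param dpf Differential pathlength factor (applied to all wavelengths).
#' @param extinction Extinction table covering the recording's wavelengths,
#'   see [extinction_coefficients()].
#' @param separation_cm Source-detector separation; defaults to the montage
#'   distance (3 cm).
#' @return An hbo-stage `optical_recording`; the HbR series is retained in
#'   the `hbr` field.
#' @export
od_to_hemo <- function(rec, dpf = 6.0, extinction = extinction_coefficients(),
                       separation_cm = NULL) {
  stopifnot(inherits(rec, "optical_recording"))
  if (rec$stage != "od") stop("expected an od-stage recording")
  wl <- rec$wavelengths_nm
  if (length(wl) < 2) stop("Beer-Lambert inversion needs >= 2 wavelengths")
  if (anyDuplicated(wl)) stop("duplicate wavelengths make the design singular")
  idx <- match(wl, extinction$wavelength_nm)
  if (anyNA(idx))
    stop("extinction table does not cover wavelength(s) ",
         paste(wl[is.na(idx)], collapse = ", "), " nm")
  if (is.null(separation_cm))
    separation_cm <- if (!is.null(rec$montage)) rec$montage$distance_cm else 3
  # design in OD per micromolar
  A <- cbind(extinction$eps_hbo[idx], extinction$eps_hbr[idx]) *
    1e-6 * separation_cm * dpf
  if (abs(det(crossprod(A))) < 1e-300) stop("singular extinction design")
  pinv <- solve(crossprod(A), t(A))      # 2 x n_wl least-squares operator

  nch <- n_channels(rec)
  n <- n_samples(rec)
  hbo <- matrix(0, nch, n)
  hbr <- matrix(0, nch, n)
  for (ch in seq_len(nch)) {
    odm <- matrix(rec$data[ch, , ], nrow = n, ncol = length(wl))
    conc <- pinv %*% t(odm)              # 2 x n
    hbo[ch, ] <- conc[1, ]
    hbr[ch, ] <- conc[2, ]
  }
  optical_recording(hbo, stage = "hbo", fs_hz = rec$fs_hz,
                    wavelengths_nm = wl, montage = rec$montage, hbr = hbr)
}

#' Forward modified Beer-Lambert model
#'
#' Maps known hemoglobin concentration changes (µM) to per-wavelength
#' optical density, the exact inverse of [od_to_hemo()] when the same
#' extinction table, separation and DPF are used.
#'
#' @param hbo,hbr Channel x sample matrices in micromolar.
#' @param wavelengths_nm Wavelengths to synthesize.
#' @inheritParams od_to_hemo
#' @param fs_hz Sampling rate of the returned recording.
#' @param montage Optional montage attached to the returned recording.
#' @return An od-stage [optical_recording()].
#' @export
hemo_to_od <- function(hbo, hbr, wavelengths_nm = c(730, 808, 850),
                       dpf = 6.0, extinction = extinction_coefficients(),
                       separation_cm = 3, fs_hz = 11, montage = NULL) {
  stopifnot(is.matrix(hbo), is.matrix(hbr), all(dim(hbo) == dim(hbr)))
  idx <- match(wavelengths_nm, extinction$wavelength_nm)
  if (anyNA(idx)) stop("extinction table does not cover all wavelengths")
  od <- array(0, dim = c(nrow(hbo), ncol(hbo), length(wavelengths_nm)))
  for (w in seq_along(wavelengths_nm)) {
    od[, , w] <- (extinction$eps_hbo[idx[w]] * hbo +
                    extinction$eps_hbr[idx[w]] * hbr) *
      1e-6 * separation_cm * dpf
  }
  optical_recording(od, stage = "od", fs_hz = fs_hz,
                    wavelengths_nm = wavelengths_nm, montage = montage)
}
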