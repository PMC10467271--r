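#' Construct an optical recording
#'
#' Container for one subject's multichannel fNIRS data at a given processing
#' stage. Raw intensity and optical density are stored as a 3-D array
#' (channel x sample x wavelength); oxygenated-hemoglobin (HbO) series as a
#' channel x sample matrix in micromolar.
#'
#' @param data Numeric matrix (`stage = "hbo"`) or 3-D array
#'   (`stage = "intensity"` or `"od"`).
#' @param stage Processing stage: `"intensity"`, `"od"` or `"hbo"`.
#' @param fs_hz Sampling rate in Hz.
#' @param wavelengths_nm Wavelengths (nm) of the optical stages.
#' @param montage Optional `channel_montage`.
#' @param hbr Optional channel x sample matrix of deoxygenated hemoglobin,
#'   retained alongside HbO after the Beer-Lambert inversion.
#' @return An object of class `optical_recording`.
#' @export
optical_recording <- function(data, stage = c("intensity", "od", "hbo"),
                              fs_hz = 11, wavelengths_nm = c(730, 808, 850),
                              montage = NULL, hbr = NULL) {
  stage <- match.arg(stage)
  stopifnot(fs_hz > 0)
  if (stage == "hbo") {
    if (!is.matrix(data)) stop("hbo stage expects a channel x sample matrix")
  } else {
    if (length(dim(data)) != 3)
      stop(stage, " stage expects a channel x sample x wavelength array")
    if (dim(data)[3] != length(wavelengths_nm))
      stop("third dimension must match the number of wavelengths")
    if (stage == "intensity" && any(data <= 0)) {
      bad <- which(data <= 0, arr.ind = TRUE)[1, ]
      stop(sprintf("non-positive intensity at channel %d, sample %d",
                   bad[1], bad[2]))
    }
  }
  if (any(!is.finite(data))) stop("recording contains non-finite values")
  structure(
    list(data = data, stage = stage, fs_hz = fs_hz,
         wavelengths_nm = wavelengths_nm, montage = montage, hbr = hbr),
    class = "optical_recording")
}

#' @export
print.optical_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Optical recording [%s]: %d channels x %d samples", x$stage,
              d[1], d[2]))
  if (x$stage != "hbo") cat(sprintf(" x %d wavelengths", d[3]))
  cat(sprintf(" @ %g Hz (%.1f s)\n", x$fs_hz, d[2] / x$fs_hz))
  invisible(x)
}

n_channels <- function(rec) dim(rec$data)[1]
n_samples <- function(rec) dim(rec$data)[2]
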