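#' Bilateral DLPFC probe montage
#'
#' Returns the fixed probe layout used throughout the package: 7 light
#' sources and 6 detectors over the left and right dorsolateral prefrontal
#' cortex, yielding 14 measurement channels, every source-detector pair
#' separated by 3 cm. Positions are planar (cm) with the midline at x = 0.
#'
#' Each hemisphere carries 3 sources and 3 detectors on a triangular lattice
#' (lattice constant 3 cm) forming 7 channels; the seventh source sits on the
#' midline as a reference optode and does not form a measurement channel.
#' Channels are ordered 1-14: 1 = most lateral left, 7 = most medial left,
#' 8 = most medial right, 14 = most lateral right, so channel 7/8 cover the
#' mid-frontal area and channels 1-2 / 13-14 the lateral areas.
#'
#' @return An object of class `channel_montage`: list with `sources` and
#'   `detectors` (named position matrices), `channels` (data frame of
#'   source/detector pairs in channel order) and `distance_cm`.
#' @examples
#' m <- dlpfc_montage()
#' nrow(m$channels)  # 14
#' @export
dlpfc_montage <- function() {
  h <- sqrt(9 - 1.5^2)  # height of a 3-cm triangular lattice

  # left hemisphere optodes (x < 0)
  src_l <- rbind(S1 = c(-10.5, 0), S2 = c(-4.5, 0), S3 = c(-6, h))
  det_l <- rbind(D1 = c(-7.5, 0), D2 = c(-9, h), D3 = c(-3, h))
  # right hemisphere: mirror through the midline
  src_r <- rbind(S5 = c(10.5, 0), S6 = c(4.5, 0), S7 = c(6, h))
  det_r <- rbind(D4 = c(7.5, 0), D5 = c(9, h), D6 = c(3, h))
  src_mid <- rbind(S4 = c(0, h))  # midline reference optode, no channel

  sources <- rbind(src_l, src_mid, src_r)
  detectors <- rbind(det_l, det_r)
  colnames(sources) <- colnames(detectors) <- c("x_cm", "y_cm")

  # left channels lateral -> medial, then right channels medial -> lateral
  left <- data.frame(
    source   = c("S1", "S1", "S3", "S3", "S2", "S3", "S2"),
    detector = c("D2", "D1", "D2", "D1", "D1", "D3", "D3"),
    stringsAsFactors = FALSE)
  right <- data.frame(
    source   = c("S6", "S7", "S6", "S7", "S7", "S5", "S5"),
    detector = c("D6", "D6", "D4", "D4", "D5", "D4", "D5"),
    stringsAsFactors = FALSE)
  channels <- rbind(left, right)
  channels$channel <- seq_len(nrow(channels))
  channels <- channels[, c("channel", "source", "detector")]

  m <- structure(
    list(sources = sources, detectors = detectors,
         channels = channels, distance_cm = 3.0),
    class = "channel_montage")
  validate_montage(m)
  m
}

#' Validate a channel montage
#'
#' Asserts exactly 7 sources, 6 detectors and 14 channels, and that every
#' source-detector pair of a channel is separated by `distance_cm`.
#'
#' @param m A `channel_montage`.
#' @return `TRUE` invisibly; stops otherwise.
#' @export
validate_montage <- function(m) {
  stopifnot(inherits(m, "channel_montage"))
  if (nrow(m$sources) != 7) stop("montage must have exactly 7 sources")
  if (nrow(m$detectors) != 6) stop("montage must have exactly 6 detectors")
  if (nrow(m$channels) != 14) stop("montage must have exactly 14 channels")
  for (k in seq_len(nrow(m$channels))) {
    s <- m$sources[m$channels$source[k], ]
    d <- m$detectors[m$channels$detector[k], ]
    sep <- sqrt(sum((s - d)^2))
    if (abs(sep - m$distance_cm) > 1e-9)
      stop("channel ", k, " separation ", format(sep),
           " cm differs from ", m$distance_cm, " cm")
  }
  invisible(TRUE)
}

#' @export
print.channel_montage <- function(x, ...) {
  cat("Bilateral DLPFC montage: 7 sources, 6 detectors, 14 channels, ",
      x$distance_cm, " cm separation\n", sep = "")
  invisible(x)
}
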