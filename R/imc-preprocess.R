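#' Analysis configuration for multiplexed-image quantification
#'
#' Collects the tunable parameters of the pericellular quantification
#' pipeline. Defaults follow common practice for imaging-mass-cytometry
#' style data: hot-pixel threshold 50 (raw-count scale), a 10 micrometre
#' pericellular radius, and quantile-based marker-high selection (top 20%).
#'
#' @param hot_pixel_threshold Hot-pixel filter threshold (see
#'   [filter_hot_pixels()]).
#' @param tissue_channels Channels summed to build the tissue/void mask;
#'   `NULL` means all channels.
#' @param radius_um Pericellular disc radius in micrometres.
#' @param min_valid_fraction Minimum fraction of disc pixels that must remain
#'   after cell/void exclusion for a pericellular mean to be reported.
#' @param high_strategy Marker-high selection: `"quantile"` (threshold at the
#'   `high_param` quantile of epithelial marker means), `"fixed_value"` or
#'   `"manual_threshold"` (both use `high_param` as an intensity threshold;
#'   the latter name flags analyst-chosen per-image values).
#' @param high_param Parameter for `high_strategy`.
#' @param epithelial_channel Channel gating epithelial cells.
#' @param epithelial_threshold Epithelial gate threshold; `NULL` uses the
#'   median of the epithelial-channel means over all cells.
#' @param ki67_threshold Threshold for Ki67 positivity.
#' @param ecm_channels Channels for which pericellular means are computed;
#'   `NULL` means every channel.
#' @return An object of class `imc_config`.
#' @export
imc_config <- function(hot_pixel_threshold = 50,
                       tissue_channels = NULL,
                       radius_um = 10,
                       min_valid_fraction = 0.1,
                       high_strategy = c("quantile", "fixed_value",
                                         "manual_threshold"),
                       high_param = 0.8,
                       epithelial_channel = "ECAD",
                       epithelial_threshold = NULL,
                       ki67_threshold = 0.5,
                       ecm_channels = NULL) {
  check_scalar(hot_pixel_threshold, "hot_pixel_threshold", 0)
  check_scalar(radius_um, "radius_um", 0, closed_lower = FALSE)
  check_scalar(min_valid_fraction, "min_valid_fraction", 0, 1,
               closed_lower = FALSE)
  structure(list(
    hot_pixel_threshold = hot_pixel_threshold,
    tissue_channels = tissue_channels,
    radius_um = radius_um,
    min_valid_fraction = min_valid_fraction,
    high_strategy = match.arg(high_strategy),
    high_param = high_param,
    epithelial_channel = epithelial_channel,
    epithelial_threshold = epithelial_threshold,
    ki67_threshold = ki67_threshold,
    ecm_channels = ecm_channels
  ), class = "imc_config")
}

# max over the 8-neighbourhood of each pixel (centre excluded),
# computed by shifting the matrix in the 8 directions.
neighbour_max <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  out <- matrix(-Inf, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- pmax(out, pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)])
  }
  out
}

#' Remove hot pixels from a multiplexed image
#'
#' A pixel whose value exceeds the maximum of its 8 neighbours by more than
#' `threshold` is replaced by that neighbourhood maximum; all other pixels are
#' left unchanged. Applied independently per channel. The operation is
#' idempotent on its own output.
#'
#' @param image A `multiplex_image` (or plain matrix).
#' @param threshold Nonnegative replacement threshold (default 50, matching
#'   the convention for raw-count multiplexed data).
#' @return Same type as `image`, filtered.
#' @export
filter_hot_pixels <- function(image, threshold = 50) {
  check_scalar(threshold, "threshold", 0)
  filt <- function(m) {
    if (length(m) == 0) abort("Empty image.")
    nm <- neighbour_max(m)
    hot <- (m - nm) > threshold
    m[hot] <- nm[hot]
    m
  }
  if (is.matrix(image)) return(filt(image))
  stopifnot(inherits(image, "multiplex_image"))
  ch <- image$channels
  for (ci in seq_len(dim(ch)[3])) ch[, , ci] <- filt(ch[, , ci])
  new_multiplex_image(ch, image$pixel_size_um)
}

#' Min-max normalize each channel to `[0, 1]`
#'
#' Per channel, `x -> (x - min) / (max - min)`. Constant channels map to all
#' zeros. Idempotent on non-constant channels.
#'
#' @param image A `multiplex_image`.
#' @return A `multiplex_image` with all channels in `[0, 1]`.
#' @export
normalize_channels <- function(image) {
  stopifnot(inherits(image, "multiplex_image"))
  ch <- image$channels
  for (ci in seq_len(dim(ch)[3])) {
    m <- ch[, , ci]
    rng <- range(m)
    ch[, , ci] <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else 0 * m
  }
  new_multiplex_image(ch, image$pixel_size_um)
}

#' Classify pixels into tissue and void
#'
#' Sums the (normalized) tissue channels, applies Otsu thresholding on the
#' rescaled sum, and closes small gaps morphologically. Pixels covered by a
#' cell label are always tissue. An all-zero image is returned as 100% void.
#'
#' @param image A `multiplex_image`, normally after [filter_hot_pixels()] and
#'   [normalize_channels()].
#' @param config An [imc_config()].
#' @param labels Optional integer label mask; labelled pixels are forced to
#'   tissue.
#' @param closing_size Diameter (pixels) of the disc brush used for
#'   morphological closing.
#' @return A logical `H x W` void mask (`TRUE` = void).
#' @export
compute_tissue_mask <- function(image, config = imc_config(), labels = NULL,
                                closing_size = 5) {
  stopifnot(inherits(image, "multiplex_image"))
  ch_names <- dimnames(image$channels)[[3]]
  use <- config$tissue_channels %||% ch_names
  missing_ch <- setdiff(use, ch_names)
  if (length(missing_ch) > 0) {
    abort(paste0("Unknown tissue channel(s): ", paste(missing_ch, collapse = ", ")))
  }
  s <- apply(image$channels[, , use, drop = FALSE], c(1, 2), sum)
  if (max(s) <= 0) {
    void <- matrix(TRUE, nrow(s), ncol(s))
  } else {
    # clip at an upper quantile so the small, very bright cell mode cannot
    # dominate the between-class variance; the threshold then separates
    # signal-free void from tissue background
    s <- pmin(s, quantile(s, 0.9))
    s01 <- s / max(s)
    thr <- EBImage::otsu(EBImage::Image(s01), range = c(0, 1))
    tissue <- s01 > thr
    brush <- EBImage::makeBrush(closing_size, shape = "disc")
    tissue <- EBImage::closing(EBImage::Image(tissue * 1), brush) > 0.5
    void <- !matrix(as.logical(tissue), nrow(s), ncol(s))
  }
  if (!is.null(labels)) void[labels > 0] <- FALSE
  void
}
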