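#' Specification for a synthetic oriented-fibre image
#'
#' Describes a grayscale image built from sinusoidal gratings emulating
#' birefringent collagen fibres. With `dispersion = 0` a single grating at
#' `dominant_angle_deg` gives a strictly periodic, perfectly aligned
#' texture; with `dispersion > 0` the image is an average of `n_waves`
#' gratings whose orientations are drawn from a normal distribution of that
#' angular SD (radians), lowering the downstream coherency. Setting
#' `amplitude = 0` with `noise_sd > 0` yields pure white noise.
#'
#' @param image_size_px Integer pair, image height and width.
#' @param dominant_angle_deg Fibre direction in degrees, `[0, 180)`,
#'   measured from the image row axis.
#' @param dispersion Angular spread (SD, radians) of grating orientations.
#' @param spatial_period_px Stripe period in pixels.
#' @param amplitude Grating amplitude (0 disables the oriented signal).
#' @param noise_sd SD of additive Gaussian pixel noise.
#' @param n_waves Number of gratings averaged when `dispersion > 0`.
#' @param seed Integer root seed.
#' @return An object of class `fibre_spec`.
#' @export
fibre_spec <- function(image_size_px = c(256L, 256L),
                       dominant_angle_deg = 30,
                       dispersion = 0,
                       spatial_period_px = 8,
                       amplitude = 1,
                       noise_sd = 0,
                       n_waves = 16L,
                       seed = 1L) {
  check_scalar(dominant_angle_deg, "dominant_angle_deg", 0, 180,
               closed_upper = FALSE)
  check_scalar(dispersion, "dispersion", 0)
  check_scalar(spatial_period_px, "spatial_period_px", 0, closed_lower = FALSE)
  check_scalar(amplitude, "amplitude", 0)
  check_scalar(noise_sd, "noise_sd", 0)
  check_scalar(n_waves, "n_waves", 1, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(image_size_px = as.integer(image_size_px),
                 dominant_angle_deg = dominant_angle_deg,
                 dispersion = dispersion,
                 spatial_period_px = spatial_period_px,
                 amplitude = amplitude, noise_sd = noise_sd,
                 n_waves = as.integer(n_waves), seed = as.integer(seed)),
            class = "fibre_spec")
}

#' Simulate an oriented-fibre grayscale image
#'
#' @param spec A [fibre_spec()].
#' @return A numeric `H x W` matrix.
#' @export
sim_fibre_image <- function(spec) {
  stopifnot(inherits(spec, "fibre_spec"))
  h <- spec$image_size_px[1]; w <- spec$image_size_px[2]
  # coordinates: x along columns, y along rows (pixel units)
  x <- matrix(rep(seq_len(w), each = h), h, w)
  y <- matrix(rep(seq_len(h), times = w), h, w)
  k <- 2 * pi / spec$spatial_period_px

  with_seed(spec$seed, {
    img <- matrix(0.5, h, w)
    if (spec$amplitude > 0) {
      if (spec$dispersion == 0) {
        # intensity varies along the normal to the fibre direction
        theta_n <- (spec$dominant_angle_deg + 90) * pi / 180
        img <- img + 0.5 * spec$amplitude *
          sin(k * (x * cos(theta_n) + y * sin(theta_n)))
      } else {
        angles <- spec$dominant_angle_deg * pi / 180 + pi / 2 +
          rnorm(spec$n_waves, 0, spec$dispersion)
        phases <- runif(spec$n_waves, 0, 2 * pi)
        acc <- matrix(0, h, w)
        for (i in seq_len(spec$n_waves)) {
          acc <- acc + sin(k * (x * cos(angles[i]) + y * sin(angles[i])) +
                             phases[i])
        }
        img <- img + 0.5 * spec$amplitude * acc / sqrt(spec$n_waves)
      }
    }
    if (spec$noise_sd > 0) img <- img + rnorm(length(img), sd = spec$noise_sd)
  })
  img
}

#' Structure-tensor coherency of an image region
#'
#' Computes the 2x2 structure tensor `J = [<Ix^2>, <IxIy>; <IxIy>, <Iy^2>]`
#' from centred finite-difference gradients of the Gaussian-smoothed image,
#' averaged over the region, and reports the coherency
#' `C = (lmax - lmin) / (lmax + lmin)` together with the dominant texture
#' orientation (the eigenvector of the smaller eigenvalue, i.e. along the
#' stripes), in degrees `[0, 180)` from the row axis. A zero-gradient region
#' has `C = 0` by convention and an undefined (`NA`) angle.
#'
#' Coherency is invariant to positive rescaling of the intensities.
#'
#' @param image Numeric matrix (grayscale image).
#' @param region `NULL` for the whole image, a length-4 vector
#'   `c(row0, col0, row1, col1)` (1-based, inclusive), or a data frame of
#'   such rectangles with columns `row0`, `col0`, `row1`, `col1` (any other
#'   columns, e.g. `lobule_id`, are carried through).
#' @param sigma Gaussian pre-smoothing scale in pixels.
#' @return A tibble with one row per region: `coherency`,
#'   `dominant_angle_deg`, `n_pixels` and the region bounds.
#' @export
region_coherency <- function(image, region = NULL, sigma = 2) {
  stopifnot(is.matrix(image), is.numeric(image))
  check_scalar(sigma, "sigma", 0, closed_lower = FALSE)
  h <- nrow(image); w <- ncol(image)

  sm <- as.matrix(EBImage::gblur(EBImage::Image(image), sigma = sigma))
  # centred differences; defined on the interior
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (sm[, 3:w] - sm[, 1:(w - 2)]) / 2      # along columns (x)
  gy[2:(h - 1), ] <- (sm[3:h, ] - sm[1:(h - 2), ]) / 2      # along rows (y)

  regions <- if (is.null(region)) {
    tibble::tibble(row0 = 1L, col0 = 1L, row1 = h, col1 = w)
  } else if (is.data.frame(region)) {
    tibble::as_tibble(region)
  } else {
    tibble::tibble(row0 = region[1], col0 = region[2],
                   row1 = region[3], col1 = region[4])
  }

  one <- function(r0, c0, r1, c1) {
    if (r0 < 1 || c0 < 1 || r1 > h || c1 > w || r1 < r0 || c1 < c0) {
      abort("Region outside the image.")
    }
    if ((r1 - r0 + 1) < 3 || (c1 - c0 + 1) < 3) {
      abort("Region must be at least 3 x 3 pixels.")
    }
    # restrict to pixels with defined centred differences
    ri <- max(r0, 2):min(r1, h - 1)
    ci <- max(c0, 2):min(c1, w - 1)
    jxx <- mean(gx[ri, ci]^2)
    jyy <- mean(gy[ri, ci]^2)
    jxy <- mean(gx[ri, ci] * gy[ri, ci])
    tr <- jxx + jyy
    if (tr == 0) {
      return(tibble::tibble(coherency = 0, dominant_angle_deg = NA_real_,
                            n_pixels = length(ri) * length(ci)))
    }
    coh <- sqrt((jxx - jyy)^2 + 4 * jxy^2) / tr
    # eigenvector of the larger eigenvalue is the gradient direction;
    # the texture runs perpendicular to it
    phi <- 0.5 * atan2(2 * jxy, jxx - jyy)
    angle <- (phi * 180 / pi + 90) %% 180
    tibble::tibble(coherency = coh, dominant_angle_deg = angle,
                   n_pixels = length(ri) * length(ci))
  }

  res <- purrr::pmap_dfr(
    regions[, c("row0", "col0", "row1", "col1")],
    function(row0, col0, row1, col1) one(row0, col0, row1, col1)
  )
  dplyr::bind_cols(regions, res)
}

#' Hierarchical lobule averaging of coherency scores
#'
#' Averages region coherency within each lobule, then lobule means within
#' each participant and timepoint, reproducing the two-level averaging
#' scheme used for peri-lobular collagen scoring (regions per lobule, at
#' least three lobules per participant and timepoint).
#'
#' @param results Tibble with columns `participant`, `timepoint`,
#'   `lobule_id` and a value column.
#' @param value Name of the value column (default `"coherency"`).
#' @param min_lobules Warn when a participant/timepoint has fewer lobules.
#' @return A paired tibble: `participant`, `timepoint`, `n_lobules`, `value`.
#' @export
lobule_average <- function(results, value = "coherency", min_lobules = 3) {
  stopifnot(all(c("participant", "timepoint", "lobule_id", value) %in%
                  names(results)))
  if (nrow(results) == 0) abort("Empty results table.")
  out <- results |>
    dplyr::group_by(.data$participant, .data$timepoint, .data$lobule_id) |>
    dplyr::summarise(lobule_mean = mean(.data[[value]]), .groups = "drop") |>
    dplyr::group_by(.data$participant, .data$timepoint) |>
    dplyr::summarise(n_lobules = dplyr::n(),
                     value = mean(.data$lobule_mean), .groups = "drop")
  low <- out[out$n_lobules < min_lobules, ]
  if (nrow(low) > 0) {
    warn(sprintf("%d participant/timepoint group(s) have fewer than %d lobules.",
                 nrow(low), min_lobules))
  }
  out
}

#' Paired test of coherency change between timepoints
#'
#' Convenience wrapper applying the two-sided Wilcoxon matched-pairs
#' signed-rank test ([wilcoxon_signed_rank()]) to the per-participant
#' baseline/post values produced by [lobule_average()].
#'
#' @param frame Tibble with columns `participant`, `timepoint` (levels
#'   `"baseline"` and `"post"`) and `value`.
#' @return A `paired_test` object.
#' @export
coherency_change_test <- function(frame) {
  d <- paired_differences(frame)
  wilcoxon_signed_rank(d)
}

# Post - baseline differences for participants present at both timepoints;
# unpaired participants are dropped with a warning.
paired_differences <- function(frame, value = "value") {
  stopifnot(all(c("participant", "timepoint", value) %in% names(frame)))
  wide <- frame |>
    dplyr::select(dplyr::all_of(c("participant", "timepoint", value))) |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = value)
  if (!all(c("baseline", "post") %in% names(wide))) {
    abort("`timepoint` must contain levels \"baseline\" and \"post\".")
  }
  ok <- !is.na(wide$baseline) & !is.na(wide$post)
  if (any(!ok)) {
    warn(sprintf("Dropping %d unpaired participant(s).", sum(!ok)))
  }
  setNames(wide$post[ok] - wide$baseline[ok], wide$participant[ok])
}
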