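#' Specification for a synthetic multiplexed tissue scene
#'
#' Describes a two-class multiplexed image in the style of an imaging mass
#' cytometry acquisition: disc-shaped cells of two classes (class A,
#' marker-high; class B, background), an epithelial channel positive in all
#' cells, a marker channel separating the classes, and ECM channels at a
#' constant tissue baseline with one channel multiplicatively enriched inside
#' an annulus around every class-A cell. A rectangular void region (signal-free
#' tissue gap) occupies the left of the image.
#'
#' All randomness (cell placement, Ki67 positivity, noise, hot pixels) derives
#' from `seed`, so the same spec always produces a bit-identical scene.
#'
#' @param image_size_px Integer pair, image height and width in pixels.
#' @param pixel_size_um Physical pixel size in micrometres.
#' @param n_cells_per_class Integer pair: number of class-A and class-B cells.
#' @param cell_radius_px Cell disc radius in pixels.
#' @param marker_mean_high,marker_mean_low Marker channel intensity inside
#'   class-A and class-B cells, on the normalized `[0, 1]` scale.
#' @param ecm_baseline Baseline ECM channel intensity over tissue.
#' @param ecm_enrichment_factor Multiplier (>= 1) applied to the enriched ECM
#'   channel within the class-A annulus.
#' @param enrichment_annulus_um Width of the enrichment annulus, measured from
#'   the cell boundary outwards, in micrometres.
#' @param void_fraction Fraction of the image occupied by the void region.
#' @param noise_sd Gaussian noise SD added to non-void pixels of all channels.
#' @param hot_pixel_count Number of isolated hot pixels (large positive spikes)
#'   injected per channel.
#' @param channels Channel names to emit; the first four are cellular, the
#'   remainder are ECM channels.
#' @param ecm_enriched_channel Which ECM channel carries the enrichment.
#' @param ki67_prob_high,ki67_prob_low Probability that a class-A / class-B
#'   cell is Ki67-positive.
#' @param seed Integer root seed.
#'
#' @return An object of class `scene_spec`.
#' @seealso [sim_multiplex_scene()]
#' @export
scene_spec <- function(image_size_px = c(256L, 256L),
                       pixel_size_um = 1,
                       n_cells_per_class = c(8L, 8L),
                       cell_radius_px = 4L,
                       marker_mean_high = 0.8,
                       marker_mean_low = 0.1,
                       ecm_baseline = 0.2,
                       ecm_enrichment_factor = 2,
                       enrichment_annulus_um = 12,
                       void_fraction = 0.25,
                       noise_sd = 0.02,
                       hot_pixel_count = 0L,
                       channels = c("DNA", "ECAD", "SOX9", "KI67",
                                    "COL6", "COL1", "FN1"),
                       ecm_enriched_channel = "COL6",
                       ki67_prob_high = 0.6,
                       ki67_prob_low = 0.15,
                       seed = 1L) {
  stopifnot(length(image_size_px) == 2L, length(n_cells_per_class) == 2L)
  check_scalar(image_size_px[1], "image_size_px[1]", 16, integer = TRUE)
  check_scalar(image_size_px[2], "image_size_px[2]", 16, integer = TRUE)
  check_scalar(pixel_size_um, "pixel_size_um", 0, closed_lower = FALSE)
  check_scalar(n_cells_per_class[1], "n_cells_per_class[1]", 0, integer = TRUE)
  check_scalar(n_cells_per_class[2], "n_cells_per_class[2]", 0, integer = TRUE)
  check_scalar(cell_radius_px, "cell_radius_px", 1, integer = TRUE)
  check_scalar(marker_mean_high, "marker_mean_high", 0, 1)
  check_scalar(marker_mean_low, "marker_mean_low", 0, 1)
  check_scalar(ecm_baseline, "ecm_baseline", 0)
  check_scalar(ecm_enrichment_factor, "ecm_enrichment_factor", 1)
  check_scalar(enrichment_annulus_um, "enrichment_annulus_um", 0,
               closed_lower = FALSE)
  check_scalar(void_fraction, "void_fraction", 0, 1, closed_upper = FALSE)
  check_scalar(noise_sd, "noise_sd", 0)
  check_scalar(hot_pixel_count, "hot_pixel_count", 0, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  if (!ecm_enriched_channel %in% channels) {
    abort("`ecm_enriched_channel` must be one of `channels`.")
  }
  structure(list(
    image_size_px = as.integer(image_size_px),
    pixel_size_um = pixel_size_um,
    n_cells_per_class = as.integer(n_cells_per_class),
    cell_radius_px = as.integer(cell_radius_px),
    marker_mean_high = marker_mean_high,
    marker_mean_low = marker_mean_low,
    ecm_baseline = ecm_baseline,
    ecm_enrichment_factor = ecm_enrichment_factor,
    enrichment_annulus_um = enrichment_annulus_um,
    void_fraction = void_fraction,
    noise_sd = noise_sd,
    hot_pixel_count = as.integer(hot_pixel_count),
    channels = channels,
    ecm_enriched_channel = ecm_enriched_channel,
    ki67_prob_high = ki67_prob_high,
    ki67_prob_low = ki67_prob_low,
    seed = as.integer(seed)
  ), class = "scene_spec")
}

#' Simulate a multiplexed tissue scene with known ground truth
#'
#' Generates a multichannel image, a 16-bit style cell label mask, a void
#' mask and a ground-truth cell table from a [scene_spec()]. Cells are placed
#' by seeded rejection sampling with a minimum centre separation of
#' `2 * (cell_radius_px + annulus_px)`, which guarantees (i) no mask overlap
#' and (ii) that a class-B pericellular disc of radius up to the annulus width
#' can never intersect a class-A enrichment annulus, so the expected
#' pericellular means are closed-form: `ecm_baseline * factor` for class A and
#' `ecm_baseline` for class B (before noise).
#'
#' Void pixels carry exactly zero signal in every channel, including after
#' noise injection.
#'
#' @param spec A [scene_spec()].
#' @return An object of class `multiplex_scene`: a list with elements
#'   `image` (a `multiplex_image`: `channels` array `H x W x C` plus
#'   `pixel_size_um`), `labels` (integer `H x W` mask, 0 = background),
#'   `void` (logical `H x W`), and `cells` (tibble of ground truth: `label`,
#'   `class`, `row`, `col`, `ki67_pos`).
#' @examples
#' sc <- sim_multiplex_scene(scene_spec(n_cells_per_class = c(3, 3), seed = 7))
#' dim(sc$image$channels)
#' sc$cells
#' @export
sim_multiplex_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$image_size_px[1]
  w <- spec$image_size_px[2]
  r_cell <- spec$cell_radius_px
  annulus_px <- spec$enrichment_annulus_um / spec$pixel_size_um
  n_a <- spec$n_cells_per_class[1]
  n_b <- spec$n_cells_per_class[2]
  n_cells <- n_a + n_b

  void_cols <- round(spec$void_fraction * w)
  void <- matrix(FALSE, h, w)
  if (void_cols > 0) void[, seq_len(void_cols)] <- TRUE

  margin <- ceiling(r_cell + annulus_px)
  row_range <- c(margin + 1L, h - margin)
  col_range <- c(void_cols + margin + 1L, w - margin)
  if (row_range[2] < row_range[1] || col_range[2] < col_range[1]) {
    abort("Infeasible packing: image too small for the requested cells.")
  }
  sep_min2 <- (2 * (r_cell + annulus_px))^2

  with_seed(spec$seed, {
    # -- cell placement by rejection sampling ------------------------------
    centres <- matrix(NA_real_, n_cells, 2)
    placed <- 0L
    tries <- 0L
    max_tries <- 2000L * max(n_cells, 1L)
    while (placed < n_cells) {
      tries <- tries + 1L
      if (tries > max_tries) {
        abort("Infeasible packing: could not place all cells without overlap.")
      }
      cand <- c(
        sample(seq(row_range[1], row_range[2]), 1L),
        sample(seq(col_range[1], col_range[2]), 1L)
      )
      if (placed > 0L) {
        d2 <- (centres[seq_len(placed), 1] - cand[1])^2 +
          (centres[seq_len(placed), 2] - cand[2])^2
        if (any(d2 < sep_min2)) next
      }
      placed <- placed + 1L
      centres[placed, ] <- cand
    }

    classes <- rep(c("A", "B"), c(n_a, n_b))
    ki67_pos <- runif(n_cells) < ifelse(classes == "A",
                                        spec$ki67_prob_high,
                                        spec$ki67_prob_low)

    # -- label mask and enrichment annulus ---------------------------------
    labels <- matrix(0L, h, w)
    enriched <- matrix(FALSE, h, w)
    cell_off <- disc_offsets(r_cell)
    ann_off <- disc_offsets(r_cell + annulus_px)
    for (k in seq_len(n_cells)) {
      rr <- centres[k, 1] + cell_off[, 1]
      cc <- centres[k, 2] + cell_off[, 2]
      labels[cbind(rr, cc)] <- k
      if (classes[k] == "A") {
        ra <- centres[k, 1] + ann_off[, 1]
        ca <- centres[k, 2] + ann_off[, 2]
        keep <- ra >= 1 & ra <= h & ca >= 1 & ca <= w
        enriched[cbind(ra[keep], ca[keep])] <- TRUE
      }
    }
    cell_mask <- labels > 0L

    # -- channels ----------------------------------------------------------
    nchan <- length(spec$channels)
    img <- array(0, dim = c(h, w, nchan),
                 dimnames = list(NULL, NULL, spec$channels))
    tissue <- !void
    ecm_channels <- setdiff(spec$channels, c("DNA", "ECAD", "SOX9", "KI67"))
    for (ch in spec$channels) {
      plane <- matrix(0, h, w)
      if (ch == "DNA") {
        plane[tissue] <- 0.02
        plane[cell_mask] <- 0.9
      } else if (ch == "ECAD") {
        plane[cell_mask] <- 0.8
      } else if (ch == "SOX9") {
        for (k in seq_len(n_cells)) {
          v <- if (classes[k] == "A") spec$marker_mean_high else spec$marker_mean_low
          plane[labels == k] <- v
        }
      } else if (ch == "KI67") {
        for (k in which(ki67_pos)) plane[labels == k] <- 0.8
      } else if (ch %in% ecm_channels) {
        plane[tissue] <- spec$ecm_baseline
        if (ch == spec$ecm_enriched_channel) {
          amp <- enriched & tissue & !cell_mask
          plane[amp] <- spec$ecm_baseline * spec$ecm_enrichment_factor
        }
      }
      img[, , ch] <- plane
    }

    # -- noise (void stays exactly zero) -----------------------------------
    if (spec$noise_sd > 0) {
      noise <- array(rnorm(length(img), sd = spec$noise_sd), dim = dim(img))
      img <- img + noise
      img[img < 0] <- 0
      img[array(rep(void, nchan), dim = dim(img))] <- 0
    }

    # -- hot pixels: isolated large spikes on tissue -----------------------
    if (spec$hot_pixel_count > 0) {
      tissue_idx <- which(tissue)
      for (ci in seq_len(nchan)) {
        pos <- sample(tissue_idx, spec$hot_pixel_count)
        plane <- img[, , ci]
        plane[pos] <- plane[pos] + 100
        img[, , ci] <- plane
      }
    }

    cells <- tibble::tibble(
      label = seq_len(n_cells),
      class = classes,
      row = centres[, 1],
      col = centres[, 2],
      ki67_pos = ki67_pos
    )
  })

  structure(list(
    image = new_multiplex_image(img, spec$pixel_size_um),
    labels = labels,
    void = void,
    cells = cells,
    spec = spec
  ), class = "multiplex_scene")
}

new_multiplex_image <- function(channels, pixel_size_um = 1) {
  stopifnot(length(dim(channels)) == 3L,
            !is.null(dimnames(channels)[[3]]))
  if (any(!is.finite(channels))) abort("Image contains non-finite values.")
  structure(list(channels = channels, pixel_size_um = pixel_size_um),
            class = "multiplex_image")
}

#' @export
print.multiplex_scene <- function(x, ...) {
  d <- dim(x$image$channels)
  cat(sprintf(
    "<multiplex_scene> %d x %d px, %d channels, %d cells (%d A / %d B), %.0f%% void\n",
    d[1], d[2], d[3], nrow(x$cells), sum(x$cells$class == "A"),
    sum(x$cells$class == "B"), 100 * mean(x$void)
  ))
  invisible(x)
}

#' @export
print.multiplex_image <- function(x, ...) {
  d <- dim(x$channels)
  cat(sprintf("<multiplex_image> %d x %d px, %d channels (%s), %.3g um/px\n",
              d[1], d[2], d[3],
              paste(dimnames(x$channels)[[3]], collapse = ", "),
              x$pixel_size_um))
  invisible(x)
}
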