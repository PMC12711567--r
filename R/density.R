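#' Specification for a synthetic labelled breast volume
#'
#' A stack of label slices with exactly `n_fg_voxels` fibroglandular (label
#' 2) and `n_fat_voxels` fat (label 1) voxels at seeded random positions,
#' the remainder background (label 0).
#'
#' @param n_slices Number of slices.
#' @param slice_size_px Integer pair, slice height and width.
#' @param n_fg_voxels,n_fat_voxels Exact voxel counts; their sum must not
#'   exceed the total voxel count.
#' @param seed Integer root seed.
#' @return An object of class `volume_spec`.
#' @export
volume_spec <- function(n_slices = 10L, slice_size_px = c(32L, 32L),
                        n_fg_voxels = 300L, n_fat_voxels = 700L, seed = 1L) {
  check_scalar(n_slices, "n_slices", 1, integer = TRUE)
  check_scalar(n_fg_voxels, "n_fg_voxels", 0, integer = TRUE)
  check_scalar(n_fat_voxels, "n_fat_voxels", 0, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  total <- n_slices * prod(slice_size_px)
  if (n_fg_voxels + n_fat_voxels > total) {
    abort("Requested tissue voxels exceed the volume size.")
  }
  structure(list(n_slices = as.integer(n_slices),
                 slice_size_px = as.integer(slice_size_px),
                 n_fg_voxels = as.integer(n_fg_voxels),
                 n_fat_voxels = as.integer(n_fat_voxels),
                 seed = as.integer(seed)),
            class = "volume_spec")
}

#' Simulate a labelled volume with exact voxel counts
#'
#' @param spec A [volume_spec()].
#' @return An integer array `H x W x n_slices` with labels 0 (background),
#'   1 (fat), 2 (fibroglandular); label counts equal the spec exactly.
#' @export
sim_label_volume <- function(spec) {
  stopifnot(inherits(spec, "volume_spec"))
  dims <- c(spec$slice_size_px, spec$n_slices)
  vol <- array(0L, dim = dims)
  with_seed(spec$seed, {
    pos <- sample(length(vol), spec$n_fg_voxels + spec$n_fat_voxels)
    vol[pos[seq_len(spec$n_fg_voxels)]] <- 2L
    if (spec$n_fat_voxels > 0) {
      vol[pos[spec$n_fg_voxels + seq_len(spec$n_fat_voxels)]] <- 1L
    }
  })
  vol
}

#' Fibroglandular volume percentage
#'
#' `FGV% = 100 * n_fibroglandular / (n_fibroglandular + n_fat)` over all
#' slices; background voxels never enter the ratio.
#'
#' @param volume Integer array/matrix of labels (0 background, 1 fat, 2
#'   fibroglandular), or a list with elements `n_fg` and `n_fat`.
#' @return FGV as a percentage in `[0, 100]`.
#' @export
compute_fgv <- function(volume) {
  if (is.list(volume) && !is.null(volume$n_fg)) {
    n_fg <- volume$n_fg; n_fat <- volume$n_fat
  } else {
    if (!all(volume %in% 0:2)) abort("Labels must be 0, 1 or 2.")
    n_fg <- sum(volume == 2L)
    n_fat <- sum(volume == 1L)
  }
  if (n_fg + n_fat == 0) {
    abort("No fibroglandular or fat voxels; FGV undefined.")
  }
  100 * n_fg / (n_fg + n_fat)
}

#' Volpara density grade from percent dense volume
#'
#' Lower-inclusive interval classification:
#' VDG1 for `0 <= PDV < 4.5`, VDG2 for `4.5 <= PDV < 7.5`, VDG3 for
#' `7.5 <= PDV < 15.5`, VDG4 for `PDV >= 15.5` (approximating BI-RADS 4th
#' edition categories A-D).
#'
#' @param pdv_percent Percent dense volume value(s) in `[0, 100]`.
#' @return Integer grade(s) 1-4.
#' @export
classify_vdg <- function(pdv_percent) {
  if (any(!is.finite(pdv_percent)) || any(pdv_percent < 0) ||
        any(pdv_percent > 100)) {
    abort("`pdv_percent` must lie in [0, 100].")
  }
  findInterval(pdv_percent, c(4.5, 7.5, 15.5)) + 1L
}

#' Paired test of fibroglandular volume change
#'
#' Wilcoxon matched-pairs signed-rank test on per-participant FGV values at
#' baseline and post-treatment. Unpaired participants are dropped with a
#' warning.
#'
#' @param frame Tibble with columns `participant`, `timepoint` (`"baseline"`
#'   / `"post"`) and `value` (FGV percent).
#' @return A `paired_test` object.
#' @export
fgv_paired_change <- function(frame) {
  wilcoxon_signed_rank(paired_differences(frame))
}
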