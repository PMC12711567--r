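# Plain-file interchange: multipage TIFF images, steinbock-style panel and
# cell CSVs, force-curve CSVs with declared units.

#' Write and read multichannel images as multipage TIFF
#'
#' One page per channel, 32-bit float. The channel order is recorded in a
#' companion panel CSV (columns `channel`, `name`).
#'
#' @param image A `multiplex_image`.
#' @param path Output TIFF path.
#' @param panel_path Optional panel CSV path.
#' @return `path`, invisibly.
#' @export
write_multiplex_tiff <- function(image, path, panel_path = NULL) {
  stopifnot(inherits(image, "multiplex_image"))
  ch <- dimnames(image$channels)[[3]]
  pages <- lapply(seq_along(ch), function(i) image$channels[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  if (!is.null(panel_path)) {
    utils::write.csv(data.frame(channel = seq_along(ch), name = ch),
                     panel_path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_multiplex_tiff
#' @param panel Either a panel CSV path or a character vector of channel
#'   names, one per TIFF page.
#' @param pixel_size_um Physical pixel size to attach.
#' @export
read_multiplex_tiff <- function(path, panel, pixel_size_um = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  names_ch <- if (length(panel) == 1 && file.exists(panel)) {
    utils::read.csv(panel)$name
  } else {
    panel
  }
  if (length(pages) != length(names_ch)) {
    abort("Channel count in TIFF does not match the panel.")
  }
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)),
               dimnames = list(NULL, NULL, names_ch))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  new_multiplex_image(arr, pixel_size_um)
}

#' Write and read 16-bit label masks as TIFF
#'
#' Labels are stored as 16-bit unsigned integers (0 = background).
#'
#' @param labels Integer label matrix.
#' @param path TIFF path.
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > 65535) abort("Labels exceed the 16-bit range.")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Read AFM force curves from CSV with declared units
#'
#' Expects columns named `indentation_<unit>` and `force_<unit>` where the
#' unit suffix is one of `m`/`um`/`nm` and `n`/`un`/`nn` (case-insensitive);
#' values are converted to SI on read.
#'
#' @param path CSV path.
#' @return A tibble with columns `indentation_m`, `force_n`.
#' @export
read_force_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  nm <- tolower(names(df))
  ind <- grep("^indentation_", nm)
  frc <- grep("^force_", nm)
  if (length(ind) != 1 || length(frc) != 1) {
    abort("Expected exactly one indentation_<unit> and one force_<unit> column.")
  }
  iscale <- switch(sub("^indentation_", "", nm[ind]),
                   m = 1, um = 1e-6, nm = 1e-9,
                   abort("Unknown indentation unit."))
  fscale <- switch(sub("^force_", "", nm[frc]),
                   n = 1, un = 1e-6, nn = 1e-9,
                   abort("Unknown force unit."))
  tibble::tibble(indentation_m = df[[ind]] * iscale,
                 force_n = df[[frc]] * fscale)
}
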