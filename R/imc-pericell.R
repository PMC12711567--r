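#' Extract per-cell mean intensities from a label mask
#'
#' One row per nonzero label with the mean intensity of every channel over
#' that label's pixels, the centroid (0-based row/col pixel-centre
#' coordinates) and the pixel area.
#'
#' @param image A `multiplex_image`.
#' @param labels Integer `H x W` label mask (0 = background), same size as
#'   the image planes.
#' @return A tibble: `label`, `centroid_row`, `centroid_col`, `area_px`, and
#'   one column per channel holding the mean intensity.
#' @export
extract_cell_intensities <- function(image, labels) {
  stopifnot(inherits(image, "multiplex_image"))
  d <- dim(image$channels)
  if (!all(dim(labels) == d[1:2])) {
    abort("`labels` must match the image dimensions.")
  }
  if (any(labels < 0) || any(labels != round(labels))) {
    abort("`labels` must contain nonnegative integers.")
  }
  idx <- which(labels > 0)
  if (length(idx) == 0) {
    return(tibble::tibble(label = integer(), centroid_row = numeric(),
                          centroid_col = numeric(), area_px = integer()))
  }
  lab <- labels[idx]
  rows <- (idx - 1) %% d[1]        # 0-based row
  cols <- (idx - 1) %/% d[1]       # 0-based col
  f <- factor(lab)
  area <- as.integer(table(f))
  out <- tibble::tibble(
    label = as.integer(levels(f)),
    centroid_row = as.numeric(tapply(rows, f, mean)),
    centroid_col = as.numeric(tapply(cols, f, mean)),
    area_px = area
  )
  for (ch in dimnames(image$channels)[[3]]) {
    v <- image$channels[, , ch][idx]
    out[[ch]] <- as.numeric(tapply(v, f, mean))
  }
  out
}

#' Classify epithelial cells into marker-high and matched-count marker-low
#'
#' Cells are first gated epithelial (epithelial-channel mean above the gate
#' threshold). Among epithelial cells, `high` are those whose marker mean
#' exceeds the class threshold, chosen by the configured strategy; `low` are
#' the equal number of lowest-expressing epithelial cells. The two classes
#' are disjoint and have exactly equal counts.
#'
#' @param cells A cell table from [extract_cell_intensities()].
#' @param marker Marker channel column name (e.g. `"SOX9"`).
#' @param config An [imc_config()].
#' @return `cells` with logical `epithelial` and factor-like `marker_class`
#'   (`"high"`, `"low"`, `"unassigned"`) columns added.
#' @export
classify_marker_classes <- function(cells, marker, config = imc_config()) {
  stopifnot(is.data.frame(cells))
  if (!marker %in% names(cells)) {
    abort(sprintf("Marker channel `%s` not found in the cell table.", marker))
  }
  epi_ch <- config$epithelial_channel
  if (!epi_ch %in% names(cells)) {
    abort(sprintf("Epithelial channel `%s` not found in the cell table.", epi_ch))
  }
  epi_thr <- config$epithelial_threshold %||%
    quantile(cells[[epi_ch]], 0.5, names = FALSE)
  cells$epithelial <- cells[[epi_ch]] > epi_thr

  epi <- which(cells$epithelial)
  mk <- cells[[marker]][epi]
  thr <- switch(config$high_strategy,
    quantile = quantile(mk, config$high_param, names = FALSE),
    fixed_value = config$high_param,
    manual_threshold = config$high_param
  )
  high <- epi[mk > thr]
  k <- length(high)
  cells$marker_class <- "unassigned"
  if (k == 0) {
    warn("No marker-high cells at the chosen threshold; both classes empty.")
    return(cells)
  }
  if (2 * k > length(epi)) {
    abort("More than half of the epithelial cells are marker-high; matched-count classes would overlap.")
  }
  rest <- setdiff(epi, high)
  low <- rest[order(cells[[marker]][rest])][seq_len(k)]
  cells$marker_class[high] <- "high"
  cells$marker_class[low] <- "low"
  cells
}

#' Pericellular mean intensity within a fixed-radius disc
#'
#' For each classified cell, a disc of radius `radius_um / pixel_size_um`
#' pixels is drawn around the cell centroid (membership by pixel-centre to
#' centroid Euclidean distance). Pixels belonging to any labelled cell
#' (including the index cell, unless `include_index_cell = TRUE`) or to the
#' void mask are removed, and the mean of each requested channel over the
#' remaining pixels is recorded. Cells whose valid-pixel fraction falls below
#' `min_valid_fraction` keep `NA` means and are flagged.
#'
#' @param image A `multiplex_image`.
#' @param labels Integer cell label mask.
#' @param void_mask Logical void mask (`TRUE` = void), or `NULL` for none.
#' @param cells Cell table, normally from [classify_marker_classes()]; when a
#'   `marker_class` column is present only classified (`high`/`low`) cells
#'   are measured, otherwise all cells.
#' @param config An [imc_config()]; uses `radius_um`, `min_valid_fraction`
#'   and `ecm_channels`.
#' @param include_index_cell Keep the index cell's own pixels inside the disc
#'   (default `FALSE`: pericellular means extracellular).
#' @return `cells` with `valid_pixel_fraction`, `pericell_valid` and one
#'   `pericell_<channel>` column per requested channel.
#' @export
pericellular_intensity <- function(image, labels, void_mask, cells,
                                   config = imc_config(),
                                   include_index_cell = FALSE) {
  stopifnot(inherits(image, "multiplex_image"), is.data.frame(cells))
  d <- dim(image$channels)
  radius_px <- config$radius_um / image$pixel_size_um
  if (radius_px < 1) abort("Pericellular radius is below one pixel.")
  if (is.null(void_mask)) void_mask <- matrix(FALSE, d[1], d[2])
  channels <- config$ecm_channels %||% dimnames(image$channels)[[3]]

  measure <- if ("marker_class" %in% names(cells)) {
    which(cells$marker_class %in% c("high", "low"))
  } else {
    seq_len(nrow(cells))
  }
  off <- disc_offsets(radius_px)
  planes <- lapply(channels, function(ch) image$channels[, , ch])
  names(planes) <- channels

  cells$valid_pixel_fraction <- NA_real_
  cells$pericell_valid <- FALSE
  for (ch in channels) cells[[paste0("pericell_", ch)]] <- NA_real_

  for (i in measure) {
    # centroids are 0-based pixel centres; convert to 1-based matrix indices
    r0 <- round(cells$centroid_row[i]) + 1L
    c0 <- round(cells$centroid_col[i]) + 1L
    rr <- r0 + off[, 1]
    cc <- c0 + off[, 2]
    inside <- rr >= 1 & rr <= d[1] & cc >= 1 & cc <= d[2]
    rr <- rr[inside]; cc <- cc[inside]
    ij <- cbind(rr, cc)
    lab_here <- labels[ij]
    keep <- !void_mask[ij]
    if (include_index_cell) {
      keep <- keep & (lab_here == 0 | lab_here == cells$label[i])
    } else {
      keep <- keep & lab_here == 0
    }
    frac <- sum(keep) / length(keep)
    cells$valid_pixel_fraction[i] <- frac
    if (frac >= config$min_valid_fraction) {
      cells$pericell_valid[i] <- TRUE
      for (ch in channels) {
        cells[[paste0("pericell_", ch)]][i] <- mean(planes[[ch]][ij][keep])
      }
    }
  }
  cells
}

#' Fraction of a cell class positive for a channel
#'
#' @param cells Classified cell table.
#' @param channel Channel column name.
#' @param threshold Positivity threshold (strictly greater than).
#' @param class Which `marker_class` to evaluate (`"high"` or `"low"`).
#' @return Fraction in `[0, 1]`.
#' @export
class_positive_fraction <- function(cells, channel, threshold,
                                    class = "high") {
  stopifnot(channel %in% names(cells), "marker_class" %in% names(cells))
  members <- cells[[channel]][cells$marker_class == class]
  if (length(members) == 0) {
    abort(sprintf("Class `%s` is empty; positive fraction undefined.", class))
  }
  mean(members > threshold)
}

#' Within-subject one-way ANOVA with Sidak pairwise contrasts
#'
#' Fits a repeated-measures one-way ANOVA to one summary value per
#' participant and condition (complete blocks), and follows up with all
#' pairwise paired t-tests adjusted by the Sidak formula
#' `p_adj = 1 - (1 - p)^m`.
#'
#' The F statistic uses the within-subject error term, obtained from the
#' additive two-way decomposition `value ~ condition + participant`
#' (equivalent to the classical repeated-measures partition when each
#' participant contributes one value per condition).
#'
#' @param frame Long tibble with columns `participant`, `condition`, `value`.
#' @return An object of class `rm_anova` with elements `anova` (tibble:
#'   `term`, `df`, `sumsq`, `meansq`, `statistic`, `p_value`) and
#'   `contrasts` (tibble of pairwise comparisons with `p_value` and
#'   `p_sidak`). Participants with incomplete condition blocks are dropped
#'   with a warning; fewer than 3 complete participants is an error.
#' @export
compare_classes <- function(frame) {
  stopifnot(all(c("participant", "condition", "value") %in% names(frame)))
  frame <- dplyr::select(tibble::as_tibble(frame),
                         "participant", "condition", "value")
  conditions <- unique(frame$condition)
  counts <- frame |>
    dplyr::count(.data$participant) |>
    dplyr::filter(.data$n == length(conditions))
  dropped <- setdiff(unique(frame$participant), counts$participant)
  if (length(dropped) > 0) {
    warn(sprintf("Dropping %d participant(s) with incomplete blocks: %s",
                 length(dropped), paste(dropped, collapse = ", ")))
    frame <- dplyr::filter(frame, .data$participant %in% counts$participant)
  }
  n_subj <- length(unique(frame$participant))
  if (n_subj < 3) abort("At least 3 participants with complete blocks are required.")

  frame$participant <- factor(frame$participant)
  frame$condition <- factor(frame$condition, levels = conditions)
  fit <- aov(value ~ condition + participant, data = frame)
  tab <- summary(fit)[[1]]
  anova_tbl <- tibble::tibble(
    term = trimws(rownames(tab)),
    df = tab[["Df"]],
    sumsq = tab[["Sum Sq"]],
    meansq = tab[["Mean Sq"]],
    statistic = tab[["F value"]],
    p_value = tab[["Pr(>F)"]]
  )

  pairs <- utils::combn(as.character(conditions), 2, simplify = FALSE)
  m <- length(pairs)
  wide <- tidyr::pivot_wider(frame, names_from = "condition",
                             values_from = "value")
  contrasts <- purrr::map_dfr(pairs, function(pr) {
    tt <- t.test(wide[[pr[1]]], wide[[pr[2]]], paired = TRUE)
    tibble::tibble(contrast = paste(pr[1], "vs", pr[2]),
                   estimate = unname(tt$estimate),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter),
                   p_value = tt$p.value)
  })
  contrasts$p_sidak <- sidak_adjust(contrasts$p_value, m)

  structure(list(anova = anova_tbl, contrasts = contrasts,
                 n_participants = n_subj,
                 n_conditions = length(conditions)),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cond <- x$anova[x$anova$term == "condition", ]
  cat(sprintf(
    "<rm_anova> F(%d, %d) = %.4g, p = %.4g (%d participants x %d conditions)\n",
    cond$df, x$anova$df[x$anova$term == "Residuals"],
    cond$statistic, cond$p_value, x$n_participants, x$n_conditions
  ))
  print(x$contrasts)
  invisible(x)
}

#' @rdname compare_classes
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @export
tidy.rm_anova <- function(x, ...) x$contrasts

#' @rdname compare_classes
#' @export
glance.rm_anova <- function(x, ...) {
  cond <- x$anova[x$anova$term == "condition", ]
  tibble::tibble(statistic = cond$statistic, p_value = cond$p_value,
                 df = cond$df,
                 df_error = x$anova$df[x$anova$term == "Residuals"],
                 n_participants = x$n_participants)
}
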