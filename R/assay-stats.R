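#' Specification for a synthetic paired pre/post assay table
#'
#' Participant-level values are `subject_effect + timepoint_mean +
#' within-subject noise`, optionally quantized to a grid to induce tied
#' paired differences.
#'
#' @param n_participants Number of participants.
#' @param baseline_mean,post_mean Population means at each timepoint.
#' @param between_subject_sd SD of the shared per-participant effect.
#' @param within_subject_sd SD of the per-measurement noise.
#' @param tie_quantization Rounding step applied to values (0 = none).
#' @param seed Integer root seed.
#' @return An object of class `assay_spec`.
#' @export
assay_spec <- function(n_participants = 20L, baseline_mean = 1,
                       post_mean = 0.7, between_subject_sd = 0.3,
                       within_subject_sd = 0.1, tie_quantization = 0,
                       seed = 1L) {
  check_scalar(n_participants, "n_participants", 2, integer = TRUE)
  check_scalar(between_subject_sd, "between_subject_sd", 0)
  check_scalar(within_subject_sd, "within_subject_sd", 0)
  check_scalar(tie_quantization, "tie_quantization", 0)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(n_participants = as.integer(n_participants),
                 baseline_mean = baseline_mean, post_mean = post_mean,
                 between_subject_sd = between_subject_sd,
                 within_subject_sd = within_subject_sd,
                 tie_quantization = tie_quantization,
                 seed = as.integer(seed)),
            class = "assay_spec")
}

#' Simulate a paired pre/post assay table
#'
#' @param spec An [assay_spec()].
#' @return A long tibble: `participant`, `timepoint` (`"baseline"`,
#'   `"post"`), `value`.
#' @export
sim_assay_table <- function(spec) {
  stopifnot(inherits(spec, "assay_spec"))
  n <- spec$n_participants
  with_seed(spec$seed, {
    subj <- rnorm(n, 0, spec$between_subject_sd)
    base <- spec$baseline_mean + subj + rnorm(n, 0, spec$within_subject_sd)
    post <- spec$post_mean + subj + rnorm(n, 0, spec$within_subject_sd)
  })
  if (spec$tie_quantization > 0) {
    q <- spec$tie_quantization
    base <- round(base / q) * q
    post <- round(post / q) * q
  }
  tibble::tibble(
    participant = rep(sprintf("P%02d", seq_len(n)), 2),
    timepoint = rep(c("baseline", "post"), each = n),
    value = c(base, post)
  )
}

#' Mammosphere-forming efficiency
#'
#' Percentage of seeded single cells that formed a mammosphere of diameter
#' at or above the threshold (inclusive, default 50 micrometres).
#'
#' @param n_cells_seeded Number of single cells seeded (> 0).
#' @param sphere_diameters_um Diameters of the observed spheres.
#' @param diameter_threshold_um Minimum qualifying diameter.
#' @return MFE as a percentage.
#' @examples
#' mfe_percent(6000, rep(60, 12))  # 0.2
#' @export
mfe_percent <- function(n_cells_seeded, sphere_diameters_um,
                        diameter_threshold_um = 50) {
  check_scalar(n_cells_seeded, "n_cells_seeded", 1, integer = TRUE)
  n_spheres <- sum(sphere_diameters_um >= diameter_threshold_um)
  100 * n_spheres / n_cells_seeded
}

#' Colony counts and lineage-type proportions
#'
#' Colonies are discrete cell clusters of at least `colony_min_cells` cells
#' (inclusive). Type proportions are percentages of the total typed colonies.
#'
#' @param cluster_sizes Integer cluster sizes (optional).
#' @param type_counts Named counts of typed colonies, e.g.
#'   `c(luminal = 3, mixed = 5, basal = 2)` (optional).
#' @param colony_min_cells Minimum cells per colony.
#' @return A list with `n_colonies` (when `cluster_sizes` given) and
#'   `proportions` (named percentages, when `type_counts` given).
#' @export
colony_metrics <- function(cluster_sizes = NULL, type_counts = NULL,
                           colony_min_cells = 50) {
  out <- list()
  if (!is.null(cluster_sizes)) {
    if (any(cluster_sizes < 0)) abort("Cluster sizes must be nonnegative.")
    out$n_colonies <- sum(cluster_sizes >= colony_min_cells)
  }
  if (!is.null(type_counts)) {
    total <- sum(type_counts)
    if (total == 0) abort("No typed colonies; proportions undefined.")
    out$proportions <- 100 * type_counts / total
  }
  out
}

#' Per-participant lobule morphometry summary
#'
#' Computes the epithelial (acinar-to-lobular) area fraction and mean acinus
#' area per lobule, then averages over lobules within each participant and
#' timepoint. Follows the convention of averaging at least `min_lobules`
#' lobules; fewer triggers a warning. Lobules with nonpositive area are
#' rejected.
#'
#' @param lobules Tibble with columns `participant`, `timepoint`,
#'   `lobule_area`, `epithelial_area` and optionally `acinus_areas` (a
#'   list-column of per-acinus areas).
#' @param min_lobules Minimum lobules per participant/timepoint.
#' @return Tibble: `participant`, `timepoint`, `n_lobules`,
#'   `epithelial_fraction`, and `mean_acinus_area` when available.
#' @export
morphometry_summary <- function(lobules, min_lobules = 3) {
  stopifnot(all(c("participant", "timepoint", "lobule_area",
                  "epithelial_area") %in% names(lobules)))
  bad <- lobules$lobule_area <= 0
  if (any(bad)) {
    warn(sprintf("Rejecting %d lobule(s) with nonpositive area.", sum(bad)))
    lobules <- lobules[!bad, ]
  }
  if (any(lobules$epithelial_area > lobules$lobule_area)) {
    abort("Epithelial area exceeds lobule area.")
  }
  lobules$epithelial_fraction <-
    lobules$epithelial_area / lobules$lobule_area
  has_acini <- "acinus_areas" %in% names(lobules)
  if (has_acini) {
    lobules$mean_acinus_area <-
      purrr::map_dbl(lobules$acinus_areas, ~ mean(.x))
  }
  out <- lobules |>
    dplyr::group_by(.data$participant, .data$timepoint) |>
    dplyr::summarise(
      n_lobules = dplyr::n(),
      epithelial_fraction = mean(.data$epithelial_fraction),
      mean_acinus_area = if (has_acini) mean(.data$mean_acinus_area) else NA_real_,
      .groups = "drop"
    )
  if (any(out$n_lobules < min_lobules)) {
    warn(sprintf("%d participant/timepoint group(s) have fewer than %d lobules.",
                 sum(out$n_lobules < min_lobules), min_lobules))
  }
  out
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Zero differences are dropped (Wilcoxon's original rule). When the
#' absolute differences carry no ties and `n <= exact_max`, a two-sided
#' exact p-value is computed from the signed-rank distribution; otherwise a
#' normal approximation with the tie-corrected variance
#' `n(n+1)(2n+1)/24 - sum(t^3 - t)/48` is used (no continuity correction).
#' The statistic is `W`, the sum of positive ranks.
#'
#' @param x Paired differences, or the first member of each pair when `y`
#'   is supplied.
#' @param y Optional second member; differences are `x - y`.
#' @param exact_max Largest `n` for which the exact distribution is used.
#' @return An object of class `paired_test` with fields `statistic`,
#'   `p_value`, `method` (`"exact"` or `"tie_corrected_normal"`) and
#'   `n_effective` (non-zero differences).
#' @examples
#' wilcoxon_signed_rank(c(1.2, 0.8, 2.1, 0.4, 1.7, 0.9))  # p = 0.03125
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) abort("All paired differences are zero; test undefined.")
  if (n < 2) abort("At least 2 non-zero differences are required.")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= exact_max) {
    # W ranges over 0..n(n+1)/2 with the symmetric signed-rank distribution
    p_lo <- psignrank(w, n)
    p_hi <- 1 - psignrank(w - 1, n)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    tie_tab <- table(r)
    mu <- n * (n + 1) / 4
    v <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    if (v <= 0) abort("Zero variance under ties; test undefined.")
    z <- (w - mu) / sqrt(v)
    p <- 2 * pnorm(-abs(z))
    method <- "tie_corrected_normal"
  }
  structure(list(statistic = w, p_value = p, method = method,
                 n_effective = n),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("<paired_test> W = %g, p = %.5g (%s, n = %d)\n",
              x$statistic, x$p_value, x$method, x$n_effective))
  invisible(x)
}

#' @rdname wilcoxon_signed_rank
#' @param ... Unused.
#' @export
tidy.paired_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 method = x$method, n_effective = x$n_effective)
}

#' @rdname wilcoxon_signed_rank
#' @export
glance.paired_test <- function(x, ...) tidy(x)

#' Sidak adjustment for multiple comparisons
#'
#' `p_adj = 1 - (1 - p)^m`, clipped to `[0, 1]`; monotone and never below
#' the raw p-value.
#'
#' @param p Raw p-values in `[0, 1]`.
#' @param m Number of comparisons (defaults to `length(p)`).
#' @return Adjusted p-values.
#' @examples
#' sidak_adjust(0.01, 3)  # 0.029701
#' @export
sidak_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  pmin(1, pmax(0, 1 - (1 - p)^m))
}

#' Paired correlation between two measurements
#'
#' Product-moment (Pearson) or rank (Spearman) correlation with a two-sided
#' p-value.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return A tibble: `r`, `p_value`, `n`, `method`.
#' @export
paired_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("At least 3 complete pairs are required.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero variance; correlation undefined.")
  ct <- suppressWarnings(cor.test(x, y, method = method))
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x), method = method)
}

#' Reported category percentage with explicit rounding
#'
#' `100 * k / n` rounded half-away-from-zero to one decimal place or to an
#' integer, matching the convention used for reported percentages.
#'
#' @param k Number of members in the category, or a logical vector (then
#'   `k = sum(x)`, `n = length(x)`).
#' @param n Total count (ignored when `k` is logical).
#' @param rounding `"one_decimal"` or `"integer"`.
#' @return The rounded percentage.
#' @examples
#' category_fraction(27, 65)                        # 41.5
#' category_fraction(1373, 1519, "integer")         # 90
#' @export
category_fraction <- function(k, n = NULL,
                              rounding = c("one_decimal", "integer")) {
  rounding <- match.arg(rounding)
  if (is.logical(k)) {
    n <- length(k)
    k <- sum(k)
  }
  if (is.null(n) || n <= 0) abort("`n` must be positive.")
  if (k < 0 || k > n) abort("`k` must lie in [0, n].")
  pct <- 100 * k / n
  round_half_away(pct, digits = if (rounding == "one_decimal") 1 else 0)
}
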