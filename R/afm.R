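#' Hertz contact force for a spherical indenter
#'
#' Forward model for the force exerted by a rigid sphere of radius `R`
#' indenting an elastic half-space to depth `delta`, in the reduced-modulus
#' convention (no Poisson-ratio assumption):
#' `F = (4/3) * E_r * sqrt(R) * delta^(3/2)`.
#'
#' @param delta_m Indentation depth(s) in metres, nonnegative.
#' @param e_r_pa Reduced elastic modulus in pascals, nonnegative.
#' @param r_m Probe radius in metres, positive.
#' @return Force in newtons, same length as `delta_m`.
#' @examples
#' hertz_force(50e-9, 5000, 2.5e-6)  # ~1.18e-10 N
#' @export
hertz_force <- function(delta_m, e_r_pa, r_m) {
  if (any(!is.finite(delta_m)) || any(delta_m < 0)) {
    abort("`delta_m` must be finite and nonnegative.")
  }
  check_scalar(e_r_pa, "e_r_pa", 0)
  check_scalar(r_m, "r_m", 0, closed_lower = FALSE)
  (4 / 3) * e_r_pa * sqrt(r_m) * delta_m^1.5
}

# Fit one curve; returns a one-row list of fit fields.
fit_hertz_one <- function(delta, force, probe_radius_m,
                          window = c(0.25, 0.75)) {
  n <- length(delta)
  out <- list(modulus_pa = NA_real_, contact_offset_m = NA_real_,
              r_squared = NA_real_, n_window = 0L, qc_status = "fail_fit")
  if (n < 4 || max(force) <= 0) return(out)

  # windows are located on a lightly smoothed force trace so that per-sample
  # noise cannot select points by their own noise realization (which would
  # bias the contact-point estimate)
  k <- min(7L, n)
  fs <- as.numeric(stats::filter(force, rep(1 / k, k)))
  fs[is.na(fs)] <- force[is.na(fs)]
  if (max(fs) <= 0) return(out)

  # nondimensionalize: delta in units of its span, force in units of the
  # smoothed maximum (keeps the least-squares gradient well conditioned)
  d_scale <- max(delta) - min(delta)
  if (d_scale <= 0) return(out)
  f_scale <- max(fs)
  u <- (delta - min(delta)) / d_scale
  g <- force / f_scale

  # stage 1: full-curve fit of amplitude, contact offset and force baseline;
  # using every sample (no force-based point selection) avoids selection
  # bias and pins the baseline from any pre-contact segment.
  # initialization from the linearized model: F^(2/3) is linear in delta
  # with slope ((4/3) E sqrt(R))^(2/3), fitted over the upper curve.
  hi <- which(fs >= 0.25 * f_scale)
  y <- pmax(g[hi], 0)^(2 / 3)
  lin <- stats::lm.fit(cbind(1, u[hi]), y)$coefficients
  a_start <- max(lin[2], 1e-6)^1.5
  u0_start <- min(max(-lin[1] / max(lin[2], 1e-6), 0), 0.9)
  try_fit <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        g ~ a * pmax(u - u0, 0)^1.5 + b,
        start = start,
        lower = c(a = 0, u0 = -1, b = -Inf),
        upper = c(a = Inf, u0 = 1, b = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }
  fit <- try_fit(list(a = a_start, u0 = u0_start, b = 0))
  if (is.null(fit)) {
    # a start lying exactly on the solution trips the singular-gradient
    # check during model construction; retry from a fixed offset start
    fit <- try_fit(list(a = a_start * 1.2 + 0.1,
                        u0 = min(u0_start + 0.05, 0.9), b = 0.01))
  }
  if (is.null(fit)) return(out)
  p <- coef(fit)
  baseline <- p[["b"]] * f_scale
  d0 <- min(delta) + p[["u0"]] * d_scale

  # stage 2: modulus by least squares on the stated 25-75%-of-maximum force
  # window (inclusive), with offset and baseline fixed; the model is linear
  # in E_r given the contact point
  fc <- force - baseline
  fsc <- fs - baseline
  fmax <- max(fsc)
  if (fmax <= 0) return(out)
  win <- which(fsc >= window[1] * fmax & fsc <= window[2] * fmax)
  out$n_window <- length(win)
  if (length(win) < 4) return(out)
  x <- (4 / 3) * sqrt(probe_radius_m) * pmax(delta[win] - d0, 0)^1.5
  if (sum(x^2) <= 0) return(out)
  e_r <- sum(x * fc[win]) / sum(x^2)

  pred <- e_r * x
  ss_res <- sum((fc[win] - pred)^2)
  ss_tot <- sum((fc[win] - mean(fc[win]))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_

  out$modulus_pa <- e_r
  out$contact_offset_m <- d0
  out$r_squared <- r2
  out$qc_status <- "pass"
  out
}

#' Fit the spherical Hertz model to force curves
#'
#' Fitting is two-stage. Stage 1 estimates the force baseline and the
#' contact offset by nonlinear least squares of the Hertz form (plus a
#' constant) over the whole curve. Stage 2 estimates the reduced modulus by
#' least squares restricted to samples whose baseline-corrected force lies
#' in the `[25%, 75%]`-of-maximum window (inclusive, located on a lightly
#' smoothed force trace), with baseline and offset fixed. The coefficient of
#' determination is computed on the fit window. The fit is deterministic:
#' initialization comes from the linearized model (`F^(2/3)` regressed on
#' indentation).
#'
#' @param curves A `force_curve_set` from [sim_force_curves()], or a data
#'   frame with columns `indentation_m`, `force_n` and optionally `curve_id`.
#' @param probe_radius_m Probe radius in metres; taken from the set metadata
#'   when `curves` is a `force_curve_set`.
#' @param window Force-window fractions used as fitting boundary.
#' @return A tibble of class `hertz_fits`, one row per curve: `curve_id`,
#'   `modulus_pa`, `contact_offset_m`, `r_squared`, `n_window`, `qc_status`
#'   (`"pass"` or `"fail_fit"`), joined with curve metadata when available.
#' @examples
#' fc <- sim_force_curves(curve_spec(n_curves = 3))
#' fit_hertz(fc)
#' @export
fit_hertz <- function(curves, probe_radius_m = NULL, window = c(0.25, 0.75)) {
  if (inherits(curves, "force_curve_set")) {
    meta <- curves$meta
    df <- curves$curves
    radii <- setNames(meta$probe_radius_m, meta$curve_id)
  } else {
    df <- tibble::as_tibble(curves)
    if (!"curve_id" %in% names(df)) df$curve_id <- 1L
    if (is.null(probe_radius_m)) {
      abort("`probe_radius_m` is required when `curves` is a plain table.")
    }
    meta <- NULL
    radii <- NULL
  }
  stopifnot(all(c("indentation_m", "force_n") %in% names(df)))

  fits <- df |>
    dplyr::group_by(.data$curve_id) |>
    dplyr::group_modify(function(d, key) {
      r <- if (!is.null(radii)) radii[[as.character(key$curve_id)]] else probe_radius_m
      tibble::as_tibble(fit_hertz_one(d$indentation_m, d$force_n, r, window))
    }) |>
    dplyr::ungroup()
  if (!is.null(meta)) fits <- dplyr::left_join(fits, meta, by = "curve_id")
  class(fits) <- c("hertz_fits", class(fits))
  fits
}

#' Two-stage quality-control filter for Hertz fits
#'
#' Stage 1 removes fits that poorly match the Hertz model
#' (`r_squared < r2_min`, or failed fits). Stage 2 computes the mean and
#' standard deviation of the surviving moduli (within each `by` group, by
#' default per sample) and removes values lying outside
#' `mean +/- sd_mult * SD`. The boundary is inclusive: with SD = 0 identical
#' values all survive. The stages are applied strictly in this order.
#'
#' @param fits A `hertz_fits` tibble from [fit_hertz()].
#' @param r2_min Minimum coefficient of determination (default 0.95).
#' @param sd_mult Standard-deviation multiplier for the outlier gate.
#' @param by Character vector of grouping columns for the stage-2 trim;
#'   defaults to `"sample_id"` when present, otherwise the whole set.
#' @return The full tibble with `qc_status` updated to one of `"pass"`,
#'   `"fail_fit"`, `"fail_r2"`, `"fail_outlier"`. Filter on
#'   `qc_status == "pass"` for the surviving population.
#' @export
qc_filter <- function(fits, r2_min = 0.95, sd_mult = 2, by = NULL) {
  stopifnot(is.data.frame(fits), nrow(fits) > 0)
  if (is.null(by)) by <- intersect("sample_id", names(fits))
  fits <- dplyr::mutate(fits, qc_status = dplyr::case_when(
    .data$qc_status == "fail_fit" ~ "fail_fit",
    is.na(.data$r_squared) | .data$r_squared < r2_min ~ "fail_r2",
    TRUE ~ "pass"
  ))
  trim <- function(d) {
    ok <- d$qc_status == "pass"
    if (sum(ok) > 0) {
      m <- mean(d$modulus_pa[ok])
      s <- sd(d$modulus_pa[ok])
      if (is.na(s)) s <- 0
      out <- ok & abs(d$modulus_pa - m) > sd_mult * s
      d$qc_status[out] <- "fail_outlier"
    }
    d
  }
  if (length(by) > 0) {
    fits <- fits |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::group_modify(~ trim(.x)) |>
      dplyr::ungroup()
  } else {
    fits <- trim(fits)
  }
  if (!any(fits$qc_status == "pass")) {
    warn("No fits survived quality control.")
  }
  class(fits) <- unique(c("hertz_fits", class(fits)))
  fits
}

#' Summarize surviving moduli and compare timepoints
#'
#' Aggregates QC-surviving reduced moduli per sample and timepoint and runs a
#' two-sided two-sample t-test (pooled variance by default, Welch optionally)
#' between the baseline and post-treatment populations of each sample.
#'
#' @param fits A `hertz_fits` tibble, normally after [qc_filter()]; only rows
#'   with `qc_status == "pass"` enter the comparison.
#' @param welch Use the Welch (unequal-variance) t-test instead of the pooled
#'   Student form.
#' @return A list of class `afm_comparison` with `summary` (per sample x
#'   timepoint: `n`, `mean_pa`, `sd_pa`) and `tests` (per sample: `t`, `df`,
#'   `p_value`, mean per timepoint). Samples with fewer than two surviving
#'   curves at either timepoint are skipped with a warning.
#' @export
afm_compare <- function(fits, welch = FALSE) {
  stopifnot(all(c("sample_id", "timepoint", "modulus_pa") %in% names(fits)))
  ok <- dplyr::filter(fits, .data$qc_status == "pass")
  summary <- ok |>
    dplyr::group_by(.data$sample_id, .data$timepoint) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_pa = mean(.data$modulus_pa),
                     sd_pa = sd(.data$modulus_pa), .groups = "drop")

  tests <- ok |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(d, key) {
      b <- d$modulus_pa[d$timepoint == "baseline"]
      p <- d$modulus_pa[d$timepoint == "post"]
      if (length(b) < 2 || length(p) < 2) {
        warn(sprintf("Sample %s: fewer than 2 surviving curves at a timepoint; comparison skipped.",
                     key$sample_id))
        return(tibble::tibble(t = NA_real_, df = NA_real_,
                              p_value = NA_real_,
                              mean_baseline = mean(b), mean_post = mean(p)))
      }
      tt <- t.test(p, b, var.equal = !welch)
      tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                     p_value = tt$p.value,
                     mean_baseline = mean(b), mean_post = mean(p))
    }) |>
    dplyr::ungroup()

  structure(list(summary = summary, tests = tests, welch = welch),
            class = "afm_comparison")
}

#' @export
print.afm_comparison <- function(x, ...) {
  cat("<afm_comparison>\n")
  print(x$tests)
  invisible(x)
}

#' @rdname afm_compare
#' @param x An `afm_comparison` object.
#' @param ... Unused.
#' @export
tidy.afm_comparison <- function(x, ...) x$tests

#' @rdname afm_compare
#' @export
glance.afm_comparison <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$tests),
                 n_significant = sum(x$tests$p_value < 0.05, na.rm = TRUE),
                 welch = x$welch)
}
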