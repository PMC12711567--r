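#' Specification for synthetic AFM force-indentation curves
#'
#' Describes a batch of spherical-indenter force curves generated from the
#' Hertz forward model `F = (4/3) * E_r * sqrt(R) * delta^(3/2)` with
#' additive Gaussian force noise. A fixed fraction of curves is corrupted
#' with a linear drift plus an adhesion dip, constructed so that they fail a
#' coefficient-of-determination gate on the standard 25-75% force fit window;
#' corrupted curves are flagged in the ground truth.
#'
#' @param n_curves Number of curves.
#' @param true_modulus_pa True reduced modulus in pascals; a scalar or one
#'   value per curve.
#' @param probe_radius_m Spherical probe radius in metres (default 2.5e-6,
#'   i.e. a 5 micrometre diameter colloidal probe).
#' @param max_indentation_m Maximum indentation depth in metres (default
#'   5e-8, i.e. 50 nm).
#' @param samples_per_curve Samples per curve (>= 4).
#' @param noise_sd_n Force noise SD in newtons.
#' @param corrupted_fraction Fraction of curves corrupted (in `[0, 1)`);
#'   the count is `round(corrupted_fraction * n_curves)`.
#' @param region_id,sample_id,timepoint Metadata labels attached to every
#'   curve (timepoint is conventionally `"baseline"` or `"post"`).
#' @param seed Integer root seed.
#' @return An object of class `curve_spec`.
#' @seealso [sim_force_curves()], [hertz_force()]
#' @export
curve_spec <- function(n_curves = 100L,
                       true_modulus_pa = 5000,
                       probe_radius_m = 2.5e-6,
                       max_indentation_m = 5e-8,
                       samples_per_curve = 100L,
                       noise_sd_n = 0,
                       corrupted_fraction = 0,
                       region_id = "R1",
                       sample_id = "S1",
                       timepoint = "baseline",
                       seed = 1L) {
  check_scalar(n_curves, "n_curves", 1, integer = TRUE)
  check_scalar(probe_radius_m, "probe_radius_m", 0, closed_lower = FALSE)
  check_scalar(max_indentation_m, "max_indentation_m", 0, closed_lower = FALSE)
  check_scalar(samples_per_curve, "samples_per_curve", 4, integer = TRUE)
  check_scalar(noise_sd_n, "noise_sd_n", 0)
  check_scalar(corrupted_fraction, "corrupted_fraction", 0, 1,
               closed_upper = FALSE)
  check_scalar(seed, "seed", integer = TRUE)
  if (!length(true_modulus_pa) %in% c(1L, n_curves)) {
    abort("`true_modulus_pa` must be length 1 or `n_curves`.")
  }
  if (any(true_modulus_pa <= 0)) abort("`true_modulus_pa` must be positive.")
  structure(list(
    n_curves = as.integer(n_curves),
    true_modulus_pa = rep_len(true_modulus_pa, n_curves),
    probe_radius_m = probe_radius_m,
    max_indentation_m = max_indentation_m,
    samples_per_curve = as.integer(samples_per_curve),
    noise_sd_n = noise_sd_n,
    corrupted_fraction = corrupted_fraction,
    region_id = region_id,
    sample_id = sample_id,
    timepoint = timepoint,
    seed = as.integer(seed)
  ), class = "curve_spec")
}

#' Simulate AFM force curves from the Hertz forward model
#'
#' @param spec A [curve_spec()].
#' @return A list of class `force_curve_set` with elements `curves` (long
#'   tibble: `curve_id`, `indentation_m`, `force_n`) and `meta` (one row per
#'   curve: `curve_id`, `true_modulus_pa`, `corrupt`, `probe_radius_m`,
#'   `region_id`, `sample_id`, `timepoint`).
#' @examples
#' fc <- sim_force_curves(curve_spec(n_curves = 5, noise_sd_n = 0))
#' head(fc$curves)
#' @export
sim_force_curves <- function(spec) {
  stopifnot(inherits(spec, "curve_spec"))
  n <- spec$n_curves
  delta <- seq(0, spec$max_indentation_m, length.out = spec$samples_per_curve)
  n_corrupt <- round(spec$corrupted_fraction * n)

  with_seed(spec$seed, {
    corrupt <- rep(FALSE, n)
    if (n_corrupt > 0) corrupt[sample(n, n_corrupt)] <- TRUE

    curves <- purrr::map(seq_len(n), function(k) {
      f <- hertz_force(delta, spec$true_modulus_pa[k], spec$probe_radius_m)
      if (corrupt[k]) {
        fmax <- max(f)
        # linear drift across the whole ramp plus an adhesion dip mid-curve;
        # amplitudes chosen so the 25-75% window r^2 drops below 0.9
        slope_sign <- sample(c(-1, 1), 1)
        drift <- slope_sign * 0.8 * fmax * seq(0, 1, length.out = length(f))
        dip_centre <- runif(1, 0.35, 0.65) * spec$max_indentation_m
        dip <- -0.9 * fmax *
          exp(-((delta - dip_centre) / (0.08 * spec$max_indentation_m))^2)
        f <- f + drift + dip
      }
      if (spec$noise_sd_n > 0) f <- f + rnorm(length(f), sd = spec$noise_sd_n)
      tibble::tibble(curve_id = k, indentation_m = delta, force_n = f)
    })

    meta <- tibble::tibble(
      curve_id = seq_len(n),
      true_modulus_pa = spec$true_modulus_pa,
      corrupt = corrupt,
      probe_radius_m = spec$probe_radius_m,
      region_id = spec$region_id,
      sample_id = spec$sample_id,
      timepoint = spec$timepoint
    )
  })

  structure(list(curves = dplyr::bind_rows(curves), meta = meta, spec = spec),
            class = "force_curve_set")
}

#' @export
print.force_curve_set <- function(x, ...) {
  cat(sprintf("<force_curve_set> %d curves x %d samples (%d corrupted), %s/%s\n",
              nrow(x$meta), x$spec$samples_per_curve, sum(x$meta$corrupt),
              x$spec$sample_id, x$spec$timepoint))
  invisible(x)
}

#' Combine force-curve sets
#'
#' Binds several [sim_force_curves()] outputs (for example baseline and
#' post-treatment batches) into one set, renumbering curve ids.
#'
#' @param ... `force_curve_set` objects.
#' @return A `force_curve_set`.
#' @export
bind_curve_sets <- function(...) {
  sets <- list(...)
  stopifnot(all(purrr::map_lgl(sets, inherits, "force_curve_set")))
  offset <- 0L
  curves <- list(); meta <- list()
  for (s in sets) {
    curves[[length(curves) + 1L]] <-
      dplyr::mutate(s$curves, curve_id = .data$curve_id + offset)
    meta[[length(meta) + 1L]] <-
      dplyr::mutate(s$meta, curve_id = .data$curve_id + offset)
    offset <- offset + nrow(s$meta)
  }
  structure(list(curves = dplyr::bind_rows(curves),
                 meta = dplyr::bind_rows(meta),
                 spec = purrr::map(sets, "spec")),
            class = "force_curve_set")
}
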