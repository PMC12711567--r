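# Hertz model, curve fitting, QC filtering and the paired comparison.

test_that("hertz_force evaluates the spherical contact form", {
  expect_equal(hertz_force(50e-9, 5000, 2.5e-6), 1.1785e-10,
               tolerance = 1e-4)
  expect_equal(hertz_force(c(0, 1e-8), 0, 2.5e-6), c(0, 0))
  expect_equal(hertz_force(3e-8, 8000, 2.5e-6),
               2 * hertz_force(3e-8, 4000, 2.5e-6))
  # strictly increasing in depth
  d <- seq(0, 5e-8, length.out = 20)
  expect_true(all(diff(hertz_force(d, 1000, 2.5e-6)) > 0))
  expect_error(hertz_force(-1e-9, 1000, 2.5e-6), "nonnegative")
})

test_that("noiseless curves are recovered to 0.1% with r2 ~ 1", {
  fc <- sim_force_curves(curve_spec(n_curves = 3, noise_sd_n = 0,
                                    true_modulus_pa = 5000, seed = 1))
  fits <- fit_hertz(fc)
  expect_true(all(abs(fits$modulus_pa / 5000 - 1) < 1e-3))
  expect_true(all(fits$r_squared > 0.9999))
  expect_true(all(fits$qc_status == "pass"))
})

test_that("fitting is scale-equivariant in force", {
  fc <- sim_force_curves(curve_spec(n_curves = 1, noise_sd_n = 0,
                                    true_modulus_pa = 2000, seed = 3))
  g <- fc$curves
  e1 <- fit_hertz(g, probe_radius_m = 2.5e-6)$modulus_pa
  e3 <- fit_hertz(dplyr::mutate(g, force_n = .data$force_n * 3),
                  probe_radius_m = 2.5e-6)$modulus_pa
  expect_equal(e3, 3 * e1, tolerance = 1e-9)
})

test_that("Monte-Carlo recovery is unbiased and accurate across the modulus grid", {
  for (e_true in c(1000, 5000, 20000)) {
    fmax <- hertz_force(5e-8, e_true, 2.5e-6)
    fc <- sim_force_curves(curve_spec(n_curves = 60, noise_sd_n = fmax / 20,
                                      true_modulus_pa = e_true, seed = 17))
    rel <- fit_hertz(fc)$modulus_pa / e_true - 1
    expect_lt(sqrt(mean(rel^2)), 0.05)
    expect_lt(abs(median(rel)), 0.02)
  }
})

test_that("qc_filter applies the two-stage gate exactly as stated", {
  base <- tibble::tibble(curve_id = 1:3, modulus_pa = c(5000, 5100, 5050),
                         r_squared = c(0.99, 0.94, 0.96),
                         qc_status = "pass")
  out <- qc_filter(base, r2_min = 0.95)
  expect_identical(sum(out$qc_status == "pass"), 2L)
  expect_identical(out$qc_status[out$r_squared == 0.94], "fail_r2")

  # a single extreme modulus among 99 tight ones falls to the 2-SD gate
  spread <- tibble::tibble(curve_id = 1:100,
                           modulus_pa = c(rnorm(99, 5000, 50), 50000),
                           r_squared = 0.99, qc_status = "pass")
  out2 <- qc_filter(spread)
  expect_identical(out2$qc_status[100], "fail_outlier")
  expect_true(all(out2$qc_status[1:99] == "pass"))

  # identical moduli: SD = 0, inclusive boundary keeps everything
  same <- tibble::tibble(curve_id = 1:5, modulus_pa = 5000,
                         r_squared = 0.99, qc_status = "pass")
  expect_true(all(qc_filter(same)$qc_status == "pass"))

  # nothing surviving stage 1 warns
  bad <- tibble::tibble(curve_id = 1:2, modulus_pa = c(1, 2),
                        r_squared = c(0.5, 0.6), qc_status = "pass")
  expect_warning(qc_filter(bad), "survived")
})

test_that("qc_filter equals the brute-force two-pass oracle on random instances", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    fits <- tibble::tibble(
      curve_id = seq_len(n),
      modulus_pa = rlnorm(n, log(5000), 0.5),
      r_squared = runif(n, 0.8, 1),
      qc_status = "pass"
    )
    out <- suppressWarnings(qc_filter(fits))
    expect_identical(out$qc_status == "pass",
                     oracle_qc_survivors(fits$modulus_pa, fits$r_squared))
  }
})

test_that("paired comparison reproduces the pooled t-test and detects softening", {
  set.seed(7)
  x <- rnorm(400, 4000, 600)
  y <- rnorm(400, 3500, 600)
  fits <- tibble::tibble(
    curve_id = seq_len(800),
    modulus_pa = c(x, y),
    r_squared = 0.99, qc_status = "pass",
    sample_id = "S1",
    timepoint = rep(c("baseline", "post"), each = 400)
  )
  cmp <- afm_compare(fits)
  expect_equal(cmp$tests$t, oracle_t_pooled(y, x), tolerance = 1e-10)

  # identical populations give t = 0, p = 1
  fits_same <- dplyr::mutate(fits, modulus_pa = rep(x, 2))
  cmp0 <- afm_compare(fits_same)
  expect_equal(cmp0$tests$t, 0, tolerance = 1e-12)
  expect_equal(cmp0$tests$p_value, 1, tolerance = 1e-12)

  # simulated treatment effect: negative shift recovered across seeds
  signs <- sapply(1:20, function(s) {
    b <- sim_force_curves(curve_spec(n_curves = 25, true_modulus_pa = 4000,
                                     noise_sd_n = 1.2e-12,
                                     timepoint = "baseline", seed = 2 * s))
    p <- sim_force_curves(curve_spec(n_curves = 25, true_modulus_pa = 2000,
                                     noise_sd_n = 1.2e-12,
                                     timepoint = "post", seed = 2 * s + 1))
    fits <- qc_filter(fit_hertz(bind_curve_sets(b, p)))
    cmp <- afm_compare(fits)
    sign(cmp$tests$mean_post - cmp$tests$mean_baseline)
  })
  expect_gte(mean(signs < 0), 0.95)
})

test_that("force-curve CSV units are converted on read", {
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(indentation_nm = c(0, 25, 50),
                              force_nN = c(0, 0.04, 0.12)),
                   tmp, row.names = FALSE)
  cur <- read_force_curve_csv(tmp)
  expect_equal(cur$indentation_m, c(0, 2.5e-8, 5e-8))
  expect_equal(cur$force_n, c(0, 4e-11, 1.2e-10))
  unlink(tmp)
})
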