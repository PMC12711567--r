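# Generators: determinism, ground-truth bookkeeping, and forward-model
# consistency.

test_that("scene generation is deterministic and labels match ground truth", {
  spec <- scene_spec(n_cells_per_class = c(5, 5), seed = 11)
  a <- sim_multiplex_scene(spec)
  b <- sim_multiplex_scene(spec)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$labels, b$labels)
  expect_identical(a$cells, b$cells)

  labs <- sort(unique(as.vector(a$labels)))
  expect_identical(labs, 0:10)
  expect_identical(nrow(a$cells), 10L)
  # different seed gives a different scene
  c <- sim_multiplex_scene(scene_spec(n_cells_per_class = c(5, 5), seed = 12))
  expect_false(identical(a$image$channels, c$image$channels))
})

test_that("void pixels carry zero signal and cells never overlap", {
  sc <- sim_multiplex_scene(scene_spec(seed = 4, noise_sd = 0.05))
  for (ci in seq_len(dim(sc$image$channels)[3])) {
    expect_true(all(sc$image$channels[, , ci][sc$void] == 0))
  }
  # disc masks place each pixel in at most one cell: total labelled area
  # equals n_cells * disc area
  disc_area <- nrow(mammostroma:::disc_offsets(sc$spec$cell_radius_px))
  expect_identical(sum(sc$labels > 0), nrow(sc$cells) * disc_area)
})

test_that("noiseless ECM annulus mean equals factor x baseline by pixel scan", {
  sc <- sim_multiplex_scene(scene_spec(
    noise_sd = 0, ecm_baseline = 0.2, ecm_enrichment_factor = 2,
    n_cells_per_class = c(3, 3), seed = 7
  ))
  plane <- sc$image$channels[, , "COL6"]
  radius_px <- 10
  for (i in which(sc$cells$class == "A")) {
    m <- oracle_pericell_mean(plane, sc$labels, sc$void,
                              sc$cells$row[i] - 1, sc$cells$col[i] - 1,
                              radius_px)
    expect_equal(m, 0.4, tolerance = 1e-12)
  }
  for (i in which(sc$cells$class == "B")) {
    m <- oracle_pericell_mean(plane, sc$labels, sc$void,
                              sc$cells$row[i] - 1, sc$cells$col[i] - 1,
                              radius_px)
    expect_equal(m, 0.2, tolerance = 1e-12)
  }
})

test_that("infeasible packings and invalid scene parameters error", {
  expect_error(sim_multiplex_scene(scene_spec(
    image_size_px = c(64, 64), n_cells_per_class = c(40, 40)
  )), "packing")
  expect_error(scene_spec(void_fraction = 1), "void_fraction")
  expect_error(scene_spec(ecm_enrichment_factor = 0.5), "ecm_enrichment_factor")
  expect_error(scene_spec(noise_sd = -1), "noise_sd")
})

test_that("clean force curves satisfy the Hertz forward model exactly", {
  fc <- sim_force_curves(curve_spec(n_curves = 4, noise_sd_n = 0,
                                    true_modulus_pa = 5000, seed = 2))
  for (k in 1:4) {
    g <- fc$curves[fc$curves$curve_id == k, ]
    expect_identical(g$force_n,
                     hertz_force(g$indentation_m, 5000, 2.5e-6))
  }
})

test_that("corrupted-curve counts are exact and seeds differentiate sets", {
  fc <- sim_force_curves(curve_spec(n_curves = 100, corrupted_fraction = 0.1,
                                    seed = 5))
  expect_identical(sum(fc$meta$corrupt), 10L)
  fc2 <- sim_force_curves(curve_spec(n_curves = 100, corrupted_fraction = 0.1,
                                     noise_sd_n = 1e-12, seed = 6))
  fc3 <- sim_force_curves(curve_spec(n_curves = 100, corrupted_fraction = 0.1,
                                     noise_sd_n = 1e-12, seed = 7))
  expect_false(identical(fc2$curves$force_n, fc3$curves$force_n))
  expect_error(curve_spec(samples_per_curve = 3), "samples_per_curve")
})

test_that("fibre images are reproducible and periodic at zero dispersion", {
  spec <- fibre_spec(dispersion = 0, spatial_period_px = 8, seed = 3)
  a <- sim_fibre_image(spec)
  expect_identical(a, sim_fibre_image(spec))
  # strict periodicity along the normal: shifting by one period along
  # columns for a horizontal-normal pattern reproduces the image
  spec_h <- fibre_spec(dominant_angle_deg = 90, dispersion = 0,
                       spatial_period_px = 8, seed = 1)
  img <- sim_fibre_image(spec_h)
  expect_equal(img[, 1:(ncol(img) - 8)], img[, 9:ncol(img)],
               tolerance = 1e-9)
})

test_that("label volumes carry exact voxel counts", {
  vol <- sim_label_volume(volume_spec(n_slices = 10, slice_size_px = c(10, 10),
                                      n_fg_voxels = 30, n_fat_voxels = 70,
                                      seed = 1))
  expect_identical(sum(vol == 2L), 30L)
  expect_identical(sum(vol == 1L), 70L)
  expect_identical(sum(vol == 0L), 900L)
  expect_equal(compute_fgv(vol), 30)
  # position invariance: permuting voxels leaves FGV unchanged
  perm <- array(sample(vol), dim = dim(vol))
  expect_equal(compute_fgv(perm), 30)
  expect_error(volume_spec(n_fg_voxels = 600, n_fat_voxels = 600,
                           n_slices = 10, slice_size_px = c(10, 10)),
               "exceed")
})

test_that("assay tables honour their spec", {
  # no within-subject noise and a lower post mean: all differences negative
  tbl <- sim_assay_table(assay_spec(n_participants = 12, baseline_mean = 1,
                                    post_mean = 0.6, within_subject_sd = 0,
                                    seed = 8))
  d <- paired_differences(tbl)
  expect_true(all(d < 0))
  # coarse quantization induces tied differences
  tblq <- sim_assay_table(assay_spec(n_participants = 30, baseline_mean = 1,
                                     post_mean = 0.9,
                                     between_subject_sd = 0.2,
                                     within_subject_sd = 0.2,
                                     tie_quantization = 0.5, seed = 9))
  dq <- paired_differences(tblq)
  expect_true(any(duplicated(abs(dq[dq != 0]))))
  # estimator recovery at n = 200: mean difference within 3 SE of truth
  big <- sim_assay_table(assay_spec(n_participants = 200, baseline_mean = 1,
                                    post_mean = 0.7, between_subject_sd = 0.3,
                                    within_subject_sd = 0.1, seed = 10))
  db <- paired_differences(big)
  se <- sd(db) / sqrt(length(db))
  expect_lt(abs(mean(db) - (-0.3)), 3 * se)
  # determinism
  expect_identical(tbl, sim_assay_table(assay_spec(
    n_participants = 12, baseline_mean = 1, post_mean = 0.6,
    within_subject_sd = 0, seed = 8
  )))
})
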