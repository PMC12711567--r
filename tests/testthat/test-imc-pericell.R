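# Multiplexed-image preprocessing and pericellular quantification.

make_image <- function(m, name = "CH1") {
  arr <- array(m, dim = c(nrow(m), ncol(m), 1),
               dimnames = list(NULL, NULL, name))
  mammostroma:::new_multiplex_image(arr)
}

test_that("hot-pixel filter replaces only pixels exceeding neighbours by > threshold", {
  m <- matrix(10, 3, 3); m[2, 2] <- 300
  expect_equal(filter_hot_pixels(m, 50)[2, 2], 10)
  # boundary: difference exactly at threshold is kept
  m[2, 2] <- 60
  expect_equal(filter_hot_pixels(m, 50)[2, 2], 60)
  m[2, 2] <- 61
  expect_equal(filter_hot_pixels(m, 50)[2, 2], 10)
  # uniform image unchanged; idempotence
  u <- matrix(5, 4, 4)
  expect_identical(filter_hot_pixels(u, 50), u)
  noisy <- matrix(runif(400, 0, 200), 20, 20)
  once <- filter_hot_pixels(noisy, 50)
  expect_identical(filter_hot_pixels(once, 50), once)
})

test_that("channel normalization maps to [0, 1] with the constant convention", {
  m <- matrix(c(2, 4, 6, 2), 2, 2)
  img <- make_image(m)
  nr <- normalize_channels(img)
  expect_equal(range(nr$channels), c(0, 1))
  expect_equal(sort(unique(as.vector(nr$channels))), c(0, 0.5, 1))
  # constant channel maps to zeros
  cst <- normalize_channels(make_image(matrix(3, 2, 2)))
  expect_true(all(cst$channels == 0))
  # idempotence
  expect_equal(normalize_channels(nr)$channels, nr$channels)
})

test_that("tissue mask recovers the generated void and never eats cells", {
  expect_true(all(compute_tissue_mask(make_image(matrix(0, 8, 8)))))
  sc <- sim_multiplex_scene(scene_spec(void_fraction = 0.25, noise_sd = 0,
                                       seed = 2))
  void <- compute_tissue_mask(sc$image, imc_config(), labels = sc$labels)
  expect_lt(abs(mean(void) - 0.25), 0.02)
  expect_true(all(!void[sc$labels > 0]))
})

test_that("cell intensity extraction matches constant values and conserves sums", {
  labels <- matrix(0L, 6, 6)
  labels[2:3, 2:3] <- 1L
  labels[5:6, 5:6] <- 2L
  m <- matrix(0, 6, 6); m[labels == 1] <- 0.3; m[labels == 2] <- 0.7
  cells <- extract_cell_intensities(make_image(m), labels)
  expect_equal(cells$CH1, c(0.3, 0.7))
  expect_equal(cells$area_px, c(4L, 4L))
  # conservation: sum over cells of mean*area equals the masked sum
  expect_equal(sum(cells$CH1 * cells$area_px), sum(m[labels > 0]))
  expect_error(extract_cell_intensities(make_image(m), labels[1:5, ]),
               "dimensions")
})

test_that("generated-scene cell means match a brute-force pixel loop", {
  sc <- sim_multiplex_scene(scene_spec(n_cells_per_class = c(3, 3),
                                       noise_sd = 0.05, seed = 13))
  cells <- extract_cell_intensities(sc$image, sc$labels)
  plane <- sc$image$channels[, , "SOX9"]
  for (i in seq_len(nrow(cells))) {
    expect_equal(cells$SOX9[i],
                 mean(plane[sc$labels == cells$label[i]]),
                 tolerance = 1e-12)
  }
})

test_that("marker classification yields disjoint, matched-count classes", {
  cells <- tibble::tibble(
    label = 1:5,
    ECAD = rep(1, 5),
    SOX9 = c(0.9, 0.8, 0.2, 0.1, 0.05)
  )
  cfg <- imc_config(high_strategy = "fixed_value", high_param = 0.7,
                    epithelial_threshold = 0.5)
  out <- classify_marker_classes(cells, "SOX9", cfg)
  expect_identical(out$marker_class, c("high", "high", "unassigned",
                                       "low", "low"))

  # quantile strategy: top 20% of 10 epithelial cells -> 2 high, 2 lowest low
  cells10 <- tibble::tibble(label = 1:10, ECAD = 1,
                            SOX9 = seq(0.05, 0.95, length.out = 10))
  out10 <- classify_marker_classes(cells10, "SOX9",
                                   imc_config(high_strategy = "quantile",
                                              high_param = 0.8,
                                              epithelial_threshold = 0.5))
  expect_identical(sum(out10$marker_class == "high"), 2L)
  expect_identical(which(out10$marker_class == "low"), 1:2)
  expect_identical(sum(out10$marker_class == "high"),
                   sum(out10$marker_class == "low"))

  # all below threshold: both classes empty, with a warning
  expect_warning(
    none <- classify_marker_classes(
      cells, "SOX9", imc_config(high_strategy = "fixed_value",
                                high_param = 2, epithelial_threshold = 0.5)
    ), "empty"
  )
  expect_true(all(none$marker_class == "unassigned"))

  # overlap guard: more than half marker-high errors
  expect_error(classify_marker_classes(
    cells, "SOX9", imc_config(high_strategy = "fixed_value",
                              high_param = 0.01, epithelial_threshold = 0.5)
  ), "overlap")
})

test_that("pericellular means equal the brute-force pixel-loop oracle", {
  sc <- sim_multiplex_scene(scene_spec(
    noise_sd = 0, ecm_baseline = 0.2, ecm_enrichment_factor = 2,
    n_cells_per_class = c(3, 3), seed = 5
  ))
  # fixed marker threshold: with zero noise every class-A mean ties at the
  # quantile, so the quantile strategy would select nothing
  cfg <- scene_test_config(high_strategy = "fixed_value", high_param = 0.5)
  cells <- classify_marker_classes(
    extract_cell_intensities(sc$image, sc$labels), "SOX9", cfg
  )
  out <- pericellular_intensity(sc$image, sc$labels, sc$void, cells, cfg)
  plane <- sc$image$channels[, , "COL6"]
  measured <- out[out$marker_class %in% c("high", "low"), ]
  truth <- sc$cells[match(measured$label, sc$cells$label), ]
  for (i in seq_len(nrow(measured))) {
    o <- oracle_pericell_mean(plane, sc$labels, sc$void,
                              measured$centroid_row[i],
                              measured$centroid_col[i], 10)
    expect_equal(measured$pericell_COL6[i], o, tolerance = 1e-12)
    expected <- if (truth$class[i] == "A") 0.4 else 0.2
    expect_equal(measured$pericell_COL6[i], expected, tolerance = 1e-12)
  }
})

test_that("cells in void-dominated surroundings are flagged and dropped", {
  # one labelled cell in a corner of an otherwise fully-void image
  h <- 32; w <- 32
  labels <- matrix(0L, h, w); labels[2:3, 2:3] <- 1L
  void <- matrix(TRUE, h, w); void[labels > 0] <- FALSE
  arr <- array(0.5, dim = c(h, w, 1), dimnames = list(NULL, NULL, "COL6"))
  img <- mammostroma:::new_multiplex_image(arr)
  cells <- extract_cell_intensities(img, labels)
  out <- pericellular_intensity(img, labels, void, cells,
                                imc_config(ecm_channels = "COL6"))
  expect_false(out$pericell_valid[1])
  expect_true(is.na(out$pericell_COL6[1]))
  expect_lt(out$valid_pixel_fraction[1], 0.1)
})

test_that("per-cell statistics are invariant to whole-pixel translation", {
  sc <- sim_multiplex_scene(scene_spec(n_cells_per_class = c(2, 2),
                                       noise_sd = 0.02, seed = 21))
  cfg <- scene_test_config()
  run <- function(image, labels, void) {
    cells <- classify_marker_classes(
      extract_cell_intensities(image, labels), "SOX9", cfg
    )
    pericellular_intensity(image, labels, void, cells, cfg)
  }
  base <- run(sc$image, sc$labels, sc$void)
  # translate everything down/right by 3 px, wrapping trimmed borders
  sh <- function(m, fill) {
    out <- matrix(fill, nrow(m), ncol(m))
    out[4:nrow(m), 4:ncol(m)] <- m[1:(nrow(m) - 3), 1:(ncol(m) - 3)]
    out
  }
  arr <- sc$image$channels
  arr2 <- arr
  for (ci in seq_len(dim(arr)[3])) arr2[, , ci] <- sh(arr[, , ci], 0)
  img2 <- mammostroma:::new_multiplex_image(arr2, sc$image$pixel_size_um)
  shifted <- run(img2, sh(sc$labels, 0L), sh(sc$void, TRUE))
  cols <- c("area_px", "SOX9", "COL6", "pericell_COL6",
            "valid_pixel_fraction", "marker_class")
  expect_equal(base[cols], shifted[cols], tolerance = 1e-12)
  expect_equal(shifted$centroid_row, base$centroid_row + 3)
})

test_that("class positive fractions count strict exceedances", {
  cells <- tibble::tibble(marker_class = c("high", "high", "high", "high"),
                          KI67 = c(0.9, 0.1, 0.2, 0.8))
  expect_equal(class_positive_fraction(cells, "KI67", 0.5), 0.5)
  expect_equal(class_positive_fraction(
    dplyr::mutate(cells, KI67 = 1), "KI67", 0.5
  ), 1)
  expect_error(class_positive_fraction(cells, "KI67", 0.5, class = "low"),
               "empty")
})

test_that("repeated-measures ANOVA matches the sum-of-squares oracle", {
  set.seed(42)
  n <- 8
  conds <- c("high_B", "low_B", "high_PT", "low_PT")
  effects <- c(0.4, 0.2, 0.3, 0.2)
  frame <- tidyr::expand_grid(participant = sprintf("P%d", 1:n),
                              condition = conds)
  subj <- rnorm(n, 0, 0.1)
  frame$value <- effects[match(frame$condition, conds)] +
    subj[match(frame$participant, sprintf("P%d", 1:n))] +
    rnorm(nrow(frame), 0, 0.05)
  res <- compare_classes(frame)
  f_pkg <- res$anova$statistic[res$anova$term == "condition"]
  expect_equal(f_pkg, oracle_rm_anova_f(frame), tolerance = 1e-8)
  # Sidak contrasts: all 6 pairs, adjusted by the closed form
  expect_identical(nrow(res$contrasts), 6L)
  expect_equal(res$contrasts$p_sidak,
               1 - (1 - res$contrasts$p_value)^6, tolerance = 1e-12)
  # glance/tidy accessors
  expect_identical(glance(res)$n_participants, 8L)
  expect_identical(nrow(tidy(res)), 6L)

  # incomplete blocks are dropped with a warning; too few participants error
  frame_inc <- frame[-1, ]
  expect_warning(compare_classes(frame_inc), "incomplete")
  expect_error(
    suppressWarnings(compare_classes(frame[frame$participant %in%
                                             c("P1", "P2"), ])),
    "participants"
  )
})
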