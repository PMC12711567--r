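# Independent brute-force oracles used to cross-check the package
# implementations. Each is written as plainly as possible (explicit loops,
# textbook formulas) and shares no code with the functions it checks.

# Mean of `plane` over the disc of radius `radius_px` around (row0, col0)
# (0-based pixel centres), excluding any labelled-cell and void pixels,
# by scanning every pixel of the image.
oracle_pericell_mean <- function(plane, labels, void, row0, col0, radius_px) {
  h <- nrow(plane); w <- ncol(plane)
  total <- 0; count <- 0
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      dr <- (r - 1) - row0
      dc <- (c - 1) - col0
      if (dr * dr + dc * dc <= radius_px^2 &&
            labels[r, c] == 0 && !void[r, c]) {
        total <- total + plane[r, c]
        count <- count + 1
      }
    }
  }
  if (count == 0) NA_real_ else total / count
}

# Two-pass QC filter: returns the logical survivor mask.
oracle_qc_survivors <- function(moduli, r2, r2_min = 0.95, sd_mult = 2) {
  stage1 <- !is.na(r2) & r2 >= r2_min
  if (!any(stage1)) return(rep(FALSE, length(moduli)))
  m <- mean(moduli[stage1])
  s <- stats::sd(moduli[stage1])
  if (is.na(s)) s <- 0
  stage1 & abs(moduli - m) <= sd_mult * s
}

# Structure-tensor coherency by direct double-loop accumulation over the
# region of a pre-smoothed image, eigenvalues via eigen().
oracle_region_coherency <- function(smoothed, r0, c0, r1, c1) {
  h <- nrow(smoothed); w <- ncol(smoothed)
  jxx <- 0; jyy <- 0; jxy <- 0; npx <- 0
  for (r in max(r0, 2):min(r1, h - 1)) {
    for (c in max(c0, 2):min(c1, w - 1)) {
      ix <- (smoothed[r, c + 1] - smoothed[r, c - 1]) / 2
      iy <- (smoothed[r + 1, c] - smoothed[r - 1, c]) / 2
      jxx <- jxx + ix * ix
      jyy <- jyy + iy * iy
      jxy <- jxy + ix * iy
      npx <- npx + 1
    }
  }
  J <- matrix(c(jxx, jxy, jxy, jyy) / npx, 2, 2)
  ev <- eigen(J, symmetric = TRUE)$values
  if (sum(ev) == 0) return(0)
  (ev[1] - ev[2]) / (ev[1] + ev[2])
}

# Exact two-sided signed-rank p-value by enumeration of all sign vectors.
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(1, p)
}

# Classical repeated-measures one-way ANOVA F from explicit sums of squares.
oracle_rm_anova_f <- function(frame) {
  wide <- tapply(frame$value, list(frame$participant, frame$condition), mean)
  n <- nrow(wide); k <- ncol(wide)
  grand <- mean(wide)
  ss_cond <- n * sum((colMeans(wide) - grand)^2)
  ss_subj <- k * sum((rowMeans(wide) - grand)^2)
  ss_tot <- sum((wide - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
}

# Pooled-variance two-sample t statistic from the textbook formula.
oracle_t_pooled <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

# Tie-corrected normal-approximation two-sided p for the signed-rank test.
oracle_wilcoxon_ties <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  v <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  2 * stats::pnorm(-abs((w - mu) / sqrt(v)))
}

# Default config used across scene tests (fixed epithelial gate so that the
# all-epithelial synthetic scenes are not split in half by the median rule).
scene_test_config <- function(...) {
  imc_config(epithelial_threshold = 0.4, ecm_channels = "COL6", ...)
}
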