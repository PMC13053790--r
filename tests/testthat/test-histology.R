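test_that("birefringence classification is exhaustive and exact on flats", {
  pal <- lvmech:::.palette_birefringence()
  mk <- function(col, h = 8, w = 8) array(rep(col, each = h * w), c(h, w, 3))
  cm_or <- classify_birefringence(mk(pal$orange_red))
  expect_true(all(cm_or == "orange_red"))
  cm_gy <- classify_birefringence(mk(pal$green_yellow))
  expect_true(all(cm_gy == "green_yellow"))
  cm_bg <- classify_birefringence(mk(c(0, 0, 0)))
  expect_true(all(cm_bg == "background"))
  # exactly one class per pixel by construction
  expect_true(all(cm_or %in% c("background", "green_yellow", "orange_red")))
})

test_that("class mix and maturity ratio recover generator truth", {
  sp <- fiber_image_spec(n_fibers = 400, mu = 10, kappa = 3,
                         class_mix = 0.7, seed = 42)
  g <- gen_fiber_image(sp)
  cm <- classify_birefringence(g$image)
  n_or <- sum(cm == "orange_red"); n_gy <- sum(cm == "green_yellow")
  truth_or <- sum(g$class_pixels == 1L); truth_gy <- sum(g$class_pixels == 2L)
  mix_est <- n_or / (n_or + n_gy)
  mix_truth <- truth_or / (truth_or + truth_gy)
  expect_equal(mix_est, mix_truth, tolerance = 0.02 / mix_truth)
  expect_equal(maturity_ratio(cm), truth_or / truth_gy,
               tolerance = 0.06)
  # ratio ~ 2.5 case
  sp2 <- fiber_image_spec(n_fibers = 400, class_mix = 5 / 7, seed = 9)
  g2 <- gen_fiber_image(sp2)
  truth_ratio <- sum(g2$class_pixels == 1L) / sum(g2$class_pixels == 2L)
  expect_equal(maturity_ratio(classify_birefringence(g2$image)), truth_ratio,
               tolerance = 0.1 / truth_ratio)
})

test_that("maturity ratio guards and trivial identities", {
  cm <- matrix(c("orange_red", "green_yellow"), 10, 10)
  expect_equal(maturity_ratio(cm), 1)
  cm_all_or <- matrix("orange_red", 5, 5)
  expect_error(maturity_ratio(cm_all_or), "undefined")
})

test_that("fiber orientation extraction recovers known angles", {
  # parallel fibers: circular median within 2 degrees of truth
  sp <- fiber_image_spec(size = c(256, 256), n_fibers = 60, mu = 30,
                         kappa = 1e5, length_mean = 80, noise = 0, seed = 5)
  g <- gen_fiber_image(sp)
  ang <- suppressWarnings(fiber_orientations(classify_birefringence(g$image)))
  expect_gt(length(ang), 30)
  expect_equal(axial_mean(ang), 30, tolerance = 2 / 30)
  # orientation equivariance: shifting mu shifts the recovered center
  sp2 <- fiber_image_spec(size = c(256, 256), n_fibers = 60, mu = 40,
                          kappa = 1e5, length_mean = 80, noise = 0, seed = 5)
  g2 <- gen_fiber_image(sp2)
  ang2 <- suppressWarnings(fiber_orientations(classify_birefringence(g2$image)))
  expect_equal(axial_mean(ang2) - axial_mean(ang), 10, tolerance = 0.2)
  # isotropic field: uniformity not rejected at alpha = 0.01. Segments
  # split from one fiber share its angle, so the null distribution of the
  # Pearson statistic is simulated with the same clustering (pairs).
  spu <- fiber_image_spec(size = c(448, 448), n_fibers = 150, kappa = 0,
                          length_mean = 80, seed = 13)
  gu <- gen_fiber_image(spu)
  angu <- suppressWarnings(
    fiber_orientations(classify_birefringence(gu$image), min_length = 35))
  hu <- orientation_histogram(angu, bin_width = 15)
  pearson <- function(cnt) {
    e <- sum(cnt) / length(cnt)
    sum((cnt - e)^2 / e)
  }
  set.seed(1)
  null_stats <- replicate(400, {
    a <- rep(runif(ceiling(length(angu) / 2), -90, 90),
             each = 2)[seq_along(angu)]
    pearson(orientation_histogram(a, bin_width = 15)$counts)
  })
  expect_lt(pearson(hu$counts), quantile(null_stats, 0.99))
})

test_that("orientation histogram bins 5-degree classes correctly", {
  h1 <- orientation_histogram(rep(2.5, 100))
  expect_equal(sum(h1$counts), 100)
  expect_equal(h1$counts[19], 100) # bin (0, 5]
  expect_equal(sum(h1$counts != 0), 1)
  expect_length(h1$counts, 36)
  set.seed(2)
  h2 <- orientation_histogram(runif(777, -90, 90))
  expect_equal(sum(h2$counts), 777)
  # von Mises sample mass matches analytic bin integrals
  n <- 4000; kap <- 3
  a <- gen_angle_sample(n, 0, kap, seed = 77)
  h3 <- orientation_histogram(a)
  dens <- function(th) exp(kap * cos(2 * th * pi / 180)) # unnormalized
  Z <- integrate(dens, -90, 90)$value
  for (b in c(17, 18, 19, 20, 26)) {
    pb <- integrate(dens, h3$breaks[b], h3$breaks[b + 1])$value / Z
    se <- sqrt(pb * (1 - pb) / n)
    expect_lt(abs(h3$counts[b] / n - pb), 4 * se + 1e-3)
  }
})

test_that("median-peak normalization shifts, preserves and idempotes", {
  mk <- function(peak_mid) {
    a <- c(rep(peak_mid, 50), runif(60, -90, 90))
    orientation_histogram(a)
  }
  set.seed(3)
  h0 <- mk(2.5)
  n0 <- normalize_peak(h0)
  expect_equal(n0$counts, h0$counts) # peak already at (0, 5]
  h30 <- mk(32.5)
  n30 <- normalize_peak(h30)
  expect_equal(which.max(n30$counts), 19L)
  expect_equal(sum(n30$counts), sum(h30$counts))
  expect_equal(n30$shift_deg %% 180, (180 - 30) %% 180)
  # idempotence
  expect_equal(normalize_peak(n30)$counts, n30$counts)
})

test_that("alignment fraction behaves on degenerate and uniform data", {
  all0 <- normalize_peak(orientation_histogram(rep(0.001, 120)))
  expect_equal(alignment_fraction(all0), 100)
  hu <- orientation_histogram(numeric(0))
  hu$counts <- rep(5L, 36); hu$normalized <- TRUE
  expect_equal(alignment_fraction(hu), 100 * 2 / 36)
  # concentration monotonicity through the full pipeline
  frac_k <- function(k) {
    a <- gen_angle_sample(800, 0, k, seed = 31)
    alignment_fraction(normalize_peak(orientation_histogram(a)))
  }
  expect_gt(frac_k(4), frac_k(0.5))
})

test_that("fibrosis fraction recovers trichrome truth", {
  pal <- lvmech:::.palette_trichrome()
  mk <- function(col, h = 8, w = 8) array(rep(col, each = h * w), c(h, w, 3))
  expect_equal(fibrosis_fraction(mk(pal$tissue)), 0)
  expect_equal(fibrosis_fraction(mk(pal$blue)), 100)
  expect_error(fibrosis_fraction(mk(c(1, 1, 1))), "tissue")
  tr <- gen_trichrome_image(trichrome_image_spec(fibrosis_fraction = 0.25,
                                                 seed = 7))
  expect_equal(fibrosis_fraction(tr$image), 100 * tr$truth_fraction,
               tolerance = 2 / 25)
  # translation invariance: rolling the image leaves the statistic alone
  img <- tr$image
  rolled <- img[c(41:nrow(img), 1:40), , , drop = FALSE]
  expect_equal(fibrosis_fraction(rolled), fibrosis_fraction(img))
})

test_that("pipeline statistics are deterministic and batch-averagable", {
  sp <- fiber_image_spec(size = c(192, 192), n_fibers = 150, seed = 55)
  g <- gen_fiber_image(sp)
  r1 <- suppressWarnings(analyze_fiber_image(g$image))
  r2 <- suppressWarnings(analyze_fiber_image(g$image))
  expect_identical(r1$maturity_ratio, r2$maturity_ratio)
  expect_identical(r1$histogram$counts, r2$histogram$counts)
  expect_identical(r1$alignment_percent, r2$alignment_percent)
  vals <- c(2.1, 2.5, 2.9, 3.3, 2.7)
  expect_equal(batch_mean(vals), mean(vals))
})
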