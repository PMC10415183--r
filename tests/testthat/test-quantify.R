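test_that("enrichment_sum boundary cases", {
  shape <- c(64L, 64L)
  cm <- oracle_dist(shape, c(31, 31)) <= 28
  roi <- cell_roi(cm)
  b <- blob_set(data.frame(row = c(25, 40), col = c(25, 40),
                           radius_px = c(4, 5)))
  disks <- oracle_disk_mask(b, shape)
  inside_only <- matrix(0, 64, 64); inside_only[disks] <- 7
  expect_equal(enrichment_sum(inside_only, b, roi)$enrichment_sum, 1)
  outside_only <- matrix(3, 64, 64); outside_only[disks] <- 0
  expect_equal(enrichment_sum(outside_only, b, roi)$enrichment_sum, 0)
  expect_warning(res <- enrichment_sum(matrix(0, 64, 64), b, roi), "zero")
  expect_true(is.na(res$enrichment_sum))
})

test_that("enrichment_sum recovers the generator budget at zero noise", {
  p <- scene_params(image_size = c(160L, 160L), cell_radius_px = 65,
                    nucleus_radius_px = 20, n_lds = 8L,
                    min_ld_separation_px = 18, decorator_mode = "filled",
                    on_ld_intensity_fraction = 0.4, noise_poisson = FALSE,
                    noise_gaussian_sd = 0, background_level = 0, seed = 61)
  sc <- simulate_cell(p)
  res <- enrichment_sum(sc$noiseless$decorator,
                        blob_set(sc$true_blobs), sc$roi)
  expect_equal(res$enrichment_sum, 0.4, tolerance = 0.02)
})

test_that("enrichment_mean follows the closed-form mean ratio", {
  shape <- c(80L, 80L)
  cm <- matrix(TRUE, 80, 80)
  roi <- cell_roi(cm)
  uniform <- matrix(13, 80, 80)
  ld <- matrix(FALSE, 80, 80); ld[1:640] <- TRUE     # 10% of the cell
  expect_equal(enrichment_mean(uniform, ld, roi)$enrichment_mean, 1)
  conc <- matrix(0, 80, 80); conc[ld] <- 5
  # all intensity in 10% of the area: mean ratio = A_cell / A_ld = 10
  expect_equal(enrichment_mean(conc, ld, roi)$enrichment_mean, 10)
  inv <- matrix(5, 80, 80); inv[ld] <- 0
  expect_equal(enrichment_mean(inv, ld, roi)$enrichment_mean, 0)
  expect_warning(r <- enrichment_mean(uniform, matrix(FALSE, 80, 80), roi),
                 "empty")
  expect_true(is.na(r$enrichment_mean))
})

test_that("masked_pearson agrees with the longhand formula", {
  set.seed(77)
  mask <- matrix(runif(120 * 120) < 0.7, 120, 120)
  n <- sum(mask)
  z1 <- rnorm(n); z2 <- rnorm(n)
  rho <- 0.6
  a <- matrix(0, 120, 120); b <- matrix(0, 120, 120)
  a[mask] <- 100 + 20 * z1
  b[mask] <- 50 + 10 * (rho * z1 + sqrt(1 - rho^2) * z2)
  got <- masked_pearson(a, b, mask)
  expect_equal(got$pearson_r, oracle_pearson(a[mask], b[mask]),
               tolerance = 1e-12)
  expect_equal(got$n_pixels, n)
  expect_lt(abs(got$pearson_r - rho), 0.03)
  expect_equal(masked_pearson(a, a, mask)$pearson_r, 1)
  expect_equal(masked_pearson(a, 100 - a, mask)$pearson_r, -1)
  expect_warning(r0 <- masked_pearson(a, matrix(1, 120, 120), mask),
                 "constant")
  expect_true(is.na(r0$pearson_r))
})

test_that("pearson and ratio statistics obey affine invariances", {
  set.seed(31)
  for (k in 1:20) {
    mask <- matrix(runif(40 * 40) < 0.5, 40, 40)
    if (sum(mask) < 10) next
    a <- matrix(rexp(1600, 1 / 50), 40, 40)
    b <- matrix(rexp(1600, 1 / 30), 40, 40)
    r0 <- masked_pearson(a, b, mask)$pearson_r
    s <- runif(1, 0.1, 10); off <- runif(1, 0, 100)
    expect_equal(masked_pearson(s * a + off, b, mask)$pearson_r, r0,
                 tolerance = 1e-9)
    expect_equal(masked_pearson(a, s * b + off, mask)$pearson_r, r0,
                 tolerance = 1e-9)
    expect_equal(masked_pearson(-a, b, mask)$pearson_r, -r0,
                 tolerance = 1e-9)
  }
})

test_that("enrichment statistics are intensity-scale invariant and radius-monotone", {
  sc <- simulate_cell(scene_params(image_size = c(128L, 128L),
                                   cell_radius_px = 52,
                                   nucleus_radius_px = 16, n_lds = 5L,
                                   min_ld_separation_px = 18,
                                   decorator_mode = "filled", seed = 71))
  dec <- sc$image$channels$decorator
  b <- blob_set(sc$true_blobs)
  e0 <- enrichment_sum(dec, b, sc$roi)$enrichment_sum
  for (k in c(0.5, 3, 100)) {
    expect_equal(enrichment_sum(k * dec, b, sc$roi)$enrichment_sum, e0,
                 tolerance = 1e-12)
  }
  grown <- sc$true_blobs
  grown$radius_px <- grown$radius_px + 2
  expect_gte(enrichment_sum(dec, blob_set(grown), sc$roi)$ld_intensity,
             enrichment_sum(dec, b, sc$roi)$ld_intensity)
})

test_that("peripheral_mask excludes the dilated nucleus exactly", {
  shape <- c(128L, 128L)
  cm <- matrix(TRUE, 128, 128)
  d <- oracle_dist(shape, c(63, 63))
  nm <- d <= 12
  roi <- cell_roi(cm, nm)
  pm <- peripheral_mask(roi, dilation_px = 20)
  expect_identical(unclass(pm), cm & !oracle_dilate(nm, 20))
  # away from discretization, the mask is the analytic annulus d > 32
  interior <- abs(d - 32) > 1.5
  expect_identical(unclass(pm)[interior], (d > 32)[interior])
  # empty nucleus: peripheral mask is the whole cell
  roi2 <- cell_roi(cm)
  expect_equal(mask_area(peripheral_mask(roi2, 160)), 128 * 128)
  # dilation swallowing the cell: empty mask
  small <- cell_roi(d <= 40, d <= 20)
  expect_equal(mask_area(peripheral_mask(small, 100)), 0)
})

test_that("ld_area_fraction recovers geometric coverage at high contrast", {
  # disks covering ~8% of the cell
  shape <- c(200L, 200L)
  cm <- oracle_dist(shape, c(99, 99)) <= 90
  blobs <- data.frame(row = c(60, 99, 140, 70, 130),
                      col = c(70, 150, 60, 130, 130),
                      radius_px = c(10, 11, 9, 10, 10))
  disks <- oracle_disk_mask(blobs, shape) & cm
  truth <- sum(disks) / sum(cm)
  ch <- matrix(20, 200, 200); ch[disks] <- 400
  set.seed(10)
  ch <- ch + matrix(rnorm(200 * 200, 0, 3), 200, 200)
  res <- ld_area_fraction(pmax(ch - 20, 0), cell_roi(cm))
  expect_equal(res$area_fraction, truth, tolerance = 0.01)
  expect_gt(truth, 0.06); expect_lt(truth, 0.10)
  # no signal: zero area fraction
  expect_warning(r0 <- ld_area_fraction(matrix(0, 50, 50),
                                        cell_roi(matrix(TRUE, 50, 50))))
  expect_equal(r0$area_fraction, 0)
  # self-normalization is 1
  expect_equal(res$area_fraction / res$area_fraction, 1)
})

test_that("ld_density_per_area reproduces the printed field constant", {
  # 2048^2 px at 0.066 um/px: 18,270 um^2 to the nearest integer
  area_um2 <- 1 / ld_density_per_area(1, c(2048L, 2048L), 0.066)
  expect_equal(round(area_um2), 18270)
  expect_equal(ld_density_per_area(0, c(512L, 512L), 0.1), 0)
  expect_equal(ld_density_per_area(4, c(256L, 256L), 0.1), 4 / 655.36,
               tolerance = 1e-12)
})
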