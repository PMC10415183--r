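small_params <- function(...) {
  scene_params(image_size = c(128L, 128L), cell_radius_px = 52,
               nucleus_radius_px = 16, n_lds = 6L,
               min_ld_separation_px = 16, ...)
}

test_that("same seed gives bit-identical scenes", {
  a <- simulate_cell(small_params(seed = 31))
  b <- simulate_cell(small_params(seed = 31))
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$true_blobs, b$true_blobs)
  expect_identical(a$true_mean_keima_ratio, b$true_mean_keima_ratio)
})

test_that("blob placement satisfies the stated constraints", {
  sc <- simulate_cell(scene_params(image_size = c(256L, 256L),
                                   cell_radius_px = 100,
                                   nucleus_radius_px = 30, n_lds = 12L,
                                   min_ld_separation_px = 20, seed = 8))
  tb <- sc$true_blobs
  expect_equal(nrow(tb), 12L)
  d <- as.matrix(dist(tb[, c("row", "col")]))
  expect_true(all(d[upper.tri(d)] >= 20))
  ctr <- c(127.5, 127.5)
  rho <- sqrt((tb$row - ctr[1])^2 + (tb$col - ctr[2])^2)
  expect_true(all(rho + tb$radius_px <= 100))       # inside cell
  expect_true(all(rho - tb$radius_px >= 30))        # outside nucleus
  expect_error(simulate_cell(scene_params(image_size = c(96L, 96L),
                                          cell_radius_px = 30,
                                          nucleus_radius_px = 10,
                                          n_lds = 40L,
                                          min_ld_separation_px = 20,
                                          seed = 1)),
               "infeasible")
})

test_that("zero-noise render equals the analytic model plus background", {
  p <- small_params(seed = 12, noise_poisson = FALSE, noise_gaussian_sd = 0,
                    background_level = 7)
  sc <- simulate_cell(p)
  for (nm in names(sc$noiseless))
    expect_equal(sc$image$channels[[nm]], sc$noiseless[[nm]] + 7,
                 tolerance = 1e-12)
})

test_that("geometry and budgets are noise-independent", {
  base <- small_params(seed = 23)
  noisy <- simulate_cell(base)
  quiet <- simulate_cell(small_params(seed = 23, noise_poisson = FALSE,
                                      noise_gaussian_sd = 0))
  expect_identical(noisy$true_blobs, quiet$true_blobs)
  expect_identical(noisy$intensity_budget, quiet$intensity_budget)
  expect_identical(noisy$true_mean_keima_ratio, quiet$true_mean_keima_ratio)
  expect_true(all(noisy$image$channels$ld >= 0))
})

test_that("decorator budget fraction is exact for requested fractions", {
  geom <- make_geom(blobs = data.frame(row = c(30, 60, 48), col = c(40, 40, 70),
                                       radius_px = c(4, 6, 5),
                                       label = rep("mature", 3)))
  for (f in c(0, 0.25, 0.4, 0.8, 1)) {
    for (mode in c("surface_ring", "filled")) {
      ch <- render_decorator(geom, mode = mode, on_fraction = f, total = 5e5)
      expect_equal(attr(ch, "on_ld_sum") / sum(ch), f, tolerance = 1e-6,
                   label = sprintf("mode=%s f=%g", mode, f))
      expect_equal(sum(ch), 5e5, tolerance = 1e-6)
    }
  }
  # on_fraction = 1 leaves no cytoplasmic intensity
  ch1 <- render_decorator(geom, mode = "filled", on_fraction = 1)
  outside <- geom$cell_mask & !oracle_disk_mask(geom$true_blobs, c(96, 96))
  expect_true(all(ch1[outside] == 0))
  expect_error(render_decorator(geom, mode = "blob"), "invalid")
})

test_that("surface rings anticorrelate with the LD core for every mature LD", {
  sc <- simulate_cell(small_params(seed = 41, decorator_mode = "surface_ring",
                                   noise_poisson = FALSE,
                                   noise_gaussian_sd = 0))
  tb <- sc$true_blobs
  for (i in seq_len(nrow(tb))) {
    r <- lipoquant:::patch_correlation(sc$noiseless$ld,
                                       sc$noiseless$decorator,
                                       tb$row[i], tb$col[i],
                                       max(ceiling(1.5 * tb$radius_px[i]), 3))
    expect_lt(r, 0, label = sprintf("blob %d", i))
  }
})

test_that("keima ground truth follows weighted-mean arithmetic", {
  geom <- make_geom()
  set.seed(99)
  k <- render_keima(geom, lyso_ratio = 3, cyto_ratio = 0.5,
                    lyso_fraction = 0.3)
  n_l <- mask_area(k$lyso_mask); n_s <- mask_area(k$reporter_mask)
  expect_equal(k$true_mean_ratio, (n_l * 3 + (n_s - n_l) * 0.5) / n_s)
  expect_equal(render_keima(geom, lyso_fraction = 0,
                            cyto_ratio = 0.5)$true_mean_ratio, 0.5)
  expect_equal(render_keima(geom, lyso_fraction = 1,
                            lyso_ratio = 3)$true_mean_ratio, 3)
  # realized lysosomal fraction tracks the request
  expect_lt(abs(n_l / n_s - 0.3), 0.02)
  # doubling ex561 doubles the measured mask-mean ratio
  r1 <- keima_ratio(k$ex488, k$ex561, k$reporter_mask)$mean_ratio
  r2 <- keima_ratio(k$ex488, 2 * k$ex561, k$reporter_mask)$mean_ratio
  expect_equal(r2, 2 * r1)
})
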