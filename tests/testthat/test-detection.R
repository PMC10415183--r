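test_that("a single zero-noise LD is localized within 1 px, radius within 2 px", {
  p <- scene_params(image_size = c(128L, 128L), cell_radius_px = 52,
                    nucleus_radius_px = 10, n_lds = 1L,
                    ld_radius_range_px = c(5, 5), min_ld_separation_px = 5,
                    noise_poisson = FALSE, noise_gaussian_sd = 0,
                    background_level = 0, seed = 3)
  sc <- simulate_cell(p)
  b <- detect_lds_log(sc$noiseless$ld, sc$roi)
  expect_equal(nrow(b), 1L)
  expect_lt(sqrt((b$row - sc$true_blobs$row)^2 +
                   (b$col - sc$true_blobs$col)^2), 1)
  expect_lt(abs(b$radius_px - 5), 2)
})

test_that("detection contracts: empty input, config validation", {
  expect_equal(nrow(detect_lds_log(matrix(0, 64, 64))), 0L)
  expect_error(detection_config(min_sigma_px = 5, max_sigma_px = 2), "<")
  expect_error(detection_config(num_sigma = 1), "num_sigma")
})

test_that("well-separated LDs at SNR >= 10 are recovered inside the cell", {
  peak <- snr_to_peak(10)
  sc <- simulate_cell(scene_params(image_size = c(256L, 256L),
                                   cell_radius_px = 105,
                                   nucleus_radius_px = 25, n_lds = 12L,
                                   ld_radius_range_px = c(4, 8),
                                   min_ld_separation_px = 24,
                                   ld_peak_intensity = peak, seed = 17))
  ld <- subtract_background(get_channel(sc$image, "ld"), 50)
  b <- detect_lds_log(ld, sc$roi)
  res <- match_blobs(b, sc$true_blobs, max_dist = 2)
  expect_gte(res$matched, 11)
  cm <- sc$roi$cell_mask
  expect_true(all(cm[cbind(round(b$row) + 1, round(b$col) + 1)]))
})

test_that("detection is translation-equivariant for interior blobs", {
  p <- scene_params(image_size = c(128L, 128L), cell_radius_px = 40,
                    nucleus_radius_px = 10, n_lds = 3L,
                    min_ld_separation_px = 18, noise_poisson = FALSE,
                    noise_gaussian_sd = 0, background_level = 0, seed = 29)
  sc <- simulate_cell(p)
  ch <- sc$noiseless$ld
  shift <- function(m, dr, dc) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  b0 <- detect_lds_log(ch)
  b1 <- detect_lds_log(shift(ch, 7, 11))
  expect_equal(nrow(b1), nrow(b0))
  o0 <- order(b0$row, b0$col); o1 <- order(b1$row + 0, b1$col)
  expect_equal(b1$row[o1], b0$row[o0] + 7, tolerance = 1e-9)
  expect_equal(b1$col[o1], b0$col[o0] + 11, tolerance = 1e-9)
})

test_that("blobs_to_mask matches the brute-force disk union", {
  # single centered blob r = 4: 49 pixels under integer pixel centers
  one <- data.frame(row = 10, col = 10, radius_px = 4)
  m <- blobs_to_mask(one, c(21L, 21L))
  expect_equal(mask_area(m), 49)
  expect_identical(unclass(m), oracle_disk_mask(one, c(21, 21)))
  expect_equal(mask_area(blobs_to_mask(one[0, ], c(21L, 21L))), 0)
  two <- data.frame(row = c(10, 12), col = c(10, 12), radius_px = c(4, 5))
  expect_identical(unclass(blobs_to_mask(two, c(24L, 24L))),
                   oracle_disk_mask(two, c(24, 24)))
})

test_that("surface_donut_mask follows the clipped expansion rule", {
  # r = 10 -> e = 3; annulus 6 <= d <= 13 around the centroid
  b10 <- data.frame(row = 20, col = 20, radius_px = 10)
  m <- surface_donut_mask(b10, c(41L, 41L))
  d <- oracle_dist(c(41, 41), c(20, 20))
  expect_identical(unclass(m), d >= 6 - 1e-9 & d <= 13 + 1e-9)
  # r = 4 -> e = clip(round(1.2), 2, 5) = 2
  expect_equal(lipoquant:::donut_expansion_px(4), 2)
  expect_equal(lipoquant:::donut_expansion_px(10), 3)
  expect_equal(lipoquant:::donut_expansion_px(30), 5)
  # donut never intersects the removed core
  b <- data.frame(row = c(15, 28), col = c(12, 30), radius_px = c(5, 8))
  donut <- surface_donut_mask(b, c(48L, 48L), core_fraction = 0.6)
  for (i in 1:2) {
    core <- oracle_dist(c(48, 48), c(b$row[i], b$col[i])) <
      0.6 * b$radius_px[i] - 1e-9
    expect_equal(sum(unclass(donut) & core), 0)
  }
  expect_error(surface_donut_mask(b, c(48L, 48L), core_fraction = 1.2),
               "core_fraction")
})

test_that("count_local_maxima counts prominent peaks", {
  # 9 equal Gaussian-free peaks on a zero background
  img <- matrix(0, 100, 100)
  for (r in c(20, 50, 80)) for (c in c(20, 50, 80)) img[r, c] <- 100
  expect_equal(count_local_maxima(img, prominence = 20), 9L)
  expect_equal(count_local_maxima(matrix(5, 50, 50), prominence = 1), 0L)
  g <- outer(dnorm(seq(-3, 3, length.out = 41)),
             dnorm(seq(-3, 3, length.out = 41))) * 1000
  expect_equal(count_local_maxima(g, prominence = 20), 1L)
})

test_that("peak prominences match the level-sweep oracle on small images", {
  set.seed(7)
  for (k in 1:5) {
    img <- matrix(runif(12 * 12) * 10, 12, 12)   # tie-free by construction
    got <- peak_prominences(img)
    ref <- oracle_peak_prominence(img)
    # compare the multiset of (height, prominence) pairs over real peaks
    gg <- got[order(got$height, got$prominence), c("height", "prominence")]
    rr <- ref[order(ref$height, ref$prominence), c("height", "prominence")]
    expect_equal(nrow(gg), nrow(rr), label = sprintf("case %d", k))
    expect_equal(gg$height, rr$height)
    expect_equal(gg$prominence, rr$prominence)
  }
})

test_that("mature-LD filter separates rings from co-labelled spots", {
  sc <- simulate_cell(scene_params(image_size = c(192L, 192L),
                                   cell_radius_px = 80,
                                   nucleus_radius_px = 20, n_lds = 5L,
                                   n_nonspecific_spots = 3L,
                                   min_ld_separation_px = 22,
                                   decorator_mode = "surface_ring",
                                   noise_poisson = FALSE,
                                   noise_gaussian_sd = 0, seed = 53))
  b <- detect_lds_log(sc$noiseless$ld, sc$roi)
  kept <- filter_mature_lds(b, sc$noiseless$ld, sc$noiseless$decorator)
  tb <- sc$true_blobs
  label_of <- function(df) vapply(seq_len(nrow(df)), function(i) {
    d <- sqrt((tb$row - df$row[i])^2 + (tb$col - df$col[i])^2)
    tb$label[which.min(d)]
  }, character(1))
  expect_equal(sum(label_of(kept) == "mature"), 5)
  expect_equal(sum(label_of(kept) == "nonspecific"), 0)
  # idempotent
  again <- filter_mature_lds(kept, sc$noiseless$ld, sc$noiseless$decorator)
  expect_equal(as.data.frame(again)[, c("row", "col", "radius_px")],
               as.data.frame(kept)[, c("row", "col", "radius_px")])
})

test_that("filter contracts: identical channels, empty sets", {
  b <- blob_set(data.frame(row = c(10, 20), col = c(10, 20),
                           radius_px = c(3, 4)))
  ch <- matrix(rexp(32 * 32), 32, 32)
  expect_equal(nrow(filter_mature_lds(b, ch, ch)), 0L)
  empty <- blob_set(data.frame(row = numeric(0), col = numeric(0),
                               radius_px = numeric(0)))
  expect_equal(nrow(filter_mature_lds(empty, ch, ch)), 0L)
})
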