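test_that("Gaussian deposition conserves mass and localizes it", {
  ch <- chain_at(rbind(c(0, 0, 0), c(40, 0, 0), c(80, 0, 0)))
  vol <- voxelize(ch, voxel_size = 2, sigma = 4)
  expect_s3_class(vol, "srev_volume")
  expect_equal(sum(vol$data), 3, tolerance = 1e-3)  # one unit per bead
  # single-bead mass in a +/- 3 sigma voxel box equals the product of 1D
  # Gaussian integrals over that box (the separable deposition oracle)
  ch1 <- chain_at(rbind(c(0, 0, 0), c(500, 0, 0)))
  v1 <- voxelize(ch1, voxel_size = 2, sigma = 4)
  w <- ceiling(3 * 4 / 2)
  idx <- floor((0 - v1$origin) / 2) + 1
  sub <- v1$data[(idx[1] - w):(idx[1] + w), (idx[2] - w):(idx[2] + w),
                 (idx[3] - w):(idx[3] + w)]
  box_mass <- prod(vapply(1:3, function(a) {
    lo <- v1$origin[a] + (idx[a] - w - 1) * 2
    hi <- v1$origin[a] + (idx[a] + w) * 2
    pnorm(hi, 0, 4) - pnorm(lo, 0, 4)
  }, numeric(1)))
  expect_equal(sum(sub), box_mass, tolerance = 1e-6)
  expect_gte(sum(sub), 0.99)
  expect_error(voxelize(ch, voxel_size = 0), "voxel_size")
})

test_that("slab projection is a partial sum over z", {
  # hand-built uniform volume
  vol <- structure(list(data = array(1, c(8, 8, 10)), voxel_size = 10,
                        origin = c(0, 0, 0), sigma = 5),
                   class = "srev_volume")
  img <- slab_projection(vol, z_center = 50, thickness = 40)
  expect_true(all(img == 4))
  expect_equal(attr(img, "pixel_size"), 10)
  # linearity: disjoint slabs sum to the full projection
  full <- slab_projection(vol, z_center = 50, thickness = 100)
  a <- slab_projection(vol, z_center = 25, thickness = 50)
  b <- slab_projection(vol, z_center = 75, thickness = 50)
  expect_equal(a + b, full)
  expect_error(slab_projection(vol, z_center = 95, thickness = 40),
               "outside")
  # beads in the slab project to blobs carrying their full mass
  ch1 <- chain_at(rbind(c(0, 0, 0), c(300, 0, 0)))
  v1 <- voxelize(ch1, voxel_size = 2, sigma = 4)
  p1 <- slab_projection(v1, z_center = 0, thickness = 30)
  expect_equal(sum(p1), 2, tolerance = 1e-2)
})

test_that("enhancement smooths, equalizes and stays within [0, 1]", {
  const <- matrix(0.5, 64, 64)
  out <- enhance(const, gaussian_radius_px = 2, clahe_block_px = 32)
  expect_equal(max(out) - min(out), 0, tolerance = 1e-6)
  # delta spike spreads on the scale of the kernel sigma
  img <- matrix(0, 65, 65)
  img[33, 33] <- 1
  sm <- EBImage::gblur(img, sigma = 3)
  spread <- sqrt(sum(sm * outer((1:65 - 33)^2, rep(1, 65))) / sum(sm))
  expect_equal(spread, 3, tolerance = 0.05)
  out2 <- enhance(img + 0.01, gaussian_radius_px = 3, clahe_block_px = 32)
  expect_true(all(out2 >= 0 & out2 <= 1))
  expect_error(enhance(const, clahe_block_px = 100), "block")
})

test_that("domain centers are found at planted blob peaks", {
  centers <- rbind(c(40, 40), c(90, 80))
  img <- simulate_blob_image(128, centers, radii = 16,
                             profile = "gaussian", background = 0)
  found <- find_domain_centers(img, min_sep_px = 5, floor_quantile = 0.5)
  expect_equal(nrow(found), 2)
  ord <- order(found$x)
  expect_true(all(abs(as.matrix(found[ord, ]) - centers) <= 2))
  # uniform image has no maxima above the floor
  expect_equal(nrow(find_domain_centers(matrix(1, 64, 64))), 0)
  # single blob
  one <- simulate_blob_image(64, rbind(c(32, 32)), 10, "gaussian",
                             background = 0)
  expect_equal(nrow(find_domain_centers(one)), 1)
})

test_that("domain radius criteria fire on constructed ground truth", {
  # noise-free synthetic profiles are probed with a 1-pixel window: the
  # 11-pixel sampling window exists to average pixel noise and would blur
  # an exact radial law
  # (1) power-law blob: M ~ r^2.5 out to r0, then flat background
  r0 <- 20
  img <- simulate_blob_image(128, rbind(c(64, 64)), r0,
                             profile = "powerlaw", exponent = 2.5,
                             background = 1e-4)
  rec <- domain_radius(img, c(64, 64), pixel_size = 1, window_px = 1,
                       r_max_px = 50)
  expect_equal(rec$criterion, "powerlaw_deviation")
  expect_equal(rec$radius_nm, r0, tolerance = 0.15)
  expect_equal(rec$local_D, 2.5, tolerance = 0.1)
  # (2) uniform ball in 3D reaches the local slope limit immediately
  ax <- -30:30
  ball <- array(0, c(61, 61, 61))
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  ball[d2 <= 28^2] <- 1
  vol <- structure(list(data = ball, voxel_size = 1, origin = c(0, 0, 0),
                        sigma = 1), class = "srev_volume")
  rec2 <- domain_radius(vol, c(31, 31, 31), window_px = 1, r_max_px = 25)
  expect_equal(rec2$criterion, "local_D_3")
  expect_equal(rec2$mode, "3d")
  # (3) density decaying as an exact power law (criteria 1-2 silent) with
  # a superposed ring: the radial shell density dips then rises
  xs <- 1:129
  d <- pmax(sqrt(outer((xs - 65)^2, (xs - 65)^2, "+")), 0.5)
  img3 <- d^(-0.3)
  img3[d >= 20 & d <= 26] <- img3[d >= 20 & d <= 26] + 0.5
  attr(img3, "pixel_size") <- 1
  rec3 <- domain_radius(img3, c(65, 65), window_px = 1, r_max_px = 40,
                        base_range_px = c(2, 8))
  expect_equal(rec3$criterion, "cvc_minimum")
  expect_true(rec3$radius_nm >= 14 && rec3$radius_nm <= 22)
  # edge center is skipped with a warning
  expect_warning(out <- domain_radius(img, c(3, 3), pixel_size = 1),
                 "edge")
  expect_null(out)
})

test_that("domain statistics summarize records", {
  rec <- data.frame(center_x = 1, center_y = 1, radius_nm = 80,
                    criterion = "powerlaw_deviation", local_D = 2.5,
                    mode = "2d")
  s <- domain_statistics(rec)
  expect_equal(s$mean_radius_nm, 80)
  expect_equal(s$n_domains, 1)
  expect_equal(sum(s$histogram$counts), 1)
  expect_error(domain_statistics(rec[0, ]), "no domain")
})

test_that("the full domain pipeline runs on an SR-EV configuration", {
  cfg <- small_srev()
  recs <- identify_domains(cfg$chain, voxel_size = 2.9, sigma = 5,
                           slab_thickness = 100, r_max_px = 30)
  expect_true(is.data.frame(recs))
  if (nrow(recs)) {
    expect_true(all(recs$radius_nm > 0))
    expect_true(all(recs$criterion %in%
                      c("powerlaw_deviation", "local_D_3", "cvc_minimum",
                        "max_range")))
  }
})

test_that("volume TIFF export writes one page per slice", {
  skip_if_not_installed("tiff")
  ch <- chain_at(rbind(c(0, 0, 0), c(30, 10, 5)))
  vol <- voxelize(ch, voxel_size = 4, sigma = 5)
  path <- tempfile(fileext = ".tif")
  write_volume_tiff(vol, path)
  pages <- tiff::readTIFF(path, all = TRUE)
  expect_length(pages, dim(vol$data)[3])
  unlink(path)
})
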