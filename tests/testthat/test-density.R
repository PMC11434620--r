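uniform_chain <- function(n, half_edge, rc = 1e4, seed = 1) {
  set.seed(seed)
  chain_at(matrix(runif(3 * n, -half_edge, half_edge), ncol = 3), rc = rc)
}

test_that("CVC grid recovers the mean volume fraction of uniform beads", {
  # Poisson oracle: random beads at overall density phi give cell CVCs
  # centered at phi
  n <- 3000
  half <- 400
  ch <- uniform_chain(n, half)
  phi_true <- n * (4 / 3) * pi * 4.9^3 / (2 * half)^3
  cvc <- cvc_distribution(ch, grid_shape = 5, cell_edge = 120)
  expect_length(cvc, 125)
  expect_equal(mean(cvc), phi_true, tolerance = 0.1)
  expect_true(all(cvc >= 0 & cvc <= 0.74))
  sigma_pois <- sqrt(phi_true * (4 / 3) * pi * 4.9^3 / 120^3)
  expect_equal(stats::sd(cvc), sigma_pois, tolerance = 0.35)
})

test_that("CVC handles empty cells and clips oversized grids", {
  # beads confined to one octant leave far cells empty
  ch <- uniform_chain(200, 50)
  cvc <- suppressWarnings(cvc_distribution(ch, grid_shape = 6,
                                           cell_edge = 120))
  expect_warning(cvc_distribution(ch, grid_shape = 6, cell_edge = 120),
                 "clipped")
  ch2 <- uniform_chain(500, 400)
  cvc2 <- cvc_distribution(ch2, grid_shape = 4, cell_edge = 120)
  expect_true(any(cvc2 == 0) || min(cvc2) < 1e-3)
})

test_that("coordination numbers count neighbors within the radius", {
  # dimer at 10 nm: each bead coordinates the other
  ch <- chain_at(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(coordination_numbers(ch, 11.5), c(1L, 1L))
  # isolated bead far away has CN 0
  ch2 <- chain_at(rbind(c(0, 0, 0), c(10, 0, 0), c(500, 0, 0)))
  expect_equal(coordination_numbers(ch2, 11.5), c(1L, 1L, 0L))
  expect_error(coordination_numbers(ch, -1), "radius")
  # SR-EV configurations stay within the close-packing bound
  cn <- coordination_numbers(small_srev()$chain)
  expect_true(all(cn >= 0))
  expect_lte(max(cn), 14)  # 12 for ideal packing; tolerance band at contact
})

test_that("pair correlation of uniform points is flat with G ~ r^3", {
  set.seed(3)
  n <- 6000
  rc <- 260
  pos <- matrix(runif(3 * n * 3, -rc, rc), ncol = 3)
  pos <- pos[rowSums(pos^2) < rc^2, ][1:n, ]
  ch <- chain_at(pos, rc = rc)
  ch$params$rc_confine <- rc
  prof <- pair_correlation(ch, r_max = 120, dr = 2)
  mid <- prof$r > 20 & prof$r < 120
  expect_equal(mean(prof$g[mid]), 1, tolerance = 0.05)
  expect_equal(packing_exponent(prof, c(20, 120))$D, 3, tolerance = 0.05)
  # G matches the ideal-gas volume integral
  expect_equal(prof$G[prof$r > 100][1], (4 / 3) * pi * 101^3,
               tolerance = 0.1)
})

test_that("excluded volume empties g(r) below the contact distance", {
  cfg <- small_srev()
  prof <- pair_correlation(cfg$chain, r_max = 60, dr = 1)
  expect_true(all(prof$g[prof$r < 9] < 0.02))
  expect_true(all(diff(prof$G) >= 0))  # monotone by construction
})

test_that("grid pair histogram equals brute-force counting", {
  cfg <- small_srev()
  pos <- cfg$chain$positions[1:800, ]
  ch <- chain_at(pos, rc = cfg$chain$params$rc_confine)
  ch$params$rc_confine <- cfg$chain$params$rc_confine
  prof <- pair_correlation(ch, r_max = 50, dr = 2)
  com <- colMeans(pos)
  centers <- which(rowSums(sweep(pos, 2, com)^2) <=
                     (ch$params$rc_confine - 50)^2)
  brute <- numeric(25)
  dm <- as.matrix(stats::dist(pos))
  for (ci in centers) {
    dd <- dm[ci, -ci]
    dd <- dd[dd < 50]
    b <- floor(dd / 2) + 1
    brute <- brute + tabulate(b, nbins = 25)
  }
  shell_vol <- (4 / 3) * pi * diff(seq(0, 50, by = 2)^3)
  rho <- prof$density
  g_brute <- brute / (length(centers) * shell_vol * rho)
  expect_equal(prof$g, g_brute, tolerance = 1e-10)
})

test_that("packing exponent recovers exact power laws", {
  r <- seq(1, 130, by = 1)
  prof3 <- structure(list(r = r, g = rep(1, length(r)), G = 2 * r^3,
                          r_max = 130), class = "srev_profile")
  expect_equal(packing_exponent(prof3)$D, 3, tolerance = 1e-10)
  prof2 <- structure(list(r = r, g = rep(1, length(r)), G = 5 * r^2,
                          r_max = 130), class = "srev_profile")
  expect_equal(packing_exponent(prof2)$D, 2, tolerance = 1e-10)
  expect_error(packing_exponent(prof3, c(200, 300)), "range")
})

test_that("local volume fraction uses exact sphere clipping", {
  # empty probe
  ch <- chain_at(rbind(c(1000, 0, 0), c(1010, 0, 0)))
  expect_equal(local_volume_fraction(ch, center = c(0, 0, 0)), 0)
  # one bead fully inside: ratio of volumes
  ch2 <- chain_at(rbind(c(0, 0, 0), c(2000, 0, 0)))
  expect_equal(local_volume_fraction(ch2, center = c(0, 0, 0),
                                     radius = 240),
               (4.9 / 240)^3, tolerance = 1e-10)
  # bead straddling the boundary: Monte-Carlo clipping oracle
  ch3 <- chain_at(rbind(c(240, 0, 0), c(2000, 0, 0)))
  set.seed(1)
  pts <- matrix(stats::rnorm(3 * 2e5), ncol = 3)
  pts <- pts[rowSums(pts^2) <= 1, ] * 4.9
  pts[, 1] <- pts[, 1] + 240
  frac_in <- mean(rowSums(pts^2) <= 240^2)
  mc <- frac_in * (4 / 3) * pi * 4.9^3 / ((4 / 3) * pi * 240^3)
  expect_equal(local_volume_fraction(ch3, center = c(0, 0, 0),
                                     radius = 240),
               mc, tolerance = 0.02)
  expect_error(local_volume_fraction(ch3, radius = -5), "radius")
})

test_that("rank correlation of local stats behaves at the extremes", {
  syn <- data.frame(config_id = 1:20, phi_i = seq(0.05, 0.24, by = 0.01))
  syn$D_i <- 2 + syn$phi_i^0.5  # strictly increasing map
  expect_equal(di_phi_correlation(syn)$rank_correlation, 1)
  set.seed(4)
  syn$D_i <- sample(syn$D_i)
  expect_lt(abs(di_phi_correlation(syn)$rank_correlation), 0.5)
  syn$D_i <- 2.5
  expect_warning(res <- di_phi_correlation(syn), "degenerate")
  expect_true(is.na(res$rank_correlation))
  expect_error(di_phi_correlation(syn[1:5, ]), "10")
})
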