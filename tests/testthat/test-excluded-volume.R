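test_that("overlap expansion turns vertex revisits into bead clusters", {
  w <- star_walk(pairs = 7)
  ch <- expand_overlaps(w, jitter = 0.1)
  expect_s3_class(ch, "srev_chain")
  expect_equal(nrow(ch$positions), nrow(w$vertices))  # one bead per visit
  expect_equal(ch$origin_vertex, seq_len(16))
  # the 8 origin visits form a cluster within the jitter radius
  origin_beads <- which(rowSums(w$vertices^2) == 0)
  expect_length(origin_beads, 8)
  d <- sqrt(rowSums(ch$positions[origin_beads, ]^2))
  expect_true(all(d <= 0.1 + 1e-12))
  expect_true(all(d > 0))  # degeneracy broken
  # a walk with no returns maps beads onto vertices unchanged
  w2 <- structure(list(
    vertices = cbind(seq(0, 490, by = 10), 0, 0),
    step_types = rep("jump", 49), step_lengths = rep(1, 49),
    params = srev_params(1.15, n_beads = 50, rc_confine = 500)),
    class = "srev_walk")
  expect_equal(expand_overlaps(w2, jitter = 0.1)$positions, w2$vertices)
})

test_that("overlap counting matches the pair-counting oracle", {
  # beads 1 and 3 non-bonded at 5 nm: one overlap; at 9.8 nm: boundary
  # counts as non-overlapping
  ch <- chain_at(rbind(c(0, 0, 0), c(2.5, 4, 0), c(5, 0, 0)))
  expect_equal(count_overlaps(ch), 1L)
  ch2 <- chain_at(rbind(c(0, 0, 0), c(4.9, 4, 0), c(9.8, 0, 0)))
  expect_equal(count_overlaps(ch2), 0L)
  # k near-coincident beads: k(k-1)/2 pairs minus the k-1 bonded ones
  for (k in c(4, 9, 15)) {
    set.seed(k)
    pos <- matrix(stats::rnorm(3 * k, sd = 0.01), ncol = 3)
    ch3 <- chain_at(pos)
    expect_equal(count_overlaps(ch3), k * (k - 1) / 2 - (k - 1))
  }
})

test_that("grid and brute-force overlap scans agree", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 500
    pos <- matrix(runif(3 * n, 0, 60), ncol = 3)
    ch <- chain_at(pos)
    expect_equal(count_overlaps(ch, method = "grid"),
                 count_overlaps(ch, method = "brute"))
    expect_equal(count_overlaps(ch, tol = 0.01, method = "grid"),
                 count_overlaps(ch, tol = 0.01, method = "brute"))
  }
})

test_that("relaxation resolves all overlaps and preserves the chain", {
  w <- star_walk(pairs = 7)
  ch0 <- expand_overlaps(w, jitter = 0.1)
  ch <- relax(ch0)
  expect_true(ch$relaxed)
  tol <- relax_params()$overlap_tol
  expect_equal(count_overlaps(ch, tol = tol, method = "brute"), 0L)
  # exhaustive pair check on the 15-bead cluster
  d <- as.matrix(stats::dist(ch$positions))
  nb <- abs(row(d) - col(d)) > 1
  expect_true(all(d[nb & upper.tri(d)] >= 9.8 * (1 - tol) - 1e-9))
  # connectivity and order intact
  expect_equal(ch$origin_vertex, ch0$origin_vertex)
  expect_equal(nrow(ch$positions), nrow(ch0$positions))
  # bond lengths stay bounded
  expect_true(all(ch$bond_lengths <
                    3 * max(pmax(ch0$bond_lengths, 9.8))))
})

test_that("an overlap-free chain is returned unchanged", {
  pos <- cbind(seq(0, 150, by = 15), 0, 0)
  ch <- chain_at(pos)
  ch$relaxed <- FALSE
  out <- relax(ch)
  expect_identical(out$positions, ch$positions)
  expect_true(out$relaxed)
  expect_equal(out$iterations, 0L)
})

test_that("close non-bonded beads separate to contact distance", {
  # 3-bead chain folded so the end beads overlap at 5 nm
  ch <- relax(chain_at(rbind(c(0, 0, 0), c(2.5, 4.33, 0), c(5, 0, 0))))
  d13 <- sqrt(sum((ch$positions[1, ] - ch$positions[3, ])^2))
  expect_gte(d13, 9.8 * (1 - relax_params()$overlap_tol) - 1e-9)
})

test_that("relaxation energy is non-increasing without thermal noise", {
  w <- star_walk(pairs = 7)
  ch <- relax(expand_overlaps(w, jitter = 0.1))
  e <- ch$energy
  expect_gt(length(e), 1)
  expect_true(all(diff(e) <= 1e-9))
})

test_that("relaxed configurations respect confinement and volume fraction", {
  cfg <- small_srev()
  ch <- cfg$chain
  p <- ch$params
  expect_equal(n_beads_to_phi(p$n_beads, p$rc_confine, p$bead_radius),
               0.12, tolerance = 1e-3)  # phi = N (r0/Rc)^3 by construction
  # the relaxation boundary encloses the initial configuration (whose
  # extent about its final center can exceed rc, since the generation
  # cutoff is measured from the running center of mass); relaxation must
  # not expand that envelope
  com0 <- colMeans(cfg$walk$vertices)
  r_pre <- sqrt(max(rowSums(sweep(cfg$walk$vertices, 2, com0)^2)))
  r_post <- sqrt(rowSums(sweep(ch$positions, 2, com0)^2))
  expect_true(all(r_post <= max(p$rc_confine, r_pre) * 1.0001 + 1))
  expect_equal(count_overlaps(ch, tol = relax_params()$overlap_tol), 0L)
})

test_that("chain XYZ export round-trips", {
  cfg <- small_srev()
  path <- tempfile(fileext = ".xyz")
  write_chain_xyz(cfg$chain, path, map = cfg$map)
  ch2 <- read_chain_xyz(path)
  expect_equal(ch2$positions, cfg$chain$positions, tolerance = 1e-8)
  bonds <- read.table(paste0(path, ".bonds.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(bonds), nrow(cfg$chain$positions) - 1)
  expect_equal(bonds$linker_bp, cfg$map$linker_bp)
  unlink(paste0(path, c("", ".json", ".bonds.tsv")))
})
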