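#' Chromatin volume concentration distribution
#'
#' Occupied volume fraction per cell of a cubic probing grid centered on
#' the configuration's center of mass (the experimental convention uses
#' (120 nm)^3 cells). Each bead's volume is split over 27 subsample
#' points on a 3x3x3 lattice inside the bead, approximating the exact
#' sphere-cube intersection; values are therefore bounded by the sphere
#' packing limits (0.74 crystal, ~0.64 jamming). A grid extending beyond
#' the configuration's bounding box is clipped (with a warning) to the
#' largest odd shape that fits.
#'
#' @param chain a relaxed `srev_chain`.
#' @param grid_shape cells per axis.
#' @param cell_edge cell edge (nm).
#' @return Numeric vector of per-cell volume fractions (length
#'   `grid_shape^3` after any clipping), with attribute `grid_shape`.
#' @export
cvc_distribution <- function(chain, grid_shape = 6, cell_edge = 120) {
  stopifnot(inherits(chain, "srev_chain"))
  pos <- chain$positions
  com <- colMeans(pos)
  half_extent <- min(apply(abs(sweep(pos, 2, com)), 2, max)) +
    chain$bead_radius
  if (grid_shape * cell_edge / 2 > half_extent) {
    grid_shape_new <- max(1, floor(2 * half_extent / cell_edge))
    warning(sprintf(
      "probing grid (%d x %g nm) exceeds the configuration bounds; clipped to %d cells per axis",
      grid_shape, cell_edge, grid_shape_new))
    grid_shape <- grid_shape_new
  }
  lo <- com - grid_shape * cell_edge / 2
  # 27 subsample offsets on a 3^3 lattice inside each bead
  off <- as.matrix(expand.grid(o1 = -1:1, o2 = -1:1, o3 = -1:1)) *
    (0.6 * chain$bead_radius)
  v_sub <- (4 / 3) * pi * chain$bead_radius^3 / nrow(off)
  acc <- numeric(grid_shape^3)
  for (k in seq_len(nrow(off))) {
    p <- sweep(pos, 2, off[k, ] - 0, "+")
    ci <- floor(sweep(p, 2, lo) / cell_edge)
    ok <- rowSums(ci >= 0 & ci < grid_shape) == 3
    ci <- ci[ok, , drop = FALSE]
    idx <- ci[, 1] + grid_shape * (ci[, 2] + grid_shape * ci[, 3]) + 1
    t <- tabulate(idx, nbins = grid_shape^3)
    acc <- acc + t * v_sub
  }
  structure(acc / cell_edge^3, grid_shape = grid_shape,
            cell_edge = cell_edge)
}

#' Per-bead coordination numbers
#'
#' Number of other bead centers within the coordination radius (11.5 nm
#' by default) of each bead: 0 for an isolated nucleosome, up to 12 for
#' one immersed in a packing domain.
#'
#' @param chain an `srev_chain`.
#' @param radius coordination radius (nm).
#' @return Integer vector, one count per bead.
#' @export
coordination_numbers <- function(chain, radius = 11.5) {
  stopifnot(inherits(chain, "srev_chain"))
  if (radius <= 0) stop("`radius` must be positive")
  coord_number_cpp(chain$positions, radius)
}

#' Pair correlation function and its cumulative integral
#'
#' g(r) between bead centers, normalized by the ideal-gas expectation at
#' the mean density of the analysis region: a sphere of radius
#' `rc_confine - r_max` about the center of mass, so that every counted
#' shell lies inside the confinement sphere (avoiding edge bias).
#' Central beads are those inside the analysis region; neighbors are all
#' beads. The cumulative integral \eqn{G(r) = \int_0^r 4 \pi r'^2 g(r')
#' dr'} smooths the short-range oscillations; its log-log slope over an
#' intermediate window is the packing exponent D (see
#' [packing_exponent()]).
#'
#' @param chain a relaxed `srev_chain`.
#' @param r_max largest distance (nm); must stay below `rc_confine`.
#' @param dr shell width (nm).
#' @return An object of class `srev_profile`: list with `r` (shell
#'   centers), `g`, `G`, `n_centers`, `density` and `r_max`.
#' @export
pair_correlation <- function(chain, r_max = 130, dr = 1) {
  stopifnot(inherits(chain, "srev_chain"))
  if (dr <= 0) stop("`dr` must be positive")
  rc <- chain$params$rc_confine
  if (r_max >= rc) stop("`r_max` must be below the confinement radius")
  pos <- chain$positions
  com <- colMeans(pos)
  r2 <- rowSums(sweep(pos, 2, com)^2)
  r_region <- rc - r_max
  centers <- which(r2 <= r_region^2)
  if (length(centers) < 10)
    stop("analysis region contains fewer than 10 beads; reduce `r_max`")
  rho <- length(centers) / ((4 / 3) * pi * r_region^3)
  counts <- pair_hist_cpp(pos, centers, r_max, dr)
  edges <- seq(0, by = dr, length.out = length(counts) + 1)
  shell_vol <- (4 / 3) * pi * diff(edges^3)
  g <- counts / (length(centers) * shell_vol * rho)
  r_mid <- edges[-1] - dr / 2
  G <- cumsum(4 * pi * r_mid^2 * g * dr)
  structure(list(r = r_mid, g = g, G = G, n_centers = length(centers),
                 density = rho, r_max = r_max),
            class = "srev_profile")
}

#' @export
print.srev_profile <- function(x, ...) {
  cat(sprintf(
    "radial profile: %d shells to %g nm, %d central beads (rho = %.2e / nm^3)\n",
    length(x$r), x$r_max, x$n_centers, x$density))
  invisible(x)
}

#' Average radial profiles over an ensemble
#'
#' Averages g(r) across configurations weighted by their center counts,
#' then recomputes G(r) from the averaged g.
#'
#' @param profiles list of [pair_correlation()] results on a common grid.
#' @return An `srev_profile` for the ensemble.
#' @export
average_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  r <- profiles[[1]]$r
  w <- vapply(profiles, function(p) p$n_centers, numeric(1))
  gmat <- vapply(profiles, function(p) p$g, numeric(length(r)))
  g <- as.vector(gmat %*% (w / sum(w)))
  dr <- r[2] - r[1]
  structure(list(r = r, g = g, G = cumsum(4 * pi * r^2 * g * dr),
                 n_centers = sum(w),
                 density = mean(vapply(profiles, function(p) p$density,
                                       numeric(1))),
                 r_max = profiles[[1]]$r_max),
            class = "srev_profile")
}

#' Packing exponent D
#'
#' Log-log least-squares slope of the cumulative pair-correlation
#' integral G(r) over the fit window (40-120 nm by default), using all
#' shells strictly inside the window. A uniform density gives D = 3; the
#' chromatin regime lies between 2 and 3.
#'
#' @param profile an `srev_profile`.
#' @param range fit window `(min, max)` in nm.
#' @return List with `D`, `intercept`, `r_squared` and `n_bins`.
#' @export
packing_exponent <- function(profile, range = c(40, 120)) {
  sel <- profile$r > range[1] & profile$r < range[2] & profile$G > 0
  if (sum(sel) < 3) stop("fit range not covered by the profile")
  lx <- log10(profile$r[sel])
  ly <- log10(profile$G[sel])
  fit <- lm(ly ~ lx)
  list(D = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = cor(lx, ly)^2, n_bins = sum(sel))
}

#' Local volume fraction in a probe sphere
#'
#' Total bead volume (spheres clipped exactly to the probe) divided by
#' the probe volume. The default 240 nm probe matches the region used
#' for the per-configuration packing exponent.
#'
#' @param chain an `srev_chain`.
#' @param center probe center (3-vector, nm); configuration center of
#'   mass when `NULL`.
#' @param radius probe radius (nm).
#' @return Volume fraction in `[0, 0.74]`.
#' @export
local_volume_fraction <- function(chain, center = NULL, radius = 240) {
  stopifnot(inherits(chain, "srev_chain"))
  if (radius <= 0) stop("`radius` must be positive")
  if (is.null(center)) center <- colMeans(chain$positions)
  local_volume_cpp(chain$positions, center, radius, chain$bead_radius) /
    ((4 / 3) * pi * radius^3)
}

#' Per-configuration packing exponent and local volume fraction
#'
#' Computes, for each configuration, the packing exponent D_i from its
#' own G_i(r) and the local volume fraction phi_i, both in the same
#' probe sphere (240 nm radius about the center of mass); the fit window
#' lies strictly inside the probe.
#'
#' @param configs list of configurations (with `chain`).
#' @param probe_radius probe sphere radius (nm).
#' @param fit_range D fit window (nm).
#' @param r_max,dr passed to [pair_correlation()].
#' @return Data frame with `config_id`, `D_i`, `phi_i`.
#' @export
local_stats <- function(configs, probe_radius = 240, fit_range = c(40, 120),
                        r_max = 130, dr = 1) {
  stopifnot(probe_radius > fit_range[2])
  out <- lapply(seq_along(configs), function(i) {
    ch <- configs[[i]]$chain
    prof <- pair_correlation(ch, r_max = r_max, dr = dr)
    data.frame(config_id = i,
               D_i = packing_exponent(prof, fit_range)$D,
               phi_i = local_volume_fraction(ch, radius = probe_radius))
  })
  do.call(rbind, out)
}

#' Correlation between local packing exponent and volume fraction
#'
#' Rank (Spearman) correlation between per-configuration D_i and phi_i.
#' Degenerate (constant) inputs yield `NA` with a warning.
#'
#' @param stats data frame from [local_stats()] (columns `D_i`, `phi_i`).
#' @return List with `pairs` (the input data frame) and `rank_correlation`.
#' @export
di_phi_correlation <- function(stats) {
  if (nrow(stats) < 10) stop("need at least 10 configurations")
  rc <- if (stats::sd(stats$D_i) == 0 || stats::sd(stats$phi_i) == 0) {
    warning("degenerate input: correlation undefined")
    NA_real_
  } else {
    cor(stats$D_i, stats$phi_i, method = "spearman")
  }
  list(pairs = stats, rank_correlation = rc)
}

#' Export a radial profile as TSV
#'
#' Columns `r_nm, g, G`.
#'
#' @param profile an `srev_profile`.
#' @param path output file.
#' @export
write_profile_tsv <- function(profile, path) {
  write.table(data.frame(r_nm = profile$r, g = profile$g, G = profile$G),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
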