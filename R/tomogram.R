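#' Voxelize a bead chain into a density volume
#'
#' Renders the configuration as a tomogram analogue: each bead deposits
#' unit mass as an isotropic normal distribution of width `sigma`, and a
#' voxel receives the integral of that normal over its volume (separable
#' 1D integrals, truncated at 4 sigma). Total mass is conserved to within
#' the truncation error (< 1e-3 relative) when the grid covers the
#' configuration.
#'
#' The defaults (2.9 nm voxels, 5 nm deposition width) put the 5-pixel
#' filter radius and 11-pixel window of the domain pipeline at physical
#' scales of roughly 15 and 32 nm.
#'
#' @param chain an `srev_chain`.
#' @param voxel_size voxel edge (nm).
#' @param sigma deposition width (nm).
#' @param origin physical coordinate of the (0,0,0) voxel corner;
#'   computed from the bead bounding box plus a 4-sigma pad when `NULL`.
#' @param dims grid dimensions (3 integers); computed when `NULL`.
#' @return An object of class `srev_volume`: list with `data` (3D array),
#'   `voxel_size`, `origin`, `sigma`.
#' @export
voxelize <- function(chain, voxel_size = 2.9, sigma = 5, origin = NULL,
                     dims = NULL) {
  stopifnot(inherits(chain, "srev_chain"))
  if (voxel_size <= 0) stop("`voxel_size` must be positive")
  pos <- chain$positions
  pad <- 4 * sigma
  if (is.null(origin)) origin <- apply(pos, 2, min) - pad
  if (is.null(dims))
    dims <- as.integer(ceiling((apply(pos, 2, max) + pad - origin) /
                                 voxel_size))
  vol <- deposit_gaussian_cpp(pos, origin, voxel_size, as.integer(dims),
                              sigma)
  structure(list(data = vol, voxel_size = voxel_size, origin = origin,
                 sigma = sigma),
            class = "srev_volume")
}

#' @export
print.srev_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "density volume: %d x %d x %d voxels of %g nm, total mass %.1f\n",
    d[1], d[2], d[3], x$voxel_size, sum(x$data)))
  invisible(x)
}

#' Project a z-slab of a density volume
#'
#' Sums the voxels whose z-extent lies inside the slab
#' `[z_center - thickness/2, z_center + thickness/2]` along z, per (x, y)
#' column, emulating the re-projection of a tomogram slab.
#'
#' @param volume an `srev_volume`.
#' @param z_center slab center (nm, physical coordinate); volume center
#'   when `NULL`.
#' @param thickness slab thickness (nm).
#' @return 2D matrix of projected density with attribute `pixel_size`.
#' @export
slab_projection <- function(volume, z_center = NULL, thickness = 100) {
  stopifnot(inherits(volume, "srev_volume"))
  nz <- dim(volume$data)[3]
  z0 <- volume$origin[3]
  v <- volume$voxel_size
  if (is.null(z_center)) z_center <- z0 + nz * v / 2
  klo <- floor((z_center - thickness / 2 - z0) / v) + 1
  khi <- ceiling((z_center + thickness / 2 - z0) / v)
  if (klo < 1 || khi > nz) stop("slab extends outside the volume")
  img <- apply(volume$data[, , klo:khi, drop = FALSE], c(1, 2), sum)
  attr(img, "pixel_size") <- v
  img
}

#' Smooth and contrast-enhance a projected density image
#'
#' Normalizes to `[0, 1]`, applies a Gaussian filter and CLAHE local
#' contrast equalization, matching the preprocessing used ahead of domain
#' identification on experimental tomogram projections.
#'
#' @param image 2D matrix (projected density).
#' @param gaussian_radius_px Gaussian filter width (pixels, used as the
#'   kernel sigma).
#' @param clahe_block_px CLAHE block size (pixels); must not exceed the
#'   image.
#' @param clahe_limit CLAHE clip limit, in EBImage's convention (multiple
#'   of the mean histogram count).
#' @return Matrix in `[0, 1]` with the input's `pixel_size` attribute.
#' @export
enhance <- function(image, gaussian_radius_px = 5, clahe_block_px = 120,
                    clahe_limit = 2) {
  if (!is.matrix(image)) stop("`image` must be a 2D matrix")
  if (clahe_block_px > min(dim(image)))
    stop("CLAHE block larger than the image")
  ps <- attr(image, "pixel_size")
  m <- max(image)
  img <- if (m > 0) image / m else image
  img <- EBImage::gblur(img, sigma = gaussian_radius_px)
  # CLAHE needs >= 2 x 2 contextual regions and dimensions divisible by
  # the region counts; pad by edge replication, equalize, crop back
  nx <- max(2L, round(nrow(img) / clahe_block_px))
  ny <- max(2L, round(ncol(img) / clahe_block_px))
  rng <- range(img)
  if (diff(rng) > 0) {
    img <- (img - rng[1]) / diff(rng)
    nr <- ceiling(nrow(img) / nx) * nx
    nc <- ceiling(ncol(img) / ny) * ny
    pad <- matrix(0, nr, nc)
    pad[seq_len(nrow(img)), seq_len(ncol(img))] <- img
    if (nr > nrow(img))
      pad[(nrow(img) + 1):nr, seq_len(ncol(img))] <-
        pad[rep(nrow(img), nr - nrow(img)), seq_len(ncol(img))]
    if (nc > ncol(img))
      pad[, (ncol(img) + 1):nc] <- pad[, rep(ncol(img), nc - ncol(img))]
    eq <- EBImage::clahe(pad, nx = nx, ny = ny, limit = clahe_limit)
    img <- matrix(eq, nrow = nr)[seq_len(nrow(img)), seq_len(ncol(img))]
  }
  img <- pmin(pmax(img, 0), 1)
  out <- matrix(img, nrow = nrow(image))
  attr(out, "pixel_size") <- ps
  out
}

#' Locate packing-domain centers as density maxima
#'
#' Local maxima of the enhanced density above a noise floor, with a
#' minimum separation enforced by the size of the maximum filter;
#' plateaus collapse to their centroid.
#'
#' @param image enhanced 2D matrix.
#' @param min_sep_px minimum center separation (pixels).
#' @param floor_quantile noise floor as a quantile of the nonzero pixels.
#' @return Data frame with pixel coordinates `x`, `y` (may be empty).
#' @export
find_domain_centers <- function(image, min_sep_px = 5,
                                floor_quantile = 0.6) {
  if (!is.matrix(image)) stop("`image` must be a 2D matrix")
  pos <- image[image > 0]
  if (!length(pos)) return(data.frame(x = integer(), y = integer()))
  floor_val <- quantile(pos, floor_quantile)
  brush <- EBImage::makeBrush(2 * min_sep_px + 1, shape = "disc")
  dil <- EBImage::dilate(image, brush)
  mask <- (image >= dil - 1e-10) & (image > floor_val)
  if (!any(mask)) return(data.frame(x = integer(), y = integer()))
  lab <- EBImage::bwlabel(mask)
  idx <- which(mask, arr.ind = TRUE)
  labs <- lab[mask]
  cx <- round(tapply(idx[, 1], labs, mean))
  cy <- round(tapply(idx[, 2], labs, mean))
  data.frame(x = as.integer(cx), y = as.integer(cy), row.names = NULL)
}

# Weighted-average mass scaling curve about a center. 2D: pixels within
# distance r; 3D: voxels within a sphere. Weights are the values at the
# window centers. The cumulative mass is interpolated along sorted pixel
# distances, which avoids the integer-shell binning wiggle that would
# otherwise trip the 5% power-law deviation criterion.
mass_scaling <- function(data, center, window_px, r_max_px) {
  dims <- dim(data)
  nd <- length(dims)
  hw <- (window_px - 1) %/% 2
  offs <- if (nd == 2) {
    as.matrix(expand.grid(dx = -hw:hw, dy = -hw:hw))
  } else {
    as.matrix(expand.grid(dx = -hw:hw, dy = -hw:hw, dz = -hw:hw))
  }
  ax <- -r_max_px:r_max_px
  d_grid <- if (nd == 2) sqrt(outer(ax^2, ax^2, "+")) else
    sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  ord <- order(d_grid)
  d_sorted <- d_grid[ord]
  keep <- d_sorted <= r_max_px + 0.5
  ord <- ord[keep]
  d_sorted <- d_sorted[keep]
  r <- seq_len(r_max_px)
  M <- numeric(r_max_px)
  wsum <- 0
  for (k in seq_len(nrow(offs))) {
    c_k <- center + offs[k, ]
    if (any(c_k - r_max_px < 1) || any(c_k + r_max_px > dims)) next
    w <- data[matrix(c_k, 1)]
    if (w <= 0) next
    sl <- lapply(seq_len(nd),
                 function(a) (c_k[a] - r_max_px):(c_k[a] + r_max_px))
    sub <- if (nd == 2) data[sl[[1]], sl[[2]]] else
      data[sl[[1]], sl[[2]], sl[[3]]]
    cum <- cumsum(sub[ord])
    Mc <- stats::approx(d_sorted, cum, xout = r, ties = "ordered",
                        rule = 2)$y
    M <- M + w * Mc
    wsum <- wsum + w
  }
  if (wsum == 0) return(NULL)
  M / wsum
}

#' Domain radius from mass scaling
#'
#' Measures the weighted-average mass-scaling curve M(r) around a domain
#' center (window of `window_px` pixels, weights given by the pixel
#' values) and returns the smallest radius triggering any of three stop
#' criteria: (1) M(r) deviates by more than `deviation_tol` from the
#' power law fitted over the base range; (2) the local log-log slope of
#' M(r) reaches 3; (3) the radial shell density reaches a local minimum
#' and begins to increase. Works on a 2D projected image or on an
#' `srev_volume` (3D mass scaling); the mode is recorded.
#'
#' @param x 2D matrix (with `pixel_size` attribute or `pixel_size`
#'   argument) or an `srev_volume`.
#' @param center pixel/voxel coordinates of the domain center (from
#'   [find_domain_centers()] for images).
#' @param window_px sampling window edge (pixels).
#' @param r_max_px largest radius evaluated (pixels).
#' @param base_range_px radii (pixels) used for the reference power-law
#'   fit.
#' @param deviation_tol relative deviation triggering criterion 1.
#' @param pixel_size physical pixel size (nm), if not carried by `x`.
#' @return A one-row data frame (domain record): `center_x`, `center_y`,
#'   `radius_nm`, `criterion`, `local_D`, `mode`; or `NULL` when the
#'   center is too close to the edge for the window.
#' @export
domain_radius <- function(x, center, window_px = 11, r_max_px = 40,
                          base_range_px = c(3, 10), deviation_tol = 0.05,
                          pixel_size = NULL) {
  if (inherits(x, "srev_volume")) {
    data <- x$data
    ps <- x$voxel_size
    mode <- "3d"
  } else {
    data <- x
    ps <- if (is.null(pixel_size)) attr(x, "pixel_size") else pixel_size
    mode <- "2d"
  }
  if (is.null(ps)) stop("pixel size unknown; supply `pixel_size`")
  center <- as.integer(round(center))
  hw <- (window_px - 1) %/% 2
  if (any(center - hw < 1) || any(center + hw > dim(data))) {
    warning("center too close to the image edge; skipped")
    return(NULL)
  }
  M <- mass_scaling(data, center, window_px, r_max_px)
  if (is.null(M) || any(M[base_range_px[1]:base_range_px[2]] <= 0)) {
    warning("no usable mass-scaling curve at this center; skipped")
    return(NULL)
  }
  r <- seq_len(r_max_px)
  base <- base_range_px[1]:base_range_px[2]
  fit <- lm(y ~ x, data.frame(x = log10(r[base]), y = log10(M[base])))
  d_base <- unname(coef(fit)[2])
  M_fit <- 10^(coef(fit)[1] + d_base * log10(r))

  start <- base_range_px[2] + 1
  cand <- c(crit1 = NA_real_, crit2 = NA_real_, crit3 = NA_real_)
  # (1) departure from the base power law
  dev <- abs(M / M_fit - 1)
  hit <- which(dev[start:r_max_px] > deviation_tol)
  if (length(hit)) cand["crit1"] <- r[start - 1 + hit[1]]
  # (2) local slope reaches 3 (5-point windowed log-log regression)
  lgr <- log10(r)
  lgM <- log10(pmax(M, .Machine$double.xmin))
  for (k in seq(max(start, 3), r_max_px - 2)) {
    w <- (k - 2):(k + 2)
    sl <- coef(lm(lgM[w] ~ lgr[w]))[2]
    if (is.finite(sl) && sl >= 3) { cand["crit2"] <- r[k]; break }
  }
  # (3) radial shell density dips then rises: a smoothed local minimum
  # followed by a clear (>= 5%) increase, so interpolation wiggle alone
  # cannot trigger it
  shell <- diff(c(0, M))
  area <- if (mode == "2d") pi * diff(c(0, r^2)) else
    (4 / 3) * pi * diff(c(0, r^3))
  dens <- stats::filter(shell / area, rep(1 / 5, 5), sides = 2)
  for (k in seq(max(start, 3), r_max_px - 3)) {
    win <- dens[(k - 2):(k + 1)]
    if (!any(is.na(c(win, dens[k + 2], dens[k + 3]))) &&
        dens[k] <= min(win) &&
        max(dens[(k + 2):(k + 3)]) >= dens[k] * 1.05) {
      cand["crit3"] <- r[k]
      break
    }
  }

  crit_names <- c("powerlaw_deviation", "local_D_3", "cvc_minimum")
  if (all(is.na(cand))) {
    radius_px <- r_max_px
    criterion <- "max_range"
  } else {
    j <- which.min(cand)
    radius_px <- cand[j]
    criterion <- crit_names[j]
  }
  data.frame(center_x = center[1], center_y = center[2],
             radius_nm = radius_px * ps, criterion = criterion,
             local_D = d_base, mode = mode)
}

#' Identify and size packing domains in a configuration
#'
#' Full image pipeline: voxelize a slab of the configuration, project it
#' along z, enhance, locate density maxima and measure each domain's
#' mass-scaling radius.
#'
#' @param chain a relaxed `srev_chain`.
#' @param voxel_size,sigma passed to [voxelize()].
#' @param slab_thickness z-slab thickness (nm).
#' @param gaussian_radius_px,clahe_block_px passed to [enhance()].
#' @param min_sep_px,floor_quantile passed to [find_domain_centers()].
#' @param ... passed to [domain_radius()].
#' @return Data frame of domain records (possibly 0 rows).
#' @export
identify_domains <- function(chain, voxel_size = 2.9, sigma = 5,
                             slab_thickness = 100, gaussian_radius_px = 5,
                             clahe_block_px = 120, min_sep_px = 5,
                             floor_quantile = 0.6, ...) {
  pos <- chain$positions
  com <- colMeans(pos)
  keep <- abs(pos[, 3] - com[3]) <= slab_thickness / 2 + 4 * sigma
  slab_chain <- chain
  slab_chain$positions <- pos[keep, , drop = FALSE]
  vol <- voxelize(slab_chain, voxel_size, sigma)
  img <- slab_projection(vol, z_center = com[3], thickness = slab_thickness)
  img <- enhance(img, gaussian_radius_px,
                 clahe_block_px = min(clahe_block_px, min(dim(img))),
                 clahe_limit = 2)
  empty <- data.frame(center_x = integer(), center_y = integer(),
                      radius_nm = numeric(), criterion = character(),
                      local_D = numeric(), mode = character())
  centers <- find_domain_centers(img, min_sep_px, floor_quantile)
  if (!nrow(centers)) return(empty)
  recs <- lapply(seq_len(nrow(centers)), function(i)
    suppressWarnings(
      domain_radius(img, c(centers$x[i], centers$y[i]),
                    pixel_size = voxel_size, ...)))
  recs <- Filter(Negate(is.null), recs)
  if (!length(recs)) return(empty)
  do.call(rbind, recs)
}

#' Summarize an ensemble of domain records
#'
#' @param records data frame of domain records ([domain_radius()] rows),
#'   optionally with a `config_id` column for per-configuration counts.
#' @param breaks histogram breaks for the radii (nm).
#' @return List with `n_domains`, `mean_radius_nm`, `radii_nm`,
#'   `histogram` and, when `config_id` is present, `domains_per_config`.
#' @export
domain_statistics <- function(records, breaks = seq(0, 400, by = 20)) {
  if (is.null(records) || nrow(records) == 0) stop("no domain records")
  radii <- records$radius_nm
  h <- graphics::hist(pmin(radii, max(breaks)), breaks = breaks,
                      plot = FALSE)
  out <- list(n_domains = length(radii), mean_radius_nm = mean(radii),
              radii_nm = radii, histogram = h)
  if ("config_id" %in% names(records))
    out$domains_per_config <- table(records$config_id)
  out
}

#' Synthetic blob fields for pipeline validation
#'
#' Ground-truth images for the domain pipeline. `profile = "gaussian"`
#' plants peaked blobs (center-recall tests); `profile = "powerlaw"`
#' plants blobs whose cumulative mass grows as r^`exponent` out to the
#' planted radius, then a uniform background (radius-recovery tests).
#'
#' @param dim_px image edge (pixels).
#' @param centers matrix (k x 2) of blob centers (pixels).
#' @param radii planted radii (pixels), recycled.
#' @param profile blob profile.
#' @param exponent mass-scaling exponent of power-law blobs.
#' @param background background density relative to the blob scale.
#' @param amplitude peak amplitude of gaussian blobs.
#' @return Matrix with attribute `pixel_size = 1`.
#' @export
simulate_blob_image <- function(dim_px, centers, radii,
                                profile = c("gaussian", "powerlaw"),
                                exponent = 2.5, background = 0.01,
                                amplitude = 1) {
  profile <- match.arg(profile)
  radii <- rep_len(radii, nrow(centers))
  img <- matrix(background, dim_px, dim_px)
  xs <- seq_len(dim_px)
  for (k in seq_len(nrow(centers))) {
    d <- sqrt(outer((xs - centers[k, 1])^2, (xs - centers[k, 2])^2, "+"))
    if (profile == "gaussian") {
      img <- img + amplitude * exp(-d^2 / (2 * (radii[k] / 2)^2))
    } else {
      # density ~ r^(exponent - 2) gives M(r) ~ r^exponent in 2D
      inside <- d <= radii[k]
      img[inside] <- img[inside] +
        amplitude * pmax(d[inside], 0.5)^(exponent - 2)
    }
  }
  attr(img, "pixel_size") <- 1
  img
}

#' Write a density volume as a multi-page TIFF
#'
#' One z-slice per page, normalized to the volume maximum; the voxel size
#' and normalization are written to a JSON sidecar (`<path>.json`).
#' Requires the `tiff` package.
#'
#' @param volume an `srev_volume`.
#' @param path output file.
#' @export
write_volume_tiff <- function(volume, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the `tiff` package is required for TIFF export")
  m <- max(volume$data, .Machine$double.eps)
  slices <- lapply(seq_len(dim(volume$data)[3]), function(k)
    volume$data[, , k] / m)
  tiff::writeTIFF(slices, path, bits.per.sample = 32L)
  jsonlite::write_json(list(voxel_size_nm = volume$voxel_size,
                            origin_nm = volume$origin,
                            deposition_sigma_nm = volume$sigma,
                            intensity_scale = m),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
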