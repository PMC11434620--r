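#' Log-spaced genomic-distance bins
#'
#' Geometric bin edges covering `[n_min, n_max]` bp at `per_decade` bins
#' per decade.
#'
#' @param n_min,n_max range (bp).
#' @param per_decade bins per decade.
#' @return Numeric vector of bin edges.
#' @export
genomic_bins <- function(n_min = 100, n_max = 1e8, per_decade = 20) {
  10^seq(log10(n_min), log10(n_max), by = 1 / per_decade)
}

# Stratified pair sampling shared by the two scaling curves: for each
# config, bead separations are taken log-spaced and up to max_per_sep
# pairs per separation are measured (all pairs when fewer exist).
sample_pairs <- function(configs, cutoff, seps_per_decade, max_per_sep) {
  do.call(rbind, lapply(configs, function(cfg) {
    n <- nrow(cfg$chain$positions)
    seps <- unique(round(10^seq(0, log10(n - 1), by = 1 / seps_per_decade)))
    pair_samples_cpp(cfg$chain$positions, cfg$map$cumulative_bp,
                     as.integer(seps), as.integer(max_per_sep), cutoff)
  }))
}

make_curve <- function(samples, bins, value_col, agg, ensemble_size) {
  idx <- findInterval(samples[, 1], bins, rightmost.closed = TRUE)
  keep <- idx >= 1 & idx < length(bins)
  idx <- idx[keep]
  v <- samples[keep, value_col]
  counts <- tabulate(idx, nbins = length(bins) - 1)
  sums <- vapply(seq_len(length(bins) - 1), function(b) sum(v[idx == b]),
                 numeric(1))
  centers <- sqrt(bins[-length(bins)] * bins[-1])
  ok <- counts > 0
  df <- data.frame(n_bp = centers[ok],
                   value = agg(sums[ok], counts[ok]),
                   count = counts[ok])
  structure(df, class = c("srev_curve", "data.frame"),
            ensemble_size = ensemble_size)
}

#' Ensemble end-to-end distance versus genomic distance
#'
#' Root of the mean squared spatial distance between bead pairs, binned
#' by their genomic separation (log-spaced bins) and averaged over the
#' ensemble. Pairs are sampled stratified by bead separation (seeded via
#' R's RNG); bins receiving no pairs are absent from the output rather
#' than reported as zero.
#'
#' @param configs list of configurations (each with `chain` and `map`,
#'   as returned by [srev_configuration()]).
#' @param bins genomic-distance bin edges (bp).
#' @param seps_per_decade sampled bead separations per decade.
#' @param max_per_sep pairs sampled per separation per configuration.
#' @return An `srev_curve` data frame: `n_bp` (geometric bin center),
#'   `value` (RMS end-to-end distance, nm), `count` (pairs in bin).
#' @export
end_to_end_curve <- function(configs, bins = genomic_bins(),
                             seps_per_decade = 30, max_per_sep = 500) {
  stopifnot(length(configs) >= 1)
  s <- sample_pairs(configs, cutoff = 0, seps_per_decade, max_per_sep)
  make_curve(s, bins, 2, function(sums, n) sqrt(sums / n), length(configs))
}

#' Ensemble contact probability versus genomic distance
#'
#' Fraction of bead pairs at genomic separation n whose spatial distance
#' is below `cutoff`, averaged over the ensemble. Contacts are computed
#' between bead centers (nucleosome proxies), the model's resolution.
#'
#' @inheritParams end_to_end_curve
#' @param cutoff contact distance (nm).
#' @return An `srev_curve` data frame (`value` is the contact
#'   probability in `[0, 1]`).
#' @export
contact_probability_curve <- function(configs, cutoff = 35,
                                      bins = genomic_bins(),
                                      seps_per_decade = 30,
                                      max_per_sep = 500) {
  stopifnot(length(configs) >= 1)
  if (cutoff <= 0) stop("`cutoff` must be positive")
  s <- sample_pairs(configs, cutoff, seps_per_decade, max_per_sep)
  make_curve(s, bins, 3, function(sums, n) sums / n, length(configs))
}

#' Power-law fit of a scaling curve
#'
#' Least-squares slope of `log(value)` versus `log(n_bp)` restricted to
#' `n_range`. For the end-to-end curve the slope below the intra/inter
#' crossover (~4e4 bp) is the intra-domain Flory exponent; for the
#' contact-probability curve over 1e5-1e6 bp it is the contact scaling
#' slope S.
#'
#' @param curve an `srev_curve` (or data frame with `n_bp` and `value`).
#' @param n_range genomic interval `(min, max)` in bp.
#' @return List with `exponent`, `intercept` (log10 scale), `r_squared`
#'   and `n_bins`.
#' @export
powerlaw_fit <- function(curve, n_range) {
  sel <- curve$n_bp >= n_range[1] & curve$n_bp <= n_range[2] &
    is.finite(curve$value) & curve$value > 0
  if (sum(sel) < 3) stop("fewer than 3 bins inside the fit range")
  lx <- log10(curve$n_bp[sel])
  ly <- log10(curve$value[sel])
  fit <- lm(ly ~ lx)
  list(exponent = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = cor(lx, ly)^2,
       n_bins = sum(sel))
}

#' Intra- and inter-domain regime fits
#'
#' Fits the two power-law regimes of a scaling curve: the intra-domain
#' window below the crossover near 4e4 bp and the inter-domain window
#' 1e5-1e6 bp.
#'
#' @param curve an `srev_curve`.
#' @param intra,inter fit windows (bp).
#' @return List with `intra` and `inter` [powerlaw_fit()] results.
#' @export
regime_fits <- function(curve, intra = c(1e3, 4e4), inter = c(1e5, 1e6)) {
  list(intra = powerlaw_fit(curve, intra),
       inter = powerlaw_fit(curve, inter))
}

#' Export a scaling curve as TSV
#'
#' Columns `n_bp, value, count`; optionally writes a JSON fit report.
#'
#' @param curve an `srev_curve`.
#' @param path output file.
#' @param fit optional [powerlaw_fit()] result written to `<path>.json`.
#' @export
write_curve_tsv <- function(curve, path, fit = NULL) {
  write.table(as.data.frame(curve), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  if (!is.null(fit))
    jsonlite::write_json(fit, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}
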