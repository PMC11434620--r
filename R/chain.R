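#' Relaxation parameters
#'
#' Controls the overlap-removal relaxation of [relax()]. The defaults give
#' a deterministic, monotone energy descent: a harmonic half-spring
#' repulsion between any two beads closer than one bead diameter (the
#' non-overlap radius applies to all beads, bonded or not), and harmonic
#' bonds whose rest length is the initial bond length, floored at the
#' contact distance \eqn{2 r_0} (beads joined by a return-derived bond
#' start essentially coincident; their physical rest state is contact).
#' Bonds are much softer than the repulsion so that cluster expansion is
#' not frustrated by bond tension.
#'
#' @param overlap_tol relative overlap tolerance in `[0, 0.05]`: a
#'   non-bonded pair is overlapping when closer than
#'   `2 * bead_radius * (1 - overlap_tol)`.
#' @param max_steps iteration cap.
#' @param step_scale initial integrator timestep; grown while the descent
#'   makes progress and shrunk whenever a step would raise the energy.
#' @param max_disp per-bead displacement cap per iteration (nm).
#' @param repulsion_stiffness,bond_stiffness potential prefactors (model
#'   units, positive).
#' @param temperature_scale amplitude of per-iteration Gaussian noise
#'   (nm); 0 gives a deterministic descent.
#' @param jitter radius (nm) of the random displacement applied by
#'   [expand_overlaps()] to coincident beads.
#' @return An object of class `srev_relax_params`.
#' @export
relax_params <- function(overlap_tol = 0.01, max_steps = 50000L,
                         step_scale = 0.1, max_disp = 1,
                         repulsion_stiffness = 1, bond_stiffness = 0.05,
                         temperature_scale = 0, jitter = 0.1) {
  if (overlap_tol < 0 || overlap_tol > 0.05)
    stop("`overlap_tol` must be in [0, 0.05]")
  if (repulsion_stiffness <= 0 || bond_stiffness <= 0)
    stop("stiffnesses must be positive")
  structure(
    list(overlap_tol = overlap_tol, max_steps = as.integer(max_steps),
         step_scale = step_scale, max_disp = max_disp,
         repulsion_stiffness = repulsion_stiffness,
         bond_stiffness = bond_stiffness,
         temperature_scale = temperature_scale, jitter = jitter),
    class = "srev_relax_params")
}

new_chain <- function(positions, bead_radius, origin_vertex, params,
                      relaxed = FALSE, iterations = 0L, energy = numeric()) {
  structure(
    list(positions = positions, bead_radius = bead_radius,
         bond_lengths = bond_lengths_of(positions),
         origin_vertex = origin_vertex, params = params,
         relaxed = relaxed, iterations = iterations, energy = energy),
    class = "srev_chain")
}

bond_lengths_of <- function(pos) {
  d <- diff(pos)
  sqrt(rowSums(d^2))
}

#' @export
print.srev_chain <- function(x, ...) {
  cat(sprintf("SR-EV bead chain: %d beads (r0 = %g nm), %s\n",
              nrow(x$positions), x$bead_radius,
              if (x$relaxed) sprintf("relaxed (%d iterations)", x$iterations)
              else "unrelaxed"))
  invisible(x)
}

#' Expand walk overlaps into distinct beads
#'
#' Every visit of a walk vertex becomes one bead of a linear chain, so a
#' vertex revisited by returns turns into a cluster of initially
#' coincident beads (a motif of k jump-and-return pairs becomes 2k + 1
#' linearly connected beads). Coincident beads are displaced by an
#' independent uniform random jitter inside a ball of radius `jitter` nm
#' to break the degeneracy before force evaluation.
#'
#' @param walk an `srev_walk`.
#' @param jitter jitter radius (nm).
#' @return An unrelaxed `srev_chain`; `origin_vertex` maps each bead to
#'   its walk vertex index.
#' @export
expand_overlaps <- function(walk, jitter = 0.1) {
  stopifnot(inherits(walk, "srev_walk"))
  pos <- walk$vertices
  n <- nrow(pos)
  key <- do.call(paste, c(as.data.frame(round(pos, 6)), sep = "/"))
  dup_group <- key %in% key[duplicated(key)]
  n_dup <- sum(dup_group)
  if (n_dup > 0 && jitter > 0) {
    # uniform in a ball: gaussian direction, radius ~ U^(1/3)
    dir <- matrix(stats::rnorm(3 * n_dup), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    pos[dup_group, ] <- pos[dup_group, , drop = FALSE] +
      dir * (jitter * runif(n_dup)^(1 / 3))
  }
  new_chain(pos, walk$params$bead_radius, seq_len(n), walk$params)
}

#' Count overlapping non-bonded bead pairs
#'
#' Number of non-bonded pairs (|i - j| > 1) whose centers are closer than
#' `2 * bead_radius * (1 - tol)`. The spatial-grid scan is O(N); the
#' brute-force scan enumerates all pairs and serves as its oracle on
#' small chains.
#'
#' @param chain an `srev_chain`.
#' @param tol relative tolerance.
#' @param method `"grid"` (cell list) or `"brute"` (all pairs).
#' @return Integer count.
#' @export
count_overlaps <- function(chain, tol = 0,
                           method = c("grid", "brute")) {
  stopifnot(inherits(chain, "srev_chain"))
  method <- match.arg(method)
  pos <- chain$positions
  if (nrow(pos) < 3) return(0L)
  if (method == "grid")
    return(count_overlaps_grid_cpp(pos, chain$bead_radius, tol))
  d <- as.matrix(stats::dist(pos))
  thr <- 2 * chain$bead_radius * (1 - tol)
  idx <- which(d < thr & upper.tri(d), arr.ind = TRUE)
  sum(abs(idx[, 1] - idx[, 2]) > 1)
}

#' Relax a bead chain until all overlaps are resolved
#'
#' Low-temperature damped inertial descent (FIRE-style adaptive timestep)
#' on a soft repulsive potential between overlapping beads plus harmonic
#' bonds, terminated as soon as no non-bonded pair remains closer than
#' `2 * bead_radius * (1 - overlap_tol)`. Connectivity is never altered; beads leaving the
#' confinement sphere (radius `rc_confine` about the initial center of
#' mass) are reflected back. With `temperature_scale = 0` the descent is
#' deterministic and the recorded energy sequence is non-increasing.
#'
#' @param chain an `srev_chain` from [expand_overlaps()].
#' @param params an [relax_params()] object.
#' @param error_on_failure raise an error when `max_steps` is reached with
#'   overlaps remaining (default); otherwise warn and return the partially
#'   relaxed chain.
#' @return A relaxed `srev_chain` with updated positions, bond lengths,
#'   iteration count and energy trajectory.
#' @export
relax <- function(chain, params = relax_params(), error_on_failure = TRUE) {
  stopifnot(inherits(chain, "srev_chain"),
            inherits(params, "srev_relax_params"))
  pos <- chain$positions
  if (count_overlaps(chain, tol = params$overlap_tol) == 0L) {
    chain$relaxed <- TRUE
    return(chain)
  }
  rest <- pmax(chain$bond_lengths, 2 * chain$bead_radius)
  com0 <- colMeans(pos)
  # the generation cutoff is measured from the running center of mass, so
  # the finished walk may poke beyond rc about its final center; the
  # reflecting boundary must enclose the initial configuration
  rc_eff <- max(chain$params$rc_confine,
                sqrt(max(rowSums(sweep(pos, 2, com0)^2))) * 1.0001)
  res <- relax_cpp(pos, chain$bead_radius, rest, params$overlap_tol,
                   params$max_steps, params$repulsion_stiffness,
                   params$bond_stiffness, params$step_scale,
                   params$max_disp, params$temperature_scale,
                   rc_eff, com0)
  if (!res$converged) {
    msg <- sprintf(
      "relaxation did not converge: %d residual overlaps after %d steps",
      res$residual_overlaps, res$iterations)
    if (error_on_failure) stop(msg) else warning(msg)
  }
  out <- new_chain(res$positions, chain$bead_radius, chain$origin_vertex,
                   chain$params, relaxed = res$converged,
                   iterations = res$iterations, energy = res$energy)
  out
}

#' Generate one relaxed SR-EV configuration
#'
#' Convenience pipeline: [generate_walk()], [expand_overlaps()],
#' [relax()], [assign_linkers()].
#'
#' @param params an [srev_params()] object.
#' @param rparams an [relax_params()] object.
#' @return List with `chain` (relaxed `srev_chain`), `map`
#'   ([assign_linkers()] output) and `walk`.
#' @export
srev_configuration <- function(params, rparams = relax_params()) {
  walk <- generate_walk(params)
  chain <- relax(expand_overlaps(walk, jitter = rparams$jitter), rparams)
  list(chain = chain, map = assign_linkers(chain), walk = walk)
}

#' Generate an ensemble of SR-EV configurations
#'
#' Ensemble member `i` is generated with seed `base seed + i - 1`; all
#' other parameters are shared.
#'
#' @param n_configs number of configurations.
#' @param params an [srev_params()] object; its `seed` is the base seed.
#' @param rparams an [relax_params()] object.
#' @param keep_walks retain the raw walks (memory).
#' @return List of `srev_configuration()` results.
#' @export
srev_ensemble <- function(n_configs, params, rparams = relax_params(),
                          keep_walks = FALSE) {
  lapply(seq_len(n_configs), function(i) {
    p <- params
    p$seed <- params$seed + i - 1L
    cfg <- srev_configuration(p, rparams)
    if (!keep_walks) cfg$walk <- NULL
    cfg
  })
}

#' Export a bead chain as extended XYZ plus a bond table
#'
#' Writes `<path>` with one record per bead (`x y z bead_index
#' origin_vertex`) and `<path>.bonds.tsv` with the bond table
#' (`i, j, length_nm, linker_bp`).
#'
#' @param chain an `srev_chain`.
#' @param path output file.
#' @param map optional [assign_linkers()] output for the `linker_bp`
#'   column.
#' @return `path`, invisibly; `read_chain_xyz()` returns the chain.
#' @export
write_chain_xyz <- function(chain, path, map = NULL) {
  stopifnot(inherits(chain, "srev_chain"))
  pos <- chain$positions
  n <- nrow(pos)
  con <- file(path, "w")
  writeLines(c(as.character(n), "x y z bead_index origin_vertex"), con)
  df <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                   bead = seq_len(n), origin = chain$origin_vertex)
  write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  close(con)
  bonds <- data.frame(i = seq_len(n - 1), j = seq_len(n - 1) + 1L,
                      length_nm = chain$bond_lengths,
                      linker_bp = if (is.null(map)) NA_integer_
                                  else map$linker_bp)
  write.table(bonds, paste0(path, ".bonds.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(chain$params), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_chain_xyz
#' @export
read_chain_xyz <- function(path) {
  df <- read.table(path, skip = 2,
                   col.names = c("x", "y", "z", "bead", "origin"))
  pj <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  params <- srev_params(alpha = pj$alpha, n_beads = pj$n_beads,
                        rc_confine = pj$rc_confine,
                        unit_length = pj$unit_length,
                        local_cutoff = pj$local_cutoff,
                        bead_radius = pj$bead_radius, seed = pj$seed)
  new_chain(unname(as.matrix(df[, 1:3])), params$bead_radius, df$origin,
            params, relaxed = TRUE)
}
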