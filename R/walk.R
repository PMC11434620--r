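#' Return-step probability
#'
#' Probability that the walk retraces the last backbone segment of length
#' `U0` (in units of the minimum jump): \eqn{P_R(U_0) = U_0^{-\alpha} /
#' \alpha}. Long last segments are rarely retraced; the maximum,
#' \eqn{1/\alpha}, is attained at \eqn{U_0 = 1}.
#'
#' @param U0 length of the last backbone step, in units (>= 1).
#' @param alpha folding parameter (> 1).
#' @return Probability in (0, 1/alpha].
#' @examples
#' return_probability(1, 1.10)  # 1/1.1
#' return_probability(2, 1.10)
#' @export
return_probability <- function(U0, alpha) {
  if (any(U0 < 1)) stop("`U0` must be >= 1 (units of the minimum jump)")
  if (alpha <= 1) stop("`alpha` must be > 1")
  U0^(-alpha) / alpha
}

#' Sample heavy-tailed jump lengths
#'
#' Draws jump lengths from \eqn{P_J(U) = (\alpha + 1) U^{-\alpha - 2}},
#' \eqn{U \ge 1}, truncated at `local_cutoff`, by inverse-CDF with
#' rejection of draws beyond the cutoff (preserving the truncated pdf
#' shape). Lengths are in units of the minimum jump. Uses R's RNG.
#'
#' @param n number of draws.
#' @param alpha folding parameter (> 1).
#' @param local_cutoff maximum length in units (`Inf` for untruncated).
#' @return Numeric vector of lengths in `[1, local_cutoff]`.
#' @examples
#' set.seed(1)
#' mean(sample_jump_length(1e4, 1.10, Inf)) # ~ (alpha+1)/alpha = 1.909
#' @export
sample_jump_length <- function(n, alpha, local_cutoff = 30) {
  if (alpha <= 1) stop("`alpha` must be > 1")
  if (local_cutoff <= 1) stop("`local_cutoff` must be > 1")
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    u <- (1 - runif(length(need)))^(-1 / (alpha + 1))
    ok <- u <= local_cutoff
    out[need[ok]] <- u[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a self-returning random walk
#'
#' Builds an SRRW trajectory: at each step the walk either returns over
#' the previous backbone segment, with probability [return_probability()]
#' applied to that segment's length, or jumps in an isotropic random
#' direction with a length drawn from the truncated heavy-tailed pdf
#' (see [sample_jump_length()]). Jump candidates farther than
#' `rc_confine` from the center of mass of the already-generated vertices
#' are rejected and resampled (up to `max_attempts` times). Consecutive
#' returns walk back along the backbone; at the origin a jump is forced.
#'
#' @param params an [srev_params()] object.
#' @param max_attempts rejection-sampling cap per vertex.
#' @return An object of class `srev_walk`: list with `vertices` (N x 3
#'   matrix, nm), `step_types` (`"jump"`/`"return"`), `step_lengths`
#'   (units) and `params`.
#' @examples
#' w <- generate_walk(srev_params(1.15, n_beads = 500, rc_confine = 200))
#' return_fraction(w)
#' @export
generate_walk <- function(params, max_attempts = 10000L) {
  stopifnot(inherits(params, "srev_params"))
  set.seed(params$seed)
  raw <- srrw_generate_cpp(params$alpha, params$n_beads, params$rc_confine,
                           params$unit_length, params$local_cutoff,
                           as.integer(max_attempts))
  structure(
    list(vertices = raw$vertices,
         step_types = c("jump", "return")[raw$step_types],
         step_lengths = raw$step_lengths,
         params = params),
    class = "srev_walk")
}

#' @export
print.srev_walk <- function(x, ...) {
  cat(sprintf("SRRW walk: %d vertices, %.1f%% return steps (alpha = %.3f)\n",
              nrow(x$vertices), 100 * return_fraction(x), x$params$alpha))
  invisible(x)
}

#' Fraction of return steps
#'
#' @param walk an `srev_walk`.
#' @return Fraction of steps labeled `"return"`, in `[0, 1]`.
#' @export
return_fraction <- function(walk) {
  stopifnot(inherits(walk, "srev_walk"))
  if (!length(walk$step_types)) stop("walk has no steps")
  mean(walk$step_types == "return")
}

#' Export / import a walk as extended XYZ
#'
#' One record per vertex (`x y z step_type step_length_units`; the first
#' vertex carries `origin 0`), with the generation parameters in a JSON
#' sidecar (`<path>.json`).
#'
#' @param walk an `srev_walk`.
#' @param path output file.
#' @return `write_xyz()` returns `path` invisibly; `read_xyz()` the
#'   reconstructed `srev_walk`.
#' @export
write_xyz <- function(walk, path) {
  stopifnot(inherits(walk, "srev_walk"))
  v <- walk$vertices
  df <- data.frame(x = v[, 1], y = v[, 2], z = v[, 3],
                   step_type = c("origin", walk$step_types),
                   step_length = c(0, walk$step_lengths))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(v)), "x y z step_type step_length_units"),
             con)
  write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(walk$params), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  df <- read.table(path, skip = 2, col.names = c("x", "y", "z",
                                                 "step_type", "step_length"))
  pj <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  params <- srev_params(alpha = pj$alpha, n_beads = pj$n_beads,
                        rc_confine = pj$rc_confine,
                        unit_length = pj$unit_length,
                        local_cutoff = pj$local_cutoff,
                        bead_radius = pj$bead_radius, seed = pj$seed)
  structure(
    list(vertices = unname(as.matrix(df[, 1:3])),
         step_types = df$step_type[-1],
         step_lengths = df$step_length[-1],
         params = params),
    class = "srev_walk")
}
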