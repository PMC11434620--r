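# Shared fixtures, built in code and cached across test files.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, fun) {
  if (is.null(.fixtures[[key]])) assign(key, fun(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# A hand-built walk: `pairs` consecutive jump-and-return motifs from the
# origin followed by one forward jump, giving 2*pairs + 2 vertices of
# which the origin is visited pairs + 1 times.
star_walk <- function(pairs = 7, alpha = 1.15) {
  params <- srev_params(alpha, n_beads = 2 * pairs + 2, rc_confine = 200,
                        seed = 1)
  verts <- matrix(0, 2 * pairs + 2, 3)
  types <- character(2 * pairs + 1)
  lens <- numeric(2 * pairs + 1)
  set.seed(42)
  for (k in seq_len(pairs)) {
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    verts[2 * k, ] <- dir * 15          # jump out 1.5 units
    types[2 * k - 1] <- "jump"
    lens[2 * k - 1] <- 1.5
    types[2 * k] <- "return"            # back to the origin
    lens[2 * k] <- 1.5
  }
  verts[2 * pairs + 2, ] <- c(30, 0, 0)
  types[2 * pairs + 1] <- "jump"
  lens[2 * pairs + 1] <- 3
  structure(list(vertices = verts, step_types = types,
                 step_lengths = lens, params = params),
            class = "srev_walk")
}

# A chain at given positions, for geometry oracles.
chain_at <- function(positions, rc = 1e4, bead_radius = 4.9) {
  params <- srev_params(1.15, n_beads = max(2L, nrow(positions)),
                        rc_confine = rc, bead_radius = bead_radius)
  srev:::new_chain(positions, bead_radius, seq_len(nrow(positions)),
                   params, relaxed = TRUE)
}

# Small relaxed SR-EV configuration, shared across files.
small_srev <- function(alpha = 1.15, phi = 0.12, rc = 120, seed = 7) {
  cached(sprintf("cfg_%s_%s_%s_%s", alpha, phi, rc, seed), function()
    srev_configuration(srev_params(alpha, phi = phi, rc_confine = rc,
                                   seed = seed)))
}

# Reduced-size ensemble, shared across files.
small_ensemble <- function(n, alpha, phi, rc, seed = 100) {
  cached(sprintf("ens_%d_%s_%s_%s_%d", n, alpha, phi, rc, seed), function()
    srev_ensemble(n, srev_params(alpha, phi = phi, rc_confine = rc,
                                 seed = seed)))
}
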