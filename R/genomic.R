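#' Map a bead chain to genomic coordinates
#'
#' Each bead carries 147 bp (the DNA wrapping one nucleosome). Bonds
#' longer than the effective bead diameter of 9.8 nm carry linker DNA:
#' the nearest integer of `(U - 9.8 nm) / 0.34 nm` base pairs, with
#' 0.34 nm the rise per base pair; shorter bonds carry none. By default
#' the rule is applied to the post-relaxation bond lengths of the SR-EV
#' configuration; `use_initial_lengths = TRUE` applies it to the
#' pre-relaxation lengths for sensitivity analysis (requires an
#' unrelaxed chain's lengths stored by the caller).
#'
#' @param chain an `srev_chain` (relaxed).
#' @param bond_lengths optional explicit bond lengths (nm) overriding the
#'   chain's own (e.g. pre-relaxation SRRW step lengths).
#' @param nucleosome_bp base pairs per bead.
#' @param contact_nm bond length carrying zero linker (nm).
#' @param bp_rise DNA rise per base pair (nm).
#' @return An object of class `srev_genomic_map`: list with `linker_bp`
#'   (per bond), `cumulative_bp` (per bead, starting at 0) and
#'   `nucleosome_bp`.
#' @examples
#' # a 20 nm bond carries round((20 - 9.8)/0.34) = 30 bp of linker
#' @export
assign_linkers <- function(chain, bond_lengths = NULL,
                           nucleosome_bp = 147L, contact_nm = 9.8,
                           bp_rise = 0.34) {
  stopifnot(inherits(chain, "srev_chain"))
  u <- if (is.null(bond_lengths)) chain$bond_lengths else bond_lengths
  if (any(u < 0)) stop("negative bond length")
  linker <- ifelse(u > contact_nm, round((u - contact_nm) / bp_rise), 0L)
  linker <- as.integer(linker)
  cumulative <- c(0, cumsum(nucleosome_bp + linker))
  structure(
    list(linker_bp = linker, cumulative_bp = cumulative,
         nucleosome_bp = as.integer(nucleosome_bp)),
    class = "srev_genomic_map")
}

#' @export
print.srev_genomic_map <- function(x, ...) {
  n <- length(x$cumulative_bp)
  cat(sprintf(
    "Genomic map: %d nucleosomes, %.0f bp total, mean linker %.1f bp\n",
    n, total_bp(x), mean(x$linker_bp)))
  invisible(x)
}

#' Total genomic length of a map (bp)
#'
#' @param map an `srev_genomic_map`.
#' @export
total_bp <- function(map) {
  map$nucleosome_bp * length(map$cumulative_bp) + sum(map$linker_bp)
}

#' Genomic separation between two beads
#'
#' Absolute difference of the beads' cumulative genomic positions
#' (position of each bead's first base pair).
#'
#' @param map an `srev_genomic_map`.
#' @param i,j bead indices (vectorized).
#' @return Separation(s) in bp.
#' @export
genomic_separation <- function(map, i, j) {
  n <- length(map$cumulative_bp)
  if (any(i < 1 | i > n | j < 1 | j > n)) stop("bead index out of range")
  abs(map$cumulative_bp[j] - map$cumulative_bp[i])
}

#' Export bead coordinates with genomic annotation as TSV
#'
#' Columns: `bead_index, x, y, z, cumulative_bp`.
#'
#' @param chain an `srev_chain`.
#' @param map matching `srev_genomic_map`.
#' @param path output file.
#' @export
write_genomic_tsv <- function(chain, map, path) {
  pos <- chain$positions
  df <- data.frame(bead_index = seq_len(nrow(pos)), x = pos[, 1],
                   y = pos[, 2], z = pos[, 3],
                   cumulative_bp = map$cumulative_bp)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
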