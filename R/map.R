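#' Haldane map function
#'
#' Converts map distance (Morgans) to recombination fraction assuming no
#' crossover interference: r = (1 - exp(-2d)) / 2.
#'
#' @param d map distance in Morgans (vector ok, d >= 0).
#' @return recombination fraction in \[0, 0.5).
#' @export
haldane <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative")
  0.5 * (1 - exp(-2 * d))
}

#' Build a linkage map from physical marker positions
#'
#' Each chromosome is assigned a fixed genetic length (default 1 Morgan) and
#' marker positions are mapped linearly from base pairs onto it. Recombination
#' fractions between adjacent markers use the Haldane function.
#'
#' @param chrom integer vector: chromosome of each marker.
#' @param pos_bp numeric vector of physical positions, sorted and unique
#'   within each chromosome. `NULL` spaces markers evenly.
#' @param chrom_length_morgans genetic length per chromosome (Morgans).
#' @return object of class `linkage_map`: `chrom`, `pos` (Morgans) and
#'   `interval_r` (length L; entry l = recombination fraction between markers
#'   l and l+1, NA at chromosome boundaries and for the last marker).
#' @export
build_linkage_map <- function(chrom, pos_bp = NULL, chrom_length_morgans = 1) {
  chrom <- as.integer(chrom)
  L <- length(chrom)
  if (L < 1L) stop("need at least one marker")
  if (is.unsorted(chrom)) stop("markers must be grouped by chromosome")
  pos <- numeric(L)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    if (is.null(pos_bp)) {
      pos[idx] <- if (length(idx) == 1L) chrom_length_morgans / 2 else
        seq(0, chrom_length_morgans, length.out = length(idx))
    } else {
      bp <- pos_bp[idx]
      if (is.unsorted(bp, strictly = TRUE))
        stop(sprintf("chromosome %d: physical positions must be strictly increasing", cc))
      rng <- range(bp)
      pos[idx] <- if (diff(rng) == 0) chrom_length_morgans / 2 else
        chrom_length_morgans * (bp - rng[1]) / diff(rng)
    }
  }
  interval_r <- rep(NA_real_, L)
  same <- which(chrom[-L] == chrom[-1])
  interval_r[same] <- haldane(pos[same + 1L] - pos[same])
  structure(list(chrom = chrom, pos = pos, interval_r = interval_r,
                 chrom_length = chrom_length_morgans),
            class = "linkage_map")
}

#' @export
print.linkage_map <- function(x, ...) {
  cat(sprintf("<linkage_map> %d markers on %d chromosome(s), %g M each\n",
              length(x$chrom), length(unique(x$chrom)), x$chrom_length))
  invisible(x)
}

# marker indices per chromosome, in map order
map_chrom_index <- function(map) split(seq_along(map$chrom), map$chrom)
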