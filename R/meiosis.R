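# Row-wise meiosis: row i of the output is one gamete sampled from the
# diplotype (H0[i, ], H1[i, ]). No interference: the transmitted haplotype
# starts uniformly per chromosome and switches at each within-chromosome
# interval independently with its Haldane recombination fraction.
meiosis_matrix <- function(H0, H1, map) {
  n <- nrow(H0); L <- ncol(H0)
  gam <- matrix(0L, n, L)
  for (idx in map_chrom_index(map)) {
    state <- stats::runif(n) < 0.5   # TRUE -> transmit hap1 at this marker
    l1 <- idx[1L]
    gam[, l1] <- ifelse(state, H1[, l1], H0[, l1])
    if (length(idx) > 1L) {
      for (k in 2L:length(idx)) {
        r <- map$interval_r[idx[k - 1L]]
        state <- xor(state, stats::runif(n) < r)
        l <- idx[k]
        gam[, l] <- ifelse(state, H1[, l], H0[, l])
      }
    }
  }
  gam
}

#' Sample one gamete from an individual
#'
#' @param pop a `phased_pop`.
#' @param i individual index.
#' @param map a `linkage_map`.
#' @param seed optional integer seed (RNG state restored afterwards).
#' @return integer 0/1 vector of length L.
#' @export
meiosis_gamete <- function(pop, i, map, seed = NULL) {
  with_seed(seed, drop(meiosis_matrix(pop$hap0[i, , drop = FALSE],
                                      pop$hap1[i, , drop = FALSE], map)))
}

#' Cross two individuals
#'
#' Each progeny receives one independent gamete from each parent.
#'
#' @param popA,popB `phased_pop`s holding the parents (same markers).
#' @param i,j parent indices within `popA` / `popB`.
#' @param map a `linkage_map`.
#' @param n_progeny number of progeny (default 15, one crossing pair's output).
#' @param seed optional seed.
#' @param generation tag for the progeny cohort.
#' @return a `phased_pop` of `n_progeny` individuals.
#' @export
cross <- function(popA, i, popB, j, map, n_progeny = 15, seed = NULL,
                  generation = "cross") {
  if (n_markers(popA) != n_markers(popB))
    stop("parents must share the same marker set")
  with_seed(seed, {
    rep_row <- function(v, n) matrix(v, n, length(v), byrow = TRUE)
    g0 <- meiosis_matrix(rep_row(popA$hap0[i, ], n_progeny),
                         rep_row(popA$hap1[i, ], n_progeny), map)
    g1 <- meiosis_matrix(rep_row(popB$hap0[j, ], n_progeny),
                         rep_row(popB$hap1[j, ], n_progeny), map)
    phased_pop(g0, g1, generation = generation)
  })
}

# Self every row of a population once: each individual is replaced by one
# offspring formed from two independent gametes of itself.
self_once_matrix <- function(hap0, hap1, map) {
  list(hap0 = meiosis_matrix(hap0, hap1, map),
       hap1 = meiosis_matrix(hap0, hap1, map))
}

#' Advance an individual to inbred lines by single-seed descent
#'
#' The first selfing produces `n_first` independent S1 progeny; each lineage is
#' then advanced by `n_self - 1` further selfing generations, keeping one
#' random seed per lineage per generation. With the defaults this yields 50
#' Inbred8 lines (7 rounds of selfing in total), fixing > 99% of loci.
#'
#' @param pop a `phased_pop`; `i` index of the individual to advance.
#' @param map a `linkage_map`.
#' @param n_self total number of selfing generations (default 7).
#' @param n_first progeny kept from the first selfing (default 50).
#' @param seed optional seed.
#' @return a `phased_pop` of `n_first` inbred lines.
#' @export
self_ssd <- function(pop, i, map, n_self = 7, n_first = 50, seed = NULL) {
  if (n_self == 0) {
    warning("n_self = 0: returning unselfed copies of the input")
    k <- rep(i, n_first)
    return(phased_pop(pop$hap0[k, , drop = FALSE], pop$hap1[k, , drop = FALSE],
                      generation = "unselfed"))
  }
  with_seed(seed, {
    h0 <- matrix(pop$hap0[i, ], n_first, n_markers(pop), byrow = TRUE)
    h1 <- matrix(pop$hap1[i, ], n_first, n_markers(pop), byrow = TRUE)
    for (g in seq_len(n_self)) {
      nxt <- self_once_matrix(h0, h1, map)
      h0 <- nxt$hap0; h1 <- nxt$hap1
    }
    phased_pop(h0, h1, generation = sprintf("inbred%d", n_self + 1L))
  })
}
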