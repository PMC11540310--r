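#' Phased population container
#'
#' Holds a set of diploid individuals as two haplotype matrices over the same
#' L biallelic markers. Alleles are coded 0/1; the marker score used throughout
#' the package is `x = hap0 + hap1 - 1`, taking values -1, 0, 1.
#'
#' @param hap0,hap1 integer matrices (individuals x markers) with entries 0/1.
#' @param ids character vector of individual labels (default `ind1..indN`).
#' @param generation free-form tag describing how the cohort arose.
#' @return An object of class `phased_pop`.
#' @export
phased_pop <- function(hap0, hap1, ids = NULL, generation = "unknown") {
  hap0 <- as.matrix(hap0); hap1 <- as.matrix(hap1)
  storage.mode(hap0) <- "integer"; storage.mode(hap1) <- "integer"
  if (!identical(dim(hap0), dim(hap1)))
    stop("hap0 and hap1 must have identical dimensions")
  if (length(hap0) && (any(hap0 < 0L | hap0 > 1L) || any(hap1 < 0L | hap1 > 1L)))
    stop("haplotype alleles must be coded 0/1")
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(hap0)))
  if (length(ids) != nrow(hap0)) stop("ids length must match individual count")
  structure(list(hap0 = hap0, hap1 = hap1, ids = as.character(ids),
                 generation = generation),
            class = "phased_pop")
}

#' Number of individuals / markers in a population
#' @param pop a `phased_pop`.
#' @return integer count.
#' @export
n_ind <- function(pop) nrow(pop$hap0)

#' @rdname n_ind
#' @export
n_markers <- function(pop) ncol(pop$hap0)

#' Marker score matrix
#'
#' @param pop a `phased_pop`.
#' @return integer matrix (individuals x markers) with entries -1/0/1.
#' @export
score_matrix <- function(pop) {
  x <- pop$hap0 + pop$hap1 - 1L
  rownames(x) <- pop$ids
  x
}

#' Per-individual heterozygosity
#'
#' Fraction of loci at which the two haplotypes differ.
#'
#' @param pop a `phased_pop`.
#' @return list with `per_ind` (numeric vector in \[0, 1\]) and `mean`.
#' @export
heterozygosity <- function(pop) {
  per <- rowMeans(pop$hap0 != pop$hap1)
  names(per) <- pop$ids
  list(per_ind = per, mean = mean(per))
}

#' Subset individuals of a population
#' @param pop a `phased_pop`.
#' @param idx integer or logical index over individuals.
#' @return a `phased_pop`.
#' @export
subset_pop <- function(pop, idx) {
  phased_pop(pop$hap0[idx, , drop = FALSE], pop$hap1[idx, , drop = FALSE],
             ids = pop$ids[idx], generation = pop$generation)
}

#' Combine populations sharing the same markers
#' @param ... `phased_pop` objects with equal marker counts.
#' @param generation tag for the combined cohort.
#' @return a `phased_pop`.
#' @export
bind_pops <- function(..., generation = "combined") {
  ps <- list(...)
  L <- unique(vapply(ps, n_markers, 1L))
  if (length(L) != 1L) stop("populations must share the same markers")
  phased_pop(do.call(rbind, lapply(ps, `[[`, "hap0")),
             do.call(rbind, lapply(ps, `[[`, "hap1")),
             ids = unlist(lapply(ps, `[[`, "ids")), generation = generation)
}

#' @export
print.phased_pop <- function(x, ...) {
  cat(sprintf("<phased_pop> %d individuals x %d markers (%s); mean het %.4f\n",
              n_ind(x), n_markers(x), x$generation, heterozygosity(x)$mean))
  invisible(x)
}
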