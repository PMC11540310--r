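#' Synthetic founder panel
#'
#' Generates a diverse panel of inbred accessions as a stand-in for a real
#' resequenced germplasm collection. Each accession haplotype is a mosaic of
#' ancestral haplotypes (segment lengths approximately exponential with mean
#' `segment_length_morgans`), and accessions are assigned to four
#' subpopulations with subpopulation-biased ancestral donors, so the panel
#' carries block LD and k-means-detectable structure. Accessions are fully
#' inbred (hap0 == hap1). Markers failing the MAF floor are re-drawn (new
#' ancestral alleles at that site, mosaic kept) until all pass.
#'
#' @param n_accessions panel size (default 198).
#' @param n_chrom chromosomes (default 20), `snp_per_chrom` markers each.
#' @param snp_per_chrom markers per chromosome before any subsampling.
#' @param n_ancestral_haplotypes number of ancestral haplotypes (>= 4).
#' @param segment_length_morgans mean mosaic segment length (Morgans).
#' @param maf_min minor-allele-frequency floor (default 0.1).
#' @param seed integer seed; same seed gives an identical panel.
#' @param max_retries rounds of re-drawing failing markers before erroring.
#' @return a `founder_panel`: `pop` (`phased_pop`), `chrom`, `pos_bp`,
#'   `provenance`.
#' @export
generate_founders <- function(n_accessions = 198, n_chrom = 20,
                              snp_per_chrom = 200,
                              n_ancestral_haplotypes = 8,
                              segment_length_morgans = 0.25,
                              maf_min = 0.1, seed = NULL, max_retries = 50) {
  if (n_ancestral_haplotypes < 4)
    stop("need at least 4 ancestral haplotypes for a structured panel")
  L <- n_chrom * snp_per_chrom
  chrom <- rep(seq_len(n_chrom), each = snp_per_chrom)
  pos_bp <- rep(round(seq(1e4, 1e6, length.out = snp_per_chrom)), n_chrom)
  with_seed(seed, {
    nanc <- n_ancestral_haplotypes
    p_anc <- stats::runif(L, 0.15, 0.85)
    anc <- matrix(stats::rbinom(nanc * L, 1L, rep(p_anc, each = nanc)), nanc, L)
    # 4 subpopulations, each biased toward its own ancestral donors
    subpop <- rep_len(1:4, n_accessions)
    donor_group <- rep_len(1:4, nanc)
    d_morg <- 1 / (snp_per_chrom - 1)          # even spacing on 1 Morgan
    p_switch <- 1 - exp(-d_morg / segment_length_morgans)
    donors <- matrix(0L, n_accessions, L)
    for (a in seq_len(n_accessions)) {
      w <- ifelse(donor_group == subpop[a], 0.85, 0.15 / 3)
      w <- w / sum(w)
      for (cc in seq_len(n_chrom)) {
        idx <- which(chrom == cc)
        cur <- sample.int(nanc, 1L, prob = w)
        for (k in seq_along(idx)) {
          if (k > 1L && stats::runif(1) < p_switch)
            cur <- sample.int(nanc, 1L, prob = w)
          donors[a, idx[k]] <- cur
        }
      }
    }
    hap <- matrix(anc[cbind(as.vector(donors), rep(seq_len(L), each = n_accessions))],
                  n_accessions, L)
    maf <- function(h) { p <- colMeans(h); pmin(p, 1 - p) }
    for (try in seq_len(max_retries)) {
      bad <- which(maf(hap) < maf_min)
      if (!length(bad)) break
      # fresh ancestral alleles at failing sites; mosaic assignment unchanged
      for (l in bad) {
        anc[, l] <- stats::rbinom(nanc, 1L, stats::runif(1, 0.3, 0.7))
        hap[, l] <- anc[cbind(donors[, l], l)]
      }
    }
    if (any(maf(hap) < maf_min))
      stop("could not satisfy the MAF floor after bounded retries")
    structure(list(pop = phased_pop(hap, hap,
                                    ids = sprintf("acc%03d", seq_len(n_accessions)),
                                    generation = "founder"),
                   chrom = chrom, pos_bp = pos_bp, provenance = "synthetic"),
              class = "founder_panel")
  })
}

#' @export
print.founder_panel <- function(x, ...) {
  cat(sprintf("<founder_panel> %d accessions x %d markers on %d chromosomes (%s)\n",
              n_ind(x$pop), n_markers(x$pop), length(unique(x$chrom)),
              x$provenance))
  invisible(x)
}

panel_keep_markers <- function(panel, keep) {
  structure(list(pop = phased_pop(panel$pop$hap0[, keep, drop = FALSE],
                                  panel$pop$hap1[, keep, drop = FALSE],
                                  ids = panel$pop$ids,
                                  generation = panel$pop$generation),
                 chrom = panel$chrom[keep], pos_bp = panel$pos_bp[keep],
                 provenance = panel$provenance),
            class = "founder_panel")
}

#' Marker filtering: LD pruning then MAF floor
#'
#' Greedy left-to-right pruning within a sliding window on each chromosome:
#' when a retained earlier marker and a later marker have squared correlation
#' (r^2 of score columns) at or above `ld_r2_max`, the later marker is
#' dropped. Markers below the MAF floor are then removed.
#'
#' @param panel a `founder_panel` with complete genotypes.
#' @param maf_min MAF floor (default 0.1).
#' @param ld_r2_max r^2 threshold (default 0.6): pairs below it are kept.
#' @param window sliding window size in markers (default 50).
#' @return filtered `founder_panel` (marker order preserved).
#' @export
filter_markers <- function(panel, maf_min = 0.1, ld_r2_max = 0.6, window = 50) {
  X <- score_matrix(panel$pop)
  L <- ncol(X)
  keep <- rep(TRUE, L)
  for (idx in split(seq_len(L), panel$chrom)) {
    kept <- integer(0)
    for (l in idx) {
      recent <- kept[kept >= l - window]
      drop <- FALSE
      if (length(recent)) {
        sl <- stats::sd(X[, l])
        if (sl > 0) {
          for (m in recent) {
            sm <- stats::sd(X[, m])
            if (sm > 0 && stats::cor(X[, l], X[, m])^2 >= ld_r2_max) {
              drop <- TRUE; break
            }
          }
        }
      }
      if (drop) keep[l] <- FALSE else kept <- c(kept, l)
    }
  }
  p <- colMeans(X + 1L) / 2
  keep <- keep & pmin(p, 1 - p) >= maf_min
  if (!any(keep)) stop("no markers survive filtering")
  panel_keep_markers(panel, which(keep))
}

#' Random per-chromosome marker subsample
#'
#' @param panel a `founder_panel`.
#' @param per_chrom markers to keep per chromosome (default 200).
#' @param seed optional seed.
#' @return subsampled `founder_panel`; surviving markers keep their order.
#' @export
subsample_markers <- function(panel, per_chrom = 200, seed = NULL) {
  with_seed(seed, {
    keep <- unlist(lapply(split(seq_along(panel$chrom), panel$chrom), function(idx) {
      if (length(idx) < per_chrom)
        stop("chromosome has fewer markers than requested")
      sort(sample(idx, per_chrom))
    }), use.names = FALSE)
    panel_keep_markers(panel, keep)
  })
}

#' Choose four founder parents by k-means clustering
#'
#' Clusters accessions on their raw -1/0/1 marker scores (Euclidean k-means,
#' `n_restarts` restarts) and returns, within each cluster, the accession with
#' the highest true genotypic value (ties -> lowest index).
#'
#' @param panel a `founder_panel`.
#' @param u true genotypic values, one per accession.
#' @param k number of clusters (default 4).
#' @param seed optional seed.
#' @param n_restarts k-means restarts (default 10).
#' @return integer vector of `k` accession indices (one per cluster).
#' @export
select_founder_parents <- function(panel, u, k = 4, seed = NULL,
                                   n_restarts = 10) {
  X <- score_matrix(panel$pop)
  if (length(u) != nrow(X)) stop("u must have one value per accession")
  with_seed(seed, {
    km <- NULL
    for (try in 1:10) {
      km <- tryCatch(stats::kmeans(X, centers = k, nstart = n_restarts,
                                   iter.max = 100),
                     error = function(e) NULL)
      if (!is.null(km) && length(unique(km$cluster)) == k) break
      km <- NULL
    }
    if (is.null(km)) stop("k-means failed to produce k non-empty clusters")
    vapply(seq_len(k), function(cl) {
      members <- which(km$cluster == cl)
      members[which.max(u[members])]
    }, 1L)
  })
}

#' Initial population from a four-way cross
#'
#' F1a = P1 x P2 and F1b = P3 x P4 are crossed to give `n` individuals mixing
#' the four founder genomes.
#'
#' @param panel a `founder_panel`.
#' @param parents integer vector of 4 distinct accession indices.
#' @param map a `linkage_map` over the panel's markers.
#' @param n population size (default 150).
#' @param seed optional seed.
#' @return a `phased_pop` of `n` individuals.
#' @export
make_initial_population <- function(panel, parents, map, n = 150, seed = NULL) {
  if (length(parents) != 4 || anyDuplicated(parents))
    stop("need 4 distinct founder parents")
  with_seed(seed, {
    f1a <- cross(panel$pop, parents[1], panel$pop, parents[2], map, 1,
                 generation = "F1")
    f1b <- cross(panel$pop, parents[3], panel$pop, parents[4], map, 1,
                 generation = "F1")
    cross(f1a, 1, f1b, 1, map, n, generation = "initial")
  })
}
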