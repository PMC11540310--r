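#' Selection intensity for choosing the single best of a pool
#'
#' The package's usefulness criteria multiply the progeny standard deviation
#' by the standard-normal quantile at 1 - 1/pool_size (the expected rank
#' position of the maximum): 750 -> 3.004, 50 -> 2.054. The classical
#' truncation intensity phi(z)/p is exposed as an alternative.
#'
#' @param pool_size number of inbred progeny the best one is picked from.
#' @param method "quantile" (default, matches the constants above) or
#'   "truncation" (phi(z)/p with p = 1/pool_size).
#' @return selection intensity (scalar).
#' @export
selection_intensity <- function(pool_size, method = c("quantile", "truncation")) {
  if (pool_size < 2) stop("pool_size must be at least 2")
  method <- match.arg(method)
  p <- 1 / pool_size
  z <- stats::qnorm(1 - p)
  switch(method, quantile = z, truncation = stats::dnorm(z) / p)
}

# Closed-form coefficients of the two-locus selfing recursion.
#
# Track D_t = E[mean within-haplotype sign product] and C_t = E[mean
# cross-haplotype sign product] for a pair of loci with recombination
# fraction r. Selfing gives the linear recursion
#   D' = (1-r) D + r C,   C' = (D + C)/2,
# with eigenvalues 1 and lambda = (1-2r)/2. After n selfings,
#   E[x_l x_m] = alpha(r, n) D_0 + gamma(r, n) C_0,
# with the closed forms below (x is the -1/0/1 marker score). Between
# chromosomes (r = 1/2 and independent assortment) the covariance is exactly
# zero and is never computed.
selfing_pair_coef <- function(r, n_self) {
  lam <- (1 - 2 * r) / 2
  ln <- lam^n_self
  denom <- 2 * (1 + 2 * r)
  list(alpha = (2 + (2 * r - 1) * ln) / denom,
       gamma = (4 * r + (1 - 2 * r) * ln) / denom)
}

#' Exact two-locus moments of inbred progeny
#'
#' Explicit 16-state diplotype Markov chain over one pair of loci: the
#' founding two-locus diplotype distribution (gamete x gamete for a cross,
#' the individual's own diplotype for selfing) is advanced through `n_self`
#' selfing transitions, and the mean scores and their covariance are read off
#' the final distribution. This is the reference implementation; the
#' vectorized engine ([cross_inbred_sigma2()]) uses the equivalent closed
#' form of the same recursion.
#'
#' @param hapA0,hapA1 parent A's alleles (0/1 length-2 vectors) at loci (l, m).
#' @param hapB0,hapB1 parent B's alleles; ignored when
#'   `initial_cross = FALSE`.
#' @param r recombination fraction between the loci, in \[0, 0.5\].
#' @param n_self selfing generations after founding (default 7 -> Inbred8).
#' @param initial_cross if TRUE the founding diplotype is (gamete from A,
#'   gamete from B); if FALSE it is A's own diplotype (selfing an individual).
#' @return list `E_xl`, `E_xm`, `cov`.
#' @export
pair_inbred_moments <- function(hapA0, hapA1, hapB0 = NULL, hapB1 = NULL,
                                r, n_self = 7, initial_cross = TRUE) {
  if (r < 0 || r > 0.5) stop("recombination fraction must lie in [0, 0.5]")
  # haplotypes over 2 loci encoded 1..4 as (a_l, a_m) = (h %/% 2, h %% 2) of h-1
  enc <- function(al, am) 2L * al + am + 1L
  al_of <- c(0L, 0L, 1L, 1L); am_of <- c(0L, 1L, 0L, 1L)
  gamete_dist <- function(h0, h1) {
    g <- numeric(4)
    g[enc(al_of[h0], am_of[h0])] <- g[enc(al_of[h0], am_of[h0])] + (1 - r) / 2
    g[enc(al_of[h1], am_of[h1])] <- g[enc(al_of[h1], am_of[h1])] + (1 - r) / 2
    g[enc(al_of[h0], am_of[h1])] <- g[enc(al_of[h0], am_of[h1])] + r / 2
    g[enc(al_of[h1], am_of[h0])] <- g[enc(al_of[h1], am_of[h0])] + r / 2
    g
  }
  # states: ordered diplotypes (h0, h1), index = 4 * (h0 - 1) + h1
  TT <- matrix(0, 16, 16)
  for (h0 in 1:4) for (h1 in 1:4) {
    g <- gamete_dist(h0, h1)
    TT[4L * (h0 - 1L) + h1, ] <- as.vector(outer(g, g))
  }
  hA0 <- enc(hapA0[1], hapA0[2]); hA1 <- enc(hapA1[1], hapA1[2])
  p0 <- numeric(16)
  if (initial_cross) {
    gA <- gamete_dist(hA0, hA1)
    gB <- gamete_dist(enc(hapB0[1], hapB0[2]), enc(hapB1[1], hapB1[2]))
    p0 <- as.vector(outer(gA, gB))
  } else {
    p0[4L * (hA0 - 1L) + hA1] <- 1
  }
  p <- p0
  for (g in seq_len(n_self)) p <- drop(p %*% TT)
  h0s <- rep(1:4, each = 4); h1s <- rep(1:4, times = 4)
  xl <- al_of[h0s] + al_of[h1s] - 1
  xm <- am_of[h0s] + am_of[h1s] - 1
  E_xl <- sum(p * xl); E_xm <- sum(p * xm)
  list(E_xl = E_xl, E_xm = E_xm, cov = sum(p * xl * xm) - E_xl * E_xm)
}

#' Precompute the progeny-variance engine for a fixed map and effect vector
#'
#' Builds, per chromosome, the pairwise weight matrices that let the Inbred8
#' progeny variance of every cross (or of every selfed individual) be
#' evaluated with a handful of matrix products. Recombination fractions
#' between all within-chromosome marker pairs come from the Haldane function;
#' between-chromosome covariances are exactly zero and are skipped.
#'
#' @param map a `linkage_map`.
#' @param beta_hat marker effect vector (length L).
#' @param n_self selfing generations (default 7 -> Inbred8).
#' @return object of class `uc_engine`.
#' @export
build_variance_engine <- function(map, beta_hat, n_self = 7) {
  if (length(beta_hat) != length(map$chrom))
    stop("beta_hat length must match the map")
  chroms <- lapply(map_chrom_index(map), function(idx) {
    pos <- map$pos[idx]
    r <- haldane(abs(outer(pos, pos, "-")))
    cf <- selfing_pair_coef(r, n_self)
    B <- outer(beta_hat[idx], beta_hat[idx])
    list(idx = idx,
         Wd = B * cf$alpha * (1 - r),   # within-gamete, non-recombinant part
         Wc = B * cf$alpha * r,         # within-gamete, recombinant part
         Wg = B * cf$gamma,             # cross-gamete part
         Wb = B)                        # mean-product correction
  })
  structure(list(chroms = chroms, n_self = n_self, L = length(beta_hat)),
            class = "uc_engine")
}

#' Inbred-progeny GEBV variance for all crosses at once
#'
#' For cross A x B the founding moments of the selfing recursion are
#' D0 = \[(1-r)(dA + dB) + r(cA + cB)\] / 2 and
#' C0 = (mA_l mB_m + mB_l mA_m) / 2, with d, c, m the within-/cross-haplotype
#' sign products and haplotype means of each parent; E\[x_l\] = (mA + mB)/2
#' is conserved by meiosis and selfing. Everything reduces to per-individual
#' quadratic forms plus one N x N cross-product matrix, so the full
#' N(N-1)/2 candidate set is evaluated in a few matrix products.
#'
#' @param pop a `phased_pop` of N candidates.
#' @param engine a [build_variance_engine()] result.
#' @return symmetric N x N matrix; entry (i, j) is the Inbred8 progeny GEBV
#'   variance of cross i x j (diagonal not meaningful).
#' @export
engine_sigma2_cross_all <- function(pop, engine) {
  if (n_markers(pop) != engine$L) stop("marker sets do not match the engine")
  N <- n_ind(pop)
  S0 <- 2 * pop$hap0 - 1; S1 <- 2 * pop$hap1 - 1
  M <- (S0 + S1) / 2
  q <- numeric(N)
  PQ <- matrix(0, N, N)
  for (ch in engine$chroms) {
    s0 <- S0[, ch$idx, drop = FALSE]; s1 <- S1[, ch$idx, drop = FALSE]
    m <- M[, ch$idx, drop = FALSE]
    dterm <- (rowSums((s0 %*% ch$Wd) * s0) + rowSums((s1 %*% ch$Wd) * s1)) / 2
    cterm <- rowSums((s0 %*% ch$Wc) * s1)      # = sum Wc o c_A by symmetry
    mterm <- rowSums((m %*% ch$Wb) * m)
    q <- q + dterm / 2 + cterm / 2 - mterm / 4
    PQ <- PQ + m %*% ch$Wg %*% t(m) - (m %*% ch$Wb %*% t(m)) / 2
  }
  sig2 <- outer(q, q, "+") + PQ
  pmax(sig2, 0)
}

#' Inbred-progeny GEBV variance for selfing every individual
#'
#' Same engine with the founding state set to each individual's own
#' diplotype: sigma_i^2 = sum (B alpha) o d_i + sum (B gamma) o c_i -
#' m' B m.
#'
#' @inheritParams engine_sigma2_cross_all
#' @return numeric vector of length N.
#' @export
engine_sigma2_self_all <- function(pop, engine) {
  if (n_markers(pop) != engine$L) stop("marker sets do not match the engine")
  S0 <- 2 * pop$hap0 - 1; S1 <- 2 * pop$hap1 - 1
  M <- (S0 + S1) / 2
  sig2 <- numeric(n_ind(pop))
  for (ch in engine$chroms) {
    s0 <- S0[, ch$idx, drop = FALSE]; s1 <- S1[, ch$idx, drop = FALSE]
    m <- M[, ch$idx, drop = FALSE]
    Wa <- ch$Wd + ch$Wc                        # = B * alpha
    sig2 <- sig2 +
      (rowSums((s0 %*% Wa) * s0) + rowSums((s1 %*% Wa) * s1)) / 2 +
      rowSums((s0 %*% ch$Wg) * s1) -
      rowSums((m %*% ch$Wb) * m)
  }
  pmax(sig2, 0)
}

#' Mean and Inbred8 variance for one cross
#'
#' The cross's Inbred8 progeny mean is the parental GEBV mean and its exact
#' GEBV variance comes from the closed-form selfing-chain engine.
#'
#' @param pop a `phased_pop` holding both parents.
#' @param i,j parent indices.
#' @param map a `linkage_map`.
#' @param beta_hat marker effect vector.
#' @param n_self selfing generations after the cross (default 7).
#' @param engine optional prebuilt [build_variance_engine()] result.
#' @return list of class `cross_moments`: `mu`, `sigma2`, `sigma`.
#' @export
cross_inbred_sigma2 <- function(pop, i, j, map, beta_hat, n_self = 7,
                                engine = NULL) {
  if (is.null(engine)) engine <- build_variance_engine(map, beta_hat, n_self)
  pair <- subset_pop(pop, c(i, j))
  sig2 <- engine_sigma2_cross_all(pair, engine)[1, 2]
  g <- gebv(score_matrix(pair), beta_hat)
  structure(list(mu = mean(g), sigma2 = sig2, sigma = sqrt(sig2)),
            class = "cross_moments")
}

#' Mean and Inbred8 variance for selfing one individual
#'
#' @inheritParams cross_inbred_sigma2
#' @param i individual index.
#' @return list of class `cross_moments`: `mu` (the individual's GEBV),
#'   `sigma2`, `sigma`.
#' @export
self_inbred_sigma2 <- function(pop, i, map, beta_hat, n_self = 7,
                               engine = NULL) {
  if (is.null(engine)) engine <- build_variance_engine(map, beta_hat, n_self)
  ind <- subset_pop(pop, i)
  sig2 <- engine_sigma2_self_all(ind, engine)[1]
  structure(list(mu = gebv(score_matrix(ind), beta_hat)[1],
                 sigma2 = sig2, sigma = sqrt(sig2)),
            class = "cross_moments")
}

#' Usefulness criterion of a cross
#'
#' UC = mu + i * h * sigma, with i the selection intensity for picking the
#' best of `pool_size` Inbred8 progeny (default 750 = 15 progeny x 50 lines)
#' and h = 1 by default so outstanding progeny are rewarded in full.
#'
#' @param mu cross mean (GEBV scale).
#' @param sigma Inbred8 progeny standard deviation.
#' @param pool_size progeny pool the best line is drawn from.
#' @param h square root of heritability weight (default 1).
#' @return list of class `usefulness`: `uc`, `mu`, `sigma`, `intensity`, `h`.
#' @export
uc_cross <- function(mu, sigma, pool_size = 750, h = 1) {
  i <- selection_intensity(pool_size)
  structure(list(uc = mu + i * h * sigma, mu = mu, sigma = sigma,
                 intensity = i, h = h),
            class = "usefulness")
}

#' Usefulness criterion of selfing an individual
#'
#' UCS = g + i * sigma with the pool of 50 Inbred8 lines per individual.
#'
#' @param g the individual's GEBV.
#' @param sigma Inbred8 progeny standard deviation under selfing.
#' @param pool_size progeny pool (default 50).
#' @return list of class `usefulness`.
#' @export
uc_self <- function(g, sigma, pool_size = 50) {
  i <- selection_intensity(pool_size)
  structure(list(uc = g + i * sigma, mu = g, sigma = sigma,
                 intensity = i, h = 1),
            class = "usefulness")
}

#' Monte-Carlo Inbred8 progeny simulation
#'
#' Gamete-dropping oracle and normality diagnostic: simulates `n_lines`
#' independent Inbred lines (cross then `n_self` selfings, or `n_self`
#' selfings of one individual) and returns their GEBVs with summary moments.
#'
#' @param pop a `phased_pop`.
#' @param i,j parent indices; `j = NULL` means selfing individual `i`.
#' @param map a `linkage_map`.
#' @param beta_hat marker effect vector.
#' @param n_lines number of simulated lines.
#' @param n_self selfing generations (default 7).
#' @param seed optional seed.
#' @return list: `gebv` (length `n_lines`), `mean`, `var`, `skewness`.
#' @export
simulate_inbred_progeny <- function(pop, i, j = NULL, map, beta_hat,
                                    n_lines = 1000, n_self = 7, seed = NULL) {
  with_seed(seed, {
    L <- n_markers(pop)
    rep_row <- function(v) matrix(v, n_lines, L, byrow = TRUE)
    if (is.null(j)) {
      h0 <- rep_row(pop$hap0[i, ]); h1 <- rep_row(pop$hap1[i, ])
    } else {
      h0 <- meiosis_matrix(rep_row(pop$hap0[i, ]), rep_row(pop$hap1[i, ]), map)
      h1 <- meiosis_matrix(rep_row(pop$hap0[j, ]), rep_row(pop$hap1[j, ]), map)
    }
    for (g in seq_len(n_self)) {
      nxt <- self_once_matrix(h0, h1, map)
      h0 <- nxt$hap0; h1 <- nxt$hap1
    }
    gv <- gebv(h0 + h1 - 1, beta_hat)
    m <- mean(gv); v <- mean((gv - m)^2)
    skew <- if (v > 0) mean((gv - m)^3) / v^1.5 else 0
    list(gebv = gv, mean = m, var = v, skewness = skew)
  })
}
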