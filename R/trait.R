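#' Assign QTN positions
#'
#' Draws `n_qtn` of `L` marker indices uniformly without replacement.
#'
#' @param L total marker count.
#' @param n_qtn number of causal markers (default 1000).
#' @param seed optional seed.
#' @return sorted integer vector of QTN indices.
#' @export
assign_qtn <- function(L, n_qtn = 1000, seed = NULL) {
  if (n_qtn > L) stop("n_qtn cannot exceed L")
  with_seed(seed, sort(sample.int(L, n_qtn)))
}

#' Sample QTN effects
#'
#' Effects are i.i.d. Normal(0, `qtn_var`) at the QTN and exactly zero at all
#' other markers.
#'
#' @param qtn_indices QTN positions (from [assign_qtn()]).
#' @param L total marker count.
#' @param qtn_var effect variance (default 0.35).
#' @param seed optional seed.
#' @return numeric effect vector of length `L`.
#' @export
sample_qtn_effects <- function(qtn_indices, L, qtn_var = 0.35, seed = NULL) {
  beta <- numeric(L)
  with_seed(seed, {
    beta[qtn_indices] <- stats::rnorm(length(qtn_indices), 0, sqrt(qtn_var))
  })
  beta
}

#' True genotypic values
#'
#' u = X beta over the -1/0/1 marker scores.
#'
#' @param X score matrix (individuals x L).
#' @param beta true effect vector of length L.
#' @return numeric vector of genotypic values.
#' @export
genotypic_value <- function(X, beta) drop(X %*% beta)

#' Simulate phenotypes at a target heritability
#'
#' y = u + e with e ~ Normal(0, sigma_e^2) and
#' sigma_e^2 = sigma_g^2 / h2 - sigma_g^2, where sigma_g^2 is the population
#' variance of u (denominator N).
#'
#' @param u true genotypic values.
#' @param h2 target narrow-sense heritability in (0, 1\].
#' @param seed optional seed.
#' @return list of class `phenotype_set`: `u`, `y`, `h2`, `sigma_g2`,
#'   `sigma_e2`.
#' @export
simulate_phenotypes <- function(u, h2, seed = NULL) {
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  sigma_g2 <- mean((u - mean(u))^2)
  if (sigma_g2 == 0) stop("genetic variance is zero: heritability undefined")
  sigma_e2 <- sigma_g2 / h2 - sigma_g2
  y <- with_seed(seed, u + stats::rnorm(length(u), 0, sqrt(sigma_e2)))
  structure(list(u = u, y = y, h2 = h2, sigma_g2 = sigma_g2,
                 sigma_e2 = sigma_e2),
            class = "phenotype_set")
}
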