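#' Fit a G-BLUP model by EMMA-style REML
#'
#' Mixed model y = 1 mu + u + e with u ~ N(0, sigma_u^2 G), G = X X'/L on the
#' -1/0/1 marker scores. The restricted likelihood is maximized over the single
#' ratio delta = sigma_e^2 / sigma_u^2 after one spectral decomposition of G,
#' then GEBVs are the BLUPs of u and marker effects are recovered with
#' [backsolve_marker_effects()].
#'
#' @param X score matrix (N x L).
#' @param y phenotype vector of length N.
#' @return list of class `gp_model`: `mu`, `sigma_u2`, `sigma_e2`, `g_hat`
#'   (centered GEBVs), `beta_hat` (length L), `loglik`.
#' @export
fit_gblup <- function(X, y) {
  if (!all(is.finite(y))) stop("non-finite phenotypes")
  n <- length(y)
  if (n < 10) stop("need at least 10 training individuals")
  if (nrow(X) != n) stop("X rows must match y")
  L <- ncol(X)
  if (stats::sd(y) < 1e-12) {
    return(structure(list(mu = mean(y), sigma_u2 = 0, sigma_e2 = 0,
                          g_hat = numeric(n), beta_hat = numeric(L),
                          loglik = NA_real_),
                     class = "gp_model"))
  }
  G <- tcrossprod(X) / L
  eig <- eigen(G, symmetric = TRUE)
  s <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- drop(crossprod(U, y))
  ws <- drop(crossprod(U, rep(1, n)))
  p <- 1L
  reml <- function(logdelta) {
    delta <- exp(logdelta)
    dinv <- 1 / (s + delta)
    wtw <- sum(ws^2 * dinv)
    bhat <- sum(ws * ys * dinv) / wtw
    r <- ys - ws * bhat
    q <- sum(r^2 * dinv)
    sig <- q / (n - p)
    -0.5 * ((n - p) * log(2 * pi * sig) + (n - p) +
              sum(log(s + delta)) + log(wtw))
  }
  opt <- stats::optimize(reml, interval = c(-12, 12), maximum = TRUE,
                         tol = 1e-8)
  if (!is.finite(opt$objective))
    stop("REML did not converge: non-finite restricted likelihood")
  delta <- exp(opt$maximum)
  dinv <- 1 / (s + delta)
  wtw <- sum(ws^2 * dinv)
  mu <- sum(ws * ys * dinv) / wtw
  r <- ys - ws * mu
  sigma_u2 <- sum(r^2 * dinv) / (n - p)
  sigma_e2 <- delta * sigma_u2
  g_hat <- drop(U %*% (s * dinv * r))
  beta_hat <- backsolve_marker_effects(X, g_hat)
  structure(list(mu = mu, sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
                 g_hat = g_hat, beta_hat = beta_hat, loglik = opt$objective),
            class = "gp_model")
}

#' Back-solve marker effects from GEBVs
#'
#' beta_hat = X' (X X')^-1 g_hat, so that X beta_hat reproduces g_hat. A small
#' ridge (1e-8 * trace/N) is added to X X' only if it is numerically
#' ill-conditioned; the perturbation of beta_hat is negligible.
#'
#' @param X score matrix (N x L, L >= N for an exact fit).
#' @param g_hat GEBV vector of length N.
#' @return effect vector of length L.
#' @export
backsolve_marker_effects <- function(X, g_hat) {
  XXt <- tcrossprod(X)
  sol <- tryCatch(solve(XXt, g_hat), error = function(e) NULL)
  if (is.null(sol) || kappa(XXt, exact = FALSE) > 1e12) {
    ridge <- 1e-8 * sum(diag(XXt)) / nrow(XXt)
    sol <- tryCatch(solve(XXt + diag(ridge, nrow(XXt)), g_hat),
                    error = function(e)
                      stop("X X' is rank deficient beyond ridge tolerance"))
  }
  drop(crossprod(X, sol))
}

#' Genomic estimated breeding values for new individuals
#'
#' g = X_new beta_hat; GEBVs are on the centered scale of the training fit.
#'
#' @param X_new score matrix of the individuals to predict.
#' @param beta_hat marker effects from [fit_gblup()] /
#'   [backsolve_marker_effects()].
#' @return numeric GEBV vector.
#' @export
gebv <- function(X_new, beta_hat) drop(X_new %*% beta_hat)

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf("<gp_model> sigma_u2 = %.4g, sigma_e2 = %.4g, N = %d, L = %d\n",
              x$sigma_u2, x$sigma_e2, length(x$g_hat), length(x$beta_hat)))
  invisible(x)
}
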