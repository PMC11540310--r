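test_that("selection intensity reproduces the quantile constants", {
  expect_equal(round(selection_intensity(750), 3), 3.004)
  expect_equal(round(selection_intensity(50), 3), 2.054)
  expect_equal(selection_intensity(2), 0)
  expect_error(selection_intensity(1), "pool_size")
  # the classical truncation intensity is larger and exposed as an option
  expect_gt(selection_intensity(750, method = "truncation"),
            selection_intensity(750))
})

test_that("pair moments: analytic single-locus, unlinked and RIL limits", {
  # identical homozygous parents: no variance at all
  mom <- pair_inbred_moments(c(1, 1), c(1, 1), c(1, 1), c(1, 1), r = 0.3)
  expect_equal(mom$cov, 0)
  expect_equal(mom$E_xl, 1)
  # one differing locus (l), n_self = 7: var(x_l) = 1 - (1/2)^7
  # (use l = m, r = 0 so cov is the variance of that locus)
  v <- pair_inbred_moments(c(1, 1), c(1, 1), c(0, 0), c(0, 0), r = 0,
                           n_self = 7)
  expect_equal(v$cov, 1 - 0.5^7)
  expect_equal(v$E_xl, 0)
  # unlinked loci: cov exactly 0 at every n_self
  for (ns in c(0, 1, 3, 7)) {
    u <- pair_inbred_moments(c(1, 0), c(0, 1), c(1, 1), c(0, 0), r = 0.5,
                             n_self = ns)
    expect_equal(u$cov, 0, tolerance = 1e-12)
  }
  # complete-inbreeding limit for coupling-phase inbred parents:
  # cov -> 1 - 2R with R = 2r/(1 + 2r)
  for (r in c(0.05, 0.2, 0.4)) {
    lim <- pair_inbred_moments(c(1, 1), c(1, 1), c(0, 0), c(0, 0), r = r,
                               n_self = 500)
    expect_equal(lim$cov, 1 - 2 * (2 * r / (1 + 2 * r)), tolerance = 1e-9)
  }
  expect_error(pair_inbred_moments(c(1, 1), c(1, 1), c(0, 0), c(0, 0),
                                   r = 0.7), "recombination")
})

test_that("closed-form coefficients agree with the explicit 16-state chain", {
  set.seed(21)
  for (rep_i in 1:25) {
    r <- runif(1, 0, 0.5)
    ns <- sample(0:9, 1)
    hA0 <- rbinom(2, 1, 0.5); hA1 <- rbinom(2, 1, 0.5)
    hB0 <- rbinom(2, 1, 0.5); hB1 <- rbinom(2, 1, 0.5)
    chain <- pair_inbred_moments(hA0, hA1, hB0, hB1, r, ns, TRUE)
    # closed form via the engine decomposition
    s <- function(a) 2 * a - 1
    dA <- (s(hA0[1]) * s(hA0[2]) + s(hA1[1]) * s(hA1[2])) / 2
    cA <- (s(hA0[1]) * s(hA1[2]) + s(hA1[1]) * s(hA0[2])) / 2
    dB <- (s(hB0[1]) * s(hB0[2]) + s(hB1[1]) * s(hB1[2])) / 2
    cB <- (s(hB0[1]) * s(hB1[2]) + s(hB1[1]) * s(hB0[2])) / 2
    mA <- (s(hA0) + s(hA1)) / 2; mB <- (s(hB0) + s(hB1)) / 2
    D0 <- ((1 - r) * (dA + dB) + r * (cA + cB)) / 2
    C0 <- (mA[1] * mB[2] + mB[1] * mA[2]) / 2
    cf <- cpsim:::selfing_pair_coef(r, ns)
    mu <- (mA + mB) / 2
    expect_equal(chain$cov, cf$alpha * D0 + cf$gamma * C0 - mu[1] * mu[2],
                 tolerance = 1e-12)
    expect_equal(chain$E_xl, mu[1], tolerance = 1e-12)
  }
})

test_that("cross and self variance engines match the gamete-dropping oracle", {
  set.seed(22)
  map <- even_map(2, 10)
  L <- 20
  for (rep_i in 1:3) {
    pop <- rand_pop(2, L, seed = 100 + rep_i)
    beta <- rnorm(L)
    cm <- cross_inbred_sigma2(pop, 1, 2, map, beta)
    mc <- simulate_inbred_progeny(pop, 1, 2, map = map, beta_hat = beta,
                                  n_lines = 20000, seed = 200 + rep_i)
    se <- mc$var * sqrt(2 / (length(mc$gebv) - 1))
    expect_lt(abs(cm$sigma2 - mc$var), 3 * se)
    expect_lt(abs(cm$mu - mc$mean), 3 * sd(mc$gebv) / sqrt(length(mc$gebv)))
    sm <- self_inbred_sigma2(pop, 1, map, beta)
    mcs <- simulate_inbred_progeny(pop, 1, NULL, map = map, beta_hat = beta,
                                   n_lines = 20000, seed = 300 + rep_i)
    expect_lt(abs(sm$sigma2 - mcs$var), 3 * mcs$var * sqrt(2 / 19999))
  }
})

test_that("degenerate crosses have zero variance; betas gate everything", {
  map <- even_map(1, 8)
  hom <- inbred_pop(matrix(rep(c(0L, 1L), 4), 1, 8))
  both <- bind_pops(hom, hom)
  cm <- cross_inbred_sigma2(both, 1, 2, map, rnorm(8))
  expect_equal(cm$sigma2, 0)
  pop <- rand_pop(2, 8, seed = 23)
  expect_equal(cross_inbred_sigma2(pop, 1, 2, map, numeric(8))$sigma2, 0)
  expect_equal(self_inbred_sigma2(hom, 1, map, rnorm(8))$sigma2, 0)
  # single heterozygous locus with effect b: sigma2 = b^2 (1 - (1/2)^7)
  het1 <- phased_pop(matrix(0L, 1, 8), matrix(c(1L, rep(0L, 7)), 1, 8))
  b <- c(1.7, rep(0, 7))
  expect_equal(self_inbred_sigma2(het1, 1, map, b)$sigma2,
               1.7^2 * (1 - 0.5^7), tolerance = 1e-12)
})

test_that("variance converges to the complete-inbreeding limit as (1/2)^n", {
  pop <- rand_pop(2, 16, seed = 24)
  map <- even_map(2, 8)
  beta <- cpsim:::with_seed(25, rnorm(16))
  inf_engine <- build_variance_engine(map, beta, n_self = 500)
  s_inf <- engine_sigma2_cross_all(subset_pop(pop, 1:2), inf_engine)[1, 2]
  gaps <- vapply(1:9, function(ns) {
    e <- build_variance_engine(map, beta, n_self = ns)
    abs(engine_sigma2_cross_all(subset_pop(pop, 1:2), e)[1, 2] - s_inf)
  }, 1)
  expect_true(all(diff(gaps) < 1e-12))      # monotone shrinking
  # residual scale tracks (1/2)^n: successive ratios near 1/2
  ratios <- gaps[-1] / gaps[-9]
  expect_true(all(ratios < 0.75))
})

test_that("marker relabeling within a chromosome preserves sigma2", {
  pop <- rand_pop(2, 12, seed = 26)
  map <- even_map(1, 12)
  beta <- cpsim:::with_seed(27, rnorm(12))
  base <- cross_inbred_sigma2(pop, 1, 2, map, beta)$sigma2
  # reverse marker order (map distances preserved by symmetry of spacing)
  rev_idx <- 12:1
  pop_r <- phased_pop(pop$hap0[, rev_idx], pop$hap1[, rev_idx])
  expect_equal(cross_inbred_sigma2(pop_r, 1, 2, map, beta[rev_idx])$sigma2,
               base, tolerance = 1e-10)
})

test_that("usefulness criteria combine mean, intensity and sd", {
  uc <- uc_cross(10, 2)
  expect_equal(uc$uc, 10 + selection_intensity(750) * 2)
  expect_equal(round(uc$uc, 3), 16.008)
  expect_equal(uc_cross(5, 0)$uc, 5)
  expect_equal(uc_cross(5, 3, h = 0)$uc, 5)
  us <- uc_self(5, 1)
  expect_equal(round(us$uc, 3), 7.054)
  expect_equal(uc_self(5, 0)$uc, 5)
  expect_gt(uc_self(0, 2)$uc, uc_self(0, 1)$uc)
})

test_that("simulated progeny are reproducible and centered on mu", {
  pop <- rand_pop(2, 20, seed = 28)
  map <- even_map(2, 10)
  beta <- cpsim:::with_seed(29, rnorm(20))
  a <- simulate_inbred_progeny(pop, 1, 2, map = map, beta_hat = beta,
                               n_lines = 500, seed = 30)
  b <- simulate_inbred_progeny(pop, 1, 2, map = map, beta_hat = beta,
                               n_lines = 500, seed = 30)
  expect_identical(a$gebv, b$gebv)
  hom <- inbred_pop(matrix(1L, 1, 20))
  z <- simulate_inbred_progeny(hom, 1, NULL, map = map, beta_hat = beta,
                               n_lines = 50, seed = 31)
  expect_equal(z$var, 0)
})
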