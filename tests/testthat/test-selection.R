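test_that("pair bookkeeping: all_pairs, pair ids, IBS and He0", {
  p <- all_pairs(5)
  expect_equal(nrow(p), 10)
  expect_true(all(p[, 1] < p[, 2]))
  expect_equal(anyDuplicated(p), 0L)
  ids <- vapply(seq_len(nrow(p)), function(k)
    cpsim:::pair_id(p[k, 1], p[k, 2], 5L), 1L)
  expect_equal(ids, seq_len(10))

  X <- matrix(c(1, 1, 1, -1, -1, -1), 2, 3, byrow = TRUE)
  K <- ibs_matrix(X)
  expect_equal(diag(K), c(1, 1))
  expect_equal(K[1, 2], 0)
  # identical homozygous individuals -> all entries 1
  expect_true(all(ibs_matrix(matrix(1, 4, 6)) == 1))
  # He0: monomorphic -> 0; all p = 0.5 -> 0.5
  expect_equal(initial_diversity(matrix(1, 4, 5)), 0)
  expect_equal(initial_diversity(matrix(c(1, -1), 4, 5)), 0.5)
})

test_that("diversity schedule is the stated piecewise curve", {
  he0 <- 0.4
  expect_equal(diversity_constraint_He(0, he0), he0)
  expect_equal(diversity_constraint_He(60, he0), 0.01 * he0)
  expect_equal(diversity_constraint_He(100, he0), 0.01 * he0)
  # s = 1, t = 30: midpoint
  expect_equal(diversity_constraint_He(30, he0),
               (he0 + 0.01 * he0) / 2)
  # s = 2 bends the trajectory
  expect_gt(diversity_constraint_He(30, he0, s = 2),
            diversity_constraint_He(30, he0, s = 1))
})

test_that("dsel: contributions and degenerate concentration", {
  K <- diag(4)
  pairs <- rbind(c(1, 2), c(3, 4))
  # uniform contribution c = 1/4 each: 1 - sum(c^2) = 1 - 4/16
  expect_equal(dsel(pairs, K), 1 - 4 * (1 / 4)^2)
  # all contribution on one self-identical individual -> Dsel = 0
  K1 <- matrix(1, 2, 2)
  expect_equal(dsel(rbind(c(1, 2)), K1), 0)
})

test_that("GS plans: top-GEBV selection, degree-2 pairing, uniform graphs", {
  set.seed(41)
  g <- rnorm(150)
  plan <- gs_select(g, 10, seed = 1)
  expect_plan_feasible(plan, 150, 10, 2)
  sel <- sort(unique(c(plan$p1, plan$p2)))
  expect_equal(sel, sort(order(-g)[1:10]))
  # every selected individual used exactly twice
  expect_true(all(tabulate(c(plan$p1, plan$p2), 150)[sel] == 2))
  # N = 10 -> selection is the whole population
  p10 <- gs_select(rnorm(10), 10, seed = 2)
  expect_setequal(unique(c(p10$p1, p10$p2)), 1:10)
  # uniformity over the 3 labeled 2-regular simple graphs on 4 vertices
  keys <- cpsim:::with_seed(7, vapply(1:6000, function(k) {
    e <- cpsim:::sample_two_regular(4)
    paste(e[order(e[, 1], e[, 2]), ], collapse = "-")
  }, ""))
  counts <- table(keys)
  expect_length(counts, 3)          # exactly the 3 possible 4-cycles occur
  expect_true(all(abs(counts - 2000) < 3 * sqrt(6000 * (1 / 3) * (2 / 3))))
})

test_that("CPS branch-and-bound equals exhaustive enumeration", {
  N <- 8; n_crosses <- 3; cap <- 2
  pairs <- all_pairs(N)
  set.seed(42)
  for (inst in 1:50) {
    uc <- rnorm(nrow(pairs))
    plan <- cps_select(uc, pairs, N, n_crosses, cap)
    opt <- enumerate_optimum(uc, pairs, N, n_crosses, cap)
    expect_equal(attr(plan, "objective"), opt$objective, tolerance = 1e-10)
    expect_plan_feasible(plan, N, n_crosses, cap)
    # with the separable bound active (arbitrary potentials) still exact
    pot <- rnorm(N)
    plan_p <- cps_select(uc, pairs, N, n_crosses, cap, potential = pot)
    expect_equal(attr(plan_p, "objective"), opt$objective, tolerance = 1e-10)
  }
})

test_that("CPS handles ties, caps and bad input", {
  N <- 6; pairs <- all_pairs(N)
  # all-equal weights: any feasible plan is optimal
  plan <- cps_select(rep(1, nrow(pairs)), pairs, N, 3, 2)
  expect_equal(attr(plan, "objective"), 3)
  expect_plan_feasible(plan, N, 3, 2)
  # one individual in the 3 heaviest pairs: cap 2 admits at most 2 of them
  uc <- rep(0.1, nrow(pairs))
  heavy <- which(pairs[, 1] == 1)[1:3]
  uc[heavy] <- 10
  plan2 <- cps_select(uc, pairs, N, 3, 2)
  expect_equal(sum(c(plan2$p1, plan2$p2) == 1), 2)
  expect_error(cps_select(c(NA, uc[-1]), pairs, N, 3, 2), "finite")
  # determinism
  set.seed(1); ucr <- rnorm(nrow(pairs))
  expect_identical(cps_select(ucr, pairs, N, 3, 2)$p1,
                   cps_select(ucr, pairs, N, 3, 2)$p1)
})

test_that("OCS returns feasible near-optimal plans on small instances", {
  N <- 8; n_crosses <- 3; cap <- 2
  pairs <- all_pairs(N)
  set.seed(43)
  hit <- 0
  for (inst in 1:20) {
    g <- rnorm(N)
    X <- matrix(sample(c(-1, 1), N * 30, replace = TRUE), N, 30)
    K <- ibs_matrix(X)
    he_t <- quantile(apply(utils::combn(nrow(pairs), n_crosses)[, 1:200],
                           2, function(s) dsel(pairs[s, ], K)), 0.3)
    mu <- (g[pairs[, 1]] + g[pairs[, 2]]) / 2
    opt <- enumerate_optimum(mu, pairs, N, n_crosses, cap,
                             feasible_fun = function(s)
                               dsel(pairs[s, , drop = FALSE], K) > he_t)
    if (!is.finite(opt$objective)) next
    plan <- ocs_select(g, K, he_t, n_crosses, cap, pop_size = 30,
                       n_gen = 60, seed = inst)
    expect_true(attr(plan, "feasible"))
    expect_gt(attr(plan, "dsel"), he_t)
    expect_plan_feasible(plan, N, n_crosses, cap)
    expect_gte(attr(plan, "objective"),
               0.95 * opt$objective - 1e-9 * abs(opt$objective))
    if (attr(plan, "objective") >= opt$objective - 1e-9) hit <- hit + 1
  }
  expect_gte(hit, 0.9 * 20 - 2)   # matches the enumerated optimum almost always
})

test_that("OCS with an inactive constraint finds the unconstrained optimum", {
  set.seed(44)
  N <- 8
  g <- rnorm(N)
  K <- ibs_matrix(matrix(sample(c(-1, 1), N * 30, replace = TRUE), N, 30))
  pairs <- all_pairs(N)
  mu <- (g[pairs[, 1]] + g[pairs[, 2]]) / 2
  opt <- enumerate_optimum(mu, pairs, N, 3, 2)
  plan <- ocs_select(g, K, he_t = -1, n_crosses = 3, usage_cap = 2,
                     pop_size = 30, n_gen = 80, seed = 5)
  expect_equal(attr(plan, "objective"), opt$objective, tolerance = 1e-9)
})

test_that("CPS objective dominates GS and OCS plans scored by summed UC", {
  set.seed(45)
  N <- 20
  g <- rnorm(N)
  pairs <- all_pairs(N)
  mu <- (g[pairs[, 1]] + g[pairs[, 2]]) / 2
  sigma <- abs(rnorm(nrow(pairs), 0, 0.5))
  uc <- mu + selection_intensity(750) * sigma
  cps <- cps_select(uc, pairs, N, 5, 2)
  gs <- gs_select(g, 5, seed = 6)
  score <- function(plan) sum(uc[cpsim:::pair_id(plan$p1, plan$p2, N)])
  expect_gte(attr(cps, "objective"), score(gs) - 1e-9)
  K <- ibs_matrix(matrix(sample(c(-1, 1), N * 40, replace = TRUE), N, 40))
  ocs <- ocs_select(g, K, he_t = 0.2, n_crosses = 5, usage_cap = 2,
                    pop_size = 20, n_gen = 30, seed = 7)
  expect_gte(attr(cps, "objective"), score(ocs) - 1e-9)
})

test_that("CPS solves degree-dominated instances at program scale", {
  # mid-parent-only weights: every 2-regular pairing of the top 10 ties, so
  # the optimum is sum of the top 10 GEBVs; the matroid slot bound must
  # prune this regime quickly
  set.seed(46)
  N <- 150
  g <- rnorm(N)
  pr <- all_pairs(N)
  mu <- (g[pr[, 1]] + g[pr[, 2]]) / 2
  plan <- cps_select(mu, pr, N, 10, 2)
  expect_equal(attr(plan, "objective"), sum(sort(g, decreasing = TRUE)[1:10]),
               tolerance = 1e-9)
  expect_plan_feasible(plan, N, 10, 2)
  # the separable-decomposition bound gives the same optimum
  plan2 <- cps_select(mu, pr, N, 10, 2, potential = g / 2)
  expect_equal(attr(plan2, "objective"), attr(plan, "objective"),
               tolerance = 1e-12)
})

test_that("SFC selection: top-n with deterministic ties", {
  ucs <- c(3, 9, 9, 1)
  expect_equal(sfc_select(ucs, 2), c(2, 3))
  expect_equal(sfc_select(rep(1, 5), 2), c(1, 2))
  # permutation equivariance
  per <- c(4, 1, 3, 2)
  expect_equal(sort(per[sfc_select(ucs[per], 2)]), c(2, 3))
})
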