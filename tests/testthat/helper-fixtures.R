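# Small in-code fixtures shared across tests.

# random phased population with given heterozygosity structure
rand_pop <- function(n, L, seed = NULL, p = 0.5) {
  cpsim:::with_seed(seed, {
    phased_pop(matrix(rbinom(n * L, 1, p), n, L),
               matrix(rbinom(n * L, 1, p), n, L))
  })
}

# fully inbred population from 0/1 haplotype matrix
inbred_pop <- function(h) phased_pop(h, h)

# map with `n_chrom` chromosomes of `per` evenly spaced markers, 1 Morgan each
even_map <- function(n_chrom, per) build_linkage_map(rep(seq_len(n_chrom), each = per))

# exhaustive optimum of a plan-selection instance (small N only)
enumerate_optimum <- function(weight, pairs, N, n_crosses, usage_cap,
                              feasible_fun = NULL) {
  combs <- utils::combn(nrow(pairs), n_crosses)
  best <- -Inf; best_set <- NULL
  for (k in seq_len(ncol(combs))) {
    sel <- combs[, k]
    deg <- tabulate(as.vector(pairs[sel, ]), nbins = N)
    if (max(deg) > usage_cap) next
    if (!is.null(feasible_fun) && !feasible_fun(sel)) next
    tot <- sum(weight[sel])
    if (tot > best) { best <- tot; best_set <- sel }
  }
  list(objective = best, sel = best_set)
}

expect_plan_feasible <- function(plan, N, n_crosses = 10, usage_cap = 2) {
  expect_equal(nrow(plan), n_crosses)
  expect_true(all(plan$p1 < plan$p2))
  key <- plan$p1 * (N + 1) + plan$p2
  expect_equal(anyDuplicated(key), 0L)
  expect_lte(max(tabulate(c(plan$p1, plan$p2), nbins = N)), usage_cap)
}
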