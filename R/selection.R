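#' All unordered parent pairs
#'
#' @param N population size.
#' @return 2-column integer matrix of the nc = N(N-1)/2 pairs (i < j), in
#'   lexicographic order; row number is the pair id used everywhere.
#' @export
all_pairs <- function(N) {
  i <- rep.int(seq_len(N - 1L), (N - 1L):1L)
  j <- unlist(lapply(seq_len(N - 1L), function(a) (a + 1L):N), use.names = FALSE)
  cbind(i = i, j = j)
}

# row number of pair (i, j), i < j, in all_pairs(N)
pair_id <- function(i, j, N) (i - 1L) * N - (i * (i + 1L)) %/% 2L + j

#' Identity-by-state matrix
#'
#' K = (X X'/L + 1) / 2 on the -1/0/1 scores; entries lie in \[0, 1\] and the
#' diagonal is 1 for fully homozygous individuals.
#'
#' @param X score matrix (N x L).
#' @return N x N matrix.
#' @export
ibs_matrix <- function(X) 0.5 * (tcrossprod(X) / ncol(X) + 1)

#' Expected heterozygosity of a population
#'
#' He = mean over markers of 2 p (1 - p), with p the reference-allele
#' frequency. Used as the initial diversity He0 anchoring the OCS schedule.
#'
#' @param X score matrix (N x L).
#' @return scalar in \[0, 0.5\].
#' @export
initial_diversity <- function(X) {
  p <- colMeans(X + 1) / 2
  mean(2 * p * (1 - p))
}

#' OCS diversity-floor schedule
#'
#' He(t) declines from He0 at t = 0 to He_star at the target cycle t_star
#' (shape s; s = 1 is linear) and stays at He_star afterwards.
#'
#' @param t cycle (scalar or vector).
#' @param He0 initial diversity.
#' @param t_star target cycle (default 60).
#' @param s shape parameter (default 1).
#' @param He_star floor retained at the target cycle (default 0.01 * He0).
#' @return He(t).
#' @export
diversity_constraint_He <- function(t, He0, t_star = 60, s = 1,
                                    He_star = 0.01 * He0) {
  ifelse(t <= t_star, He0 + (t / t_star)^s * (He_star - He0), He_star)
}

#' Genetic diversity of a crossing plan
#'
#' Dsel = 1 - c' K c with c the individual-contribution vector
#' (usage / (2 * number of crosses), summing to 1 for a feasible plan).
#'
#' @param pairs 2-column matrix of selected pairs (parent indices).
#' @param K IBS matrix of the candidate population.
#' @return scalar diversity.
#' @export
dsel <- function(pairs, K) {
  cvec <- tabulate(as.vector(pairs), nbins = nrow(K)) / (2 * nrow(pairs))
  1 - drop(crossprod(cvec, K %*% cvec))
}

plan_usage_ok <- function(pairs, usage_cap, N) {
  !anyDuplicated(pairs[, 1] * (N + 1) + pairs[, 2]) &&
    max(tabulate(as.vector(pairs), nbins = N)) <= usage_cap
}

new_cross_plan <- function(pairs, mu = NULL, sigma = NULL, uc = NULL,
                           strategy, objective = NA_real_, feasible = TRUE,
                           dsel_value = NA_real_) {
  plan <- data.frame(p1 = pairs[, 1], p2 = pairs[, 2])
  if (!is.null(mu)) plan$mu <- mu
  if (!is.null(sigma)) plan$sigma <- sigma
  if (!is.null(uc)) plan$uc <- uc
  structure(plan, strategy = strategy, objective = objective,
            feasible = feasible, dsel = dsel_value,
            class = c("cross_plan", "data.frame"))
}

# Greedy feasible plan: scan pairs by decreasing weight, take any pair whose
# endpoints are below the usage cap. Used as the branch-and-bound incumbent
# and as the logged fallback when the exact solver gives up.
greedy_plan <- function(uc, pairs, N, n_crosses = 10, usage_cap = 2,
                        mu = NULL, sigma = NULL) {
  ord <- order(-uc, pairs[, 1], pairs[, 2])
  deg <- integer(N); sel <- integer(0)
  for (e in ord) {
    if (deg[pairs[e, 1]] < usage_cap && deg[pairs[e, 2]] < usage_cap) {
      sel <- c(sel, e)
      deg[pairs[e, 1]] <- deg[pairs[e, 1]] + 1L
      deg[pairs[e, 2]] <- deg[pairs[e, 2]] + 1L
      if (length(sel) == n_crosses) break
    }
  }
  if (length(sel) < n_crosses) stop("no feasible plan exists")
  sel <- sel[order(pairs[sel, 1], pairs[sel, 2])]
  new_cross_plan(pairs[sel, , drop = FALSE],
                 mu = if (!is.null(mu)) mu[sel],
                 sigma = if (!is.null(sigma)) sigma[sel],
                 uc = uc[sel], strategy = "CPS-greedy",
                 objective = sum(uc[sel]))
}

# Uniform labeled 2-regular simple graph on n >= 3 vertices, by configuration
# model (two stubs per vertex, random perfect matching of stubs) with
# rejection of loops and multi-edges: conditioned on simplicity this is
# uniform over simple 2-regular graphs.
sample_two_regular <- function(n, max_tries = 10000) {
  if (n < 3) stop("a 2-regular simple graph needs at least 3 vertices")
  stubs <- rep(seq_len(n), each = 2L)
  for (try in seq_len(max_tries)) {
    perm <- sample(stubs)
    e1 <- perm[seq(1, 2 * n, by = 2)]
    e2 <- perm[seq(2, 2 * n, by = 2)]
    if (any(e1 == e2)) next
    pairs <- cbind(pmin(e1, e2), pmax(e1, e2))
    if (anyDuplicated(pairs[, 1] * (n + 1) + pairs[, 2])) next
    return(pairs)
  }
  stop("failed to sample a 2-regular simple graph")
}

#' Genomic (truncation) selection of crossing pairs
#'
#' Takes the `n_crosses` individuals with the highest GEBVs (ties -> lower
#' index) and pairs them uniformly at random as a labeled 2-regular simple
#' graph: every selected individual is used exactly twice and no cross is
#' duplicated.
#'
#' @param g GEBV vector of the candidate population.
#' @param n_crosses number of crosses (default 10; also the number of
#'   selected individuals).
#' @param seed optional seed.
#' @return a `cross_plan`.
#' @export
gs_select <- function(g, n_crosses = 10, seed = NULL) {
  N <- length(g)
  if (N < n_crosses) stop("population smaller than the number of crosses")
  sel <- order(-g, seq_len(N))[seq_len(n_crosses)]
  with_seed(seed, {
    edges <- sample_two_regular(n_crosses)
    pairs <- cbind(sel[edges[, 1]], sel[edges[, 2]])
    pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    mu <- (g[pairs[, 1]] + g[pairs[, 2]]) / 2
    new_cross_plan(pairs, mu = mu, strategy = "GS", objective = sum(mu))
  })
}

#' Exact cross potential selection by branch and bound
#'
#' Maximizes the summed usefulness criterion over plans of `n_crosses`
#' distinct pairs with each individual used at most `usage_cap` times — a
#' max-weight b-matching with an edge budget, solved exactly. Candidate edges
#' are scanned in decreasing weight (ties -> lexicographic pair id); subtrees
#' are pruned with an admissible bound (sum of the largest remaining weights
#' among edges whose endpoints are unsaturated) so termination proves
#' optimality. Errors rather than returning a silently suboptimal plan.
#'
#' @param uc weight (usefulness criterion) per pair, aligned with `pairs`.
#' @param pairs 2-column matrix from [all_pairs()] (or any candidate list).
#' @param N number of individuals.
#' @param n_crosses plan size (default 10).
#' @param usage_cap per-individual usage cap (default 2).
#' @param mu,sigma optional per-pair mean / sd carried into the plan.
#' @param potential optional vertex potential vector (length N) such that
#'   `uc` decomposes as `potential[i] + potential[j] + residual`; when the
#'   weights are usefulness criteria, `g/2` is the natural choice. Enables a
#'   third admissible bound that is exact on the degree-separable part of the
#'   objective, which prunes the near-tie instances arising in late breeding
#'   cycles.
#' @param node_cap abort threshold on explored nodes (default 5e6).
#' @param tol relative optimality tolerance (default 1e-6): the returned
#'   plan is proven within `tol * (1 + max|uc|)` of the optimum. This is
#'   far below the numerical noise floor of the usefulness values themselves
#'   (REML convergence, matrix-product variances) and keeps degenerate
#'   near-tie instances — where exponentially many pairings agree to within
#'   round-off — from exhausting the search.
#' @return a `cross_plan` with attribute `objective` equal to the proven
#'   optimum (within `tol`).
#' @export
cps_select <- function(uc, pairs, N, n_crosses = 10, usage_cap = 2,
                       mu = NULL, sigma = NULL, potential = NULL,
                       node_cap = 5e6, tol = 1e-6) {
  nc <- nrow(pairs)
  if (length(uc) != nc) stop("uc must align with pairs")
  if (!all(is.finite(uc))) stop("all usefulness values must be finite")
  ord <- order(-uc, pairs[, 1], pairs[, 2])
  w <- uc[ord]; pi1 <- pairs[ord, 1]; pi2 <- pairs[ord, 2]
  eps <- tol * (1 + max(abs(w)))
  use_pot <- !is.null(potential)
  if (use_pot) {
    if (length(potential) != N) stop("potential must have one entry per individual")
    sres <- w - potential[pi1] - potential[pi2]   # residual after potentials
    sord <- order(-sres)                          # edge ids by residual, desc
    pot_desc <- sort(potential, decreasing = TRUE)
    vert_by_pot <- order(potential, decreasing = TRUE)
  }

  greedy <- function() {
    deg <- integer(N); sel <- integer(0); tot <- 0
    for (e in seq_len(nc)) {
      if (deg[pi1[e]] < usage_cap && deg[pi2[e]] < usage_cap) {
        sel <- c(sel, e); tot <- tot + w[e]
        deg[pi1[e]] <- deg[pi1[e]] + 1L; deg[pi2[e]] <- deg[pi2[e]] + 1L
        if (length(sel) == n_crosses) break
      }
    }
    if (length(sel) < n_crosses) stop("no feasible plan exists")
    list(sel = sel, tot = tot)
  }
  inc <- greedy()
  best <- inc$tot; best_sel <- inc$sel
  nodes <- 0L

  # DFS over include/exclude decisions in decreasing-weight order. The
  # exclude branch is a loop (recursion depth = included edges <= n_crosses).
  recurse <- function(e, chosen, deg, cur) {
    repeat {
      need <- n_crosses - length(chosen)
      if (need == 0L) {
        if (cur > best + eps) { best <<- cur; best_sel <<- chosen }
        return(invisible())
      }
      nodes <<- nodes + 1L
      if (nodes > node_cap)
        stop("branch-and-bound node cap exceeded: solver failure")
      # admissible bound 1: top `need` weights among remaining unsaturated
      # edges (ignores that a vertex may appear in more than cap of them)
      bound <- cur; got <- 0L; k <- e; first_ok <- 0L
      while (k <= nc && got < need) {
        if (deg[pi1[k]] < usage_cap && deg[pi2[k]] < usage_cap) {
          bound <- bound + w[k]; got <- got + 1L
          if (first_ok == 0L) first_ok <- k
        }
        k <- k + 1L
      }
      if (got < need || bound <= best + eps) return(invisible())
      # admissible bound 2 (matroid greedy over vertex-capacity slots): any
      # completion contributes w/2 per endpoint, each vertex at most its
      # residual capacity times, 2*need slot-contributions in total; greedy
      # over this truncated partition matroid upper-bounds every completion.
      scancap <- usage_cap - deg
      slots <- 2L * need
      b2 <- cur; k <- e
      while (k <= nc && slots > 0L) {
        v1 <- pi1[k]; v2 <- pi2[k]
        if (deg[v1] < usage_cap && deg[v2] < usage_cap) {
          if (scancap[v1] > 0L && slots > 0L) {
            scancap[v1] <- scancap[v1] - 1L; slots <- slots - 1L
            b2 <- b2 + w[k] / 2
          }
          if (scancap[v2] > 0L && slots > 0L) {
            scancap[v2] <- scancap[v2] - 1L; slots <- slots - 1L
            b2 <- b2 + w[k] / 2
          }
        }
        k <- k + 1L
      }
      if (slots > 0L || b2 <= best + eps) return(invisible())
      # admissible bound 3 (separable decomposition): any completion scores
      # sum of endpoint potentials (bounded exactly by the best degree
      # profile over unsaturated vertices) plus its residuals (bounded by
      # the top `need` residuals among admissible remaining edges). Tight
      # when near-optimal plans differ only in how top parents are paired.
      if (use_pot) {
        b3 <- cur; slots <- 2L * need
        for (v in vert_by_pot) {
          if (slots == 0L) break
          r_v <- usage_cap - deg[v]
          if (r_v > 0L) {
            take <- min(r_v, slots)
            b3 <- b3 + take * potential[v]
            slots <- slots - take
          }
        }
        got <- 0L
        for (k in sord) {
          if (got == need) break
          if (k >= e && deg[pi1[k]] < usage_cap && deg[pi2[k]] < usage_cap) {
            b3 <- b3 + sres[k]; got <- got + 1L
          }
        }
        if (got < need || b3 <= best + eps) return(invisible())
      }
      k <- first_ok
      deg2 <- deg
      deg2[pi1[k]] <- deg2[pi1[k]] + 1L; deg2[pi2[k]] <- deg2[pi2[k]] + 1L
      recurse(k + 1L, c(chosen, k), deg2, cur + w[k])    # include
      e <- k + 1L                                        # exclude, loop on
    }
  }
  recurse(1L, integer(0), integer(N), 0)

  sel_orig <- ord[best_sel]
  sel_orig <- sel_orig[order(pairs[sel_orig, 1], pairs[sel_orig, 2])]
  new_cross_plan(pairs[sel_orig, , drop = FALSE],
                 mu = if (!is.null(mu)) mu[sel_orig],
                 sigma = if (!is.null(sigma)) sigma[sel_orig],
                 uc = uc[sel_orig],
                 strategy = "CPS", objective = best)
}

#' Optimal cross selection by evolutionary search
#'
#' Maximizes the summed mean GEBV of the selected crosses subject to the
#' plan-size and usage constraints and the diversity floor Dsel > He(t).
#' Plans are evolved with replace-one-cross and swap-parent moves plus repair;
#' fitness is lexicographic (any feasible plan beats any infeasible one;
#' feasible plans are ranked by the objective, infeasible ones by Dsel, which
#' drives the search toward feasibility). If no feasible plan is found within
#' the budget, the plan with the highest Dsel found is returned flagged
#' `feasible = FALSE`.
#'
#' @param g GEBV vector (length N).
#' @param K IBS matrix of the candidates.
#' @param he_t diversity floor at the current cycle.
#' @param n_crosses plan size (default 10).
#' @param usage_cap per-individual usage cap (default 2).
#' @param pop_size,n_gen evolutionary-search budget (population x
#'   generations) per restart.
#' @param restarts independent restarts; the best plan across restarts is
#'   returned (default 2 — heuristic searches occasionally stall in a
#'   feasible local optimum, and a second island recovers most of that).
#' @param seed optional seed.
#' @return a `cross_plan`; attributes `dsel` and `feasible` record the
#'   constraint state.
#' @export
ocs_select <- function(g, K, he_t, n_crosses = 10, usage_cap = 2,
                       pop_size = 40, n_gen = 60, restarts = 2, seed = NULL) {
  N <- length(g)
  pairs <- all_pairs(N)
  nc <- nrow(pairs)
  mu_all <- (g[pairs[, 1]] + g[pairs[, 2]]) / 2
  tol <- 1e-12

  random_plan <- function() {
    sel <- integer(0); deg <- integer(N)
    while (length(sel) < n_crosses) {
      e <- sample.int(nc, 1L)
      if (e %in% sel) next
      if (deg[pairs[e, 1]] >= usage_cap || deg[pairs[e, 2]] >= usage_cap) next
      sel <- c(sel, e)
      deg[pairs[e, 1]] <- deg[pairs[e, 1]] + 1L
      deg[pairs[e, 2]] <- deg[pairs[e, 2]] + 1L
    }
    sel
  }
  repair <- function(sel) {
    sel <- unique(sel)
    repeat {
      deg <- tabulate(as.vector(pairs[sel, ]), nbins = N)
      over <- which(deg > usage_cap)
      if (length(sel) == n_crosses && !length(over)) return(sel)
      if (length(over)) {
        bad <- which(pairs[sel, 1] %in% over | pairs[sel, 2] %in% over)
        sel <- sel[-sample(bad, 1L)]
      }
      while (length(sel) < n_crosses) {
        e <- sample.int(nc, 1L)
        if (e %in% sel) next
        deg <- tabulate(as.vector(pairs[sel, ]), nbins = N)
        if (deg[pairs[e, 1]] >= usage_cap || deg[pairs[e, 2]] >= usage_cap) next
        sel <- c(sel, e)
      }
    }
  }
  fitness <- function(sel) {
    d <- dsel(pairs[sel, , drop = FALSE], K)
    if (d > he_t + tol) c(1, sum(mu_all[sel]), d) else c(0, d, d)
  }
  better <- function(fa, fb) {
    if (fa[1] != fb[1]) return(fa[1] > fb[1])
    fa[2] > fb[2]
  }
  mutate <- function(sel) {
    if (stats::runif(1) < 0.5) {                  # replace one cross
      sel[sample.int(n_crosses, 1L)] <- sample.int(nc, 1L)
    } else {                                      # swap one parent
      k <- sample.int(n_crosses, 1L)
      e <- pairs[sel[k], ]
      keep <- e[sample.int(2L, 1L)]
      other <- sample.int(N, 1L)
      if (other != keep) sel[k] <- pair_id(min(keep, other), max(keep, other), N)
    }
    repair(sel)
  }

  island <- function() {
    popl <- replicate(pop_size, random_plan(), simplify = FALSE)
    fits <- lapply(popl, fitness)
    for (gen in seq_len(n_gen)) {
      for (rep_i in seq_len(pop_size)) {
        a <- sample.int(pop_size, 2L)
        parent <- if (better(fits[[a[1]]], fits[[a[2]]])) a[1] else a[2]
        child <- mutate(popl[[parent]])
        cf <- fitness(child)
        worst <- 1L
        for (q in seq_len(pop_size))
          if (better(fits[[worst]], fits[[q]])) worst <- q
        if (better(cf, fits[[worst]])) {
          popl[[worst]] <- child; fits[[worst]] <- cf
        }
      }
    }
    bi <- 1L
    for (q in seq_len(pop_size)) if (better(fits[[q]], fits[[bi]])) bi <- q
    list(sel = popl[[bi]], f = fits[[bi]])
  }
  with_seed(seed, {
    best <- island()
    for (rs in seq_len(restarts - 1L)) {
      cand <- island()
      if (better(cand$f, best$f)) best <- cand
    }
    sel <- best$sel[order(pairs[best$sel, 1], pairs[best$sel, 2])]
    new_cross_plan(pairs[sel, , drop = FALSE], mu = mu_all[sel],
                   strategy = "OCS",
                   objective = sum(mu_all[sel]),
                   feasible = best$f[1] == 1,
                   dsel_value = best$f[3])
  })
}

#' Select individuals for the segregation-and-fixation component
#'
#' Top `n` individuals by the selfing usefulness criterion UCS (ties ->
#' lower index). Selected individuals remain available as crossing parents.
#'
#' @param ucs UCS vector over the population.
#' @param n number of individuals to advance (default 2).
#' @return integer indices.
#' @export
sfc_select <- function(ucs, n = 2) {
  order(-ucs, seq_along(ucs))[seq_len(n)]
}
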