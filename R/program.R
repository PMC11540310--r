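#' Breeding-program configuration
#'
#' Defaults reproduce the simulated two-part program: 60 selection/crossing
#' cycles (2 per year over 30 years), 10 crosses of 15 progeny each (150
#' individuals per cycle), usage cap 2, two individuals advanced annually to
#' Inbred8 (7 selfings, 50 lines each), OCS schedule t_star = 60, s = 1,
#' He_star = 0.01 He0, 4,000 markers carrying 1,000 QTN with effect variance
#' 0.35.
#'
#' @param strategy "GS", "OCS" or "CPS".
#' @param h2 heritability of the simulated trait (0.3 or 0.6 scenarios).
#' @param n_cycles,crosses_per_cycle,progeny_per_cross,usage_cap program shape.
#' @param n_self,n_first_self segregation-and-fixation component settings.
#' @param sfc_n individuals advanced per year (default 2).
#' @param t_star,s,he_star_frac OCS diversity schedule.
#' @param n_chrom,snp_per_chrom,n_qtn,qtn_var,n_accessions,maf_min genome and
#'   trait setup.
#' @param pool_cross,pool_self selection-intensity pools (750 and 50).
#' @param h_uc heritability weight in the cross usefulness criterion
#'   (default 1).
#' @param ocs_pop,ocs_gen evolutionary-search budget for OCS.
#' @param seed master seed; all stage seeds are derived from it.
#' @return list of class `program_config`.
#' @export
program_config <- function(strategy = "CPS", h2 = 0.6, n_cycles = 60,
                           crosses_per_cycle = 10, progeny_per_cross = 15,
                           usage_cap = 2, n_self = 7, n_first_self = 50,
                           sfc_n = 2, t_star = 60, s = 1, he_star_frac = 0.01,
                           n_chrom = 20, snp_per_chrom = 200, n_qtn = 1000,
                           qtn_var = 0.35, n_accessions = 198, maf_min = 0.1,
                           pool_cross = NULL, pool_self = NULL, h_uc = 1,
                           ocs_pop = 40, ocs_gen = 60, seed = 1) {
  strategy <- match.arg(toupper(strategy), c("GS", "OCS", "CPS"))
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  cfg <- list(strategy = strategy, h2 = h2, n_cycles = n_cycles,
              crosses_per_cycle = crosses_per_cycle,
              progeny_per_cross = progeny_per_cross, usage_cap = usage_cap,
              n_self = n_self, n_first_self = n_first_self, sfc_n = sfc_n,
              t_star = t_star, s = s, he_star_frac = he_star_frac,
              n_chrom = n_chrom, snp_per_chrom = snp_per_chrom,
              n_qtn = n_qtn, qtn_var = qtn_var,
              n_accessions = n_accessions, maf_min = maf_min,
              pool_cross = pool_cross %||%
                (progeny_per_cross * n_first_self),
              pool_self = pool_self %||% n_first_self,
              h_uc = h_uc, ocs_pop = ocs_pop, ocs_gen = ocs_gen,
              seed = as.integer(seed))
  cfg$pop_size <- crosses_per_cycle * progeny_per_cross
  structure(cfg, class = "program_config")
}

#' Genetic gain in the Inbred8 population
#'
#' GI8(t) = (max u in the Inbred8 batch - baseline) / denominator, where the
#' baseline is the maximum genotypic value of the initial 150 individuals.
#' The printed formula divides by the initial genetic variance
#' (`denominator_mode = "variance"`); dividing by its square root is exposed
#' as `"sd"`.
#'
#' @param u_batch genotypic values of the Inbred8 batch at cycle t.
#' @param baseline max genotypic value of the initial population.
#' @param sigma_g2 genetic variance of the initial population.
#' @param denominator_mode "variance" (as printed) or "sd".
#' @return scalar gain.
#' @export
gain_inbred8 <- function(u_batch, baseline, sigma_g2,
                         denominator_mode = c("variance", "sd")) {
  denominator_mode <- match.arg(denominator_mode)
  den <- if (denominator_mode == "variance") sigma_g2 else sqrt(sigma_g2)
  (max(u_batch) - baseline) / den
}

#' Genetic gain in the population improvement component
#'
#' Same form as [gain_inbred8()] over the current 150 PIC individuals; the
#' baseline is shared with GI8.
#'
#' @inheritParams gain_inbred8
#' @param u_pic genotypic values of the current PIC population.
#' @export
gain_pic <- function(u_pic, baseline, sigma_g2,
                     denominator_mode = c("variance", "sd")) {
  gain_inbred8(u_pic, baseline, sigma_g2, denominator_mode)
}

#' Genetic variance of the population improvement component
#'
#' Population variance with denominator N.
#'
#' @param u_pic genotypic values.
#' @return scalar variance.
#' @export
variance_pic <- function(u_pic) mean((u_pic - mean(u_pic))^2)

#' Weighted QTN allele-state rates
#'
#' A QTN is fixed when every haplotype in the population carries the same
#' allele; the fixed allele is favorable when its score points in the
#' beneficial direction of the true effect. Rates are weighted by |effect|
#' and sum to 1 over (fixed favorable, fixed negative, non-fixed).
#'
#' @param pop a `phased_pop`.
#' @param beta true effect vector.
#' @param qtn_indices QTN marker indices.
#' @return named numeric vector `fixed_favorable`, `fixed_negative`,
#'   `non_fixed`.
#' @export
allele_state_rates <- function(pop, beta, qtn_indices) {
  h0 <- pop$hap0[, qtn_indices, drop = FALSE]
  h1 <- pop$hap1[, qtn_indices, drop = FALSE]
  csum <- colSums(h0) + colSums(h1)
  nh <- 2L * n_ind(pop)
  fixed1 <- csum == nh
  fixed0 <- csum == 0L
  b <- beta[qtn_indices]
  wt <- abs(b); wt_tot <- sum(wt)
  fav <- (fixed1 & b > 0) | (fixed0 & b < 0)
  neg <- (fixed1 & b < 0) | (fixed0 & b > 0)
  c(fixed_favorable = sum(wt[fav]) / wt_tot,
    fixed_negative = sum(wt[neg]) / wt_tot,
    non_fixed = sum(wt[!(fixed1 | fixed0)]) / wt_tot)
}

#' Run one two-part breeding program
#'
#' Loops over `n_cycles` selection/crossing cycles in the population
#' improvement component; at every even cycle the segregation-and-fixation
#' component advances the 2 highest-UCS individuals to 50 Inbred8 lines each,
#' whose true genotypic values are logged for strategy evaluation. Marker
#' effects come from the model fitted once on the initial population and are
#' never re-estimated.
#'
#' @param config a [program_config()].
#' @param init_pop the initial `phased_pop` (150 individuals).
#' @param map the `linkage_map`.
#' @param beta_true true effect vector.
#' @param model fitted `gp_model` (provides `beta_hat`).
#' @param qtn_indices QTN marker indices (for allele-state logging).
#' @return list of class `simulation_log`: `cycles` (per-cycle metrics),
#'   `inbred` (per-even-cycle Inbred8 gains), `plans`, `baseline`,
#'   `sigma_g2`, `he0`, `config`.
#' @export
run_program <- function(config, init_pop, map, beta_true, model,
                        qtn_indices = which(beta_true != 0)) {
  stopifnot(inherits(config, "program_config"))
  beta_hat <- model$beta_hat
  X0 <- score_matrix(init_pop)
  u0 <- genotypic_value(X0, beta_true)
  baseline <- max(u0)
  sigma_g2 <- variance_pic(u0)
  he0 <- initial_diversity(X0)
  engine <- build_variance_engine(map, beta_hat, config$n_self)
  i_cross <- selection_intensity(config$pool_cross)
  i_self <- selection_intensity(config$pool_self)

  pop <- init_pop
  n_cyc <- config$n_cycles
  cyc <- data.frame(t = 0:n_cyc, gpic = NA_real_, var_pic = NA_real_,
                    max_u = NA_real_, mean_u = NA_real_,
                    fixed_favorable = NA_real_, fixed_negative = NA_real_,
                    non_fixed = NA_real_, dsel = NA_real_, he_t = NA_real_,
                    objective = NA_real_, feasible = NA)
  record_cycle <- function(row, popc, extra = list()) {
    u <- genotypic_value(score_matrix(popc), beta_true)
    st <- allele_state_rates(popc, beta_true, qtn_indices)
    cyc$gpic[row] <<- gain_pic(u, baseline, sigma_g2)
    cyc$var_pic[row] <<- variance_pic(u)
    cyc$max_u[row] <<- max(u); cyc$mean_u[row] <<- mean(u)
    cyc$fixed_favorable[row] <<- st["fixed_favorable"]
    cyc$fixed_negative[row] <<- st["fixed_negative"]
    cyc$non_fixed[row] <<- st["non_fixed"]
    for (nm in names(extra)) cyc[[nm]][row] <<- extra[[nm]]
  }
  record_cycle(1L, pop)
  inbred <- data.frame(t = integer(0), gi8 = numeric(0), max_u = numeric(0),
                       mean_u = numeric(0))
  plans <- vector("list", n_cyc)

  for (t in seq_len(n_cyc)) {
    X <- score_matrix(pop)
    g <- gebv(X, beta_hat)
    seed_t <- derive_seed(config$seed, "cycle", t)
    plan <- switch(config$strategy,
      GS = gs_select(g, config$crosses_per_cycle, seed = seed_t),
      OCS = {
        K <- ibs_matrix(X)
        he_t <- diversity_constraint_He(t, he0, config$t_star, config$s,
                                        config$he_star_frac * he0)
        ocs_select(g, K, he_t, config$crosses_per_cycle, config$usage_cap,
                   pop_size = config$ocs_pop, n_gen = config$ocs_gen,
                   seed = seed_t)
      },
      CPS = {
        sig2 <- engine_sigma2_cross_all(pop, engine)
        pr <- all_pairs(n_ind(pop))
        mu <- (g[pr[, 1]] + g[pr[, 2]]) / 2
        sigma <- sqrt(sig2[pr])
        uc <- mu + i_cross * config$h_uc * sigma
        # logged fallback: if the exact solver gives up (degenerate late-cycle
        # ties beyond its node cap), fall back to the greedy feasible plan and
        # flag it — never silent, never a crashed program
        tryCatch(
          cps_select(uc, pr, n_ind(pop), config$crosses_per_cycle,
                     config$usage_cap, mu = mu, sigma = sigma,
                     potential = g / 2),
          error = function(e) {
            warning(sprintf("cycle %d: CPS solver fallback (%s)", t,
                            conditionMessage(e)), call. = FALSE)
            plan <- greedy_plan(uc, pr, n_ind(pop), config$crosses_per_cycle,
                                config$usage_cap, mu = mu, sigma = sigma)
            attr(plan, "feasible") <- FALSE
            plan
          })
      })
    plans[[t]] <- plan
    progeny <- lapply(seq_len(nrow(plan)), function(k)
      cross(pop, plan$p1[k], pop, plan$p2[k], map, config$progeny_per_cross,
            seed = derive_seed(config$seed, "progeny", t * 1000L + k),
            generation = sprintf("cycle%d", t)))
    pop <- do.call(bind_pops, c(progeny,
                                list(generation = sprintf("cycle%d", t))))
    record_cycle(t + 1L, pop,
                 extra = list(dsel = attr(plan, "dsel") %||% NA_real_,
                              he_t = if (config$strategy == "OCS")
                                diversity_constraint_He(t, he0, config$t_star,
                                                        config$s,
                                                        config$he_star_frac * he0)
                              else NA_real_,
                              objective = attr(plan, "objective"),
                              feasible = attr(plan, "feasible")))
    if (t %% 2L == 0L) {
      gt <- gebv(score_matrix(pop), beta_hat)
      sig_i <- sqrt(engine_sigma2_self_all(pop, engine))
      ucs <- gt + i_self * sig_i
      picks <- sfc_select(ucs, config$sfc_n)
      u_lines <- unlist(lapply(seq_along(picks), function(kk) {
        lines <- self_ssd(pop, picks[kk], map, config$n_self,
                          config$n_first_self,
                          seed = derive_seed(config$seed, "sfc",
                                             t * 10L + kk))
        genotypic_value(score_matrix(lines), beta_true)
      }))
      inbred <- rbind(inbred,
                      data.frame(t = t,
                                 gi8 = gain_inbred8(u_lines, baseline,
                                                    sigma_g2),
                                 max_u = max(u_lines),
                                 mean_u = mean(u_lines)))
    }
  }
  structure(list(cycles = cyc, inbred = inbred, plans = plans,
                 baseline = baseline, sigma_g2 = sigma_g2, he0 = he0,
                 config = config),
            class = "simulation_log")
}

#' @export
print.simulation_log <- function(x, ...) {
  cat(sprintf("<simulation_log> %s, %d cycles; final GPIC %.3f, final GI8 %.3f\n",
              x$config$strategy, x$config$n_cycles,
              utils::tail(x$cycles$gpic, 1),
              if (nrow(x$inbred)) utils::tail(x$inbred$gi8, 1) else NA))
  invisible(x)
}

# Build one replicate's world (markers, trait, initial population, model)
# from a shared founder panel; the same replicate seed is used for every
# strategy so comparisons are matched.
setup_replicate <- function(config, panel, rep_seed) {
  sub <- subsample_markers(panel, config$snp_per_chrom,
                           seed = derive_seed(rep_seed, "subsample"))
  map <- build_linkage_map(sub$chrom, sub$pos_bp)
  L <- n_markers(sub$pop)
  qtn <- assign_qtn(L, config$n_qtn, seed = derive_seed(rep_seed, "qtn"))
  beta <- sample_qtn_effects(qtn, L, config$qtn_var,
                             seed = derive_seed(rep_seed, "effects"))
  u_panel <- genotypic_value(score_matrix(sub$pop), beta)
  parents <- select_founder_parents(sub, u_panel,
                                    seed = derive_seed(rep_seed, "kmeans"))
  init <- make_initial_population(sub, parents, map, config$pop_size,
                                  seed = derive_seed(rep_seed, "initpop"))
  u0 <- genotypic_value(score_matrix(init), beta)
  ph <- simulate_phenotypes(u0, config$h2,
                            seed = derive_seed(rep_seed, "pheno"))
  model <- fit_gblup(score_matrix(init), ph$y)
  list(panel = sub, map = map, qtn = qtn, beta = beta, init = init,
       phenotypes = ph, model = model)
}

#' Replicated, matched comparison of breeding strategies
#'
#' Runs `n_rep` independent replicates. The founder panel is shared; each
#' replicate redraws the marker subsample, QTN positions and effects, the
#' initial population and phenotypes, then runs every strategy on the
#' identical starting world (matched seeds). Returns per-strategy mean GI8 /
#' GPIC / variance curves and per-cycle win fractions (ties split equally).
#'
#' @param config a [program_config()] (its `strategy` field is ignored).
#' @param strategies character vector of strategies to compare.
#' @param n_rep number of replicates.
#' @param base_seed master seed.
#' @param panel optional prebuilt `founder_panel` (generated from
#'   `base_seed` otherwise).
#' @return list of class `replicate_set`: `gi8` / `gpic` / `var_pic`
#'   (arrays rep x cycle x strategy), mean curves, and `win_frac`.
#' @export
replicate_runner <- function(config, strategies = c("GS", "OCS", "CPS"),
                             n_rep = 20, base_seed = 1, panel = NULL) {
  if (is.null(panel))
    panel <- generate_founders(config$n_accessions, config$n_chrom,
                               max(config$snp_per_chrom * 2L, 50L),
                               maf_min = config$maf_min,
                               seed = derive_seed(base_seed, "panel"))
  n_even <- config$n_cycles %/% 2L
  gi8 <- array(NA_real_, c(n_rep, n_even, length(strategies)),
               dimnames = list(NULL, NULL, strategies))
  gpic <- array(NA_real_, c(n_rep, config$n_cycles + 1L, length(strategies)),
                dimnames = list(NULL, NULL, strategies))
  varp <- gpic
  for (r in seq_len(n_rep)) {
    rep_seed <- derive_seed(base_seed, "replicate", r)
    world <- setup_replicate(config, panel, rep_seed)
    for (stg in strategies) {
      cfg <- config
      cfg$strategy <- stg
      cfg$seed <- derive_seed(rep_seed, "program")
      log <- run_program(cfg, world$init, world$map, world$beta, world$model,
                         world$qtn)
      gi8[r, , stg] <- log$inbred$gi8
      gpic[r, , stg] <- log$cycles$gpic
      varp[r, , stg] <- log$cycles$var_pic
    }
  }
  win <- matrix(0, n_even, length(strategies),
                dimnames = list(NULL, strategies))
  for (tt in seq_len(n_even)) {
    for (r in seq_len(n_rep)) {
      vals <- gi8[r, tt, ]
      tied <- which(vals == max(vals))
      win[tt, tied] <- win[tt, tied] + 1 / length(tied)
    }
  }
  structure(list(gi8 = gi8, gpic = gpic, var_pic = varp,
                 mean_gi8 = apply(gi8, c(2, 3), mean),
                 mean_gpic = apply(gpic, c(2, 3), mean),
                 mean_var = apply(varp, c(2, 3), mean),
                 win_frac = win / n_rep,
                 even_cycles = seq(2L, config$n_cycles, by = 2L),
                 strategies = strategies, n_rep = n_rep),
            class = "replicate_set")
}
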