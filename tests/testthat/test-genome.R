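test_that("linkage map: linear bp -> Morgan mapping and Haldane fractions", {
  # two markers at chromosome ends: d = 1 M, r = (1 - exp(-2))/2
  map <- build_linkage_map(c(1L, 1L), pos_bp = c(0, 1e6))
  expect_equal(map$pos, c(0, 1))
  expect_equal(map$interval_r[1], 0.5 * (1 - exp(-2)), tolerance = 1e-12)
  expect_equal(round(map$interval_r[1], 4), 0.4323)
  # coincident map positions -> r = 0; huge distance -> r -> 0.5
  expect_equal(haldane(0), 0)
  expect_equal(haldane(1e6), 0.5)
  # interior positions interpolate linearly within the chromosome span
  m2 <- build_linkage_map(c(1L, 1L, 1L), pos_bp = c(100, 300, 500))
  expect_equal(m2$pos, c(0, 0.5, 1))
  # unsorted / duplicate positions rejected
  expect_error(build_linkage_map(c(1L, 1L), pos_bp = c(5, 5)), "increasing")
  expect_error(build_linkage_map(c(1L, 1L), pos_bp = c(9, 2)), "increasing")
  # chromosome boundaries carry no recombination fraction
  m3 <- even_map(2, 3)
  expect_true(is.na(m3$interval_r[3]))
})

test_that("meiosis: homozygote transmission, single-marker chromosomes, r recovery", {
  L <- 10
  hom <- inbred_pop(matrix(rep(c(0L, 1L), each = 5), 1, L))
  map <- even_map(1, L)
  gam <- meiosis_gamete(hom, 1, map, seed = 1)
  expect_identical(gam, hom$hap0[1, ])
  # single-marker chromosome: allele is hap0 or hap1 with prob 1/2
  one <- phased_pop(matrix(0L, 1, 1), matrix(1L, 1, 1))
  m1 <- build_linkage_map(1L)
  draws <- cpsim:::with_seed(5, replicate(4000, meiosis_gamete(one, 1, m1)))
  expect_equal(mean(draws), 0.5, tolerance = 3 * sqrt(0.25 / 4000) / 0.5)
  # two loci, r = 0.1: recombinant gamete fraction over 1e5 draws
  d <- -log(1 - 2 * 0.1) / 2   # invert Haldane
  mr <- build_linkage_map(c(1L, 1L), pos_bp = c(0, 1e6),
                          chrom_length_morgans = d)
  par <- phased_pop(matrix(c(0L, 0L), 1), matrix(c(1L, 1L), 1))
  n <- 1e5
  gams <- cpsim:::with_seed(11, {
    cpsim:::meiosis_matrix(matrix(par$hap0[1, ], n, 2, byrow = TRUE),
                           matrix(par$hap1[1, ], n, 2, byrow = TRUE), mr)
  })
  rec <- mean(gams[, 1] != gams[, 2])
  expect_lt(abs(rec - 0.1), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("cross: progeny structure and heterozygosity of F1s", {
  L <- 30
  a <- inbred_pop(matrix(0L, 1, L))
  b <- inbred_pop(matrix(1L, 1, L))
  map <- even_map(3, 10)
  f1 <- cross(a, 1, b, 1, map, n_progeny = 15, seed = 3)
  expect_equal(n_ind(f1), 15)
  expect_true(all(heterozygosity(f1)$per_ind == 1))
  # self cross of a homozygote reproduces the parent
  s <- cross(a, 1, a, 1, map, 5, seed = 4)
  expect_true(all(s$hap0 == 0L) && all(s$hap1 == 0L))
})

test_that("selfing: per-generation halving and SSD fixation at Inbred8", {
  L <- 1000
  het <- phased_pop(matrix(0L, 1, L), matrix(1L, 1, L))
  map <- even_map(1, L)
  # expected heterozygosity after t selfings = (1/2)^t, t = 1..7
  h0 <- matrix(het$hap0, 200, L, byrow = TRUE)
  h1 <- matrix(het$hap1, 200, L, byrow = TRUE)
  cpsim:::with_seed(21, {
    for (t in 1:7) {
      nxt <- cpsim:::self_once_matrix(h0, h1, map)
      h0 <- nxt$hap0; h1 <- nxt$hap1
      obs <- mean(h0 != h1)
      expect_equal(obs, 0.5^t, tolerance = 0.15)
    }
  })
  # SSD: 50 Inbred8 lines from a fully heterozygous individual fix > 99%
  lines <- self_ssd(het, 1, map, n_self = 7, n_first = 50, seed = 9)
  expect_equal(n_ind(lines), 50)
  # lines are independent but loci within a line are linked: compare the
  # mean per-line heterozygosity with its empirical between-line SE
  # expected fixation 1 - (1/2)^7 = 99.22% > 99%; the 50-line draw agrees
  # within 3 SEs (empirical between-line SE: loci within a line are linked)
  expect_gt(1 - 0.5^7, 0.99)
  per <- heterozygosity(lines)$per_ind
  expect_lt(abs(mean(per) - 0.5^7), 3 * sd(per) / sqrt(length(per)))
  # homozygous input unchanged; n_self = 0 warns and copies
  hom <- inbred_pop(matrix(1L, 1, L))
  out <- self_ssd(hom, 1, map, n_self = 7, n_first = 10, seed = 2)
  expect_true(all(out$hap0 == 1L) && all(out$hap1 == 1L))
  expect_warning(self_ssd(het, 1, map, n_self = 0, n_first = 3), "n_self")
})

test_that("heterozygosity accessor", {
  p <- phased_pop(matrix(c(0L, 1L, 0L, 1L), 2, 2),
                  matrix(c(0L, 0L, 1L, 1L), 2, 2))
  h <- heterozygosity(p)
  expect_equal(unname(h$per_ind), c(0.5, 0.5))
  expect_equal(heterozygosity(inbred_pop(matrix(1L, 2, 4)))$mean, 0)
})

test_that("allele frequency is conserved through meiosis in expectation", {
  L <- 20
  pop <- rand_pop(1, L, seed = 31)
  map <- even_map(2, 10)
  n <- 2e4
  gams <- cpsim:::with_seed(32, {
    cpsim:::meiosis_matrix(matrix(pop$hap0[1, ], n, L, byrow = TRUE),
                           matrix(pop$hap1[1, ], n, L, byrow = TRUE), map)
  })
  pexp <- (pop$hap0[1, ] + pop$hap1[1, ]) / 2
  se <- sqrt(pmax(pexp * (1 - pexp), 1e-9) / n)
  expect_true(all(abs(colMeans(gams) - pexp) <= 3 * se + 1e-12))
  # between-chromosome transmission independent: covariance across the
  # boundary pair within 3 SEs of zero (het at both loci -> var 1/4 each)
  hetloci <- which(pexp == 0.5)
  c1 <- hetloci[hetloci <= 10][1]; c2 <- hetloci[hetloci > 10][1]
  skip_if(is.na(c1) || is.na(c2))
  cv <- cov(gams[, c1], gams[, c2])
  expect_lt(abs(cv), 3 * 0.25 / sqrt(n))
})
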