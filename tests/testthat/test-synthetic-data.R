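test_that("sim_params validates its invariants", {
  expect_s3_class(sim_params(), "sim_params")
  expect_error(sim_params(t_split = 10, t_bottleneck = 20), "t_split")
  expect_error(sim_params(n_pop_a = 0), "sizes")
  expect_error(sim_params(s_lof = 0.5), "selection")
  expect_error(sim_params(s_missense = -1.5), "selection")
})

test_that("identical parameters and seed give byte-identical VCF output", {
  s1 <- simulate_genotypes(sim_params(seed = 42))
  s2 <- simulate_genotypes(sim_params(seed = 42))
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  vcf_export(s1, f1); vcf_export(s2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  s3 <- simulate_genotypes(sim_params(seed = 43))
  expect_false(identical(s1$geno, s3$geno))
})

test_that("site ledger keeps requested class counts; genotypes drop monomorphics", {
  p <- sim_params(seed = 7)
  sim <- simulate_genotypes(p)
  expect_equal(table(sim$ledger$class)[names(p$n_sites)],
               table(rep(names(p$n_sites), p$n_sites))[names(p$n_sites)])
  expect_equal(nrow(sim$geno), sum(sim$ledger$segregating))
  # every genotype row is polymorphic in the sample
  rng <- apply(sim$geno, 1, function(g) diff(range(g, na.rm = TRUE)))
  expect_true(all(rng > 0))
})

test_that("additively lethal LOF alleles never reach frequency above 0.5", {
  sim <- simulate_genotypes(sim_params(seed = 5, s_lof = -1, h_lof = 0.5))
  lof <- sim$ledger$class == "lof"
  for (popv in list(1:15, 16:30)) {
    ids <- sim$ledger$id[lof & sim$ledger$segregating]
    g <- sim$geno[rownames(sim$geno) %in% ids, popv, drop = FALSE]
    anc_is_ref <- sim$sites$ref[match(rownames(g), sim$sites$id)] ==
      sim$sites$ancestral_true[match(rownames(g), sim$sites$id)]
    der <- g
    der[!anc_is_ref, ] <- 2L - der[!anc_is_ref, ]
    freq <- rowMeans(der, na.rm = TRUE) / 2
    expect_true(all(freq <= 0.5))
  }
})

test_that("the bottlenecked population is less heterozygous (sign test over seeds)", {
  het <- function(g) mean(colMeans(g == 1L, na.rm = TRUE))
  wins <- 0L
  for (s in 1:10) {
    sim <- default_sim(s)
    pop <- sim$samples$population
    if (het(sim$geno[, pop == "A"]) < het(sim$geno[, pop == "B"]))
      wins <- wins + 1L
  }
  # one-sided sign test at alpha = 0.05: >= 9 of 10
  expect_gte(wins, 9)
})

test_that("population extinction is reported, naming the regime", {
  # saturating mutation pressure onto a dominant lethal wipes the population
  p <- sim_params(seed = 2, s_lof = -1, h_lof = 1, mu = 1)
  expect_error(simulate_genotypes(p), "extinct")
})

test_that("landscape futures shift the present grid exactly", {
  lp0 <- landscape_params(seed = 3, future_shift = list(none = c(BIO7 = 0)))
  land0 <- simulate_landscape(lp0)
  expect_equal(land0$futures$none$layers, land0$present$layers)
  lp2 <- landscape_params(seed = 3,
                          future_shift = list(up = c(BIO7 = 2, BIO15 = 2)))
  land2 <- simulate_landscape(lp2)
  for (v in c("BIO7", "BIO15"))
    expect_equal(land2$futures$up$layers[[v]] - land2$present$layers[[v]],
                 matrix(2, nrow(land2$present$layers[[v]]),
                        ncol(land2$present$layers[[v]])))
})

test_that("identical coordinates give identical environmental vectors", {
  land <- simulate_landscape(landscape_params(seed = 3))
  e <- extract_env(land$present, c(105.3, 105.3), c(30.7, 30.7))
  expect_equal(e[1, ], e[2, ])
  expect_error(extract_env(land$present, 140, 30), "outside grid extent")
})

test_that("adaptive cline embedding obeys its contract", {
  sim <- default_sim(11)
  land <- simulate_landscape(landscape_params(seed = 12),
                             samples = sim$samples)
  env <- land$env[, 1]
  # ledger size always equals n_causal
  s1 <- embed_adaptive_cline(sim, env, n_causal = 15, steepness = 4,
                             seed = 13)
  expect_equal(nrow(s1$causal), 15)
  expect_true(all(s1$causal$id %in% sim$sites$id))
  expect_error(embed_adaptive_cline(sim, env, n_causal = 1e6),
               "exceeds available")

  # steepness = 0: causal frequencies independent of env across seeds
  cors <- numeric(8)
  for (k in 1:8) {
    s0 <- embed_adaptive_cline(sim, env, n_causal = 15, steepness = 0,
                               seed = 100 + k)
    g <- s0$geno[s0$causal$id, , drop = FALSE]
    anc_ref <- s0$sites$ref[match(s0$causal$id, s0$sites$id)] ==
      s0$sites$ancestral_true[match(s0$causal$id, s0$sites$id)]
    g[!anc_ref, ] <- 2L - g[!anc_ref, ]
    cors[k] <- mean(apply(g, 1, function(x)
      suppressWarnings(cor(x, env))), na.rm = TRUE)
  }
  expect_lt(abs(mean(cors)), 0.1)

  # large steepness, bimodal env: near-fixed difference between env groups
  env_bi <- rep(c(-1, 1), length.out = length(env))
  sb <- embed_adaptive_cline(sim, env_bi, n_causal = 10, steepness = 50,
                             seed = 14)
  g <- sb$geno[sb$causal$id, , drop = FALSE]
  anc_ref <- sb$sites$ref[match(sb$causal$id, sb$sites$id)] ==
    sb$sites$ancestral_true[match(sb$causal$id, sb$sites$id)]
  g[!anc_ref, ] <- 2L - g[!anc_ref, ]
  expect_lt(mean(g[, env_bi == -1]), 0.1)
  expect_gt(mean(g[, env_bi == 1]), 1.9)
})

test_that("niche-based occurrences concentrate where true suitability is high", {
  land <- simulate_landscape(landscape_params(seed = 21))
  occ <- simulate_occurrences(land$present, n = 300, seed = 22)
  truth <- attr(occ, "suitability_truth")
  e <- extract_env(land$present, occ$lon, occ$lat)[, 1]
  opt <- attr(occ, "optimum")
  # occurrence climates cluster around the optimum relative to the grid
  expect_lt(mean(abs(e - opt)),
            mean(abs(as.vector(land$present$layers[[1]]) - opt)))
  expect_equal(dim(truth), dim(land$present$layers[[1]]))
})
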