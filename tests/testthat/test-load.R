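test_that("L_A,B matches the hand-worked ratio of burden sums", {
  # C: fA=0.8, fB=0.4; I: fA=fB=0.5 -> (0.8*0.6)/(0.5*0.5) = 1.92
  expect_equal(l_ab(0.8, 0.4, 0.5, 0.5), 1.92)
  # A and B identical and C = I -> 1
  f <- c(0.1, 0.4, 0.9)
  expect_equal(l_ab(f, f, f, f), 1)
  # no derived alleles in A on C sites -> 0
  expect_equal(l_ab(c(0, 0), c(0.3, 0.6), 0.5, 0.5), 0)
  # zero intergenic normaliser is reported as undefined, never silently 0
  expect_warning(out <- l_ab(0.5, 0.5, 0, 0.5), "undefined")
  expect_true(is.na(out))
})

test_that("R_A/B matches hand arithmetic and is exact for identical groups", {
  ft <- make_ft(fA = c(0.8, 0.5), fB = c(0.4, 0.5),
                class = c("lof", "intergenic"))
  r <- suppressWarnings(r_ab(ft, "lof"))
  expect_equal(r$l_ab, 1.92)
  expect_equal(r$l_ba, 0.32)
  expect_equal(r$r, 6.0)

  f <- runif(50, 0.05, 0.95)
  ft2 <- make_ft(fA = c(f, f), fB = c(f, f),
                 class = rep(c("lof", "intergenic"), each = 50))
  r2 <- r_ab(ft2, "lof")
  expect_equal(r2$r, 1)
  expect_equal(r2$sd, 0)
})

test_that("reciprocity R_A/B * R_B/A = 1 on random fixtures", {
  set.seed(77)
  for (k in 1:100) {
    m <- sample(60:150, 1)
    fA <- runif(m); fB <- runif(m)
    cls <- sample(c("lof", "intergenic"), m, replace = TRUE, prob = c(.4, .6))
    if (!any(cls == "lof") || !any(cls == "intergenic")) next
    ft <- make_ft(fA, fB, cls)
    swapped <- ft; swapped$fA <- ft$fB; swapped$fB <- ft$fA
    r1 <- suppressWarnings(r_ab(ft, "lof"))
    r2 <- suppressWarnings(r_ab(swapped, "lof"))
    expect_equal(r1$r * r2$r, 1, tolerance = 1e-12)
  }
})

test_that("jackknife SD is non-negative and shrinks with more sites", {
  set.seed(42)
  sd_at <- function(m) {
    fA <- rbeta(m, 0.6, 2); fB <- rbeta(m, 0.6, 2)
    cls <- rep(c("lof", "intergenic"), length.out = m)
    r_ab(make_ft(fA, fB, cls), "lof")$sd
  }
  s_small <- sd_at(300)
  s_big <- sd_at(6000)
  expect_gte(s_small, 0)
  expect_lt(s_big, s_small)
})

test_that("fewer polymorphic sites than blocks reduces the block count", {
  ft <- make_ft(runif(30), runif(30),
                rep(c("lof", "intergenic"), each = 15))
  expect_warning(r <- r_ab(ft, "lof", blocks = 100), "fewer")
  expect_lte(r$blocks, 30)
})

test_that("per-individual burdens match the hand count and are synonymous-normalised", {
  # individual 1: LOF {2}, syn {1,1}; individual 2: all reference
  g <- rbind(c(2L, 0L), c(1L, 0L), c(1L, 0L))
  pol <- make_pol(g, class = c("lof", "synonymous", "synonymous"))
  cnt <- per_individual_counts(pol, classes = c("lof", "synonymous"))
  i1_lof <- cnt[cnt$id == "i1" & cnt$class == "lof", ]
  expect_equal(i1_lof$derived_total_norm, 1.0)   # 2 derived / 2 syn derived
  expect_equal(i1_lof$derived_hom_norm, 1.0)     # one hom genotype = 2 alleles
  i2 <- cnt[cnt$id == "i2", ]
  expect_true(all(i2$derived_total == 0))
  expect_true(all(is.na(i2$derived_total_norm)))  # zero syn derived: undefined
})

test_that("normalised counts are per-individual statistics (duplication invariant)", {
  set.seed(5)
  g <- matrix(sample(0:2, 40, replace = TRUE), nrow = 10)
  pol <- make_pol(g, class = rep(c("lof", "synonymous"), each = 5))
  cnt <- per_individual_counts(pol, classes = "lof")
  gdup <- cbind(g, g[, 2])
  poldup <- make_pol(gdup, class = rep(c("lof", "synonymous"), each = 5))
  cntdup <- per_individual_counts(poldup, classes = "lof")
  expect_equal(cntdup$derived_total_norm[2], cnt$derived_total_norm[2])
  expect_equal(cntdup$derived_total_norm[5], cnt$derived_total_norm[2])
})

test_that("masked and realized GERP loads match the worked example", {
  # two het deleterious sites (GERP 4.5, 5.0), 10 called sites, no hom
  g <- matrix(0L, nrow = 10, ncol = 2)
  g[1, 1] <- 1L; g[2, 1] <- 1L
  gerp <- c(4.5, 5.0, rep(0, 8))
  pol <- make_pol(g, gerp = gerp)
  load <- gerp_load(pol)
  expect_equal(load$masked_load[1], 0.95)
  expect_equal(load$realized_load[1], 0)
  # fully homozygous-ancestral individual
  expect_equal(load$masked_load[2], 0)
  expect_equal(load$realized_load[2], 0)
})

test_that("GERP loads are additive over disjoint site subsets", {
  set.seed(13)
  g <- matrix(sample(0:2, 200, replace = TRUE), nrow = 20)
  gerp <- runif(20, 4, 8)
  pol <- make_pol(g, gerp = gerp)
  whole <- gerp_load(pol)
  half1 <- gerp_load(make_pol(g[1:10, ], gerp = gerp[1:10]))
  half2 <- gerp_load(make_pol(g[11:20, ], gerp = gerp[11:20]))
  expect_equal(whole$masked_load * whole$called,
               half1$masked_load * half1$called +
                 half2$masked_load * half2$called)
  expect_true(all(whole$masked_load >= 0 & whole$realized_load >= 0))
  expect_error(gerp_load(make_pol(matrix(NA_integer_, 2, 2))), "no called")
})

test_that("shuffling individuals between groups pushes R towards 1", {
  sim <- default_sim(4)
  pol <- default_pol(4)
  set.seed(99)
  rs <- replicate(60, {
    perm <- sample(pol$samples$population)
    polp <- pol
    polp$samples$population <- perm
    ft <- derived_freq_table(polp)
    suppressWarnings(r_ab(ft, "synonymous", blocks = 50))$r
  })
  ft0 <- derived_freq_table(pol)
  r0 <- r_ab(ft0, "synonymous", blocks = 50)
  expect_lt(abs(mean(rs) - 1), 2 * sd(rs))
})
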