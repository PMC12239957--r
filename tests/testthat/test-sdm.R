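test_that("AUC matches brute-force pair enumeration", {
  # 4-point toy {(1,.9),(1,.4),(0,.6),(0,.1)}: 3 of 4 pairs concordant
  labels <- c(1, 1, 0, 0)
  scores <- c(0.9, 0.4, 0.6, 0.1)
  expect_equal(auc_score(labels, scores), 0.75)

  set.seed(2)
  for (k in 1:5) {
    n <- 60
    lab <- rbinom(n, 1, 0.4)
    if (length(unique(lab)) < 2) next
    sc <- round(rnorm(n), 1)             # ties included
    pairs <- expand.grid(i = which(lab == 1), j = which(lab == 0))
    brute <- mean(ifelse(sc[pairs$i] > sc[pairs$j], 1,
                         ifelse(sc[pairs$i] == sc[pairs$j], 0.5, 0)))
    expect_equal(auc_score(lab, sc), brute)
  }
  expect_error(auc_score(rep(1, 5), rnorm(5)), "both classes")
})

test_that("AUC and TSS hit their extremes and nulls", {
  lab <- rep(c(1, 0), each = 50)
  sc <- c(runif(50, 0.6, 1), runif(50, 0, 0.4))
  expect_equal(auc_score(lab, sc), 1)
  expect_equal(as.numeric(tss_score(lab, sc)), 1)
  set.seed(3)
  lab2 <- rbinom(2000, 1, 0.5)
  sc2 <- runif(2000)
  expect_lt(abs(auc_score(lab2, sc2) - 0.5), 0.05)
  expect_lt(as.numeric(tss_score(lab2, sc2)), 0.12)
})

test_that("presence thinning and background sampling follow the contract", {
  grid <- make_grid(list(BIO7 = matrix(runif(400), 20)))
  # two presences ~1 arc-minute apart: one survives a 5 arc-min thinning
  occ <- data.frame(lon = c(105, 105.017, 108), lat = c(30, 30, 33))
  pb <- make_presence_background(occ, grid, n_background = 100,
                                 thin_arcmin = 5, seed = 1)
  expect_equal(sum(pb$label == 1), 2)
  expect_equal(sum(pb$label == 0), 100)
  pb2 <- make_presence_background(occ, grid, n_background = 100,
                                  thin_arcmin = 5, seed = 1)
  expect_identical(pb, pb2)              # seeded runs identical
  expect_error(make_presence_background(occ[0, ], grid), "no occurrence")
})

test_that("ensemble gates admit separable members and reject a random dummy", {
  pb <- separable_pb()
  dummy <- list(fit = function(d) NULL,
                predict = function(m, nd) runif(nrow(nd)))
  members <- c(genovuln:::.sdm_members()[c("glm", "rf")],
               list(dummy = dummy))
  ens <- fit_sdm_ensemble(pb, members = members, reps = 3, seed = 4)
  met <- ens$metrics
  expect_true(all(met$accepted[met$member %in% c("glm", "rf")]))
  expect_false(met$accepted[met$member == "dummy"])
  expect_equal(sum(ens$weights), 1)
  expect_true(all(ens$weights >= 0))

  # all members failing is an explicit error with per-member metrics
  expect_error(fit_sdm_ensemble(pb, members = list(dummy = dummy),
                                reps = 2, seed = 5),
               "failed the TSS/AUC gates")
})

test_that("gating is monotone: raising a gate never admits a member", {
  pb <- separable_pb(seed = 6)
  ens_lo <- fit_sdm_ensemble(pb, members = c("glm", "rf"), reps = 3,
                             gate_tss = 0.5, gate_auc = 0.7, seed = 7)
  ens_hi <- fit_sdm_ensemble(pb, members = c("glm", "rf"), reps = 3,
                             gate_tss = 0.8, gate_auc = 0.9, seed = 7)
  admitted_lo <- ens_lo$metrics$member[ens_lo$metrics$accepted]
  admitted_hi <- ens_hi$metrics$member[ens_hi$metrics$accepted]
  expect_true(all(admitted_hi %in% admitted_lo))
})

test_that("suitability maps stay in [0,1], are uniform for uniform climate, and track gradients", {
  pb <- separable_pb(seed = 8)
  ens <- fit_sdm_ensemble(pb, members = c("glm", "rf"), reps = 3, seed = 9)
  gu <- make_grid(list(BIO7 = matrix(2, 6, 6), BIO15 = matrix(0, 6, 6)))
  su <- suitability_map(ens, gu)
  expect_equal(max(su) - min(su), 0)
  gg <- make_grid(list(BIO7 = matrix(rep(seq(-4, 4, length.out = 6), 6), 6,
                                     byrow = TRUE),
                       BIO15 = matrix(0, 6, 6)))
  sg <- suitability_map(ens, gg)
  expect_true(all(sg >= 0 & sg <= 1))
  # suitability increases towards the presence niche (BIO7 ~ +3)
  expect_gt(cor(sg[1, ], seq_len(6)), 0.8)
  expect_gt(sg[1, 6], sg[1, 1] + 0.5)
  expect_error(suitability_map(ens, make_grid(list(BIO7 = matrix(0, 2, 2)))),
               "missing layer")
})

test_that("ecological vulnerability is an antisymmetric bounded difference", {
  set.seed(10)
  sp <- matrix(runif(36), 6)
  sf <- matrix(runif(36), 6)
  ve <- ecological_vulnerability(sf, sp)
  expect_equal(ve, -ecological_vulnerability(sp, sf))
  expect_true(all(ve >= -1 & ve <= 1))
  expect_equal(ecological_vulnerability(sp, sp), matrix(0, 6, 6))
  expect_equal(ecological_vulnerability(matrix(0, 2, 2), matrix(1, 2, 2)),
               matrix(-1, 2, 2))
  # per-cell loop oracle
  ve_o <- sf
  for (i in 1:6) for (j in 1:6) ve_o[i, j] <- sf[i, j] - sp[i, j]
  expect_equal(ve, ve_o)
  expect_error(ecological_vulnerability(matrix(0, 2, 2), matrix(0, 3, 3)),
               "geometry")
})

test_that("habitat-area change matches the hand count on an equal-area toy grid", {
  areas <- matrix(1, 4, 4)
  sp <- matrix(0, 4, 4); sp[1:2, ] <- 1      # 8 suitable cells now
  sf <- matrix(0, 4, 4); sf[1, 1:2] <- 1     # 2 suitable cells in future
  hc <- habitat_area_change(sp, sf, threshold = 0.5, cell_areas = areas)
  expect_equal(hc$area_present, 8)
  expect_equal(hc$area_future, 2)
  expect_equal(hc$pct_change, (2 - 8) / 8 * 100)  # -75%
  expect_equal(habitat_area_change(sp, sp, 0.5,
                                   cell_areas = areas)$pct_change, 0)
  expect_equal(habitat_area_change(sp, matrix(0, 4, 4), 0.5,
                                   cell_areas = areas)$pct_change, -100)
  expect_error(habitat_area_change(sp, sf, threshold = 1.5,
                                   cell_areas = areas), "threshold")
  # spherical cell areas shrink with latitude
  grid <- make_grid(list(v = matrix(0, 4, 4)))
  hc2 <- habitat_area_change(sp, sf, 0.5, grid = grid)
  expect_lt(hc2$area_future, hc2$area_present)
})
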