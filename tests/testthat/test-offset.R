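# turnover model with hand-specified step transforms, for law tests
manual_model <- function(vars, breaks, cum, ranges) {
  structure(list(method = "forest_turnover", variables = vars,
                 transforms = Map(function(b, cm) list(breaks = b, cum = cm),
                                  breaks, cum),
                 ranges = ranges,
                 importance = vapply(cum, max, numeric(1)),
                 snp_weights = numeric(0)),
            class = "turnover_model")
}

test_that("forest turnover transforms are monotone and rank the causal variable", {
  set.seed(1)
  n <- 24
  env <- data.frame(causal = seq(0, 10, length.out = n),
                    shuffled = sample(seq(0, 10, length.out = n)))
  freqs <- vapply(1:25, function(k)
    plogis(0.8 * (env$causal - 5) + rnorm(n, 0, 0.3)), numeric(n))
  model <- fit_turnover_forest(freqs, env, seed = 2)
  expect_lt(model$importance["shuffled"], 0.1 * model$importance["causal"])
  for (v in model$variables) {
    tr <- model$transforms[[v]]
    expect_true(all(diff(tr$cum) >= 0))
  }
  # prediction is monotone non-decreasing along each variable
  grid_x <- data.frame(causal = seq(-2, 12, 0.25), shuffled = 5)
  y <- predict(model, grid_x)[, "causal"]
  expect_true(all(diff(y) >= 0))
})

test_that("a single step cline is localised near the true breakpoint", {
  set.seed(3)
  n <- 30
  env <- data.frame(x = seq(0, 10, length.out = n))
  freqs <- matrix(ifelse(env$x > 5, 0.9, 0.1) + rnorm(n, 0, 0.02), ncol = 1)
  model <- fit_turnover_forest(freqs, env, seed = 4)
  tr <- model$transforms$x
  # most cumulative importance accrues within one grid bin of the midpoint
  gain_near <- max(tr$cum[tr$breaks <= 5.6]) -
    if (any(tr$breaks <= 4.4)) max(tr$cum[tr$breaks <= 4.4]) else 0
  expect_gt(gain_near, 0.8 * max(tr$cum))
  expect_warning(
    fit_turnover_forest(cbind(freqs, freqs), data.frame(x = env$x,
                                                        flat = rep(1, n)),
                        seed = 5),
    "constant")
})

test_that("climate transformation clamps beyond the training range", {
  m <- manual_model("v", list(v = c(2, 4)), list(v = c(1, 3)),
                    list(v = c(0, 6)))
  out <- predict(m, data.frame(v = c(-5, 1, 3, 5, 99)))
  expect_equal(as.numeric(out), c(0, 0, 1, 3, 3))
})

test_that("local, forward and reverse offsets obey their laws and oracles", {
  set.seed(6)
  grid <- make_grid(list(v1 = matrix(runif(25, 0, 10), 5),
                         v2 = matrix(runif(25, 0, 10), 5)))
  future <- grid
  future$layers <- lapply(grid$layers, function(z) z + runif(25, 0, 2))
  m <- manual_model(c("v1", "v2"),
                    list(v1 = c(2, 5, 8), v2 = c(3, 6)),
                    list(v1 = c(0.5, 1.2, 2.0), v2 = c(0.3, 0.9)),
                    list(v1 = c(0, 10), v2 = c(0, 10)))
  tp <- transform_climate(m, grid)
  tf <- transform_climate(m, future)
  coords <- grid_coords(grid)

  # future = present: all offsets identically zero
  expect_equal(local_offset(tp, tp), rep(0, 25))
  expect_equal(forward_offset(tp, tp, coords, Inf), rep(0, 25))
  expect_equal(reverse_offset(tp, tp), rep(0, 25))

  loc <- local_offset(tp, tf)
  caps <- c(100, 250, 500, 1000, Inf)
  fwd <- vapply(caps, function(d) forward_offset(tp, tf, coords, d),
                numeric(25))
  for (j in 1:(length(caps) - 1))
    expect_true(all(fwd[, j] >= fwd[, j + 1] - 1e-12))
  expect_true(all(fwd[, 5] <= loc + 1e-12))

  # brute-force oracles (double loops)
  d_euc <- function(a, b) sqrt(sum((a - b)^2))
  loc_o <- vapply(1:25, function(i) d_euc(tp[i, ], tf[i, ]), numeric(1))
  expect_equal(loc, loc_o)
  gd <- geosphere::distm(coords, coords,
                         fun = function(p1, p2)
                           geosphere::distHaversine(p1, p2, r = 6371))
  for (cap in c(250, Inf)) {
    fwd_o <- vapply(1:25, function(i) {
      pool <- which(gd[i, ] <= cap)
      min(vapply(pool, function(j) d_euc(tp[i, ], tf[j, ]), numeric(1)))
    }, numeric(1))
    expect_equal(forward_offset(tp, tf, coords, cap), fwd_o)
  }
  rev_o <- vapply(1:25, function(i)
    min(vapply(1:25, function(j) d_euc(tf[i, ], tp[j, ]), numeric(1))),
    numeric(1))
  expect_equal(reverse_offset(tp, tf), rev_o)
})

test_that("a shifted variable under an identity transform gives a constant offset", {
  grid <- make_grid(list(v = matrix(runif(16, 2, 8), 4)))
  future <- grid
  future$layers$v <- grid$layers$v + 1.5
  # identity transform: dense unit steps approximating f(x) = x
  br <- seq(-20, 30, by = 0.001)
  m <- manual_model("v", list(v = br),
                    list(v = cumsum(rep(0.001, length(br)))),
                    list(v = c(-20, 30)))
  tp <- transform_climate(m, grid)
  tf <- transform_climate(m, future)
  expect_equal(local_offset(tp, tf), rep(1.5, 16), tolerance = 1e-2)
})

test_that("reverse offset is zero when a future climate exists somewhere today", {
  z <- matrix(seq(1, 16), 4)
  grid <- make_grid(list(v = z))
  future <- grid
  # future at each cell equals the present climate of another cell
  future$layers$v <- matrix(rev(seq(1, 16)), 4)
  br <- seq(0, 20, 0.001)
  m <- manual_model("v", list(v = br),
                    list(v = cumsum(rep(0.001, length(br)))),
                    list(v = c(0, 20)))
  expect_equal(reverse_offset(transform_climate(m, grid),
                              transform_climate(m, future)),
               rep(0, 16), tolerance = 1e-12)
})

test_that("dissimilarity-spline turnover recovers the informative variable", {
  set.seed(7)
  npop <- 8
  env <- data.frame(active = seq(0, 10, length.out = npop),
                    inert = rnorm(npop))
  d <- abs(outer(env$active, env$active, "-")) / 10
  fst <- d * 0.4
  diag(fst) <- 0
  model <- fit_dissimilarity_spline(fst, env)
  expect_gt(model$deviance_explained, 0.8)
  expect_gt(model$importance["active"],
            9 * max(model$importance["inert"], 1e-9))
  # transforms monotone
  xx <- data.frame(active = seq(0, 10, 0.1), inert = 0)
  expect_true(all(diff(predict(model, xx)[, "active"]) >= -1e-12))

  # all-zero dissimilarity: zero transforms, zero offsets
  z0 <- fit_dissimilarity_spline(matrix(0, 5, 5),
                                 data.frame(a = 1:5, b = rnorm(5)))
  expect_true(all(vapply(z0$transforms, function(t) all(t$coefs == 0),
                         logical(1))))
  expect_error(fit_dissimilarity_spline(matrix(0, 3, 3),
                                        data.frame(a = 1:3)), ">= 4")
})

test_that("Fst rescaling maps the extremes to exactly 0 and 1", {
  fst <- matrix(0, 4, 4)
  fst[upper.tri(fst)] <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  fst <- fst + t(fst)
  env <- data.frame(a = 1:4)
  # reconstruct the rescaled response the model fits: range must be [0, 1]
  d <- fst[upper.tri(fst)]
  d01 <- (d - min(d)) / (max(d) - min(d))
  expect_equal(range(d01), c(0, 1))
  expect_silent(fit_dissimilarity_spline(fst, env))
})

test_that("RGB composite scales bands to [0,1] with the fixed band order", {
  loc <- c(0, 1, 2, 4)
  fwd <- c(0, 2, 1, 4)
  rev_ <- c(4, 0, 2, 4)
  img <- rgb_composite(loc, fwd, rev_)
  expect_equal(colnames(img), c("R", "G", "B"))
  expect_equal(img[, "R"], loc / 4)
  expect_equal(img[, "G"], fwd / 4)
  expect_equal(img[4, ], c(R = 1, G = 1, B = 1))  # maximal cell is white
  expect_warning(img0 <- rgb_composite(rep(0, 3), c(0, 1, 2), c(2, 1, 0)),
                 "constant")
  expect_equal(unname(img0[, "R"]), rep(0, 3))
  # three all-zero maps give a black image
  suppressWarnings(black <- rgb_composite(rep(0, 4), rep(0, 4), rep(0, 4)))
  expect_true(all(black == 0))
})
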