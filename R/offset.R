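#' Fit a gradient-forest-style turnover model
#'
#' Fits, for every candidate SNP, a bootstrap ensemble of regression trees of
#' population allele frequency on the climate variables, and accumulates each
#' split's variance-reduction at its split position along the variable's
#' axis. Summed over trees and SNPs (weighted by each SNP's out-of-bag R^2;
#' SNPs with non-positive fit are dropped), this yields one monotone
#' non-decreasing cumulative-importance curve per variable: the turnover
#' function mapping climate space to a compositional-importance space in
#' which genomic offsets are Euclidean distances.
#'
#' @param freqs matrix of allele frequencies, sampling sites/populations in
#'   rows, SNPs in columns.
#' @param env data.frame of climate variables at the same sites.
#' @param n_trees bootstrap trees per SNP.
#' @param maxdepth tree depth.
#' @param seed RNG seed.
#' @return object of class `turnover_model` (method `"forest_turnover"`)
#'   with per-variable step transforms, training ranges, per-variable total
#'   importance and per-SNP weights.
#' @export
fit_turnover_forest <- function(freqs, env, n_trees = 25, maxdepth = 3,
                                seed = 1L) {
  env <- as.data.frame(env)
  freqs <- as.matrix(freqs)
  if (nrow(freqs) < 5)
    stop("need >= 5 sites/populations with frequencies")
  stopifnot(nrow(env) == nrow(freqs))
  set.seed(seed)
  vars <- names(env)
  const <- vapply(env, function(v) stats::sd(v) == 0, logical(1))
  if (any(const))
    warning("constant variable(s) get zero transforms: ",
            paste(vars[const], collapse = ", "))
  splits <- stats::setNames(
    lapply(vars, function(v) list(x = numeric(0), w = numeric(0))), vars)
  n <- nrow(freqs)
  weights <- numeric(ncol(freqs))
  for (s in seq_len(ncol(freqs))) {
    y <- freqs[, s]
    if (stats::sd(y) == 0) next
    oob_pred <- rep(0, n)
    oob_n <- rep(0L, n)
    snp_splits <- list()
    for (b in seq_len(n_trees)) {
      bag <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(bag))
      d <- data.frame(y = y[bag], env[bag, , drop = FALSE])
      fit <- rpart::rpart(y ~ ., data = d, method = "anova",
                          control = rpart::rpart.control(
                            maxdepth = maxdepth, minsplit = 4, cp = 1e-3,
                            xval = 0, maxsurrogate = 0, maxcompete = 0))
      if (length(oob)) {
        pr <- stats::predict(fit, env[oob, , drop = FALSE])
        oob_pred[oob] <- oob_pred[oob] + pr
        oob_n[oob] <- oob_n[oob] + 1L
      }
      sp <- fit$splits
      if (!is.null(sp) && nrow(sp) > 0) {
        prim <- sp[sp[, "adj"] == 0 | is.na(sp[, "adj"]), , drop = FALSE]
        snp_splits[[b]] <- data.frame(var = rownames(prim),
                                      x = prim[, "index"],
                                      w = pmax(prim[, "improve"], 0))
      }
    }
    has <- oob_n > 0
    if (sum(has) < 3) next
    res <- y[has] - oob_pred[has] / oob_n[has]
    r2 <- 1 - sum(res^2) / sum((y[has] - mean(y[has]))^2)
    if (!is.finite(r2) || r2 <= 0) next   # non-positive OOB fit: drop SNP
    weights[s] <- r2
    if (length(snp_splits)) {
      all_sp <- do.call(rbind, snp_splits)
      for (v in unique(all_sp$var)) {
        rows <- all_sp$var == v
        splits[[v]]$x <- c(splits[[v]]$x, all_sp$x[rows])
        splits[[v]]$w <- c(splits[[v]]$w, all_sp$w[rows] * r2 / n_trees)
      }
    }
  }
  transforms <- lapply(vars, function(v) {
    xs <- splits[[v]]$x
    ws <- splits[[v]]$w
    if (!length(xs)) return(list(breaks = numeric(0), cum = numeric(0)))
    o <- order(xs)
    list(breaks = xs[o], cum = cumsum(ws[o]))
  })
  names(transforms) <- vars
  ranges <- lapply(env, range)
  importance <- vapply(transforms, function(tr)
    if (length(tr$cum)) max(tr$cum) else 0, numeric(1))
  structure(list(method = "forest_turnover", variables = vars,
                 transforms = transforms, ranges = ranges,
                 importance = importance, snp_weights = weights),
            class = "turnover_model")
}

# monotone quadratic smoothstep ramp from x0 to x1
.ramp <- function(x, x0, x1) {
  if (x1 <= x0) return(as.numeric(x >= x1))
  t <- pmin(pmax((x - x0) / (x1 - x0), 0), 1)
  t * t * (3 - 2 * t)
}

# monotone spline basis: one ramp per knot interval boundary
.ispline_basis <- function(x, knots) {
  k <- length(knots)
  b <- matrix(0, length(x), k - 1)
  for (j in seq_len(k - 1)) b[, j] <- .ramp(x, knots[j], knots[j + 1])
  b
}

#' Fit a dissimilarity (GDM-style) turnover model from pairwise Fst
#'
#' Rescales the pairwise Fst matrix to `[0, 1]` and regresses the rescaled
#' dissimilarities on per-variable monotone (I-spline-type) basis
#' differences with non-negative coefficients, yielding one monotone
#' non-decreasing transform per climate variable. The fitted transforms plug
#' into the same offset operators as the forest model.
#'
#' @param fst symmetric pairwise Fst matrix (diagonal 0) across >= 4
#'   populations.
#' @param env data.frame of climate variables at the populations.
#' @param geo_dist optional matrix of pairwise geographic distances included
#'   as an additional (monotone) predictor to absorb isolation by distance.
#' @param n_knots knots per variable (quantile-placed, including range ends).
#' @return object of class `turnover_model` (method
#'   `"dissimilarity_spline"`) with per-variable spline transforms,
#'   training ranges and per-variable importance (total transform rise).
#' @export
fit_dissimilarity_spline <- function(fst, env, geo_dist = NULL, n_knots = 3) {
  fst <- as.matrix(fst)
  env <- as.data.frame(env)
  npop <- nrow(fst)
  if (npop < 4) stop("need >= 4 populations")
  if (any(abs(fst - t(fst)) > 1e-8) || any(diag(fst) != 0))
    stop("fst must be symmetric with zero diagonal")
  stopifnot(nrow(env) == npop)
  pairs <- which(upper.tri(fst), arr.ind = TRUE)
  d <- fst[upper.tri(fst)]
  rng <- range(d)
  d01 <- if (diff(rng) > 0) (d - rng[1]) / diff(rng) else d * 0
  vars <- names(env)
  knots <- lapply(env, function(x)
    unique(stats::quantile(x, seq(0, 1, length.out = n_knots),
                           names = FALSE)))
  design <- NULL
  cols <- character(0)
  for (v in vars) {
    bi <- .ispline_basis(env[[v]][pairs[, 1]], knots[[v]])
    bj <- .ispline_basis(env[[v]][pairs[, 2]], knots[[v]])
    db <- abs(bi - bj)
    if (ncol(db)) {
      design <- cbind(design, db)
      cols <- c(cols, paste0(v, "_", seq_len(ncol(db))))
    }
  }
  if (!is.null(geo_dist)) {
    gd <- as.matrix(geo_dist)[upper.tri(fst)]
    design <- cbind(design, gd / max(gd, 1e-12))
    cols <- c(cols, "geo")
  }
  colnames(design) <- cols
  coef <- if (all(d01 == 0)) rep(0, ncol(design))
    else pracma::lsqnonneg(design, d01)$x
  names(coef) <- cols
  transforms <- list()
  for (v in vars) {
    kn <- knots[[v]]
    cv <- coef[grep(paste0("^", v, "_"), names(coef))]
    transforms[[v]] <- list(knots = kn, coefs = unname(cv))
  }
  fitted <- as.numeric(design %*% coef)
  ss_tot <- sum((d01 - mean(d01))^2)
  importance <- vapply(vars, function(v) sum(transforms[[v]]$coefs),
                       numeric(1))
  structure(list(method = "dissimilarity_spline", variables = vars,
                 transforms = transforms, ranges = lapply(env, range),
                 importance = importance,
                 deviance_explained = if (ss_tot > 0)
                   1 - sum((d01 - fitted)^2) / ss_tot else NA_real_,
                 coefficients = coef),
            class = "turnover_model")
}

#' @export
print.turnover_model <- function(x, ...) {
  cat("turnover_model [", x$method, "] on ",
      paste(x$variables, collapse = ", "), "\n", sep = "")
  imp <- x$importance
  cat("  importance:", paste(sprintf("%s=%.4f", names(imp), imp),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate the fitted turnover transforms at new climate values
#'
#' @param object a `turnover_model`.
#' @param newdata matrix or data.frame of climate values with the model's
#'   variables as columns. Values beyond the training range clamp to the
#'   boundary transform value.
#' @param ... unused.
#' @return numeric matrix (rows of `newdata` x variables) of transformed
#'   values.
#' @export
predict.turnover_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$variables, names(newdata))
  if (length(miss)) stop("missing variable(s): ", paste(miss, collapse = ", "))
  out <- matrix(0, nrow(newdata), length(object$variables),
                dimnames = list(NULL, object$variables))
  for (v in object$variables) {
    x <- pmin(pmax(newdata[[v]], object$ranges[[v]][1]),
              object$ranges[[v]][2])
    tr <- object$transforms[[v]]
    out[, v] <- if (object$method == "forest_turnover") {
      if (!length(tr$breaks)) rep(0, length(x))
      else {
        idx <- findInterval(x, tr$breaks)
        c(0, tr$cum)[idx + 1L]
      }
    } else {
      b <- .ispline_basis(x, tr$knots)
      if (length(tr$coefs)) as.numeric(b %*% tr$coefs) else rep(0, length(x))
    }
  }
  out
}

#' Transform every cell of a climate grid through a turnover model
#'
#' @param model a `turnover_model`.
#' @param grid a `climate_grid` whose layers cover the model variables.
#' @return matrix (cells x variables) in row-major (north-first) cell order,
#'   with the source grid in attribute `grid`.
#' @export
transform_climate <- function(model, grid) {
  stopifnot(inherits(grid, "climate_grid"))
  miss <- setdiff(model$variables, names(grid$layers))
  if (length(miss)) stop("missing layer(s): ", paste(miss, collapse = ", "))
  vals <- vapply(model$variables,
                 function(v) as.vector(t(grid$layers[[v]])),
                 numeric(length(grid$lon) * length(grid$lat)))
  colnames(vals) <- model$variables
  out <- stats::predict(model, vals)
  attr(out, "grid") <- grid
  out
}

#' Local genomic offset
#'
#' Euclidean distance, cell by cell, between present and future transformed
#' climate: the expected disruption of the genotype-climate relationship if
#' the population stays in place.
#'
#' @param t_present,t_future transformed grids from [transform_climate()]
#'   with identical geometry.
#' @return numeric vector, one offset (>= 0) per cell.
#' @export
local_offset <- function(t_present, t_future) {
  if (!identical(dim(t_present), dim(t_future)))
    stop("geometry mismatch between present and future grids")
  sqrt(rowSums((t_present - t_future)^2))
}

# great-circle distance matrix (km) between cell centres, R = 6371 km
.haversine_km <- function(coords1, coords2 = coords1) {
  geosphere::distm(coords1[, c("lon", "lat")], coords2[, c("lon", "lat")],
                   fun = function(p1, p2)
                     geosphere::distHaversine(p1, p2, r = 6371))
}

#' Forward genomic offset under a dispersal cap
#'
#' For every current cell, the minimum Euclidean distance between its
#' transformed present climate and the transformed future climate of any
#' cell within `max_km` great-circle kilometres (the focal cell is always in
#' the pool, so forward offset never exceeds local offset). Smaller caps can
#' only raise the offset.
#'
#' @param t_present,t_future transformed grids (same geometry).
#' @param coords data.frame of cell-centre `lon`/`lat` (see [grid_coords()]).
#' @param max_km dispersal cap in km (`Inf` = unlimited).
#' @return numeric vector of offsets per current cell.
#' @export
forward_offset <- function(t_present, t_future, coords, max_km = Inf) {
  if (!identical(dim(t_present), dim(t_future)))
    stop("geometry mismatch")
  if (max_km <= 0) stop("max_km must be > 0")
  n <- nrow(t_present)
  gd <- if (is.finite(max_km)) .haversine_km(coords) else NULL
  out <- numeric(n)
  for (i in seq_len(n)) {
    # self-distance is 0 km, so the focal cell is always in the pool
    pool <- if (is.null(gd)) seq_len(n) else which(gd[i, ] <= max_km)
    diffs <- t_future[pool, , drop = FALSE] -
      matrix(t_present[i, ], length(pool), ncol(t_present), byrow = TRUE)
    out[i] <- sqrt(min(rowSums(diffs^2)))
  }
  out
}

#' Reverse genomic offset
#'
#' For every future cell, the minimum Euclidean distance between its
#' transformed future climate and the transformed present climate of any
#' current cell (no dispersal cap): how alien the future climate of a site
#' is relative to anywhere in the present range.
#'
#' @param t_present,t_future transformed grids (same geometry).
#' @return numeric vector of offsets per future cell.
#' @export
reverse_offset <- function(t_present, t_future) {
  if (!identical(dim(t_present), dim(t_future)))
    stop("geometry mismatch")
  n <- nrow(t_future)
  out <- numeric(n)
  for (i in seq_len(n)) {
    diffs <- t_present -
      matrix(t_future[i, ], n, ncol(t_future), byrow = TRUE)
    out[i] <- sqrt(min(rowSums(diffs^2)))
  }
  out
}

#' RGB composite of the three offset maps
#'
#' Min-max scales the local, forward and reverse offsets to `[0, 1]` and maps
#' them to the red, green and blue bands respectively; cells bright in all
#' three are near-white. NA cells propagate; a constant band scales to 0 with
#' a warning.
#'
#' @param local,forward,reverse offset vectors (same length / geometry).
#' @return numeric matrix (cells x 3) with columns `R`, `G`, `B`.
#' @export
rgb_composite <- function(local, forward, reverse) {
  stopifnot(length(local) == length(forward),
            length(forward) == length(reverse))
  scale01 <- function(x, band) {
    rng <- range(x, na.rm = TRUE)
    if (diff(rng) == 0) {
      warning("constant ", band, " band scaled to 0")
      return(x * 0)
    }
    (x - rng[1]) / diff(rng)
  }
  cbind(R = scale01(local, "local"), G = scale01(forward, "forward"),
        B = scale01(reverse, "reverse"))
}

#' Compute the full set of offset maps for one scenario
#'
#' @param model a `turnover_model`.
#' @param present,future `climate_grid`s sharing geometry.
#' @param dispersal_km forward-offset dispersal caps in km.
#' @return list of class `offset_maps`: `local`, `forward` (matrix cells x
#'   caps), `reverse`, `rgb` (using the uncapped forward band), plus the
#'   grid and transformed spaces.
#' @export
offset_maps <- function(model, present, future,
                        dispersal_km = c(100, 250, 500, 1000, Inf)) {
  tp <- transform_climate(model, present)
  tf <- transform_climate(model, future)
  coords <- grid_coords(present)
  loc <- local_offset(tp, tf)
  fwd <- vapply(dispersal_km, function(d) forward_offset(tp, tf, coords, d),
                numeric(nrow(tp)))
  colnames(fwd) <- ifelse(is.finite(dispersal_km),
                          paste0("km", dispersal_km), "unlimited")
  rev_off <- reverse_offset(tp, tf)
  structure(list(local = loc, forward = fwd, reverse = rev_off,
                 rgb = rgb_composite(loc, fwd[, ncol(fwd)], rev_off),
                 dispersal_km = dispersal_km, grid = present,
                 t_present = tp, t_future = tf),
            class = "offset_maps")
}

#' Reshape a per-cell vector to the grid's matrix layout
#'
#' @param values per-cell vector in row-major (north-first) order.
#' @param grid the `climate_grid` defining the geometry.
#' @return matrix (lat rows x lon columns).
#' @export
as_grid_matrix <- function(values, grid) {
  matrix(values, nrow = length(grid$lat), ncol = length(grid$lon),
         byrow = TRUE)
}

#' @export
print.offset_maps <- function(x, ...) {
  cat("offset_maps on", length(x$local), "cells\n")
  cat(sprintf("  local:   mean %.4f, max %.4f\n", mean(x$local), max(x$local)))
  for (j in seq_len(ncol(x$forward)))
    cat(sprintf("  forward[%s]: mean %.4f\n", colnames(x$forward)[j],
                mean(x$forward[, j])))
  cat(sprintf("  reverse: mean %.4f\n", mean(x$reverse)))
  invisible(x)
}
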