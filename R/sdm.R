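#' Build a thinned presence / background data set
#'
#' Spatially thins occurrence records so no two retained presences lie
#' within `thin_arcmin` arc-minutes (great-circle) of each other, samples
#' background cells uniformly from the climate grid (excluding presence
#' cells; with replacement when the grid has fewer cells than requested),
#' and extracts the environmental vector at every point.
#'
#' @param occurrences data.frame with `lon`, `lat` presence coordinates
#'   (must fall inside the grid extent).
#' @param grid a `climate_grid` of present climate.
#' @param n_background number of background rows to generate.
#' @param thin_arcmin thinning radius in arc-minutes (1 arc-min ~ 1.853 km).
#' @param seed RNG seed.
#' @return data.frame of class `presence_background`: `lon`, `lat`,
#'   `label` (1 presence, 0 background) and one column per climate variable.
#' @export
make_presence_background <- function(occurrences, grid, n_background = 10000,
                                     thin_arcmin = 5, seed = 1L) {
  set.seed(seed)
  occ <- as.data.frame(occurrences)[, c("lon", "lat")]
  if (!nrow(occ)) stop("no occurrence records")
  thin_km <- thin_arcmin * 1.853
  keep <- integer(0)
  for (i in seq_len(nrow(occ))) {
    if (!length(keep)) { keep <- i; next }
    d <- .haversine_km(occ[i, , drop = FALSE], occ[keep, , drop = FALSE])
    if (all(d >= thin_km)) keep <- c(keep, i)
  }
  occ <- occ[keep, , drop = FALSE]
  if (!nrow(occ)) stop("zero presences after thinning")
  cells <- grid_coords(grid)
  res <- abs(diff(grid$lon[1:2]))
  occ_cell <- unique(paste(round(occ$lon / res), round(occ$lat / res)))
  free <- !(paste(round(cells$lon / res), round(cells$lat / res)) %in% occ_cell)
  pool <- which(free)
  if (!length(pool)) pool <- seq_len(nrow(cells))
  bg_idx <- sample(pool, n_background, replace = n_background > length(pool))
  pts <- rbind(occ, cells[bg_idx, ])
  env <- extract_env(grid, pts$lon, pts$lat)
  out <- data.frame(pts, label = rep(c(1L, 0L), c(nrow(occ), n_background)),
                    env, row.names = NULL)
  class(out) <- c("presence_background", class(out))
  out
}

#' Area under the ROC curve (rank-based)
#'
#' Probability that a random presence scores higher than a random background
#' point, with ties counted half (Mann-Whitney formulation; identical to
#' brute-force enumeration over all pairs).
#'
#' @param labels 0/1 vector.
#' @param scores numeric prediction scores.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(labels, scores) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True skill statistic
#'
#' Maximum over candidate thresholds of sensitivity + specificity - 1
#' (prediction positive when score >= threshold).
#'
#' @param labels 0/1 vector.
#' @param scores numeric prediction scores.
#' @return TSS in `[-1, 1]`, with the maximising threshold in attribute
#'   `threshold`.
#' @export
tss_score <- function(labels, scores) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  thr <- sort(unique(scores))
  best <- -Inf
  best_thr <- thr[1]
  for (t in thr) {
    sens <- sum(scores >= t & labels == 1) / n1
    spec <- sum(scores < t & labels == 0) / n0
    if (sens + spec - 1 > best) {
      best <- sens + spec - 1
      best_thr <- t
    }
  }
  structure(best, threshold = best_thr)
}

# built-in member model families: each is fit(data) -> model plus
# predict(model, newdata) -> probability
.sdm_members <- function() {
  list(
    glm = list(
      fit = function(d) stats::glm(label ~ ., data = d,
                                   family = stats::binomial()),
      predict = function(m, nd) as.numeric(
        stats::predict(m, nd, type = "response"))),
    gam = list(
      fit = function(d) {
        vars <- setdiff(names(d), "label")
        k <- max(3, min(5, floor(nrow(d) / (3 * length(vars)))))
        f <- stats::as.formula(paste("label ~",
          paste(sprintf("s(%s, k = %d)", vars, k), collapse = " + ")))
        mgcv::gam(f, data = d, family = stats::binomial())
      },
      predict = function(m, nd) as.numeric(
        mgcv::predict.gam(m, nd, type = "response"))),
    rf = list(
      fit = function(d) randomForest::randomForest(
        x = d[setdiff(names(d), "label")], y = factor(d$label),
        ntree = 250),
      predict = function(m, nd) as.numeric(
        stats::predict(m, nd, type = "prob")[, "1"])),
    svm = list(
      fit = function(d) e1071::svm(
        x = as.matrix(d[setdiff(names(d), "label")]), y = factor(d$label),
        kernel = "radial", probability = TRUE),
      predict = function(m, nd) {
        p <- stats::predict(m, as.matrix(nd), probability = TRUE)
        as.numeric(attr(p, "probabilities")[, "1"])
      }),
    brt = list(
      fit = function(d) {
        x <- as.matrix(d[setdiff(names(d), "label")])
        xgboost::xgboost(data = x, label = d$label, nrounds = 40,
                         params = list(objective = "binary:logistic",
                                       max_depth = 3, eta = 0.2),
                         verbose = 0)
      },
      predict = function(m, nd) as.numeric(
        stats::predict(m, as.matrix(nd))))
  )
}

#' Fit a gated, weighted ensemble habitat-suitability model
#'
#' Repeatedly splits presences and background into calibration (70%) and
#' validation (30%) subsamples, fits every member family on the calibration
#' part, and scores validation AUC and TSS. Members whose mean validation
#' metrics fail the gates (TSS > 0.8 and AUC > 0.9 by default) are excluded.
#' Accepted members are refit on the full data and combined as a TSS-weighted
#' (or equal-weight) average.
#'
#' @param data a `presence_background` data.frame.
#' @param members character vector of built-in family names
#'   (`"glm","gam","rf","svm","brt"`) or a named list of custom
#'   `list(fit=, predict=)` members.
#' @param reps number of subsampling replicates.
#' @param split calibration fraction.
#' @param gate_tss,gate_auc acceptance gates (strict inequalities).
#' @param weighting `"tss"` or `"equal"`.
#' @param seed RNG seed (splits are reproducible).
#' @return object of class `sdm_ensemble`: fitted members, per-member metric
#'   table (`metrics`), normalised `weights`, and the ensemble's
#'   TSS-maximising suitability `threshold`.
#' @export
fit_sdm_ensemble <- function(data, members = c("glm", "gam", "rf", "svm",
                                               "brt"),
                             reps = 10, split = 0.7,
                             gate_tss = 0.8, gate_auc = 0.9,
                             weighting = c("tss", "equal"), seed = 1L) {
  weighting <- match.arg(weighting)
  if (is.character(members)) members <- .sdm_members()[members]
  stopifnot(length(members) > 0, !is.null(names(members)))
  d <- as.data.frame(data)[, setdiff(names(data), c("lon", "lat"))]
  pres <- which(d$label == 1)
  bg <- which(d$label == 0)
  if (length(pres) < 4)
    stop("too few presences for a ", split, " calibration split")
  set.seed(seed)
  met <- array(NA_real_, c(length(members), reps, 2),
               dimnames = list(names(members), NULL, c("auc", "tss")))
  for (r in seq_len(reps)) {
    cal <- c(sample(pres, max(2, round(split * length(pres)))),
             sample(bg, max(2, round(split * length(bg)))))
    val <- setdiff(seq_len(nrow(d)), cal)
    if (length(unique(d$label[val])) < 2) next
    for (m in names(members)) {
      fit <- try(members[[m]]$fit(d[cal, , drop = FALSE]), silent = TRUE)
      if (inherits(fit, "try-error")) next
      sc <- try(members[[m]]$predict(
        fit, d[val, setdiff(names(d), "label"), drop = FALSE]),
        silent = TRUE)
      if (inherits(sc, "try-error") || anyNA(sc)) next
      met[m, r, "auc"] <- auc_score(d$label[val], sc)
      met[m, r, "tss"] <- as.numeric(tss_score(d$label[val], sc))
    }
  }
  metrics <- data.frame(
    member = names(members),
    auc = apply(met[, , "auc", drop = FALSE], 1, mean, na.rm = TRUE),
    tss = apply(met[, , "tss", drop = FALSE], 1, mean, na.rm = TRUE),
    row.names = NULL)
  metrics$accepted <- !is.na(metrics$auc) & !is.na(metrics$tss) &
    metrics$tss > gate_tss & metrics$auc > gate_auc
  if (!any(metrics$accepted))
    stop("all members failed the TSS/AUC gates:\n",
         paste(sprintf("  %s: AUC = %.3f, TSS = %.3f", metrics$member,
                       metrics$auc, metrics$tss), collapse = "\n"))
  acc <- metrics$member[metrics$accepted]
  fits <- lapply(acc, function(m) members[[m]]$fit(d))
  names(fits) <- acc
  w <- if (weighting == "tss") metrics$tss[metrics$accepted]
    else rep(1, length(acc))
  w <- w / sum(w)
  names(w) <- acc
  obj <- structure(list(members = members[acc], fits = fits, weights = w,
                        metrics = metrics,
                        variables = setdiff(names(d), "label"),
                        gates = c(tss = gate_tss, auc = gate_auc)),
                   class = "sdm_ensemble")
  full_scores <- stats::predict(obj, d[setdiff(names(d), "label")])
  obj$threshold <- attr(tss_score(d$label, full_scores), "threshold")
  obj
}

#' @export
predict.sdm_ensemble <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$variables, names(newdata))
  if (length(miss)) stop("missing variable(s): ", paste(miss, collapse = ", "))
  nd <- newdata[object$variables]
  s <- rep(0, nrow(nd))
  for (m in names(object$fits))
    s <- s + object$weights[[m]] * object$members[[m]]$predict(
      object$fits[[m]], nd)
  pmin(pmax(s, 0), 1)
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat("sdm_ensemble with", length(x$fits), "accepted member(s)\n")
  print(x$metrics, row.names = FALSE)
  cat("weights:", paste(sprintf("%s=%.3f", names(x$weights), x$weights),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Project ensemble suitability onto a climate grid
#'
#' @param ensemble a fitted `sdm_ensemble`.
#' @param grid a `climate_grid` covering the model variables.
#' @return suitability matrix in the grid layout (values in `[0, 1]`,
#'   NA cells propagated).
#' @export
suitability_map <- function(ensemble, grid) {
  stopifnot(inherits(grid, "climate_grid"))
  miss <- setdiff(ensemble$variables, names(grid$layers))
  if (length(miss)) stop("missing layer(s): ", paste(miss, collapse = ", "))
  nd <- as.data.frame(lapply(grid$layers[ensemble$variables],
                             function(z) as.vector(t(z))))
  ok <- stats::complete.cases(nd)
  s <- rep(NA_real_, nrow(nd))
  if (any(ok)) s[ok] <- stats::predict(ensemble, nd[ok, , drop = FALSE])
  as_grid_matrix(s, grid)
}

#' Ecological vulnerability map
#'
#' `V_E = S_future - S_present`, cell by cell: negative values mean suitable
#' habitat is lost under the future scenario.
#'
#' @param s_future,s_present co-registered suitability grids in `[0, 1]`.
#' @return matrix of V_E values in `[-1, 1]`.
#' @export
ecological_vulnerability <- function(s_future, s_present) {
  if (!identical(dim(s_future), dim(s_present)))
    stop("geometry mismatch between suitability grids")
  s_future - s_present
}

#' Suitable-habitat area change between scenarios
#'
#' Counts area (latitude-corrected spherical cell areas) with suitability at
#' or above the threshold in each scenario and reports the percent change of
#' the future scenario relative to the present.
#'
#' @param s_present,s_future suitability matrices in grid layout.
#' @param threshold suitability cutoff in (0, 1).
#' @param grid the `climate_grid` (for cell geometry), or `NULL` with
#'   explicit `cell_areas`.
#' @param cell_areas optional matrix of cell areas overriding the spherical
#'   computation.
#' @return list: `area_present`, `area_future` (km^2), `pct_change`.
#' @export
habitat_area_change <- function(s_present, s_future, threshold = 0.5,
                                grid = NULL, cell_areas = NULL) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (is.null(cell_areas)) {
    stopifnot(!is.null(grid))
    res <- abs(diff(grid$lon[1:2]))
    km_deg <- 111.32
    row_area <- (res * km_deg)^2 * cos(grid$lat * pi / 180)
    cell_areas <- matrix(row_area, nrow = length(grid$lat),
                         ncol = length(grid$lon))
  }
  a_p <- sum(cell_areas[!is.na(s_present) & s_present >= threshold])
  a_f <- sum(cell_areas[!is.na(s_future) & s_future >= threshold])
  list(area_present = a_p, area_future = a_f,
       pct_change = if (a_p > 0) (a_f - a_p) / a_p * 100 else NA_real_)
}
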