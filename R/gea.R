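#' Iterative variance-inflation-factor pruning of environmental variables
#'
#' Repeatedly removes the variable with the largest VIF until all remaining
#' VIFs are at or below the threshold. Exact VIF ties are broken by variable
#' name order, so the result does not depend on column order.
#'
#' @param env data.frame or matrix of environmental variables (observations
#'   in rows).
#' @param threshold maximum admissible VIF (default 10).
#' @return character vector of retained variable names, with the final VIFs
#'   in attribute `vif` and removed variables in attribute `removed`.
#' @export
prune_vif <- function(env, threshold = 10) {
  env <- as.data.frame(env)
  if (ncol(env) < 2) stop("need at least 2 variables")
  if (nrow(env) < ncol(env) + 1)
    stop("need at least variables + 1 observations")
  sds <- vapply(env, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("constant column(s) make the centered design singular: ",
         paste(names(env)[sds == 0], collapse = ", "))
  vif_of <- function(dat) {
    vapply(names(dat), function(v) {
      rhs <- dat[setdiff(names(dat), v)]
      rhs$.response <- dat[[v]]
      r2 <- summary(stats::lm(.response ~ ., data = rhs))$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  keep <- sort(names(env))
  removed <- character(0)
  while (length(keep) > 1) {
    v <- vif_of(env[keep])
    if (max(v) <= threshold) break
    worst <- names(v)[v == max(v)][1]   # keep is name-sorted: ties by name
    removed <- c(removed, worst)
    keep <- setdiff(keep, worst)
  }
  final_vif <- if (length(keep) > 1) vif_of(env[keep])
    else stats::setNames(1, keep)
  structure(keep, vif = final_vif, removed = removed)
}

# per-SNP mean imputation of missing dosages, individuals in rows
.impute_dosage <- function(geno) {
  x <- t(geno)
  for (j in which(colSums(is.na(x)) > 0)) {
    m <- mean(x[, j], na.rm = TRUE)
    x[is.na(x[, j]), j] <- if (is.finite(m)) m else 0
  }
  x
}

#' Constrained-ordination (RDA) outlier scan for climate-associated SNPs
#'
#' Ordinates mean-imputed, centred SNP dosages on the environmental
#' variables, keeps the constrained axes that are significant under a row
#' permutation test, and flags as outliers the SNPs whose loading on any
#' significant axis lies more than `sd_mult` standard deviations from the
#' mean loading of that axis.
#'
#' @param geno dosage matrix (sites x individuals).
#' @param env data.frame of (pruned) environmental variables, one row per
#'   individual.
#' @param permutations permutations for the per-axis significance test.
#' @param alpha axis significance level.
#' @param sd_mult loading outlier cutoff in per-axis SDs.
#' @param seed RNG seed for the permutation test.
#' @return data.frame: per SNP, loadings on each retained axis and an
#'   `outlier` flag; attributes `axis_p` (per-axis p-values) and
#'   `sig_axes`.
#' @export
rda_scan <- function(geno, env, permutations = 999, alpha = 0.05,
                     sd_mult = 2, seed = 1L) {
  env <- as.data.frame(env)
  if (ncol(env) >= nrow(env)) stop("more constraints than samples - 1")
  x <- .impute_dosage(geno)
  set.seed(seed)
  mod <- vegan::rda(x ~ ., data = env)
  n_axes <- ncol(env)
  if (is.finite(alpha) && permutations >= 1) {
    an <- vegan::anova.cca(mod, by = "axis", permutations = permutations)
    axis_p <- an[["Pr(>F)"]][seq_len(nrow(an) - 1)]
    names(axis_p) <- rownames(an)[seq_len(nrow(an) - 1)]
    sig <- which(axis_p < alpha)
  } else {                              # keep every constrained axis
    axis_p <- stats::setNames(rep(NA_real_, n_axes),
                              paste0("RDA", seq_len(n_axes)))
    sig <- seq_len(n_axes)
  }
  snp_ids <- rownames(geno)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(nrow(geno)))
  res <- data.frame(id = snp_ids, outlier = FALSE)
  if (length(sig)) {
    sc <- vegan::scores(mod, choices = sig, display = "species")
    sc <- as.matrix(sc)
    out <- rep(FALSE, nrow(sc))
    for (k in seq_len(ncol(sc))) {
      z <- sc[, k]
      out <- out | abs(z - mean(z)) > sd_mult * stats::sd(z)
      res[[colnames(sc)[k]]] <- z
    }
    res$outlier <- out
  }
  attr(res, "axis_p") <- axis_p
  attr(res, "sig_axes") <- names(axis_p)[sig]
  res
}

#' Latent-factor association scan
#'
#' Tests each SNP's dosage for association with the environmental variables
#' while adjusting for `K` latent factors that absorb neutral population
#' structure. Factors are estimated in two stages so genuine environmental
#' signal is not swallowed by the structure correction: a first pass uses the
#' leading axes of the genotype matrix after projecting out the environment,
#' provisionally flags associated SNPs, and the final factors are the leading
#' principal axes of the remaining (putatively neutral) SNPs. The per-SNP
#' joint F-test p-values are then calibrated with the genomic inflation
#' factor (standard latent-factor-model practice) before Benjamini-Hochberg
#' adjustment.
#'
#' @param geno dosage matrix (sites x individuals).
#' @param env data.frame of environmental variables (no constant columns).
#' @param K number of latent factors (`0 <= K < n individuals`); `K = 0`
#'   adjusts for the intercept only and illustrates structure confounding.
#' @param fdr candidate q-value cutoff.
#' @param gif apply genomic-inflation-factor calibration (default TRUE).
#' @return data.frame: `id`, `f`, `p_raw`, `p` (calibrated), `q`,
#'   `candidate`; the estimated inflation factor is in attribute `lambda`.
#' @export
latent_factor_scan <- function(geno, env, K = 2, fdr = 0.05, gif = TRUE) {
  env <- as.matrix(as.data.frame(env))
  n <- ncol(geno)
  if (K >= n) stop("K must be smaller than the number of individuals")
  if (any(apply(env, 2, stats::sd) == 0))
    stop("constant environmental column")
  x <- .impute_dosage(geno)               # individuals x SNPs
  f_pvals <- function(covars) {
    qc <- qr.Q(qr(covars))
    g_r <- x - qc %*% crossprod(qc, x)
    e_r <- env - qc %*% crossprod(qc, env)
    qe <- qr.Q(qr(e_r))
    p_e <- ncol(qe)
    rss0 <- colSums(g_r^2)
    expl <- colSums(crossprod(qe, g_r)^2)
    rss1 <- pmax(rss0 - expl, 0)
    df2 <- n - ncol(covars) - p_e
    if (df2 <= 0) stop("not enough individuals for the requested model")
    f <- (expl / p_e) / (rss1 / df2)
    p <- stats::pf(f, p_e, df2, lower.tail = FALSE)
    p[rss0 < 1e-12] <- 1                  # monomorphic after imputation
    list(f = f, p = p)
  }
  if (K > 0) {
    qx <- qr.Q(qr(cbind(1, env)))
    u1 <- svd(x - qx %*% crossprod(qx, x), nu = K, nv = 0)$u
    p1 <- f_pvals(cbind(1, u1))$p
    excl <- stats::p.adjust(p1, "BH") < fdr
    if (mean(excl) > 0.2) excl <- rank(p1) <= 0.2 * length(p1)
    u2 <- svd(scale(x[, !excl, drop = FALSE], scale = FALSE),
              nu = K, nv = 0)$u
    res <- f_pvals(cbind(1, u2))
  } else {
    res <- f_pvals(matrix(1, n, 1))
  }
  z <- stats::qchisq(res$p, df = 1, lower.tail = FALSE)
  lambda <- stats::median(z) / stats::qchisq(0.5, df = 1)
  p_cal <- if (gif && is.finite(lambda) && lambda > 0)
    stats::pchisq(z / lambda, df = 1, lower.tail = FALSE) else res$p
  q <- stats::p.adjust(p_cal, method = "BH")
  ids <- rownames(geno)
  if (is.null(ids)) ids <- paste0("snp", seq_len(nrow(geno)))
  out <- data.frame(id = ids, f = res$f, p_raw = res$p, p = p_cal, q = q,
                    candidate = q < fdr, row.names = NULL)
  attr(out, "lambda") <- lambda
  out
}

#' Genomic inflation factor of a p-value set
#'
#' Median observed chi-square (1 df) statistic divided by its null median;
#' values near 1 indicate a well-calibrated test.
#'
#' @param p numeric vector of p-values.
#' @return scalar lambda.
#' @export
inflation_factor <- function(p) {
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE), na.rm = TRUE) /
    stats::qchisq(0.5, df = 1)
}

#' Two-method genotype-environment association screen
#'
#' Runs the ordination loading-outlier scan and the latent-factor scan and
#' intersects their candidate sets: only SNPs flagged by both methods are
#' final climate-association candidates.
#'
#' @param geno dosage matrix (sites x individuals).
#' @param env environmental data.frame; pruned first when `prune = TRUE`.
#' @param K latent factor count.
#' @param fdr FDR cutoff for the latent-factor arm.
#' @param permutations,alpha,sd_mult ordination-arm settings.
#' @param prune apply [prune_vif()] before testing.
#' @param seed RNG seed.
#' @return list of class `gea_result`: `candidates` (ids), `rda`, `lfa`
#'   (per-method tables), `variables` used, and per-method counts.
#' @export
gea_scan <- function(geno, env, K = 2, fdr = 0.05, permutations = 999,
                     alpha = 0.05, sd_mult = 2, prune = TRUE, seed = 1L) {
  env <- as.data.frame(env)
  vars <- if (prune && ncol(env) > 1) prune_vif(env) else names(env)
  env <- env[, vars, drop = FALSE]
  rda_res <- rda_scan(geno, env, permutations, alpha, sd_mult, seed)
  lfa_res <- latent_factor_scan(geno, env, K, fdr)
  cand <- intersect_gea(rda_res$id[rda_res$outlier],
                        lfa_res$id[lfa_res$candidate])
  structure(list(candidates = cand$candidates, rda = rda_res, lfa = lfa_res,
                 variables = vars,
                 counts = c(rda = sum(rda_res$outlier),
                            lfa = sum(lfa_res$candidate),
                            both = length(cand$candidates))),
            class = "gea_result")
}

#' Intersect the candidate sets of the two association methods
#'
#' @param rda_ids,lfa_ids candidate SNP identifiers from each method
#'   (shared namespace).
#' @return list: `candidates` (sorted intersection) and per-method counts.
#' @export
intersect_gea <- function(rda_ids, lfa_ids) {
  list(candidates = sort(intersect(rda_ids, lfa_ids)),
       n_rda = length(unique(rda_ids)), n_lfa = length(unique(lfa_ids)))
}

#' @export
print.gea_result <- function(x, ...) {
  cat("GEA screen on variables:", paste(x$variables, collapse = ", "), "\n")
  cat("  ordination outliers:", x$counts["rda"],
      "| latent-factor candidates:", x$counts["lfa"],
      "| intersection:", x$counts["both"], "\n")
  invisible(x)
}
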