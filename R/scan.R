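#' Weir-Cockerham variance components for one biallelic site
#'
#' Returns the a (among-population), b (among-individual) and c
#' (within-individual) components of the Weir-Cockerham Fst estimator for two
#' (or more) populations of diploids, from genotype dosages.
#'
#' @param g integer vector of allele dosage (0/1/2, NA = missing) for one site.
#' @param pop factor of population labels, aligned with `g`.
#' @return numeric vector `c(a, b, c)`; all zero when fewer than two
#'   populations have calls.
#' @export
wc_components <- function(g, pop) {
  ok <- !is.na(g)
  g <- g[ok]
  pop <- factor(pop[ok])
  n_i <- tabulate(pop)
  keep <- n_i > 0
  r <- sum(keep)
  if (r < 2) return(c(a = 0, b = 0, c = 0))
  n_i <- n_i[keep]
  lev <- levels(pop)[keep]
  p_i <- vapply(lev, function(l) mean(g[pop == l]) / 2, numeric(1))
  h_i <- vapply(lev, function(l) mean(g[pop == l] == 1L), numeric(1))
  n_bar <- mean(n_i)
  if (n_bar <= 1) return(c(a = 0, b = 0, c = 0))
  nc <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n_i * p_i) / (r * n_bar)
  s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n_i * h_i) / (r * n_bar)
  a <- (n_bar / nc) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
       (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  c(a = a, b = b, c = cc)
}

# per-site nucleotide diversity (average pairwise difference) from dosages
.pi_site <- function(g) {
  g <- g[!is.na(g)]
  n <- 2L * length(g)
  if (n < 2) return(0)
  d <- sum(g)
  2 * d * (n - d) / (n * (n - 1))
}

#' Sliding-window Fst and nucleotide-diversity scan
#'
#' Computes the Weir-Cockerham weighted (ratio-of-sums) Fst and per-population
#' nucleotide diversity in sliding windows (default 50 kb windows, 25 kb
#' step). Window pi divides the summed per-site pairwise diversity by the
#' window length in bp (unobserved positions count as invariant). Chromosomes
#' or scaffolds shorter than one window length are skipped. The Hudson
#' estimator (ratio of averages of 1 - Hw/Hb) is available via
#' `estimator = "hudson"`.
#'
#' @param geno dosage matrix (sites x individuals); allele coding (ALT or
#'   derived) does not affect the estimators.
#' @param sites data.frame with `chrom` and `pos` (1-based) per row of `geno`.
#' @param pop population label vector, one per column of `geno`.
#' @param pop_a,pop_b the two populations to contrast.
#' @param window,step window size and step in bp (both > 0).
#' @param min_snps windows with fewer SNPs are flagged `low_support`.
#' @param chrom_lengths optional named vector; defaults to the largest
#'   observed position per chromosome.
#' @param estimator `"wc"` (Weir-Cockerham, default) or `"hudson"`.
#' @return data.frame of class `window_stats`: `chrom, start, end` (0-based
#'   half-open), `n_snps, fst, pi_a, pi_b, pi_ratio, low_support`.
#'   `pi_ratio` is `pi_a / pi_b`, `NA`-flagged where `pi_b` is 0.
#' @export
windowed_fst <- function(geno, sites, pop, pop_a = "A", pop_b = "B",
                         window = 50000, step = 25000, min_snps = 3,
                         chrom_lengths = NULL, estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  if (window <= 0 || step <= 0) stop("window and step must be > 0")
  sel <- pop %in% c(pop_a, pop_b)
  geno <- geno[, sel, drop = FALSE]
  pop <- factor(pop[sel], levels = c(pop_a, pop_b))
  comp <- t(apply(geno, 1, wc_components, pop = pop))
  pi_a_site <- apply(geno[, pop == pop_a, drop = FALSE], 1, .pi_site)
  pi_b_site <- apply(geno[, pop == pop_b, drop = FALSE], 1, .pi_site)
  if (estimator == "hudson") {
    hud <- t(apply(geno, 1, function(g) {
      pa <- mean(g[pop == pop_a], na.rm = TRUE) / 2
      pb <- mean(g[pop == pop_b], na.rm = TRUE) / 2
      na <- 2 * sum(!is.na(g[pop == pop_a]))
      nb <- 2 * sum(!is.na(g[pop == pop_b]))
      if (na < 2 || nb < 2) return(c(num = 0, den = 0))
      hw <- (2 * pa * (1 - pa) * na / (na - 1) +
               2 * pb * (1 - pb) * nb / (nb - 1)) / 2
      hb <- pa * (1 - pb) + pb * (1 - pa)
      c(num = hb - hw, den = hb)
    }))
  }
  out <- list()
  for (chr in unique(sites$chrom)) {
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[chr]]
      else max(sites$pos[sites$chrom == chr])
    if (is.na(len) || len < window) next   # scaffold shorter than one window
    starts <- seq(0, max(0, len - window), by = step)
    on_chr <- sites$chrom == chr
    for (st in starts) {
      en <- st + window
      idx <- which(on_chr & sites$pos > st & sites$pos <= en)
      n <- length(idx)
      if (estimator == "wc") {
        den <- sum(comp[idx, , drop = FALSE])
        fst <- if (n && den > 0) sum(comp[idx, 1]) / den else NA_real_
      } else {
        den <- sum(hud[idx, "den"])
        fst <- if (n && den > 0) sum(hud[idx, "num"]) / den else NA_real_
      }
      pa <- sum(pi_a_site[idx]) / window
      pb <- sum(pi_b_site[idx]) / window
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = st, end = en, n_snps = n, fst = fst,
        pi_a = pa, pi_b = pb,
        pi_ratio = if (pb > 0) pa / pb else NA_real_,
        low_support = n < min_snps)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("window_stats", class(res))
  res
}

#' Pairwise Weir-Cockerham Fst matrix across populations
#'
#' Genome-wide ratio-of-sums Weir-Cockerham Fst for every pair of
#' populations; negative estimates are kept (small negatives are expected
#' from the unbiased estimator). Used to calibrate the dissimilarity-based
#' turnover model.
#'
#' @param geno dosage matrix (sites x individuals).
#' @param pop population label vector per column.
#' @return symmetric matrix of pairwise Fst with zero diagonal.
#' @export
pairwise_fst <- function(geno, pop) {
  lev <- sort(unique(pop))
  k <- length(lev)
  out <- matrix(0, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    sel <- pop %in% lev[c(i, j)]
    comp <- t(apply(geno[, sel, drop = FALSE], 1, wc_components,
                    pop = pop[sel]))
    den <- sum(comp)
    out[i, j] <- out[j, i] <- if (den > 0) sum(comp[, 1]) / den else 0
  }
  out
}

#' Top-quantile outlier windows
#'
#' Returns the rows whose score is at or above the empirical `1 - q` quantile
#' (ties at the threshold included) — the "top 1%" genome-wide cut by default.
#'
#' @param stats a data.frame (e.g. from [windowed_fst()]).
#' @param score column name to rank on.
#' @param q upper tail fraction (default 0.01); `q = 1` returns everything.
#' @param na_rm drop rows with missing scores first.
#' @return the outlier subset, with the threshold in attribute `threshold`.
#' @export
top_quantile_outliers <- function(stats, score = "fst", q = 0.01,
                                  na_rm = TRUE) {
  x <- stats[[score]]
  keep <- if (na_rm) !is.na(x) else rep(TRUE, length(x))
  if (sum(keep) < 100 && q < 1)
    warning("fewer than 100 scored windows; the top-", q * 100,
            "% cut is poorly resolved")
  thr <- stats::quantile(x[keep], 1 - q, names = FALSE)
  out <- stats[keep & x >= thr, , drop = FALSE]
  attr(out, "threshold") <- thr
  out
}

#' Intersect candidate sets from multiple selection-scan methods
#'
#' Given named sets of window/gene identifiers produced by different methods
#' (e.g. an Fst + pi-ratio scan plus externally computed composite-likelihood
#' scans), reports per-combination Venn counts and the identifiers supported
#' by at least `k` methods.
#'
#' @param sets named list of character vectors sharing one identifier
#'   namespace.
#' @param k minimum number of supporting methods (the headline candidate set
#'   typically uses `k = 2` or `k = length(sets)`).
#' @return list: `candidates` (sorted ids in >= k sets), `support` (named
#'   integer vector), `venn` (data.frame: membership pattern and count).
#' @export
intersect_candidates <- function(sets, k = 2) {
  if (!length(sets)) stop("need at least one candidate set")
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- paste0("set", seq_along(sets))
  all_ids <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) all_ids %in% s,
                 logical(length(all_ids)))
  memb <- matrix(memb, nrow = length(all_ids),
                 dimnames = list(all_ids, names(sets)))
  support <- rowSums(memb)
  pattern <- apply(memb, 1, function(r) paste(names(sets)[r], collapse = "&"))
  venn <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(venn) <- c("combination", "count")
  list(candidates = all_ids[support >= k],
       support = support,
       venn = venn)
}
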