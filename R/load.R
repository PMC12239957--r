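#' Per-site derived-allele frequencies for two populations
#'
#' For every site, counts derived alleles (`d`) and called alleles (`n`,
#' two per non-missing genotype) in each population and returns
#' `f = d / n`. Sites with no called alleles in either population are
#' excluded (and counted in the `dropped` attribute).
#'
#' @param pol a `polarized_data` object (derived-dosage genotypes).
#' @param pop_a,pop_b population labels in `pol$samples$population`.
#' @return data.frame with columns `id, chrom, pos, class, grantham, gerp,
#'   deleterious_missense, gerp_deleterious, dA, nA, fA, dB, nB, fB`.
#' @export
derived_freq_table <- function(pol, pop_a = "A", pop_b = "B") {
  pops <- pol$samples$population
  ga <- pol$geno[, pops == pop_a, drop = FALSE]
  gb <- pol$geno[, pops == pop_b, drop = FALSE]
  dA <- rowSums(ga, na.rm = TRUE)
  nA <- 2L * rowSums(!is.na(ga))
  dB <- rowSums(gb, na.rm = TRUE)
  nB <- 2L * rowSums(!is.na(gb))
  keep <- nA > 0 & nB > 0
  ft <- data.frame(pol$sites[, c("id", "chrom", "pos", "class", "grantham",
                                 "gerp", "deleterious_missense",
                                 "gerp_deleterious")],
                   dA = dA, nA = nA, fA = dA / nA,
                   dB = dB, nB = nB, fB = dB / nB)[keep, , drop = FALSE]
  rownames(ft) <- NULL
  attr(ft, "dropped") <- sum(!keep)
  ft
}

# rows of a frequency table belonging to a load class
.class_rows <- function(ft, class) {
  switch(class,
         harmful_missense = which(ft$class == "missense" &
                                    ft$deleterious_missense %in% TRUE),
         gerp_deleterious = which(ft$gerp_deleterious),
         which(ft$class == class))
}

#' Normalised derived-allele burden L_A,B for a site class
#'
#' Computes `sum_{i in C} fA_i (1 - fB_i) / sum_{j in I} fA_j (1 - fB_j)`,
#' the burden of class-C derived alleles in population A private relative to
#' B, normalised by the same quantity over intergenic (putatively neutral)
#' sites.
#'
#' @param fa_c,fb_c derived-allele frequencies of A and B at class-C sites.
#' @param fa_i,fb_i frequencies at the intergenic reference sites.
#' @return a scalar; `NA` (with a warning) when the intergenic denominator
#'   is zero — never silently 0.
#' @export
l_ab <- function(fa_c, fb_c, fa_i, fb_i) {
  stopifnot(length(fa_c) == length(fb_c), length(fa_i) == length(fb_i))
  if (!length(fa_c) || !length(fa_i)) stop("C and I must be non-empty")
  den <- sum(fa_i * (1 - fb_i))
  if (den == 0) {
    warning("intergenic normaliser is zero; L_A,B undefined")
    return(NA_real_)
  }
  sum(fa_c * (1 - fb_c)) / den
}

#' R_A/B ratio with block-jackknife standard deviation
#'
#' `R_A/B(C) = L_A,B(C) / L_B,A(C)`: values above 1 mean class-C derived
#' alleles are relatively more frequent in population A. The standard
#' deviation is a delete-one block jackknife over `blocks` contiguous
#' positional blocks; class and intergenic sites are blocked jointly in
#' genome order so linked sites leave together.
#'
#' @param ft a [derived_freq_table()].
#' @param class one of `"synonymous"`, `"missense"`, `"harmful_missense"`,
#'   `"lof"`, `"gerp_deleterious"`.
#' @param intergenic_class class used as the neutral reference set.
#' @param blocks number of jackknife blocks (reduced with a warning when
#'   there are fewer polymorphic sites than blocks).
#' @return list: `r` (the ratio), `sd` (jackknife SD), `l_ab`, `l_ba`,
#'   `blocks` (number used), `n_class`, `n_intergenic`.
#' @export
r_ab <- function(ft, class, intergenic_class = "intergenic", blocks = 100) {
  ci <- .class_rows(ft, class)
  ii <- .class_rows(ft, intergenic_class)
  if (!length(ci)) stop("no sites in class ", class)
  if (!length(ii)) stop("no intergenic reference sites")
  lab <- l_ab(ft$fA[ci], ft$fB[ci], ft$fA[ii], ft$fB[ii])
  lba <- l_ab(ft$fB[ci], ft$fA[ci], ft$fB[ii], ft$fA[ii])
  if (is.na(lab) || is.na(lba) || lba == 0)
    stop("R_A/B undefined: L values ", lab, " / ", lba)
  r <- lab / lba

  used <- sort(union(ci, ii))
  ord <- used[order(ft$chrom[used], ft$pos[used])]
  b <- min(blocks, length(ord))
  if (b < blocks)
    warning("fewer polymorphic sites than blocks; using ", b, " blocks")
  blk <- stats::setNames(
    rep(seq_len(b), each = ceiling(length(ord) / b))[seq_along(ord)],
    as.character(ord))
  r_jack <- vapply(seq_len(b), function(k) {
    drop <- as.integer(names(blk)[blk == k])
    ck <- setdiff(ci, drop)
    ik <- setdiff(ii, drop)
    if (!length(ck) || !length(ik)) return(NA_real_)
    labk <- l_ab(ft$fA[ck], ft$fB[ck], ft$fA[ik], ft$fB[ik])
    lbak <- l_ab(ft$fB[ck], ft$fA[ck], ft$fB[ik], ft$fA[ik])
    labk / lbak
  }, numeric(1))
  r_jack <- r_jack[is.finite(r_jack)]
  bb <- length(r_jack)
  sd_jack <- if (bb > 1)
    sqrt((bb - 1) / bb * sum((r_jack - mean(r_jack))^2)) else 0
  list(r = r, sd = sd_jack, l_ab = lab, l_ba = lba, blocks = bb,
       n_class = length(ci), n_intergenic = length(ii))
}

#' Per-individual derived-allele counts, normalised by synonymous burden
#'
#' For each individual and site class, counts the total number of derived
#' alleles (sum of dosage) and the number of derived alleles in homozygous
#' state (2 per homozygous-derived genotype), then divides both by that
#' individual's total derived synonymous count, making burdens comparable
#' across individuals with different call rates. Individuals with zero
#' derived synonymous alleles get `NA` normalised counts.
#'
#' @param pol a `polarized_data` object.
#' @param classes site classes to report.
#' @return data.frame: one row per individual x class with raw and
#'   normalised total/homozygous derived counts.
#' @export
per_individual_counts <- function(pol, classes = c("lof", "harmful_missense",
                                                   "missense", "synonymous")) {
  st <- pol$sites
  syn <- which(st$class == "synonymous")
  syn_tot <- colSums(pol$geno[syn, , drop = FALSE], na.rm = TRUE)
  res <- lapply(classes, function(cl) {
    rows <- switch(cl,
                   harmful_missense = which(st$class == "missense" &
                                              st$deleterious_missense %in% TRUE),
                   which(st$class == cl))
    g <- pol$geno[rows, , drop = FALSE]
    tot <- colSums(g, na.rm = TRUE)
    hom <- 2 * colSums(g == 2L, na.rm = TRUE)
    data.frame(id = pol$samples$id, population = pol$samples$population,
               class = cl, n_sites = length(rows),
               derived_total = tot, derived_hom = hom,
               derived_total_norm = ifelse(syn_tot > 0, tot / syn_tot, NA),
               derived_hom_norm = ifelse(syn_tot > 0, hom / syn_tot, NA),
               row.names = NULL)
  })
  do.call(rbind, res)
}

#' Two-sample t-tests on normalised per-individual burdens
#'
#' @param counts output of [per_individual_counts()].
#' @param pop_a,pop_b population labels to compare.
#' @return data.frame: per class and measure (total / homozygous), group
#'   means, t statistic and p-value (Welch).
#' @export
load_t_tests <- function(counts, pop_a = "A", pop_b = "B") {
  out <- list()
  for (cl in unique(counts$class)) {
    d <- counts[counts$class == cl, ]
    for (meas in c("derived_total_norm", "derived_hom_norm")) {
      xa <- d[[meas]][d$population == pop_a]
      xb <- d[[meas]][d$population == pop_b]
      tt <- tryCatch(stats::t.test(xa, xb), error = function(e) NULL)
      out[[paste(cl, meas)]] <- data.frame(
        class = cl, measure = meas,
        mean_a = mean(xa, na.rm = TRUE), mean_b = mean(xb, na.rm = TRUE),
        t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
        p = if (is.null(tt)) NA_real_ else tt$p.value)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' GERP-weighted masked and realized genetic load per individual
#'
#' Masked load: sum of GERP scores of deleterious derived alleles carried in
#' heterozygous genotypes (hidden from selection under recessivity), divided
#' by the number of called genotypes of that individual. Realized load: the
#' same sum over homozygous-derived genotypes (expressed), with an identical
#' denominator by default; `denominator = "genome_wide"` divides by the total
#' number of annotated sites instead.
#'
#' @param pol a `polarized_data` object with `gerp_deleterious` flags.
#' @param denominator `"per_individual"` (called, non-missing sites of the
#'   individual) or `"genome_wide"` (all annotated sites).
#' @return data.frame: per individual, `called`, `masked_load`,
#'   `realized_load` (GERP-score units per genotype).
#' @export
gerp_load <- function(pol, denominator = c("per_individual", "genome_wide")) {
  denominator <- match.arg(denominator)
  del <- which(pol$sites$gerp_deleterious)
  g <- pol$geno[del, , drop = FALSE]
  gerp <- pol$sites$gerp[del]
  called <- colSums(!is.na(pol$geno))
  if (any(called == 0))
    stop("individual(s) with no called sites: ",
         paste(pol$samples$id[called == 0], collapse = ", "))
  den <- if (denominator == "per_individual") called
    else rep(nrow(pol$geno), ncol(pol$geno))
  masked <- colSums(gerp * (g == 1L), na.rm = TRUE) / den
  realized <- colSums(gerp * (g == 2L), na.rm = TRUE) / den
  data.frame(id = pol$samples$id, population = pol$samples$population,
             called = called, masked_load = masked, realized_load = realized,
             row.names = NULL)
}

#' Full genetic-load report
#'
#' Computes R_A/B ratios (with jackknife SDs) for the requested classes,
#' per-individual normalised burdens with group t-tests, and GERP-based
#' masked/realized loads.
#'
#' @param pol a `polarized_data` object.
#' @param pop_a,pop_b population labels (A is the focal, e.g. bottlenecked,
#'   group).
#' @param classes classes for the R statistics.
#' @param blocks jackknife block count.
#' @return list of class `load_report`: `r_stats` (data.frame), `counts`,
#'   `t_tests`, `gerp` and the frequency table used.
#' @export
load_report <- function(pol, pop_a = "A", pop_b = "B",
                        classes = c("synonymous", "harmful_missense", "lof"),
                        blocks = 100) {
  ft <- derived_freq_table(pol, pop_a, pop_b)
  r_stats <- do.call(rbind, lapply(classes, function(cl) {
    r <- r_ab(ft, cl, blocks = blocks)
    data.frame(class = cl, r = r$r, sd = r$sd, l_ab = r$l_ab, l_ba = r$l_ba,
               blocks = r$blocks, n_class = r$n_class)
  }))
  counts <- per_individual_counts(pol)
  structure(list(r_stats = r_stats, counts = counts,
                 t_tests = load_t_tests(counts, pop_a, pop_b),
                 gerp = gerp_load(pol), freq_table = ft,
                 pop_a = pop_a, pop_b = pop_b),
            class = "load_report")
}

#' @export
print.load_report <- function(x, ...) {
  cat("Genetic-load report (A =", x$pop_a, ", B =", x$pop_b, ")\n")
  cat("R_A/B ratios (+/- 2 SD):\n")
  with(x$r_stats, for (i in seq_along(class))
    cat(sprintf("  %-18s R = %.3f +/- %.3f (n = %d sites)\n",
                class[i], r[i], 2 * sd[i], n_class[i])))
  gm <- stats::aggregate(cbind(masked_load, realized_load) ~ population,
                         x$gerp, mean)
  cat("Mean GERP load per population:\n")
  for (i in seq_len(nrow(gm)))
    cat(sprintf("  %s: masked = %.4f, realized = %.4f\n",
                gm$population[i], gm$masked_load[i], gm$realized_load[i]))
  invisible(x)
}
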