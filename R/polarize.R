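#' Infer ancestral alleles from outgroup observations
#'
#' The ancestral allele at a site is the majority allele across the observed
#' outgroup columns; when no strict majority exists (including a 1-1 tie with
#' two outgroups) the site is `"UNRESOLVED"` and is excluded downstream. A
#' single observed outgroup resolves the site by itself. Missing outgroup
#' calls may be `NA`, `""`, `"."` or `"N"`.
#'
#' @param outgroups character matrix (sites x outgroup columns) of observed
#'   alleles.
#' @param ref,alt reference/alternate alleles per site; outgroup alleles
#'   outside `{ref, alt, missing}` are a malformed-input error.
#' @return character vector: the ancestral allele or `"UNRESOLVED"` per site.
#' @export
infer_ancestral <- function(outgroups, ref, alt) {
  outgroups <- as.matrix(outgroups)
  stopifnot(nrow(outgroups) == length(ref), length(ref) == length(alt))
  miss <- is.na(outgroups) | outgroups %in% c("", ".", "N")
  ok <- miss | outgroups == ref[row(outgroups)] | outgroups == alt[row(outgroups)]
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop("malformed outgroup allele at site ", bad[1], ", column ", bad[2],
         ": ", outgroups[bad[1], bad[2]], " not in {ref, alt, missing}")
  }
  n_ref <- rowSums(outgroups == ref[row(outgroups)] & !miss)
  n_alt <- rowSums(outgroups == alt[row(outgroups)] & !miss)
  out <- rep("UNRESOLVED", length(ref))
  out[n_ref > n_alt] <- ref[n_ref > n_alt]
  out[n_alt > n_ref] <- alt[n_alt > n_ref]
  out
}

#' Polarize ALT-coded genotypes to derived-allele dosage
#'
#' Sites whose ancestral allele equals ALT have their dosage flipped
#' (`2 - g`); sites with ancestral equal to REF are unchanged; missing stays
#' missing. Sites with `"UNRESOLVED"` ancestral state are removed from the
#' genotype matrix and reported in the exclusion list. Polarizing twice
#' restores the input dosage.
#'
#' @param geno integer matrix of ALT dosage (sites x individuals).
#' @param ancestral character vector per site: REF allele, ALT allele, or
#'   `"UNRESOLVED"`.
#' @param ref,alt per-site alleles.
#' @return list: `geno` (derived dosage, resolved sites only), `kept`
#'   (row indices kept), `excluded` (row indices of UNRESOLVED sites).
#' @export
polarize <- function(geno, ancestral, ref, alt) {
  stopifnot(nrow(geno) == length(ancestral))
  valid <- ancestral == ref | ancestral == alt | ancestral == "UNRESOLVED"
  if (!all(valid))
    stop("ancestral allele not in {ref, alt, UNRESOLVED} at site ",
         which(!valid)[1])
  excluded <- which(ancestral == "UNRESOLVED")
  kept <- setdiff(seq_len(nrow(geno)), excluded)
  out <- geno[kept, , drop = FALSE]
  flip <- ancestral[kept] == alt[kept]
  out[flip, ] <- 2L - out[flip, ]
  list(geno = out, kept = kept, excluded = excluded)
}

#' Classify missense deleteriousness from the Grantham score
#'
#' Radical (deleterious) amino-acid exchanges are those with Grantham score
#' at or above the threshold (default 150); scores below are benign. Valid
#' Grantham scores span 5-215; out-of-range scores are classified by the same
#' rule with a warning.
#'
#' @param grantham numeric vector of Grantham scores.
#' @param threshold deleteriousness cutoff (inclusive).
#' @return logical vector (`NA` where the score is `NA`).
#' @export
classify_missense <- function(grantham, threshold = 150) {
  oob <- !is.na(grantham) & (grantham < 5 | grantham > 215)
  if (any(oob))
    warning(sum(oob), " Grantham score(s) outside [5, 215]; classified anyway")
  grantham >= threshold
}

#' Classify site deleteriousness from the GERP score
#'
#' A mutation at a strongly constrained position (GERP rejected-substitutions
#' score at or above the threshold, default 4) is flagged as potentially
#' deleterious.
#'
#' @param gerp numeric vector of GERP scores.
#' @param threshold cutoff (inclusive).
#' @return logical vector.
#' @export
classify_gerp <- function(gerp, threshold = 4) {
  gerp >= threshold
}

#' Polarize and annotate a simulated (or imported) data set
#'
#' Runs ancestral inference from the outgroup columns, polarizes the genotype
#' matrix to derived dosage, and attaches `deleterious_missense` and
#' `gerp_deleterious` flags.
#'
#' @param sim a `sim_data` object (or any list with `geno`, `sites`,
#'   `samples` in the same layout).
#' @param grantham_threshold,gerp_threshold classification cutoffs.
#' @return list of class `polarized_data`: `geno` (derived dosage), `sites`
#'   (annotation for retained sites, with `ancestral`, `deleterious_missense`,
#'   `gerp_deleterious`), `samples`, and `excluded` (annotation rows of
#'   unresolved sites).
#' @export
polarize_annotate <- function(sim, grantham_threshold = 150,
                              gerp_threshold = 4) {
  st <- sim$sites
  anc <- infer_ancestral(cbind(st$out1, st$out2), st$ref, st$alt)
  pol <- polarize(sim$geno, anc, st$ref, st$alt)
  sites <- st[pol$kept, , drop = FALSE]
  sites$ancestral <- anc[pol$kept]
  sites$deleterious_missense <- ifelse(
    sites$class == "missense",
    classify_missense(sites$grantham, grantham_threshold), NA)
  sites$gerp_deleterious <- classify_gerp(sites$gerp, gerp_threshold)
  rownames(sites) <- NULL
  structure(list(geno = pol$geno, sites = sites, samples = sim$samples,
                 excluded = st[pol$excluded, , drop = FALSE]),
            class = "polarized_data")
}

#' @export
print.polarized_data <- function(x, ...) {
  cat("polarized_data:", nrow(x$geno), "resolved sites x", ncol(x$geno),
      "individuals;", nrow(x$excluded), "sites excluded (unresolved ancestral)\n")
  invisible(x)
}
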