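#' Export genotypes as VCF
#'
#' Writes a biallelic-SNP VCF (v4.2) with genotypes as GT fields. For raw
#' simulated data the two outgroup alleles travel in INFO fields `AA1`/`AA2`;
#' for polarized data the inferred ancestral allele travels as `AA`. Files
#' ending in `.gz` are written bgzip-compressed via vcfR, otherwise plain
#' text.
#'
#' @param x a `sim_data` or `polarized_data` object.
#' @param file output path.
#' @return the path, invisibly.
#' @export
vcf_export <- function(x, file) {
  st <- x$sites
  anc <- st[["ancestral"]]              # exact match: sim data has none
  info <- if (!is.null(anc)) paste0("AA=", anc)
    else paste0("AA1=", st$out1, ";AA2=", st$out2)
  fix <- cbind(CHROM = st$chrom, POS = as.character(st$pos), ID = st$id,
               REF = st$ref, ALT = st$alt, QUAL = ".", FILTER = "PASS",
               INFO = info)
  gt_code <- c("0/0", "0/1", "1/1")
  g <- x$geno
  if (!is.null(anc)) {                        # derived dosage -> ALT dosage
    flip <- anc == st$alt
    g[flip, ] <- 2L - g[flip, ]
  }
  gt <- matrix(gt_code[g + 1L], nrow = nrow(g), ncol = ncol(g))
  gt[is.na(g)] <- "./."
  colnames(gt) <- x$samples$id
  gt <- cbind(FORMAT = "GT", gt)
  meta <- c("##fileformat=VCFv4.2",
            "##source=genovuln",
            "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
            "##INFO=<ID=AA1,Number=1,Type=String,Description=\"Outgroup 1 allele\">",
            "##INFO=<ID=AA2,Number=1,Type=String,Description=\"Outgroup 2 allele\">")
  if (grepl("\\.gz$", file)) {
    v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
    vcfR::write.vcf(v, file = file)
  } else {
    hdr <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$samples$id), collapse = "\t")
    writeLines(c(meta, hdr, apply(cbind(fix, gt), 1, paste, collapse = "\t")),
               file)
  }
  invisible(file)
}

#' Import a VCF into the package's genotype layout
#'
#' Reads a (possibly compressed) biallelic-SNP VCF via vcfR and returns the
#' ALT-dosage matrix plus a site table carrying any `AA`/`AA1`/`AA2` INFO
#' fields.
#'
#' @param file VCF path.
#' @return list: `geno` (sites x individuals ALT dosage), `sites`
#'   (chrom, pos, id, ref, alt and available INFO alleles).
#' @export
vcf_import <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt),
                   dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dosage[clean == "0/0"] <- 0L
  dosage[clean %in% c("0/1", "1/0")] <- 1L
  dosage[clean == "1/1"] <- 2L
  info <- as.character(v@fix[, "INFO"])
  info_field <- function(key) {
    out <- rep(NA_character_, length(info))
    hit <- grepl(paste0("(^|;)", key, "="), info)
    out[hit] <- sub(paste0(".*(?:^|;)", key, "=([^;]+).*"), "\\1", info[hit])
    out
  }
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      id = fix[, "ID"], ref = fix[, "REF"],
                      alt = fix[, "ALT"],
                      ancestral = info_field("AA"),
                      out1 = info_field("AA1"), out2 = info_field("AA2"),
                      stringsAsFactors = FALSE)
  rownames(dosage) <- sites$id
  list(geno = dosage, sites = sites)
}

#' Write a data.frame as a tab-separated file
#'
#' @param x data.frame.
#' @param file path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
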