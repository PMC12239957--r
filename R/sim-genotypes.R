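#' Parameters for the two-population Wright-Fisher genotype simulator
#'
#' Builds a validated parameter list describing two populations that split
#' `t_split` generations ago, with population A passing through a recent
#' bottleneck (effective size `ne_bottleneck` between `t_bottleneck` and
#' `t_recovery` generations before present) while population B keeps the
#' ancestral size. Sites fall into four functional classes with class-specific
#' selection coefficients; selection is diploid with per-class dominance.
#'
#' @param n_pop_a,n_pop_b diploid sample sizes drawn at present.
#' @param ne_ancestral,ne_bottleneck effective population sizes.
#' @param t_split,t_bottleneck,t_recovery times in generations before present;
#'   must satisfy `t_split > t_bottleneck > t_recovery >= 0`.
#' @param n_sites named integer vector of site counts for classes
#'   `synonymous`, `missense`, `lof`, `intergenic`.
#' @param s_missense,s_lof per-generation selection coefficients (in `[-1, 0]`)
#'   of the derived homozygote.
#' @param h_missense,h_lof dominance of the derived allele. Missense defaults
#'   to additive (0.5); loss-of-function defaults to strong recessivity
#'   (0.02), the regime under which bottlenecks expose and purge high-impact
#'   variants while letting their carriers drift to appreciable frequency.
#' @param mu per-site per-generation mutation rate (recurrent, towards the
#'   derived allele). The default is a desk-scale rate: each simulated site
#'   stands in for a larger functional locus, so mutation input keeps the
#'   deleterious classes segregating at mutation-selection-drift balance.
#' @param n_chromosomes,chrom_length_bp genome layout; loci are unlinked.
#' @param outgroup_error probability that an outgroup column shows the derived
#'   rather than the true ancestral allele.
#' @param f_inbreeding_a,f_inbreeding_b inbreeding coefficient applied when
#'   drawing present-day genotypes (0 = Hardy-Weinberg sampling).
#' @param missing_rate per-genotype missingness probability.
#' @param seed integer RNG seed; identical parameters and seed give
#'   bit-identical output.
#' @return an object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_pop_a = 15, n_pop_b = 15,
                       ne_ancestral = 1000, ne_bottleneck = 10,
                       t_split = 400, t_bottleneck = 120, t_recovery = 20,
                       n_sites = c(synonymous = 600, missense = 600,
                                   lof = 300, intergenic = 1200),
                       s_missense = -0.02, s_lof = -0.15,
                       h_missense = 0.5, h_lof = 0.02,
                       mu = 1e-4,
                       n_chromosomes = 4, chrom_length_bp = 2e6,
                       outgroup_error = 0.02,
                       f_inbreeding_a = 0, f_inbreeding_b = 0,
                       missing_rate = 0,
                       seed = 1L) {
  p <- list(n_pop_a = as.integer(n_pop_a), n_pop_b = as.integer(n_pop_b),
            ne_ancestral = as.integer(ne_ancestral),
            ne_bottleneck = as.integer(ne_bottleneck),
            t_split = as.integer(t_split),
            t_bottleneck = as.integer(t_bottleneck),
            t_recovery = as.integer(t_recovery),
            n_sites = n_sites,
            s_missense = s_missense, s_lof = s_lof,
            h_missense = h_missense, h_lof = h_lof,
            mu = mu,
            n_chromosomes = as.integer(n_chromosomes),
            chrom_length_bp = as.integer(chrom_length_bp),
            outgroup_error = outgroup_error,
            f_inbreeding_a = f_inbreeding_a, f_inbreeding_b = f_inbreeding_b,
            missing_rate = missing_rate,
            seed = as.integer(seed))
  sizes <- c(p$n_pop_a, p$n_pop_b, p$ne_ancestral, p$ne_bottleneck,
             p$n_chromosomes, p$chrom_length_bp, unname(p$n_sites))
  if (any(sizes <= 0)) stop("all sizes and site counts must be > 0")
  needed <- c("synonymous", "missense", "lof", "intergenic")
  if (!all(needed %in% names(p$n_sites)))
    stop("n_sites must name classes: ", paste(needed, collapse = ", "))
  if (!(p$t_split > p$t_bottleneck && p$t_bottleneck > p$t_recovery &&
        p$t_recovery >= 0))
    stop("need t_split > t_bottleneck > t_recovery >= 0")
  for (s in c(p$s_missense, p$s_lof))
    if (s > 0 || s < -1) stop("selection coefficients must lie in [-1, 0]")
  if (p$outgroup_error < 0 || p$outgroup_error >= 1)
    stop("outgroup_error must be in [0, 1)")
  structure(p, class = "sim_params")
}

# class-specific selection/dominance vectors aligned with a class factor
.class_sel <- function(cls, params) {
  s <- numeric(length(cls))
  h <- rep(0.5, length(cls))
  s[cls == "missense"] <- params$s_missense
  s[cls == "lof"] <- params$s_lof
  h[cls == "missense"] <- params$h_missense
  h[cls == "lof"] <- params$h_lof
  list(s = s, h = h)
}

# one Wright-Fisher generation: deterministic selection + mutation, then
# binomial drift at population size n. q is the derived-allele frequency.
.wf_step <- function(q, n, s, h) {
  w11 <- 1 + s
  w01 <- 1 + h * s
  wbar <- q^2 * w11 + 2 * q * (1 - q) * w01 + (1 - q)^2
  if (any(wbar <= 0))
    stop("population extinct during simulation: mean fitness reached 0 ",
         "(lethal derived allele at high frequency; regime s = ",
         min(s), ", N = ", n, ")")
  qs <- (q^2 * w11 + q * (1 - q) * w01) / wbar
  stats::rbinom(length(q), 2L * n, qs) / (2 * n)
}

# sample diploid genotypes (derived dosage) for n individuals at frequencies q,
# with inbreeding coefficient f
.sample_genotypes <- function(q, n, f = 0) {
  m <- length(q)
  qq <- rep(q, times = n)
  g <- stats::rbinom(m * n, 2L, qq)
  if (f > 0) {
    ib <- stats::rbinom(m * n, 1L, f) == 1L
    g[ib] <- 2L * stats::rbinom(sum(ib), 1L, qq[ib])
  }
  matrix(g, nrow = m, ncol = n)
}

#' Simulate genotypes for two diverged populations, one recently bottlenecked
#'
#' Forward Wright-Fisher simulation at allele-frequency resolution with free
#' recombination (independent loci). Derived alleles start from a neutral-SFS
#' draw in the ancestral population, are burnt in under selection, split into
#' populations A and B, and evolve independently; A passes through the
#' configured bottleneck. Present-day diploid genotypes are then sampled.
#' Per-site conservation (GERP-like) scores are drawn so that stronger
#' selection implies stochastically higher scores; missense sites receive
#' Grantham scores spanning 5-215; two outgroup columns carry the true
#' ancestral allele with error `outgroup_error`.
#'
#' @param params a [sim_params()] object.
#' @param coords optional data.frame with columns `lon`, `lat` (one row per
#'   individual, A first); defaults place A in the east and B in the west of
#'   the default landscape extent.
#' @return a list of class `sim_data` with elements:
#'   \describe{
#'     \item{geno}{integer matrix of ALT-allele dosage, segregating sites in
#'       rows, individuals in columns (NA = missing).}
#'     \item{sites}{annotation for segregating sites (chrom, pos, ref, alt,
#'       outgroup columns, true ancestral allele, effect class, Grantham and
#'       GERP scores).}
#'     \item{ledger}{annotation for all simulated sites, with a `segregating`
#'       flag (monomorphic sites are dropped from `geno` only).}
#'     \item{samples}{sample table (id, population, lon, lat).}
#'   }
#' @export
simulate_genotypes <- function(params, coords = NULL) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  cls <- rep(names(params$n_sites), times = params$n_sites)
  m <- length(cls)
  cls <- sample(cls)                      # interleave classes along the genome
  chrom <- sort(sample.int(params$n_chromosomes, m, replace = TRUE))
  pos <- integer(m)
  for (k in seq_len(params$n_chromosomes)) {
    idx <- which(chrom == k)
    pos[idx] <- sort(sample.int(params$chrom_length_bp, length(idx)))
  }
  sel <- .class_sel(cls, params)

  ne <- params$ne_ancestral
  # initial derived frequencies from a discretised neutral SFS (P(j) ~ 1/j)
  jmax <- 2L * ne - 1L
  q <- sample.int(jmax, m, replace = TRUE, prob = 1 / seq_len(jmax)) / (2 * ne)
  for (g in seq_len(200))                 # burn-in towards selection-drift balance
    q <- .wf_step(q + params$mu * (1 - q), ne, sel$s, sel$h)

  qa <- qb <- q
  for (g in seq(params$t_split, 1L)) {
    na <- if (g <= params$t_bottleneck && g > params$t_recovery)
      params$ne_bottleneck else ne
    qa <- .wf_step(qa + params$mu * (1 - qa), na, sel$s, sel$h)
    qb <- .wf_step(qb + params$mu * (1 - qb), ne, sel$s, sel$h)
  }

  ga <- .sample_genotypes(qa, params$n_pop_a, params$f_inbreeding_a)
  gb <- .sample_genotypes(qb, params$n_pop_b, params$f_inbreeding_b)
  geno_der <- cbind(ga, gb)               # derived-allele dosage
  if (params$missing_rate > 0) {
    miss <- stats::rbinom(length(geno_der), 1L, params$missing_rate) == 1L
    geno_der[miss] <- NA_integer_
  }

  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, m, replace = TRUE)
  der <- vapply(anc, function(b) sample(setdiff(bases, b), 1L), character(1))
  ref_is_anc <- stats::runif(m) < 0.5
  ref <- ifelse(ref_is_anc, anc, der)
  alt <- ifelse(ref_is_anc, der, anc)
  err1 <- stats::runif(m) < params$outgroup_error
  err2 <- stats::runif(m) < params$outgroup_error
  out1 <- ifelse(err1, der, anc)
  out2 <- ifelse(err2, der, anc)
  grantham <- ifelse(cls == "missense", sample(5:215, m, replace = TRUE),
                     NA_integer_)
  # conservation scores: mean increases with |s| (monotone), neutral classes low
  mu_gerp <- ifelse(sel$s < 0, 1 + 6 * abs(sel$s)^0.25,
                    ifelse(cls == "intergenic", -2, -1))
  gerp <- round(stats::rnorm(m, mu_gerp, 1.5), 3)

  # convert derived dosage to ALT dosage where REF is the derived allele
  geno <- geno_der
  flip <- !ref_is_anc
  geno[flip, ] <- 2L - geno[flip, ]

  called_max <- apply(geno, 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) 0L else 2L * length(x)
  })
  alt_count <- rowSums(geno, na.rm = TRUE)
  segregating <- alt_count > 0 & alt_count < called_max

  ledger <- data.frame(
    chrom = paste0("chr", chrom), pos = pos,
    id = paste0("chr", chrom, ":", pos),
    ref = ref, alt = alt, out1 = out1, out2 = out2,
    ancestral_true = anc,
    class = cls, grantham = grantham, gerp = gerp,
    segregating = segregating,
    stringsAsFactors = FALSE)

  ids <- c(sprintf("A%02d", seq_len(params$n_pop_a)),
           sprintf("B%02d", seq_len(params$n_pop_b)))
  if (is.null(coords)) {
    n_tot <- params$n_pop_a + params$n_pop_b
    coords <- data.frame(
      lon = c(stats::runif(params$n_pop_a, 105.5, 109.5),
              stats::runif(params$n_pop_b, 100.5, 104.5)),
      lat = stats::runif(n_tot, 25.5, 34.5))
  }
  samples <- data.frame(
    id = ids,
    population = rep(c("A", "B"), c(params$n_pop_a, params$n_pop_b)),
    lon = coords$lon, lat = coords$lat,
    stringsAsFactors = FALSE)

  geno <- geno[segregating, , drop = FALSE]
  rownames(geno) <- ledger$id[segregating]
  colnames(geno) <- ids
  sites <- ledger[segregating, setdiff(names(ledger), "segregating")]
  rownames(sites) <- NULL

  structure(list(geno = geno, sites = sites, ledger = ledger,
                 samples = samples, params = params),
            class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat("sim_data:", nrow(x$geno), "segregating sites x",
      ncol(x$geno), "individuals\n")
  cat("  site classes:",
      paste(names(table(x$sites$class)), table(x$sites$class),
            sep = "=", collapse = ", "), "\n")
  cat("  populations:",
      paste(names(table(x$samples$population)), table(x$samples$population),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Embed an adaptive allele-frequency cline at known causal loci
#'
#' Re-draws the genotypes of `n_causal` intergenic segregating loci so the
#' derived-allele probability of each individual follows a logistic function
#' of its (standardised) environmental value. A ledger of the causal loci is
#' returned for power assessment.
#'
#' @param sim a `sim_data` object.
#' @param env numeric vector, one environmental value per individual
#'   (column order of `sim$geno`).
#' @param n_causal number of causal loci.
#' @param steepness logistic slope per standard deviation of `env`;
#'   0 makes causal frequencies independent of the environment.
#' @param seed RNG seed.
#' @return `sim` with modified genotypes and an added `causal` data.frame.
#' @export
embed_adaptive_cline <- function(sim, env, n_causal = 20, steepness = 2,
                                 seed = 1L) {
  stopifnot(inherits(sim, "sim_data"), length(env) == ncol(sim$geno))
  set.seed(seed)
  pool <- which(sim$sites$class == "intergenic")
  if (n_causal > length(pool))
    stop("n_causal (", n_causal, ") exceeds available intergenic loci (",
         length(pool), ")")
  causal <- sort(sample(pool, n_causal))
  z <- as.numeric(scale(env))
  p <- stats::plogis(steepness * z)
  n <- length(z)
  for (i in causal) {
    gder <- stats::rbinom(n, 2L, p)
    # keep ALT coding consistent with the site's REF/ALT assignment
    if (sim$sites$ref[i] == sim$sites$ancestral_true[i])
      sim$geno[i, ] <- gder else sim$geno[i, ] <- 2L - gder
  }
  sim$causal <- sim$sites[causal, c("id", "chrom", "pos")]
  rownames(sim$causal) <- NULL
  sim
}

#' Embed a hard selective sweep in population A
#'
#' Drives the derived allele of every site inside a genomic window to (near)
#' fixation in population A while keeping it rare in population B, emulating a
#' completed hard sweep for selection-scan power checks.
#'
#' @param sim a `sim_data` object.
#' @param chrom chromosome name (e.g. `"chr1"`).
#' @param center,width sweep window centre and width in bp; defaults pick a
#'   region of `width` bp centred on the median site of `chrom`.
#' @param freq_b derived-allele frequency used for population B draws.
#' @param seed RNG seed.
#' @return `sim` with modified genotypes and an added `sweep` list
#'   (chrom, start, end, site ids).
#' @export
embed_sweep <- function(sim, chrom = "chr1", center = NULL, width = 50000,
                        freq_b = 0.05, seed = 1L) {
  stopifnot(inherits(sim, "sim_data"))
  set.seed(seed)
  on_chr <- sim$sites$chrom == chrom
  if (!any(on_chr)) stop("no segregating sites on ", chrom)
  if (is.null(center)) center <- stats::median(sim$sites$pos[on_chr])
  lo <- center - width / 2
  hi <- center + width / 2
  idx <- which(on_chr & sim$sites$pos >= lo & sim$sites$pos < hi)
  if (!length(idx)) stop("no segregating sites in sweep window")
  pop <- sim$samples$population
  na <- sum(pop == "A")
  nb <- sum(pop == "B")
  for (i in idx) {
    gder <- c(rep(2L, na), stats::rbinom(nb, 2L, freq_b))
    if (sim$sites$ref[i] == sim$sites$ancestral_true[i])
      sim$geno[i, ] <- gder else sim$geno[i, ] <- 2L - gder
  }
  sim$sweep <- list(chrom = chrom, start = lo, end = hi,
                    ids = sim$sites$id[idx])
  sim
}
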