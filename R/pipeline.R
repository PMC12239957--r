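#' Group individuals into sampling sites by coordinate clustering
#'
#' @param samples sample table with `lon`, `lat`.
#' @param k number of sampling sites.
#' @param seed RNG seed.
#' @return integer vector of site assignments.
#' @export
cluster_sampling_sites <- function(samples, k = 6, seed = 1L) {
  set.seed(seed)
  stats::kmeans(cbind(samples$lon, samples$lat), centers = k,
                nstart = 5)$cluster
}

#' Per-group derived-allele frequencies
#'
#' @param geno dosage matrix (sites x individuals).
#' @param group grouping vector per individual.
#' @return matrix, groups in rows, SNPs in columns.
#' @export
group_frequencies <- function(geno, group) {
  lev <- sort(unique(group))
  out <- t(vapply(lev, function(g)
    rowMeans(geno[, group == g, drop = FALSE], na.rm = TRUE) / 2,
    numeric(nrow(geno))))
  rownames(out) <- lev
  colnames(out) <- rownames(geno)
  out
}

#' Build the canonical genotype-environment association fixture
#'
#' A compact two-population data set for association power and calibration
#' studies: both populations are sampled across the whole environmental
#' gradient (so climate is not collinear with ancestry), with an optional
#' adaptive cline embedded at known intergenic loci. With `causal = FALSE`
#' the fixture carries population structure but no environmental effect.
#'
#' @param seed RNG seed.
#' @param causal embed the adaptive cline?
#' @param n_causal,steepness cline parameters (see [embed_adaptive_cline()]).
#' @param n_sites per-class site counts (smaller than the full simulator
#'   default so the constrained-ordination arm sees a clear signal share).
#' @return list: `pol` (polarized data), `env` (data.frame), `truth`
#'   (causal ids, empty when `causal = FALSE`), `sim`, `landscape`.
#' @export
gea_fixture <- function(seed = 1L, causal = TRUE, n_causal = 50,
                        steepness = 5,
                        n_sites = c(synonymous = 150, missense = 150,
                                    lof = 80, intergenic = 500)) {
  set.seed(seed + 1000L)
  coords <- data.frame(lon = stats::runif(30, 100.5, 109.5),
                       lat = stats::runif(30, 25.5, 34.5))
  sim <- simulate_genotypes(sim_params(seed = seed, n_sites = n_sites),
                            coords = coords)
  land <- simulate_landscape(landscape_params(seed = seed + 50L),
                             samples = sim$samples)
  env <- as.data.frame(land$env)
  truth <- character(0)
  if (causal) {
    sim <- embed_adaptive_cline(sim, env[[1]], n_causal = n_causal,
                                steepness = steepness, seed = seed + 70L)
    truth <- sim$causal$id
  }
  list(pol = polarize_annotate(sim), env = env, truth = truth,
       sim = sim, landscape = land)
}

#' Run the whole analysis pipeline on synthetic data
#'
#' Simulates genotypes and climate, embeds an adaptive cline, polarizes and
#' annotates, computes the load report, the windowed selection scan, the
#' two-method GEA screen, forest- and spline-based genomic offsets, and the
#' ensemble SDM vulnerability map, writing every declared output file under
#' `outdir`.
#'
#' @param outdir output directory (created if needed).
#' @param seed master RNG seed.
#' @param sim_p,land_p optional [sim_params()] / [landscape_params()]
#'   overrides.
#' @param n_background background points for the SDM stage.
#' @param quick reduce permutations and SDM replicates for a fast smoke run.
#' @return invisible list of the main result objects and output paths.
#' @export
run_pipeline <- function(outdir = tempfile("genovuln"), seed = 1L,
                         sim_p = NULL, land_p = NULL, n_background = 2000,
                         quick = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(sim_p)) sim_p <- sim_params(seed = seed)
  if (is.null(land_p)) land_p <- landscape_params(seed = seed + 1L)

  # --- simulate ---
  sim <- simulate_genotypes(sim_p)
  land <- simulate_landscape(land_p, samples = sim$samples)
  env <- as.data.frame(land$env)
  sim <- embed_adaptive_cline(sim, env[[1]],
                              n_causal = land_p$n_causal_loci,
                              steepness = land_p$cline_steepness,
                              seed = seed + 2L)
  sim <- embed_sweep(sim, seed = seed + 3L)
  samples_out <- cbind(sim$samples, env)
  vcf_export(sim, file.path(outdir, "genotypes.vcf"))
  write_tsv(samples_out, file.path(outdir, "samples.tsv"))
  write_tsv(sim$ledger, file.path(outdir, "annotation.tsv"))
  for (v in names(land$present$layers)) {
    write_csv_grid(land$present, v,
                   file.path(outdir, paste0("climate_present_", v, ".csvgrid")))
    for (sc in names(land$futures))
      write_csv_grid(land$futures[[sc]], v,
                     file.path(outdir,
                               paste0("climate_", sc, "_", v, ".csvgrid")))
  }

  # --- polarize + annotate ---
  pol <- polarize_annotate(sim)
  vcf_export(pol, file.path(outdir, "genotypes_polarized.vcf"))
  write_tsv(pol$excluded[, c("chrom", "pos", "id")],
            file.path(outdir, "excluded_sites.tsv"))

  # --- genetic load ---
  load_rep <- load_report(pol)
  write_tsv(load_rep$r_stats, file.path(outdir, "load_r_stats.tsv"))
  write_tsv(load_rep$counts, file.path(outdir, "load_counts.tsv"))
  write_tsv(load_rep$gerp, file.path(outdir, "load_gerp.tsv"))
  jsonlite::write_json(
    list(r_stats = load_rep$r_stats, t_tests = load_rep$t_tests),
    file.path(outdir, "load_summary.json"), auto_unbox = TRUE, digits = NA)

  # --- selection scan ---
  ws <- windowed_fst(pol$geno, pol$sites, pol$samples$population)
  write_tsv(ws, file.path(outdir, "window_stats.tsv"))
  out_fst <- top_quantile_outliers(ws, "fst", 0.01)
  bed <- data.frame(chrom = out_fst$chrom, start = out_fst$start,
                    end = out_fst$end,
                    name = sprintf("fst_%.4f", out_fst$fst))
  utils::write.table(bed, file.path(outdir, "fst_outliers.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  out_pi <- top_quantile_outliers(
    ws[!is.na(ws$pi_ratio), ], "pi_ratio", 0.01)
  wid <- function(w) paste0(w$chrom, ":", w$start, "-", w$end)
  venn <- intersect_candidates(list(fst = wid(out_fst), pi = wid(out_pi)),
                               k = 2)
  jsonlite::write_json(venn$venn, file.path(outdir, "venn_counts.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- GEA ---
  gea <- gea_scan(pol$geno, env, K = 2,
                  permutations = if (quick) 199 else 999, seed = seed + 4L)
  write_tsv(gea$lfa, file.path(outdir, "gea_latent_factor.tsv"))
  cand_sites <- pol$sites[pol$sites$id %in% gea$candidates,
                          c("chrom", "pos", "id")]
  write_tsv(cand_sites, file.path(outdir, "gea_candidates.tsv"))

  # --- genomic offset ---
  cand_ids <- gea$candidates
  if (length(cand_ids) < 5)               # fall back to truth for tiny runs
    cand_ids <- union(cand_ids, sim$causal$id)
  site_grp <- cluster_sampling_sites(sim$samples, k = 6, seed = seed + 5L)
  freqs <- group_frequencies(
    pol$geno[rownames(pol$geno) %in% cand_ids, , drop = FALSE], site_grp)
  env_grp <- apply(env, 2, function(e) tapply(e, site_grp, mean))
  fwd_model <- fit_turnover_forest(freqs, as.data.frame(env_grp),
                                   seed = seed + 6L)
  scen <- names(land$futures)[1]
  om <- offset_maps(fwd_model, land$present, land$futures[[scen]])
  grid <- land$present
  off_grid <- function(v) {
    g <- grid
    g$layers <- list(offset = as_grid_matrix(v, grid))
    g
  }
  write_csv_grid(off_grid(om$local), "offset",
                 file.path(outdir, paste0("offset_local_", scen, ".csvgrid")))
  for (j in seq_len(ncol(om$forward)))
    write_csv_grid(off_grid(om$forward[, j]), "offset",
                   file.path(outdir, paste0("offset_forward_", scen, "_",
                                            colnames(om$forward)[j],
                                            ".csvgrid")))
  write_csv_grid(off_grid(om$reverse), "offset",
                 file.path(outdir, paste0("offset_reverse_", scen, ".csvgrid")))
  for (b in colnames(om$rgb))
    write_csv_grid(off_grid(om$rgb[, b]), "offset",
                   file.path(outdir,
                             paste0("offset_rgb_", b, "_", scen, ".csvgrid")))

  fst_mat <- pairwise_fst(pol$geno[rownames(pol$geno) %in% cand_ids, ,
                                   drop = FALSE], site_grp)
  gdm_model <- fit_dissimilarity_spline(fst_mat, as.data.frame(env_grp))
  om_gdm <- offset_maps(gdm_model, land$present, land$futures[[scen]],
                        dispersal_km = Inf)
  write_csv_grid(off_grid(om_gdm$local), "offset",
                 file.path(outdir, paste0("offset_local_gdm_", scen,
                                          ".csvgrid")))
  jsonlite::write_json(
    list(scenario = scen, dispersal_km = om$dispersal_km,
         forest_importance = as.list(fwd_model$importance),
         spline_importance = as.list(gdm_model$importance)),
    file.path(outdir, "offset_manifest.json"), auto_unbox = TRUE, digits = NA)

  # --- SDM vulnerability ---
  occ <- simulate_occurrences(land$present, n = 400, seed = seed + 7L)
  ex <- land_p$grid_extent
  occ$lon <- pmin(pmax(occ$lon, ex["lon_min"]), ex["lon_max"])
  occ$lat <- pmin(pmax(occ$lat, ex["lat_min"]), ex["lat_max"])
  write_tsv(occ, file.path(outdir, "occurrences.tsv"))
  pb <- make_presence_background(occ, land$present,
                                 n_background = n_background,
                                 thin_arcmin = 5, seed = seed + 8L)
  ens <- try(fit_sdm_ensemble(pb, reps = if (quick) 3 else 10,
                              seed = seed + 9L), silent = TRUE)
  sdm_outputs <- list()
  if (!inherits(ens, "try-error")) {
    s_now <- suitability_map(ens, land$present)
    s_fut <- suitability_map(ens, land$futures[[scen]])
    ve <- ecological_vulnerability(s_fut, s_now)
    sg <- grid
    sg$layers <- list(S = s_now)
    write_csv_grid(sg, "S", file.path(outdir, "suitability_present.csvgrid"))
    sg$layers <- list(S = s_fut)
    write_csv_grid(sg, "S",
                   file.path(outdir, paste0("suitability_", scen, ".csvgrid")))
    sg$layers <- list(VE = ve)
    write_csv_grid(sg, "VE",
                   file.path(outdir, paste0("vulnerability_", scen,
                                            ".csvgrid")))
    write_tsv(ens$metrics, file.path(outdir, "sdm_member_metrics.tsv"))
    sdm_outputs <- list(ensemble = ens, s_present = s_now, s_future = s_fut,
                        vulnerability = ve)
  }

  invisible(c(list(outdir = outdir, sim = sim, landscape = land, pol = pol,
                   load = load_rep, windows = ws, gea = gea,
                   forest_model = fwd_model, offsets = om,
                   spline_model = gdm_model),
              sdm_outputs))
}
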