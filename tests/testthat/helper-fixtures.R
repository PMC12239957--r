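# shared fixtures, built once per test run and cached

.fx_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fx_cache)) assign(key, expr, envir = .fx_cache)
  get(key, envir = .fx_cache)
}

default_sim <- function(seed = 1) {
  cached(paste0("sim", seed), simulate_genotypes(sim_params(seed = seed)))
}

default_pol <- function(seed = 1) {
  cached(paste0("pol", seed), polarize_annotate(default_sim(seed)))
}

# a hand-built polarized_data object from explicit derived-dosage genotypes
make_pol <- function(geno, class = rep("synonymous", nrow(geno)),
                     gerp = rep(0, nrow(geno)), grantham = NA_integer_,
                     pop = NULL, chrom = rep("chr1", nrow(geno)),
                     pos = seq_len(nrow(geno))) {
  n <- ncol(geno)
  if (is.null(pop)) pop <- rep(c("A", "B"), length.out = n)
  ids <- paste0(chrom, ":", pos)
  rownames(geno) <- ids
  sites <- data.frame(
    chrom = chrom, pos = pos, id = ids,
    ref = "A", alt = "G", out1 = "A", out2 = "A", ancestral_true = "A",
    class = class, grantham = grantham, gerp = gerp,
    ancestral = "A",
    deleterious_missense = ifelse(class == "missense", grantham >= 150, NA),
    gerp_deleterious = gerp >= 4,
    stringsAsFactors = FALSE)
  structure(list(geno = geno, sites = sites,
                 samples = data.frame(id = paste0("i", seq_len(n)),
                                      population = pop,
                                      lon = seq(100, 101, length.out = n),
                                      lat = seq(30, 31, length.out = n)),
                 excluded = sites[0, ]),
            class = "polarized_data")
}

# a frequency table built directly from per-site frequencies
make_ft <- function(fA, fB, class, chrom = "chr1",
                    pos = seq_along(fA)) {
  data.frame(id = paste0(chrom, ":", pos), chrom = chrom, pos = pos,
             class = class, grantham = NA, gerp = 0,
             deleterious_missense = NA, gerp_deleterious = FALSE,
             dA = round(fA * 20), nA = 20, fA = fA,
             dB = round(fB * 20), nB = 20, fB = fB)
}

# small climate grid with explicit layer values
make_grid <- function(z, lon = NULL, lat = NULL, scenario = "present") {
  z <- lapply(z, as.matrix)
  nr <- nrow(z[[1]]); nc <- ncol(z[[1]])
  if (is.null(lon)) lon <- seq(100.25, by = 0.5, length.out = nc)
  if (is.null(lat)) lat <- seq(35 - 0.25, by = -0.5, length.out = nr)
  structure(list(lon = lon, lat = lat, layers = z, scenario = scenario),
            class = "climate_grid")
}

# independent brute-force Weir-Cockerham window Fst (oracle; explicit loops)
brute_fst <- function(geno, sites, pop, pop_a, pop_b, window, step,
                      chrom_lengths = NULL) {
  res <- list()
  for (chr in unique(sites$chrom)) {
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[chr]]
      else max(sites$pos[sites$chrom == chr])
    if (len < window) next
    for (st in seq(0, max(0, len - window), by = step)) {
      idx <- which(sites$chrom == chr & sites$pos > st &
                     sites$pos <= st + window)
      num <- den <- 0
      for (i in idx) {
        g <- geno[i, ]
        comps <- list()
        for (p in c(pop_a, pop_b)) {
          gp <- g[pop == p]
          gp <- gp[!is.na(gp)]
          comps[[p]] <- gp
        }
        n1 <- length(comps[[1]]); n2 <- length(comps[[2]])
        if (n1 == 0 || n2 == 0) next
        r <- 2
        p1 <- sum(comps[[1]]) / (2 * n1); p2 <- sum(comps[[2]]) / (2 * n2)
        h1 <- mean(comps[[1]] == 1); h2 <- mean(comps[[2]] == 1)
        nbar <- (n1 + n2) / 2
        if (nbar <= 1) next
        nc_ <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
        pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
        s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
        hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
        a <- nbar / nc_ *
          (s2 - 1 / (nbar - 1) *
             (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
        b <- nbar / (nbar - 1) *
          (pbar * (1 - pbar) - (r - 1) / r * s2 -
             (2 * nbar - 1) / (4 * nbar) * hbar)
        cc <- hbar / 2
        num <- num + a
        den <- den + a + b + cc
      }
      res[[length(res) + 1]] <- data.frame(
        chrom = chr, start = st,
        fst = if (length(idx) && den > 0) num / den else NA_real_)
    }
  }
  do.call(rbind, res)
}

# a perfectly separable presence/background set on a known niche
separable_pb <- function(n = 240, seed = 1) {
  set.seed(seed)
  x <- c(rnorm(n / 2, 3, 0.4), rnorm(n / 2, -3, 0.4))
  d <- data.frame(lon = runif(n, 100, 110), lat = runif(n, 25, 35),
                  label = rep(c(1L, 0L), each = n / 2),
                  BIO7 = x, BIO15 = rnorm(n))
  class(d) <- c("presence_background", class(d))
  d
}

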