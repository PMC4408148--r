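# Synthetic data with known truth: F-model allele frequencies, pure and
# hybrid genotypes, a spatial mating pedigree producing isolation by
# distance, covariate-linked introgression probabilities, and
# order-structured flower-visitor observations.

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic world. Defaults describe the
#' reference scenario used throughout the test suite: five wild clusters
#' under moderate drift plus a more strongly drifted crop gene pool,
#' 26 microsatellite-like loci, 50 diploids per pool and roughly 10%
#' first-generation and backcross hybrids.
#'
#' @param n_wild_clusters number of wild clusters (>= 1).
#' @param n_loci number of loci.
#' @param alleles_per_locus length-2 integer range; allele number per locus
#'   is drawn uniformly from it (>= 2).
#' @param divergence_f drift parameter F of each wild cluster, in (0,1).
#' @param crop_divergence_f drift parameter of the crop pool, in (0,1).
#' @param n_per_cluster diploid individuals per pool (wild clusters and crop).
#' @param sites_per_cluster sampling sites per wild cluster; individuals
#'   are spread round-robin over them (the crop pool keeps one site).
#' @param hybrid_spec list of `list(ancestry = <vector over the
#'   n_wild_clusters + 1 pools, crop last>, count = <int>, label = <chr>)`.
#'   `NULL` gives the default 5% F1 + 5% BC1 design; `list()` disables
#'   hybrids.
#' @param missing_rate per-call missing probability in `[0, 0.2)`; both gene
#'   copies of a call are masked jointly.
#' @param dispersal list with `pollen_sigma` and `seed_sigma` (km, > 0),
#'   `n_generations` (>= 0), and the rectangle `extent` (km, length 2).
#' @param landscape_effects named numeric: `beta0`, `beta_density`,
#'   `beta_orchards`, `beta_interaction` on the log scale of the expected
#'   introgression rate.
#' @param seed integer seed; a fixed seed makes every generator
#'   byte-reproducible.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_wild_clusters = 5, n_loci = 26,
                       alleles_per_locus = c(5, 15),
                       divergence_f = 0.15, crop_divergence_f = 0.30,
                       n_per_cluster = 50, sites_per_cluster = 4,
                       hybrid_spec = NULL, missing_rate = 0.02,
                       dispersal = list(pollen_sigma = 1, seed_sigma = 0.5,
                                        n_generations = 10,
                                        extent = c(20, 20)),
                       landscape_effects = c(beta0 = -2.0,
                                             beta_density = 0.08,
                                             beta_orchards = 0.015,
                                             beta_interaction = 0.003),
                       seed = 1L) {
  stopifnot(n_wild_clusters >= 1, n_loci >= 1,
            length(alleles_per_locus) == 2, alleles_per_locus[1] >= 2,
            divergence_f > 0, divergence_f < 1,
            crop_divergence_f > 0, crop_divergence_f < 1,
            missing_rate >= 0, missing_rate < 0.2,
            n_per_cluster >= 0)
  if (is.null(dispersal$extent)) dispersal$extent <- c(20, 20)
  if (is.null(hybrid_spec)) {
    n_hyb <- max(1L, round(0.05 * n_per_cluster))
    hybrid_spec <- list()
    for (k in seq_len(n_wild_clusters)) {
      f1 <- bc1 <- rep(0, n_wild_clusters + 1)
      f1[k] <- 0.5; f1[n_wild_clusters + 1] <- 0.5
      bc1[k] <- 0.75; bc1[n_wild_clusters + 1] <- 0.25
      hybrid_spec <- c(hybrid_spec,
                       list(list(ancestry = f1, count = n_hyb,
                                 label = "F1"),
                            list(ancestry = bc1, count = n_hyb,
                                 label = "BC1")))
    }
  }
  for (h in hybrid_spec) {
    if (length(h$ancestry) != n_wild_clusters + 1 ||
        abs(sum(h$ancestry) - 1) > 1e-9 || any(h$ancestry < 0))
      stop("hybrid ancestry vectors must be length n_wild_clusters + 1 ",
           "(crop last) and sum to 1")
  }
  stopifnot(sites_per_cluster >= 1)
  structure(list(n_wild_clusters = n_wild_clusters, n_loci = n_loci,
                 alleles_per_locus = alleles_per_locus,
                 divergence_f = divergence_f,
                 crop_divergence_f = crop_divergence_f,
                 n_per_cluster = n_per_cluster,
                 sites_per_cluster = sites_per_cluster,
                 hybrid_spec = hybrid_spec,
                 missing_rate = missing_rate, dispersal = dispersal,
                 landscape_effects = landscape_effects,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw cluster allele frequencies under the F-model
#'
#' Per locus, an ancestral frequency vector is drawn from a flat Dirichlet;
#' each wild cluster then draws its own frequencies from
#' `Dirichlet(p_anc * (1 - F) / F)` (mean `p_anc`, drift increasing with F),
#' and the crop pool does the same with `crop_divergence_f`. Allele codes
#' are even-stepped integers emulating microsatellite repeat sizes.
#'
#' @param config a [sim_config()].
#' @return list of class `allele_freqs`: `freqs` (per locus, a
#'   `(n_wild_clusters + 1) x A_l` matrix, crop pool last row, columns named
#'   by allele code), `ancestral` (per-locus ancestral vectors), and
#'   `pool_names`.
#' @export
sample_cluster_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  K <- config$n_wild_clusters
  f <- c(rep(config$divergence_f, K), config$crop_divergence_f)
  pools <- c(paste0("wild", seq_len(K)), "crop")
  freqs <- vector("list", config$n_loci)
  anc <- vector("list", config$n_loci)
  for (l in seq_len(config$n_loci)) {
    rng <- config$alleles_per_locus
    A <- if (rng[1] == rng[2]) rng[1] else
      sample(seq(rng[1], rng[2]), 1)
    p_anc <- rdirichlet(1, rep(1, A))[1, ]
    m <- t(vapply(seq_along(pools), function(k) {
      rdirichlet(1, p_anc * (1 - f[k]) / f[k])[1, ]
    }, numeric(A)))
    codes <- 100L + 2L * (seq_len(A) - 1L)
    dimnames(m) <- list(pools, as.character(codes))
    freqs[[l]] <- m
    anc[[l]] <- stats::setNames(p_anc, as.character(codes))
  }
  structure(list(freqs = freqs, ancestral = anc, pool_names = pools,
                 locus_ids = sprintf("L%02d", seq_len(config$n_loci))),
            class = "allele_freqs")
}

# Dirichlet sampler via gamma draws; rows are draws.
rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Sample genotypes for pure and hybrid individuals
#'
#' Pure individuals draw both gene copies i.i.d. from their own pool's
#' frequencies (Hardy-Weinberg within pool). Hybrid individuals follow
#' diploid genetics: the ancestry vector is decomposed into two parental
#' gamete distributions (greedy split of the doubled ancestry mass into
#' two unit vectors, largest contributions first), and each gene copy
#' draws its source pool from its own parent's distribution, then an
#' allele from that pool. An F1 (0.5/0.5) therefore carries one crop and
#' one wild copy at every locus, and a BC1 (0.75/0.25) one pure-wild copy
#' plus one F1-gamete copy. Missing calls are masked jointly (both
#' alleles) at `missing_rate`.
#'
#' @param freqs an `allele_freqs` from [sample_cluster_frequencies()].
#' @param config a [sim_config()].
#' @return list with `genotypes` (a [genotype_matrix()]) and `truth` (a
#'   data.frame: id, site_id, hybrid_class, true crop ancestry and per-pool
#'   ancestry columns).
#' @export
sample_genotypes <- function(freqs, config) {
  stopifnot(inherits(freqs, "allele_freqs"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  K <- config$n_wild_clusters
  n_pools <- K + 1L
  # design: per-pool pure individuals then hybrids
  spc <- if (is.null(config$sites_per_cluster)) 1L else
    config$sites_per_cluster
  site_of <- function(k, idx) {
    if (k > K)                                   # crop pool: single site
      return(rep(freqs$pool_names[k], length(idx)))
    sprintf("%s_s%d", freqs$pool_names[k], 1L + (idx - 1L) %% spc)
  }
  anc_rows <- list(); labels <- character(0); sites <- character(0)
  for (k in seq_len(n_pools)) {
    a <- rep(0, n_pools); a[k] <- 1
    nk <- config$n_per_cluster
    if (nk > 0) {
      anc_rows <- c(anc_rows, rep(list(a), nk))
      labels <- c(labels, rep(if (k <= K) "pure_wild" else "pure_crop", nk))
      sites <- c(sites, site_of(k, seq_len(nk)))
    }
  }
  for (h in config$hybrid_spec) {
    if (h$count > 0) {
      anc_rows <- c(anc_rows, rep(list(h$ancestry), h$count))
      labels <- c(labels, rep(h$label, h$count))
      home <- which.max(h$ancestry[seq_len(K)])
      sites <- c(sites, site_of(home, seq_len(h$count)))
    }
  }
  n <- length(anc_rows)
  if (n == 0) stop("empty design")
  anc <- do.call(rbind, anc_rows)
  # parental gamete decomposition: split 2 * ancestry into two unit
  # vectors, assigning the largest contributions first
  gam1 <- gam2 <- matrix(0, n, n_pools)
  for (i in seq_len(n)) {
    mass <- 2 * anc[i, ]
    left1 <- 1
    for (k in order(mass, decreasing = TRUE)) {
      take <- min(mass[k], left1)
      gam1[i, k] <- take
      gam2[i, k] <- mass[k] - take
      left1 <- left1 - take
    }
  }
  L <- config$n_loci
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    fm <- freqs$freqs[[l]]
    codes <- as.integer(colnames(fm))
    draw_copy <- function(gam) {
      src <- vapply(seq_len(n), function(i)
        sample.int(n_pools, 1, prob = gam[i, ]), integer(1))
      vapply(src, function(k)
        codes[sample.int(length(codes), 1, prob = fm[k, ])], integer(1))
    }
    a1[, l] <- draw_copy(gam1)
    a2[, l] <- draw_copy(gam2)
    if (config$missing_rate > 0) {
      miss <- stats::runif(n) < config$missing_rate
      a1[miss, l] <- NA_integer_; a2[miss, l] <- NA_integer_
    }
  }
  ids <- sprintf("ind%04d", seq_len(n))
  species <- ifelse(labels == "pure_crop", "crop", "wild")
  meta <- data.frame(id = ids, site_id = sites, species_label = species,
                     stringsAsFactors = FALSE)
  truth <- data.frame(id = ids, site_id = sites, hybrid_class = labels,
                      crop_ancestry = anc[, n_pools],
                      stringsAsFactors = FALSE)
  colnames(anc) <- paste0("anc_", freqs$pool_names)
  truth <- cbind(truth, as.data.frame(anc))
  list(genotypes = genotype_matrix(a1, a2, ids, freqs$locus_ids, meta),
       truth = truth)
}

#' Simulate a spatially limited mating pedigree
#'
#' Founders (genotypes drawn from the ancestral frequencies, i.e. one
#' panmictic pool) are placed uniformly on a rectangle. Each generation of
#' constant size: a mother is sampled uniformly, a father with probability
#' proportional to a Gaussian kernel of distance to the mother
#' (`pollen_sigma`), and the offspring is displaced from the mother by an
#' isotropic Gaussian (`seed_sigma`) with reflecting boundaries. Smaller
#' sigmas yield stronger fine-scale spatial genetic structure (larger Sp in
#' expectation). Coordinates are emitted both in km and as lat/lon around
#' 47 N, 2 E.
#'
#' @param freqs an `allele_freqs`; its per-locus ancestral vectors seed the
#'   founder pool.
#' @param config a [sim_config()]; population size is
#'   `n_per_cluster * n_wild_clusters`.
#' @return list with `genotypes` (a [genotype_matrix()] of the final
#'   generation, coordinates in metadata) and `truth` (id, x_km, y_km,
#'   mother, father).
#' @export
simulate_spatial_pedigree <- function(freqs, config) {
  stopifnot(inherits(freqs, "allele_freqs"), inherits(config, "sim_config"))
  dsp <- config$dispersal
  if (dsp$n_generations < 0) stop("n_generations must be >= 0")
  if (dsp$pollen_sigma <= 0 || dsp$seed_sigma <= 0)
    stop("dispersal sigmas must be positive")
  set.seed(config$seed + 2L)
  n <- config$n_per_cluster * config$n_wild_clusters
  if (n < 2) stop("need at least 2 individuals")
  ext <- dsp$extent
  L <- config$n_loci
  codes <- lapply(freqs$ancestral, function(p) as.integer(names(p)))
  # founders
  draw_pool <- function(m) {
    g <- matrix(NA_integer_, m, L)
    for (l in seq_len(L))
      g[, l] <- codes[[l]][sample.int(length(codes[[l]]), m, replace = TRUE,
                                      prob = freqs$ancestral[[l]])]
    g
  }
  a1 <- draw_pool(n); a2 <- draw_pool(n)
  x <- stats::runif(n, 0, ext[1]); y <- stats::runif(n, 0, ext[2])
  mother <- father <- rep(NA_integer_, n)
  reflect <- function(v, lim) {
    v <- abs(v)                       # reflect at 0
    v <- lim - abs(lim - v %% (2 * lim))
    v
  }
  if (dsp$n_generations > 0) {
    for (g in seq_len(dsp$n_generations)) {
      mom <- sample.int(n, n, replace = TRUE)
      na1 <- matrix(NA_integer_, n, L); na2 <- matrix(NA_integer_, n, L)
      dad <- integer(n)
      for (i in seq_len(n)) {
        d2 <- (x - x[mom[i]])^2 + (y - y[mom[i]])^2
        w <- exp(-d2 / (2 * dsp$pollen_sigma^2))
        w[mom[i]] <- 0                # no selfing
        if (sum(w) <= 0) w[-mom[i]] <- 1
        dad[i] <- sample.int(n, 1, prob = w)
      }
      for (l in seq_len(L)) {
        from_mom <- stats::runif(n) < 0.5
        na1[, l] <- ifelse(from_mom, a1[cbind(mom, l)], a2[cbind(mom, l)])
        from_dad <- stats::runif(n) < 0.5
        na2[, l] <- ifelse(from_dad, a1[cbind(dad, l)], a2[cbind(dad, l)])
      }
      nx <- reflect(x[mom] + stats::rnorm(n, 0, dsp$seed_sigma), ext[1])
      ny <- reflect(y[mom] + stats::rnorm(n, 0, dsp$seed_sigma), ext[2])
      a1 <- na1; a2 <- na2; x <- nx; y <- ny
      mother <- mom; father <- dad
    }
  }
  ids <- sprintf("tree%04d", seq_len(n))
  km_per_deg <- pi * 6371.0088 / 180
  meta <- data.frame(id = ids, site_id = "sim",
                     species_label = "wild",
                     latitude = 47 + y / km_per_deg,
                     longitude = 2 + x / (km_per_deg * cos(47 * pi / 180)),
                     stringsAsFactors = FALSE)
  truth <- data.frame(id = ids, x_km = x, y_km = y,
                      mother = mother, father = father,
                      stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(a1, a2, ids, freqs$locus_ids, meta),
       truth = truth)
}

#' Generate landscape covariates and covariate-linked introgression rates
#'
#' Apple-production density, orchard count and orchard area are drawn
#' log-normally, with count and area correlated on the log scale (default
#' target Pearson r = 0.9, mirroring their strong collinearity in real
#' regional statistics). The expected introgression rate per site is
#' `exp(beta0 + beta_density * density + beta_orchards * orchards +
#' beta_interaction * density * orchards)`, rescaled so the largest site
#' rate equals `max_rate`.
#'
#' @param site_ids character vector of site names (>= 2).
#' @param landscape_effects named numeric as in [sim_config()].
#' @param seed integer seed.
#' @param target_cor target correlation between log orchard count and log
#'   orchard area.
#' @param max_rate expected introgression probability at the most exposed
#'   site.
#' @return list with `landscape` (site_id, apple_density, n_orchards,
#'   orchard_area, management_class) and `p_hybrid` (named per-site
#'   probability vector).
#' @export
attach_landscape_covariates <- function(site_ids, landscape_effects,
                                        seed = 1L, target_cor = 0.9,
                                        max_rate = 0.6) {
  if (length(site_ids) < 2) stop("need at least 2 sites")
  set.seed(as.integer(seed))
  ns <- length(site_ids)
  density <- stats::rlnorm(ns, log(5), 0.5)
  z1 <- stats::rnorm(ns)
  z2 <- target_cor * z1 + sqrt(1 - target_cor^2) * stats::rnorm(ns)
  n_orchards <- pmax(1, round(exp(log(20) + 0.7 * z1)))
  orchard_area <- exp(log(40) + 0.7 * z2)
  if (any(density < 0) || any(orchard_area < 0))
    stop("negative covariates")
  b <- landscape_effects
  eta <- b[["beta0"]] + b[["beta_density"]] * density +
    b[["beta_orchards"]] * n_orchards +
    b[["beta_interaction"]] * density * n_orchards
  r <- exp(eta - max(eta))            # in (0, 1], max site = 1
  p <- max_rate * r
  management <- ifelse(density > stats::median(density),
                       "intensive", "extensive")
  list(landscape = data.frame(site_id = site_ids, apple_density = density,
                              n_orchards = n_orchards,
                              orchard_area = orchard_area,
                              management_class = management,
                              stringsAsFactors = FALSE),
       p_hybrid = stats::setNames(p, site_ids))
}

#' Assign per-individual hybrid status from site-level probabilities
#'
#' Companion to [attach_landscape_covariates()]: given per-site hybrid
#' probabilities, draws Bernoulli hybrid status for `n_per_site` individuals
#' per site and attaches a plausible crop-ancestry value (F1/BC1-like for
#' hybrids, near-zero for pure trees).
#'
#' @param p_hybrid named per-site probability vector.
#' @param n_per_site individuals per site.
#' @param seed integer seed.
#' @return data.frame: id, site_id, is_hybrid, crop_ancestry.
#' @export
simulate_site_individuals <- function(p_hybrid, n_per_site = 50,
                                      seed = 1L) {
  set.seed(as.integer(seed))
  site <- rep(names(p_hybrid), each = n_per_site)
  n <- length(site)
  is_hyb <- stats::runif(n) < p_hybrid[site]
  crop_anc <- ifelse(is_hyb,
                     sample(c(0.5, 0.25), n, replace = TRUE) +
                       stats::rnorm(n, 0, 0.04),
                     abs(stats::rnorm(n, 0, 0.015)))
  crop_anc <- pmin(pmax(crop_anc, 0), 1)
  data.frame(id = sprintf("ind%05d", seq_len(n)), site_id = site,
             is_hybrid = is_hyb, crop_ancestry = crop_anc,
             stringsAsFactors = FALSE)
}

#' Simulate flower-visitor observations
#'
#' Observations are spread over six insect orders. Each order has a fixed
#' pool of taxa; under intensive cultivation and management the available
#' pool shrinks multiplicatively by `exp(-management_effect)` (floor of one
#' taxon), so distinct-taxon richness per order is depressed in the
#' intensive class.
#'
#' @param rates_by_order relative observation rates for the six orders
#'   (recycled/normalized); default weights typical flower-visitor surveys
#'   dominated by bees and flies.
#' @param management_effect non-negative; 0 means no richness depression.
#' @param n_obs total number of observations.
#' @param seed integer seed.
#' @param intensive_fraction fraction of observations made in the intensive
#'   class (default matches a 59:247 split).
#' @param taxa_per_order taxon-pool sizes per order (default sums to 86).
#' @return data.frame: record_id, taxon_id, insect_order, management_class.
#' @export
simulate_visitor_observations <- function(rates_by_order = NULL,
                                          management_effect = 1.0,
                                          n_obs = 306, seed = 1L,
                                          intensive_fraction = 59 / 306,
                                          taxa_per_order = c(30, 25, 12,
                                                             10, 6, 3)) {
  stopifnot(management_effect >= 0, n_obs >= 1)
  orders <- c("Hymenoptera", "Diptera", "Coleoptera", "Lepidoptera",
              "Hemiptera", "Neuroptera")
  if (is.null(rates_by_order))
    rates_by_order <- c(0.45, 0.30, 0.10, 0.08, 0.05, 0.02)
  rates_by_order <- rep_len(rates_by_order, 6)
  set.seed(as.integer(seed))
  cls <- ifelse(stats::runif(n_obs) < intensive_fraction,
                "intensive", "extensive")
  ord <- sample(orders, n_obs, replace = TRUE, prob = rates_by_order)
  pool_size <- stats::setNames(rep_len(taxa_per_order, 6), orders)
  intensive_pool <- stats::setNames(
    pmax(1L, round(pool_size * exp(-management_effect))), orders)
  taxon <- vapply(seq_len(n_obs), function(i) {
    avail <- if (cls[i] == "intensive") intensive_pool[[ord[i]]] else
      pool_size[[ord[i]]]
    sprintf("%s_t%02d", substr(ord[i], 1, 3), sample.int(avail, 1))
  }, character(1))
  data.frame(record_id = sprintf("obs%04d", seq_len(n_obs)),
             taxon_id = taxon, insect_order = ord, management_class = cls,
             stringsAsFactors = FALSE)
}
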