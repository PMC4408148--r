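# Synthetic-data generator: F-model frequencies, genotypes, pedigree,
# landscape covariates, visitor observations.

test_that("sim_config validates ranges and hybrid ancestry vectors", {
  expect_error(sim_config(divergence_f = 0), "divergence_f > 0")
  expect_error(sim_config(divergence_f = 1), "divergence_f < 1")
  expect_error(sim_config(missing_rate = 0.2), "missing_rate < 0.2")
  expect_error(
    sim_config(n_wild_clusters = 2,
               hybrid_spec = list(list(ancestry = c(0.5, 0.6, 0),
                                       count = 1, label = "bad"))),
    "sum to 1")
})

test_that("cluster frequency rows are simplex and deterministic", {
  cfg <- sim_config(n_wild_clusters = 3, n_loci = 8, seed = 5)
  fr <- sample_cluster_frequencies(cfg)
  for (m in fr$freqs)
    expect_equal(rowSums(m), rep(1, 4), tolerance = 1e-12,
                 ignore_attr = TRUE)
  fr2 <- sample_cluster_frequencies(cfg)
  expect_identical(fr, fr2)
  expect_false(identical(
    fr, sample_cluster_frequencies(sim_config(n_wild_clusters = 3,
                                              n_loci = 8, seed = 6))))
})

test_that("near-zero drift reproduces the ancestral frequencies", {
  cfg <- sim_config(n_wild_clusters = 2, n_loci = 10,
                    divergence_f = 1e-6, crop_divergence_f = 1e-6,
                    seed = 2)
  fr <- sample_cluster_frequencies(cfg)
  for (l in seq_along(fr$freqs)) {
    tv <- apply(fr$freqs[[l]], 1,
                function(p) sum(abs(p - fr$ancestral[[l]])) / 2)
    expect_lt(max(tv), 1e-2)
  }
})

test_that("realized between-cluster divergence matches the F-model moment", {
  # E[sum_a (p1a - p2a)^2] = 2F * sum_a p_anc_a (1 - p_anc_a): recompute
  # both sides from the same draws over many replicate loci
  cfg <- sim_config(n_wild_clusters = 2, n_loci = 4000,
                    alleles_per_locus = c(4, 4), divergence_f = 0.5,
                    crop_divergence_f = 0.5, seed = 3)
  fr <- sample_cluster_frequencies(cfg)
  lhs <- mean(vapply(seq_along(fr$freqs), function(l)
    sum((fr$freqs[[l]][1, ] - fr$freqs[[l]][2, ])^2), numeric(1)))
  rhs <- mean(vapply(seq_along(fr$freqs), function(l)
    2 * 0.5 * sum(fr$ancestral[[l]] * (1 - fr$ancestral[[l]])),
    numeric(1)))
  expect_equal(lhs, rhs, tolerance = 0.03)
})

test_that("pure-pool genotypes are Hardy-Weinberg draws from their pool", {
  cfg <- sim_config(n_wild_clusters = 1, n_loci = 30, n_per_cluster = 200,
                    hybrid_spec = list(), missing_rate = 0, seed = 4)
  fr <- sample_cluster_frequencies(cfg)
  gen <- sample_genotypes(fr, cfg)
  expect_true(all(gen$truth$hybrid_class %in% c("pure_wild", "pure_crop")))
  rows <- which(gen$truth$hybrid_class == "pure_wild")
  het <- heterozygosities(gen$genotypes, rows)
  exp_het <- mean(vapply(fr$freqs, function(m) 1 - sum(m[1, ]^2),
                         numeric(1)))
  expect_equal(het$H_O, exp_het, tolerance = 0.05)
  # every simulated allele exists in the generating table (conservation)
  for (l in seq_along(fr$freqs))
    expect_true(all(stats::na.omit(c(gen$genotypes$a1[, l],
                                     gen$genotypes$a2[, l])) %in%
                      as.integer(colnames(fr$freqs[[l]]))))
})

test_that("an F1 between fixed disjoint pools is heterozygous everywhere", {
  cfg <- sim_config(n_wild_clusters = 1, n_loci = 12, n_per_cluster = 0,
                    divergence_f = 0.5, crop_divergence_f = 0.5,
                    missing_rate = 0,
                    hybrid_spec = list(list(ancestry = c(0.5, 0.5),
                                            count = 20, label = "F1")),
                    seed = 8)
  fr <- sample_cluster_frequencies(cfg)
  # force fixation for disjoint alleles
  for (l in seq_along(fr$freqs)) {
    fr$freqs[[l]][] <- 0
    fr$freqs[[l]][1, 1] <- 1      # wild fixed for first allele
    fr$freqs[[l]][2, 2] <- 1      # crop fixed for second allele
  }
  gen <- sample_genotypes(fr, cfg)
  expect_true(all(gen$genotypes$a1 != gen$genotypes$a2))
  for (l in seq_along(fr$freqs)) {
    codes <- as.integer(colnames(fr$freqs[[l]]))
    expect_true(all(gen$genotypes$a1[, l] == codes[1]))
    expect_true(all(gen$genotypes$a2[, l] == codes[2]))
  }
})

test_that("missingness is per-call and hits its target rate", {
  cfg <- sim_config(n_wild_clusters = 2, n_loci = 20, n_per_cluster = 25,
                    hybrid_spec = list(), missing_rate = 0.15, seed = 9)
  gen <- sample_genotypes(sample_cluster_frequencies(cfg), cfg)
  n_calls <- length(gen$genotypes$a1)
  obs <- sum(is.na(gen$genotypes$a1))
  bounds <- stats::qbinom(c(0.005, 0.995), n_calls, 0.15)
  expect_gte(obs, bounds[1])
  expect_lte(obs, bounds[2])
  # both alleles jointly missing
  expect_identical(is.na(gen$genotypes$a1), is.na(gen$genotypes$a2))
})

test_that("empty design errors; truth ancestry rows sum to 1", {
  cfg <- sim_config(n_per_cluster = 0, hybrid_spec = list())
  fr <- sample_cluster_frequencies(cfg)
  expect_error(sample_genotypes(fr, cfg), "empty design")
  cfg2 <- sim_config(n_wild_clusters = 2, n_loci = 4, n_per_cluster = 3,
                     seed = 1)
  gen <- sample_genotypes(sample_cluster_frequencies(cfg2), cfg2)
  anc <- as.matrix(gen$truth[, grep("^anc_", names(gen$truth))])
  expect_equal(unname(rowSums(anc)), rep(1, nrow(anc)), tolerance = 1e-12)
})

test_that("pedigree simulation: identity at zero generations, errors", {
  cfg <- sim_config(n_wild_clusters = 1, n_loci = 6, n_per_cluster = 20,
                    dispersal = list(pollen_sigma = 1, seed_sigma = 1,
                                     n_generations = 0, extent = c(10, 10)),
                    seed = 12)
  fr <- sample_cluster_frequencies(cfg)
  ped <- simulate_spatial_pedigree(fr, cfg)
  expect_true(all(is.na(ped$truth$mother)))    # founders unchanged
  expect_equal(nrow(ped$genotypes$a1), 20)
  cfg$dispersal$seed_sigma <- 0
  expect_error(simulate_spatial_pedigree(fr, cfg), "sigma")
  # coordinates stay in the rectangle after reflection
  cfg$dispersal <- list(pollen_sigma = 0.5, seed_sigma = 2,
                        n_generations = 5, extent = c(10, 10))
  ped2 <- simulate_spatial_pedigree(fr, cfg)
  expect_true(all(ped2$truth$x_km >= 0 & ped2$truth$x_km <= 10))
  expect_true(all(ped2$truth$y_km >= 0 & ped2$truth$y_km <= 10))
})

test_that("landscape covariates: flat betas, interaction monotonicity,
           count/area correlation", {
  zero <- c(beta0 = -2, beta_density = 0, beta_orchards = 0,
            beta_interaction = 0)
  lc <- attach_landscape_covariates(paste0("s", 1:10), zero, seed = 3)
  expect_equal(diff(range(lc$p_hybrid)), 0)
  expect_error(attach_landscape_covariates("s1", zero), "2 sites")
  # beta_dn > 0: (high, high) rate exceeds (high, low) by construction
  b <- c(beta0 = -3, beta_density = 0, beta_orchards = 0,
         beta_interaction = 0.01)
  lc2 <- attach_landscape_covariates(paste0("s", 1:30), b, seed = 4)
  prod_dn <- lc2$landscape$apple_density * lc2$landscape$n_orchards
  expect_equal(order(lc2$p_hybrid), order(prod_dn))
  # default config, 20 sites: realized log-scale count/area correlation
  # near the 0.9 target
  r <- replicate(30, {
    lcx <- attach_landscape_covariates(
      paste0("s", 1:20), sim_config()$landscape_effects,
      seed = sample.int(1e6, 1))
    stats::cor(log(lcx$landscape$n_orchards),
               log(lcx$landscape$orchard_area))
  })
  expect_lt(abs(mean(r) - 0.9), 0.1)
})

test_that("visitor observations: order vocabulary, richness depression,
           floor at one taxon", {
  v0 <- simulate_visitor_observations(management_effect = 0, n_obs = 4000,
                                      seed = 5)
  expect_equal(sort(unique(v0$insect_order)),
               sort(c("Hymenoptera", "Diptera", "Coleoptera",
                      "Lepidoptera", "Hemiptera", "Neuroptera")))
  rich <- function(v) tapply(v$taxon_id, v$management_class,
                             function(x) length(unique(x)))
  r0 <- rich(v0)
  expect_lt(abs(r0[["intensive"]] - r0[["extensive"]]) /
              r0[["extensive"]], 0.25)
  vinf <- simulate_visitor_observations(management_effect = 50,
                                        n_obs = 2000, seed = 6)
  per_order <- with(vinf[vinf$management_class == "intensive", ],
                    tapply(taxon_id, insect_order,
                           function(x) length(unique(x))))
  expect_true(all(per_order == 1))
  # determinism
  expect_identical(simulate_visitor_observations(seed = 7),
                   simulate_visitor_observations(seed = 7))
})
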