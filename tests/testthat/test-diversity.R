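# Heterozygosities, Weir-Cockerham F-statistics, HWE deficit test,
# rarefied allelic and private allelic richness, site filters.

test_that("heterozygosities match hand arithmetic", {
  # all homozygous (a, a): H_O = H_E = 0
  G0 <- gm_from_calls(replicate(4, matrix(1, 2, 2), simplify = FALSE))
  h0 <- heterozygosities(G0)
  expect_equal(h0$H_O, 0)
  expect_equal(h0$H_E, 0)
  # two individuals (a,b), (a,b): H_O = 1, H_E = (4/3)(0.5) = 0.667
  G1 <- gm_from_calls(replicate(2, rbind(1, 2), simplify = FALSE))
  h1 <- heterozygosities(G1)
  expect_equal(h1$H_O, 1)
  expect_equal(h1$H_E, 4 / 3 * 0.5)
})

test_that("H_O tracks H_E in a large Hardy-Weinberg pool", {
  cfg <- sim_config(n_wild_clusters = 1, n_loci = 40, n_per_cluster = 300,
                    hybrid_spec = list(), missing_rate = 0, seed = 30)
  gen <- sample_genotypes(sample_cluster_frequencies(cfg), cfg)
  wild <- which(gen$truth$hybrid_class == "pure_wild")  # one panmictic pool
  h <- heterozygosities(gen$genotypes, wild)
  expect_equal(h$H_O, h$H_E, tolerance = 0.02)
})

test_that("F-statistics: fixation, null, and oracle equivalence", {
  Gfix <- fixed_difference_gm(5, 4)
  expect_equal(wc_f_statistics(Gfix)$F_ST, 1)
  # one unit under HWE: F_IS ~ 0, F_ST undefined and flagged
  cfg <- sim_config(n_wild_clusters = 1, n_loci = 30, n_per_cluster = 250,
                    hybrid_spec = list(), missing_rate = 0, seed = 31)
  gen1 <- sample_genotypes(sample_cluster_frequencies(cfg), cfg)
  G1 <- gen1$genotypes[which(gen1$truth$hybrid_class == "pure_wild"), ]
  fs <- wc_f_statistics(G1, rep("u", nrow(G1$a1)))
  expect_true(is.na(fs$F_ST))
  expect_match(fs$flags, "single unit")
  expect_equal(fs$F_IS, 0, tolerance = 0.02)
  # oracle equivalence on small unbalanced instances with missing calls
  set.seed(32)
  for (rep in 1:5) {
    n <- 8
    calls <- replicate(n, matrix(sample(1:4, 6, replace = TRUE), 2, 3),
                       simplify = FALSE)
    G <- gm_from_calls(calls, sites = sample(c("A", "B"), n,
                                             replace = TRUE,
                                             prob = c(0.6, 0.4)))
    G$a1[1, 1] <- NA_integer_; G$a2[1, 1] <- NA_integer_
    got <- wc_f_statistics(G)
    want <- oracle_wc(G, G$meta$site_id)
    expect_equal(got$F_ST, want$F_ST, tolerance = 1e-12)
    expect_equal(got$F_IS, want$F_IS, tolerance = 1e-12)
  }
})

test_that("pairwise F_ST permutation p-values behave at the extremes", {
  Gfix <- fixed_difference_gm(10, 6)
  res <- pairwise_fst_permutation(Gfix, n_perm = 99, seed = 1)
  expect_equal(res$theta["A", "B"], 1)
  expect_equal(res$p["A", "B"], 1 / 100)      # most extreme possible
  expect_true(isSymmetric(res$theta))
  expect_error(pairwise_fst_permutation(Gfix, n_perm = 0), "n_perm")
  # identical units: theta near zero, p not extreme
  cfg <- sim_config(n_wild_clusters = 1, n_loci = 10, n_per_cluster = 40,
                    hybrid_spec = list(), missing_rate = 0, seed = 33)
  G <- sample_genotypes(sample_cluster_frequencies(cfg), cfg)$genotypes
  G$meta$site_id <- rep(c("x", "y"), 20)
  r2 <- pairwise_fst_permutation(G, n_perm = 99, seed = 2)
  expect_lt(abs(r2$theta["x", "y"]), 0.05)
  expect_gt(r2$p["x", "y"], 0.05)
})

test_that("heterozygote-deficit test flags extremes and monomorphism", {
  # all homozygotes, two alleles at 0.5: maximal deficit
  calls <- c(replicate(6, matrix(1, 2, 3), simplify = FALSE),
             replicate(6, matrix(2, 2, 3), simplify = FALSE))
  G <- gm_from_calls(calls)
  res <- hwe_deficit_test(G, n_perm = 199, seed = 3)
  expect_equal(res$p, 1 / 200)
  expect_gt(res$F_IS, 0.9)
  # monomorphic: flagged
  Gm <- gm_from_calls(replicate(5, matrix(1, 2, 2), simplify = FALSE))
  resm <- hwe_deficit_test(Gm, n_perm = 19)
  expect_true(is.na(resm$p))
  expect_match(resm$flag, "undefined")
  # HWE pool: p is not small (single calibration point; the full
  # type-I-error sweep lives in the acceptance suite)
  cfg <- sim_config(n_wild_clusters = 1, n_loci = 20, n_per_cluster = 80,
                    hybrid_spec = list(), missing_rate = 0, seed = 34)
  genh <- sample_genotypes(sample_cluster_frequencies(cfg), cfg)
  Gh <- genh$genotypes[which(genh$truth$hybrid_class == "pure_wild"), ]
  resh <- hwe_deficit_test(Gh, n_perm = 199, seed = 4)
  expect_gt(resh$p, 0.05)
})

test_that("rarefied allelic richness: hand combinatorics and bounds", {
  # monomorphic locus: A_R(g) = 1 for every g
  Gm <- gm_from_calls(replicate(4, matrix(1, 2, 1), simplify = FALSE))
  expect_equal(rarefied_allelic_richness(Gm, g = 2)$mean, 1)
  expect_equal(rarefied_allelic_richness(Gm, g = 5)$mean, 1)
  # allele counts {5, 5}, g = 2: 2 (1 - C(5,2)/C(10,2)) = 14/9
  calls <- c(replicate(2, matrix(1, 2, 1), simplify = FALSE),
             replicate(2, matrix(2, 2, 1), simplify = FALSE),
             list(rbind(1, 2)))
  G55 <- gm_from_calls(calls)
  expect_equal(rarefied_allelic_richness(G55, g = 2)$mean, 14 / 9,
               tolerance = 1e-12)
  # unit with fewer copies than g: locus excluded and flagged
  small <- rarefied_allelic_richness(G55, unit = 1:2, g = 6)
  expect_true(is.na(small$per_locus$A_R[1]))
  expect_equal(small$excluded, "L01")
})

test_that("rarefaction equals exhaustive enumeration (A_R and A_P)", {
  set.seed(35)
  for (rep in 1:8) {
    counts <- sample(1:5, sample(2:4, 1), replace = TRUE)
    while (sum(counts) > 12 || sum(counts) < 4)
      counts <- sample(1:5, sample(2:4, 1), replace = TRUE)
    g <- sample(2:min(4, sum(counts)), 1)
    # build a unit holding exactly these allele copies
    copies <- rep(seq_along(counts), counts)
    if (length(copies) %% 2 == 1) copies <- c(copies, copies[1])
    n_ind <- length(copies) / 2
    calls <- lapply(seq_len(n_ind), function(i)
      rbind(copies[2 * i - 1], copies[2 * i]))
    G <- gm_from_calls(calls)
    tab <- table(factor(c(G$a1[, 1], G$a2[, 1])))
    expect_equal(rarefied_allelic_richness(G, g = g)$mean,
                 oracle_rarefied_richness(as.integer(tab), g),
                 tolerance = 1e-12)
  }
  # A_R(g) nondecreasing in g
  cfg <- sim_config(n_wild_clusters = 1, n_loci = 6, n_per_cluster = 10,
                    hybrid_spec = list(), missing_rate = 0, seed = 36)
  G <- sample_genotypes(sample_cluster_frequencies(cfg), cfg)$genotypes
  ar <- vapply(2:10, function(g)
    rarefied_allelic_richness(G, g = g)$mean, numeric(1))
  expect_true(all(diff(ar) >= -1e-12))
  expect_true(ar[1] >= 1 && ar[1] <= 2)
})

test_that("private allelic richness: trivial cases and exhaustive oracle", {
  # allele private to unit A and fixed there contributes 1; shared fixed
  # alleles contribute 0
  calls <- c(replicate(3, matrix(1, 2, 2), simplify = FALSE),
             replicate(3, matrix(2, 2, 2), simplify = FALSE))
  G <- gm_from_calls(calls, sites = rep(c("A", "B"), each = 3))
  ap <- private_allelic_richness(G, g = 2)
  expect_equal(unname(ap$per_unit), c(1, 1))
  Gshared <- gm_from_calls(replicate(6, matrix(1, 2, 1),
                                     simplify = FALSE),
                           sites = rep(c("A", "B"), each = 3))
  expect_equal(unname(private_allelic_richness(Gshared, g = 2)$per_unit),
               c(0, 0))
  # exhaustive double-enumeration oracle, 2 units, g = 4
  set.seed(37)
  for (rep in 1:3) {
    mk_unit <- function() {
      copies <- sample(1:4, 10, replace = TRUE)
      lapply(1:5, function(i) rbind(copies[2 * i - 1], copies[2 * i]))
    }
    G2 <- gm_from_calls(c(mk_unit(), mk_unit()),
                        sites = rep(c("A", "B"), each = 5))
    res <- private_allelic_richness(G2, g = 4)
    tabA <- table(factor(c(G2$a1[1:5, 1], G2$a2[1:5, 1])))
    tabB <- table(factor(c(G2$a1[6:10, 1], G2$a2[6:10, 1])))
    expect_equal(unname(res$per_unit[["A"]]),
                 oracle_private_richness_2u(tabA, tabB, 4),
                 tolerance = 1e-12)
  }
})

test_that("site filters emit both analysis sets with reasons", {
  cfg <- sim_config(n_wild_clusters = 2, n_loci = 4, n_per_cluster = 5,
                    sites_per_cluster = 1, hybrid_spec = list(),
                    missing_rate = 0, seed = 38)
  G <- sample_genotypes(sample_cluster_frequencies(cfg), cfg)$genotypes
  # shrink one site to 3 individuals; knock a locus down in another
  keep <- c(1:3, 6:15)
  G2 <- G[keep, ]
  G2$a1[4:8, 2] <- NA_integer_       # wild2 locus 2 typed in 0 of 5
  G2$a2[4:8, 2] <- NA_integer_
  f <- site_filters(G2)
  expect_false("wild1_s1" %in% f$diversity_sites)    # 3 individuals
  expect_true("wild2_s1" %in% f$diversity_sites)
  expect_false("wild2_s1" %in% f$map_sites)          # locus below 2
  expect_true("crop" %in% f$map_sites)
  expect_match(f$excluded$reason[f$excluded$site == "wild1_s1"],
               "3 individuals")
  # all sites complete: identity
  f2 <- site_filters(G)
  expect_equal(sort(f2$map_sites), sort(unique(G$meta$site_id)))
})
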