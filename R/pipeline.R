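# End-to-end orchestration: simulate -> validate -> admixture -> classify
# -> diversity -> spatial structure -> landscape GLMs -> report bundle.

#' Pipeline configuration
#'
#' @param sim a [sim_config()] describing the synthetic world (or NULL
#'   with `genepop`/`metadata` paths to analyse existing files).
#' @param genepop,metadata optional input paths used when `sim` is NULL.
#' @param K number of clusters for the main admixture run (defaults to
#'   wild clusters + 1 when simulating).
#' @param n_replicates replicate admixture runs (aligned and averaged).
#' @param n_sweeps,burn_in Gibbs sampler schedule.
#' @param pure_threshold,crop_threshold,assign_threshold classification
#'   thresholds (0.9 / 0.1 / 0.55).
#' @param g_richness,g_private rarefaction sizes for allelic and private
#'   allelic richness.
#' @param sgs list: `max_d` (km), `first_class_edge` (km), `n_perm`.
#' @param model3_granularity `"cells"` or `"observation"` (must be
#'   explicit).
#' @param seed master seed; per-stage child seeds are derived as
#'   `seed + stage offset` so stages can be rerun in isolation.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), genepop = NULL,
                            metadata = NULL, K = NULL, n_replicates = 2,
                            n_sweeps = 600, burn_in = 200,
                            pure_threshold = 0.9, crop_threshold = 0.1,
                            assign_threshold = 0.55, g_richness = 2,
                            g_private = 20,
                            sgs = list(max_d = 10, first_class_edge = 1,
                                       n_perm = 499),
                            model3_granularity = "cells", seed = 1L) {
  if (is.null(sim) && (is.null(genepop)))
    stop("either a sim config or a genepop path is required")
  if (!is.null(genepop) && !file.exists(genepop))
    stop("genepop file not found: ", genepop)
  if (!is.null(metadata) && !file.exists(metadata))
    stop("metadata file not found: ", metadata)
  stopifnot(crop_threshold < pure_threshold)
  structure(list(sim = sim, genepop = genepop, metadata = metadata,
                 K = K, n_replicates = n_replicates, n_sweeps = n_sweeps,
                 burn_in = burn_in, pure_threshold = pure_threshold,
                 crop_threshold = crop_threshold,
                 assign_threshold = assign_threshold,
                 g_richness = g_richness, g_private = g_private,
                 sgs = sgs, model3_granularity = model3_granularity,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# stage seed fan-out: fixed offsets keep stages independently rerunnable
stage_seed <- function(config, stage)
  (config$seed + 101L * stage) %% .Machine$integer.max

#' Run the full pipeline
#'
#' Runs the stages in order with per-stage seeds, halting on the first
#' failure. When simulating, both the cluster/hybrid genotype set (for
#' admixture, classification, diversity, GLMs) and a dispersal-pedigree
#' set (for spatial genetic structure) are generated; the crop cluster of
#' the admixture solution is identified as the cluster carrying the
#' largest mean membership of crop-labelled individuals.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the artifact list written by [write_report()].
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # -- simulate / load ------------------------------------------------
  truth <- NULL
  if (!is.null(config$sim)) {
    simc <- config$sim
    simc$seed <- stage_seed(config, 1L)
    freqs <- sample_cluster_frequencies(simc)
    gen <- sample_genotypes(freqs, simc)
    G <- gen$genotypes
    truth <- gen$truth
    ped <- simulate_spatial_pedigree(freqs, simc)
    visitors <- simulate_visitor_observations(
      management_effect = 1.0, seed = stage_seed(config, 2L))
  } else {
    G <- read_genepop(config$genepop)
    if (!is.null(config$metadata)) G <- read_metadata(G, config$metadata)
    ped <- NULL
    visitors <- NULL
  }

  # -- validate / filter ----------------------------------------------
  G <- filter_missingness(G)
  if (nrow(G$a1) == 0) stop("validation failed: no individuals retained")

  # -- admixture -------------------------------------------------------
  K <- config$K
  if (is.null(K))
    K <- if (!is.null(config$sim)) config$sim$n_wild_clusters + 1L else 2L
  fits <- lapply(seq_len(config$n_replicates), function(r)
    gibbs_admixture(G, K, config$n_sweeps, config$burn_in,
                    seed = stage_seed(config, 3L) + r))
  al <- align_replicates(lapply(fits, `[[`, "Q"))
  Q <- consensus_membership(al$aligned)

  # -- classification --------------------------------------------------
  crop_lab <- G$meta$species_label == "crop"
  crop_cluster <- if (any(crop_lab))
    which.max(colMeans(Q[crop_lab, , drop = FALSE])) else ncol(Q)
  wild_clusters <- setdiff(seq_len(ncol(Q)), crop_cluster)
  wild_rows <- which(!crop_lab)
  w <- cumulative_wild_membership(Q[wild_rows, , drop = FALSE],
                                  wild_clusters)
  categories <- classify_individuals(w, config$pure_threshold,
                                     config$crop_threshold)
  rates_site <- introgression_rate(w, categories,
                                   G$meta$site_id[wild_rows])
  rates_all <- introgression_rate(w, categories)
  classified <- data.frame(id = G$individual_ids[wild_rows],
                           site_id = G$meta$site_id[wild_rows],
                           wild_membership = w,
                           crop_ancestry = 1 - w,
                           category = as.character(categories),
                           stringsAsFactors = FALSE)

  # -- within-wild structure -------------------------------------------
  pure <- wild_rows[categories == "pure_wild"]
  Gp <- G[pure, ]
  Qw <- Q[pure, wild_clusters, drop = FALSE]
  colnames(Qw) <- paste0("pop", seq_along(wild_clusters))
  asg <- assign_wild_populations(Qw, config$assign_threshold)
  admix_counts <- admixed_pair_counts(Qw, asg$assignment)

  # -- diversity -------------------------------------------------------
  filt <- site_filters(Gp)
  div_rows <- lapply(filt$diversity_sites, function(s) {
    rows <- which(Gp$meta$site_id == s)
    het <- heterozygosities(Gp, rows)
    ar <- rarefied_allelic_richness(Gp, rows, g = config$g_richness)
    fis <- wc_f_statistics(Gp[rows, ], rep("u", length(rows)))$F_IS
    data.frame(site = s, n = length(rows), H_O = het$H_O, H_E = het$H_E,
               F_IS = fis, A_R = ar$mean, stringsAsFactors = FALSE)
  })
  diversity_tab <- do.call(rbind, div_rows)
  ap <- if (length(filt$diversity_sites) >= 2) {
    keep <- Gp$meta$site_id %in% filt$diversity_sites
    private_allelic_richness(Gp[which(keep), ],
                             Gp$meta$site_id[keep],
                             g = config$g_private)$per_unit
  } else NULL
  if (!is.null(ap))
    diversity_tab$A_P <- ap[diversity_tab$site]
  fst <- if (length(unique(asg$assignment[asg$assignment !=
                                          "unassigned"])) >= 2) {
    rows_asg <- which(asg$assignment != "unassigned")
    pairwise_fst_permutation(Gp[rows_asg, ],
                             asg$assignment[rows_asg], n_perm = 99,
                             seed = stage_seed(config, 4L))
  } else NULL

  # -- spatial genetic structure ---------------------------------------
  sgs <- if (!is.null(ped)) {
    sgs_analysis(ped$genotypes, max_d = config$sgs$max_d,
                 first_class_edge = config$sgs$first_class_edge,
                 n_perm = config$sgs$n_perm,
                 seed = stage_seed(config, 5L))
  } else NULL

  # -- landscape GLMs --------------------------------------------------
  glm_res <- NULL
  sites <- unique(classified$site_id)
  if (length(sites) >= 2) {
    lc <- attach_landscape_covariates(sites,
                                      config$sim$landscape_effects,
                                      seed = stage_seed(config, 6L))
    glm_res <- run_model_1_2(classified, lc$landscape)
  }
  glm3 <- if (!is.null(visitors))
    run_model_3(visitors, config$model3_granularity) else NULL

  artifacts <- list(config = config, Q = Q, classified = classified,
                    rates_site = rates_site, rates_all = rates_all,
                    diversity = diversity_tab, fst = fst,
                    admixed_counts = admix_counts, assignment = asg,
                    sgs = sgs, glm12 = glm_res, glm3 = glm3,
                    truth = truth)
  write_report(artifacts, out_dir)
  invisible(artifacts)
}

#' Write the pipeline report bundle
#'
#' Validates the artifact schemas and writes CSV tables plus a JSON
#' summary with the headline numbers and a provenance block (seed, package
#' version, config hash). Deterministic: identical artifacts yield
#' byte-identical files.
#'
#' @param artifacts list produced by [run_pipeline()].
#' @param out_dir output directory.
#' @return invisibly, the manifest data.frame (file, md5).
#' @export
write_report <- function(artifacts, out_dir) {
  if (length(artifacts) == 0) stop("empty artifact set")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  need <- c("classified", "rates_site")
  miss <- setdiff(need, names(artifacts))
  if (length(miss))
    stop("missing artifact(s): ", paste(miss, collapse = ", "))
  cls <- artifacts$classified
  for (col in c("id", "site_id", "crop_ancestry", "category"))
    if (!col %in% names(cls))
      stop("classified table lacks column '", col, "'")
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  wr(cls, "classification.csv")
  wr(artifacts$rates_site, "introgression_rates_by_site.csv")
  if (!is.null(artifacts$rates_all))
    wr(artifacts$rates_all, "introgression_rates_overall.csv")
  if (!is.null(artifacts$diversity)) wr(artifacts$diversity,
                                        "diversity_by_site.csv")
  if (!is.null(artifacts$Q)) {
    qdf <- data.frame(id = rownames(artifacts$Q),
                      round(artifacts$Q, 6), check.names = FALSE)
    wr(qdf, "ancestry_Q.csv")
  }
  if (!is.null(artifacts$glm12)) {
    wr(artifacts$glm12$model1$table, "glm_model1.csv")
    wr(artifacts$glm12$model2$table, "glm_model2.csv")
  }
  if (!is.null(artifacts$glm3)) wr(artifacts$glm3$table, "glm_model3.csv")
  if (!is.null(artifacts$admixed_counts))
    wr(as.data.frame(artifacts$admixed_counts), "admixed_counts.csv")
  if (!is.null(artifacts$fst))
    wr(as.data.frame(artifacts$fst$theta), "pairwise_fst.csv")
  summary <- list(
    provenance = list(
      seed = artifacts$config$seed,
      package_version = as.character(utils::packageVersion("crabflow")),
      config_hash = config_hash(artifacts$config)),
    introgression = if (!is.null(artifacts$rates_all))
      as.list(artifacts$rates_all[1, ]) else NULL,
    sgs = artifacts$sgs[c("b", "b_Ld", "F_1", "r2", "p", "Sp")],
    glm = list(
      model1_F = if (!is.null(artifacts$glm12))
        artifacts$glm12$model1$table$F else NULL,
      model3_F = if (!is.null(artifacts$glm3))
        artifacts$glm3$table$F else NULL))
  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, null = "null")
  files <- c(files, json_path)
  manifest <- data.frame(file = basename(files),
                         md5 = vapply(files, function(f)
                           as.character(tools::md5sum(f)), character(1)),
                         row.names = NULL)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

# stable hash of the configuration (serialization-based)
config_hash <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  # fold the raw bytes into a short hex digest without extra deps
  v <- as.integer(raw)
  h <- 0
  for (chunk in split(v, ceiling(seq_along(v) / 1000)))
    h <- (h * 31 + sum(chunk * seq_along(chunk))) %% 2^31
  sprintf("%08x", as.integer(h))
}
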