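# Threshold-based crop-to-wild introgression classification on ancestry
# matrices, group-level introgression rates, and within-wild population
# assignment.

#' Cumulative wild membership
#'
#' Sums each individual's membership coefficients over the clusters that
#' belong to the wild gene pool; `1 - w` is the crop membership.
#'
#' @param Q N x K ancestry matrix (rows on the simplex).
#' @param wild_clusters column indices or names of the wild clusters (may
#'   be empty).
#' @return named numeric vector `w` in `[0, 1]`.
#' @export
cumulative_wild_membership <- function(Q, wild_clusters) {
  Q <- as.matrix(Q)
  if (is.character(wild_clusters))
    wild_clusters <- match(wild_clusters, colnames(Q))
  if (anyNA(wild_clusters) || any(wild_clusters < 1) ||
      any(wild_clusters > ncol(Q)))
    stop("wild_clusters must reference columns of Q")
  if (length(wild_clusters) == 0)
    return(stats::setNames(rep(0, nrow(Q)), rownames(Q)))
  w <- rowSums(Q[, wild_clusters, drop = FALSE])
  pmin(pmax(w, 0), 1)
}

#' Classify individuals by cumulative wild membership
#'
#' Individuals sampled as wild are `pure_wild` when `w > pure_threshold`
#' (strict), `misidentified_crop` when `w < crop_threshold` (strict), and
#' `hybrid` otherwise. The two boundary values therefore fall in the
#' hybrid class — a measure-zero convention fixed for determinism.
#'
#' @param w cumulative wild membership vector (see
#'   [cumulative_wild_membership()]).
#' @param pure_threshold strict lower bound for pure wild (default 0.9).
#' @param crop_threshold strict upper bound for misidentified crop
#'   (default 0.1).
#' @return factor with levels `pure_wild`, `hybrid`, `misidentified_crop`.
#' @export
classify_individuals <- function(w, pure_threshold = 0.9,
                                 crop_threshold = 0.1) {
  if (crop_threshold >= pure_threshold)
    stop("crop_threshold must be below pure_threshold")
  if (any(w < 0 | w > 1, na.rm = TRUE)) stop("w must lie in [0, 1]")
  cat_ <- ifelse(w > pure_threshold, "pure_wild",
                 ifelse(w < crop_threshold, "misidentified_crop", "hybrid"))
  factor(cat_, levels = c("pure_wild", "hybrid", "misidentified_crop"))
}

#' Group-level introgression rates
#'
#' Computes both readings of the crop-to-wild "introgression rate" per
#' group and labels them: `hybrid_fraction` — hybrids over
#' non-misidentified individuals — and `mean_crop_ancestry` — mean
#' `1 - w` over non-misidentified individuals. The fraction of hybrids in
#' the *total* group (misidentified included in the denominator) is also
#' reported, matching headline percentages quoted over whole datasets.
#'
#' @param w cumulative wild membership vector.
#' @param categories factor from [classify_individuals()] (recomputed from
#'   `w` with default thresholds when omitted).
#' @param group optional grouping vector (site, country, ...); a single
#'   `all` group when omitted.
#' @return data.frame per group: `group`, `n_total`, `n_hybrid`,
#'   `n_misidentified`, `hybrid_fraction`, `hybrid_fraction_total`,
#'   `mean_crop_ancestry`.
#' @export
introgression_rate <- function(w, categories = NULL, group = NULL) {
  if (is.null(categories)) categories <- classify_individuals(w)
  if (is.null(group)) group <- rep("all", length(w))
  stopifnot(length(categories) == length(w), length(group) == length(w))
  res <- lapply(split(seq_along(w), group), function(idx) {
    cat_g <- categories[idx]
    keep <- cat_g != "misidentified_crop"
    n_tot <- length(idx)
    n_hyb <- sum(cat_g == "hybrid")
    n_mis <- sum(!keep)
    data.frame(n_total = n_tot, n_hybrid = n_hyb, n_misidentified = n_mis,
               hybrid_fraction = if (sum(keep)) n_hyb / sum(keep) else NaN,
               hybrid_fraction_total = n_hyb / n_tot,
               mean_crop_ancestry = if (sum(keep))
                 mean(1 - w[idx][keep]) else NaN)
  })
  out <- do.call(rbind, res)
  out <- cbind(group = names(res), out)
  rownames(out) <- NULL
  out
}

#' Assign nonintrogressed individuals to wild populations
#'
#' An individual is assigned to the wild cluster with its largest
#' membership when that membership strictly exceeds `threshold`; otherwise
#' it is `unassigned`.
#'
#' @param Q_wild N x K_wild ancestry matrix restricted to wild clusters
#'   (columns need not sum to 1).
#' @param threshold assignment threshold (default 0.55).
#' @return list with `assignment` (character vector: cluster name or
#'   `"unassigned"`), `counts` (table incl. unassigned), `threshold`.
#' @export
assign_wild_populations <- function(Q_wild, threshold = 0.55) {
  Q_wild <- as.matrix(Q_wild)
  if (is.null(colnames(Q_wild)))
    colnames(Q_wild) <- paste0("pop", seq_len(ncol(Q_wild)))
  top <- max.col(Q_wild, ties.method = "first")
  val <- Q_wild[cbind(seq_len(nrow(Q_wild)), top)]
  asg <- ifelse(val > threshold, colnames(Q_wild)[top], "unassigned")
  names(asg) <- rownames(Q_wild)
  list(assignment = asg,
       counts = table(factor(asg, levels = c(colnames(Q_wild),
                                             "unassigned"))),
       threshold = threshold)
}

#' Pairwise admixed-genotype counts between wild populations
#'
#' For each assigned individual, counts it as admixed between its assigned
#' population and the population with the second-largest membership when
#' the assigned membership lies in `(lo, hi]` — the "membership 0.55-0.9"
#' convention used for between-population admixture bookkeeping.
#'
#' @param Q_wild N x K_wild wild-cluster ancestry matrix.
#' @param assignment from [assign_wild_populations()].
#' @param lo,hi membership band defining an admixed assigned genotype.
#' @return symmetric integer matrix of admixed counts (diagonal 0).
#' @export
admixed_pair_counts <- function(Q_wild, assignment, lo = 0.55, hi = 0.9) {
  Q_wild <- as.matrix(Q_wild)
  pops <- colnames(Q_wild)
  cnt <- matrix(0L, length(pops), length(pops),
                dimnames = list(pops, pops))
  for (i in seq_len(nrow(Q_wild))) {
    a <- assignment[i]
    if (a == "unassigned") next
    j <- match(a, pops)
    v <- Q_wild[i, j]
    if (v > lo && v <= hi) {
      second <- order(Q_wild[i, ], decreasing = TRUE)[2]
      cnt[j, second] <- cnt[j, second] + 1L
      cnt[second, j] <- cnt[second, j] + 1L
    }
  }
  diag(cnt) <- 0L
  cnt
}
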