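# Per-unit genetic diversity: heterozygosities, Weir-Cockerham
# F-statistics with permutation significance, a heterozygote-deficit
# permutation test, and rarefaction-standardized allelic richness.

unit_rows <- function(G, unit) {
  if (is.character(unit) && length(unit) == 1 &&
      unit %in% G$meta$site_id) {
    which(G$meta$site_id == unit)
  } else if (is.logical(unit)) {
    which(unit)
  } else {
    as.integer(unit)
  }
}

#' Observed and expected heterozygosity
#'
#' Per locus: `H_O` is the fraction of typed individuals that are
#' heterozygous; `H_E` is Nei's unbiased gene diversity
#' `(2n / (2n - 1)) (1 - sum p^2)` with `n` the typed individuals.
#' Multilocus values are unweighted means over loci polymorphic (and typed)
#' in the unit; when no locus is polymorphic the mean over typed loci
#' (zero) is returned.
#'
#' @param G a [genotype_matrix()].
#' @param unit rows of the unit: site id, logical, or integer indices;
#'   defaults to all individuals.
#' @return list: `per_locus` (data.frame locus, n, H_O, H_E), `H_O`,
#'   `H_E` (multilocus means).
#' @export
heterozygosities <- function(G, unit = seq_len(nrow(G$a1))) {
  rows <- unit_rows(G, unit)
  L <- length(G$locus_ids)
  ho <- he <- rep(NA_real_, L)
  n_typed <- integer(L)
  for (l in seq_len(L)) {
    a1 <- G$a1[rows, l]; a2 <- G$a2[rows, l]
    ok <- !is.na(a1)
    n <- sum(ok)
    n_typed[l] <- n
    if (n == 0) next
    ho[l] <- mean(a1[ok] != a2[ok])
    p <- table(c(a1[ok], a2[ok])) / (2 * n)
    he[l] <- if (2 * n > 1) (2 * n / (2 * n - 1)) * (1 - sum(p^2)) else 0
  }
  poly <- which(n_typed > 0 & he > 0)
  use <- if (length(poly)) poly else which(n_typed > 0)
  list(per_locus = data.frame(locus = G$locus_ids, n = n_typed,
                              H_O = ho, H_E = he),
       H_O = mean(ho[use]), H_E = mean(he[use]))
}

# Weir & Cockerham (1984) variance components per locus x allele.
# Returns matrix with columns a, b, c (one row per locus-allele term).
wc_components <- function(G, grouping, rows = seq_len(nrow(G$a1))) {
  grouping <- as.character(grouping)
  stopifnot(length(grouping) == nrow(G$a1))
  comp <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("a", "b", "c")))
  for (l in seq_along(G$locus_ids)) {
    a1 <- G$a1[rows, l]; a2 <- G$a2[rows, l]
    grp <- grouping[rows]
    ok <- !is.na(a1)
    if (!any(ok)) next
    a1 <- a1[ok]; a2 <- a2[ok]; grp <- grp[ok]
    alleles <- sort(unique(c(a1, a2)))
    if (length(alleles) < 2) next           # monomorphic overall: excluded
    units <- unique(grp)
    r <- length(units)
    n_i <- vapply(units, function(u) sum(grp == u), numeric(1))
    nbar <- mean(n_i)
    if (nbar <= 1) next
    n_c <- if (r > 1)
      (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1) else NA_real_
    for (al in alleles) {
      p_i <- vapply(units, function(u) {
        g <- grp == u
        (sum(a1[g] == al) + sum(a2[g] == al)) / (2 * sum(g))
      }, numeric(1))
      h_i <- vapply(units, function(u) {
        g <- grp == u
        mean((a1[g] == al) != (a2[g] == al))
      }, numeric(1))
      pbar <- sum(n_i * p_i) / (r * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      s2 <- if (r > 1) sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar) else 0
      frac <- if (r > 1) (r - 1) / r else 0
      a <- if (r > 1)
        (nbar / n_c) * (s2 - (pbar * (1 - pbar) - frac * s2 - hbar / 4) /
                          (nbar - 1)) else 0
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - frac * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      comp <- rbind(comp, c(a, b, cc))
    }
  }
  comp
}

#' Weir-Cockerham F-statistics
#'
#' Multilocus `F_ST = sum(a) / sum(a + b + c)` and
#' `F_IS = sum(b) / sum(b + c)` as ratios of summed variance components
#' over loci and alleles (Weir & Cockerham 1984). Loci monomorphic over
#' the whole analysis set are excluded. With a single unit `F_ST` is
#' undefined (NA, flagged) while `F_IS` is still estimated.
#'
#' @param G a [genotype_matrix()].
#' @param grouping unit label per individual (defaults to `site_id`).
#' @return list: `F_ST`, `F_IS`, `components` (summed a, b, c), `flags`.
#' @export
wc_f_statistics <- function(G, grouping = G$meta$site_id) {
  comp <- wc_components(G, grouping)
  if (nrow(comp) == 0)
    return(list(F_ST = NA_real_, F_IS = NA_real_,
                components = c(a = 0, b = 0, c = 0),
                flags = "no polymorphic locus"))
  s <- colSums(comp)
  single <- length(unique(as.character(grouping))) < 2
  fst <- if (single) NA_real_ else s["a"] / sum(s)
  fis <- s["b"] / (s["b"] + s["c"])
  list(F_ST = unname(fst), F_IS = unname(fis), components = s,
       flags = if (single) "single unit: F_ST undefined" else character(0))
}

#' Pairwise F_ST with permutation p-values
#'
#' Weir-Cockerham theta for every pair of units, with significance from
#' permuting individuals between the two units:
#' `p = (1 + #{theta_perm >= theta_obs}) / (n_perm + 1)`.
#'
#' @param G a [genotype_matrix()].
#' @param units unit label per individual (defaults to `site_id`).
#' @param n_perm permutations (>= 1).
#' @param seed integer seed.
#' @return list of symmetric matrices `theta` and `p`.
#' @export
pairwise_fst_permutation <- function(G, units = G$meta$site_id,
                                     n_perm = 999, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  set.seed(as.integer(seed))
  units <- as.character(units)
  lev <- unique(units)
  nu <- length(lev)
  theta <- p <- matrix(NA_real_, nu, nu, dimnames = list(lev, lev))
  diag(theta) <- 0; diag(p) <- NA
  for (i in seq_len(nu - 1)) for (j in (i + 1):nu) {
    rows <- which(units %in% c(lev[i], lev[j]))
    sub <- G[rows, ]
    grp <- units[rows]
    obs <- wc_f_statistics(sub, grp)$F_ST
    ge <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample(grp)
      tb <- wc_f_statistics(sub, perm)$F_ST
      if (!is.na(tb) && !is.na(obs) && tb >= obs) ge <- ge + 1L
    }
    theta[i, j] <- theta[j, i] <- obs
    p[i, j] <- p[j, i] <- (1 + ge) / (n_perm + 1)
  }
  list(theta = theta, p = p)
}

#' Heterozygote-deficit permutation test
#'
#' One-sided test of the multilocus `F_IS` against its null distribution
#' under random reassembly of gene copies into diploids within the unit
#' and locus (allele counts preserved):
#' `p = (1 + #{F_IS_perm >= F_IS_obs}) / (n_perm + 1)`.
#'
#' @param G a [genotype_matrix()].
#' @param unit rows of the unit (site id, logical or indices); default all.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @return list: `F_IS`, `p`, `flag` (non-empty when undefined, e.g. all
#'   loci monomorphic).
#' @export
hwe_deficit_test <- function(G, unit = seq_len(nrow(G$a1)),
                             n_perm = 9999, seed = 1L) {
  rows <- unit_rows(G, unit)
  sub <- G[rows, ]
  one <- rep("u", nrow(sub$a1))
  obs <- wc_f_statistics(sub, one)$F_IS
  if (is.na(obs) || !is.finite(obs))
    return(list(F_IS = obs, p = NA_real_, flag = "F_IS undefined"))
  set.seed(as.integer(seed))
  n <- nrow(sub$a1)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    pa1 <- sub$a1; pa2 <- sub$a2
    for (l in seq_along(sub$locus_ids)) {
      ok <- which(!is.na(sub$a1[, l]))
      if (length(ok) < 2) next
      copies <- sample(c(sub$a1[ok, l], sub$a2[ok, l]))
      m <- length(ok)
      x1 <- copies[seq_len(m)]; x2 <- copies[m + seq_len(m)]
      pa1[ok, l] <- pmin(x1, x2); pa2[ok, l] <- pmax(x1, x2)
    }
    perm <- sub
    perm$a1 <- pa1; perm$a2 <- pa2
    fb <- wc_f_statistics(perm, one)$F_IS
    if (!is.na(fb) && fb >= obs) ge <- ge + 1L
  }
  list(F_IS = obs, p = (1 + ge) / (n_perm + 1), flag = character(0))
}

#' Rarefied allelic richness A_R(g)
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies: `A_R(g) = sum_a [1 - C(N_g - N_a, g) / C(N_g, g)]` per locus,
#' averaged (unweighted) over loci with at least `g` typed gene copies in
#' the unit; loci below the threshold are flagged, not imputed.
#'
#' @param G a [genotype_matrix()].
#' @param unit rows of the unit; default all.
#' @param g standardized number of gene copies (>= 1; 2 reproduces the
#'   one-individual standardization).
#' @return list: `per_locus` (locus, N_g, A_R; NA when excluded),
#'   `mean` (over included loci), `excluded` (locus ids).
#' @export
rarefied_allelic_richness <- function(G, unit = seq_len(nrow(G$a1)), g = 2) {
  stopifnot(g >= 1)
  rows <- unit_rows(G, unit)
  counts <- allele_counts(G, rows)
  ar <- vapply(counts, function(tab) {
    Ng <- sum(tab)
    if (Ng < g) return(NA_real_)
    sum(1 - exp(lchoose(Ng - as.numeric(tab), g) - lchoose(Ng, g)))
  }, numeric(1))
  Ng <- vapply(counts, sum, numeric(1))
  excl <- G$locus_ids[is.na(ar)]
  list(per_locus = data.frame(locus = G$locus_ids, N_g = Ng, A_R = ar),
       mean = mean(ar, na.rm = TRUE), excluded = excl)
}

#' Rarefied private allelic richness A_P(g)
#'
#' With `Q_ja(g) = 1 - C(N_gj - N_aj, g) / C(N_gj, g)` the probability
#' that allele `a` appears in a size-`g` rarefied sample from unit `j`,
#' the private allelic richness of unit `j` is
#' `sum_a Q_ja(g) prod_{j' != j} (1 - Q_j'a(g))`, averaged over loci where
#' every unit has at least `g` typed gene copies.
#'
#' @param G a [genotype_matrix()].
#' @param units unit label per individual (defaults to `site_id`).
#' @param g standardized number of gene copies.
#' @return list: `per_unit` (named mean A_P per unit), `per_locus`
#'   (matrix loci x units), `excluded` (locus ids).
#' @export
private_allelic_richness <- function(G, units = G$meta$site_id, g = 2) {
  units <- as.character(units)
  lev <- unique(units)
  L <- length(G$locus_ids)
  ap <- matrix(NA_real_, L, length(lev), dimnames = list(G$locus_ids, lev))
  for (l in seq_len(L)) {
    tabs <- lapply(lev, function(u) {
      v <- c(G$a1[units == u, l], G$a2[units == u, l])
      table(factor(v[!is.na(v)]))
    })
    Ngs <- vapply(tabs, sum, numeric(1))
    if (any(Ngs < g)) next
    alleles <- sort(unique(unlist(lapply(tabs, names))))
    # Qm[j, a]: presence probability of allele a in unit j's rarefied sample
    Qm <- vapply(alleles, function(al) {
      vapply(seq_along(lev), function(j) {
        Na <- if (al %in% names(tabs[[j]])) as.numeric(tabs[[j]][[al]]) else 0
        1 - exp(lchoose(Ngs[j] - Na, g) - lchoose(Ngs[j], g))
      }, numeric(1))
    }, numeric(length(lev)))
    Qm <- matrix(Qm, nrow = length(lev))
    for (j in seq_along(lev)) {
      others <- apply((1 - Qm)[-j, , drop = FALSE], 2, prod)
      ap[l, j] <- sum(Qm[j, ] * others)
    }
  }
  excl <- G$locus_ids[apply(ap, 1, function(x) all(is.na(x)))]
  list(per_unit = colMeans(ap, na.rm = TRUE), per_locus = ap,
       excluded = excl)
}

#' Site filters for the diversity analyses
#'
#' Emits the two standard analysis sets: sites with at least
#' `min_individuals` genotyped individuals (diversity tables), and the
#' stricter subset in which every marker is typed in at least
#' `min_per_marker` individuals (richness maps). Exclusion reasons are
#' reported.
#'
#' @param G a [genotype_matrix()].
#' @param min_individuals site-size threshold (default 4).
#' @param min_per_marker per-marker typed-individual threshold (default 2).
#' @return list: `diversity_sites`, `map_sites` (character vectors),
#'   `excluded` (data.frame site, reason).
#' @export
site_filters <- function(G, min_individuals = 4, min_per_marker = 2) {
  sites <- unique(G$meta$site_id)
  reasons <- character(0); bad <- character(0)
  set1 <- character(0); set2 <- character(0)
  for (s in sites) {
    rows <- which(G$meta$site_id == s)
    if (length(rows) < min_individuals) {
      bad <- c(bad, s)
      reasons <- c(reasons, sprintf("only %d individuals", length(rows)))
      next
    }
    set1 <- c(set1, s)
    typed <- colSums(!is.na(G$a1[rows, , drop = FALSE]))
    if (all(typed >= min_per_marker)) {
      set2 <- c(set2, s)
    } else {
      bad <- c(bad, s)
      reasons <- c(reasons,
                   sprintf("marker(s) typed in < %d individuals",
                           min_per_marker))
    }
  }
  list(diversity_sites = set1, map_sites = set2,
       excluded = data.frame(site = bad, reason = reasons,
                             stringsAsFactors = FALSE))
}

#' Inverse-distance-weighted grid of a per-site statistic
#'
#' Minimal spatial export (in lieu of kriged maps): the value at each grid
#' node is the inverse-distance-squared weighted mean of the site values.
#'
#' @param site_values data.frame with `latitude`, `longitude`, `value`.
#' @param n_grid nodes per axis.
#' @param power inverse-distance exponent.
#' @return data.frame: latitude, longitude, value.
#' @export
idw_grid <- function(site_values, n_grid = 25, power = 2) {
  stopifnot(all(c("latitude", "longitude", "value") %in%
                  names(site_values)))
  la <- seq(min(site_values$latitude), max(site_values$latitude),
            length.out = n_grid)
  lo <- seq(min(site_values$longitude), max(site_values$longitude),
            length.out = n_grid)
  grid <- expand.grid(latitude = la, longitude = lo)
  d <- haversine_matrix(rbind(grid[, c("latitude", "longitude")],
                              site_values[, c("latitude", "longitude")]))
  d <- d[seq_len(nrow(grid)), nrow(grid) + seq_len(nrow(site_values)),
         drop = FALSE]
  w <- 1 / pmax(d, 1e-6)^power
  grid$value <- as.numeric(w %*% site_values$value / rowSums(w))
  grid
}
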