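# Pairwise Loiselle kinship, isolation-by-distance regression with
# permutation inference, and the Sp statistic.

#' Great-circle distance matrix
#'
#' Haversine distances in km (Earth radius 6371.0088 km) between rows of a
#' coordinate table.
#'
#' @param coords data.frame or matrix with columns `latitude` and
#'   `longitude` (degrees), or two unnamed columns in that order.
#' @return symmetric distance matrix (km), zero diagonal.
#' @export
haversine_matrix <- function(coords) {
  coords <- as.data.frame(coords)
  if (!all(c("latitude", "longitude") %in% names(coords)))
    names(coords)[1:2] <- c("latitude", "longitude")
  R <- 6371.0088
  lat <- coords$latitude * pi / 180
  lon <- coords$longitude * pi / 180
  n <- length(lat)
  dlat <- outer(lat, lat, `-`)
  dlon <- outer(lon, lon, `-`)
  h <- sin(dlat / 2)^2 +
    outer(cos(lat), cos(lat)) * sin(dlon / 2)^2
  h <- pmin(pmax(h, 0), 1)
  d <- 2 * R * asin(sqrt(h))
  diag(d) <- 0
  d
}

#' Loiselle/Nason pairwise kinship coefficients
#'
#' For reference allele frequencies `p_la` (computed over the supplied
#' analysis set) and half-dosages `x_ila` in {0, 1/2, 1}, the per-locus
#' numerator for a pair is
#' `sum_a (x_ila - p_la)(x_jla - p_la) + sum_a p_la (1 - p_la) / (n_l - 1)`
#' (small-sample bias correction with `n_l` the individuals typed at the
#' locus) and the denominator is `sum_a p_la (1 - p_la)`. The multilocus
#' `F_ij` is the ratio of sums over loci typed in both individuals. Pairs
#' sharing no typed locus are NA; the diagonal is NA (self-pairs are
#' excluded from all downstream regressions).
#'
#' @param G a [genotype_matrix()] holding the analysis set (reference
#'   frequencies are computed from it).
#' @return symmetric matrix of `F_ij` with NA diagonal.
#' @export
loiselle_kinship <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- nrow(G$a1)
  NUM <- matrix(0, n, n)
  DEN <- matrix(0, n, n)
  any_shared <- matrix(FALSE, n, n)
  informative <- FALSE
  for (l in seq_along(G$locus_ids)) {
    a1 <- G$a1[, l]; a2 <- G$a2[, l]
    typed <- !is.na(a1)
    n_l <- sum(typed)
    if (n_l < 2) next
    alleles <- sort(unique(c(a1[typed], a2[typed])))
    X <- matrix(0, n, length(alleles))
    for (j in seq_along(alleles))
      X[, j] <- ((a1 == alleles[j]) + (a2 == alleles[j])) / 2
    X[!typed, ] <- 0
    p <- colSums(X[typed, , drop = FALSE]) / n_l
    h <- sum(p * (1 - p))
    if (h <= 0) next                     # monomorphic at this locus
    informative <- TRUE
    Xc <- sweep(X, 2, p)
    Xc[!typed, ] <- 0
    C <- tcrossprod(Xc)
    M <- tcrossprod(as.numeric(typed))   # 1 when both typed
    NUM <- NUM + C + (h / (n_l - 1)) * M
    DEN <- DEN + h * M
    any_shared <- any_shared | (M > 0)
  }
  if (!informative)
    stop("all loci monomorphic: kinship undefined")
  Fij <- NUM / DEN
  Fij[!any_shared | DEN == 0] <- NA_real_
  diag(Fij) <- NA_real_
  dimnames(Fij) <- list(G$individual_ids, G$individual_ids)
  Fij
}

# Upper-triangle pair slope of F on ln d with the analysis restrictions.
ibd_slope <- function(Fv, ldv, ok) {
  x <- ldv[ok]; y <- Fv[ok]
  vx <- stats::var(x)
  if (!is.finite(vx) || vx == 0) return(c(b = NA_real_, r2 = NA_real_))
  b <- stats::cov(x, y) / vx
  vy <- stats::var(y)
  r2 <- if (is.finite(vy) && vy > 0) stats::cor(x, y)^2 else NA_real_
  c(b = b, r2 = r2)
}

#' Isolation-by-distance regression on kinship
#'
#' Ordinary least squares of pairwise kinship `F_ij` on `ln(d_ij)` over
#' retained pairs (`d > 0`, finite `F`, and `d <= max_d` when set), the
#' mean kinship in the first distance class `F_1` (pairs with
#' `d <= first_class_edge`), and a permutation test in which individual
#' spatial positions are permuted among individuals and the slope
#' recomputed; two-sided
#' `p = (1 + #{|b_perm| >= |b_obs|}) / (n_perm + 1)`.
#'
#' @param F_mat symmetric kinship matrix (see [loiselle_kinship()]).
#' @param d_mat symmetric distance matrix, km.
#' @param max_d optional distance cap (e.g. 10 for the 10 km restricted
#'   slope `b_Ld`).
#' @param first_class_edge edge of the first distance class (km) defining
#'   `F_1`.
#' @param n_perm permutations (0 skips the test, p = NA).
#' @param seed integer seed.
#' @return list: `b`, `F_1` (NA + flag when the first class is empty),
#'   `r2`, `p`, `n_pairs`, `flag`.
#' @export
kinship_ibd_regression <- function(F_mat, d_mat, max_d = NULL,
                                   first_class_edge = 1.0, n_perm = 9999,
                                   seed = 1L) {
  F_mat <- as.matrix(F_mat); d_mat <- as.matrix(d_mat)
  stopifnot(identical(dim(F_mat), dim(d_mat)))
  n <- nrow(F_mat)
  ut <- upper.tri(F_mat)
  Fv <- F_mat[ut]; dv <- d_mat[ut]
  keep <- function(dvec) {
    ok <- dvec > 0 & is.finite(Fv)
    if (!is.null(max_d)) ok <- ok & dvec <= max_d
    ok
  }
  ok <- keep(dv)
  if (sum(ok) < 3) stop("fewer than 3 retained pairs")
  ldv <- log(dv)
  fit <- ibd_slope(Fv, ldv, ok)
  fc <- dv > 0 & dv <= first_class_edge & is.finite(Fv)
  flag <- character(0)
  F_1 <- if (any(fc)) mean(Fv[fc]) else {
    flag <- "no pair in first distance class"
    NA_real_
  }
  p <- NA_real_
  if (n_perm > 0) {
    set.seed(as.integer(seed))
    b_obs <- abs(fit[["b"]])
    ge <- 0L
    ld_full <- log(d_mat)
    for (bb in seq_len(n_perm)) {
      perm <- sample.int(n)
      dp <- d_mat[perm, perm][ut]
      okp <- keep(dp)
      if (sum(okp) < 3) next
      bp <- ibd_slope(Fv, log(dp), okp)[["b"]]
      if (!is.na(bp) && abs(bp) >= b_obs) ge <- ge + 1L
    }
    p <- (1 + ge) / (n_perm + 1)
  }
  list(b = unname(fit[["b"]]), F_1 = F_1, r2 = unname(fit[["r2"]]),
       p = p, n_pairs = sum(ok), flag = flag)
}

#' Sp statistic
#'
#' `Sp = -b_Ld / (1 - F_N)`: the distance-restricted regression slope of
#' kinship on ln distance, standardized by the mean kinship between
#' neighboring individuals (approximated by the first-distance-class mean
#' `F_1`). Larger Sp means stronger fine-scale spatial genetic structure.
#'
#' @param b_Ld regression slope (typically restricted to d <= 10 km).
#' @param F_N mean kinship in the first distance class (must be < 1).
#' @return scalar Sp.
#' @export
sp_statistic <- function(b_Ld, F_N) {
  if (!is.finite(F_N) || F_N >= 1) stop("F_N must be finite and < 1")
  -b_Ld / (1 - F_N)
}

#' Full spatial-genetic-structure analysis of one population
#'
#' Computes Loiselle kinship from the genotypes, great-circle distances
#' from the metadata coordinates, the overall and distance-restricted
#' isolation-by-distance slopes, `F_1`, the permutation p-value for the
#' overall slope, and Sp. When no pair falls within `max_d`, Sp falls back
#' to the overall slope (flagged).
#'
#' @param G a [genotype_matrix()] with coordinates in its metadata.
#' @param max_d restricted-slope distance cap (km), default 10.
#' @param first_class_edge first distance class edge (km), default 1.
#' @param n_perm permutations for the slope test.
#' @param seed integer seed.
#' @return list: `b`, `b_Ld`, `F_1`, `r2`, `p`, `Sp`, `n`, `flag`.
#' @export
sgs_analysis <- function(G, max_d = 10, first_class_edge = 1.0,
                         n_perm = 9999, seed = 1L) {
  if (anyNA(G$meta$latitude) || anyNA(G$meta$longitude))
    stop("all individuals need coordinates")
  Fij <- loiselle_kinship(G)
  d <- haversine_matrix(G$meta[, c("latitude", "longitude")])
  overall <- kinship_ibd_regression(Fij, d, max_d = NULL,
                                    first_class_edge = first_class_edge,
                                    n_perm = n_perm, seed = seed)
  flag <- overall$flag
  restricted <- tryCatch(
    kinship_ibd_regression(Fij, d, max_d = max_d,
                           first_class_edge = first_class_edge,
                           n_perm = 0),
    error = function(e) NULL)
  if (is.null(restricted)) {
    flag <- c(flag, sprintf("no pairs within %g km: Sp uses overall b",
                            max_d))
    b_Ld <- overall$b
  } else {
    b_Ld <- restricted$b
  }
  Sp <- if (is.finite(overall$F_1) && overall$F_1 < 1)
    sp_statistic(b_Ld, overall$F_1) else NA_real_
  list(b = overall$b, b_Ld = b_Ld, F_1 = overall$F_1, r2 = overall$r2,
       p = overall$p, Sp = Sp, n = nrow(G$a1), flag = flag)
}
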