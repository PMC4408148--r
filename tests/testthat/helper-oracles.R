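# Independent oracle implementations, deliberately coded via different
# routes than the package functions they check.

# Build a genotype_matrix from a plain list of per-individual calls:
# calls[[i]] is a 2 x L matrix (rows = the two alleles).
gm_from_calls <- function(calls, sites = NULL, loci = NULL, meta = NULL) {
  n <- length(calls)
  L <- ncol(calls[[1]])
  a1 <- matrix(unlist(lapply(calls, function(m) pmin(m[1, ], m[2, ]))),
               nrow = n, ncol = L, byrow = TRUE)
  a2 <- matrix(unlist(lapply(calls, function(m) pmax(m[1, ], m[2, ]))),
               nrow = n, ncol = L, byrow = TRUE)
  ids <- sprintf("i%02d", seq_len(n))
  if (is.null(loci)) loci <- sprintf("L%02d", seq_len(L))
  if (is.null(meta) && !is.null(sites))
    meta <- data.frame(id = ids, site_id = sites)
  crabflow::genotype_matrix(a1, a2, ids, loci, meta)
}

# Weir-Cockerham theta via the nested ANOVA mean-squares route (gene-copy
# indicators, individuals nested in populations), independent of the
# package's direct variance-component formulas.
oracle_wc <- function(G, grouping) {
  grouping <- as.character(grouping)
  num_a <- num_b <- num_c <- 0
  for (l in seq_along(G$locus_ids)) {
    a1 <- G$a1[, l]; a2 <- G$a2[, l]
    ok <- !is.na(a1)
    if (sum(ok) == 0) next
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    if (length(alleles) < 2) next
    grp <- grouping[ok]
    x1 <- a1[ok]; x2 <- a2[ok]
    pops <- unique(grp)
    r <- length(pops)
    n_i <- sapply(pops, function(p) sum(grp == p))
    N <- sum(n_i)
    n_c <- if (r > 1) (N - sum(n_i^2) / N) / (r - 1) else NA
    for (al in alleles) {
      u <- cbind(as.numeric(x1 == al), as.numeric(x2 == al))
      ubar_ind <- rowMeans(u)
      ubar_pop <- sapply(pops, function(p) mean(u[grp == p, ]))
      ubar <- mean(u)
      SSP <- sum(2 * n_i * (ubar_pop - ubar)^2)
      SSI <- sum(2 * (ubar_ind - ubar_pop[match(grp, pops)])^2)
      SSG <- sum((u - ubar_ind)^2)
      MSI <- SSI / (N - r)
      MSG <- SSG / N
      if (r > 1) {
        MSP <- SSP / (r - 1)
        num_a <- num_a + (MSP - MSI) / (2 * n_c)
      }
      num_b <- num_b + (MSI - MSG) / 2
      num_c <- num_c + MSG
    }
  }
  list(F_ST = num_a / (num_a + num_b + num_c),
       F_IS = num_b / (num_b + num_c))
}

# Loiselle kinship for one pair, single-pass textbook implementation.
oracle_loiselle_pair <- function(G, i, j) {
  num <- den <- 0
  for (l in seq_along(G$locus_ids)) {
    if (is.na(G$a1[i, l]) || is.na(G$a1[j, l])) next
    typed <- which(!is.na(G$a1[, l]))
    n_l <- length(typed)
    copies <- c(G$a1[typed, l], G$a2[typed, l])
    alleles <- sort(unique(copies))
    if (length(alleles) < 2) next
    for (al in alleles) {
      p <- mean(copies == al)
      xi <- (sum(G$a1[i, l] == al) + sum(G$a2[i, l] == al)) / 2
      xj <- (sum(G$a1[j, l] == al) + sum(G$a2[j, l] == al)) / 2
      num <- num + (xi - p) * (xj - p) + p * (1 - p) / (n_l - 1)
      den <- den + p * (1 - p)
    }
  }
  num / den
}

# Exhaustive rarefaction oracle: mean number of distinct alleles over all
# C(N_g, g) subsamples of the gene-copy multiset at one locus.
oracle_rarefied_richness <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
}

# Exhaustive private-richness oracle for 2 units: expected number of
# alleles present in unit j's rarefied sample and absent from the other
# unit's rarefied sample, by double enumeration.
oracle_private_richness_2u <- function(counts_j, counts_o, g) {
  cj <- rep(as.integer(names(counts_j)), counts_j)
  co <- rep(as.integer(names(counts_o)), counts_o)
  sj <- utils::combn(length(cj), g)
  so <- utils::combn(length(co), g)
  tot <- 0
  for (u in seq_len(ncol(sj))) {
    aj <- unique(cj[sj[, u]])
    for (v in seq_len(ncol(so))) {
      tot <- tot + length(setdiff(aj, co[so[, v]]))
    }
  }
  tot / (ncol(sj) * ncol(so))
}

# Small fixed-difference two-population genotype set: pop A fixed for
# allele 1, pop B fixed for allele 2 at every locus.
fixed_difference_gm <- function(n_per_pop = 5, n_loci = 10) {
  calls <- c(
    replicate(n_per_pop, matrix(1, 2, n_loci), simplify = FALSE),
    replicate(n_per_pop, matrix(2, 2, n_loci), simplify = FALSE))
  gm_from_calls(calls, sites = rep(c("A", "B"), each = n_per_pop))
}
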