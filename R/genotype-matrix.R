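# Core container: diploid multilocus genotypes plus per-individual metadata.

#' Construct a genotype matrix
#'
#' The central container of the package: unordered diploid allele-code pairs
#' for each (individual, locus) cell, together with per-individual metadata
#' (sampling site, a-priori species label, coordinates). Allele codes are
#' positive integers (microsatellite repeat sizes or arbitrary labels); 0 is
#' reserved for missing data in the GENEPOP dialect and never stored. Call
#' pairs are order-normalized so that `allele1 <= allele2`.
#'
#' @param allele1,allele2 integer matrices, individuals x loci; `NA` in both
#'   marks a missing call. Missingness must affect both gene copies jointly.
#' @param individual_ids unique character vector, one per row.
#' @param locus_ids unique character vector, one per column.
#' @param meta optional data.frame with columns `id`, `site_id`,
#'   `species_label` (one of `"wild"`, `"crop"`, `"unknown"`), `latitude`,
#'   `longitude`. Rows are matched to `individual_ids`; absent individuals
#'   get `species_label = "unknown"` and `NA` elsewhere.
#' @return an object of class `genotype_matrix` with elements `a1`, `a2`
#'   (normalized allele matrices), `individual_ids`, `locus_ids`, `meta`.
#' @export
genotype_matrix <- function(allele1, allele2, individual_ids, locus_ids,
                            meta = NULL) {
  allele1 <- as.matrix(allele1)
  allele2 <- as.matrix(allele2)
  storage.mode(allele1) <- "integer"
  storage.mode(allele2) <- "integer"
  if (!identical(dim(allele1), dim(allele2)))
    stop("allele1 and allele2 must have identical dimensions")
  if (nrow(allele1) != length(individual_ids))
    stop("individual_ids length must equal number of rows")
  if (ncol(allele1) != length(locus_ids))
    stop("locus_ids length must equal number of columns")
  if (anyDuplicated(individual_ids))
    stop("duplicate individual ids")
  if (anyDuplicated(locus_ids))
    stop("duplicate locus ids")
  if (any(xor(is.na(allele1), is.na(allele2))))
    stop("missingness must be per diploid call: both alleles NA or neither")
  if (any(allele1 < 1L, na.rm = TRUE) || any(allele2 < 1L, na.rm = TRUE))
    stop("allele codes must be >= 1 (0 is the GENEPOP missing sentinel)")
  # order-normalize each call pair
  lo <- pmin(allele1, allele2)
  hi <- pmax(allele1, allele2)
  dimnames(lo) <- dimnames(hi) <- list(individual_ids, locus_ids)
  meta <- normalize_meta(meta, individual_ids)
  structure(
    list(a1 = lo, a2 = hi,
         individual_ids = as.character(individual_ids),
         locus_ids = as.character(locus_ids),
         meta = meta),
    class = "genotype_matrix")
}

normalize_meta <- function(meta, individual_ids) {
  n <- length(individual_ids)
  base <- data.frame(id = as.character(individual_ids),
                     site_id = rep(NA_character_, n),
                     species_label = rep("unknown", n),
                     latitude = rep(NA_real_, n),
                     longitude = rep(NA_real_, n),
                     stringsAsFactors = FALSE)
  if (is.null(meta)) return(base)
  meta <- as.data.frame(meta)
  if (!"id" %in% names(meta)) stop("meta must have an 'id' column")
  if (anyDuplicated(meta$id)) stop("duplicate ids in metadata")
  for (col in c("site_id", "species_label", "latitude", "longitude"))
    if (!col %in% names(meta)) meta[[col]] <- base[[col]][1]
  bad <- !meta$species_label %in% c("wild", "crop", "unknown") &
    !is.na(meta$species_label)
  if (any(bad))
    stop("species_label must be one of wild/crop/unknown")
  if (any(abs(meta$latitude) > 90, na.rm = TRUE))
    stop("latitude out of range [-90, 90]")
  if (any(abs(meta$longitude) > 180, na.rm = TRUE))
    stop("longitude out of range [-180, 180]")
  j <- match(base$id, as.character(meta$id))
  for (col in c("site_id", "species_label", "latitude", "longitude")) {
    v <- meta[[col]][j]
    base[[col]][!is.na(j)] <- v[!is.na(j)]
  }
  base$species_label[is.na(base$species_label)] <- "unknown"
  base
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci\n",
              nrow(x$a1), ncol(x$a1)))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * mean(is.na(x$a1))))
  tab <- table(x$meta$species_label)
  cat("  species labels:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$a1)

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param i individual index (logical, integer or id character vector).
#' @param j locus index.
#' @param ... unused.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$individual_ids)
  if (missing(j)) j <- seq_along(x$locus_ids)
  if (is.character(i)) i <- match(i, x$individual_ids)
  if (is.character(j)) j <- match(j, x$locus_ids)
  ids <- x$individual_ids[i]
  genotype_matrix(x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE],
                  ids, x$locus_ids[j],
                  x$meta[match(ids, x$meta$id), , drop = FALSE])
}

#' Per-individual missing-call fraction
#'
#' @param G a `genotype_matrix`.
#' @return named numeric vector, fraction of loci with a missing call.
#' @export
missing_fraction <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  rowMeans(is.na(G$a1))
}

# Internal: recode allele values to compact 1..A_l factor levels per locus.
# Returns list(codes = n x 2L integer matrix (locus-major pairs), n_alleles,
# levels = list of original codes per locus).
locus_index_encoding <- function(G) {
  L <- length(G$locus_ids)
  n <- length(G$individual_ids)
  codes <- matrix(NA_integer_, n, 2L * L)
  n_alleles <- integer(L)
  levels <- vector("list", L)
  for (l in seq_len(L)) {
    obs <- sort(unique(c(G$a1[, l], G$a2[, l])))
    obs <- obs[!is.na(obs)]
    levels[[l]] <- obs
    n_alleles[l] <- length(obs)
    codes[, 2L * l - 1L] <- match(G$a1[, l], obs)
    codes[, 2L * l] <- match(G$a2[, l], obs)
  }
  list(codes = codes, n_alleles = n_alleles, levels = levels)
}

# Internal: per-locus allele count tables for a subset of individuals.
# Returns list per locus: named integer vector of allele-copy counts.
allele_counts <- function(G, rows = seq_len(nrow(G$a1))) {
  lapply(seq_along(G$locus_ids), function(l) {
    v <- c(G$a1[rows, l], G$a2[rows, l])
    v <- v[!is.na(v)]
    table(factor(v))
  })
}
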