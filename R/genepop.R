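# GENEPOP text I/O, metadata joins and the missingness filter.

#' Read a GENEPOP file
#'
#' Parses the classic GENEPOP layout: a title line, locus names (either one
#' per line or a single comma-separated line), then `POP` blocks of
#' individuals written as `name , a1a2 a1a2 ...` with a fixed 2- or 3-digit
#' allele encoding. `00`/`000` encodes a missing allele; a call with either
#' allele missing is treated as a fully missing diploid call. The POP block
#' index (`pop1`, `pop2`, ...) is recorded as `site_id` unless metadata
#' attached later overrides it.
#'
#' @param path path to a GENEPOP text file.
#' @return a [genotype_matrix()].
#' @seealso [write_genepop()], [read_metadata()]
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("GENEPOP file too short: ", path)
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no POP line found in ", path)
  if (first_pop < 3) stop("POP before any locus names (line ", first_pop, ")")
  header <- lines[2:(first_pop - 1)]
  if (length(header) == 1 && grepl(",", header)) {
    loci <- trimws(strsplit(header, ",")[[1]])
  } else {
    loci <- trimws(header)
  }
  loci <- loci[nzchar(loci)]
  L <- length(loci)
  if (L == 0) stop("no locus names in header")

  ids <- character(0); sites <- character(0)
  rows1 <- list(); rows2 <- list()
  width <- NA_integer_
  pop_i <- 0L
  pop_size <- 0L
  for (ln in seq(first_pop, length(lines))) {
    line <- lines[ln]
    if (toupper(trimws(line)) == "POP") {
      if (pop_i > 0L && pop_size == 0L)
        stop("empty POP block ending at line ", ln)
      pop_i <- pop_i + 1L
      pop_size <- 0L
      next
    }
    if (!nzchar(trimws(line))) next
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2)
      stop("line ", ln, ": expected 'name , genotypes'")
    nm <- trimws(parts[1])
    gts <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
    gts <- gts[nzchar(gts)]
    if (length(gts) != L)
      stop("line ", ln, ": ", length(gts), " genotype fields for ",
           L, " loci")
    w <- unique(nchar(gts)) / 2
    if (length(w) != 1 || !w %in% c(2, 3))
      stop("line ", ln, ": mixed or unsupported allele digit widths")
    if (is.na(width)) width <- as.integer(w)
    if (w != width)
      stop("line ", ln, ": digit width ", w,
           " conflicts with earlier width ", width)
    a1 <- as.integer(substr(gts, 1, width))
    a2 <- as.integer(substr(gts, width + 1, 2 * width))
    miss <- a1 == 0L | a2 == 0L
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    ids <- c(ids, nm)
    sites <- c(sites, paste0("pop", pop_i))
    rows1[[length(rows1) + 1L]] <- a1
    rows2[[length(rows2) + 1L]] <- a2
    pop_size <- pop_size + 1L
  }
  if (pop_size == 0L) stop("empty trailing POP block")
  if (length(ids) == 0) stop("no individuals in ", path)
  if (anyDuplicated(ids))
    ids <- make.unique(ids, sep = "_")
  meta <- data.frame(id = ids, site_id = sites, stringsAsFactors = FALSE)
  genotype_matrix(do.call(rbind, rows1), do.call(rbind, rows2),
                  ids, loci, meta)
}

#' Write a GENEPOP file
#'
#' Emits newline-separated locus names and individuals in input order,
#' opening a new `POP` block whenever the `site_id` changes from the
#' previous row (so a site-sorted matrix yields one block per site).
#' Missing calls are encoded as zeros.
#'
#' @param G a [genotype_matrix()].
#' @param path output path.
#' @param digit_width 2 or 3 digits per allele; all codes must be
#'   `< 10^digit_width`.
#' @param title title line (first line of the file).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(G, path, digit_width = 3,
                          title = "crabflow genotypes") {
  stopifnot(inherits(G, "genotype_matrix"), digit_width %in% c(2, 3))
  lim <- 10^digit_width
  over <- which(apply(G$a2, 2, function(v) any(v >= lim, na.rm = TRUE)))
  if (length(over))
    stop("allele code >= 10^", digit_width, " at locus ",
         paste(G$locus_ids[over], collapse = ", "))
  fmt <- function(m) {
    m[is.na(m)] <- 0L
    matrix(formatC(m, width = digit_width, flag = "0"), nrow = nrow(m))
  }
  s1 <- fmt(G$a1); s2 <- fmt(G$a2)
  calls <- matrix(paste0(s1, s2), nrow = nrow(s1))
  site <- G$meta$site_id
  site[is.na(site)] <- "__nosite__"
  out <- c(title, G$locus_ids)
  prev <- NULL
  for (i in seq_along(G$individual_ids)) {
    if (is.null(prev) || site[i] != prev) {
      out <- c(out, "POP")
      prev <- site[i]
    }
    out <- c(out, paste0(G$individual_ids[i], " , ",
                         paste(calls[i, ], collapse = " ")))
  }
  if (length(G$individual_ids) == 0) out <- c(out, "POP")
  writeLines(out, path)
  invisible(path)
}

#' Attach individual metadata from a CSV file
#'
#' Left-joins a metadata table (columns `id`, `site_id`, `species_label`,
#' `latitude`, `longitude`; extra columns ignored) onto the individuals of a
#' genotype matrix. Genotyped individuals absent from the CSV keep
#' `species_label = "unknown"` and trigger one warning. Coordinates are
#' validated.
#'
#' @param G a [genotype_matrix()].
#' @param path CSV file with a header row, or a data.frame.
#' @return `G` with updated `meta`.
#' @export
read_metadata <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  meta <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  if (anyDuplicated(meta$id))
    stop("duplicate ids in metadata: ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "))
  unmatched <- setdiff(G$individual_ids, as.character(meta$id))
  if (length(unmatched))
    warning(length(unmatched),
            " genotyped individual(s) not in metadata; labelled 'unknown'")
  G$meta <- normalize_meta(meta, G$individual_ids)
  G
}

#' Remove individuals with too many missing calls
#'
#' Individuals are retained when their missing-call fraction is strictly
#' below `max_missing` (the "<20% missing" retention rule); loci are never
#' removed. Idempotent.
#'
#' @param G a [genotype_matrix()].
#' @param max_missing strict upper bound on the per-individual missing
#'   fraction; default 0.20.
#' @return the filtered `genotype_matrix`, with the removed ids in
#'   attribute `"removed"`.
#' @export
filter_missingness <- function(G, max_missing = 0.20) {
  stopifnot(inherits(G, "genotype_matrix"), max_missing >= 0)
  mf <- missing_fraction(G)
  keep <- mf < max_missing | (max_missing >= 1 & mf <= 1)
  out <- G[which(keep), ]
  attr(out, "removed") <- G$individual_ids[!keep]
  out
}
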