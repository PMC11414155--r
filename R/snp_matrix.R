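#' Construct a biallelic SNP genotype matrix
#'
#' Holds haploid biallelic genotypes (`0`, `1` or `NA` for missing) for a set
#' of isolates at a set of loci, together with per-genotype read depth and the
#' fraction of reads supporting the called allele. Loci may optionally carry
#' genomic coordinates (contig plus 0-based half-open interval), which the
#' region-exclusion filter uses.
#'
#' @param isolate_ids Unique isolate labels (rows).
#' @param locus_ids Unique locus labels (columns).
#' @param allele Integer matrix of 0/1/NA, `length(isolate_ids)` x
#'   `length(locus_ids)`.
#' @param depth Optional integer matrix of read depths (same shape); `NULL`
#'   when the source format carries no depth (e.g. genepop).
#' @param support Optional numeric matrix in `[0, 1]` of read-support
#'   fractions; `NULL` when absent.
#' @param loci Optional data frame with columns `locus_id`, `contig`,
#'   `start`, `end` (0-based half-open) giving coordinates.
#' @return An object of class `snp_matrix`.
#' @export
snp_matrix <- function(isolate_ids, locus_ids, allele, depth = NULL,
                       support = NULL, loci = NULL) {
  isolate_ids <- as.character(isolate_ids)
  locus_ids <- as.character(locus_ids)
  if (anyDuplicated(isolate_ids)) stop("duplicate isolate ids")
  if (anyDuplicated(locus_ids)) stop("duplicate locus ids")
  allele <- as.matrix(allele)
  storage.mode(allele) <- "integer"
  if (!all(dim(allele) == c(length(isolate_ids), length(locus_ids)))) {
    stop("allele matrix dimensions do not match id lists")
  }
  if (!all(allele %in% c(0L, 1L, NA_integer_))) stop("alleles must be 0, 1 or NA")
  dimnames(allele) <- list(isolate_ids, locus_ids)
  check_shape <- function(m, what) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (!all(dim(m) == dim(allele))) stop(what, " matrix shape mismatch")
    dimnames(m) <- dimnames(allele)
    m
  }
  depth <- check_shape(depth, "depth")
  support <- check_shape(support, "support")
  if (!is.null(support) && any(support < 0 | support > 1, na.rm = TRUE)) {
    stop("support fractions must lie in [0, 1]")
  }
  if (!is.null(loci)) {
    loci <- as.data.frame(loci)
    stopifnot(all(c("locus_id", "contig", "start", "end") %in% names(loci)))
    loci <- loci[match(locus_ids, loci$locus_id), , drop = FALSE]
    if (anyNA(loci$locus_id)) stop("loci table must cover every locus id")
    bad <- !is.na(loci$start) & !is.na(loci$end) & loci$start >= loci$end
    if (any(bad)) stop("locus coordinates must satisfy start < end")
    rownames(loci) <- NULL
  }
  structure(
    list(isolate_ids = isolate_ids, locus_ids = locus_ids, allele = allele,
         depth = depth, support = support, loci = loci),
    class = "snp_matrix"
  )
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf(
    "snp_matrix: %d isolates x %d loci (%.1f%% missing)%s\n",
    length(x$isolate_ids), length(x$locus_ids),
    100 * mean(is.na(x$allele)),
    if (is.null(x$depth)) ", no depth/support metadata" else ""
  ))
  invisible(x)
}

#' @export
dim.snp_matrix <- function(x) dim(x$allele)

#' Read a SNP genotype matrix
#'
#' Two dialects are supported. The `tsv` dialect is native to this package:
#' a header row of locus ids (first column `isolate_id`), one row per isolate,
#' each cell `allele:depth:support` or `.` for missing. A locus id of the form
#' `name@contig:start-end` carries 0-based half-open coordinates. The
#' `genepop` dialect reads allele codes only (codes `01`/`02` or `001`/`002`;
#' `00` missing); depth and support are then absent and depth/support filters
#' down-stream become no-ops with a warning.
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"genepop"`.
#' @return A `snp_matrix`.
#' @export
read_snp_matrix <- function(path, dialect = c("tsv", "genepop")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") read_snp_tsv(path) else read_snp_genepop(path)
}

parse_locus_header <- function(locus_ids) {
  has_coord <- grepl("@.+:[0-9]+-[0-9]+$", locus_ids)
  if (!any(has_coord)) return(list(ids = locus_ids, loci = NULL))
  ids <- sub("@.*$", "", locus_ids)
  loci <- data.frame(locus_id = ids, contig = NA_character_,
                     start = NA_integer_, end = NA_integer_)
  coord <- sub("^[^@]*@", "", locus_ids[has_coord])
  loci$contig[has_coord] <- sub(":.*$", "", coord)
  span <- sub("^.*:", "", coord)
  loci$start[has_coord] <- as.integer(sub("-.*$", "", span))
  loci$end[has_coord] <- as.integer(sub("^.*-", "", span))
  list(ids = ids, loci = loci)
}

read_snp_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("SNP TSV needs a header and at least one isolate row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  n_col <- length(header)
  hdr <- parse_locus_header(header[-1])
  n_loc <- n_col - 1L
  rows <- fields[-1]
  n_iso <- length(rows)
  allele <- matrix(NA_integer_, n_iso, n_loc)
  depth <- matrix(NA_integer_, n_iso, n_loc)
  support <- matrix(NA_real_, n_iso, n_loc)
  isolate_ids <- character(n_iso)
  for (i in seq_len(n_iso)) {
    r <- rows[[i]]
    if (length(r) != n_col) {
      stop("row ", i + 1L, ": expected ", n_col, " columns, found ", length(r))
    }
    isolate_ids[i] <- r[1]
    cells <- r[-1]
    filled <- cells != "."
    if (any(filled)) {
      parts <- strsplit(cells[filled], ":", fixed = TRUE)
      if (any(lengths(parts) != 3L)) {
        stop("row ", i + 1L, ": cells must be 'allele:depth:support' or '.'")
      }
      pm <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
      allele[i, filled] <- as.integer(pm[, 1])
      depth[i, filled] <- as.integer(pm[, 2])
      support[i, filled] <- as.numeric(pm[, 3])
    }
  }
  snp_matrix(isolate_ids, hdr$ids, allele, depth, support, loci = hdr$loci)
}

read_snp_genepop <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3L) stop("genepop file too short")
  body <- lines[-1]  # drop title line
  pop_idx <- which(toupper(body) == "POP")
  if (length(pop_idx) == 0L) stop("genepop file lacks a 'Pop' line")
  locus_lines <- body[seq_len(pop_idx[1] - 1L)]
  locus_ids <- unlist(strsplit(locus_lines, ",", fixed = TRUE))
  locus_ids <- trimws(locus_ids)
  locus_ids <- locus_ids[nzchar(locus_ids)]
  ind_lines <- body[-seq_len(pop_idx[1])]
  ind_lines <- ind_lines[toupper(ind_lines) != "POP"]
  n_iso <- length(ind_lines)
  n_loc <- length(locus_ids)
  allele <- matrix(NA_integer_, n_iso, n_loc)
  isolate_ids <- character(n_iso)
  for (i in seq_len(n_iso)) {
    parts <- strsplit(ind_lines[i], ",", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("genepop individual line ", i, " lacks a single comma")
    isolate_ids[i] <- trimws(parts[1])
    codes <- strsplit(trimws(parts[2]), "[[:space:]]+")[[1]]
    if (length(codes) != n_loc) {
      stop("genepop row ", i, ": ", length(codes), " genotypes for ", n_loc, " loci")
    }
    num <- suppressWarnings(as.integer(codes))
    if (anyNA(num)) stop("genepop row ", i, ": non-numeric allele code")
    if (any(num > 2L)) stop("genepop row ", i, ": allele code > 2; matrix is not biallelic")
    allele[i, ] <- ifelse(num == 0L, NA_integer_, num - 1L)
  }
  snp_matrix(isolate_ids, locus_ids, allele)
}

#' Write a SNP matrix in the package's TSV dialect
#' @param m A `snp_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_snp_matrix <- function(m, path) {
  ids <- m$locus_ids
  if (!is.null(m$loci)) {
    has <- !is.na(m$loci$contig)
    ids[has] <- sprintf("%s@%s:%d-%d", ids[has], m$loci$contig[has],
                        m$loci$start[has], m$loci$end[has])
  }
  n_iso <- length(m$isolate_ids)
  n_loc <- length(m$locus_ids)
  cells <- matrix(".", n_iso, n_loc)
  filled <- !is.na(m$allele)
  dep <- if (is.null(m$depth)) matrix(0L, n_iso, n_loc) else m$depth
  sup <- if (is.null(m$support)) matrix(0, n_iso, n_loc) else m$support
  cells[filled] <- sprintf("%d:%d:%s", m$allele[filled], dep[filled],
                           format(sup[filled], digits = 10, trim = TRUE, scientific = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("isolate_id", ids), collapse = "\t"), con)
  for (i in seq_len(n_iso)) {
    writeLines(paste(c(m$isolate_ids[i], cells[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}
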