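#' Transition/transversion pair counts between two aligned sequences
#'
#' Columns with `-` or `N` in either sequence are excluded (pairwise
#' deletion). Transitions are `A<->G` and `C<->T`; every other mismatch is a
#' transversion. The G+C fraction `theta` is pooled over both sequences at
#' the usable columns.
#'
#' @param a,b Aligned nucleotide sequences of equal length.
#' @return List with `usable_sites`, `P_count` (transitions), `Q_count`
#'   (transversions) and `gc_fraction`.
#' @export
pair_counts <- function(a, b) {
  va <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  vb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  if (length(va) != length(vb)) stop("sequences differ in length")
  ok <- va %in% gc_bases & vb %in% gc_bases
  if (!any(ok)) stop("no comparable sites between the two sequences")
  va <- va[ok]; vb <- vb[ok]
  diff <- va != vb
  ts <- diff & ((va == "A" & vb == "G") | (va == "G" & vb == "A") |
                  (va == "C" & vb == "T") | (va == "T" & vb == "C"))
  gc <- (sum(va %in% c("G", "C")) + sum(vb %in% c("G", "C"))) / (2 * sum(ok))
  list(usable_sites = sum(ok), P_count = sum(ts), Q_count = sum(diff & !ts),
       gc_fraction = gc)
}

tamura3p_from_counts <- function(P, Q, theta, labels = c("a", "b")) {
  if (P == 0 && Q == 0) return(0)
  h <- 2 * theta * (1 - theta)
  arg1 <- 1 - P / h - Q  # h = 0 with P > 0 yields -Inf, caught below
  arg2 <- 1 - 2 * Q
  if (!is.finite(arg1) || arg1 <= 0 || arg2 <= 0) {
    stop("saturated pair (", labels[1], ", ", labels[2],
         "): Tamura 3-parameter distance undefined")
  }
  -h * log(arg1) - 0.5 * (1 - h) * log(arg2)
}

#' Tamura 3-parameter distance between two aligned sequences
#'
#' `d = -h log(1 - P/h - Q) - (1/2)(1 - h) log(1 - 2Q)` with
#' `h = 2 theta (1 - theta)`, where `P` and `Q` are the transition and
#' transversion proportions at usable sites and `theta` the pooled G+C
#' fraction of the pair. Corrects for transition/transversion bias and G+C
#' content.
#'
#' @param a,b Aligned nucleotide sequences of equal length.
#' @return Distance in substitutions per site.
#' @export
tamura3p <- function(a, b) {
  pc <- pair_counts(a, b)
  tamura3p_from_counts(pc$P_count / pc$usable_sites,
                       pc$Q_count / pc$usable_sites,
                       pc$gc_fraction)
}

#' Pairwise distance matrix of an alignment
#'
#' @param aln A `locus_alignment` with at least 2 sequences.
#' @param model `"tamura3p"` or `"p_distance"` (proportion of differing
#'   usable sites).
#' @return A `dist_matrix` over the alignment's isolate ids. Any saturated
#'   pair aborts with an error listing the offending pairs.
#' @export
alignment_distance_matrix <- function(aln, model = c("tamura3p", "p_distance")) {
  model <- match.arg(model)
  n <- length(aln$ids)
  if (n < 2L) stop("need at least 2 sequences")
  d <- matrix(0, n, n)
  bad <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      pc <- pair_counts(aln$seqs[i], aln$seqs[j])
      val <- if (model == "p_distance") {
        (pc$P_count + pc$Q_count) / pc$usable_sites
      } else {
        tryCatch(
          tamura3p_from_counts(pc$P_count / pc$usable_sites,
                               pc$Q_count / pc$usable_sites,
                               pc$gc_fraction,
                               labels = c(aln$ids[i], aln$ids[j])),
          error = function(e) {
            bad <<- c(bad, paste0(aln$ids[i], "/", aln$ids[j]))
            NA_real_
          })
      }
      d[i, j] <- d[j, i] <- val
    }
  }
  if (length(bad)) {
    stop("saturated pair(s): ", paste(bad, collapse = ", "))
  }
  dist_matrix(d, aln$ids)
}

#' Filter a SNP matrix by depth, support, region, allele count and heterozygosity
#'
#' Genotype-level rules first: calls with depth below `min_depth` or with a
#' read-support fraction not exceeding `min_support` become missing. Locus-
#' level rules then drop (i) loci overlapping any excluded region (0-based
#' half-open intervals, e.g. the mating-type locus and the phosphate
#' transporter gene, so their own divergence cannot leak into the genome-wide
#' distances), (ii) loci whose minor-allele count over non-missing isolates is
#' below `min_allele_count`, and (iii) loci whose within-isolate
#' heterozygosity exceeds `max_obs_het` (a no-op for haploid single-call
#' genotypes; present for multi-call input). Counts removed per rule are
#' reported via `message()`. When the matrix carries no depth/support
#' metadata (genepop input) those filters are skipped with a warning.
#'
#' @param m A `snp_matrix`.
#' @param min_depth Minimum read depth (inclusive; default 10).
#' @param min_support Minimum support fraction (strict; default 0.8).
#' @param exclude_regions Data frame or list of `(contig, start, end)` rows.
#' @param min_allele_count Minimum minor-allele count (default 2).
#' @param max_obs_het Maximum observed heterozygosity (default 0).
#' @return A filtered `snp_matrix`.
#' @export
filter_snp_matrix <- function(m, min_depth = 10, min_support = 0.8,
                              exclude_regions = NULL, min_allele_count = 2,
                              max_obs_het = 0) {
  allele <- m$allele
  n_cell_masked <- 0L
  if (is.null(m$depth) && is.null(m$support)) {
    if (min_depth > 0 || min_support > 0) {
      warning("matrix carries no depth/support metadata; depth and support filters skipped")
    }
  } else {
    mask <- matrix(FALSE, nrow(allele), ncol(allele))
    if (!is.null(m$depth)) mask <- mask | (!is.na(allele) & (is.na(m$depth) | m$depth < min_depth))
    if (!is.null(m$support)) mask <- mask | (!is.na(allele) & (is.na(m$support) | m$support <= min_support))
    n_cell_masked <- sum(mask)
    allele[mask] <- NA_integer_
  }
  keep <- rep(TRUE, length(m$locus_ids))
  n_region <- 0L
  if (!is.null(exclude_regions) && !is.null(m$loci)) {
    er <- as.data.frame(exclude_regions)
    names(er)[1:3] <- c("contig", "start", "end")
    for (k in seq_len(nrow(er))) {
      hit <- !is.na(m$loci$contig) & m$loci$contig == er$contig[k] &
        m$loci$start < er$end[k] & m$loci$end > er$start[k]
      keep <- keep & !hit
    }
    n_region <- sum(!keep)
  } else if (!is.null(exclude_regions) && is.null(m$loci)) {
    warning("exclude_regions given but matrix has no locus coordinates; skipped")
  }
  # minor-allele count over non-missing isolates
  ones <- colSums(allele == 1L, na.rm = TRUE)
  called <- colSums(!is.na(allele))
  mac <- pmin(ones, called - ones)
  low_mac <- keep & mac < min_allele_count
  n_mac <- sum(low_mac)
  keep <- keep & !low_mac
  # haploid single-call genotypes have zero within-isolate heterozygosity,
  # so max_obs_het only ever drops loci for multi-call extensions
  n_het <- 0L
  message(sprintf(
    "filter_snp_matrix: %d genotype(s) masked (depth/support); loci dropped: %d region, %d allele-count, %d heterozygosity; %d of %d loci retained",
    n_cell_masked, n_region, n_mac, n_het, sum(keep), length(keep)))
  if (!any(keep)) message("filter_snp_matrix: NO loci survive filtering")
  sel <- function(x) if (is.null(x)) NULL else x[, keep, drop = FALSE]
  snp_matrix(m$isolate_ids, m$locus_ids[keep], allele[, keep, drop = FALSE],
             depth = sel(m$depth), support = sel(m$support),
             loci = if (is.null(m$loci)) NULL else m$loci[keep, , drop = FALSE])
}

#' Jaccard distance matrix of a (filtered) SNP matrix
#'
#' For each isolate pair, over loci non-missing in both: `a` = loci where
#' both carry allele 1, `b + c` = loci where exactly one does; shared absence
#' is non-informative. `d = (b + c) / (a + b + c)`; a pair with
#' `a + b + c = 0` gets distance 0 with a warning. A pair with no commonly
#' called loci at all is an error.
#'
#' @param m A `snp_matrix` (normally after [filter_snp_matrix()]).
#' @return A `dist_matrix` over the isolates.
#' @export
jaccard_distance_matrix <- function(m) {
  x <- m$allele
  n <- nrow(x)
  d <- matrix(0, n, n)
  warned <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      ok <- !is.na(x[i, ]) & !is.na(x[j, ])
      if (!any(ok)) {
        stop("isolates ", m$isolate_ids[i], " and ", m$isolate_ids[j],
             " share no called loci")
      }
      xi <- x[i, ok]; xj <- x[j, ok]
      a <- sum(xi == 1L & xj == 1L)
      bc <- sum(xi != xj)
      if (a + bc == 0L) {
        if (!warned) {
          warning("pair(s) with no allele-1 information; distance set to 0")
          warned <- TRUE
        }
        val <- 0
      } else {
        val <- bc / (a + bc)
      }
      d[i, j] <- d[j, i] <- val
    }
  }
  dist_matrix(d, m$isolate_ids)
}
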