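default_pipeline_config <- function() {
  list(
    snp_dialect = "tsv",
    min_depth = 10, min_support = 0.8, min_allele_count = 2, max_obs_het = 0,
    exclude_regions = NULL,
    distance_model = "tamura3p",
    n_perm_mantel = 9999, n_perm_gamma = 1000, n_perm_permanova = 999,
    n_boot = 999, n_random_cai = 500,
    alpha = 0.05, max_dist = 0.03,
    mat_references = NULL, reference_cds = NULL,
    seed = 1L, out_dir = NULL
  )
}

# de novo typing when no reference set exists: single-linkage clusters at
# max_dist, labelled novel-1, novel-2, ... (sorted-id founders)
de_novo_types <- function(aln, max_dist) {
  n <- length(aln$ids)
  ord <- order(aln$ids)
  cluster <- integer(n)
  n_clust <- 0L
  for (i in ord) {
    linked <- 0L
    for (j in ord) {
      if (cluster[j] > 0L && p_distance_pair(aln$seqs[i], aln$seqs[j]) <= max_dist) {
        linked <- cluster[j]
        break
      }
    }
    if (linked == 0L) {
      n_clust <- n_clust + 1L
      linked <- n_clust
    }
    cluster[i] <- linked
  }
  repeat {
    merged <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (cluster[i] != cluster[j] &&
          p_distance_pair(aln$seqs[i], aln$seqs[j]) <= max_dist) {
        keep <- min(cluster[i], cluster[j])
        cluster[cluster %in% c(cluster[i], cluster[j])] <- keep
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  types <- paste0("novel-", match(cluster, sort(unique(cluster))))
  names(types) <- aln$ids
  types
}

mantel_summary <- function(x) {
  list(r = x$r, p = x$p, n_perm = x$n_perm, seed = x$seed, n = x$n)
}

#' Run the full congruence-of-loci analysis
#'
#' Executes the whole pipeline on three datasets: filter the SNP matrix
#' (depth, support, region exclusion of the two coding loci, minor-allele
#' count), build the three distance matrices (Tamura 3-parameter for the two
#' coding loci, Jaccard for the genome-wide SNPs), run the three pairwise
#' Mantel tests and Baker's gamma comparisons on Ward dendrograms, PERMANOVA
#' by available metadata factors, codon-based selection Z-tests per coding
#' locus, CAI/eCAI when a reference CDS collection is supplied, mating-type
#' and allele assignment, and finally a verdict: all three congruence tests
#' significant at `alpha` is "congruent-clonal-like", none significant is
#' "decoupled-sexual-like", anything else "mixed".
#'
#' @param mat_fasta Path to the MAT alignment FASTA, or a `locus_alignment`.
#' @param ptg_fasta Path to the PTG alignment FASTA, or a `locus_alignment`.
#' @param snp_path Path to the SNP matrix (dialect per config), or a
#'   `snp_matrix`.
#' @param metadata Optional data frame with `isolate_id` plus factor columns
#'   (e.g. `origin`), or a path to such a TSV.
#' @param config Named list overriding the defaults (see
#'   `matcongruence:::default_pipeline_config()`): filter thresholds,
#'   permutation/bootstrap counts, `alpha`, `seed`, `exclude_regions`,
#'   `mat_references`, `reference_cds`, `out_dir` for TSV/Newick sidecars.
#' @return An `analysis_report` list with per-stage results, all seeds and
#'   parameters, and a `verdict` block.
#' @export
run_all <- function(mat_fasta, ptg_fasta, snp_path, metadata = NULL,
                    config = list()) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  mat_aln <- if (inherits(mat_fasta, "locus_alignment")) mat_fasta else
    read_alignment(mat_fasta, frame = 0L, locus_name = "MAT")
  ptg_aln <- if (inherits(ptg_fasta, "locus_alignment")) ptg_fasta else
    read_alignment(ptg_fasta, frame = 0L, locus_name = "PTG")
  snps <- if (inherits(snp_path, "snp_matrix")) snp_path else
    read_snp_matrix(snp_path, dialect = cfg$snp_dialect)
  if (is.character(metadata)) {
    metadata <- utils::read.delim(metadata, stringsAsFactors = FALSE)
  }
  shared <- Reduce(intersect, list(mat_aln$ids, ptg_aln$ids, snps$isolate_ids))
  if (length(shared) < 3L) {
    stop("insufficient shared isolates across the three datasets (",
         length(shared), " shared, need >= 3)")
  }
  shared <- sort(shared)
  mat_aln <- subset_alignment(mat_aln, shared)
  ptg_aln <- subset_alignment(ptg_aln, shared)
  keep_rows <- match(shared, snps$isolate_ids)
  snps <- snp_matrix(shared, snps$locus_ids,
                     snps$allele[keep_rows, , drop = FALSE],
                     depth = if (is.null(snps$depth)) NULL else snps$depth[keep_rows, , drop = FALSE],
                     support = if (is.null(snps$support)) NULL else snps$support[keep_rows, , drop = FALSE],
                     loci = snps$loci)
  n_loci_in <- length(snps$locus_ids)
  filtered <- filter_snp_matrix(snps, min_depth = cfg$min_depth,
                                min_support = cfg$min_support,
                                exclude_regions = cfg$exclude_regions,
                                min_allele_count = cfg$min_allele_count,
                                max_obs_het = cfg$max_obs_het)
  seed <- as.integer(cfg$seed)

  d_mat <- alignment_distance_matrix(mat_aln, model = cfg$distance_model)
  d_ptg <- alignment_distance_matrix(ptg_aln, model = cfg$distance_model)
  d_snp <- jaccard_distance_matrix(filtered)

  pairs <- list(
    mat_vs_ptg = list(d_mat, d_ptg),
    mat_vs_snp = list(d_mat, d_snp),
    ptg_vs_snp = list(d_ptg, d_snp)
  )
  mantel_res <- mapply(function(p, k) {
    mantel_test(p[[1]], p[[2]], n_perm = cfg$n_perm_mantel, seed = seed + k)
  }, pairs, seq_along(pairs), SIMPLIFY = FALSE)
  pearson_res <- lapply(pairs, function(p) {
    suppressMessages(pearson_distance_correlation(p[[1]], p[[2]]))
  })
  trees <- list(MAT = ward_dendrogram(d_mat), PTG = ward_dendrogram(d_ptg),
                SNP = ward_dendrogram(d_snp))
  gamma_res <- list(
    mat_vs_ptg = bakers_gamma(trees$MAT, trees$PTG, n_perm = cfg$n_perm_gamma, seed = seed + 11L),
    mat_vs_snp = bakers_gamma(trees$MAT, trees$SNP, n_perm = cfg$n_perm_gamma, seed = seed + 12L),
    ptg_vs_snp = bakers_gamma(trees$PTG, trees$SNP, n_perm = cfg$n_perm_gamma, seed = seed + 13L)
  )

  # typing (used as a PERMANOVA factor when informative)
  typing <- if (!is.null(cfg$mat_references)) {
    mat_type_alignment(mat_aln, cfg$mat_references, max_dist = cfg$max_dist)
  } else {
    types <- de_novo_types(mat_aln, cfg$max_dist)
    assign_alleles(types, translate_partial(mat_aln))
  }

  permanova_res <- list()
  mt <- typing$main_type
  names(mt) <- typing$isolate_id
  informative <- function(f) length(unique(f)) >= 2L && length(unique(f)) < length(f)
  if (informative(mt)) {
    permanova_res$mat_type <- permanova(d_snp, mt, n_perm = cfg$n_perm_permanova,
                                        seed = seed + 21L, factor_name = "mat_type")
  }
  if (!is.null(metadata)) {
    for (col in setdiff(names(metadata), "isolate_id")) {
      fac <- metadata[[col]]
      names(fac) <- metadata$isolate_id
      fac <- fac[shared]
      if (informative(fac) && !anyNA(fac)) {
        permanova_res[[col]] <- permanova(d_snp, fac, n_perm = cfg$n_perm_permanova,
                                          seed = seed + 22L, factor_name = col)
      }
    }
  }

  selection <- list(
    MAT = codon_selection_test(mat_aln, n_boot = cfg$n_boot, seed = seed + 31L),
    PTG = codon_selection_test(ptg_aln, n_boot = cfg$n_boot, seed = seed + 32L)
  )
  cai_res <- NULL
  if (!is.null(cfg$reference_cds)) {
    usage <- build_codon_usage(cfg$reference_cds)
    cai_res <- lapply(list(MAT = mat_aln, PTG = ptg_aln), function(aln) {
      per <- cai_per_isolate(aln, usage)
      consensus <- gsub("-", "", aln$seqs[1], fixed = TRUE)
      thr <- ecai_threshold(consensus, usage, n_random = cfg$n_random_cai,
                            seed = seed + 41L)
      list(per_isolate = per, mean_cai = mean(per$cai), ecai = thr$ecai,
           ecai_empirical = thr$ecai_empirical, p = thr$p,
           n_random = thr$n_random, seed = thr$seed)
    })
  }

  sig <- vapply(mantel_res, function(m) m$p < cfg$alpha, logical(1))
  classification <- if (all(sig)) "congruent-clonal-like" else
    if (!any(sig)) "decoupled-sexual-like" else "mixed"

  report <- list(
    schema_version = "1.0",
    inputs = list(
      n_isolates_shared = length(shared), isolates = shared,
      n_mat_records = length(mat_aln$ids), n_ptg_records = length(ptg_aln$ids),
      n_snp_loci_input = n_loci_in,
      n_snp_loci_filtered = length(filtered$locus_ids)
    ),
    parameters = cfg[c("min_depth", "min_support", "min_allele_count",
                       "max_obs_het", "distance_model", "n_perm_mantel",
                       "n_perm_gamma", "n_perm_permanova", "n_boot",
                       "alpha", "max_dist", "seed")],
    distances = list(
      MAT = list(mean = mean(upper_tri_values(d_mat)), max = max(d_mat)),
      PTG = list(mean = mean(upper_tri_values(d_ptg)), max = max(d_ptg)),
      SNP = list(mean = mean(upper_tri_values(d_snp)), max = max(d_snp))
    ),
    mantel = lapply(mantel_res, mantel_summary),
    pearson = pearson_res,
    bakers_gamma = lapply(gamma_res, function(x) {
      list(gamma = x$gamma, p = x$p, n_perm = x$n_perm, seed = x$seed)
    }),
    permanova = lapply(permanova_res, function(x) {
      list(factor = x$factor_name, pseudo_F = x$pseudo_F, R2 = x$R2, p = x$p,
           n_perm = x$n_perm, seed = x$seed)
    }),
    selection = lapply(selection, function(x) {
      list(dN = x$dN, dS = x$dS, var_dN = x$var_dN, var_dS = x$var_dS,
           Z = x$Z, p_positive = x$p_positive, p_purifying = x$p_purifying,
           z_defined = x$z_defined, n_boot = x$n_boot, seed = x$seed)
    }),
    cai = cai_res,
    mat_typing = list(
      n_main_types = unname(count_alleles(typing)["n_main_types"]),
      n_alleles = unname(count_alleles(typing)["n_alleles"]),
      table = typing
    ),
    verdict = list(
      mat_vs_ptg_significant = unname(sig[1]),
      mat_vs_snp_significant = unname(sig[2]),
      ptg_vs_snp_significant = unname(sig[3]),
      alpha = cfg$alpha,
      classification = classification
    )
  )
  class(report) <- "analysis_report"
  if (!is.null(cfg$out_dir)) {
    write_report_files(report, d_mat, d_ptg, d_snp, trees, typing, cfg$out_dir)
  }
  report
}

write_report_files <- function(report, d_mat, d_ptg, d_snp, trees, typing, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_distance_matrix(d_mat, file.path(dir, "dist_mat.tsv"))
  write_distance_matrix(d_ptg, file.path(dir, "dist_ptg.tsv"))
  write_distance_matrix(d_snp, file.path(dir, "dist_snp.tsv"))
  for (nm in names(trees)) {
    write_newick(trees[[nm]], file.path(dir, paste0("dendrogram_", tolower(nm), ".nwk")))
  }
  write_mat_typing(typing, file.path(dir, "mat_typing.tsv"))
  write_report_json(report, file.path(dir, "report.json"))
  invisible(dir)
}

#' Write an analysis report as JSON
#' @param report An `analysis_report` from [run_all()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  rep2 <- unclass(report)
  rep2$mat_typing$table <- as.data.frame(rep2$mat_typing$table)
  jsonlite::write_json(rep2, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Congruence-of-loci analysis report\n")
  cat(sprintf("  isolates: %d shared; SNP loci: %d in, %d after filtering\n",
              x$inputs$n_isolates_shared, x$inputs$n_snp_loci_input,
              x$inputs$n_snp_loci_filtered))
  for (nm in names(x$mantel)) {
    m <- x$mantel[[nm]]
    cat(sprintf("  Mantel %-10s r = %7.4f  p = %.4g\n", nm, m$r, m$p))
  }
  for (nm in names(x$bakers_gamma)) {
    g <- x$bakers_gamma[[nm]]
    cat(sprintf("  gamma  %-10s g = %7.4f  p = %.4g\n", nm, g$gamma, g$p))
  }
  for (nm in names(x$selection)) {
    s <- x$selection[[nm]]
    cat(sprintf("  %s: dN = %.4f dS = %.4f Z = %s\n", nm, s$dN, s$dS,
                if (isTRUE(s$z_defined)) sprintf("%.3f (purifying p = %.4g)", s$Z, s$p_purifying)
                else "undefined"))
  }
  cat(sprintf("  MAT typing: %d main type(s), %d allele(s)\n",
              x$mat_typing$n_main_types, x$mat_typing$n_alleles))
  cat(sprintf("  verdict: %s (alpha = %g)\n", x$verdict$classification, x$verdict$alpha))
  invisible(x)
}
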