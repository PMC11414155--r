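#' Build a codon-usage table from a reference CDS collection
#'
#' Pools codon counts over a collection of coding sequences and derives the
#' relative adaptiveness `w(codon) = count / max count within its synonymous
#' family`. Sense codons never observed in the collection receive a
#' pseudo-count of 0.5 before `w` is computed (with a message), so `w` never
#' annihilates a geometric mean.
#'
#' @param cds_collection Character vector (or list) of coding nucleotide
#'   sequences, each of length divisible by 3. Trailing stop codons are
#'   counted but never contribute to `w` of sense codons.
#' @return An object of class `codon_usage_table`: list with `counts`
#'   (named, 64 codons) and `w` (named, 61 sense codons).
#' @export
build_codon_usage <- function(cds_collection) {
  gc_init()
  cds_collection <- unlist(cds_collection, use.names = TRUE)
  if (length(cds_collection) == 0L) stop("empty CDS collection")
  nm <- names(cds_collection)
  if (is.null(nm)) nm <- paste0("cds", seq_along(cds_collection))
  seqs <- toupper(gsub("U", "T", as.character(cds_collection), fixed = TRUE))
  badlen <- nchar(seqs) %% 3L != 0L
  if (any(badlen)) {
    stop("sequence length not divisible by 3: ", paste(nm[badlen], collapse = ", "))
  }
  counts <- integer(64)
  for (s in seqs) {
    b <- match(strsplit(s, "", fixed = TRUE)[[1]], gc_bases)
    n_cod <- length(b) %/% 3L
    ci <- codon_to_index(b[seq(1, by = 3, length.out = n_cod)],
                         b[seq(2, by = 3, length.out = n_cod)],
                         b[seq(3, by = 3, length.out = n_cod)])
    ci <- ci[!is.na(ci)]
    tab <- tabulate(ci, nbins = 64L)
    counts <- counts + tab
  }
  names(counts) <- .gc$codons
  sense <- which(!.gc$is_stop)
  eff <- as.numeric(counts)
  zero_sense <- sense[eff[sense] == 0]
  if (length(zero_sense)) {
    message(length(zero_sense), " unobserved sense codon(s) given pseudo-count 0.5")
    eff[zero_sense] <- 0.5
  }
  w <- numeric(64)
  for (aa in unique(.gc$aa[sense])) {
    fam <- which(.gc$aa == aa & !.gc$is_stop)
    w[fam] <- eff[fam] / max(eff[fam])
  }
  w <- w[sense]
  names(w) <- .gc$codons[sense]
  structure(list(counts = counts, w = w), class = "codon_usage_table")
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat(sprintf("codon_usage_table: %d codons counted, w in [%.3f, 1]\n",
              sum(x$counts), min(x$w)))
  invisible(x)
}

# Codon strings of a sequence (frame 0), dropping any trailing partial codon.
split_codons <- function(seq) {
  seq <- toupper(gsub("U", "T", as.character(seq), fixed = TRUE))
  n_cod <- nchar(seq) %/% 3L
  if (n_cod == 0L) return(character(0))
  substring(seq, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
}

# Codons entering a CAI geometric mean: sense codons excluding the
# single-codon families Met (ATG) and Trp (TGG); stops and codons with
# ambiguous characters are dropped.
cai_included_w <- function(seq, table) {
  gc_init()
  cods <- split_codons(seq)
  ci <- vapply(cods, codon_string_to_index, integer(1))
  keep <- !is.na(ci) & !.gc$is_stop[ifelse(is.na(ci), 1L, ci)] &
    !(cods %in% c("ATG", "TGG"))
  table$w[cods[keep]]
}

#' Codon adaptation index of a coding sequence
#'
#' Geometric mean of the relative adaptiveness `w` over the sequence's sense
#' codons, excluding the single-codon families Met and Trp (which carry no
#' codon-choice information) and stop codons.
#'
#' @param seq Coding nucleotide sequence (frame 0).
#' @param table A `codon_usage_table` from [build_codon_usage()].
#' @return CAI value in (0, 1].
#' @export
cai <- function(seq, table) {
  w <- cai_included_w(seq, table)
  if (length(w) == 0L) stop("no codons eligible for CAI in sequence")
  exp(mean(log(w)))
}

#' Expected-CAI threshold under a composition-matched null
#'
#' Tests whether an observed CAI could arise purely from the sequence's
#' amino-acid composition and overall G+C/nucleotide composition. Random
#' sequences are generated that preserve the query's exact amino-acid
#' sequence; at each position the codon is drawn from the synonymous family
#' with probability proportional to the product of the query's overall
#' nucleotide frequencies across the codon's three bases. The threshold
#' `eCAI` is the upper one-sided 95% point of the null CAI distribution under
#' a normal approximation (`mean + 1.645 sd`); the empirical 95th percentile
#' is reported alongside.
#'
#' @param seq Coding nucleotide sequence (frame 0).
#' @param table A `codon_usage_table`.
#' @param n_random Number of null sequences (>= 30; default 500).
#' @param seed Integer seed.
#' @return List with `cai` (observed), `ecai`, `ecai_empirical`, `p`
#'   (fraction of null CAIs >= observed; 0 means < 1/n_random), `n_random`,
#'   `seed`.
#' @export
ecai_threshold <- function(seq, table, n_random = 500, seed = 1L) {
  gc_init()
  if (n_random < 30) stop("n_random must be >= 30 for the normal approximation")
  obs <- cai(seq, table)
  seq <- toupper(gsub("U", "T", as.character(seq), fixed = TRUE))
  base_freq <- table(factor(strsplit(seq, "", fixed = TRUE)[[1]], levels = gc_bases))
  base_freq <- as.numeric(base_freq) / sum(base_freq)
  cods <- split_codons(seq)
  ci <- vapply(cods, codon_string_to_index, integer(1))
  ci <- ci[!is.na(ci) & !.gc$is_stop[ifelse(is.na(ci), 1L, ci)]]
  if (length(ci) == 0L) stop("no usable codons in sequence")
  aa_seq <- .gc$aa[ci]
  # per-position family sampling weights, composition-matched
  fam_codons <- lapply(unique(aa_seq), function(aa) which(.gc$aa == aa & !.gc$is_stop))
  names(fam_codons) <- unique(aa_seq)
  fam_weights <- lapply(fam_codons, function(members) {
    wts <- vapply(members, function(m) prod(base_freq[.gc$base_idx[m, ]]), numeric(1))
    if (sum(wts) == 0) wts <- rep(1, length(members))
    wts / sum(wts)
  })
  set.seed(as.integer(seed))
  null_cai <- numeric(n_random)
  sense_names <- names(table$w)
  for (r in seq_len(n_random)) {
    drawn <- vapply(aa_seq, function(aa) {
      members <- fam_codons[[aa]]
      members[sample.int(length(members), 1L, prob = fam_weights[[aa]])]
    }, integer(1))
    keep <- !(.gc$codons[drawn] %in% c("ATG", "TGG"))
    w <- table$w[.gc$codons[drawn[keep]]]
    null_cai[r] <- if (length(w)) exp(mean(log(w))) else NA_real_
  }
  null_cai <- null_cai[is.finite(null_cai)]
  list(cai = obs,
       ecai = mean(null_cai) + 1.645 * stats::sd(null_cai),
       ecai_empirical = unname(stats::quantile(null_cai, 0.95, type = 7)),
       p = mean(null_cai >= obs),
       n_random = as.integer(n_random), seed = as.integer(seed))
}

#' Per-sequence CAI of every record in an alignment
#'
#' Convenience wrapper applying [cai()] to each (gap-stripped) record of a
#' coding alignment against a reference codon-usage table.
#'
#' @param aln An in-frame `locus_alignment`.
#' @param table A `codon_usage_table`.
#' @return Data frame with columns `isolate_id` and `cai`.
#' @export
cai_per_isolate <- function(aln, table) {
  frame <- if (is.na(aln$frame)) 0L else aln$frame
  vals <- vapply(seq_along(aln$ids), function(i) {
    s <- substring(aln$seqs[i], frame + 1L)
    s <- gsub("-", "", s, fixed = TRUE)
    cai(s, table)
  }, numeric(1))
  data.frame(isolate_id = aln$ids, cai = vals)
}
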