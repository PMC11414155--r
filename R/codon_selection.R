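# Codon-index matrix of a coding alignment: one row per sequence, one column
# per complete codon after the frame offset; NA where the codon contains a
# gap, N, or any non-ACGT character. Errors on internal stop codons.
codon_index_matrix <- function(aln, check_stops = TRUE) {
  gc_init()
  frame <- if (is.na(aln$frame)) 0L else aln$frame
  mat <- as.matrix(aln)
  if (frame > 0L) mat <- mat[, -seq_len(frame), drop = FALSE]
  n_cod <- ncol(mat) %/% 3L
  if (n_cod < 1L) stop("alignment shorter than one codon after frame offset")
  mat <- mat[, seq_len(3L * n_cod), drop = FALSE]
  b <- match(mat, gc_bases)  # NA for N and '-'
  dim(b) <- dim(mat)
  i1 <- b[, seq(1L, by = 3L, length.out = n_cod), drop = FALSE]
  i2 <- b[, seq(2L, by = 3L, length.out = n_cod), drop = FALSE]
  i3 <- b[, seq(3L, by = 3L, length.out = n_cod), drop = FALSE]
  ci <- codon_to_index(i1, i2, i3)
  dim(ci) <- c(nrow(mat), n_cod)
  if (check_stops) {
    stops <- !is.na(ci) & matrix(.gc$is_stop[ci], nrow(ci), ncol(ci))
    # a stop in the final codon position is a natural terminator, allowed
    internal <- stops[, -ncol(stops), drop = FALSE]
    if (any(internal)) {
      bad <- aln$ids[which(rowSums(internal) > 0)]
      stop("internal stop codon(s) in: ", paste(bad, collapse = ", "))
    }
    ci[stops] <- NA_integer_
  }
  rownames(ci) <- aln$ids
  ci
}

# Per-pair, per-codon-column Nei-Gojobori profile for an alignment.
# Returns matrices (n_pairs x n_codons): nd, sd, n_sites, s_sites, all 0
# where either codon is unusable, plus the pair index table.
ng_profile <- function(ci) {
  n_seq <- nrow(ci)
  n_cod <- ncol(ci)
  pairs <- which(upper.tri(matrix(0, n_seq, n_seq)), arr.ind = TRUE)
  # upper.tri arr.ind gives (row, col) with row < col
  pi <- pairs[, 1]
  pj <- pairs[, 2]
  n_pairs <- length(pi)
  A <- ci[pi, , drop = FALSE]
  B <- ci[pj, , drop = FALSE]
  ok <- !is.na(A) & !is.na(B)
  Az <- ifelse(ok, A, 1L)
  Bz <- ifelse(ok, B, 1L)
  # linear index into the transposed 64x64 tables; as.vector prevents R's
  # coordinate-matrix subscript semantics when the index happens to be n x 2
  lin <- as.vector((Az - 1L) * 64L + Bz)
  nd_tab <- t(.gc$nd)
  sd_tab <- t(.gc$sd)
  nd <- matrix(nd_tab[lin], n_pairs, n_cod)
  sd <- matrix(sd_tab[lin], n_pairs, n_cod)
  ssA <- matrix(.gc$syn_sites[Az], n_pairs, n_cod)
  ssB <- matrix(.gc$syn_sites[Bz], n_pairs, n_cod)
  s_sites <- (ssA + ssB) / 2
  n_sites <- 3 - s_sites
  nd[!ok] <- 0; sd[!ok] <- 0; s_sites[!ok] <- 0; n_sites[!ok] <- 0
  list(nd = nd, sd = sd, n_sites = n_sites, s_sites = s_sites,
       i = pi, j = pj, n_codons = n_cod)
}

jc_correct <- function(p, context = "p", strict = TRUE) {
  sat <- !is.na(p) & p >= 0.75
  if (any(sat)) {
    if (strict) stop("saturated pair: ", context, " >= 3/4, Jukes-Cantor correction undefined")
    p[sat] <- NA_real_
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori synonymous/non-synonymous divergence of one sequence pair
#'
#' Counts synonymous (`sd`) and non-synonymous (`nd`) differences per codon by
#' averaging, with equal weight, over every minimal mutational pathway between
#' the two codons that avoids stop codons; synonymous and non-synonymous site
#' totals (`S`, `N`) are averaged over the two sequences. Proportions are
#' Jukes-Cantor corrected: `d = -(3/4) log(1 - (4/3) p)`.
#'
#' @param a,b Coding nucleotide sequences (equal length, in frame 0, length a
#'   multiple of 3 up to a trailing remainder that is dropped). Codon pairs
#'   containing `-` or `N` in either sequence are excluded pairwise.
#' @return List with `pN`, `pS`, `dN`, `dS` and the underlying counts
#'   `nd`, `sd`, `N`, `S`.
#' @export
nei_gojobori_pair <- function(a, b) {
  aln <- locus_alignment(c("a", "b"), c(a, b), frame = 0L)
  ci <- codon_index_matrix(aln)
  prof <- ng_profile(ci)
  N <- sum(prof$n_sites)
  S <- sum(prof$s_sites)
  if (N + S == 0) stop("no comparable codons between the two sequences")
  nd <- sum(prof$nd)
  sd <- sum(prof$sd)
  pN <- if (N > 0) nd / N else 0
  pS <- if (S > 0) sd / S else 0
  list(pN = pN, pS = pS,
       dN = jc_correct(pN, "pN"), dS = jc_correct(pS, "pS"),
       nd = nd, sd = sd, N = N, S = S)
}

pair_averaged_d <- function(prof, cols = NULL, strict = TRUE) {
  nd <- prof$nd; sd <- prof$sd; ns <- prof$n_sites; ss <- prof$s_sites
  if (!is.null(cols)) {
    nd <- nd[, cols, drop = FALSE]; sd <- sd[, cols, drop = FALSE]
    ns <- ns[, cols, drop = FALSE]; ss <- ss[, cols, drop = FALSE]
  }
  N <- rowSums(ns); S <- rowSums(ss)
  pN <- ifelse(N > 0, rowSums(nd) / N, NA_real_)
  pS <- ifelse(S > 0, rowSums(sd) / S, NA_real_)
  dN <- jc_correct(pN, "pN", strict = strict)
  dS <- jc_correct(pS, "pS", strict = strict)
  c(dN = mean(dN, na.rm = TRUE), dS = mean(dS, na.rm = TRUE))
}

#' Codon-based Z-test of selection on a coding alignment
#'
#' Computes Nei-Gojobori dN and dS averaged over all unordered sequence
#' pairs, estimates their variances by bootstrap over codon columns
#' (columns resampled with replacement, pair-averaged dN and dS recomputed
#' per replicate), and forms `Z = (dN - dS) / sqrt(Var(dN) + Var(dS))`.
#' One-tailed p-values against strict neutrality are reported for both
#' alternatives: positive selection (`Z > 0`) and purifying selection
#' (`Z < 0`), using the standard-normal reference.
#'
#' @param aln An in-frame `locus_alignment` with at least 2 sequences.
#' @param n_boot Number of bootstrap replicates (default 999).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `codon_selection_result`: a list with `dN`,
#'   `dS`, `var_dN`, `var_dS`, `Z`, `p_positive`, `p_purifying`,
#'   `z_defined`, `n_boot`, `seed`, `n_pairs`, `n_codons` and the sequence
#'   ids used.
#' @export
codon_selection_test <- function(aln, n_boot = 999, seed = 1L) {
  if (length(aln$ids) < 2L) stop("need at least 2 sequences")
  ci <- codon_index_matrix(aln)
  if (ncol(ci) < 2L) stop("alignment shorter than 2 codons")
  prof <- ng_profile(ci)
  obs <- pair_averaged_d(prof)
  set.seed(as.integer(seed))
  n_cod <- prof$n_codons
  boot <- matrix(NA_real_, n_boot, 2L)
  for (r in seq_len(n_boot)) {
    cols <- sample.int(n_cod, n_cod, replace = TRUE)
    boot[r, ] <- pair_averaged_d(prof, cols, strict = FALSE)
  }
  var_dN <- stats::var(boot[, 1], na.rm = TRUE)
  var_dS <- stats::var(boot[, 2], na.rm = TRUE)
  vsum <- var_dN + var_dS
  z_defined <- is.finite(vsum) && vsum > 0
  Z <- if (z_defined) (obs[["dN"]] - obs[["dS"]]) / sqrt(vsum) else NA_real_
  structure(
    list(dN = obs[["dN"]], dS = obs[["dS"]],
         var_dN = var_dN, var_dS = var_dS,
         Z = unname(Z),
         p_positive = if (z_defined) stats::pnorm(Z, lower.tail = FALSE) else NA_real_,
         p_purifying = if (z_defined) stats::pnorm(Z) else NA_real_,
         z_defined = z_defined,
         n_boot = n_boot, seed = as.integer(seed),
         n_pairs = length(prof$i), n_codons = n_cod,
         ids = aln$ids, locus_name = aln$locus_name),
    class = "codon_selection_result"
  )
}

#' @export
print.codon_selection_result <- function(x, ...) {
  cat(sprintf("Codon-based Z-test (Nei-Gojobori, %d bootstrap replicates) on '%s'\n",
              x$n_boot, x$locus_name))
  cat(sprintf("  dN = %.4f  dS = %.4f  (%d pairs, %d codons)\n",
              x$dN, x$dS, x$n_pairs, x$n_codons))
  if (x$z_defined) {
    cat(sprintf("  Z = %.4f   P(purifying) = %.4g   P(positive) = %.4g\n",
                x$Z, x$p_purifying, x$p_positive))
  } else {
    cat("  Z undefined (zero bootstrap variance)\n")
  }
  invisible(x)
}

#' Tidy one-row summary of a codon selection test
#' @param x A `codon_selection_result`.
#' @return A one-row data frame.
#' @export
tidy_codon_selection <- function(x) {
  data.frame(locus = x$locus_name, dN = x$dN, dS = x$dS,
             var_dN = x$var_dN, var_dS = x$var_dS, Z = x$Z,
             p_positive = x$p_positive, p_purifying = x$p_purifying,
             n_boot = x$n_boot, n_pairs = x$n_pairs, n_codons = x$n_codons)
}
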