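# Shared standard-genetic-code tables, built once at load time.
# Codon index convention: 16*(b1-1) + 4*(b2-1) + b3 with A=1, C=2, G=3, T=4.

.gc <- new.env(parent = emptyenv())

gc_bases <- c("A", "C", "G", "T")

gc_init <- function() {
  if (!is.null(.gc$codons)) return(invisible())
  idx <- expand.grid(b3 = 1:4, b2 = 1:4, b1 = 1:4)[, 3:1]
  codons <- apply(idx, 1L, function(b) paste0(gc_bases[b], collapse = ""))
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  .gc$codons <- codons
  .gc$base_idx <- as.matrix(idx)
  .gc$aa <- aa
  .gc$is_stop <- aa == "*"
  .gc$syn_sites <- vapply(seq_len(64), gc_syn_sites_one, numeric(1))
  paths <- gc_pathway_tables()
  .gc$nd <- paths$nd
  .gc$sd <- paths$sd
  invisible()
}

codon_to_index <- function(b1, b2, b3) 16L * (b1 - 1L) + 4L * (b2 - 1L) + b3

codon_string_to_index <- function(codon) {
  b <- match(strsplit(codon, "", fixed = TRUE)[[1]], gc_bases)
  if (length(b) != 3L || anyNA(b)) return(NA_integer_)
  codon_to_index(b[1], b[2], b[3])
}

# Synonymous site count of one codon: per position, the fraction of the
# non-stop single-base mutants that preserve the amino acid.
gc_syn_sites_one <- function(ci) {
  if (.gc$is_stop[ci]) return(NA_real_)
  b <- .gc$base_idx[ci, ]
  aa0 <- .gc$aa[ci]
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; nonstop <- 0L
    for (nb in setdiff(1:4, b[pos])) {
      bb <- b
      bb[pos] <- nb
      mi <- codon_to_index(bb[1], bb[2], bb[3])
      if (.gc$is_stop[mi]) next
      nonstop <- nonstop + 1L
      if (.gc$aa[mi] == aa0) syn <- syn + 1L
    }
    if (nonstop > 0L) s <- s + syn / nonstop
  }
  s
}

# nd/sd for every ordered codon pair, averaged with equal weight over all
# minimal mutational pathways that avoid stop codons.
gc_pathway_tables <- function() {
  nd <- matrix(NA_real_, 64, 64)
  sd <- matrix(NA_real_, 64, 64)
  perms3 <- list(1L, c(1L, 2L), c(2L, 1L),
                 c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                 c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  for (i in seq_len(64)) {
    if (.gc$is_stop[i]) next
    for (j in seq_len(64)) {
      if (.gc$is_stop[j]) next
      if (i == j) { nd[i, j] <- 0; sd[i, j] <- 0; next }
      diffs <- which(.gc$base_idx[i, ] != .gc$base_idx[j, ])
      k <- length(diffs)
      perms <- if (k == 1L) list(diffs) else
        lapply(gc_perms(k), function(p) diffs[p])
      tot_n <- 0; tot_s <- 0; n_paths <- 0L
      for (ord in perms) {
        cur <- .gc$base_idx[i, ]
        pn <- 0; ps <- 0; ok <- TRUE
        for (pos in ord) {
          nxt <- cur
          nxt[pos] <- .gc$base_idx[j, pos]
          mi <- codon_to_index(nxt[1], nxt[2], nxt[3])
          if (.gc$is_stop[mi]) { ok <- FALSE; break }
          prev <- codon_to_index(cur[1], cur[2], cur[3])
          if (.gc$aa[mi] == .gc$aa[prev]) ps <- ps + 1 else pn <- pn + 1
          cur <- nxt
        }
        if (ok) { tot_n <- tot_n + pn; tot_s <- tot_s + ps; n_paths <- n_paths + 1L }
      }
      if (n_paths > 0L) {
        nd[i, j] <- tot_n / n_paths
        sd[i, j] <- tot_s / n_paths
      }
    }
  }
  list(nd = nd, sd = sd)
}

gc_perms <- function(k) {
  if (k == 1L) return(list(1L))
  if (k == 2L) return(list(c(1L, 2L), c(2L, 1L)))
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
}

# Translate an integer base vector (length divisible by 3); returns amino
# acid letters, "*" for stops.
gc_translate_ints <- function(b) {
  gc_init()
  n <- length(b) %/% 3L
  i1 <- b[seq(1L, by = 3L, length.out = n)]
  i2 <- b[seq(2L, by = 3L, length.out = n)]
  i3 <- b[seq(3L, by = 3L, length.out = n)]
  .gc$aa[codon_to_index(i1, i2, i3)]
}

#' Synonymous and non-synonymous site counts of a codon
#'
#' For each of the nine single-base mutants of a sense codon, counts the
#' fraction that preserve the encoded amino acid; mutants that create a stop
#' codon are excluded from the denominator at their position (the
#' Nei-Gojobori convention). Non-synonymous sites are `3 - syn_sites`.
#'
#' @param codon A 3-letter sense codon, e.g. `"TTT"`.
#' @return Named numeric vector `c(syn_sites, nonsyn_sites)`.
#' @export
codon_sites <- function(codon) {
  gc_init()
  ci <- codon_string_to_index(toupper(codon))
  if (is.na(ci)) stop("not a valid codon: ", codon)
  if (.gc$is_stop[ci]) stop("stop codon has no site decomposition: ", codon)
  s <- .gc$syn_sites[ci]
  c(syn_sites = s, nonsyn_sites = 3 - s)
}
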