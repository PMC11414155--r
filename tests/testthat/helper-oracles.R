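# Independent oracles, written from first principles against the standard
# genetic code and the textbook definitions; they never call package internals.

oracle_code <- Biostrings::GENETIC_CODE
oracle_bases <- c("A", "C", "G", "T")
oracle_sense_codons <- names(oracle_code)[oracle_code != "*"]

oracle_translate_codon <- function(codon) unname(oracle_code[codon])

# Synonymous site count of a codon: per position, fraction of non-stop
# single-base mutants preserving the amino acid.
oracle_codon_sites <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  aa0 <- oracle_translate_codon(codon)
  syn <- 0
  for (pos in 1:3) {
    s <- 0L
    k <- 0L
    for (nb in setdiff(oracle_bases, b[pos])) {
      mb <- b
      mb[pos] <- nb
      m <- paste0(mb, collapse = "")
      if (oracle_translate_codon(m) == "*") next
      k <- k + 1L
      if (oracle_translate_codon(m) == aa0) s <- s + 1L
    }
    if (k > 0L) syn <- syn + s / k
  }
  syn
}

# nd/sd between two sense codons, averaged over all stop-free orderings of
# the differing positions (depth-first recursion; independent of the
# package's permutation-table approach).
oracle_codon_path_counts <- function(c1, c2) {
  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  diffs <- which(b1 != b2)
  if (length(diffs) == 0L) return(c(nd = 0, sd = 0))
  acc <- list(nd = 0, sd = 0, n = 0L)
  recurse <- function(cur, remaining, nd, sd) {
    if (length(remaining) == 0L) {
      acc$nd <<- acc$nd + nd
      acc$sd <<- acc$sd + sd
      acc$n <<- acc$n + 1L
      return(invisible())
    }
    for (pos in remaining) {
      nxt <- cur
      nxt[pos] <- b2[pos]
      ncod <- paste0(nxt, collapse = "")
      if (oracle_translate_codon(ncod) == "*") next
      syn <- oracle_translate_codon(ncod) == oracle_translate_codon(paste0(cur, collapse = ""))
      recurse(nxt, setdiff(remaining, pos), nd + !syn, sd + syn)
    }
  }
  recurse(b1, diffs, 0, 0)
  if (acc$n == 0L) return(c(nd = NA_real_, sd = NA_real_))
  c(nd = acc$nd / acc$n, sd = acc$sd / acc$n)
}

# Direct evaluation of the Tamura 3-parameter closed form.
oracle_tamura3p <- function(P, Q, theta) {
  h <- 2 * theta * (1 - theta)
  -h * log(1 - P / h - Q) - 0.5 * (1 - h) * log(1 - 2 * Q)
}

# Brute-force Ward clustering: at each step recompute, from scratch, the
# merge cost Delta(A,B) = SS(A union B) - SS(A) - SS(B) with
# SS(C) = sum of squared pairwise dissimilarities within C / (2|C|),
# and merge the minimising pair. Returns the sequence of merged label sets.
oracle_ward_merge_sequence <- function(d) {
  labs <- rownames(d)
  clusters <- as.list(labs)
  ss <- function(members) {
    if (length(members) < 2L) return(0)
    sub <- d[members, members, drop = FALSE]
    sum(sub[upper.tri(sub)]^2) / length(members)
  }
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    best_cost <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        cost <- ss(c(clusters[[a]], clusters[[b]])) - ss(clusters[[a]]) - ss(clusters[[b]])
        if (cost < best_cost - 1e-12) {
          best_cost <- cost
          best <- c(a, b)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- merged
    clusters[[best[1]]] <- merged
    clusters <- clusters[-best[2]]
  }
  merges
}

# Merge sequence (as sorted label sets) of an hclust object.
hclust_merge_sequence <- function(h) {
  labs <- h$labels
  sets <- vector("list", nrow(h$merge))
  for (k in seq_len(nrow(h$merge))) {
    get <- function(v) if (v < 0) labs[-v] else sets[[v]]
    sets[[k]] <- sort(c(get(h$merge[k, 1]), get(h$merge[k, 2])))
  }
  sets
}

# Exact Mantel p on a tiny matrix: enumerate every relabelling of d2.
oracle_mantel_exact_p <- function(d1, d2) {
  m1 <- unclass(d1)
  m2 <- unclass(d2)
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  r_obs <- cor(v1, m2[ut])
  perms <- all_permutations(nrow(m1))
  rs <- apply(perms, 1, function(idx) cor(v1, m2[idx, idx][ut]))
  mean(rs >= r_obs - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  out <- NULL
  for (i in seq_len(n)) {
    sub <- all_permutations(n - 1L)
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  storage.mode(out) <- "integer"
  unname(out)
}

# Random valid distance matrix from points in Euclidean space.
random_euclidean_dist <- function(n, dim = 3, labels = sprintf("L%02d", seq_len(n))) {
  pts <- matrix(rnorm(n * dim), n, dim)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(labels, labels)
  matcongruence::dist_matrix(d, labels)
}
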