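#' Translate a partial coding alignment
#'
#' Standard-code translation from the alignment's frame offset. Codons
#' containing `-` or `N` translate to `X`; the trailing incomplete codon is
#' dropped. Internal stop codons are retained as `*` with a warning naming
#' the records, since a partial amplicon with a frameshifted or pseudogenised
#' copy is worth flagging, not hiding.
#'
#' @param aln A `locus_alignment` with `frame` set.
#' @return Named character vector of amino-acid sequences (names = ids).
#' @export
translate_partial <- function(aln) {
  if (is.na(aln$frame)) stop("alignment has no frame annotation")
  gc_init()
  ci <- codon_index_matrix(aln, check_stops = FALSE)
  n_cod <- ncol(ci)
  aa <- matrix("X", nrow(ci), n_cod)
  ok <- !is.na(ci)
  aa[ok] <- .gc$aa[ci[ok]]
  has_internal_stop <- rowSums(aa[, -n_cod, drop = FALSE] == "*") > 0
  if (any(has_internal_stop)) {
    warning("internal stop codon(s) in: ",
            paste(aln$ids[has_internal_stop], collapse = ", "))
  }
  out <- apply(aa, 1L, paste0, collapse = "")
  names(out) <- aln$ids
  out
}

p_distance_pair <- function(a, b) {
  pc <- pair_counts(a, b)
  (pc$P_count + pc$Q_count) / pc$usable_sites
}

#' Assign main mating types by nearest reference
#'
#' Each query is assigned the type of its nearest reference by p-distance
#' when that distance is at most `max_dist`; ties between equally near
#' references break toward the lexicographically smaller type label (and are
#' reported). Queries beyond the threshold from every reference are
#' single-linkage clustered among themselves at `max_dist` and each cluster
#' becomes a novel type (`novel-1`, `novel-2`, ... in order of first
#' appearance by sorted isolate id), mirroring how an unreported mating type
#' is discovered.
#'
#' @param aln Query `locus_alignment`.
#' @param references `locus_alignment` whose ids are type labels (one
#'   representative per id) or of the form `label` repeated; each reference
#'   id is used as its type label.
#' @param max_dist p-distance threshold (default 0.03).
#' @return Named character vector of main-type labels (names = isolate ids).
#' @export
assign_main_types <- function(aln, references, max_dist = 0.03) {
  if (length(references$ids) == 0L) stop("empty reference set")
  n <- length(aln$ids)
  types <- character(n)
  unassigned <- integer(0)
  ref_order <- order(references$ids)
  for (i in seq_len(n)) {
    dists <- vapply(references$seqs, function(r) p_distance_pair(aln$seqs[i], r),
                    numeric(1))
    best <- min(dists)
    if (best <= max_dist) {
      hits <- references$ids[dists <= best + 1e-12]
      if (length(hits) > 1L) {
        message("isolate ", aln$ids[i], ": tie between references ",
                paste(sort(hits), collapse = ", "), "; taking ", sort(hits)[1])
      }
      types[i] <- sort(hits)[1]
    } else {
      unassigned <- c(unassigned, i)
    }
  }
  if (length(unassigned)) {
    # single-linkage clusters at max_dist among the unassigned queries,
    # processed in sorted-id order for determinism
    ord <- unassigned[order(aln$ids[unassigned])]
    n_novel <- 0L
    assigned_cluster <- setNames(integer(length(ord)), aln$ids[ord])
    for (i in ord) {
      linked <- 0L
      for (j in ord[ord != i]) {
        cj <- assigned_cluster[[aln$ids[j]]]
        if (cj > 0L && p_distance_pair(aln$seqs[i], aln$seqs[j]) <= max_dist) {
          linked <- cj
          break
        }
      }
      if (linked == 0L) {
        n_novel <- n_novel + 1L
        linked <- n_novel
      }
      assigned_cluster[[aln$ids[i]]] <- linked
      types[i] <- paste0("novel-", linked)
    }
    # single linkage: merge clusters transitively
    repeat {
      merged <- FALSE
      for (a in seq_along(ord)) {
        for (b in seq_along(ord)) {
          ia <- ord[a]; ib <- ord[b]
          ca <- assigned_cluster[[aln$ids[ia]]]
          cb <- assigned_cluster[[aln$ids[ib]]]
          if (ca != cb && p_distance_pair(aln$seqs[ia], aln$seqs[ib]) <= max_dist) {
            keep <- min(ca, cb)
            assigned_cluster[assigned_cluster %in% c(ca, cb)] <- keep
            merged <- TRUE
          }
        }
      }
      if (!merged) break
    }
    relabel <- setNames(match(assigned_cluster, sort(unique(assigned_cluster))),
                        names(assigned_cluster))
    for (k in seq_along(ord)) {
      types[ord[k]] <- paste0("novel-", relabel[[aln$ids[ord[k]]]])
    }
  }
  names(types) <- aln$ids
  types
}

#' Assign amino-acid-distinct alleles within main types
#'
#' Within each main type, isolates are grouped by exact amino-acid sequence
#' identity; allele groups are numbered by decreasing size, then by
#' lexicographically smallest representative isolate id (`TYPE.1`,
#' `TYPE.2`, ...). A main type with a single amino-acid group keeps its bare
#' label, so synonymous-only divergence never splits an allele.
#'
#' @param main_types Named character vector from [assign_main_types()].
#' @param aa_sequences Named character vector from [translate_partial()]
#'   covering the same isolates.
#' @return Data frame with columns `isolate_id`, `main_type`, `allele`,
#'   `aa_sequence` (class `mat_typing_table`).
#' @export
assign_alleles <- function(main_types, aa_sequences) {
  ids <- names(main_types)
  if (!setequal(ids, names(aa_sequences))) {
    stop("main_types and aa_sequences must cover the same isolates")
  }
  aa_sequences <- aa_sequences[ids]
  out <- data.frame(isolate_id = ids, main_type = unname(main_types),
                    allele = NA_character_, aa_sequence = unname(aa_sequences),
                    stringsAsFactors = FALSE)
  for (ty in unique(out$main_type)) {
    idx <- which(out$main_type == ty)
    groups <- split(idx, out$aa_sequence[idx])
    if (length(groups) == 1L) {
      out$allele[idx] <- ty
      next
    }
    reps <- vapply(groups, function(g) min(out$isolate_id[g]), character(1))
    ord <- order(-lengths(groups), reps)
    for (k in seq_along(ord)) {
      out$allele[groups[[ord[k]]]] <- sprintf("%s.%d", ty, k)
    }
  }
  out <- out[order(out$isolate_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mat_typing_table", "data.frame")
  out
}

#' Count main types and alleles in a typing table
#' @param assignments A `mat_typing_table` from [assign_alleles()].
#' @return Named integer vector `c(n_main_types, n_alleles)`.
#' @export
count_alleles <- function(assignments) {
  if (nrow(assignments) == 0L) stop("empty assignment table")
  c(n_main_types = length(unique(assignments$main_type)),
    n_alleles = nrow(unique(assignments[, c("main_type", "allele")])))
}

#' Full mating-type typing of an alignment
#'
#' Convenience wrapper: deduplicates identical nucleotide sequences, assigns
#' main types against the references, translates, assigns amino-acid
#' alleles, and re-expands to all isolates.
#'
#' @inheritParams assign_main_types
#' @return A `mat_typing_table`.
#' @export
mat_type_alignment <- function(aln, references, max_dist = 0.03) {
  # deduplicate identical nucleotide sequences for determinism and speed
  key <- aln$seqs
  rep_idx <- which(!duplicated(key))
  rep_aln <- locus_alignment(aln$ids[rep_idx], aln$seqs[rep_idx],
                             frame = aln$frame, locus_name = aln$locus_name)
  types_rep <- assign_main_types(rep_aln, references, max_dist = max_dist)
  types <- types_rep[match(key, key[rep_idx])]
  names(types) <- aln$ids
  aa <- translate_partial(aln)
  assign_alleles(types, aa)
}

#' Write a typing table as TSV
#' @param assignments A `mat_typing_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mat_typing <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
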