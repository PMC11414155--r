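#' Construct a locus alignment
#'
#' A `locus_alignment` holds labelled, equal-length nucleotide sequences over
#' the alphabet `A, C, G, T, N, -`, the substrate of all sequence statistics
#' in the package. An optional reading-frame offset (`0`, `1` or `2`) marks
#' the first coding position for codon-based analyses.
#'
#' @param ids Character vector of unique isolate labels.
#' @param seqs Character vector of sequences, same length as `ids`.
#' @param frame Optional integer frame offset (0, 1 or 2); `NA` for
#'   non-coding use.
#' @param locus_name Name of the locus (e.g. `"MAT"`, `"PTG"`).
#' @return An object of class `locus_alignment` with elements `ids`, `seqs`,
#'   `frame` and `locus_name`.
#' @export
locus_alignment <- function(ids, seqs, frame = NA_integer_, locus_name = "locus") {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (length(ids) != length(seqs)) {
    stop("ids and seqs must have the same length")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    stop("ragged alignment: sequence lengths differ (", paste(unique(lens), collapse = ", "), ")")
  }
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    stop("illegal characters in record(s): ", paste(ids[bad], collapse = ", "))
  }
  if (!is.na(frame)) {
    frame <- as.integer(frame)
    if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
    if (length(seqs) && (lens[1] - frame) < 3) {
      stop("alignment too short for frame: fewer than one full codon")
    }
  }
  structure(
    list(ids = ids, seqs = seqs, frame = frame, locus_name = locus_name),
    class = "locus_alignment"
  )
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf(
    "locus_alignment '%s': %d sequences x %d bp (frame %s)\n",
    x$locus_name, length(x$ids), alignment_width(x),
    if (is.na(x$frame)) "unset" else x$frame
  ))
  invisible(x)
}

#' @export
length.locus_alignment <- function(x) length(x$ids)

#' Alignment width in base pairs
#' @param aln A `locus_alignment`.
#' @return Integer number of columns.
#' @export
alignment_width <- function(aln) {
  if (length(aln$seqs) == 0L) return(0L)
  nchar(aln$seqs[1])
}

#' Character matrix view of an alignment (rows = isolates)
#' @param x A `locus_alignment`.
#' @param ... Unused.
#' @export
as.matrix.locus_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

#' Subset an alignment by isolate id
#' @param aln A `locus_alignment`.
#' @param ids Isolate labels to keep, in the requested order.
#' @return A `locus_alignment` restricted to `ids`.
#' @export
subset_alignment <- function(aln, ids) {
  idx <- match(ids, aln$ids)
  if (anyNA(idx)) stop("unknown isolate id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  locus_alignment(aln$ids[idx], aln$seqs[idx], frame = aln$frame, locus_name = aln$locus_name)
}

#' Read an aligned FASTA file
#'
#' Reads an aligned (equal record length) nucleotide FASTA. Lowercase is
#' normalised to uppercase and `U` to `T`; record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param frame Optional frame offset passed to [locus_alignment()].
#' @param locus_name Locus label; defaults to the file stem.
#' @return A `locus_alignment`.
#' @export
read_alignment <- function(path, frame = NA_integer_, locus_name = NULL) {
  if (is.null(locus_name)) {
    locus_name <- sub("\\.[^.]*$", "", basename(path))
  }
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    stop("ragged alignment in ", path, ": lengths ", paste(unique(lens), collapse = ", "))
  }
  locus_alignment(ids, seqs, frame = frame, locus_name = locus_name)
}

#' Write an alignment as FASTA
#' @param aln A `locus_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  ss <- Biostrings::BStringSet(aln$seqs)
  names(ss) <- aln$ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
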