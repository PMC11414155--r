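# Fixtures built in code at test time.

write_tmp_fasta <- function(records, path = tempfile(fileext = ".fasta")) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(records)) {
    writeLines(c(paste0(">", nm), records[[nm]]), con)
  }
  path
}

# 4-isolate toy SNP matrix used for the filter-fidelity hand enumeration.
# Loci (all depth 30, support 1 unless stated):
#  s1: alleles 1,1,0,0            -> mac 2, keeps
#  s2: alleles 1,0,0,0            -> mac 1, dropped (allele count)
#  s3: alleles 1,1,1,1            -> mac 0, dropped (allele count)
#  s4: alleles 1,0,1,0 but iso1 depth 9 -> cell masked; mac over rest = 1 -> dropped
#  s5: alleles 1,0,1,0 but iso1 support 0.8 (not > 0.8) -> masked; mac 1 -> dropped
#  s6: alleles 0,1,0,1, inside excluded region -> dropped (region)
#  s7: alleles 0,1,1,0            -> mac 2, keeps
# Hand enumeration: survivors = {s1, s7} -> 2 loci.
toy_filter_matrix <- function() {
  allele <- rbind(
    c(1, 1, 1, 1, 1, 0, 0),
    c(1, 0, 1, 0, 0, 1, 1),
    c(0, 0, 1, 1, 1, 0, 1),
    c(0, 0, 1, 0, 0, 1, 0)
  )
  depth <- matrix(30L, 4, 7)
  depth[1, 4] <- 9L
  support <- matrix(1, 4, 7)
  support[1, 5] <- 0.8
  loci <- data.frame(
    locus_id = paste0("s", 1:7),
    contig = "chr1",
    start = c(0, 100, 200, 300, 400, 500, 600),
    end = c(1, 101, 201, 301, 401, 501, 601)
  )
  matcongruence::snp_matrix(paste0("iso", 1:4), loci$locus_id, allele,
                            depth = depth, support = support, loci = loci)
}

toy_filter_excluded_region <- function() {
  data.frame(contig = "chr1", start = 450, end = 550)
}

# Deterministic small coding alignment with both synonymous and
# non-synonymous divergence (no stops).
toy_coding_alignment <- function() {
  matcongruence::locus_alignment(
    c("q1", "q2", "q3", "q4"),
    c("ATGGCTTTAGGTCAT",
      "ATGGCCTTAGGTCAT",   # syn change in codon 2 (GCT->GCC, Ala)
      "ATGGATTTAGGTCAT",   # nonsyn in codon 2 (Ala->Asp)
      "ATGGCTTTGGGTCAT"),  # syn in codon 3 (TTA->TTG, Leu)
    frame = 0L, locus_name = "toy"
  )
}
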