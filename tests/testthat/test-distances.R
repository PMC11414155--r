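test_that("pair_counts classifies transitions, transversions and deletion", {
  pc <- pair_counts("ACGT", "ACGT")
  expect_equal(pc$usable_sites, 4L)
  expect_equal(pc$P_count, 0L)
  expect_equal(pc$Q_count, 0L)
  pc <- pair_counts("ACGT", "GCGT")
  expect_equal(pc$P_count, 1L)  # A<->G transition
  expect_equal(pc$Q_count, 0L)
  pc <- pair_counts("ACGT", "CCGT")
  expect_equal(pc$Q_count, 1L)  # A<->C transversion
  pc <- pair_counts("AC-T", "ACGT")
  expect_equal(pc$usable_sites, 3L)
  pc <- pair_counts("ACNT", "ACGT")
  expect_equal(pc$usable_sites, 3L)
  expect_error(pair_counts("----", "ACGT"), "no comparable sites")
  # pooled GC fraction
  pc <- pair_counts("GGCC", "AATT")
  expect_equal(pc$gc_fraction, 0.5)
})

test_that("tamura3p matches the closed form and its oracle example", {
  # 100-site pair: 10 transitions, 5 transversions, pooled GC 0.5
  # direct evaluation: d = -0.5 log(0.75) - 0.25 log(0.9) ~= 0.17018
  expect_equal(oracle_tamura3p(0.1, 0.05, 0.5), 0.1701812, tolerance = 1e-6)
  # build an actual sequence pair with exactly those counts, GC-balanced:
  # 5 A->G and 5 G->A transitions cancel in GC; C->G transversions are neutral
  a <- paste0(c(rep("A", 25), rep("G", 25), rep("C", 25), rep("T", 25)), collapse = "")
  b_vec <- strsplit(a, "")[[1]]
  b_vec[1:5] <- "G"     # 5 A->G transitions
  b_vec[26:30] <- "A"   # 5 G->A transitions
  b_vec[51:55] <- "G"   # 5 C->G transversions
  b <- paste0(b_vec, collapse = "")
  pc <- pair_counts(a, b)
  expect_equal(pc$P_count, 10L)
  expect_equal(pc$Q_count, 5L)
  expect_equal(pc$gc_fraction, 0.5)
  expect_equal(tamura3p(a, b), 0.1701812, tolerance = 1e-6)
  expect_equal(tamura3p(a, a), 0)
})

test_that("tamura3p agrees with an independent implementation and dominates p-distance", {
  set.seed(31)
  for (rep in 1:20) {
    L <- 300
    a <- sample(c("A", "C", "G", "T"), L, TRUE)
    b <- a
    mut <- sample(L, 12)
    b[mut] <- vapply(b[mut], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1),
                     character(1))
    sa <- paste0(a, collapse = ""); sb <- paste0(b, collapse = "")
    d <- tamura3p(sa, sb)
    pc <- pair_counts(sa, sb)
    expect_equal(d, oracle_tamura3p(pc$P_count / L, pc$Q_count / L, pc$gc_fraction),
                 tolerance = 1e-12)
    p <- (pc$P_count + pc$Q_count) / L
    expect_gte(d, p)  # correction inflates observed differences
  }
  # cross-check against ape's T92 distance on a two-sequence alignment,
  # where ape's alignment-wide GC equals the pooled pair GC
  aln <- matrix(c(strsplit("ACGTTGCAACGGTACCGTAT", "")[[1]],
                  strsplit("ACATTGCAACGGTGCCGTTT", "")[[1]]),
                nrow = 2, byrow = TRUE)
  rownames(aln) <- c("x", "y")
  ape_d <- as.numeric(ape::dist.dna(ape::as.DNAbin(tolower(aln)), model = "T92"))
  expect_equal(tamura3p(paste0(aln[1, ], collapse = ""), paste0(aln[2, ], collapse = "")),
               ape_d, tolerance = 1e-9)
})

test_that("tamura3p increases strictly in P at fixed Q and theta", {
  ds <- vapply(seq(0.01, 0.3, by = 0.01),
               function(P) oracle_tamura3p(P, 0.05, 0.4), numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("saturated pairs abort with labelled errors", {
  a <- paste0(rep("A", 50), collapse = "")
  g <- paste0(rep("G", 50), collapse = "")
  expect_error(tamura3p(a, g), "saturated")
  aln <- locus_alignment(c("s1", "s2", "s3"), c(a, g, a))
  expect_error(alignment_distance_matrix(aln), "s1/s2")
})

test_that("alignment distance matrices are symmetric with per-pair values", {
  sim <- make_fixture("tiny", seed = 21)
  aln <- sim$mat_alignment
  d <- alignment_distance_matrix(aln)
  expect_s3_class(d, "dist_matrix")
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(unclass(d)[i, j], tamura3p(aln$seqs[i], aln$seqs[j]))
  }
  # an all-gap column changes nothing versus removing it
  seqs <- c("AC-TA", "AC-TT", "GC-TA")
  d1 <- alignment_distance_matrix(locus_alignment(c("a", "b", "c"), seqs))
  d2 <- alignment_distance_matrix(locus_alignment(c("a", "b", "c"), sub("-", "", seqs)))
  expect_equal(unclass(d1), unclass(d2))
})

test_that("SNP filtering applies genotype and locus rules per hand enumeration", {
  m <- toy_filter_matrix()
  f <- suppressMessages(filter_snp_matrix(
    m, min_depth = 10, min_support = 0.8,
    exclude_regions = toy_filter_excluded_region(), min_allele_count = 2))
  expect_setequal(f$locus_ids, c("s1", "s7"))
  # threshold boundaries: depth 9 < 10 masks, depth 10 keeps;
  # support 0.8 masks (strict), 0.81 keeps
  m2 <- snp_matrix(c("a", "b", "c"), c("l1", "l2"),
                   rbind(c(1L, 1L), c(0L, 0L), c(1L, 1L)),
                   depth = rbind(c(9L, 10L), c(30L, 30L), c(30L, 30L)),
                   support = rbind(c(1, 1), c(0.8, 0.81), c(1, 1)))
  f2 <- suppressMessages(filter_snp_matrix(m2, min_allele_count = 0))
  expect_true(is.na(f2$allele["a", "l1"]))
  expect_false(is.na(f2$allele["a", "l2"]))
  expect_true(is.na(f2$allele["b", "l1"]))
  expect_false(is.na(f2$allele["b", "l2"]))
})

test_that("SNP filtering is idempotent", {
  m <- toy_filter_matrix()
  args <- list(min_depth = 10, min_support = 0.8,
               exclude_regions = toy_filter_excluded_region(), min_allele_count = 2)
  f1 <- suppressMessages(do.call(filter_snp_matrix, c(list(m), args)))
  f2 <- suppressMessages(do.call(filter_snp_matrix, c(list(f1), args)))
  expect_identical(f1$allele, f2$allele)
  expect_identical(f1$locus_ids, f2$locus_ids)
})

test_that("Jaccard distances follow the binary presence/absence convention", {
  m <- snp_matrix(c("i", "j"), paste0("l", 1:4),
                  rbind(c(1L, 0L, 1L, 1L), c(1L, 1L, 0L, 1L)))
  d <- jaccard_distance_matrix(m)
  expect_equal(unclass(d)["i", "j"], 0.5)  # 1 - 2/4
  m2 <- snp_matrix(c("i", "j"), c("l1", "l2"), rbind(c(1L, 1L), c(0L, 0L)))
  expect_equal(unclass(jaccard_distance_matrix(m2))["i", "j"], 1.0)
  m3 <- snp_matrix(c("i", "j"), c("l1", "l2"), rbind(c(1L, 0L), c(1L, 0L)))
  expect_equal(unclass(jaccard_distance_matrix(m3))["i", "j"], 0)
  # identical rows -> 0
  m4 <- snp_matrix(c("i", "j"), paste0("l", 1:3),
                   rbind(c(1L, 0L, 1L), c(1L, 0L, 1L)))
  expect_equal(unclass(jaccard_distance_matrix(m4))["i", "j"], 0)
  # missing handling: loci not called in both are ignored; no shared loci errors
  m5 <- snp_matrix(c("i", "j"), paste0("l", 1:3),
                   rbind(c(1L, NA, 1L), c(NA, 1L, 1L)))
  expect_equal(unclass(jaccard_distance_matrix(m5))["i", "j"], 0)
  m6 <- snp_matrix(c("i", "j"), c("l1", "l2"), rbind(c(1L, NA), c(NA, 1L)))
  expect_error(jaccard_distance_matrix(m6), "share no called loci")
})

test_that("Jaccard agrees with vegan's binary Jaccard on complete matrices", {
  set.seed(12)
  x <- matrix(rbinom(8 * 40, 1, 0.4), 8, 40)
  # ensure no all-zero pair-wise comparisons
  x[, 1] <- 1L
  m <- snp_matrix(sprintf("i%d", 1:8), sprintf("l%d", 1:40), x)
  d <- jaccard_distance_matrix(m)
  dv <- as.matrix(vegan::vegdist(x, method = "jaccard", binary = TRUE))
  expect_equal(unname(unclass(d)), unname(dv), tolerance = 1e-12)
})
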