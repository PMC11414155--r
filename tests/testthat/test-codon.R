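test_that("codon site counts match exhaustive enumeration for all sense codons", {
  for (codon in oracle_sense_codons) {
    s <- codon_sites(codon)
    expect_equal(unname(s["syn_sites"]), oracle_codon_sites(codon),
                 tolerance = 1e-9, label = codon)
    expect_equal(unname(sum(s)), 3, tolerance = 1e-12)
  }
  expect_equal(unname(codon_sites("TTT")["syn_sites"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(codon_sites("TTA")["syn_sites"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(codon_sites("ATG")["syn_sites"]), 0)
  expect_error(codon_sites("TAA"), "stop")
  expect_error(codon_sites("TXT"), "not a valid codon")
})

test_that("pathway-averaged difference counts match the enumeration oracle on all sense pairs", {
  pairs <- expand.grid(a = oracle_sense_codons, b = oracle_sense_codons,
                       stringsAsFactors = FALSE)
  # identical padding codons keep the pair below Jukes-Cantor saturation
  # without touching the difference counts of the codon under test
  pad <- paste(rep("GGA", 8), collapse = "")
  got_nd <- got_sd <- want_nd <- want_sd <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    res <- nei_gojobori_pair(paste0(pairs$a[k], pad), paste0(pairs$b[k], pad))
    orc <- oracle_codon_path_counts(pairs$a[k], pairs$b[k])
    got_nd[k] <- res$nd; got_sd[k] <- res$sd
    want_nd[k] <- orc["nd"]; want_sd[k] <- orc["sd"]
  }
  expect_false(anyNA(want_nd))  # every sense pair has a stop-free pathway
  expect_equal(got_nd, want_nd, tolerance = 1e-9)
  expect_equal(got_sd, want_sd, tolerance = 1e-9)
})

test_that("nei_gojobori_pair reproduces the worked single-codon example", {
  res <- nei_gojobori_pair("TTT", "TTA")
  expect_equal(res$nd, 1)
  expect_equal(res$sd, 0)
  expect_equal(res$S, 0.5)
  expect_equal(res$N, 2.5)
  expect_equal(res$pN, 0.4)
  expect_equal(res$dN, -0.75 * log(1 - 4 * 0.4 / 3), tolerance = 1e-9)
  expect_equal(res$dN, 0.5716, tolerance = 1e-4)
  expect_equal(res$dS, 0)
  # identity
  res0 <- nei_gojobori_pair("TTTAAA", "TTTAAA")
  expect_equal(c(res0$pN, res0$pS, res0$dN, res0$dS), c(0, 0, 0, 0))
  # purely synonymous third-position change (glycine padding keeps pS
  # below Jukes-Cantor saturation)
  res_s <- nei_gojobori_pair("GGAGGATTA", "GGAGGATTG")
  expect_equal(res_s$dN, 0)
  expect_gt(res_s$dS, 0)
})

test_that("gap/N codons are excluded pairwise and stops are rejected", {
  res <- nei_gojobori_pair("ATG-TTTTA", "ATGCTTTTA")
  expect_equal(res$N + res$S, 6)  # only codons 1 and 3 usable
  res_n <- nei_gojobori_pair("ATGNTTTTA", "ATGCTTTTA")
  expect_equal(res_n$N + res_n$S, 6)
  expect_error(nei_gojobori_pair("TAATTT", "TAATTC"), "internal stop")
  # saturation
  expect_error(nei_gojobori_pair(
    paste(rep("GCT", 20), collapse = ""),
    paste(rep("CGA", 20), collapse = "")), "saturated")
})

test_that("pairwise nd/sd on random multi-codon sequences match a from-scratch sum", {
  set.seed(77)
  for (rep in 1:30) {
    n_cod <- sample(3:8, 1)
    pad <- rep("GGA", 8)  # identical padding avoids Jukes-Cantor saturation
    a <- paste(c(sample(oracle_sense_codons, n_cod, TRUE), pad), collapse = "")
    b <- paste(c(sample(oracle_sense_codons, n_cod, TRUE), pad), collapse = "")
    n_cod <- n_cod + 8L
    res <- nei_gojobori_pair(a, b)
    cods_a <- substring(a, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
    cods_b <- substring(b, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
    nd_sum <- 0; sd_sum <- 0; s_sites <- 0
    for (k in seq_len(n_cod)) {
      counts <- oracle_codon_path_counts(cods_a[k], cods_b[k])
      nd_sum <- nd_sum + counts["nd"]
      sd_sum <- sd_sum + counts["sd"]
      s_sites <- s_sites + (oracle_codon_sites(cods_a[k]) + oracle_codon_sites(cods_b[k])) / 2
    }
    expect_equal(res$nd, unname(nd_sum), tolerance = 1e-9)
    expect_equal(res$sd, unname(sd_sum), tolerance = 1e-9)
    expect_equal(res$S, unname(s_sites), tolerance = 1e-9)
    expect_equal(res$N, 3 * n_cod - unname(s_sites), tolerance = 1e-9)
  }
})

test_that("Z statistic follows the printed formula and is seed-reproducible", {
  # arithmetic of the formula: dN - dS = -0.05, Var sum = 4.41e-4 -> Z ~= -2.381
  expect_equal(-0.05 / sqrt(4.41e-4), -2.380952, tolerance = 1e-6)
  aln <- toy_coding_alignment()
  r1 <- codon_selection_test(aln, n_boot = 199, seed = 42)
  r2 <- codon_selection_test(aln, n_boot = 199, seed = 42)
  expect_identical(r1$Z, r2$Z)
  expect_identical(r1$var_dN, r2$var_dN)
  r3 <- codon_selection_test(aln, n_boot = 199, seed = 43)
  expect_false(identical(r1$var_dN, r3$var_dN))
  expect_true(r1$var_dN >= 0 && r1$var_dS >= 0)
  if (r1$z_defined) {
    expect_equal(r1$Z, (r1$dN - r1$dS) / sqrt(r1$var_dN + r1$var_dS))
    expect_equal(r1$p_purifying, pnorm(r1$Z))
    expect_equal(r1$p_positive, pnorm(r1$Z, lower.tail = FALSE))
  }
})

test_that("identical alignments give a flagged undefined Z", {
  aln <- locus_alignment(c("a", "b", "c"), rep("ATGGCTTTA", 3), frame = 0)
  r <- codon_selection_test(aln, n_boot = 99, seed = 1)
  expect_equal(r$dN, 0)
  expect_equal(r$dS, 0)
  expect_false(r$z_defined)
  expect_true(is.na(r$Z))
})

test_that("observed dN/dS equal the mean over pairwise nei_gojobori_pair values", {
  aln <- toy_coding_alignment()
  r <- codon_selection_test(aln, n_boot = 49, seed = 1)
  combs <- combn(length(aln$ids), 2)
  dns <- apply(combs, 2, function(ij) {
    p <- nei_gojobori_pair(aln$seqs[ij[1]], aln$seqs[ij[2]])
    c(p$dN, p$dS)
  })
  expect_equal(r$dN, mean(dns[1, ]), tolerance = 1e-12)
  expect_equal(r$dS, mean(dns[2, ]), tolerance = 1e-12)
})

test_that("bootstrap variance shrinks with alignment length on simulated data", {
  var_sums <- vapply(c(12, 96), function(n_cod) {
    sim <- simulate_population(sim_config(
      mode = "clonal", N = 60, generations = 150, mat_codons = n_cod,
      ptg_codons = 2, n_snps = 2, mu_coding = 1e-3, mu_snp = 0,
      sample_n = 10, seed = 7))
    r <- codon_selection_test(sim$mat_alignment, n_boot = 199, seed = 3)
    r$var_dN + r$var_dS
  }, numeric(1))
  expect_lt(var_sums[2], var_sums[1])
})
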