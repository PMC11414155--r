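#' Configuration of a clonal-or-sexual haploid population simulation
#'
#' Parameterises a discrete-generation haploid Wright-Fisher population in
#' which each individual carries a mating-type-like coding locus (MAT), a
#' second unrelated coding locus (PTG) and a vector of unlinked neutral
#' biallelic SNP loci. Defaults give the study-scale conditions used
#' throughout the package: locus sizes matching a 261 bp partial MAT
#' amplicon and a 639 bp PTG CDS, thousands of SNPs, and a purifying-
#' selection strength (`omega`) well below 1.
#'
#' @param mode `"clonal"` or `"sexual"`.
#' @param N Population size (haploid individuals, >= 2).
#' @param generations Number of generations.
#' @param mat_codons,ptg_codons Codon counts of the two coding loci.
#' @param n_snps Number of unlinked neutral biallelic loci.
#' @param mu_coding Per-base per-generation mutation probability at coding
#'   loci.
#' @param mu_snp Per-locus per-generation 0<->1 flip probability.
#' @param omega Acceptance probability for non-synonymous coding mutations
#'   in (0, 1]; synonymous changes are always accepted and premature stops
#'   always rejected, so realised dN/dS < 1 when `omega < 1`.
#' @param sample_n Number of distinct individuals sampled at the final
#'   generation.
#' @param seed Integer seed; identical configs give bit-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(mode = c("clonal", "sexual"), N = 200, generations = 500,
                       mat_codons = 87, ptg_codons = 213, n_snps = 2000,
                       mu_coding = 1e-4, mu_snp = 5e-4, omega = 0.3,
                       sample_n = 20, seed = 1L) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, N = as.integer(N), generations = as.integer(generations),
              mat_codons = as.integer(mat_codons), ptg_codons = as.integer(ptg_codons),
              n_snps = as.integer(n_snps), mu_coding = mu_coding, mu_snp = mu_snp,
              omega = omega, sample_n = as.integer(sample_n), seed = as.integer(seed))
  if (cfg$N < 2L) stop("N must be >= 2")
  if (cfg$sample_n > cfg$N) stop("sample_n must be <= N")
  if (cfg$sample_n < 1L || cfg$generations < 0L) stop("invalid sample_n or generations")
  rates <- c(cfg$mu_coding, cfg$mu_snp)
  if (any(rates < 0 | rates > 1)) stop("mutation rates must lie in [0, 1]")
  if (cfg$omega <= 0 || cfg$omega > 1) stop("omega must lie in (0, 1]")
  if (cfg$mat_codons < 1L || cfg$ptg_codons < 1L || cfg$n_snps < 1L) {
    stop("locus sizes must be positive")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Random stop-free coding sequence (integer bases) of n_codons codons.
random_cds_ints <- function(n_codons) {
  gc_init()
  sense <- which(!.gc$is_stop)
  ci <- sample(sense, n_codons, replace = TRUE)
  as.vector(t(.gc$base_idx[ci, , drop = FALSE]))
}

# Apply coding mutations in place. events: matrix (ind, site). Proposes a
# uniform random different base; rejects premature stops always and
# non-synonymous changes with probability 1 - omega.
apply_coding_mutations <- function(pop, events, omega) {
  for (k in seq_len(nrow(events))) {
    ind <- events[k, 1]; site <- events[k, 2]
    cod_start <- site - (site - 1L) %% 3L
    old_codon <- pop[ind, cod_start:(cod_start + 2L)]
    old_idx <- codon_to_index(old_codon[1], old_codon[2], old_codon[3])
    new_base <- sample(setdiff(1:4, pop[ind, site]), 1L)
    new_codon <- old_codon
    new_codon[(site - cod_start) + 1L] <- new_base
    new_idx <- codon_to_index(new_codon[1], new_codon[2], new_codon[3])
    if (.gc$is_stop[new_idx]) next
    if (.gc$aa[new_idx] != .gc$aa[old_idx] && stats::runif(1) >= omega) next
    pop[ind, site] <- new_base
  }
  pop
}

#' Simulate a clonal or sexual haploid multilocus population
#'
#' Discrete-generation haploid Wright-Fisher simulation. Each generation,
#' children are drawn and then mutated. Under clonal reproduction each child
#' copies one uniformly chosen parent. Under sexual reproduction each child
#' draws two parents whose MAT haplotypes differ at >= 1 nucleotide
#' (rejection sampling; generations in which the population is monomorphic
#' at MAT fall back to clonal reproduction and are counted), then inherits
#' the MAT locus from one parent by fair coin, the PTG locus independently
#' by fair coin, and every SNP locus independently by fair coin (free
#' recombination). Coding mutations propose a uniform different base and are
#' rejected if they create a premature stop, or with probability
#' `1 - omega` if non-synonymous. SNP loci flip 0<->1 with probability
#' `mu_snp` per generation. The initial population is monomorphic (one
#' random stop-free ancestor), so all diversity traces to in-run mutation.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_output`: list with `mat_alignment` and
#'   `ptg_alignment` (`locus_alignment`, frame 0), `snp_matrix`
#'   (`snp_matrix` with constant depth 30 and support 1), `truth` (data
#'   frame: isolate_id, species, origin, mat_haplotype id), `genealogy`
#'   (per-generation parent indices of the whole population), `config` and
#'   `clonal_fallback_generations` (count, sexual mode only).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gc_init()
  set.seed(config$seed)
  N <- config$N
  L_mat <- 3L * config$mat_codons
  L_ptg <- 3L * config$ptg_codons
  S <- config$n_snps
  mat <- matrix(rep(random_cds_ints(config$mat_codons), each = N), N, L_mat)
  ptg <- matrix(rep(random_cds_ints(config$ptg_codons), each = N), N, L_ptg)
  snp <- matrix(0L, N, S)
  mat_key <- rep(paste0(mat[1, ], collapse = ""), N)  # MAT haplotype keys
  fallback <- 0L
  genealogy <- vector("list", config$generations)
  for (g in seq_len(config$generations)) {
    if (config$mode == "clonal") {
      par <- sample.int(N, N, replace = TRUE)
      mat <- mat[par, , drop = FALSE]
      ptg <- ptg[par, , drop = FALSE]
      snp <- snp[par, , drop = FALSE]
      mat_key <- mat_key[par]
      genealogy[[g]] <- cbind(p1 = par, p2 = par)
    } else {
      if (length(unique(mat_key)) < 2L) {
        fallback <- fallback + 1L
        par <- sample.int(N, N, replace = TRUE)
        mat <- mat[par, , drop = FALSE]
        ptg <- ptg[par, , drop = FALSE]
        snp <- snp[par, , drop = FALSE]
        mat_key <- mat_key[par]
        genealogy[[g]] <- cbind(p1 = par, p2 = par)
      } else {
        p1 <- sample.int(N, N, replace = TRUE)
        p2 <- sample.int(N, N, replace = TRUE)
        tries <- 0L
        repeat {
          bad <- mat_key[p1] == mat_key[p2]
          if (!any(bad) || tries >= 10000L) break
          p1[bad] <- sample.int(N, sum(bad), replace = TRUE)
          p2[bad] <- sample.int(N, sum(bad), replace = TRUE)
          tries <- tries + 1L
        }
        mat_from_1 <- stats::runif(N) < 0.5
        mat_parent <- ifelse(mat_from_1, p1, p2)
        ptg_parent <- ifelse(stats::runif(N) < 0.5, p1, p2)
        mat <- mat[mat_parent, , drop = FALSE]
        mat_key <- mat_key[mat_parent]
        ptg <- ptg[ptg_parent, , drop = FALSE]
        snp_new <- snp[p1, , drop = FALSE]
        pick2 <- matrix(stats::runif(N * S) < 0.5, N, S)
        from2 <- snp[p2, , drop = FALSE]
        snp_new[pick2] <- from2[pick2]
        snp <- snp_new
        genealogy[[g]] <- cbind(p1 = p1, p2 = p2)
      }
    }
    # coding mutations (count ~ Binomial, positions uniform without
    # replacement: exactly the iid per-base Bernoulli process)
    for (locus in c("mat", "ptg")) {
      L <- if (locus == "mat") L_mat else L_ptg
      n_mut <- stats::rbinom(1L, N * L, config$mu_coding)
      if (n_mut > 0L) {
        cells <- sample.int(N * L, n_mut)
        ev <- cbind((cells - 1L) %% N + 1L, (cells - 1L) %/% N + 1L)
        if (locus == "mat") {
          inds <- unique(ev[, 1])
          before <- mat[inds, , drop = FALSE]
          mat <- apply_coding_mutations(mat, ev, config$omega)
          after <- mat[inds, , drop = FALSE]
          changed <- inds[rowSums(before != after) > 0]
          # keys are the sequences themselves, so identity is exact even
          # under back-mutation
          for (ind in changed) {
            mat_key[ind] <- paste0(mat[ind, ], collapse = "")
          }
        } else {
          ptg <- apply_coding_mutations(ptg, ev, config$omega)
        }
      }
    }
    n_flip <- stats::rbinom(1L, N * S, config$mu_snp)
    if (n_flip > 0L) {
      cells <- sample.int(N * S, n_flip)
      snp[cells] <- 1L - snp[cells]
    }
  }
  final_key <- match(mat_key, unique(mat_key))
  sampled <- sample.int(N, config$sample_n)
  ids <- sprintf("iso%02d", seq_len(config$sample_n))
  ints_to_seq <- function(m) apply(m, 1L, function(r) paste0(gc_bases[r], collapse = ""))
  mat_aln <- locus_alignment(ids, ints_to_seq(mat[sampled, , drop = FALSE]),
                             frame = 0L, locus_name = "MAT")
  ptg_aln <- locus_alignment(ids, ints_to_seq(ptg[sampled, , drop = FALSE]),
                             frame = 0L, locus_name = "PTG")
  loci <- data.frame(
    locus_id = sprintf("snp%05d", seq_len(S)),
    contig = "sim_genome",
    start = 100L * (seq_len(S) - 1L),
    end = 100L * (seq_len(S) - 1L) + 1L
  )
  snp_m <- snp_matrix(ids, loci$locus_id, snp[sampled, , drop = FALSE],
                      depth = matrix(30L, config$sample_n, S),
                      support = matrix(1, config$sample_n, S),
                      loci = loci)
  truth <- data.frame(
    isolate_id = ids,
    species = "simulated",
    origin = "in_silico",
    mat_haplotype = paste0("hap", final_key[sampled]),
    population_index = sampled
  )
  structure(
    list(mat_alignment = mat_aln, ptg_alignment = ptg_aln, snp_matrix = snp_m,
         truth = truth, genealogy = genealogy, config = config,
         clonal_fallback_generations = fallback),
    class = "sim_output"
  )
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf(
    "sim_output (%s): %d isolates sampled from N = %d after %d generations\n",
    x$config$mode, x$config$sample_n, x$config$N, x$config$generations))
  if (x$config$mode == "sexual" && x$clonal_fallback_generations > 0L) {
    cat(sprintf("  %d generation(s) fell back to clonal reproduction (MAT monomorphic)\n",
                x$clonal_fallback_generations))
  }
  invisible(x)
}

#' Write a simulation's three datasets plus truth table to a directory
#'
#' @param sim A `sim_output`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Files: `mat.fasta`, `ptg.fasta`,
#'   `snp_matrix.tsv`, `truth.tsv`.
#' @export
write_sim_output <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_alignment(sim$mat_alignment, file.path(dir, "mat.fasta"))
  write_alignment(sim$ptg_alignment, file.path(dir, "ptg.fasta"))
  write_snp_matrix(sim$snp_matrix, file.path(dir, "snp_matrix.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Generate a named simulation fixture
#'
#' `"tiny"` is a fast unit-test fixture (6 isolates, 30 SNPs, 10-codon
#' loci); `"paper_like"` mirrors the shape of a 27-homokaryon study with
#' ~2000 SNP loci and default-size coding loci.
#'
#' @param name `"tiny"` or `"paper_like"`.
#' @param seed Integer seed.
#' @param mode `"clonal"` (default) or `"sexual"`.
#' @param dir Optional directory; when given, the three datasets are written
#'   there via [write_sim_output()].
#' @return The `sim_output`, invisibly when `dir` is given.
#' @export
make_fixture <- function(name = c("tiny", "paper_like"), seed = 1L,
                         mode = "clonal", dir = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = sim_config(mode = mode, N = 30, generations = 120, mat_codons = 10,
                      ptg_codons = 10, n_snps = 30, mu_coding = 2e-3,
                      mu_snp = 2e-3, omega = 0.3, sample_n = 6, seed = seed),
    paper_like = sim_config(mode = mode, N = 200, generations = 500,
                            sample_n = 27, seed = seed)
  )
  sim <- simulate_population(cfg)
  if (!is.null(dir)) {
    write_sim_output(sim, dir)
    return(invisible(sim))
  }
  sim
}
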