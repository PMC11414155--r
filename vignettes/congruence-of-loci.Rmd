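---
title: "Testing clonality by congruence of loci: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing clonality by congruence of loci: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matcongruence)
```

## The question and the inferential logic

Arbuscular mycorrhizal fungi such as *Rhizophagus irregularis* carry a
putative mating-type (MAT) locus, yet whether the lineage actually
reproduces sexually is contested. The test implemented here rests on a
simple population-genetic contrast. In a strictly clonal haploid lineage,
every locus is transmitted together, so the genealogy of the MAT locus, of
any arbitrary gene (here a phosphate transporter gene, PTG), and of
genome-wide SNPs is one and the same; pairwise divergence measured at the
three data sources must then be *congruent*. Under sexual reproduction with
recombination and independent reassortment, unlinked loci have decoupled
genealogies and no such congruence is expected.

The package turns that contrast into a pipeline: per-locus distance
matrices, a genome-wide Jaccard distance on filtered SNPs, three pairwise
Mantel tests (plus Baker's gamma on Ward dendrograms and a one-factor
PERMANOVA), codon-level selection and codon-usage analyses for the two
coding loci, mating-type/allele assignment, and a final verdict:
`congruent-clonal-like` when all three pairwise congruence tests are
significant at `alpha` (default 0.05), `decoupled-sexual-like` when none
is, `mixed` otherwise. The all-or-none rule deliberately refuses to
over-claim on partial evidence.

## Distances

**Tamura 3-parameter.** For a sequence pair, with transition proportion
$P$, transversion proportion $Q$ over the usable sites, pooled G+C fraction
$\theta$ and $h = 2\theta(1-\theta)$:

$$d = -h \log\!\big(1 - P/h - Q\big) - \tfrac12 (1-h) \log\!\big(1 - 2Q\big).$$

$\theta$ is pooled over the *pair* (not the whole alignment) so each pair
is self-contained. Columns with a gap or `N` in either sequence are removed
for that pair only (pairwise deletion; whether complete deletion would be
preferable is not decidable from the data the method consumes, and pairwise
deletion wastes none of a short amplicon). A pair whose log arguments are
non-positive is *saturated*; the package aborts with the pair labels rather
than clamping, because a silently truncated distance would corrupt every
downstream Mantel input.

**SNP filtering.** Genotype calls need at least 10 reads (inclusive) and
strictly more than 80% read support, mirroring the usual ddRAD practice of
"at least 10 reads" and "more than 80%". Loci overlapping the MAT or PTG
regions are excluded before genome-wide distances are computed, so
divergence at the two focal genes cannot leak into the genome-wide matrix
they are being compared against. A minor-allele count of 2 and a maximum
observed heterozygosity of 0 reproduce the conventional haploid SNP-calling
thresholds; the heterozygosity rule is a structural no-op for single-call
haploid genotypes and exists for multi-call inputs. The filter is
idempotent, and genepop input (which carries no depth/support metadata)
downgrades the two genotype-level rules to logged no-ops.

**Jaccard.** For isolates $i, j$ over loci called in both, with $a$ loci
sharing allele 1 and $b + c$ loci where exactly one carries it,
$d = (b+c)/(a+b+c)$. Shared absence is non-informative, the standard
binary convention for presence/absence data.

## Congruence tests

**Mantel.** Pearson correlation of the $n(n-1)/2$ upper-triangle entries
after restriction to the shared label set, with the null generated by
jointly permuting rows and columns of one matrix. The p-value is one-tailed
for *positive* association — the direction genealogical coupling predicts —
and uses the $(1 + \#\{r^\ast \ge r\})/(1 + n_\mathrm{perm})$ estimator, so
it can never be zero. The default 9999 permutations resolve p-values below
$10^{-3}$; Baker's gamma defaults to 1000 permutations and PERMANOVA to
999. A Pearson correlation with its parametric t-test is reported alongside
as a descriptive companion, never instead of the permutation test, because
distance-pair entries are not independent observations.

**Ward dendrograms and Baker's gamma.** Dendrograms use the Ward.D2
convention (Lance–Williams updates on squared dissimilarities, heights on
the distance scale); labels are sorted before clustering so equal-cost
merges break lexicographically and deterministically. Baker's gamma is the
Spearman correlation of pairwise merge depths (the number of clusters at
which a leaf pair first co-clusters), with a two-sided permutation null
from relabelling one tree's leaves. Which Ward flavour and which
correlation flavour the classical tools apply differs between
implementations; both choices here are explicit and recorded in every
result object.

**PERMANOVA.** Anderson's one-factor formulation:
$SS_\mathrm{total} = \sum d^2 / n$ over all pairs, the within-group
analogue per group, and pseudo-$F = (SS_B/(a-1)) / (SS_W/(n-a))$, with
group labels permuted. The implementation is cross-checked in the test
suite against `vegan::adonis2`.

## Codon evolution

**Nei–Gojobori.** Synonymous sites of a codon are, per position, the
fraction of non-stop single-base mutants preserving the amino acid;
non-synonymous sites are the complement to 3. Differences between two
codons are averaged with equal weight over every minimal mutational
pathway that avoids stop codons (the unweighted original method — the
transition/transversion-biased modification is deliberately out of scope).
Proportions are Jukes–Cantor corrected,
$d = -\tfrac34\log(1 - \tfrac43 p)$, and a proportion at or beyond $3/4$
aborts as saturated. Sites and differences are summed over codon columns
before the ratio is taken, then Jukes–Cantor corrected per pair, and dN and
dS are averaged over all unordered sequence pairs.

**The Z-test.** $Z = (d_N - d_S) / \sqrt{\mathrm{Var}(d_N) +
\mathrm{Var}(d_S)}$, with variances from a bootstrap over codon *columns*
(999 replicates by default): columns are resampled with replacement, the
pair-averaged $d_N, d_S$ recomputed per replicate, and sample variances
taken. Both one-tailed p-values (positive selection, purifying selection)
are reported against the standard normal. When an alignment is invariant
the variance sum is zero and Z is flagged undefined rather than infinite.
Within bootstrap replicates a saturated pair yields `NA` and is dropped
from that replicate's pair average; the observed statistic never silently
tolerates saturation.

**CAI and eCAI.** Relative adaptiveness $w$ is each codon's count divided
by the maximum within its synonymous family, from a pooled reference CDS
collection; unobserved sense codons receive a pseudo-count of 0.5 (logged)
so the geometric mean is never annihilated. CAI is the geometric mean of
$w$ over a sequence's codons, excluding stop codons and the single-codon
families Met and Trp, which carry no codon-choice information. The
expected-CAI threshold asks whether an observed CAI could be an artefact of
amino-acid composition and nucleotide composition alone: null sequences
preserve the query's exact amino-acid sequence while drawing each codon
from its synonymous family with probability proportional to the product of
the query's overall base frequencies across the codon's three positions.
The threshold is the normal-approximation upper 95% point
($\mathrm{mean} + 1.645\,\mathrm{sd}$) of the null CAI distribution — the
behaviour of the classical eCAI tool — with the empirical 95th percentile
reported alongside for transparency; fewer than 30 null draws is refused.

## Mating-type and allele assignment

Queries are typed by their nearest reference under p-distance when within
`max_dist` (default 0.03); ties break toward the lexicographically smaller
type label and are logged. Queries beyond the threshold from all references
are single-linkage clustered among themselves at the same threshold and
become novel types, which is how a previously unreported mating type
surfaces. Within a type, alleles are groups of identical *amino-acid*
sequence — synonymous divergence never splits an allele — numbered by
decreasing group size then lexicographic representative. The 0.03 default
is a pragmatic proxy for the posterior-probability clustering a Bayesian
phylogeny would provide (tree inference is out of scope here); it is
surfaced in every report precisely because reproducing a particular
published type count may require adjusting it. Identical nucleotide
sequences are deduplicated before typing and re-expanded afterwards, making
assignment order-invariant and fast.

## The simulator

`simulate_population()` is a discrete-generation haploid Wright–Fisher
model whose individuals carry a MAT coding locus (default 87 codons,
matching a 261 bp partial amplicon), a PTG coding locus (213 codons,
639 bp) and `n_snps` (default 2000) unlinked neutral biallelic loci.
Defaults — `N = 200`, 500 generations, `mu_coding = 1e-4`,
`mu_snp = 5e-4`, `omega = 0.3`, 20 isolates sampled — are the package's
study-scale conditions: no quantitative mutation or selection estimates
exist for these fungi, so the values are chosen once to give realistic
levels of polymorphism at desk scale (a handful of substitutions per
coding-locus pair, tens of percent SNP heterozygosity) rather than as
biological estimates.

Purifying selection is implemented as biased mutation acceptance —
non-synonymous proposals are accepted with probability `omega`, premature
stops never — which yields realised $d_N < d_S$ without a fitness
machinery the tests do not need. Clonal reproduction copies one uniform
parent per child. Sexual reproduction rejection-samples parent pairs whose
MAT haplotypes differ at one nucleotide or more (the simplest faithful
reading of MAT-based non-self recognition); each child inherits the MAT
locus by fair coin, the PTG locus by an independent coin, and every SNP
locus by independent coins (free recombination, which makes the sexual
null as sharp as possible). A generation with a MAT-monomorphic population
falls back to clonal reproduction and is counted in the output. The
initial population is a single random stop-free ancestor, so all observed
diversity traces to in-run mutation and the genealogical contrast stays
clean. Identical configurations give bit-identical output.

What the simulator does *not* emulate: read-depth noise (emitted depth is
a constant 30, support 1 — the depth/support filters are exercised by
dedicated corrupted fixtures instead), linkage between SNPs, indels,
demographic structure, dikaryosis. Passing tests on simulated data
therefore demonstrate that the statistical machinery recovers the
clonal/sexual contrast its model generates; they cannot certify behaviour
under mapping artefacts or structured sampling that real ddRAD data may
contain.

## Numerical choices and degenerate inputs

* Permutation p-values all use the `+1` estimator and are exactly
  reproducible given `seed`; every result object records its seed and
  permutation/bootstrap count.
* Saturation (Tamura or Jukes–Cantor) is an error carrying the offending
  pair labels, never a clamped value.
* A Jaccard pair with no informative loci gets distance 0 with a warning;
  a pair with no commonly called loci at all is an error.
* Ties: Ward merges and nearest-reference typing break lexicographically;
  both are deterministic under input reordering.
* The alphabet admits only `A C G T N -`; other IUPAC ambiguity codes are
  rejected at parse time because the divergence formulas are defined only
  for unambiguous bases, and `N` is treated as missing for the affected
  pair/codon.
* Alignment length is taken from the data; the MAT amplicon length is not
  hard-coded anywhere (published descriptions of the amplicon differ, and
  nothing downstream depends on the value).

## Problem sizes used by the shipped checks

The package's own validation runs at sizes a laptop handles comfortably:
scenario recovery uses 20 clonal and 20 sexual replicates at the full
default scale (N = 200, 500 generations, 2000 SNPs); the neutral
calibration of the codon Z-test uses 200 replicates at N = 100,
300 generations with the two coding loci concatenated (the pooled test);
null-calibration of the permutation tests uses 200 independent seeds with
199–200 permutations per test on 10-label matrices. These sizes are the
package's chosen trade-off between statistical resolution and run time.

## Known limitations

* The verdict is a three-way classification at a single `alpha` with no
  multiple-testing correction across the three Mantel tests (the classical
  analyses it mirrors apply none); users needing strict error control
  should interpret `mixed` conservatively.
* Nearest-reference typing with a fixed p-distance threshold is a proxy
  for phylogenetic cluster support; counts of types/alleles on real data
  are sensitive to `max_dist`.
* The parametric Pearson p-value on distances is anti-conservative by
  construction and is reported only next to its permutation counterpart.
* Maximum-likelihood dN/dS, rate heterogeneity, partial Mantel tests and
  multi-factor PERMANOVA are out of scope.
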