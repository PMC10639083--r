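---
title: "Methods: minor-intron classification, conservation and ancestral reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: minor-intron classification, conservation and ancestral reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minorintrons)
```

Minor (U12-type) introns are spliced by a dedicated machinery whose snRNAs
(U11, U12, U4atac, U6atac) recognize motifs distinct from those of the
ordinary U2-type spliceosome. This vignette documents the models and
procedures the package implements, the parameters that matter, what the
synthetic-data generators do and do not emulate, and the numerical choices
made where the design was genuinely open.

## Intron extraction

A transcriptome is built by choosing, per gene, the isoform with the largest
summed CDS length; ties fall deterministically to the lexicographically
smaller transcript id. Introns are the gaps between consecutive CDS segments
in transcription order. Introns implied only by exon features (UTR introns)
are extracted and counted in per-genome totals but carry `NA` phase and
relative position and are excluded from phase, conservation and all
comparative analyses, which are restricted to protein-coding regions.

Definitions, all forced once the segment model is fixed:

* **phase** = (cumulative preceding coding length) mod 3 — 0 between codons,
  1 or 2 after the first or second codon base;
* **relative position** = cumulative preceding coding length ÷ total coding
  length, in [0, 1];
* **termini** = first and last two intron bases on the sense strand
  (minus-strand sequences are reverse-complemented before reading them);
* introns shorter than `min_length` (default 30 nt) are discarded —
  shorter gaps are overwhelmingly annotation artifacts.

Coordinates are 1-based inclusive wherever they cross an I/O boundary (the
GFF3 convention); annotations with CDS features lacking an mRNA parent are
attached permissively to a synthetic single-isoform transcript and logged,
since such files are common in practice. An elevated fraction of CT-AC
termini — the exact reverse complement of GT-AG — indicates genes annotated
on the wrong strand, and `strand_sanity_report()` warns above 1%.

## Scoring model

The classifier is a transparent two-feature log-odds scorer with percentile
calibration, standing in for heavier splice-site classifiers at reduced
fidelity; the behavioral contract (threshold semantics, boundary-correction
flag) is what downstream curation consumes, not any particular score value.

* **Donor feature**: position weight matrices over the window −3..+8 around
  the donor site (three exonic bases and eight intronic bases, so scoring
  sequences must carry exonic context), one PWM per class, scored as
  log2-odds minor vs major.
* **Branch-point feature**: a 9-nt minor branch-point PWM scored against the
  background composition at every placement inside −40..−5 upstream of the
  acceptor; the best placement wins. The window bounds are standard practice
  for minor introns, whose branch points sit unusually close to the 3′ end.
* **Training**: PWMs use a 0.5 pseudocount. The branch-point register is
  unknown in the references, so the PWM is seeded from the most frequent
  candidate 9-mer and refined by four deterministic best-placement
  re-estimation passes — a register-anchored seed is essential, since a flat
  average over windows can converge to a shifted motif.
* **Calibration**: the minor score of a query is its percentile among the
  combined (donor + branch point) scores of the pooled training references,
  so thresholding at *t* keeps exactly the upper (100 − *t*)% of the
  calibration population. The default threshold is 90; a stricter 95 is
  warranted for genomes whose major-intron motifs drift toward minor-like
  sequences.

The packaged reference sets are synthetic — sampled from the
consensus-derived motif models at noise 0.1 — and shipped as FASTA
(`inst/extdata/synthetic_*_reference.fa`). With consensus-exact references
and consensus-exact queries the two classes separate completely (AUROC 1)
and recovery is error-free; with noisy references the percentile of a query
within its own class blurs, which is the realistic regime: scores near the
threshold are genuinely ambiguous.

**Boundary correction.** Annotated boundaries are sometimes off by a few
bases, turning a real minor intron into an apparently non-canonical one.
For introns whose termini are non-canonical (5′ not GT/GC/AT or 3′ not
AG/AC), the donor PWM is slid up to ±10 nt; if a placement reaches the
correction cutoff — the 95th percentile of the minor references' donor
scores, a deliberately conservative choice since correction fabricates
evidence — both boundaries shift by that offset (length preserved) and the
call is flagged `boundary_corrected`. The corrected fraction feeds the
curation rules below. The cutoff is configurable because the appropriate
notion of a "strong" donor motif depends on the reference set.

## Curation

Classification alone cannot distinguish a genome with a handful of true
minor introns from one with a handful of false positives. The curation rules
therefore combine three independent evidence streams: the minor-intron calls
themselves, detected minor snRNAs (an intron needs machinery to be spliced),
and BUSCO completeness (a poorly annotated genome can lack minor introns for
uninteresting reasons). The thresholds are inclusive exactly as stated in
the package documentation: presence needs corrected fraction ≤ 0.25, ≥ 3
minor calls and ≥ 2 snRNAs; absence needs ≤ 3 calls and < 2 snRNAs, or ≤ 5
calls, < 2 snRNAs, < 5 uncorrected AT-AC calls and RefSeq annotation or
BUSCO ≥ Q1 − 1.5·IQR of the species' clade; low-evidence species with minor
density ≥ 1% are forced to *uncertain*, since massive intron loss plus a few
false positives can masquerade as high minor density. Quartiles use the
type-7 (linear interpolation) definition, R's default. Whether the ≤ 3 rule
should count boundary-corrected calls is ambiguous; we count all minor
calls.

By construction presence and absence cannot both fire (they sit on opposite
sides of the two-snRNA line), and added snRNA evidence can never demote a
verdict — both properties are fuzz-tested.

## Orthology and conservation

Orthologs are reciprocal best hits (RBH): pairwise similarity searches are
consumed as 12-column tabular input filtered at E ≤ 1e-10, each query's best
subject per target species is kept (bitscore, ties to the smaller subject
id), and an undirected edge joins mutual best hits. Ortholog groups are the
maximal cliques containing exactly one gene from every requested species;
clique enumeration is delegated to igraph and checked against exhaustive
search in the tests. Restricting the search to a gene subset (e.g. minor
intron-containing genes) reproduces the corresponding subgraph of a full
run. A toy k-mer-containment scorer exists solely so synthetic end-to-end
tests need no external aligner.

Intron positions are mapped to the alignment column of the residue whose
codon they interrupt; two introns occupy the same site iff they share
column *and* phase — an intron at the same column but different phase
interrupts a different codon boundary and is a different site. Sites enter
any tally only if, for every member pair, the ten alignment columns on each
side are gap-free and ≥ 40% identical (each side separately — the strictest
reading of a local ungapped quality requirement, and configurable). Sites
too close to the alignment edge fail the filter rather than passing
vacuously.

Conservation states per site follow the scores: minor above 90, major at or
below 60 in conversion analyses, anything in (60, 90] is borderline and
excludes its site from conversion tallies, so that borderline minor introns
are not mistaken for conversions. Intron sliding is not modeled; a slid
intron is counted as a loss. Pairwise outputs follow the two conventions in
use: `N_cons`/`N_var` (sites conserved as the type vs introns of the type
whose partner position lacks it) and per-row-species shared fractions.

For non-canonical termini surveys, introns sharing sites across alignments
are clustered (connected components through hub species); termini are
tallied only from clusters with ≥ 2 members of the focal type, so an
isolated misclassified intron cannot contribute.

## Ancestral reconstruction

For sister lineages α, β and outgroup γ, introns shared by any two of the
three species are ancestral to the α–β split under negligible parallel gain.
The retained fraction in β is
$\hat P_\beta = N_{\alpha\beta\gamma}/N_{\alpha\gamma}$ (and symmetrically),
and solving $N_{\alpha\beta\gamma} = N_\Omega \hat P_\alpha \hat P_\beta
\hat P_\gamma$ gives

$$\hat N_\Omega = \frac{N_{\alpha\beta} N_{\alpha\gamma} N_{\beta\gamma}}
{N_{\alpha\beta\gamma}^2}.$$

The estimator assumes independent per-lineage retention; on simulated
three-taxon data its mean relative error is within 2% at 5000 ancestral
introns per type over retention 0.6–0.95 (tested). Counts are type-specific
and restricted to sites passing the quality filter. Combinations with
$N_{\alpha\beta\gamma} = 0$ are dropped (the estimator is undefined) rather
than scored as zero density. Estimates stay real-valued internally and are
rounded for reporting; the density chain
$\hat\rho_{minor} = 100\,\hat N_{minor}/(\hat N_{minor}+\hat N_{major})$
follows the reporting convention of carrying the rounded counts forward.
Because the aligned gene set differs between species combinations, densities
are normalized to a reference species measured in the same alignments, and
combinations are aggregated as an unweighted mean ± SEM (sample sd, n − 1)
— unweighted because each combination is one estimate of the same node, not
a sample proportional to its alignment count.

Loss decomposes against the ancestral set (present as the focal type in
both sister and outgroup): retained (same type in focal), converted (other
type) or deleted (absent). Conversion estimates are conservative: a
conversion followed by deletion is indistinguishable from a deletion.

## Statistical battery

* Two-tailed exact binomial tests use the minimum-likelihood two-tail (the
  `binom.test` convention). The 5′-bias flag requires all three criteria:
  binomial significance of 5′-half occupancy, Mann–Whitney significance of
  minor vs major positions, and a more-5′ minor median — the first two tests
  alone do not say which type is biased in which direction. Batch runs
  report uncorrected and Benjamini–Hochberg-corrected flags side by side.
  Note the composite flag is much rarer than its nominal α under the null
  (it conjoins three criteria); the calibration tests therefore check the
  component tests individually.
* Fisher exact tests are two-sided by default; the hypergeometric
  enumeration is validated exhaustively in the tests.
* Boschloo's exact unconditional test (for phase-0 fraction comparisons)
  maximizes the exact tail probability, with the Fisher p-value as test
  statistic, over a 1000-point grid of the nuisance proportion; beyond
  250,000 table cells it falls back to Fisher with an explicit method flag.
* MIG vs non-MIG comparisons exclude species with fewer than ten minor
  introns, and stratify by gene-age category (BH-corrected) when one is
  supplied.

## Expression and splicing metrics

Per-feature z-scores are computed across all samples (sample sd, n − 1) and
summarized per cell type by the mean of its replicates' z-scores; features
constant across samples have no z-score and are excluded and listed. Gene
sets are summarized by the median of the top half of z-scores (`ceiling(n/2)`
values), a statistic robust to the lower tail. Splicing efficiency per
sample is EE/(EE + mean(IE)); sample–intron pairs with fewer than five reads
on the exon–exon junction or on either intron–exon junction are excluded,
and replicates combine as a weighted mean with weight mean(IE) + EE — the
additive reading of "combining the junction supports"; a multiplicative
variant is available behind `weight_scheme = "product"` and recorded in the
output. Externally computed retention values combine with the same weights
after dropping rows flagged LowSplicing/LowCover. Paired gene-set
comparisons between cell types use the two-sided Wilcoxon signed-rank test
with BH correction across pairs; with fewer than ~6 paired genes the exact
test cannot reach conventional significance, so a minimum of 4 is enforced
and small sets should be interpreted accordingly.

## Synthetic data: what it emulates and what it does not

The generators produce every input the pipeline consumes, with planted
truth, under one explicit seed each and no global RNG state:

* `simulate_three_taxon`: independent per-lineage, per-type retention;
  conversion applies only to minor introns that survive in a lineage
  (conversion is a fate of a present intron, not a loss) and is
  unidirectional minor → major; no parallel gain. These are exactly the
  assumptions of the ancestral estimator, so the simulator doubles as its
  oracle.
* `generate_toy_genome`: one gene per contig, fully coding exons, planted
  donor/branch-point motifs per type (consensus-exact by default), both
  strands, optional deliberate wrong-strand annotation. Intron lengths
  60–120 nt and exon lengths 60–120 nt are arbitrary but realistic for
  compact genomes.
* `generate_junction_table`: junction counts are Poisson around the
  specified depth with binomial thinning by retention — the simplest model
  with the correct mean structure, so expected efficiency equals
  1 − retention.
* `generate_expression_matrix`: log-scale expression, gene baselines
  N(6, 2), sample noise N(0, 1), with the first cell type's PI genes shifted
  by log2(effect size).

None of the generators emulate substitution processes, indels, read-level
sequencing error, annotation noise beyond the planted strand errors, or
paralogy. Passing tests on these fixtures therefore demonstrate correctness
of the algorithms under their stated assumptions — planted motifs are
recovered, planted retention/conversion rates are re-estimated within
binomial error, planted effects are detected, and nulls are calibrated —
not classifier performance on real genomes, where motif degeneracy,
annotation quality and lineage-specific composition dominate.

## Problem sizes and determinism

The test suite runs the estimator-recovery property at 5000 ancestral
introns per type × 200 replicates, the loss decomposition at 2000, the
Fisher-vs-enumeration oracle exhaustively over all 2×2 tables with total
≤ 40 plus 2000 random tables up to 100, binomial enumeration exhaustively to
n = 50, and the null calibration of the positional battery over 1000
simulated species — sizes at which every stochastic check has comfortable
margins while the whole suite stays fast. All generator outputs and the
pipeline runner are byte-identical under a fixed seed; every threshold
defaults to the values documented above and is carried in a hashed,
YAML-serializable configuration object.

## Known limitations

* The scorer is deliberately simpler than SVM-based splice-site
  classifiers: no 3′SS model beyond the termini, no base-pairing
  energetics, no local GC context. Its percentile scores are
  reference-relative, not probabilities.
* Conservation calling requires all clique members to be present in an
  alignment; missing annotations shrink the usable gene set rather than
  biasing states, but reduce power.
* The ancestral estimator ignores rate heterogeneity across genes and
  assumes the three-species topology is correct; with a misidentified
  outgroup the reconstruction still describes an ancestor, just not the
  intended node.
* Boschloo's test is exact but O(n₁·n₂·grid); it is intended for the small
  counts of phase-composition comparisons.
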