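---
title: "Sequence signals of CpG-island methylation state: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence signals of CpG-island methylation state: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgisig)
```

## Scope

CpG islands (CGIs) are CpG-dense regions of a few hundred to a few thousand
base pairs found at most mammalian promoters. During oogenesis a minority of
CGIs acquire DNA methylation while the majority resist it, and several DNA
sequence features have been proposed to distinguish the two fates: regular
8–10 bp CpG spacing (the geometry of the two active sites of the
Dnmt3a/Dnmt3l de novo methyltransferase complex), short sequence motifs
recognised by DNA-binding proteins, G-skew as a proxy for R-loop formation
potential, and the position of the CGI relative to transcription units.
`cgisig` implements the statistical machinery needed to interrogate these
hypotheses on any set of CGI sequences and annotations:

1. dinucleotide-frequency-invariant shuffling and empirical permutation
   nulls (`dinuc_shuffle`, `empirical_null`, `empirical_p`);
2. CpG-pair spacing profiles and range-enrichment tests (`obs_exp_profile`,
   `range_enrichment_test`, `category_average_profile`);
3. IUPAC motif scanning with presence/density statistics and two
   composition controls (`scan_motif`, `motif_stats`, `shuffle_reduction`,
   `local_density_control`);
4. discriminative motif discovery with a characteristic-motif criterion
   (`discriminative_search`, `characteristic_motif`);
5. CGI classification relative to transcripts and active promoters plus
   methylation-state calling (`classify_cgis`, `define_promoters`,
   `call_methylation_state`);
6. multi-factor logistic deviance/interaction analysis
   (`fit_logistic`, `deviance_ranking`, `added_value_test`,
   `interaction_network`, `stratified_or`, `gskew_rloop_potential`);
7. synthetic-data generators with ground truth (`sim_cgi_seqs`,
   `sim_periodic_seqs`, `sim_factor_table`, `sim_layout`) and an
   orchestrating `run_pipeline`.

## The permutation null

All spacing inference rests on a null model that preserves a sequence's
entire dinucleotide composition — in particular its CpG count and its GC
content — while destroying any longer-range arrangement. A sequence is
represented as an Eulerian path on the graph whose vertices are the four
bases and whose edge multiset is the observed dinucleotides; a uniformly
random valid rearrangement is drawn by the Altschul–Erickson construction:
reserve one uniformly chosen "last" out-edge per vertex, reject until the
reserved edges form an arborescence into the final base, randomly permute
the remaining out-edges, and walk the path. Naive swap-based shuffling does
not sample this set uniformly, which is why it is not offered. The test
suite verifies exact dinucleotide preservation and chi-square goodness of
fit against the brute-force enumerated arrangement set of short sequences.

For a per-sequence statistic $T$, the empirical p-value against $N$
shuffles is

$$p = \frac{1 + \#\{T_{\mathrm{null}} \ge T_{\mathrm{obs}}\}}{N + 1},$$

one-sided in the enrichment direction. The add-one form keeps $p$ positive,
and ties count toward the tail, which makes the test conservative for
discrete statistics. With heterogeneous sequence sets the discreteness
largely averages out: the pooled null distribution of range-test p-values
is close to uniform (the acceptance suite checks a Kolmogorov–Smirnov
distance below 0.05 over 200 null sequences at $N = 499$).

## CpG spacing

`cpg_positions` records the 0-based start offsets of every CpG;
`pair_distance_counts` counts **all** unordered CpG pairs at each start-offset
distance (not only adjacent pairs), so the largest realisable distance in a
sequence of length $L$ is $L - 2$. The observed/expected profile divides
observed counts by the mean over permutations, reporting a missing value
where the expectation is zero; category averages at distance $D$ include
only sequences with $L - 2 \ge D$ and a positive expectation. The default
profile range is 0–200 bp (plotting) and up to 1,000 bp for p-value work.
The range-enrichment test sums pair counts over a distance window —
defaults 8–10 bp, with 12–14 bp as a non-harmonic control window — and uses
the permutation p above with $N = 1000$ by default.

## Motif statistics and their controls

Motif occurrence uses IUPAC patterns, scans both strands by default
(reverse-complement hits are reported in forward coordinates), counts
overlapping occurrences, and never matches `N`. Presence is the percentage
of sequences with at least one hit; density is pooled occurrences per kbp
(`1000 * total hits / total bp`, not a mean of per-sequence densities);
relative density divides by a background density computed with the same
scanner.

Two controls separate genuine motif enrichment from CpG composition:

* **Global composition** (`shuffle_reduction`): each sequence is shuffled
  once preserving dinucleotides, and the motif re-counted. A motif equal to
  a single dinucleotide is reduced by exactly 0%; a large reduction means
  occurrences are not explained by composition alone. Because pooled length
  is invariant under shuffling, the pooled occurrence reduction and the
  change in the mean per-sequence density are reported as distinct numbers.
* **Local composition** (`local_density_control`): occurrences are binned by
  the CpG count of the window (default 100 bp) centred on them, for real and
  shuffled sequences, and the explained fraction is the histogram overlap
  $100 \sum_b \min(r_b, s_b) / \sum_b r_b$. The window size and the overlap
  formula are this package's operationalisation of the "attributable to
  local CpG density" idea; both are exposed as configuration.

## Discriminative motif discovery

`discriminative_search` is a deliberately simplified discriminative search:
candidates are the exact words of length $k_{\min}..k_{\max}$ present in at
least one positive sequence, with a word and its reverse complement
collapsed into one canonical candidate (this makes reports exactly
strand-symmetric). Each candidate is scored by the one-sided Fisher exact
test on presence in positives versus negatives, and
$E = p \times n_{\mathrm{candidates}}$ is a Bonferroni-style analogue of the
E-value of occurrence-based searches. Byte-compatibility with beam-search
tools is a non-goal: downstream inference uses only ranks and
order-of-magnitude gaps, both of which presence statistics support. An
optional greedy generalisation step degenerates the top word one IUPAC
position at a time while the E-value improves; it is off by default because
exact words already answer the discrimination question.

A top motif is **characteristic** of the positive set iff it is significant
($E < 0.05$) and the next most significant *distinct* motif — one that is
not a substring or superstring of the top motif or of its reverse
complement — has an E-value at least 5 orders of magnitude larger. The gap
threshold of 5 is a conservative default chosen between clearly
characteristic separations (6–9 orders) and ordinary top-of-list gaps
(0–2 orders); it is a parameter, not a constant. The substring/reverse-
complement rule for "distinct" is a declared convention: without it, the
runner-up is almost always a shifted fragment of the winner. With no second
distinct motif the gap is infinite and a significant top motif is
characteristic by convention.

## CGI classification and methylation calls

Intervals are 0-based half-open everywhere (BED-native); overlap means a
shared base under half-open arithmetic, so abutting intervals do not
overlap. Relative to a stranded transcript, a CGI is *promoter-associated*
if it overlaps the 1 kbp window around the TSS by at least 1 bp;
*intragenic* if it lies within the transcript at least 1 kbp from the TSS
(operationalised as full containment without touching the TSS window —
partial body overlap without any window contact is flagged
`boundary_overlap` rather than silently labelled); *distal intragenic* if
it overlaps the 1 kbp window immediately downstream of the transcript end.
Relative to a strand-unknown transcript, overlap of the 1 kbp window around
either end makes it *end-associated*. Labels accumulate over all
transcripts; intragenic and distal intragenic collapse to
`intragenic_like`, promoter- or end-association combined with anything else
is `ambiguous` (and excluded from cross-tabulations), and no transcript
contact at all is `transcript_free`.

Active promoters are TSS±1 kbp windows of stranded transcripts that overlap
both an unmethylated CGI and an H3K4me3-enriched region, merged when
overlapping or abutting. Methylation states are called from percent
methylation with configurable thresholds, defaulting to the usual RRBS
rules — below 20% unmethylated, above 80% methylated, in between
intermediate, and no call with 5 or fewer assayed CpGs. The thresholds are
configuration because different upstream data sets publish calls under
different cutoffs.

## The factor model

The binary methylation state $M$ is modelled by logistic regression on
binary factors (promoter activity, R-loop potential, Cfp1 binding, H3K4me3
enrichment, motif presence), fitted by maximum likelihood (IRLS via
`stats::glm`, convergence at relative deviance change $10^{-8}$, 100
iterations, complete separation flagged). All reported tests are
likelihood-ratio tests on deviance differences, matching the deviance
language of the analysis, with Wald standard errors reported alongside:

* single-factor predictive value = null deviance minus model deviance
  (1-df chi-square), with factors ranked by reduction;
* added value of factor B over factor A = LRT of `M ~ A` vs `M ~ A + B`;
* the interaction network tests every unordered factor pair for an
  interaction term (LRT, 1 df), Bonferroni-corrected by the number of pairs
  tested in the run (10 for five factors), with the interaction's deviance
  reduction as effect size; pairs whose interaction model separates are
  reported non-estimable rather than given a fabricated p;
* stratified odds ratios are reported protective-oriented (OR > 1 means the
  exposure protects against methylation) with the risk orientation and the
  percentage-point reduction in the methylated fraction alongside, since
  printed odds ratios in the literature are ambiguous about direction;
* factor correlations are phi coefficients (Pearson on 0/1 columns).

R-loop formation potential is G-skew: strictly more G than C on the sense
(RNA-like) strand of the overlapping transcript, ties scoring 0. The
"transcribed strand" phrase is ambiguous in the field; the sense-strand
reading is the default and the orientation is a single argument
(`transcript_strand`), so the template-strand convention is one
reverse-complement away.

## Synthetic data and what it does (not) show

The generators define the study conditions under which the package
validates itself:

* `sim_cgi_seqs`: first-order Markov backgrounds with $P(G\mid C)$
  calibrated by root-finding so the stationary CpG rate hits a target
  density — defaults 80 CpG/kbp at GC 0.6, a CGI-like composition;
  CGI-like lengths (hundreds of bp to a few kbp) are drawn uniformly from a
  range. A first-order background (rather than i.i.d.) makes
  dinucleotide-preserving shuffles non-trivial. Motifs are embedded by
  splicing at uniform or CpG-density-weighted positions, re-drawn (up to
  100 times) if splicing created or destroyed off-target occurrences, and
  the per-sequence embedded counts are returned as truth.
* `sim_periodic_seqs`: CpGs placed at successive offsets period±jitter
  (default 9±1 bp) in CpG-free filler, so all pair distances stem from the
  construction; matched controls place the same number of CpGs uniformly.
* `sim_factor_table`: binary factors at stated prevalences (optionally one
  pair correlated to a target phi via a Gaussian copula, with the
  phi-to-rho map solved by quadrature on the bivariate-normal orthant
  probability), continuous predictors uniform over ranges, and the outcome
  drawn from the stated logistic coefficients.
* `sim_layout`: transcript/CGI layouts planting every classification
  outcome, including the ambiguous promoter-plus-intragenic configuration.

All generators are deterministic given their mandatory seed; independent
streams are derived with `derive_seed` so one master seed reproduces an
entire analysis. What passing tests on these inputs shows is that the
machinery is correct and calibrated under its assumptions. What they do not
show: real CGIs have repeat structure, mutational CpG depletion gradients,
shore effects and correlated annotation errors that no first-order chain
emulates, so power numbers on synthetic data are upper bounds, not field
estimates.

## Numerical choices and degenerate inputs

* Empirical p-values are never 0 (add-one formula); ties count toward the
  tail; range tests on sequences too short for the window return `NA` with
  a `defined = FALSE` flag; zero-CpG sequences give statistic 0 and p 1.
* obs/exp ratios with zero expectation are missing, and excluded from
  category averages, rather than infinite.
* The shuffle of a length-<2 sequence is a domain error; single-letter
  graphs return the sequence unchanged.
* Fisher odds ratios with an empty off-diagonal are `Inf` (or `NaN` for
  doubly empty tables); all-zero tables are errors.
* Logistic fits on rank-deficient designs error naming the collinear
  terms, except in the added-value test where an aliased added factor is
  the documented "no added information" case (reduction 0, p 1).
* Simulation problem sizes used in the validation suite (e.g. 200 null
  sequences at 499 permutations; 100 replicates at $n = 10{,}000$ for
  coefficient recovery; 400 calibration replicates at $n = 1{,}000$) were
  chosen to keep Monte-Carlo error well below the margins being tested
  while remaining comfortable on a single CPU; assertions on simulated
  probability guarantees allow two binomial standard errors of simulation
  noise on the stated bound.

## Known limitations

* The discovery module reports presence-based E-values; occurrence-count
  statistics (which favour multi-copy motifs) are out of scope, as are
  position-weight-matrix refinement and database matching of discovered
  motifs.
* Spectral/autocorrelation periodicity methods are not implemented; the
  range test answers the targeted 8–10 bp question only.
* `classify_cgis` is quadratic in (CGIs × transcripts) and intended for
  CGI-scale inputs (tens of thousands), not base-pair-resolution scans.
* The local-CpG-density control's histogram-overlap statistic is one
  reasonable operationalisation among several; conclusions that depend
  finely on its value should vary the window size.

## A worked example

```{r example, eval = FALSE}
library(cgisig)

# simulate a protected-CGI-like set with TGCCGC embedded, and a matched
# background set
pos <- sim_cgi_seqs(100, c(500, 1500), cpg_per_kbp = 80, gc = 0.6,
                    motifs = list(list(pattern = "TGCCGC", count = 2,
                                       in_fraction = 0.9)), seed = 1)
neg <- sim_cgi_seqs(100, c(500, 1500), cpg_per_kbp = 80, gc = 0.6, seed = 2)

# is the motif enrichment explained by composition?
presence_fraction(pos$seqs, "TGCCGC")
shuffle_reduction(pos$seqs, "TGCCGC", seed = 3)$occurrence_reduction_pct

# discover it ab initio and test whether it is characteristic
rep_ <- discriminative_search(pos$seqs, neg$seqs, k_min = 4, k_max = 6)
rep_$characteristic

# spacing periodicity test on one sequence
range_enrichment_test(pos$seqs[[1]], 8, 10, n_perm = 999, seed = 4)$p
```

The same stages, with TSV reports and a JSON manifest, run end to end via
`run_pipeline(list(seed = 1), out_dir = "demo_run")`.
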