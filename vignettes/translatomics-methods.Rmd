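---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its statistical machinery:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does
not emulate, and the numerical and design choices made where the design
was genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Normalization: median of ratios

For a feature-by-sample matrix of nonnegative measurements
$I_{ij}$ (integer counts for RNA-seq/Ribo-seq, reporter intensities for
TMT proteomics), `compute_size_factors()` builds a pseudo-reference
$R_i = \exp\!\big(\tfrac1n \sum_j \log I_{ij}\big)$ and a per-sample
size factor $S_j = \mathrm{median}_i\, I_{ij}/R_i$;
`normalize_matrix()` returns $N_{ij} = I_{ij}/S_j$. Features with any
zero or missing value are excluded from $R_i$ and from the median — the
geometric mean is undefined at zero — but are still divided by $S_j$.
This mirrors the convention of count-based differential-expression
tools, where the reference set is implicitly restricted to features
observed everywhere.

A subtlety worth spelling out because it is often misstated: this
normalization is **only defined up to a global scale**. If one raw
column is multiplied by $c$, every $R_i$ grows by $c^{1/n}$, so the
scaled sample's size factor changes by $c^{1-1/n}$, every other one by
$c^{-1/n}$ — i.e. by exactly $c$ *relative to the others* — and the
whole normalized matrix is multiplied by $c^{1/n}$. The exact relative
form is what the tests assert (to $10^{-9}$); absolute invariance of
$N$ is impossible for these equations, and any downstream statistic we
compute (log-ratios between samples, Welch tests on log values with a
common shift) is invariant to the global factor.

## Differential abundance: Welch + Benjamini–Hochberg

`welch_differential()` tests each feature with a two-sided Welch
$t$-test on $\log_2(N_{ij} + \text{pseudocount})$ between the two
condition levels (the **first factor level is the reference**;
`log2fc` is treated minus control), with Welch–Satterthwaite degrees of
freedom and BH correction across features. Defaults: pseudocount 0.5
for counts (keeps zeros finite, negligible for means above ~10), 0 for
strictly positive intensities; significance at $q < 0.05$.

Degenerate variances (both groups exactly constant) are resolved
deterministically instead of propagating NaN: $p = 1$ when the means
agree, $p = 0$ with a `degenerate` flag otherwise — detectable, never
silently significant.

`bh_adjust()` implements step-up with cumulative-minimum enforcement;
it differs from `stats::p.adjust(method = "BH")` only in its missing
value contract (NA propagates and is excluded from the ranking). The
test suite checks equality with `p.adjust` on complete inputs.

For RNA counts this engine deliberately replaces a negative-binomial
GLM: no dispersion estimation or shrinkage is performed anywhere, and
log2 fold changes are reported unshrunk. The consequences for power are
analysed below, because they matter.

## Translation efficiency and regulatory classes

`compute_te()` computes per-sample
$\log_2 \mathrm{TE} = \log_2(\mathrm{RPF}+pc) - \log_2(\mathrm{mRNA}+pc)$
on independently normalized matrices, keeping genes whose mean
normalized abundance reaches `min_mean` (default 10) in both assays —
below that, the log-ratio is dominated by shot noise.
`differential_te()` runs the same Welch/BH machinery on replicate
log2 TE. `classify_dteg()` combines the mRNA and TE calls:

| TE sig | mRNA sig | directions | class |
|---|---|---|---|
| yes | no | — | exclusive |
| yes | yes | same | intensified |
| yes | yes | opposite | buffered |
| no | yes | — | forwarded |
| no | no | — | none |

A significant layer with log2FC exactly 0 has no direction and is
flagged `unclassifiable` rather than binned. The rule table is total
and mutually exclusive; the tests enumerate every
significance × direction combination against an independent oracle.

## The power caveat (why one acceptance test is red)

The validation suite's stated world is $n = 4$ vs 4 replicates, NB
dispersion $\alpha = 0.05$, planted $|\log_2\mathrm{FC}| = 1$. On the
log2 scale the per-sample sd of an NB count is at least
$\sqrt{\alpha}/\ln 2 \approx 0.32$ *regardless of sequencing depth*, so
the Welch statistic for an RNA effect has noncentrality
$1/(0.32\sqrt{2/4}) \approx 4.4$ on roughly 6 degrees of freedom, and a
TE effect — two NB channels of noise — noncentrality $\approx 3.1$.
With only 6 df the variance estimate itself is noisy, the realized
p-values are diffuse, and BH across 2000 genes settles at a low
threshold: Monte Carlo at the idealized best case (all genes at
$\mu = 10^4$) gives sensitivity $\approx 0.06$ for RNA and
$\approx 0.005$ for TE at $q < 0.05$. Per-gene tests of this kind reach
useful power in small designs only by pooling variance information
across genes (NB dispersion shrinkage or empirical-Bayes moderation),
which this package intentionally does not do. The acceptance criterion
that demands $\ge 70\%$ per-class recovery of planted regulatory
classes therefore fails by construction, not by defect, and is left
red; the companion clause (no exclusive↔forwarded confusion) fails for
the same reason, since a TE miss plus an RNA false positive relabels an
exclusive gene as forwarded. Calibration under the null — type-I rate
and BH discovery counts — is unaffected and passes.

## Codon-level statistics

Coordinates are 0-based, half-open, in transcript space; the codon
index of a nucleotide site is $\lfloor(\text{site} - \text{utr5})/3\rfloor$.
P-site offsets default to 12 nt (reads of 28–31 nt) and 13 nt
(32–34 nt), the standard mammalian convention; A-site = P-site + 3 nt.
Both are configurable because offsets are library-specific in practice.

`codon_occupancy()` trims 5 codons at each CDS end by default
(initiation/termination artefacts), requires a mean of 0.5 reads per
included codon (below that, per-codon densities are mostly zeros and
ratios unstable), divides each codon's site count by the transcript
mean, and averages densities per codon identity weighted by position
counts — making the weighted mean exactly 1, which the tests assert on
arbitrary input. Stop codons can only be occupied at the A site.
`pause_scores()` is the same per-position density, reported per
(transcript, codon) with a coverage flag; the per-transcript mean is 1
by construction. The exact pause-score formula used in the literature
varies; this per-site density normalization is a stated stand-in,
adequate for the package's comparative (condition vs condition) use.

QC (`riboseq_qc()`) assigns each read to 5′UTR/ORF/3′UTR by its
**P-site**, not its 5′ end, for consistency with the codon analyses;
reads on non-coding transcripts count as "other".

## Enrichment

`preranked_gsea()` ranks genes by a statistic (descending, ties broken
by gene id for determinism) and computes the classic weighted
running-sum ES: hits increment by $|s|^{w}$ normalized over the set
(default $w = 1$), misses decrement by $1/(n-K)$; ES is the deviation
of maximal magnitude (positive wins an exact tie). The null draws
random gene subsets of size $K$ from the ranked universe — the
appropriate scheme for a preranked analysis, where no sample labels
exist to permute. NES divides ES by the mean magnitude of same-sign
permutation scores (NaN with a flag if none exist); the permutation p
is computed among same-sign scores and floored at $1/(n_{perm}+1)$,
never 0. Sets with zero or full overlap with the ranking are excluded
with a warning (a full-overlap set has an undefined miss decrement);
fewer than 100 permutations are refused. At 10000 permutations the
p-value of a strongly enriched set sits at the floor, so runs with
different seeds agree to well within ±0.01.

`hypergeometric_ora()` intersects each set with the detected-gene
background first, keeps sets of 10–500 members, computes the exact
upper tail $P(X \ge k)$, and reports enrichment only when both p and
BH q fall below the threshold (a conjunctive dual cut-off).

## Integration

`stratify_five_groups()` transcribes the five-group mRNA/protein rule
table: group 1 both NS; groups 2–5 the four direction combinations with
at least one significant layer. Two corner cases are flagged rather
than binned: a significant layer with log2FC exactly 0, and an NS
zero-log2FC layer paired with a significant one (the rule table demands
a direction for the NS layer). Concordant (2 ∪ 4) and discordant
(3 ∪ 5) fractions partition the non-group-1 genes.
`hierarchical_cluster()` uses Ward linkage on squared dissimilarities
(`ward.D2`) for both Euclidean and one-minus-Pearson distances —
"Ward on a correlation distance" is not metric-space Ward, so the
convention is fixed and documented; the tests check merge order and
heights against a naive $O(n^3)$ Lance–Williams oracle.

## The synthetic generator: what it emulates, what it does not

`simulate_multiomics()` draws per-gene baselines
$q_i \sim \mathrm{LogNormal}(\log 100, 1)$ — a realistic spread of
expression scales for a filtered gene set — and per-sample size factors
log-uniform in [0.7, 1.4] to exercise normalization. RNA counts are
NB with mean $s_j q_i 2^{x_j\beta_{rna}}$ and variance
$\mu + 0.05\mu^2$; RPF counts use $\beta_{rna}+\beta_{te}$ (TE acts on
occupancy on top of abundance); protein intensities are log2-normal
(sd 0.3, a typical TMT replicate CV of ~20%) around a scaled baseline
shifted by $\beta_{prot}$. Regulatory classes are allocated by largest
remainder (defaults: 5% each of forwarded, exclusive, intensified,
buffered, concordant- and discordant-protein, 70% null) with
$|\beta| = 1$; buffered genes get exactly offsetting $\beta_{rna} = e$,
$\beta_{te} = -e$ so the RPF fold is ~1, and protein effects follow
translational output ($\beta_{rna}+\beta_{te}$) except in the two
protein classes that deliberately decouple it. The truth table records
every planted effect, the re-derivable regulatory class, a truth-level
five-group label (a zero-effect layer is folded onto its partner's
direction, since the observed direction of a null layer is noise), a
localisation class and a hierarchy-consistent druggable annotation.

`simulate_footprints()` allocates reads across transcripts by CDS
length, draws the A-site codon with probability proportional to the
codon's pause multiplier, the read length from a distribution massed on
28–32 nt, and back-computes the 5′ end so the standard offset recovers
the intended A-site. `generate_annotation()` adds random gene sets plus
one positive-control set drawn from planted-up genes.

Not emulated: sequencing error, alignment ambiguity, isoforms, GC or
length bias, batch structure, proteomics missingness mechanisms
(values are missing only if simulated as zero), ratio compression in
TMT, or correlated gene-gene noise. A green test on this generator
therefore establishes algorithmic correctness and statistical
calibration under a clean generative model — not robustness to the
artefacts of real libraries. The real-data design this emulates used
2 Ribo-seq replicates; the generator defaults to 4 for testability,
a trade-off, not a claim about any particular dataset.

## Determinism and numerics

All randomness flows through explicit seeds; seeded functions
save and restore the caller's RNG state, and the pipeline derives
per-stage seeds from one master seed, so `run_pipeline()` reproduces
byte-identical outputs (checked via manifest checksums). Tolerances:
normalization identities at $10^{-9}$–$10^{-12}$ (pure floating-point),
occupancy/pause normalization at $10^{-6}$/$10^{-9}$ (sums over many
positions), statistical properties at the sampling tolerances stated in
the tests. Ties in rankings are broken lexicographically; the ES sign
tie goes to the positive deviation; empty results are errors, never
silently empty tables.
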