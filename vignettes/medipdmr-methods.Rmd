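---
title: "Methods: regional MeDIP scoring, DMR calling and simulation design in medipdmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional MeDIP scoring, DMR calling and simulation design in medipdmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipdmr)
```

# The measurement model

MeDIP-seq reports *relative* regional methylation: an anti-5-methylcytosine
antibody pulls down methylated fragments, so the expected number of reads a
region attracts grows with the amount of methylated CpG it carries. The
package's scoring statistic follows that logic directly. Every uniquely
aligned read is extended to 250 bp from its 5' end toward its 3' end —
sequenced reads are much shorter than the sonicated fragments they came
from, and extension restores the fragment's footprint. The **MeDIP score**
of a region is then

$$\mathrm{score}(R) = \frac{\#\{\text{extended reads overlapping } R\}}{|R| / 1000}\ \ \text{reads·kb}^{-1},$$

with overlap meaning at least 1 bp (the simplest monotone rule; no midpoint
or minimum-overlap refinement is applied). Three-state methylation calls
use fixed absolute thresholds: unmethylated below 9.48 reads·kb⁻¹,
completely methylated above 50.62, partially methylated on the closed
interval between them. The boundary values both map to *partial* so the
three classes partition $[0, \infty)$. The two cut-offs are treated purely
as configuration — they were calibrated on real sequencing depth profiles
upstream of this package and carry no meaning at other library sizes
unless scores are depth-normalised. For that reason `scoring_config()`
offers a per-million normalisation mode, off by default because the
canonical thresholds are absolute; `score_matrix()` warns when group
depths differ by more than 10% without it.

## Assumptions

* Read density is proportional to methylated-CpG mass. CpG-density
  coupling (CpG-poor regions saturating the antibody differently) is not
  modelled; Bayesian absolute-methylation estimators are out of scope.
* Duplicate reads are retained; no input/IgG subtraction is performed
  (the IgG control is wet-lab QC, not part of scoring).
* One TSS per gene model; multi-isoform promoters are not resolved.

# Annotation windows

Promoters are the strand-aware window from 700 bp upstream to 200 bp
downstream of the TSS; gene bodies run from TSS+2000 bp to the TTS and
exist only for genes *strictly longer* than 3000 bp ("longer than" is read
strictly, so a 3000 bp gene has no body). Windows crossing a contig edge
are clipped with a warning rather than rejected — losing a few bases of a
promoter is preferable to silently dropping the gene. All in-memory
intervals are `GRanges` (1-based, closed); BED I/O converts to 0-based
half-open coordinates at the boundary, so files on disk follow the BED
convention exactly.

# CpG island detection

An island must be at least 200 bp long, have G+C content of at least 50%,
and a CpG observed/expected ratio of at least 0.6, where
$\mathrm{obs/exp} = \frac{N_{CpG}}{N_C \cdot N_G} \cdot L$ — the
Gardiner–Garden dinucleotide statistic (the classical formula adopted as
the field standard; the ratio is defined as 0 when a sequence lacks C or
G entirely). All three thresholds are inclusive (minimum-qualifying
reading).

**Algorithm choice.** The common heuristic — slide a fixed 200 bp window,
merge qualifying windows, trim — is *not* equivalent to the definition
above: a 300 bp stretch can satisfy all three criteria while no 200 bp
window inside it does. `find_cpg_islands()` therefore searches
*exhaustively over substrings*: an island is a maximal run of positions
covered by at least one qualifying substring (length ≥ 200, GC ≥ 50%,
obs/exp ≥ 0.6, no `N`). Two observations make this tractable. First, for
a fixed start the union of qualifying substrings is the prefix up to the
largest qualifying end, so one vectorised pass per start suffices. Second,
GC feasibility is a linear constraint: with $f(i) = \mathrm{GC}[0,i) -
0.5\,i$, a substring $[s,e)$ has GC ≥ 50% iff $f(e) \ge f(s)$, which
yields an $O(L)$ prune (prefix minima against suffix maxima of $f$) that
restricts the quadratic scan to candidate blocks. On AT-biased genomes
islands are sparse and megabase inputs complete in seconds to tens of
seconds.

Merging unions of qualifying substrings can occasionally dilute a run
below the composition criteria (two GC-marginal substrings overlapping on
a GC-rich core). Such a run is replaced by its longest qualifying
substring, leftmost on ties — a deterministic closure rule guaranteeing
that **every reported island itself satisfies all three criteria**. One
consequence worth knowing: a CpG-rich core shorter than 200 bp flanked by
AT can still seed an island, because a 200+ bp substring spanning core
plus flank may reach GC 50% on its own; the reported island is then the
maximally diluted qualifying substring around the core. That is the
definition operating as specified, not a bug.

Numerical comparisons of the ratio criteria are done in integer count
products with a relative tolerance of $10^{-9}$, so exact-boundary
compositions (GC exactly 50%, obs/exp exactly 0.6) qualify regardless of
floating-point representation. The test suite verifies exact equality
against an independently written exhaustive-enumeration oracle on 50
random sequences up to 3 kb.

# DMR calling

Per promoter, group means of per-sample scores give a pseudocounted fold
change $\mathrm{fc} = (\bar{s}_{trn} + c)/(\bar{s}_{sed} + c)$ with
$c = 0.5$ reads·kb⁻¹, folded to ≥ 1 with a direction label (hyper/hypo in
the trained condition); folding makes one threshold serve both directions
and the statistic symmetric under group swap. The differential test is
deliberately pluggable, because the upstream analysis convention only
fixes the *thresholds* (P < 0.05, fold change > 1.5, both strict), not the
test:

* `welch_t_log` (default): Welch's t on $\log_2(\mathrm{score} + c)$ —
  robust to unequal variances at small n; at n = 4 + 4 it is mildly
  conservative (empirical type-I ≈ 0.037 at nominal 0.05).
* `permutation`: |difference of group means| of log scores under
  group-label reassignment; exact enumeration whenever there are at most
  12,870 arrangements (up to a balanced 8 + 8), Monte Carlo with the +1
  correction beyond that.

No multiple-testing correction is applied by default (the cascade is
defined on raw P); Benjamini–Hochberg q-values are always reported and can
drive the filter behind `adjust = TRUE`. The candidate filter retains
promoters whose *larger* group-mean score exceeds 10 reads·kb⁻¹ — the
larger mean is used because a promoter methylated in only one condition is
exactly the interesting case; filtering on the smaller or pooled mean
would discard it. A separate ±500 bp TSS window (`candidate_window`) is
kept as distinct configuration for candidate reporting; it is not the
scoring window and the two are intentionally not merged.

# Enrichment and motif scanning

Gene-set enrichment uses the classic weighted Kolmogorov–Smirnov-like
running sum on a list ranked by the signed promoter log2 fold change
(the default metric; any named metric works). Hits increment by
$|m|^p / \sum_{hits} |m|^p$ (default $p = 1$), misses decrement by
$1/(N - N_{hit})$; the enrichment score is the extremum, and significance
comes from a **gene-label** permutation null with
$p = (1 + \#\{|ES_0| \ge |ES|\})/(1 + n_{perm})$ and
$NES = ES / \overline{|ES_0|}_{\text{same sign}}$. Sample permutation is
impossible at n = 4 per group; the gene-label null ignores inter-gene
correlation and is the stated limitation of this module. For unranked
selections a hypergeometric over-representation test (`ora_test()`) is
provided. The implementation is cross-checked in the tests against both a
brute-force running sum (exhaustive on lists of length ≤ 8) and an
independent library implementation of the same statistic.

Motif scanning builds log-odds matrices from JASPAR-format counts with a
total pseudocount of 0.8 distributed by background frequency (the
JASPAR/MEME convention), scores both strands, and thresholds either in
bits or as a fraction $t$ of the achievable range
($\min + t(\max - \min)$, default 0.8). Windows containing `N` score
$-\infty$. The bundled `nbre_like_motif()` (consensus `AAAGGTCA`) is a
synthetic orphan-receptor-response-element-like matrix built in code for
tests and demonstrations — it is a labelled stand-in, not a database
matrix.

# Pyrosequencing validation

Percent methylation is $100\,n_C/(n_C + n_T)$ per CpG. Non-CpG cytosines
act as conversion controls; pooled efficiency below 0.95 flags a sample
(the control is standard practice, the 0.95 default is this package's
choice). Condition effects across the CpGs of one promoter are tested
with a fixed-effects balanced two-way ANOVA (condition × site, with
interaction) computed via `stats::aov`; unbalanced designs are rejected
rather than silently reweighted, zero-variance factors report p = 1 by
convention, and the SS decomposition is verified exactly against textbook
formulas in the tests. Whether site should be treated as a repeated
measure within animal is a genuine modelling fork; the fixed-effects
version is implemented and this deviation risk is documented here.
Per-CpG condition tests are unadjusted two-sided Welch t-tests, mirroring
per-site significance stars on methylation bar plots; Bonferroni is
available behind a flag, and an arcsine-square-root transform is offered
though percentages are analysed untransformed by default.

# What the simulator emulates — and what it does not

`simulate_genome()` lays the genome out in equal per-gene slots so that
every gene carries a −700/+200 promoter window that never overlaps a
neighbouring locus; per-promoter tests then measure their own region's
signal rather than a neighbour's. The background is AT-biased (40% GC,
roughly mammalian intergenic), promoter sequence is CpG-containing but
deliberately below the island criteria (≈ 44% GC), and planted islands
are drawn from a CpG-rich composition and re-drawn until they satisfy the
criteria by construction. Methylation levels: non-planted promoters
U(0.2, 0.8) shared between conditions; planted promoters get a base level
$b \sim U(0.15, \min(0.3, 0.95/e))$ and an $e$-fold shift (default
$e = 3$) in a random direction, keeping all levels inside [0, 1]; gene
bodies U(0.3, 0.9); islands mostly unmethylated U(0.02, 0.2); background
U(0.05, 0.15).

Reads: per sample, a Poisson($\bar{d}$) total (default 10,000) with a
10% uniform background component; the rest are placed multinomially over
regions with weight level × CpG count — the minimal model that makes the
MeDIP score proportional to methylation, which is precisely the
assumption the scoring stage relies on. Read lengths are uniform 36–150 bp
(the sequenced end of a fragment; deliberately shorter than the 250 bp
extension applied downstream) and strands uniform. Pyrosequencing counts
are Binomial(depth, level) per CpG, with conversion failures
Binomial(depth, 1 − efficiency) applied to non-CpG control cytosines
only.

The default study size is 200 genes on a 1 Mb genome with n = 4 per
group. Two hundred non-overlapping 900 bp promoter windows geometrically
require well over 180 kb; 1 Mb gives each gene a 5 kb slot, room for
genes long enough (up to ~3.9 kb) to exercise the gene-body annotation,
and realistic intergenic space for planted islands. The generator raises
a sizing error naming the constraint when a configuration cannot host its
genes. The group-size default of 4 is configurable — the number of
animals sequenced per group is not something the analysis conventions pin
down.

**Not emulated:** base quality and FASTQ simulation, alignment and
mapping ambiguity, PCR duplicates, CpG-density-dependent antibody
saturation, fragment-size distributions beyond the uniform read length,
diploid genomes, inter-gene correlation in methylation. Consequently,
passing tests demonstrate that the *statistics and interval machinery*
behave as specified under their own model — they say nothing about
mapping artefacts or antibody biases in real libraries.

# Calibration and problem sizes used by the test suite

* **Planted-DMR recovery** runs the default study (200 promoters, 10%
  planted at 3-fold, n = 4/group, 10,000 reads/sample) over 10 seeds and
  requires pooled sensitivity ≥ 0.8, pooled observed FDR ≤ 0.25, and
  every detected planted direction correct.
* **Null calibration** uses n = 5 per group with exact permutation. This
  is a discreteness decision, not a power one: at n = 4 + 4 the exact
  two-sided permutation p-values form the grid $\{2k/70\}$, and the only
  achievable value below 0.05 is 2/70 ≈ 0.0286, so the expected fraction
  of null promoters with p < 0.05 cannot sit near 0.05. At n = 5 + 5
  there are 252 arrangements and the attainable mass below 0.05 is
  12/252 ≈ 0.0476, which a calibration check centred on 0.05 can
  meaningfully measure. One thousand null promoter tests (5 seeds × 200
  promoters) must land in [0.03, 0.07].
* **Oracle equivalences**: islands on 50 random sequences ≤ 3 kb (exact
  equality); scores on 100 random read sets; GSEA on all subsets of
  lists of length ≤ 8; GSEA null uniformity over 200 runs of 1,000
  permutations (KS at α = 0.01); motif recovery on 100 planted seeds per
  strand with ≥ 95/100 clean motif-free scans at the 0.95-of-max
  threshold.
* **Pyro**: estimator within 1 percentage point of planted truth at
  depth 10⁴; ANOVA decomposition exact on a hand-worked 2×2×2 fixture;
  per-CpG type-I error within 0.05 ± 0.02 over 1,000 null draws.

RNG design: one root seed; per-sample and per-stage streams are derived
by fixed offsets, so enlarging a design never reshuffles the streams of
existing samples, and every simulator output is a pure function of its
configuration.

# Known limitations

* The status thresholds (9.48/50.62) are depth-bound constants; applying
  them to libraries of very different depth without per-million
  normalisation misclassifies status, and the package only warns.
* The gene-label GSEA null understates inter-gene correlation; its
  p-values are optimistic on correlated ranks.
* Island detection is exact but quadratic within candidate blocks; a
  genome that is one giant near-threshold GC plateau would be slow.
* The DMR test menu does not claim to replicate the original study's
  (unnamed) test; both options are reported so users can check agreement.
* Promoter windows of real annotations can overlap neighbouring genes;
  the simulator avoids this by construction, so cross-promoter read
  bleed-through is untested.
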