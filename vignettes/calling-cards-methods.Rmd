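---
title: "Models and methods behind callingcardr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind callingcardr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(callingcardr)
```

# The measurement being modelled

Calling cards couples a chromatin-binding protein to Ty5 integrase via the
Sir4 tethering domain, so each binding episode can leave a retrotransposon
permanently integrated at the binding site. The sequencing assay recovers
each insertion's flanking DNA: genomic DNA is digested in three separate
restriction reactions (HindIII `AAGCTT`, HpaII `CCGG`, TaqI `TCGA`),
fragments are circularised by intramolecular ligation, and inverse PCR
amplifies outward from the Ty5 end, yielding reads of the form
*Ty5 terminal tag + genomic sequence starting at the junction base*. The
three digests are pooled before sequencing.

Everything downstream is the analysis this package implements: call unique
insertion events from junction reads, normalise them two ways, and compare
the resulting signal to replication-timing windows and to feature-centred
windows (ACS/origin sites, Orc1 sites, centromeres, TSS).

# Coordinate and event conventions

All coordinates are 0-based half-open internally; conversion happens only
at the SAM boundary (1-based) and in BED/bedGraph serialisation (already
0-based). An insertion's position is the 0-based coordinate of the first
genomic base 3′ of the Ty5 junction *on the reference plus strand*; for a
minus-strand insertion this is the plus-strand coordinate of the last base
of the mapped fragment. This single-base, strand-resolved convention
matches the anatomy of a junction read and lets the SAM importer and the
built-in mapper agree exactly (a minus-strand alignment's junction base is
its exclusive alignment end minus one).

Events are keyed by (chromosome, position, strand): Ty5 integrates
directionally, so opposite-strand insertions at one position are distinct
molecular events. `call_insertions(merge_strands = TRUE)` collapses them
for users who prefer unstranded events. Deduplication is by insertion
coordinate only — the three digests produce different fragment *ends* for
one insertion, so fragment ends carry no event identity.

Multi-mapping fragments are discarded (`MULTI`), never assigned: a calling
card is only useful if it certifies one location. The mapper itself is an
exact both-strand substring lookup (Biostrings `PDict`), sufficient for the
error-free synthetic reads; externally aligned real data enters through
`import_sam()`.

# The generative model

`sim_insertions()` draws insertion positions without replacement with
per-base weight

$$ w(p) = \beta \cdot \prod_{c} \bigl(1 + (e_c - 1)\,
   \mathrm{e}^{-d_c(p)/\lambda_c}\bigr) \cdot \mathrm{e}^{-T_{rep}(p)/\tau} $$

where $\beta$ is a uniform background, $d_c(p)$ is the distance to the
nearest midpoint of feature class $c$, $e_c \ge 1$ and $\lambda_c$ set the
fold and reach of feature-proximal binding, and $\tau$ (minutes) couples
binding to replication timing ($\tau = \infty$ disables it). The sampler
uses exponential-key (Efraimidis–Spirakis) weighted sampling, which is
distributionally identical to sequential weighted draws but $O(N \log N)$.

Parameters that matter, with defaults:

| parameter | default | meaning |
|---|---|---|
| `background_rate` | 1 | uniform per-base weight (units cancel) |
| `feature_enrichment` | none | per-class `fold` ≥ 1 and `lambda` (bp) |
| `tau` | `Inf` | timing-coupling scale, minutes |
| `pcr_meanlog`, `pcr_sdlog` | 2.3, 0.8 | log-normal read multiplicity |
| `read_length` | 50 bp | total read length incl. 20-bp tag |
| `enzymes` | HindIII, HpaII, TaqI | recognition sequences |

Per-insertion read multiplicity is rounded log-normal (floored at 1):
31 cycles of inverse PCR produce heavy-tailed duplication, and a median of
~10 reads per insertion with occasional 100-fold jackpots is a realistic
regime in which the two normalisations visibly diverge. The read count is
split as evenly as possible across the three digests (remainders rotate
with insertion index), mirroring pooling of three separately amplified
reactions.

The read model recovers, for each insertion and digest, the genomic
sequence from the junction base to the nearest downstream recognition site
*on the insertion strand*, reading through the site itself: sticky-end
ligation regenerates the recognition sequence at the circle junction, so
the read matches the reference through the full site before diverging into
the other side of the circle. An insertion-digest pair with no downstream
site before the chromosome end is a *digest escape*: its fragment is
dropped, counted and reported, which is the physically expected fate of a
terminal fragment that cannot circularise. Read accounting closes exactly:
emitted + dropped = total amplified.

The replication-timing landscape is a fork-propagation model,
$T_{rep}(p) = t_0 + \min_o |p - o| / v$ capped at `t_max` (default 70 min),
stored piecewise-constant. With ~60-kb origin spacing, a 1 kb/min fork
speed and $t_0$ of 5–10 min it spans the 10–35 min range typical of yeast
microarray timing profiles.

What the generator does *not* emulate: sequencing errors and quality
variation (qualities are constant `I`), barcode demultiplexing, mappability
structure of a real genome (repeats beyond what an i.i.d. sequence
produces), chromatin accessibility, and Ty5's intrinsic sequence
preferences. Passing tests therefore demonstrate the *analysis* is correct
under its stated assumptions, not that real libraries are this clean — real
data should enter through `import_sam()` after alignment with a
mismatch-tolerant aligner.

# Normalisations

`rpm_track()` computes $10^6 \cdot \text{reads}(p) / \text{aligned reads}$;
strands at one position are summed because display tracks are unstranded.
The denominator is the library's unique-status reads (multi-mapped reads
are excluded from both numerator and denominator). A full library's RPM
track sums to exactly $10^6$.

`unique_track()` is the 0/1 indicator of insertion positions. Downstream
summaries of this track (window and profile means) are means over
positions, which is how "normalised to the mean number of unique
insertions" is interpreted here; no additional scaling constant is
applied. The pair of tracks is the diagnostic for amplification artefacts:
the indicator is invariant to any per-insertion reweighting, RPM only to
uniform duplication.

# Windows and meta-profiles

`window_signal()` partitions T_rep into left-closed `width`-minute windows
(`[0,5), [5,10), …`, last window open-ended) so every position falls in
exactly one window. Two granularities are offered because they answer
different questions:

* per tracked position (default) — the distribution of signal *heights*;
* per genomic bin (`bin = 500` say) — per-bp signal *density* including
  zeros, the right unit for comparing binding density between constructs.
  With deduplicated events, two constructs' per-position unique-track
  values are all 1 regardless of where they bind, so only the binned view
  can detect that one construct concentrates in early windows; the window
  comparisons and the monotonicity checks therefore use it.

`feature_profile()` tiles ±`flank` around each feature midpoint
(`floor((start+end)/2)`) into `bin_width`-bp bins and reports, per bin, the
mean per-position value (zeros included; bin mass / bin width), averaged
over sites. This makes RPM and unique bins comparable across bin widths.
Offsets are unstranded, matching the symmetric construction of published
origin-centred profiles. Sites whose window would cross a chromosome end
are dropped and counted rather than zero-padded, which would bias bin
means toward 0. The early-replication filter (`filter_by_timing()`,
default ≤ 30 min) keeps the library denominator unchanged: RPM is a
per-library normalisation, and subsetting events must not rescale the
remaining signal.

`profile_ratio()` compares mean bin values over the central ±100 bp by
default, the region where origin-proximal binding concentrates; 0/0 is
reported as an explicit `undefined` flag rather than an error or NaN.

# Statistics

`wilcoxon_rank_sum()` uses midranks and reports
$U = \min(U_1, n_1 n_2 - U_1)$. For pooled $n \le 16$ the two-sided
p-value is computed by full enumeration of all $\binom{n_1+n_2}{n_1}$
labelings as $P(|U - n_1 n_2/2| \ge |u_{obs} - n_1 n_2/2|)$, which is
exact in the presence of ties (the permutation distribution of $U$ is
symmetric about $n_1 n_2 / 2$). Beyond that, a normal approximation with
tie-corrected variance and 0.5 continuity correction is used; at the
switch point the approximation error (≲ 0.01) is far below the resolution
of the star bands. The cutoff of 16 keeps enumeration ≤ 12,870 labelings —
instant — while the criterion bands (`***` < 0.001, `**` < 0.01,
`*` ≤ 0.05, else NS) are two-sided throughout and reported without
multiple-testing adjustment, matching the per-window presentation
convention; `compare_windows(adjust = "BH")` opts into
Benjamini–Hochberg-adjusted stars.

`transposition_efficiency()` is the plate-count ratio
FOA-resistant colonies / (viable cells × dilution), in events per cell; it
deliberately models no count overdispersion and reports no interval.

# Numerical and degenerate-input choices

* All randomness flows through explicit integer seeds via `withr`
  (`with_seed`), leaving the caller's RNG state untouched; identical calls
  are byte-identical.
* bedGraph values are written with 12 significant digits, so track
  round-trips are exact to better than $10^{-9}$ relative tolerance.
* Ties in the exact Wilcoxon enumeration are compared with a $10^{-9}$
  slack on rank-sum deviations (ranks are multiples of 0.5, so this can
  never misclassify).
* Empty inputs degrade explicitly: zero insertions give valid empty truth
  tables/FASTQs, empty windows are reported with `n = 0`, a window empty
  on either side of a comparison is flagged untestable instead of raising,
  and an all-dropped site list is an error naming the cause.
* Feature placement uses the sorted-draws-plus-cumulative-spacing
  construction, which is uniform over feasible configurations and fails
  with a capacity error naming the class when the pigeonhole bound is
  violated.

# Problem sizes used in the shipped checks

The test-suite and acceptance-script study conditions are chosen to be the
smallest sizes at which each behaviour is unambiguous: 50-kb genomes with
200 insertions for exact round-trip recovery; a 1-Mb genome, 40 ACS sites
and 5,000 insertions for profile-peak localisation (fold 50, λ 100 bp) and
enrichment-ratio recovery (fold 30 vs 10, tolerance 25%); a 300-kb genome
with five origins and 5,000 insertions for the timing-window comparisons
(τ = 15 vs ∞, 500-bp bins giving ~100 density values per 5-min window).

# Known limitations

* The exact mapper tolerates no mismatches or indels in the genomic
  portion; it is intended for synthetic reads and small references, with
  `import_sam()` as the path for real libraries.
* The SAM importer classifies records by flags only; it does not
  reconstruct multi-mapping groups from `XA`/`NH` tags (a secondary record
  marks itself, not its primary, as ambiguous).
* Fragment recovery simulates one junction-side fragment per digest; the
  non-junction side of the inverse-PCR circle is not emitted.
* The Ty5 tag is synthetic and configurable; no target-site duplication is
  modelled, so positions are recovered exactly rather than within a
  duplication-length ambiguity.
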