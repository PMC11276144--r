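---
title: "Methods: trio-based UPD landscape analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio-based UPD landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(updtrio)
library(ggplot2)
```

# Problem and model

Uniparental disomy (UPD) is the inheritance of both copies of a chromosome,
or a chromosomal segment, from a single parent. Two forms are
distinguished. In **isodisomy** the two copies are identical (duplicated
sister-chromatid material), so the child is homozygous across the region —
which can *unmask* a recessive allele carried heterozygously by one parent.
In **heterodisomy** the two copies are the parent's two different homologs;
the child can be heterozygous but carries no allele from the other parent.

Segmental mixtures of the two arise from meiotic crossing-over followed by
nondisjunction (NDJ) and trisomy rescue. With the centromere at coordinate
1 of an acrocentric chromosome:

* **Meiosis-II NDJ** retains the two sister chromatids of one homolog. They
  are identical from the centromere to each crossover and exchange
  thereafter, giving *centromeric isodisomy, telomeric heterodisomy* (with
  one crossover).
* **Meiosis-I NDJ** retains one chromatid of each homolog, giving the
  mirror pattern: *centromeric heterodisomy, telomeric isodisomy*.

Given trio genotypes (proband, mother, father), the pipeline recovers this
landscape in five steps: site classification, ROH calling, clustering,
disomy typing, and breakpoint refinement.

# Site classification

Every biallelic-or-multiallelic site is assigned exactly one category:

| Category | Pattern |
|---|---|
| `MAT_ISO_SUPPORT` / `PAT_ISO_SUPPORT` | proband homozygous non-reference, that parent carries the allele, the other parent is homozygous reference |
| `BIPARENTAL_CONSISTENT` | some assignment of the proband's two alleles gives one to each parent |
| `MAT_HET_SUPPORT` / `PAT_HET_SUPPORT` | proband heterozygous, not biparentally explicable, but fully explicable by one parent alone |
| `MENDELIAN_ERROR_OTHER` | a proband allele absent from both parents, or an inconsistency not matching a UPD pattern |
| `UNINFORMATIVE` | missing genotypes, or none of the above |

Iso-support takes precedence over biparental consistency: `1/1, 0/1, 0/0`
is counted as maternal iso support even though a biparental reading exists,
because under biparental inheritance such sites occur only through
genotyping error, while inside isodisomy they occur at every
parent-heterozygous marker. The het-support categories capture
heterodisomy: `1/2, 1/2, 0/0` cannot be biparental (the father contributes
no allele) but is exactly what heterodisomy of the maternal homologs
produces.

A population-frequency filter (`af_threshold`, default 0.01) demotes
supportive sites whose alternate allele is common: common alleles produce
supportive-looking patterns by chance (e.g. both parents and the proband
homozygous alternate at a common SNP is biparental, but one miscall away
from an iso pattern). The category is kept; only the `supportive` flag is
withdrawn, and `af_filtered` records the demotion. Sites with unknown
frequency are never filtered.

```{r}
classify_site("1/1", "0/1", "0/0", pop_af = 0.001)[, c("category", "supportive")]
```

# ROH calling

Isodisomy is distinguished from heterodisomy by runs of homozygosity
(ROH) in the proband. `call_roh()` decodes a two-state hidden Markov model
over the proband's called genotypes with the Viterbi algorithm:

* emission inside ROH: heterozygosity probability `p_het_in_roh = 0.005`
  (residual genotyping error);
* emission outside: `max(2 af (1 - af), 0.05)` from the site's population
  frequency, floored so that rare-variant-dense regions are not
  misclassified, and `0.25` where the frequency is unknown;
* state switch probability `t_switch = 1e-4` per marker step;
* uniform initial state distribution, so the decoding is not biased toward
  either state at the chromosome start;
* ties broken toward the non-ROH state, so ROH is only called on positive
  evidence.

Decoded runs shorter than `min_length_bp` (1 Mbp) or with fewer than
`min_markers` (25) are discarded. The implementation is verified
exhaustively against `brute_force_roh()`, which enumerates all `2^n` state
paths for small inputs.

# Clustering, typing, refinement

Supportive variants are clustered per chromosome by a gap rule: a new
cluster starts whenever the gap to the previous supportive variant exceeds
`max_gap_bp`. Clusters must span at least `min_span_bp` (4 Mbp) and
contain at least `min_support` (20) supportive variants. A cluster is
attributed to a parent only if *every* supportive member names that parent;
mixed clusters are reported as ambiguous and dropped with a warning —
genuine UPD produces single-parent evidence, so mixtures indicate artifact.

Clusters are then split along ROH boundaries and typed by ROH coverage:
fraction of the segment covered by proband ROH at or above
`iso_coverage_threshold` (0.8) is isodisomy, below is heterodisomy.

**Breakpoint refinement.** The raw cluster boundary systematically
overshoots the true crossover, because iso-pattern supportive variants
(proband hom-alt, parent hom-alt, other parent hom-ref) continue to occur
inside a heterodisomy region wherever the transmitting parent is
homozygous. The only sites that discriminate the two states are
*parent-heterozygous* sites: inside isodisomy the proband is homozygous
there, inside heterodisomy heterozygous. `locate_breakpoint()` therefore
places the boundary at the last parent-het/proband-hom site of the
proximal isodisomy run, reports the gap to the first discordant site as
the uncertainty interval, and tiles the two segments as
`end + 1 == next start`. With error-free genotypes the breakpoint error is
bounded by the local spacing of informative (parent-heterozygous) markers
— no estimator can do better, since no marker between two informative
sites carries any boundary information.

# Unmasking scan

Within called isodisomy segments, `scan_unmasked()` reports every site
where the proband is homozygous non-reference, the transmitting parent
carries the allele, and the other parent lacks it — the configuration by
which a single carrier parent produces a homozygous (potentially
disease-causing) genotype in the child. Candidates can be flagged against
a list of known pathogenic variant keys. For interpretation,
`aggregate_insilico()` combines missense prediction scores by unweighted
mean (≥ 0.7 deleterious, < 0.15 benign, otherwise uncertain) and
`classify_splice()` applies splice-model thresholds (≥ 0.7 deleterious,
≤ 0.2 benign).

# The simulator and study conditions

`simulate_trio()` draws parental haplotypes marker-by-marker from
population frequencies, forms the proband by the configured mechanism, and
returns the dataset with its ground truth. Defaults: a chr15-like map of
102,531,392 bp, 5000 markers placed uniformly at random, allele
frequencies from U[0.01, 0.5], maternal meiosis-II NDJ with one crossover,
no genotyping error. An optional *planted variant* — a rare allele
heterozygous in the carrier parent — rides the transmitted chromatid, so
it becomes homozygous in the proband exactly when it falls in an isodisomy
region.

Three consequences of the generator's design shape the studies:

* **The AF filter is disabled (`af_threshold = 1`) in simulation studies.**
  The generator draws all marker frequencies from U[0.01, 0.5], i.e. at or
  above the default filter threshold, because markers need minor-allele
  carriers to be informative. Applying the 0.01 filter would remove every
  supportive site. On real data the filter stands; in this synthetic
  frequency regime it must be switched off.
* **The clustering gap is widened to 8 Mbp.** Heterodisomy-supportive
  sites occur only where the transmitting parent is heterozygous *and* the
  other parent is homozygous for the opposite allele: per-marker
  probability `E[2af(1-af) * ((1-af)^2 + ...)]` ≈ 0.035 under the
  frequency law, i.e. ≈ 1.7 supportive sites per Mbp at the study's marker
  density, giving exponential-like gaps with mean ≈ 0.6 Mbp. The default
  2 Mbp gap is then exceeded inside a true segment with non-negligible
  probability over a 40 Mbp region, splitting it; 8 Mbp makes such a split
  vanishingly rare while still separating segments from unrelated distal
  clusters. This was derived from the spacing model before any recovery
  experiment was run.
* **The study crossover is drawn on the central half** `[0.25 L, 0.75 L]`,
  so that both resulting segments comfortably exceed the 4 Mbp / 20-variant
  reporting minima and the "exactly two segments" criterion tests the
  caller rather than the reporting filter.

# Worked example

```{r example, fig.width = 7, fig.height = 4}
sim <- simulate_trio(sim_config(
  n_markers = 5000, ndj_stage = "meiosis_II", ndj_parent = "maternal",
  crossover_positions = 0.6 * 102531392, seed = 42
))
res <- run_upd_landscape(sim$data, af_threshold = 1,
                         cluster = cluster_params(max_gap_bp = 8e6))
tidy(res)
glance(res)
evaluate_recovery(res, sim$truth)
autoplot(res)
```

# Limitations

* The simulator draws markers independently (no linkage disequilibrium)
  and uses a uniform genotype-miscall model; real error is
  platform-structured.
* Whole-chromosome heterodisomy without any isodisomic stretch yields few
  proband-ROH markers and relies entirely on het-support evidence;
  mosaicism is not modelled.
* The classifier assumes a correctly matched, contamination-free trio.
* The ROH HMM uses physical distance only through marker order, not a
  genetic map.
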