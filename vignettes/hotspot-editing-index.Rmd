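---
title: "Methods: hotspot-panel editing indices and downstream association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hotspot-panel editing indices and downstream association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adarindex)
```

# The measurement model

A-to-I editing by ADAR enzymes is read by sequencers as guanosine, so an
edited transcript position appears as an A>G mismatch against the reference
when the gene lies on the plus strand, and as T>C when it lies on the minus
strand. The package quantifies per-sample editing over a curated panel of
24 exonic hotspot sites in 20 genes — positions that are recurrently edited
across most tissues and therefore usable as markers of global ADAR
activity — rather than scanning all known editing positions, which is
orders of magnitude slower and more sensitive to alignment artifacts in
repetitive regions.

Two indices summarize a sample:

* the **weighted index** pools reads over sites before taking the ratio,
  $100\sum_i e_i / \sum_i (e_i + r_i)$, so deeply covered sites dominate —
  this is the primary, most stable metric;
* the **mean index** averages per-site rates with equal weight over sites
  with more than five informative reads, reducing the influence of
  expression level at the cost of more per-site noise.

Here $e_i$ and $r_i$ are edit- and reference-supporting read counts after
filtering. Both indices are percentages in $[0, 100]$. An index whose
denominator is empty is *undefined* and reported as `NA`; zero is a
meaningful editing level and is never substituted for missing.

## Read filtering

Counting (in `count_bases_at_site()` / `pileup_sample()`) uses only mapped,
primary, non-duplicate, non-supplementary alignments with mapping quality
at least `min_mapq` (default 20, the conventional uniquely-mapped
threshold), and only base calls with base quality at least `min_baseq`
(default 20). Deletions and reference skips spanning the site contribute
nothing. Bases other than the ref/edit pair (e.g. a sequencing-error C at
an A site) enter neither numerator nor denominator, mirroring the
G/(A+G) definition.

Mate pairs whose reads overlap a site are counted **once per fragment** by
default (`dedup_overlaps = TRUE`), keeping the higher-quality call and
breaking ties in favor of the first-seen mate. Pooled coverage is a weight
in the weighted index, so double-counting a fragment would double its vote.
Some established counters count mates independently; `dedup_overlaps =
FALSE` restores parity with that behavior. Both behaviors are exposed
because upstream conventions differ and neither is canonical.

## Germline exclusion

A germline A/G (or T/C) DNA polymorphism at a panel site is
indistinguishable from editing in RNA reads. When a matched-DNA VCF is
supplied, any *passing* single-nucleotide variant overlapping a panel
position whose unordered ref/alt pair is {A,G} or {T,C} — in either
orientation, and regardless of zygosity, since any such DNA variant
contaminates the RNA signal — removes that site from both indices for that
sample. Other substitutions (A>C, T>G, ...) never trigger exclusion. A VCF
whose contigs share no name with the panel after "chr"-prefix
normalization raises an error instead of silently excluding nothing, since
that almost always means a genome-build or naming mismatch.

## The panel file

The shipped panel (`inst/extdata/hotspot_panel.tsv`) is a TSV with columns
`gene`, `chrom`, `pos` (1-based, fully closed, hg38), `ref_base_plus`,
`label`. The `ref_base_plus` column ("A" for plus-strand genes, "T" for
minus-strand genes) is a **curation annotation added by the packagers**
from gene orientation; public site tables typically print positions
without strand. It determines only which base pair is counted at each
site on real alignments — none of the package's validated quantities
depend on it being correct for any particular external genome — but users
applying the panel to real data should verify it against their annotation
source. Coordinates follow the VCF/readcount convention (1-based); a BED
export (0-based half-open) is provided for interoperability, and both
"chr15" and "15" chromosome dialects are accepted and normalized.

# Downstream analyses

## Pathway activation levels

For a pathway $p$ with member genes annotated as activators
($ARR_{n,p}=+1$), repressors ($-1$) or ambiguous ($0$):

$$PAL_p = 100 \times \frac{\sum_n ARR_{n,p}\,\lg CNR_n}{\sum_n |ARR_{n,p}|}$$

where $CNR_n$ is the gene's expression divided by its geometric mean over
the sample's normalization group. Choices made where the definition is
open:

* "lg" is log base 10; any base only rescales all PALs uniformly, so the
  choice is cosmetic and exposed as `log_base`.
* A pseudocount (default 1) is added before both the geometric mean and
  the ratio, keeping zero-expression genes finite; the underlying
  references are silent on zeros.
* The normalization group is "samples with the same tissue status within
  the same dataset", supplied as a sample→group map; with no map, all
  columns form one group.
* Ambiguous-role genes contribute to neither sum (the literal reading of
  the denominator $\sum|ARR|$), and genes absent from the matrix drop out
  of both sums. A pathway with no measured nonzero-role gene has an
  undefined PAL, with a diagnostic.
* Pathways with more than 10 member gene products are retained
  (strictly greater: a 10-gene pathway is dropped).

Useful identities, all enforced by tests: PAL is 0 when every CNR is 1,
negating all roles negates PAL, and a pathway of $k$ activators at common
CNR $c$ scores $100\lg c$ independent of $k$.

## Instability scores

The MMR-deficiency score is $-\sum \log(x_g + 1)$ over MLH1, MSH2, MSH6,
PMS2 (log base 2 by default); the hypermutator score is a weighted sum of
log expression over a fixed 10-gene signature. The signature coefficients
and the MSI decision line $a\cdot\text{mmr} + b\cdot\text{hyper} + c > 0$
are **mandatory configuration**: the published values are not distributed
here, and shipping invented defaults as if they were the reference values
would be worse than requiring input. The example files under
`inst/extdata/` are labelled synthetic and document only the format.
Samples exactly on the decision line are called MSS (strict inequality);
the call is invariant under joint positive rescaling of $(a,b,c)$. TMB is
mutations per megabase with a user-supplied coding-exome size, and the
insertional-signature score sums log expression of L1Hs, L1PA2, TERT and
APOBEC3B.

## Association framework

Spearman correlation (two-sided, tie-corrected, normal approximation) of
the editing score against each feature, Benjamini–Hochberg adjustment,
then significant sets: positive means $\rho$ strictly above the threshold
(0 by default; 0.2 for the instability-feature screen) *and* adjusted
$p < 0.05$. Sets from several groups (cancer type × dataset) are
intersected, and the intersection size is tested against a null in which
each group's set is redrawn uniformly from the universe at its observed
size, with the small-sample-corrected empirical p-value
$(1 + \#\{\text{perm} \ge \text{obs}\})/(B+1)$. The permutation scheme and
the universe are deliberate design choices: size-preserving uniform
resampling is the standard exchangeable null for set overlap, and since
reasonable analyses differ on whether the universe is "all genes" or
"tested genes", the universe is an explicit argument, defaulting in the
workflow command to the union of tested features. Correlations are
averaged on the Fisher-z scale (`tanh(mean(atanh(r)))`), with $|\rho|=1$
clamped to $1-10^{-12}$ under a warning; group comparisons use the
two-sided Mann–Whitney test with BH across the battery of pairwise
comparisons.

# The synthetic world

The generators exist so every stage can be exercised with known truth, and
their defaults are fixed descriptions of a plausible cohort, not tuning
knobs:

* **Site counts**: edit counts are $\text{Binomial}(d, r)$ at true rate
  $r$ and depth $d$. Default rates are 40% at the NEIL1 and IGFBP7 sites
  and 3% elsewhere — in real tissue these two genes carry the strongest
  hotspot editing (tens of percent) while most panel positions sit below
  5%. Depth is negative binomial (mean 50, size 5) to mimic the uneven
  coverage of expression-dependent RNA-seq; `depth_dispersion = Inf`
  gives fixed depth for closed-form checks.
* **Alignments**: each panel locus is remapped to the centre of its own
  short contig (sidecar table maps back to genome coordinates), and
  single-end 50 bp reads carrying ref/edit alleles are written as SAM,
  converted, sorted and indexed to BAM — so tests traverse the same
  Rsamtools counting path as real data. Optional extra MAPQ-10 reads
  exist purely to verify the filter.
* **Expression**: planted features follow
  $\log_2 x = \text{baseline} + \delta\,\text{effect}\cdot z(\text{score}) +
  \mathcal{N}(0, \sigma)$ with $\delta \in \{+1, -1\}$, nulls are
  independent log-normal noise, and the named score genes (MMR,
  hypermutator signature, retroelement features) are always present as
  null rows. Defaults: effect 2 (log2 units per SD of editing score),
  noise SD 0.5, 300 features with 20 + 20 planted.
* **Germline VCF**: `round(fraction × n_sites)` sites drawn without
  replacement get a passing A>G (T>C) SNV.

All generators are seed-deterministic (byte-identical outputs for a fixed
seed). What a green test does **not** establish: the simulator has no
splicing, no fragment-length or GC model, no alignment ambiguity, no
FFPE/autopsy RNA degradation, and planted monotone effects are far cleaner
than real covariation — so passing recovery tests validates the
*machinery*, not cohort-level biological claims, which require the
original patient data and are out of scope.

# Numerical and degenerate-input choices

* Rates and indices are kept at full floating precision; rounding is
  presentation-only.
* The mean-index depth filter is strictly "more than five" reads; a
  depth-5 site is excluded. The weighted index applies no depth filter by
  default — the printed definitions attach the filter only to the mean
  metric — but `weighted_min_total` can impose one, exposing the ambiguity
  as configuration rather than resolving it silently.
* Whether zero-coverage sites are "dropped" or treated as 0/0 contributions
  is mathematically indistinguishable in both indices; `n_sites_used`
  counts sites with at least one informative read.
* Empty intersections give permutation $p = 1$ by construction; the
  empirical p-value is bounded below by $1/(B+1)$.
* Ties in mate-overlap deduplication keep the first-seen mate; ties on the
  MSI decision line go to MSS; BH preserves input order and passes `NA`
  through.
* The workflow layer uses JSON configuration (guaranteed parser
  availability) and writes provenance headers (package version, config
  hash, seed — no timestamps, keeping reruns byte-identical). Exit codes:
  0 ok, 1 input error, 2 configuration error.

# Known limitations

* The per-read counter is pure R; at 24 sites per sample this is
  negligible next to I/O, but the package is not a general-purpose
  pileup engine.
* Germline exclusion reads whole VCFs; for exome-scale files, pre-slicing
  to the panel regions is advisable.
* The panel's strand annotation is curation, not computation (above).
* Single-cell data, coordinate liftover between genome builds, discovery
  of new editing sites, and the external genome-wide editing indices are
  out of scope.
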