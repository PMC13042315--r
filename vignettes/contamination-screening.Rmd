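---
title: "Screening genome resequencing data for intraspecies contamination with B-allele frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening genome resequencing data for intraspecies contamination with B-allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bafscreen)
```

## The problem

When short reads from one individual are mixed with a small proportion of
reads from a second individual of the same species, the contamination is
easy to miss: mapping rates, coverage and overall base quality all look
normal, and between-species contamination screens find nothing. Yet even a
5-10% admixture of same-species reads measurably distorts downstream
population genomics -- heterozygosity estimates, ancestry proportions and
phylogenetic placement.

The screen implemented here works from the B-allele frequency (BAF): at
every biallelic site, the fraction of mapped reads carrying the
non-reference allele, `alt_depth / depth`. In clean data BAFs concentrate
in discrete bands determined by ploidy: a site with $k$ alternate copies
out of ploidy $p$ sits at $k/p$, so haploids and homozygous sites sit at
1.0, heterozygous diploids add a band at 0.5, triploids at 1/3 and 2/3, and
so on. A contaminant fraction $c$ shifts every band: the recipient
contributes $(1-c)\,k/p$ and the contaminant adds $0$ or $c$ depending on
which allele it carries, giving the two-population band set

$$\{(1-c)\,k/p\}_{k=1..p} \;\cup\; \{(1-c)\,k/p + c\}_{k=0..p} \setminus \{0\}.$$

A haploid with 5% contamination by a reference-like strain therefore shows
its SNP band at 0.95 instead of 1.0 -- a genome-wide signature, unlike
aneuploidy, which shifts bands on one chromosome only.

```{r bands}
expected_bands(3, 0)$positions
expected_bands(1, 0.05, contaminant_matches_reference = TRUE)$positions
```

## Fitting the band model

Visual inspection of BAF plots is the traditional screen; this package
operationalizes it as a robust band-fit loss. For a profile of sites with
BAF $b_i$ at depth $d_i$, the loss of a candidate band set is the mean over
sites of

$$\min_B \; \frac{|b_i - B_\varepsilon|}{\sqrt{B_\varepsilon(1-B_\varepsilon)/d_i}}
\quad \text{truncated at } 3,$$

where $B_\varepsilon = B(1-\varepsilon) + (1-B)\varepsilon$ is the band
position after symmetric sequencing error $\varepsilon$. Measuring distance
in binomial standard deviations makes bands at 0.5 appropriately "wide" and
bands at 1.0 "narrow"; truncation at 3 SD keeps off-model sites (repetitive
regions produce variants at arbitrary frequencies) from dominating the fit.

Ploidy is classified by fitting the clean band sets for $p = 1..4$.
Because band sets are nested (all data fitting $\{0.5, 1\}$ also fit
$\{0.25, 0.5, 0.75, 1\}$), a plain argmin always drifts to higher ploidy;
the classifier therefore takes the smallest $p$ whose loss is within 10% of
the best, a parsimony tie-break.

The contamination fraction is estimated by scanning $c$ over 0.01-0.45 in
steps of 0.005 and refining the best grid point with a local optimizer --
deterministic and initialization-free, unlike EM. The scan stops at 0.45
because higher fractions are genuinely confounded with polyploidy (a 50/50
mixture of two haploids is statistically a heterozygous diploid). A genome
is *called* contaminated only when four conditions hold:

* $\hat c \ge 0.05$ -- the screening threshold. A 1% threshold is not used
  because at moderate depth (30-50x) a 1% band is indistinguishable from
  sequencing error around 1.0.
* at least 5% of SNP sites support a *secondary* band: within $\pm 0.03$ of
  a contamination-shifted band and separated from every clean band by more
  than both 0.03 and two binomial SDs of that band at the site's depth.
  The depth-scaled guard stops ordinary sampling noise around 0.5 (SD
  $\approx 0.056$ at 80x) from masquerading as secondary support -- without
  it, a clean heterozygous diploid can be "fit" by a spurious
  $\hat c \approx 0.07$ that splits the 0.5 peak.
* the secondary signal is present on every chromosome with at least 100
  SNPs. Contamination is genome-wide; a shift confined to one chromosome is
  reported as `aneuploidy_suspect` instead (a trisomic chromosome in a
  diploid produces exactly the 1/3 / 2/3 bands that a $c = 1/3$ fit would).
* median depth is at least 30x; below that the call is flagged unreliable.

All four thresholds are arguments of `estimate_contamination()` with these
defaults.

## What the synthetic-data generator emulates

Real contaminated mixtures are made by subsampling and pooling read sets;
the generator reproduces the statistics that matter for BAF screening at
the allele-count level, because per-site BAFs depend only on the proportion
of reads from each source:

* **Lineage panel.** A pure-birth tree over the panel strains, with the
  reference sequence at the root and a single-rate substitution process
  (optional transition bias) along branches; branch lengths are rescaled so
  the mean pairwise divergence equals `divergence` (default 0.01, i.e.
  ~0.5% per strain against the reference, matching typical within-species
  strain identities of 99.3-99.5%).
* **Strains.** A strain of ploidy $p$ is $p$ copies of its lineage sequence
  with private heterozygous sites added at rate `heterozygosity` (default
  0.005; at each such site 1..$p-1$ copies carry the derived base so every
  intermediate band is populated). The published studies do not state their
  strains' heterozygosity; 0.5% is typical of wild heterozygous diploid
  yeasts and is fixed once here.
* **Read counts.** Site depth is Poisson with mean `depth` (default 80x,
  within the 75-165x range of the real screens, and above the 30x
  reliability floor); of $d$ reads, $m \sim \mathrm{Binomial}(d, c)$ come
  from the contaminant; each read draws an allele uniformly from its
  strain's haplotypes and is flipped ref/alt with error `eps` (default
  0.002). One record is emitted per site where any haplotype differs from
  the reference.
* **Coverage gaps.** A strain contributes no reads from `gap_frac`
  (default 5%) of its genome, in 100 bp blocks -- emulating deletions and
  divergent regions that fail to map. Contaminant alleles can be called
  *homozygously* only where the recipient has no coverage; this asymmetry
  (the donor mapping better than the recipient) is what lets heavy
  contamination drag a genome toward the contaminant in trees. The
  contaminant strain is simulated without gaps.
* **Repeat-like sites.** 1% of emitted sites get a uniform BAF, mimicking
  multi-copy regions whose variants appear at arbitrary frequencies.

Features deliberately not emulated: aligner behaviour and mapping bias,
indels and structural variation, per-base quality profiles, PCR duplicates.
Passing tests therefore demonstrate the statistical machinery under an
idealized mapping, not robustness to alignment artefacts.

## The consensus caller

The caller scores three genotypes (two in haploid mode) with binomial
likelihoods $\mathrm{Bin}(a; d, \theta)$, $\theta \in \{\varepsilon, 0.5,
1-\varepsilon\}$, under a flat prior, and phred-scales the posterior error
of the best genotype, capping at Q99 and masking calls below Q40 (estimated
error above 1 in 10,000) -- the thresholded consensus-FASTA convention of
standard mpileup/consensus pipelines, reduced to the features that the
downstream claims depend on (genotype category and Q40 masking; no BAQ, no
strand or mapping features, depth capped at 100,000). Heterozygous calls
become two-base IUPAC codes; masked calls become `N`. Diploid mode is the
default for all ploidies, mirroring how standard pipelines are run blind to
ploidy; contamination then surfaces as heterozygous calls at the sites
where recipient and contaminant differ.

Two consequences, both reproduced by the experiment driver
(`run_experiment()`): the masked fraction barely moves with contamination
(binomial quality at 80x is decisive for almost any allele ratio), while
high-quality heterozygous calls grow steeply -- at 80x a site needs about
11 minority reads to be called het at Q40, so the het count is negligible
at 5% contamination ($P(\mathrm{Bin}(80, 0.05) \ge 11) \approx 0.002$),
partial at 10% ($\approx 0.2$) and nearly complete at 20%
($\approx 0.93$). That is why haploid heterozygosity reaches clean-diploid
levels only around 20% contamination.

## Distances, trees and placement

Consensus sequences are compared with pairwise-deletion distances:
ambiguity codes and `N` are missing data, so heterozygous sites carry no
distance information -- the property that makes phylogenetics sensitive to
contamination in a non-obvious way (the recipient's own SNPs vanish into
het calls while its distance to the contaminant collapses). TN93 distances
use the closed-form estimator with empirical base frequencies pooled per
pair; F84 distances maximize the likelihood under a fixed
transition:transversion ratio (default 0.5, the classic `dnadist`
setting; ratios below the model's frequency-determined minimum fall back to
the F81 limit). Neighbor joining is implemented with deterministic
tie-breaking (lowest index pair) and negative branch lengths clamped to
zero with the deficit moved to the sister branch; it is exact on additive
matrices. Bootstrap support resamples alignment columns, drops replicates
with saturated (undefined) distances, and counts bipartitions of the
full-data tree. Exact 1-D k-means (dynamic programming over sorted values)
supports panel thinning by distance from an anchor strain.

Placement diagnostics ask whether the focal genome attaches next to the
contaminant's lineage: in `run_experiment()` the recipient and contaminant
are drawn from lineages at *typical* (mean) pairwise divergence rather
than the most distant pair. This matters: strains of one species mapped to
a strain reference share a large backbone of non-reference alleles (their
common ancestry below the reference), and it is precisely those shared
homozygous calls that keep a heavily contaminated genome inside the tree
instead of collapsing toward the reference; two maximally distant lineages
in a reference-rooted panel would share nothing, which no real
within-species pair does. The "lineage" of each focal strain is its set of
close relatives (tips within half the mean pairwise divergence).

## Problem sizes and numerical choices

The package's own validation runs use: 1.5 Mb genomes over 2 chromosomes
(about 20,000 SNP sites at 1% panel divergence) for contamination-fraction
recovery across 20 seeds; 52-strain panels over 50 kb alignments for the
tree experiments across 10 seeds; and 100 kb genomes for base-call
composition. These sizes keep the full suite inside a few minutes while
leaving every per-test statistic (hundreds to tens of thousands of sites)
comfortably above its noise floor.

Other numerical details: grid scan before local refinement avoids the
optimizer finding a secondary minimum of the band loss; the band-fit SD has
a floor of $10^{-6}$ in the variance so error-free bands at exactly 1.0
remain well-defined; Fisher r x 2 probabilities are accumulated in log
space with a $10^{-7}$ slack on the probability-ordering comparison; the
F84 likelihood is maximized in two passes (coarse, then a narrow bracket)
for closed-form-level precision.

## Limitations

* Contamination above ~45% is reported as indistinguishable from
  polyploidy, by design.
* The screen assumes a single contaminant; multiple simultaneous
  contaminants blur the secondary bands.
* Between-species contamination is out of scope (reads from another
  species mostly fail to map).
* The caller's flat genotype prior slightly favours het calls relative to
  priors used by production callers; downstream conclusions depend only on
  category counts and are insensitive to this.
* Ancestry/admixture analyses are not reimplemented; contamination's
  effect there is only reflected indirectly through the heterozygosity
  properties.

## A worked screen

```{r worked, fig.width = 7, fig.height = 3}
ref <- random_reference(2e5, n_chrom = 2, seed = 1)
panel <- simulate_panel(ref, n_strains = 4, divergence_target = 0.01, seed = 1)
recipient <- simulate_strain(panel, "L1", ploidy = 1, seed = 2)
donor <- simulate_strain(panel, "L4", ploidy = 1, seed = 3, gap_frac = 0,
                         role = "contaminant")
records <- simulate_read_counts(recipient, donor,
                                mixture_spec(c = 0.10, depth = 80, seed = 4))
profile <- compute_baf(records, min_depth = 10, genome_id = "demo")
call <- estimate_contamination(profile, p = classify_ploidy(profile)$ploidy)
call
plot_baf(profile, bands = expected_bands(1, call$c_hat))
```
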