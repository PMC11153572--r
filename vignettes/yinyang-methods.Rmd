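---
title: "Detecting exclusive yin-yang haplotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting exclusive yin-yang haplotypes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yinyangscan)
```

## The problem

A yin-yang haplotype pair is a pair of haplotypes that differ at every
constituent locus. An *exclusive* pair is one for which intermediate
("mosaic") haplotypes mixing the two forms are absent or vanishingly rare,
so essentially every chromosome in the population carries one of the two
complete forms. Because the reference/alternate designation of common human
variants is essentially arbitrary, an exclusive pair discovered from VCF
data can be defined - restrictively but conveniently - as one haplotype
carrying only reference alleles and the other only alternate alleles at
every member SNP. Under that definition the pair leaves a distinctive
fingerprint in *unphased* genotypes: every subject carries 0, 1 or 2 copies
of the alternate haplotype, so all member SNPs have *identical dosage
vectors* across subjects, and no phasing is required to find them.

`yinyangscan` implements the full discovery and characterisation procedure:
a windowed genotype-distance scan, greedy chain assembly, exclusion of
documented alternate-scaffold regions and poorly called lead SNPs, a
repeat-artifact filter, per-haplotype metrics (genetic length, fixation
indices with matched controls, background variation), ancestry
classification against chimpanzee and Neanderthal outgroups, and gene/GWAS
annotation. A seeded generator produces synthetic cohorts with planted
structure so every stage can be validated without external data.

## The scan

**Average genotype distance.** For variants $v$ and $w$ with per-subject
alternate-allele dosages $a_s, b_s \in \{0,1,2\}$,
$$ d(v, w) = \frac{1}{N} \sum_{s=1}^{N} |a_s - b_s|, $$
with $N$ the number of subjects called at both loci. This phase-free proxy
is far cheaper than $R^2$ or $D'$, and $d \approx 0$ implies near-complete
LD with matching ref/alt orientation. Subjects missing a call at either
locus are excluded from numerator and denominator alike: with the canonical
threshold $d \le 0.0015$ and 2504 fully called subjects, two variants may
differ by one allele in at most 3 subjects, and the per-pair denominator
generalises that bound gracefully in the presence of missingness. A `./.`
genotype is always treated as missing, never as dosage 0.

Each variant is compared with its next `window = 10` successors on the same
chromosome (fewer at chromosome ends, never across a boundary).

**Chain assembly.** Starting from every variant, a chain is grown greedily:
from the current last member, the *nearest* following variant within the
next `gap_max + 1 = 10` positions with $d \le$ `distance_threshold` is
appended until none qualifies. Chains with fewer than `min_snps = 20`
members are dropped. Two consequences of this construction are worth
stating:

* *Extension reference point.* Distance is always measured from the most
  recently added member - the windowed table stores nothing else - so
  near-identical genotype vectors can drift slightly along a very long
  chain. This is inherent to the windowed formulation and is accepted.
* *De-duplication.* Because extension is deterministic (nearest qualifying
  successor), each variant has at most one successor, and a chain started
  at an interior member of a longer chain is exactly a suffix of it.
  Reporting only *maximal* chains - those whose start is never chosen as a
  successor - therefore removes every nested duplicate while keeping
  overlapping-but-non-nested chains, which can arise when two chains merge.
  The tests verify this against a brute-force search over all starting
  points on hundreds of random instances.

**Exclusions.** A candidate whose physical span overlaps a documented
alternate scaffold/patch region by at least one base pair is discarded
(span overlap was chosen over member-SNP overlap as the stricter reading),
as is any candidate whose lead SNP - the first member, carrier of all
per-haplotype summary statistics - is called in fewer than `lead_call_min`
unrelated subjects. The default 2000 is the canonical value for a
2504-subject cohort (about 80%); for the synthetic 500-subject scenarios in
this package the same fraction, 400, is used. The callability rule is
applied to lead SNPs only, as stated for the original procedure; non-lead
members are not re-checked.

Coordinates are 1-based inclusive externally (VCF convention) and half-open
0-based internally. A haplotype's physical length is last member position
minus first member position, so printed coordinates reproduce printed
lengths exactly (e.g. 3:121056668-121325164 gives 268.5 kb). Dosages are
taken from the VCF as recorded, with no re-polarisation to an ancestral
allele and no sex-specific handling of X (males may appear as 0/2-coded);
the definition being tested is explicitly in terms of reference/alternate
designations.

## The repeat-artifact filter

An unrecognised repeat - two near-identical paralogous sequences whose
reads co-map - masquerades as a run of SNPs heterozygous in almost every
subject, with roughly doubled read depth and, when more than two paralogs
collapse, skewed allele balance. Evidence is collected at each candidate's
lead SNP: genotype counts over unrelated subjects, and depth/allele-balance
summaries over *all* subjects including children (depth is a property of
the sequencing, not the pedigree). Verdicts are checked in order:

1. `repeat_all_het` - every called genotype heterozygous, a biological
   impossibility for a real variant;
2. `repeat_missing_hom` - heterozygote fraction above `het_max = 0.53` and
   one or both homozygote classes essentially absent. "Essentially absent"
   is operationalised as min(n_RR, n_AA) below max(10, 0.5% of called
   subjects); the original description gives an example (7 RR among 2503)
   but no cutoff, so the bound is configurable;
3. `repeat_low_AA` - fewer than `min_minor_hom = 20` AA homozygotes
   together with heterozygote depth mean above `depth_flag = 55`. The
   depth flag defaults to the midpoint between typical clean (~34) and
   artifact (~74) heterozygote depth means; depth corroborates rather than
   defines this class, so the flag is configurable.

The low-AA rule deliberately carries no upper bound on the heterozygote
fraction: guarding it with `het_fraction <= het_max` would make the
classifier non-monotone (an evidence row flagged at heterozygosity 0.50
could become *clean* at 0.60, which is absurd for a filter whose whole
premise is that heterozygote excess indicates artifacts). The ordered rules
guarantee that raising the heterozygote fraction, everything else fixed,
never converts a repeat verdict to clean; a property test sweeps this.
Heterozygosity here is always the *observed heterozygote call fraction*,
not expected Hardy-Weinberg heterozygosity (which is bounded by 0.5 and
could never exceed 0.53).

## Per-haplotype metrics

**Genetic length.** Given a recombination map of per-interval rates in
cM/Mb, a chain span's genetic length is the overlap-pro-rated sum of rate
times overlap. The statistic is additive under any split of the span; map
gaps contribute zero and chromosomes absent from the map yield `NA` rather
than zero, so "no map" is never confused with "no recombination".

**Fixation index.** With $p_i$ the frequency of the globally minor allele
in superpopulation $i$, $c_i$ the relative sample size and
$\bar p = \sum_i c_i p_i$:
$$ F_{ST} = \frac{\bar p(1-\bar p) - \sum_i c_i\, p_i(1-p_i)}
                 {\bar p(1-\bar p)}. $$
The same allele is tracked in every superpopulation, so individual $p_i$
may exceed 0.5; the index is undefined (returned as `NA`) when
$\bar p \in \{0,1\}$. Two versions are computed per lead SNP: all
superpopulations, and all except AFR (weights renormalised), to allow for
frequency differences created purely by the out-of-Africa bottleneck.
$c_i$ is taken as the count of unrelated subjects with called genotypes at
the SNP - "relative sample size" admits subjects or chromosomes, and
subjects were chosen; with diploid autosomal data the two differ only under
differential missingness. Each lead SNP is paired with a control SNP on the
same chromosome, outside every chain span, with the nearest global MAF;
exact MAF equality is rarely attainable, so candidates within
`control_maf_tol = 0.005` qualify, and ties break by a seeded draw so runs
are reproducible.

**Background variation.** Singletons and doubletons (minor allele observed
exactly once or twice across all unrelated subjects) are assigned to the
superpopulation(s) of their carriers - a doubleton with carriers in two
superpopulations counts once in each - and expressed per Mb per subject,
inside versus outside the union of autosomal chain spans. The union (rather
than the sum of spans) is used for the inside length so overlapping chains
are not double-counted. Average heterozygosity sums
$2\,\mathrm{MAF}(1-\mathrm{MAF})$ over all variants in the region using
superpopulation-specific MAFs, per Mb. These statistics need the
*unfiltered* variant set, which is why MAF filtering is a separate step
from loading.

## Ancestry classification

Each chain member called in both the chimpanzee and the Neanderthal (with
alleles matching the VCF ref or alt; a third allele makes the site
non-informative) falls into one of four categories by where the alternate
allele appears: neither outgroup, chimpanzee only, Neanderthal only, or
both. Haplotypes with at least `min_informative = 5` informative members
are classified:

* **derived** - all informative sites `alt_in_both` or all
  `alt_in_neither`: both outgroups carry one complete haplotype, the other
  arose entirely in humans after the human-Neanderthal split;
* **ancient** - one outgroup carries the all-reference and the other the
  all-alternate haplotype at every informative site: both forms predate
  the split;
* **mixed** - discordant sites in both directions, suggesting
  recombination between earlier haplotypes;
* **partial** - anything else: an outgroup carries a partial form,
  implying gradual assembly with subsequent loss of intermediates.

Only chain members are classified (non-member variants inside the span are
ignored), and X-chromosome chains are skipped because the outgroup calls
are autosomal. The five classes (including `uninformative`) are mutually
exclusive and exhaustive, and invariant under swapping the outgroup labels
where they should be; both properties are tested over random category
multisets. One known caveat is inherited from the classification scheme
itself: if both haplotypes segregated in Neanderthals, a pair's
ancient/derived assignment depends on which haplotype the single sampled
Neanderthal genome happens to carry; no correction is attempted.

## The synthetic generator

`scenario_config()` / `simulate_cohort()` emulate exactly the structure
the scan assumes:

* **Planted pairs** - at each pair, every chromosome copy is independently
  the all-alternate or all-reference haplotype with its superpopulation's
  configured frequency, so Hardy-Weinberg holds in expectation (the
  implicit null of a randomly mating population). Optional leaked
  intermediates replace single chromosome copies with one-breakpoint
  recombinants at a uniform position - the mechanism by which real
  exclusive pairs decay.
* **Repeat-artifact loci** - runs of SNPs with a configured heterozygote
  (and optional AA) fraction, constant per subject across the run, with
  negative-binomial read depth (overdispersed sequencing depth is
  standard; only means and sds matter to the filter) and beta-distributed
  heterozygote allele balance applied directly to the depth so the
  observed balance sd recovers the configured value at any depth.
* **Background** - common SNPs as Hardy-Weinberg draws at uniform
  frequencies, plus singletons and doubletons placed uniformly over
  subjects and positions.
* **Outgroups** - `simulate_outgroups()` realises each pair's configured
  class (derived / ancient / partial / mixed) exactly, closing the loop
  with the classifier.

The default scenario is the package's reference study condition: 500
unrelated subjects split evenly over AFR/AMR/EAS/EUR/SAS plus 10 children,
one 2 Mb chromosome, five planted pairs of 20-40 SNPs spanning 12-25 kb
(sizes around the scale reported for real exclusive pairs, about 35 SNPs
over about 16 kb), one pair strongly AFR-divergent (0.70 vs 0.20) for
differentiation recovery, three repeat loci covering the three artifact
signatures with depth mean 74.3/sd 34.6 and balance sd 0.11 against clean
depth 33.9/sd 10.8 and balance sd 0.03 (the published contrast between
artifact and clean lead SNPs), common-SNP density 0.5/kb and
singleton/doubleton densities of 4 and 1.5 per Mb per subject. The
generator is fully determined by its seed.

What the generator does *not* emulate - and hence what passing tests do
not show about real data: LD decay around the planted spans (background
SNPs are independent), realistic demography or site-frequency spectra
beyond the singleton/doubleton classes, sex-chromosome dosage coding,
genotyping error outside the planted artifact loci, and real pedigree
structure (children are labelled, not simulated as trios). Recovery of
planted pairs at sensitivity 1.0 on these scenarios validates the
algorithmic chain - not the behaviour of the thresholds on real
sequencing noise.

## Numerical and degenerate-input choices

* A variant pair with no subject called at both loci has undefined
  distance; the pair is skipped with a warning and can never join a chain.
* `fst()` returns `NA` when the pooled frequency is 0 or 1; lead SNPs
  with fewer than two informative superpopulations likewise yield `NA`.
* Empty excluded-region files, empty GWAS joins and scenarios with no
  planted pairs are all valid and produce empty (not failing) results;
  the stage ledger still balances, trivially.
* Control-SNP matching with no candidate within tolerance records a
  missing control rather than relaxing the tolerance.
* All randomised steps (generator, tie-breaks) consume explicit seeds and
  restore the caller's RNG state.

## Problem sizes

The test suite and acceptance script run entirely on synthetic data at the
reference scale above (500-subject cohorts, about 8,000 variants, of which
about 1,200 pass the MAF filter), with oracle-equivalence suites on
hundreds of random instances of up to 50 variants and 100 subjects, and
single worked-example fixtures at 2504 subjects where a published count is
tied to that cohort size. These sizes were chosen as the smallest at which
every planted feature (five pairs, three artifact classes, four ancestry
classes, superpopulation differentiation) is individually resolvable;
the implementation itself is vectorised over the distance window and runs
comfortably on cohorts orders of magnitude larger.

## Limitations

* The scan finds only the restricted all-reference/all-alternate form of
  yin-yang pairs; pairs whose members mix ref and alt designations are
  invisible to it by design.
* Greedy nearest-successor extension is faithful to the windowed
  formulation but is not guaranteed to find the longest possible chain in
  pathological near-threshold configurations.
* The repeat filter's three thresholds approximate artifact groups that
  were described, not algorithmically defined; they are all exposed as
  parameters.
* GWAS annotation joins on identifier strings; mapping positions to rsIDs
  is out of scope and identifiers must be supplied in the inputs.
* Gene-ontology enrichment and haplotype phasing are out of scope.
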