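---
title: "radsexmap: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{radsexmap: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Species with homomorphic sex chromosomes cannot be sexed cytogenetically;
the sex-determination system (XY vs ZW) has to be inferred from genotype
patterns. In an XY system, markers in linkage disequilibrium with the
sex-determining locus show an excess of heterozygotes in males — males carry
one X and one Y haplotype, and the Y haplotype accumulates alleles absent
from the X pool — while females, carrying two X haplotypes, are mostly
homozygous. When X and Y diverge strongly, the Y allele assembles as its own
RADtag and is sequenced in males only. A ZW system mirrors every statement
with the sexes swapped. Because recombination between young sex chromosomes
is common, linkage is typically *imperfect*: the inference machinery must
tolerate heterozygous homogametic individuals and homozygous heterogametic
ones, which is why threshold criteria plus an explicit permutation null are
used instead of exact segregation logic.

`radsexmap` implements that machinery, together with the supporting stages a
RADseq study needs: genotype QC, a Mendelian segregation filter for the F1
mapping family used to build a linkage map, an association fallback with FDR
control, and map utilities to localize the candidate region.

# Genotype container and filters

Genotypes are bi-allelic codes AA/AB/BB/missing (stored 0/1/2/NA) with
optional per-call read depth; a missing call and depth 0 are kept mutually
consistent. Monomorphic markers (no alternate allele) are first-class
citizens because Y/W-specific tags typically surface as monomorphic markers
present in one sex.

Threshold semantics follow the wording they implement, uniformly: "at
least"/"minimum" thresholds are inclusive, "below"/"above"/"more than" are
strict. Concretely: `filter_markers()` masks calls with depth outside
`[depth_min, depth_max]` (defaults 5 and 50) *before* evaluating call rate
(default ≥ 0.60) and MAF (default ≥ 0.02, computed over called genotypes
only); `filter_samples()` drops samples with *more than* 40% missing calls,
never auto-dropping parents; `dedupe_replicates()` keeps the least-missing
member of each replicate group, ties broken by lexicographic sample id for
determinism. A separate ≥ 7× depth knob exists for error-rate control via
the same `depth_min` argument. Each removed marker is attributed to the
first criterion it fails, so removal accounting is auditable; no attempt is
made to reproduce any particular study's (under-specified) marker
bookkeeping.

# The Mendelian segregation filter

For a bi-allelic marker in an outbred F1 family there are exactly seven
segregation models: AAxAA, BBxBB, AAxBB (uninformative: all offspring
identical), AAxAB (offspring AA:AB = 1:1), BBxAB (BB:AB = 1:1), ABxAB
(AA:AB:BB = 1:2:1), and ABx– — the special case of one heterozygous parent,
one unsequenced parent, and offspring AA:BB = 1:1 (AB offspring are
*incompatible* under this model; biologically it is best read as a
null-allele artifact, and we implement it exactly as defined without
modelling its mechanism).

A marker passes a model when (a) the fraction of called offspring outside
the model's expected classes is ≤ 2% (`max_error`), and (b) for multi-class
models, the chi-square goodness-of-fit of compatible class counts against
the expected ratios is not rejected at alpha = 0.005 (no continuity
correction, df = classes − 1). Single-class models have df 0: only the error
criterion applies. Missing offspring genotypes never count as errors.

Among passing models, a model is *parent-compatible* if both observed parent
genotypes match its unordered parental configuration, or exactly one parent
is missing and a single imputation creates the match (recorded as a
correction); ABx– is compatible only with exactly one called-AB parent plus
one missing parent. Exactly one parent-compatible passing model is assigned.
Zero → the marker is removed as a parent mismatch; several → removed as
*ambiguous*. We deliberately do not break ties by best p-value: the source
procedure does not state a tie-break, and inventing one would silently
reclassify markers; removing them keeps the choice auditable (ambiguous
counts are reported separately). Retained markers have incompatible
offspring genotypes silenced (set missing) and imputed parents written back.

Two consequences worth knowing. First, with *zero* genotyping error the
filter still removes a small fraction of markers: at alpha = 0.005 the
chi-square rejects ≈ 0.5% of perfectly Mendelian markers by sampling noise
alone (binomial counts at n ≈ 318 offspring). Our acceptance tests therefore
assert that *every assigned* type equals the simulated truth and that ≥ 99%
of informative markers are recovered — a verbatim "100% of informative
markers assigned" is unattainable in any finite family, not a software
property. Second, silencing can only touch genotype classes outside the
assigned model, so with correct assignment the silenced set is a subset of
genuine errors; on 1%-error simulations we require ≥ 95% of silenced calls
to coincide with injected errors.

# Sex-linkage criteria and orientation

Five criteria are evaluated per marker (or RADtag), each under both XY and
ZW orientation (ZW swaps the sexes everywhere):

1. X-allele frequency > 0.95 in the homogametic sex and in [0.4, 0.6]
   (inclusive) in the heterogametic sex.
2. No called homogametic individual heterozygous, and ≥ 50% of called
   heterogametic individuals heterozygous.
3. RADtag absent in every homogametic individual and present in ≥ 50% of
   heterogametic individuals (tag level; includes monomorphic tags; exempt
   from the call-rate gate).
4. Heterogametic heterozygosity > 0.75; homogametic sex: > 80% homozygous
   for the X allele, < 20% heterozygous, < 10% homozygous for the Y-linked
   allele.
5. As 4 but heterozygosity > 0.55 and *no* homogametic individual homozygous
   for the Y-linked allele (a count, not a frequency).

Criteria 1, 2, 4, 5 apply only to markers called in ≥ 60% of *each* sex;
frequencies are computed over called genotypes.

**Allele orientation.** The criteria reference "the X allele" and "the
reference allele", but a de novo pipeline has no oriented reference. We
designate the X (or Z) allele as the major allele among called
homogametic-sex genotypes — the only orientation consistent with "females
homozygous for the reference allele" under XY. An exact 0.5/0.5 tie is
evaluated under both orientations and hits if either passes (for criterion 1
the tie can never hit, since the homogametic frequency must exceed 0.95).
All boundary comparisons implement the wording: "more than"/"higher
than"/"fewer than" strict, "at least" and "between 0.4 and 0.6" inclusive.

SNP-level criteria report marker ids and the presence/absence criterion
reports RADtag ids; scan summaries give both unique-marker and unique-RADtag
totals per system rather than forcing one deduplication.

# Permutation significance

For each (criterion, system) the null distribution of hit counts is built by
shuffling the sex labels — a uniform permutation of the label multiset, so
sex counts are preserved exactly. The per-sex call-rate gate is recomputed
inside every permutation because which markers pass it depends on the
labels. Quantiles are order statistics of the sorted null counts at
`ceil(0.95 n)` and `ceil(0.99 n)` (integer counts; no interpolation), and the
empirical p-value uses the add-one form `(1 + #{null ≥ obs}) / (n_perm + 1)`,
which avoids p = 0 and is exchangeability-valid. Default `n_perm` is 10,000;
tests and the acceptance script use 2,000 to stay inside their runtime
budgets, which moves the smallest achievable p from 1/10001 to 1/2001 and
nothing else of consequence.

The hot path evaluates every criterion as pure count comparisons
(frequency f > t over n called ⇔ count > t·n) on matrices produced by a
single genotype-indicator × permutation-matrix product, so a 2,000-rep null
over 10,000 markers runs in seconds; the slow per-marker scan and the fast
counter are tested against each other.

# Association scan

The codominant test treats genotype as an unordered factor: per marker, a
likelihood-ratio chi-square `2 Σ O log(O/E)` on the sex × genotype table of
called genotypes, df = (observed classes − 1), Pearson available as an
option. Markers below 80% overall call rate, monomorphic markers and
single-class tables are skipped; p-values get Benjamini–Hochberg adjustment
over tested markers with significance at q < 0.05. Because fine structure
confounds association, `prefilter_structure()` first estimates pairwise
relatedness as allele-sharing (1 − |gᵢ − gⱼ|/2 averaged over jointly called
markers), links pairs above a threshold (default 0.9, safely above the
unrelated background at intermediate allele frequencies), and flags
connected components — by default removing whole clusters (the conservative
mirror of removing all clustered individuals), with a keep-least-missing
variant available. This estimator is a documented stand-in for whichever
package-specific estimator a given study used; it is meant for detecting
duplicates and tight family clusters, not for kinship-corrected modelling.

# The synthetic-data generator

The generator states a world and keeps it fixed; it is how every downstream
stage is tested without external data.

**F1 family** (defaults: 2 parents + 318 offspring, 13 LGs, ~137 cM female
and ~106 cM male per LG — the observed averages behind a ≈1.29 female:male
length ratio). Markers are placed uniformly per LG; parental haplotypes are
drawn from population allele frequencies (default U(0.1, 0.9)) under
Hardy–Weinberg, so all seven segregation types arise at their HWE rates.
Meioses follow the Haldane model — crossovers ~ Poisson(length/100), no
interference — with female crossover positions uniform and male positions
carrying only 0.1 probability mass in the central 50% of the LG, emulating
the terminal-chiasmata heterochiasmy of male amphibians.

**Sexed cohort** (defaults: 19M + 19F). Homogametic individuals draw two
haplotypes from population frequencies; heterogametic individuals draw one,
plus a Y (or W) haplotype. In the sex-determining region (default: the 20
markers nearest the locus, which defaults to the centre of LG6) the
population alternate-allele frequency is set to 0 — the alternate allele is
Y-specific — and the Y haplotype carries it, except that each linked allele
independently reverts to a population draw with probability
min(1, decay × distance in cM), default decay 0.5%/cM. Per-individual
reversion (rather than a single shared Y lineage) is a deliberate
simplification: it produces the graded, imperfect linkage the criteria are
designed to tolerate, without simulating pedigree history. A configurable
number of Y/W-specific tags (monomorphic markers present only in the
heterogametic sex) feed the presence/absence criterion.

**Noise.** Each called genotype flips to a uniformly chosen different code
with probability `genotype_error_rate` (default 1% for the family; the
cohort acceptance scenario uses 5%), then goes missing with probability
`missing_rate` (default 5%); a cell hit by both is recorded as missing only,
keeping the truth tables disjoint. Monomorphic markers are exempt from flips
— their realistic error mode is dropout. Depth is negative-binomial (mean
13, dispersion 5, matching ~13× effective coverage), with depth 0 forcing a
missing call. Errors are injected into parents and offspring alike; real
mapping parents are usually sequenced deeper (often with replicated
libraries), so simulated parent genotypes are noisier than real ones — a
conservative direction for testing the segregation filter.

**What a green test does not establish.** The generator has no population
structure, drift, selection, null alleles, paralogy or depth-dependent error
— so passing tests demonstrate the *statistical machinery* is correct under
the stated model, not that any particular biological dataset will behave.
In particular the ABx– model never arises in truth (it requires a missing
parent plus a null-allele-like mechanism); it is exercised by construction
in unit tests instead.

# Calibration design

Under a null cohort (no sex locus) the permutation p-value should be
uniform. With 19 individuals per sex, however, the strict criteria almost
never fire by chance: observed and null counts are all zero and the p-value
degenerates at 1, so a uniformity test would be vacuous. The calibration
suite therefore shrinks the world until the statistic has support — 8M/8F,
mid-range allele frequencies U(0.2, 0.8), 2,000 markers — giving null hit
counts with real spread, and then checks Kolmogorov–Smirnov uniformity of
the empirical p over 200 seeded null cohorts at the 1% level (n_perm = 500,
the stated scaled-down budget). This design was chosen once, for count
support, and frozen.

# Map utilities

`clean_map()` removes RADtags spanning multiple LGs (a biological
impossibility, hence an artifact) and, iteratively, single-RADtag terminal
segments separated from the rest of an LG by a gap > 10 cM, re-anchoring
positions at 0; it is idempotent and never lengthens an LG.
`merge_sex_maps()` places markers shared by both sex-specific maps
(double-heterozygous anchors) at the arithmetic mean of their positions and
carries single-map markers by piecewise-linear interpolation between
flanking anchors (terminal markers by extrapolation from the two nearest
anchors; an LG with < 2 anchors passes through from the female map, the
denser and more evenly spread of the two). Interpolation is the minimal
order-preserving completion consistent with reporting *all* markers on an
averaged map when only shared markers have defined averages.
`summarize_map()` reports per-LG SNP counts, unique positions, length (max
position), non-zero interval (mean positive gap between consecutive unique
positions, equal to length/(unique − 1) when all gaps are positive), and —
when male and female maps are both supplied — the F:M length ratio, at both
the total-length level and as the unweighted mean of per-LG ratios, because
a map-level ratio is legitimately read either way. Genome coverage uses
`c = 1 − exp(−2dn/L)` with d the mean marker spacing (cM), n the marker
count and L the map length; c ∈ [0, 1) always and equals 1 − e⁻² when
dn = L.

# Numerical and interface choices

- Chi-square tests: no continuity correction anywhere; expected counts from
  compatible classes only.
- Degenerate inputs: zero called offspring → explicit no-pass with reason;
  empty p-vector → empty q-vector; an empty post-filter matrix is allowed
  with a warning; L ≤ 0 is fatal for coverage.
- VCF dialect: VCFv4.2, one record per marker, unphased GT with per-call DP;
  coordinates are synthetic (LG as contig, per-LG marker index as position)
  since no reference genome exists; RADtag id and SNP offset ride in INFO.
  Reading is delegated to VariantAnnotation; writing emits the fixed dialect
  directly.
- Pipeline config round-trips through JSON (no YAML parser in the supported
  environment); every random stage receives an explicit seed, and identical
  configs reproduce identical outputs bit for bit.

# Known limitations

No genotype-likelihood modelling (hard calls only); no multi-allelic
handling beyond reject/drop; no linkage-group formation or marker ordering
(that is an external mapper's job — maps are consumed, cleaned, merged and
summarized here); no kinship-corrected association; relatedness estimator is
allele-sharing only; the linkage-decay model is linear per cM rather than
pedigree-derived.
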