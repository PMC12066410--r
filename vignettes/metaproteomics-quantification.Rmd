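---
title: "Quantifying gut microbiota composition and function from metaproteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gut microbiota composition and function from metaproteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaproteo)
```

## The measurement model

Shotgun metaproteomics digests the proteins of a faecal sample into tryptic
peptides, acquires fragmentation spectra, and assigns each spectrum to a
peptide in a protein sequence database (a peptide-spectrum match, PSM). When
the database is built from metagenome-assembled genomes of the same
community, each protein carries a taxon code, and the number of PSMs
accumulated by a taxon's proteins is a proxy for that taxon's share of the
community's protein mass — its *proteinaceous biomass*. The same counts,
normalized per protein, measure the community's investment in metabolic
functions. `metaproteo` implements this quantification chain and a
synthetic-data generator that emulates its statistical structure, so that
each inference rule can be validated against a known ground truth.

## The taxon-coded database

Bins from metagenomic assembly are screened in two tiers: bins with
completeness above 50% and contamination below 10% keep their species-group
assignment, while a second tier (completeness above 30%, contamination
below 5%) is retained for database comprehensiveness but coded `LOWQ`,
because its taxonomic assignment is not trusted for quantification. Both
bounds are strict inequalities. Gene calls from unbinned contigs enter the
database (code `UNBINNED`) only when no binned sequence matches them at 90%
identity or more; identical sequences occurring in bins of *different*
species groups are coded `AMBIGUOUS`; and a sequence present in both a
species-tier and a low-quality-tier bin keeps the species code (species >
LOWQ precedence — the species assignment carries strictly more information,
and the choice is reported). Host and dietary reference proteomes are
appended after within-proteome redundancy clustering at 95% identity, and
database sequences matching an external reference proteome at 95% identity
or more can be recoded to a named species of interest.

Percent identity is defined as the number of matching positions in an
optimal global alignment divided by the length of the shorter sequence,
mirroring the semantics of the `-c` cutoff in greedy-clustering tools; the
alignment is scored with unit match/mismatch/gap weights because only
percent identity, not a substitution-model score, enters any decision. A
k-mer prefilter skips pairs that provably cannot reach the threshold: if an
alignment of the shorter length $L$ has at least $\lceil cL \rceil$ matches,
those matches form at most $\lfloor (1-c)L \rfloor + 1$ runs, so a shared
exact k-mer of length $\lceil cL / (\lfloor(1-c)L\rfloor + 1) \rceil$ must
exist. The filter is exact — it never discards a pair that could pass.

## PSM filtering and protein inference

False-discovery rates are estimated by target–decoy competition at the PSM
level: at a score threshold $s$,
$\widehat{FDR}(s) = \#\text{decoys}(\ge s) / \max(1, \#\text{targets}(\ge s))$,
and the q-value is the monotone non-increasing envelope of this estimate in
score. Targets with $q \le 0.05$ are retained. This is a deliberate
simplification of search-engine rescoring pipelines, which estimate FDR at
the PSM, peptide and protein levels jointly; the package promises only the
PSM-level contract, and the realized false-discovery proportion is checked
against the generator's ground truth in the test suite.

A peptide is *protein-unique* when it occurs in exactly one protein
accession. Spectral counting uses a unique-only policy by default: a PSM
whose peptide is shared between accessions is counted toward none of them,
so no spectrum is ever counted twice and the sum of protein counts never
exceeds the number of retained PSMs (a count-to-all policy is available as
an explicit switch). A protein is reported at all only if at least one
protein-unique peptide was identified for it. Peptide identity is the plain
amino-acid string — modified forms collapse to the same peptide, and I/L
are kept distinct because peptides derive from database sequences rather
than de novo calls.

For biomass, a stricter rule applies: only proteins with at least **two**
protein-unique peptides contribute, and "protein-unique" means unique to
the accession, not merely to the species (a species-unique variant is
available for sensitivity analysis). The two-peptide filter is applied on
peptides pooled across the whole sample set by default — a protein
confidently identified study-wide contributes its counts in every sample —
with a per-sample option. Species percentages are expressed relative to the
summed species-assigned counts only; the ambiguous, low-quality and
unbinned partitions are excluded from the denominator because they cannot
be attributed to any single species. The microbe:host ratio, by contrast,
uses the broader microbial numerator (species + ambiguous + low-quality +
unbinned) over host counts, and dietary protein counts enter neither side.

## Diversity and PERMANOVA

Alpha diversity is the Shannon index in nats; beta diversity is
Bray–Curtis. The PERMANOVA is the package's own implementation: the squared
distance matrix is Gower-centered, $G = C(-\tfrac12 D^2)C$ with
$C = I - \mathbf{1}\mathbf{1}'/n$, and factors are partitioned
sequentially (Type I) in the order given — each factor's sum of squares is
the increment of $\mathrm{tr}(HG)$ as its dummy columns join the design.
Sequential partitioning matches the convention of a single ordered factor
table (protein source, amount, mouse group, age); with unbalanced designs
the order matters, which is why the factor order is an explicit argument.
Pseudo-F is $(SS_f/df_f)/(SS_{res}/df_{res})$ and p-values come from free
permutation of sample labels with $p = (b+1)/(m+1)$ and a mandatory seed;
$SS$, $R^2$ and $F$ are deterministic. The default 999 permutations bound
the smallest attainable p at 0.001. On small instances the partition is
checked to $10^{-9}$ against both a literal normal-equations brute force
and `vegan::adonis2(by = "terms")`, and the null distribution of p is
checked for uniformity. Pairwise PERMANOVAs between group levels are
BH-adjusted across pairs; pairs with a single-sample group are skipped.

For ordination, species percents are centered-log-ratio transformed,
$\mathrm{clr}(x) = \ln(x + c) - \overline{\ln(x + c)}$, before PCA. The
pseudocount $c$ defaults to half the smallest nonzero abundance — a common
compositional-data convention; the zero-handling choice is otherwise
unconstrained, so it is exposed as an argument. Heatmap-style clustering
uses Ward.D2 on Euclidean distances of log-transformed values and exports
Newick with merge heights.

## Functional profiling

NSAF% includes length normalization — $SAF_i = c_i/\ell_i$,
$NSAF\%_i = 100 \cdot SAF_i / \sum_j SAF_j$ — because spectral counts scale
with the number of observable peptides and hence with protein length; the
canonical NSAF form is adopted explicitly. The denominator spans all
microbial-coded proteins (species, ambiguous, low-quality, unbinned) and
excludes host and diet; it uses every identified protein (the one-unique-
peptide filter), not only the biomass-qualifying subset, since functional
profiling needs no species attribution. orgNSAF restricts numerator and
denominator to one organism's proteins, making a species' functional
profile invariant to the rest of the community.

Annotation consensus follows a provenance precedence: a direct manual label
wins; otherwise a protein that shares its complete automated label
signature with a curated protein inherits the curated name (extrapolation);
otherwise, if all automated tools agree, their consensus is used; otherwise
the protein is unannotated. If two curated proteins share a signature but
disagree, that signature is not extrapolated. Rollups sum member-protein
NSAF% per category/GH-family/PUL and report the unannotated remainder as an
explicit feature so columns always total 100%; PUL membership must
partition the proteins. Amino-acid pathway rollups classify enzymes by
amino acid and reaction direction (degradation, synthesis, interconversion,
reversible), with derived panels for ammonia-producing enzymes (degrading
or reversible enzymes with ammonia among the products) and named enzymes
such as urease or tryptophanase.

## Per-feature statistics

Each feature (species percent, category NSAF%, ...) is modeled as
`value ~ group * diet + (1 | mouse)` by REML, with the interacting fixed
effects capturing the two mouse groups' different background communities
and the random intercept the repeated measures per mouse. The diet factor
is tested with a marginal (Type III) F-test under sum-to-zero contrasts and
Satterthwaite degrees of freedom — the common default of the lme4/lmerTest
ecosystem; the ANOVA type is a documented choice, as is the equal-weight
averaging over groups in the per-diet marginal means (95% Wald CIs).
Features with zero variance return a flagged null result; designs in which
some diet is observed in only one group cannot estimate the interaction and
degrade, flagged, to `value ~ diet + (1 | mouse)`. Two-condition contrasts
use Welch's unequal-variance t-test with log₂ fold-changes floored at half
the smallest nonzero value of the compared matrices, and all p-value
families are Benjamini–Hochberg adjusted.

## The synthetic-data generator

The generator emulates exactly the statistical structure the pipeline
assumes. Species biomass fractions are drawn from a symmetric
Dirichlet($\alpha = 0.5$ by default), giving the skewed rank-abundance
profiles of real gut communities. Proteins are concatenations of globally
unique random tryptic peptides (7–30 residues, ending K/R, no internal K/R,
no missed cleavages — digestion fidelity is irrelevant to the counting
math under test); protein lengths are log-normal with median 300 aa so
NSAF's length normalization is genuinely exercised. A configurable fraction
of microbial peptides is duplicated into a second species, creating the
shared-peptide ambiguity the inference rules must handle; host and diet
proteins never share peptides with microbial ones, isolating the
microbe:host contract from the ambiguity contract.

Target PSMs are multinomial with protein weight proportional to
taxon fraction × relative expression × length, so with no sharing and
matched length/expression distributions the expected species PSM shares
equal the biomass fractions — the identifiability condition behind the
recovery tests. Scores are normal with a 4-standard-deviation separation
between correct and incorrect matches; a configurable fraction of targets
are false (null-scored) and decoys are appended at a matching rate, which
is what makes the nominal 5% FDR threshold recover approximately the
intended fraction of true targets. The per-sample PSM depth is a
configuration choice (defaults of 2 000–100 000 depending on context), as
real studies do not fix it. The multi-sample study generator imposes
species-specific log-normal diet, group and mouse effects on the base
community, mirroring a crossed repeated-measures feeding design (12 mice,
two groups, three per cage, every mouse sampled under every diet).

What the generator does *not* emulate: spectrum-level physics (m/z,
retention time, dynamic exclusion), post-translational modifications,
correlated peptide detectability, protein-level score dependencies, or
compositional coupling between function and taxonomy. Passing tests
therefore demonstrate the correctness of the quantification arithmetic and
the calibration of the statistical procedures under the stated sampling
model — not robustness to instrument artefacts in real data.

## Numerical choices and problem sizes

Identity thresholds (0.90 merge, 0.95 reference/clustering), the 5% FDR,
the two-unique-peptide biomass rule and the 5% abundant-species rule are
the pipeline's fixed defaults, surfaced in `run_config()`. Greedy
clustering orders sequences by descending length with first-seen
tie-breaks, making database construction deterministic. All stochastic
stages require explicit seeds, and per-sample/stage seeds are derived
deterministically from a single registry seed, so pipeline re-runs are
byte-identical (verified by checksum manifests).

The validation suite runs at deliberately modest sizes chosen to make the
statistical checks sharp without excess computation: biomass recovery uses
ten 50-species communities at $10^5$ PSMs per sample (binomial noise there
is an order of magnitude below the 0.01 RMSE bound); FDR calibration pools
twenty simulated samples; PERMANOVA null calibration uses 500 simulated
8-sample datasets at 199 permutations; mixed-model power uses 100
simulations of a 12-mouse × 10-diet design with a 2σ effect.

## Known limitations

The ANOVA type (III) and emmeans weighting (equal) are conventions, not
uniquely implied by the modeling description, and are flagged as such; the
PSM-level FDR is a simplification of joint peptide/protein-level control;
database construction assumes its upstream inputs (bins, quality scores,
species-group maps, annotations) are given, and none of the upstream tools
(assembly, binning, taxonomy, homology search) are reimplemented. Biomass
is relative — no absolute-abundance calibration or genome-size correction
is attempted.
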