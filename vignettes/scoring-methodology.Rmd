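---
title: "Methodology: CADD-style deleteriousness scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methodology: CADD-style deleteriousness scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`caddscore` implements the combined annotation dependent depletion
strategy for estimating how deleterious a single nucleotide variant is
likely to be. The strategy rests on one biological assumption: purifying
selection removes deleterious alleles before they fix. Alleles that have
(nearly) fixed in a population despite differing from the inferred
ancestral allele — *derived* variants — are therefore depleted in
deleterious effects, while *simulated* de novo variants, drawn from
neutral substitution rates, are not. A classifier trained to separate
the two classes from genomic annotations learns, indirectly, which
annotation patterns selection disfavours. Its output is not a direct
probability of pathogenicity: it is a relative ranking signal, which is
why the user-facing score is a rank transform rather than the raw
posterior.

Three caveats follow from the construction and should temper
interpretation. First, the simulated class contains many effectively
neutral variants, so even a perfect model would not reach AUC 1 — test
AUC measures separation of the proxy classes, not clinical accuracy.
Second, fixation can also result from drift or founder effects,
especially in domesticated populations with small effective size, so
some truly functional alleles sit in the "benign" class. Third, the
annotation set leans heavily on conservation, so deleterious effects
invisible to cross-species conservation (recent regulatory changes,
epigenetic effects) are systematically under-scored.

## Pipeline stages and the parameters that matter

**Derived-class selection** (`find_derived_variants`). A site enters the
proxy-benign class when the population's major allele frequency strictly
exceeds `high_af_threshold` (default 0.9) and that allele differs from
the ancestral allele read from the closest-ancestor FASTA. Two removal
rules follow: sites where an allele equal to the ancestral allele
segregates strictly above `ancestral_af_ceiling` (default 0.05), and —
to guard against alignment artefacts near indels — sites with another
variant site at distance exactly 1 bp. "Another variant site" here
includes segregating population sites as well as fixed
population-vs-ancestor differences; this is the stricter of the two
possible readings and is exposed as
`adjacent_includes_segregating`. Frequency comparisons are strict but
applied with a `1e-9` tolerance so that a frequency landing exactly on a
threshold (up to floating-point representation) does not count as
exceeding it. Multi-allelic records are skipped with a warning —
dropping them is conservative and keeps the biallelic SNV contract
simple.

**Rate estimation and simulation** (`estimate_rates`,
`simulate_variants`). Substitution rates are estimated per ordered base
change in windows (default 100 kb) tiling each chromosome, as
substitution count over opportunity count, pooled with equal weight over
all supplied ancestor pairs (no pair weighting is published for this
design; equal pooling is the symmetric default and a config knob). CpG
context — defined on the older sequence as the C or the G of a
forward-strand CpG dinucleotide, both members counting — is tracked
separately because deamination of methylated cytosine elevates those
rates several-fold. Windows without opportunity for a given change yield
`NA` rates and fall back to the pooled genome-wide rate at simulation
time, avoiding zero-probability deserts in sparse fixtures. Simulation
draws `(site, alternate)` pairs without replacement with weight equal to
the context-appropriate rate; without replacement because a genome-wide
score table has at most three alternates per site. Simulated variants
may not duplicate a derived position when an exclusion set is supplied
(the default in the pipeline), since contradictory labels at one site
help no classifier. The training design is class-balanced:
`balance_classes` downsamples the simulated pool to the derived count.

**Annotation** (`annotate_consequence`, `build_feature_matrix`).
Consequences come from a self-contained classifier over the GFF3 gene
model, using a 14-category severity hierarchy (splice donor, splice
acceptor, stop gained, stop lost, start lost, missense, splice region,
synonymous, 5'UTR, 3'UTR, non-coding transcript, intron,
upstream/downstream, intergenic); when several transcripts or features
overlap a variant, the most severe category wins. The hierarchy is a
configurable argument because severity orderings differ slightly between
annotation tools. Splice windows follow common annotation practice: 1–2
bp into the intron are donor/acceptor, 3–8 bp intronic and 1–3 bp exonic
are splice region — so an intronic variant 4 bp from a splice site is a
splice-region variant. Coordinates are 1-based inclusive in all
user-facing structures (VCF, GFF3, site tables); any 0-based arithmetic
is internal. Numeric features are the Grantham amino-acid distance (the
published symmetric 20×20 matrix is bundled; stop codons yield a missing
value rather than an error), four DNA-shape deltas computed as the mean
pentamer-lookup value over the alternate context minus the reference
context, and per-position conservation-track values. Imputation policy:
conservation tracks impute to 0 (a missing conservation score most often
means an unalignable, weakly constrained region, so neutral is the least
wrong guess), all other numeric features impute to the training median;
every imputable column gains a paired was-missing indicator so the model
can learn from missingness itself. Categorical features are one-hot
encoded over training-observed levels; a scoring-time category unseen in
training maps to all-zero indicators with a warning rather than an
error, because a genome-wide scoring pass must not die on a rare
category. All columns are scaled by their training-set standard
deviation, and the catalogue (columns, levels, imputation values,
divisors, fingerprint) is serialised alongside the matrix so that
scoring-time data reuses training parameters exactly — no leakage, and a
fingerprint mismatch at prediction time is a hard error. The composite
annotation space is deliberately reduced to this documented minimal set;
reproducing a full several-hundred-column catalogue is out of scope and
config-driven growth is the intended extension path.

**Classifier** (`train_model`). An L2-penalised logistic regression fit
by Newton/IRLS with step-halving. The objective is the negative
log-likelihood plus `0.5 * l2_penalty * ||w||^2` over the feature
weights; the intercept is not penalised (penalising it would make the
fitted base rate depend on the penalty, which has no justification
here). Defaults follow the hyper-parameters established for this model
family: `l2_penalty = 0.1`, an iteration cap of 100 (a bound, not an
exact count — convergence at `max |Δβ| < 1e-8` typically arrives within
10–15 Newton steps), and no internal rescaling, because scaling is owned
by the feature-matrix step. The fit is deterministic; a unit test
cross-checks the solver against an independent ridge-logistic
implementation (`glmnet` with `lambda = l2_penalty / n`,
standardisation off) to guard the parameterisation.

**Score creation** (`phred_transform`). Raw posteriors for all scored
substitutions are sorted descending and mapped to
`-10 * log10(i / N)`. Tied raw scores receive the rank of the first
element of their tied block (the minimum `i`): ties must map to equal
transformed scores, and taking the block minimum keeps the guarantee
that the top fraction `q` of substitutions scores at least
`-10 log10(q)`. Note that with `N` in the billions the analytic maximum
of the transform is about 98.5; descriptions quoting a ceiling of ~95
reflect tie blocks at the top of empirical score distributions, not the
formula, and this implementation follows the formula. User-facing score
output is written at 3 decimals, coordinate-sorted with alternates in
lexical order, and can be bgzip-compressed and tabix-indexed for
browser use.

**Evaluation and region analyses.** Test-set evaluation splits by
consequence into six nested subsets (all; intergenic/flank; transcribed;
transcribed non-coding; coding; synonymous; missense) and reports
ROC-AUC per subset via the rank identity `U/(n1 n0)`. The region
analyses follow one convention for per-site summaries: the *maximum* of
the three alternate scores for miRNA, intron and tissue analyses (these
ask "does this region harbour sites that would matter if mutated"), and
the *minimum* for the codon analysis (which asks how redundant a codon
position is even in the most tolerant substitution); both are arguments,
not hard-coded. Mann–Whitney p-values use exact enumeration of label
assignments for pooled sizes up to 12 (valid under ties, and cheap:
at most C(12,6) = 924 assignments) and the normal approximation with tie
and continuity correction above that; "significant" means Bonferroni-
adjusted p < 0.05 throughout. For intron tests, each intron ordinal is
tested against the pooled sites of all other introns of the same
transcript — pooling matches the "higher than all the other introns"
phrasing and is flagged as the configurable choice it is. The tissue
analysis tests the tissue-below-housekeeping tail, but since some tissue
sets (brain-derived tissues in particular) genuinely score above
housekeeping genes, the reverse tail is computed and reported alongside.
miRNA flanks are one upstream plus one downstream interval of the
miRNA's own length, pooled; flanks are truncated at contig edges with a
message, and miRNAs overlapping training variants are excluded when a
training set is supplied.

## What the synthetic fixtures emulate — and what they do not

The fixture module is first-class, tested code. It emulates: base
composition (i.i.d. bases at a target GC), a chain of increasingly
distant ancestors under SNV-only evolution with CpG hypermutability
(sequence length is conserved — no indels by design, matching the
SNV-only scoring target), a population allele-frequency table on a
`1/(2N)` grid with designed categories on both sides of the derivation
thresholds, gene models with valid ORFs (in-frame CDS, start/stop
codons, introns ≥ 12 bp, non-overlapping genes, miRNAs disjoint from
CDS), Gaussian conservation tracks with a CDS boost and configurable
coverage gaps, and an expression table with a housekeeping set.

Fixture defaults are study conditions, chosen once: branch substitution
probabilities 0.01/0.02/0.04/0.06 along the ancestor chain (the span
from a close to a far mammalian ancestor at desk scale), CpG multiplier
4 (within the empirically reported several-fold elevation), 48 diploid
individuals (a reduced-scale stand-in for a few-hundred-animal,
multi-breed panel), window sizes equal to the fixture chromosome length
so every window is well-populated. The DNA-shape pentamer table bundled
for fixtures is synthetic — a smooth deterministic function of the
pentamer, in plausible ranges per parameter — and is labelled as such;
`shape_delta` accepts any user-supplied table with the same columns.

Not emulated: linkage and recombination, demography, indels and
structural variation, overlapping genes, alternative splicing beyond a
minimal optional second transcript, genuine conservation structure, and
genuine regulatory biology. Consequently, a passing suite demonstrates
that the machinery is correct (thresholds, codon arithmetic, rank
transforms, test statistics, recovery of planted signal), not that the
scores are biologically validated; the latter requires real population
and annotation data at genome scale. The pipeline's streaming-friendly
design (windowed rates, catalogue reuse, tabix output) is built for that
scale, but tests run at fixture scale: chromosomes of 20–30 kb for
pipeline tests, a 300-kb single window for rate-recovery checks, 10,000
simulated variants for the multinomial oracle, 20,000 observations for
parameter-recovery of the classifier, and 10,000 scores for transform
checks — sizes chosen so each statistical check has the power it needs.

## Numerical and degenerate-input decisions

* Strict threshold comparisons carry a `1e-9` tolerance (floating-point
  frequencies like `1 - 0.95` must not leak across `0.05`).
* `rank(-raw, ties.method = "min")` defines tie handling in the score
  transform; a regression test pins it.
* Newton convergence at `max |Δβ| < 1e-8`, with step-halving to keep the
  penalised objective non-increasing; degenerate single-class labels and
  non-finite features are input errors, perfect separation is handled by
  the ridge penalty (finite weights) or the iteration cap (logged
  message) when the penalty is 0.
* Empty Mann–Whitney samples and empty percentile reference sets are
  input errors; empty evaluation subsets report `n = 0` with `NA` AUC.
* Rate windows with zero opportunity are `NA`, imputed from pooled
  rates; simulation beyond the eligible `(site, alternate)` capacity is
  a capacity error.
* Variants beyond a chromosome end are coordinate errors; `N` in the
  ancestor makes a site unknowable rather than erroneous, and soft-masked
  (lowercase) bases are treated as valid calls.

## Known limitations

Scores inherit every bias of the annotation set — above all the
dominance of conservation features. The consequence classifier is
deliberately lightweight: it does not model alternative start codons,
selenocysteine, splice-site sequence motifs, or overlapping transcripts
beyond most-severe-wins. The simulator draws variants independently per
site, without mutational clusters. The region statistics treat sites as
exchangeable within regions, ignoring autocorrelation along the
sequence, as the analysis design they implement does. And the test-set
AUC at fixture scale reflects fixture signal strength only; its value is
the *gradient* across genomic subsets (coding > transcribed >
intergenic), which the planted-signal tests verify qualitatively.
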