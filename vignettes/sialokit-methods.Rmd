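---
title: "SialoKit: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SialoKit: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SialoKit)
```

SialoKit reconstructs a salivary-gland transcriptome ("sialome") analysis
from assembled transcripts to an annotated, quantified and statistically
tested coding-sequence catalogue.  The motivating design is a two-condition
insect study: salivary glands from control (buffer-injected) flies versus
glands infected with a salivary-gland hypertrophy virus whose 108 annotated
ORFs form the viral coding set.  This vignette explains each model and
rule, the tunable parameters and their defaults, what the synthetic data
generator does and does not emulate, and the numerical choices that an
auditor of the results would want written down.

## Coding-sequence extraction

**ORF definition.** `findOrfs()` scans all six reading frames.  An ORF is
a *maximal* stop-to-stop segment (or an edge-to-stop/edge segment at the
transcript boundaries); its nucleotide length *includes* the terminal stop
codon when present.  Segments touching a sequence edge without a stop are
retained because de novo assemblies truncate UTRs and coding ends.  The
default floor is 150 nt.  Coordinates are 0-based half-open on the forward
strand; hit tables keep the 1-based inclusive convention of the tabular
alignment format, and `toHalfOpen()`/`toOneBased()` are the only
conversion points.

**Homology route.** An ORF is promoted to a CDS when a protein hit of its
transcript covers at least 70% of the *matching protein* — subject
coverage `(send - sstart + 1)/slen`, not query coverage — and the hit's
query span fits inside the ORF translation.  Among qualifying hits the
highest bitscore is recorded as evidence.  ORF boundaries are deliberately
not trimmed to the hit: the stop-to-stop segment is kept in full.

**Signal-peptide route.** Met-initiated sub-ORFs of at least 40 aa are
screened by the signal-peptide caller; when one or more are positive, the
*most 5' positive methionine* becomes the start codon.  When both routes
qualify for the same transcript the homology anchor wins (it fixes the
reading frame more reliably) and the signal evidence is still recorded.

**Consolidation.** The merged CDS set (de novo + reference genome + viral;
id collisions resolved genome > viral > de novo) is consolidated at 95%
identity by greedy longest-first clustering, the behaviour of CD-HIT-style
tools: sequences are sorted by length (ties by id), and each sequence
joins the first cluster whose representative aligns at or above the
threshold, else founds its own.  Identity is defined explicitly — a global
alignment scored match = 1, mismatch = 0, gap opening 10, gap extension 1,
with identity = matching columns / alignment columns — because the
threshold only has meaning relative to a stated alignment model.
Consolidation operates at the nucleotide level by default (`level = "aa"`
switches).  A pair whose length ratio is below the threshold cannot reach
it and is skipped; a shared-8-mer lower bound (an alignment with identity
`t` has at most `(1 - t)(l1 + l2)` non-match columns, each destroying at
most eight 8-mers) prunes the remaining non-candidates before any
alignment is computed.

## Signal-peptide heuristic

The external predictor used in sialome practice is a closed binary, so the
package ships a transparent rule-based caller with the three textbook
features of a classical signal peptide, and accepts external predictor
tables (`parseExternalSpTable()`) wherever the heuristic would be used:

1. *n-region*: net charge of residues 1-5 (K/R = +1, D/E = -1) at least 0;
2. *h-region*: some 7-residue window within residues 3-20 with mean
   Kyte-Doolittle hydropathy at least `hThreshold`;
3. *cleavage site* ((-3, -1) rule): a small residue (A, G, S, C, T) at a
   0-based position p in [12, 35) with no charged or aromatic residue at
   p - 2; the smallest qualifying p is the reported cleavage position.

Sequences shorter than 15 aa are negative (`too_short`).  The hydropathy
default is 2.4: it was calibrated once on the generator's own
template/scramble simulation so that template-built signal peptides are
recovered (99.8%) while composition-matched scrambled N-termini stay below
a 10% false-positive rate; at the textbook-looking value 1.6 nearly a
third of scrambles pass, which would make the "secreted" catalogue
untrustworthy.  The window width (7) and all other constants are
arguments.

## Quantification

TPM is computed from counts and effective lengths exactly as defined:
per-sample `rate = count/eff_length`, scaled so each sample sums to 1e6.
Effective lengths are taken from the input (upstream quantifiers estimate
them); the package applies no internal length correction.  A transcript is
*detected in a condition* when its condition-mean TPM reaches the floor
(default 3); the mean — not the max — of replicates is used because the
family tables report per-condition average TPM, and the same aggregator
should drive detection.  `presencePartition()` splits transcripts into
detected-in-both / only-A / only-B / dropped; `zscoreMatrix()` produces
the row-standardized matrix used for heatmap displays (sample sd, n - 1;
constant rows map to zero).

## Functional classification

The classifier is rule-exact, not statistical.  For each CDS:

1. viral records are class `virus`, unconditionally;
2. databases are consulted in precedence order; within the first database
   holding an *acceptable* hit (pident >= 35 and subject coverage >= 0.50,
   both configurable), the best hit by bitscore supplies the description;
3. the description is scanned against the lexicon; matches are ranked by
   **priority first, then leftmost position, then longer term**;
4. the winning term fixes the class, and the family when the class is
   secreted;
5. with no acceptable hit or no matching term, a signal-peptide-positive
   record becomes secreted/family `Unknown` ("unknown secreted"), else
   class `unknown`.

The priority tier exists for compound phrases: in
"serine protease inhibitor, Kunitz type" the leftmost term is
"serine protease", but the record describes an inhibitor; inhibitor-family
terms (Kunitz, Kazal, serpin, cystatin, TIL) carry priority 10 in the
shipped lexicon so the family resolves to Kunitz.  Among equal-priority
terms, order of appearance in the description decides.  The shipped
lexicon (`defaultLexicon()`, ~130 terms, 26 classes, all the
secreted-protein families of the domain) is a reconstruction — the
vocabularies used in sialome annotation practice are unpublished — and is
fully user-replaceable through `loadLexicon()`.

`classAbundanceSummary()` reports per-class percent of summed TPM per
sample (sums to 100 by construction) with mean and sd across replicates
per condition.  `secretedFamilyTable()` counts detected members and sums
condition-mean TPMs per family, with a percent-change column relative to
the reference condition; a family absent from the other condition shows a
100% reduction.

## Differential expression

The testing model is the classical two-group negative-binomial exact test
with a single common dispersion.

**Normalization.** Effective library sizes are column sums (default) or
TMM-scaled column sums (30% trim on log-ratios, 5% on abundance,
precision-weighted, factors centred at geometric mean 1).  The default is
plain library sizes; TMM is one flag away.

**Dispersion.** The common dispersion maximizes the conditional NB
log-likelihood given per-group gene totals, summed over genes, after
scaling counts to the geometric-mean library size.  The likelihood is
evaluated on a log grid over [1e-6, 10] and refined by golden-section
search.  Conditioning removes the per-gene means from the problem, which
is what makes a single shared dispersion estimable from 3 + 3 replicates.

**Exact test.** For each gene the counts are scaled to a common library
size and summed within groups; the two rounded group totals (rounding each
total separately keeps the test exactly antisymmetric under swapping the
reference label) are compared under the conditional null: with equal
per-sample means, the reference total given the gene total follows a
negative-hypergeometric law free of the mean, with group "sizes"
`n_g/phi`.  The two-sided p-value sums the probabilities of all splits as
likely or less likely than the observed one (probability-mass rule);
`phi = 0` uses the conditional binomial (Poisson limit).  The enumeration
cost is bounded by the grand total of counts, so the exact computation is
used for every gene.  Library equalization by global scaling is an
approximation to exact conditioning under unequal sizes, and is the
documented trade-off.

**Calls.** `logFC = log2(other/reference)` with a display-only
pseudo-count of 0.125 per group mean (p-values never see pseudo-counts).
A transcript is `up` — enriched in the *reference* condition — when
`logFC <= -2` with BH-FDR < 0.05, `down` when `logFC >= 2` with
FDR < 0.05.  The sign convention is pinned by a dedicated test because it
is the easiest thing in this analysis to silently flip.

**MDS.** Sample distances are the root-mean-square of the 500 largest
absolute log2 fold changes of log-CPM (pseudo-count 2) between each pair,
followed by classical metric MDS; per-axis shares of retained variance
accompany the coordinates.

## The synthetic study

`simulationConfig()` fixes the study design; `simulateStudy()` generates
transcripts, hit tables and counts with full truth labels.  Defaults,
chosen once as the package's study conditions:

* 300 host transcripts, ~10% of them non-coding decoys with no ORF of
  150 nt in any frame (decoys are built by rejection against the
  six-frame scan); 108 viral ORFs of which ORFs 6, 7, 8, 9, 26, 60 and 61
  are transcriptionally silent in every sample, and no viral ORF is
  expressed in the reference condition;
* planted Met-initiated ORFs of 150-1800 nt (stop included) inside random
  UTRs; secreted-class transcripts start from the generative
  signal-peptide template (positive n-region, 8-residue hydrophobic core,
  A-X-A site) — the same rule family the caller tests, so recovery is a
  construction property, with scrambled N-termini as negative controls;
* hits: 1-5 per informative transcript, description embedding exactly the
  lexicon term of the true class/family among neutral filler words,
  identity U(40, 95), subject coverage U(0.55, 1); unknown-class
  transcripts get no hits or hits with identity U(10, 30) — below the
  acceptance gate but carrying a term, so opening the identity gate
  converts them to classed records (a monotone threshold effect);
* counts: per-condition expected TPM shares follow the class targets
  (reference: secreted 38.8%, energy metabolism 22.6%, unknown 20.2%;
  infected: virus 62.1%, unknown 22.8%, secreted 4.3% — the only printed
  abundance structure available for calibration), split within a class by
  a symmetric Dirichlet(5) (concentrated enough that no expressed viral
  ORF ever drops below the detection floor); library size ~2e5 reads
  (U(0.9, 1.1) jitter), three replicates per condition, NB dispersion
  phi = 0.1, and a planted |log2 FC| = 3 on 10% of background-class host
  transcripts (half up, half down).

What the generator does *not* emulate: read-level errors, assembly
chimerism and fragmentation, multi-mapping ambiguity, length-dependent
coverage bias, correlated replicates, batch structure, and homology hits
with conflicting descriptions.  Passing tests therefore demonstrate that
the algorithms implement their stated rules and recover planted structure
under the stated noise model — not that the pipeline is robust to every
artefact of real sequencing data.

`simulateDeCounts()` is the minimal count-matrix generator used to
calibrate the testing module (null uniformity, dispersion recovery,
planted-fold-change recovery) at 2000-5000 genes, sizes chosen so the
whole suite runs comfortably on a laptop.

## Numerical and degenerate-case decisions

* All-zero samples: TPM warns and returns a zero column;
  `normalizeLibSizes()` refuses (a zero library has no size).
* Constant rows z-score to zero rather than NaN.
* `s = 0` in the exact test gives p = 1 and logFC 0.
* Dispersion estimates hitting the lower grid bound report 1e-6, i.e.
  "no evidence of overdispersion".
* Consolidation ties (equal length) break by id, making output
  order-independent and reproducible.
* Description scanning lowercases both sides and matches fixed substrings;
  ties at the same position break toward the longer term.
* The generator consumes the RNG only through `set.seed(seed + k)` per
  stage, so each stage is independently reproducible.

## Known limitations

* The conditional exact test treats equalized (scaled) counts as NB; under
  strongly unequal library sizes the conditioning is approximate.
* The classifier trusts the first acceptable database's description; a
  descriptive term in a lower-precedence database never overrides it.
* The shipped lexicon is a reconstruction; real annotation work should
  curate it (`loadLexicon()`), which is why it is data, not code.
* The signal-peptide caller is a deliberately simple stand-in: it
  implements the von Heijne-era rules, not a modern probabilistic
  predictor, and its operating point was tuned on template positives.
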