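---
title: "Methods: detecting, dating and characterising horizontally transferred genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting, dating and characterising horizontally transferred genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`xenolog` re-implements, as a tested pipeline, the workflow by which
fungus-originated genes are discovered in grass genomes and
transcriptomes, their transfer events dated on calibrated species trees,
and the transferred genes characterised by selection pressure, codon usage
and expression.  This vignette is the package's own account of the models
behind each stage, the tunable parameters, and the choices made where the
design was genuinely open.

## The scientific setting

*Epichloë* fungal endophytes live inside cool-season grasses, often in
reproductive tissue.  That physical intimacy has permitted occasional
horizontal gene transfer (HGT) from fungus to host: a grass lineage
acquires a fungal coding sequence, which then descends vertically and
diverges under host-side selection.  A transferred gene betrays itself by
(i) anomalously high DNA identity to a fungal gene, (ii) a phylogenetic
position nested among fungal sequences rather than plant ones, and
(iii) a presence/absence pattern that respects host clade boundaries —
present in every descendant of the recipient ancestor, absent outside.

The pipeline runs these three lines of evidence in order:

1. **Screen** — collapse short reads to unique sequences and search them
   (plus the host transcriptome) against the donor fungal transcriptome
   with a seeded local-alignment search under an E-value threshold.
2. **Triage** — classify hits into `low_similarity`,
   `conserved_eukaryote`, `microbiome` and `hgt_candidate` with explicit,
   configurable rules.
3. **Date** — build a cross-taxon presence/absence matrix, place the gain
   on the calibrated host tree under a Dollo (single-gain) model, and cap
   the window with a donor-side constraint from the candidate phylogram.
4. **Characterise** — Nei–Gojobori Ka/Ks with Jukes–Cantor correction and
   age-normalised rates, codon usage profiles including the termination
   signal, and read-count expression (CPM).

Every stage is exercised end to end on a synthetic sequence-evolution
bundle that plants HGT events at known times, so that correctness claims
are claims about recovery of known truth.

## The similarity screen

The search is a classic seed-and-extend: exact words of `word_size`
(default 28, as in megablast-style screens; 64 is supported) are matched
on both strands, deduplicated by diagonal, and extended with a banded
local dynamic program (half-width 16, X-drop 20 score units, ties broken
by leftmost query then subject start).  The default scoring is match +1 /
mismatch −2 with a *linear* gap penalty of 4 per gap character — the
simulator emits no indels, real candidate alignments at these identities
are substitution-dominated, and a linear penalty keeps the
Smith–Waterman oracle comparison in the test suite exact.

Raw scores convert to bit scores and E-values through the Karlin–Altschul
relation

$$E = K \, m \, n \, e^{-\lambda S},$$

with $m$ the query length, $n$ the total subject length, and $\lambda$
the unique positive root of $\sum_{ij} p_i p_j e^{\lambda s(i,j)} = 1$,
solved numerically to 1e−9.  $K$ is **fixed** at 0.3 rather than
estimated: at a threshold of 1e−10 the decision boundary moves by well
under one alignment column for any plausible $K$, so the Karlin–Altschul
$K$ machinery would add complexity out of proportion to its effect.  The
reporting threshold defaults to `E <= 1e-10`.

The published screen triaged hits **manually**; the package
operationalises that judgement with fixed-order rules so it is
reproducible: a hit is `low_similarity` below 60% identity or 50 nt
aligned; `conserved_eukaryote` if its query also hits an outgroup-plant
panel at the E threshold (actin/ubiquitin-like confounders);
`microbiome` at ≥ 98% donor identity with no support in the host genome
assembly (a fungal read is verbatim fungal and has no host home); else
`hgt_candidate`.  All four thresholds are configurable, and the exact
hit-count split of any particular manual analysis is *not* a target —
the partition property (categories sum to the hit total) and perfect
accuracy against synthetic truth labels are.

## Dating a gain on a calibrated tree

Node ages in million years (MYA) are inputs, either as `[&age=X]`
annotations in Newick or derived from ultrametric branch lengths.  Under
the single-gain (Dollo) model, the gene arose once: the gain branch is
the branch above the MRCA of all present taxa, so the window is
(age of MRCA, age of its parent) — the split from the nearest absent
lineage.  A donor-side constraint caps the upper bound: a candidate
nesting *inside* the donor crown radiation must have left after the
crown age (7.2 MYA on the template donor tree); one attaching to the
donor stem may be as old as the stem divergence (58.8 MYA).  The
placement itself comes from a neighbour-joining phylogram of the
candidate's protein sequences, rooted with the outgroup fungus.

Two policies govern absences inside the presence clade.  The default
`strict` policy treats them as an error — this is the implicit model of a
single transfer with no loss, and it is the right default because
presence screens fail in one direction: a gene can be missed (low or
tissue-specific expression in a transcriptome assembly — the package
models exactly this discordance by letting PCR evidence override
in-silico evidence), but a present call is hard evidence.  The
`dollo_losses` policy accepts the pattern, reports the implied losses,
and **widens** the window: once losses are admitted, any absence above
the MRCA may itself be a loss, so the host-side upper bound relaxes to
the root age and only the donor constraint still caps it.  The window
lower bound (MRCA age) is robust to detection failures — dropping
present taxa can only move the MRCA tipward, never past the true gain —
which is why coverage of the true transfer time survives miscall noise
in the loss-tolerant mode.

The presence/absence matrix records per-cell evidence (`in_silico`,
`pcr`, `both`), flags conflicts, and marks in-silico-only absences as
low-confidence.  In-silico PCR matches primers exactly (the assay this
mirrors designed primers in highly conserved regions; degenerate matching
is off by default) on either strand, reverse-complement of the reverse
primer downstream on the same strand, and suppresses products over
250 bp.

## Nei–Gojobori Ka/Ks and the rate table

For each sense codon, each of the nine single-nucleotide changes is
classified synonymous or nonsynonymous under the standard code (changes
to stop codons count nonsynonymous), giving fractional site counts with
$S + N = 3$.  Differences between aligned codons are averaged over all
minimal mutational pathways (1, 2 or 6 orderings), excluding pathways
through stop codons (with an all-excluded fallback that warns).  The
proportions $p_s = S_d/S$ and $p_n = N_d/N$ are corrected for multiple
hits with Jukes–Cantor, $d = -\tfrac34\ln(1 - \tfrac43 p)$, undefined at
$p \ge 0.75$ (saturation is flagged, never silently truncated).  Codons
containing gaps or ambiguity in either sequence, and stop codons, are
skipped.  This matches the default counting method of the phylogenetics
program used for the original analysis, and the test suite pins the
implementation to an independent full-enumeration oracle over all
61 × 61 codon pairs.

Group summaries average pairwise `Ks`/`Ka` over a combination of taxa
(population standard deviations) and normalise by the combination's
divergence age: `rate = avg / T`.  Note the **single-T convention**: a
per-lineage rate would conventionally divide by $2T$, since two extant
lineages each accumulate substitutions for $T$ million years, but the
summary-table arithmetic this reproduces divides by the age once, and the
package follows that convention so its cells are comparable.  The
simulator documentation states the complementary fact (expected pairwise
`Ks` between two extant taxa is $2T \times$ rate), so tests compare like
with like.  The group ratio is `Ka_avg / Ks_avg` by default
(ratio-of-averages); per-pair ratio averaging is exposed via
`ratio_mode` because published tables are ambiguous between the two in
their last digit, and only cells where both conventions agree at printed
precision are used as checks.

Codon usage profiles report, for each of the 18 amino acids with more
than one codon, each synonymous codon's share of that amino acid's
occurrences pooled over the set, plus the termination signal over
terminal `TAA`/`TAG`/`TGA`.  The termination profile is the
discriminating signal here: fungal gene sets use all three stops while
the plant copies of a transferred gene can be fixed for one, so the
profile is computed per set and compared.

## The synthetic-data generator

The generator is first-class, tested code — it defines the study
conditions under which every downstream claim is verified.

**Trees.** The template host tree carries outgroup angiosperms
(Arabidopsis, rice, sorghum, maize analogues), a Brachypodieae analogue
splitting from the core Pooideae at 39 MYA (the older end of the
32–39 MYA calibration interval; the interval itself is reported, the tree
node carries its upper value), Triticeae and Poeae splitting at 21 MYA, a
Triticeae crown at 11 MYA, a Poeae crown at 15 MYA and a Loliinae crown
at 5 MYA.  The donor tree has a Claviceps analogue splitting at
58.8 MYA from an Epichloë clade whose crown radiation is 7.2 MYA, the
first crown split separating the *E. gansuensis* analogue.  Ages not
fixed by the calibrations above (root 160 MYA, rice 50, PACMAD 45,
sorghum–maize 12, Dactylidinae 10, inner Epichloë nodes 4 and 2) are
field-standard placeholder values chosen once; none of them affects a
reported quantity.

**Sequence evolution.** Codon sequences evolve by a continuous-time
(Gillespie) process: every admissible single-nucleotide codon change is
classified under the standard code; synonymous changes occur at
per-change rate $\mu_s$, nonsynonymous at $\omega \mu_s$.  Because a
codon with $k$ synonymous neighbours has $k/3$ synonymous sites, setting
$\mu_s = r/3$ makes the expected number of synonymous substitutions per
synonymous site per million years equal $r$ (`syn_rate_per_my`, default
0.015 — a free calibration parameter chosen so that simulated divergences
reach the magnitude of the published rate table, not itself a published
value).  Changes creating stop codons are rejected; a terminal stop codon
wanders only among the three stops.  The rate model deliberately mirrors
the Nei–Gojobori estimator (per-change classification, no
transition/transversion asymmetry, no full GY94 matrix) so that estimator
recovery tests are exact in expectation and transparent to audit.

**Transfers.** An HGT event copies the donor lineage's sequence state at
time `t_mya` on a named donor branch onto a named host branch; the copy
then evolves under the host ω.  All host tips below the branch carry the
gene, all others lack it.  The default bundle plants the two events the
study conditions describe: an old transfer into the Triticeae+Poeae
ancestor at 30 MYA from the donor stem, and a recent one into the
Loliinae ancestor at 6 MYA from inside the donor crown.

**Reads.** Libraries draw 140–150 nt reads uniformly from the focal
taxon's transcripts, emit a configurable duplicate fraction (default
30%) to exercise read collapsing, and mix in contaminants: verbatim
donor-only reads (microbiome) and reads from slow-evolving conserved
genes shared by all taxa (rate 3e−4/MY, ω = 0.05) that cross-hit both
the donor and the outgroup panels.  Every read and gene carries exactly
one truth label (`vertical`, `hgt`, `conserved`, `microbiome`).

**What is not modelled** — and hence what passing tests do *not* show
about real data: indels (alignments are gap-free by construction, so the
screen's gapped extension is exercised only by dedicated tests),
sequencing error and adapters (reads are clean; real data must be
pre-trimmed), genome-scale synteny and the repetitive-element context of
real insertion loci, isoform structure, and rate heterogeneity across
sites or lineages.  A real screen also faces a far larger and more
diverse search space, so the synthetic 100% triage accuracy is a
correctness check of the rules, not an accuracy forecast.

**Seeding.** One master seed drives everything; per-gene and per-library
child seeds are derived by stable integer hashing of the gene or sample
identifier (kept below 2^31), so runs are reproducible and individual
genes are reproducible in isolation.

## Expression profiling

A read counts for a gene when the two share an exact common substring of
at least `min_perfect` nt (default 60) on either strand — the most
literal reading of a "no mismatch for 60 bp or longer" containment
criterion, implemented by hashing the gene's 60-mers (a shared substring
of length ≥ 60 exists iff a 60-mer is shared) and verified against a
longest-common-substring dynamic program in the tests.  Duplicate reads
count individually through their multiplicities; reads matching two genes
count for each independently.  Counts normalise to CPM as
`count / library_size × 1e6`.

## Numerical and degenerate-input choices

* E-value solver: bisection-bracketed `uniroot` to 1e−12 on the
  Karlin–Altschul equation; invalid schemes (non-negative expected score)
  are rejected.
* Banded extension: integer-valued scores make traceback re-derivation
  exact; alignments wholly contained in a higher-scoring one are dropped.
* Neighbour-joining: canonical Q-criterion implementation (via `ape`),
  with negative branch lengths clamped to zero and the deficit moved to
  the sibling so tip-to-tip path lengths through the parent are
  preserved; asymmetric matrices (beyond 1e−9) are rejected.
* Jukes–Cantor at `p >= 0.75` raises a typed saturation condition; group
  summaries drop saturated pairs and error only if none remain.
* Coordinates are 0-based half-open everywhere internally; the tabular
  hits format alone uses the 1-based inclusive convention of its
  de-facto standard, reversing subject coordinates on minus-strand hits.
* Sequence normalisation: upper case; IUPAC ambiguity codes other than N
  map to N with a warning; CDS validation rejects internal stops.

## Problem sizes in the shipped tests

The defaults were sized so a full check runs on one CPU in a few
minutes: the demo bundle uses 6 vertical genes of 300 codons, 2 planted
transfers, 2 conserved and 2 donor-only genes, and a 2,000-read library;
estimator-recovery tests use 1,000-codon pairs over 20 seeded
replicates; the window-coverage properties use 100 replicates on the
template tree; oracle comparisons run over all 61 × 61 codon pairs and
dozens of small alignment instances.

## Known limitations

Beyond the simulator's idealisations listed above: the screen does not
reproduce any specific BLAST implementation's scoring internals (K fixed,
linear gaps, no low-complexity masking), so E-values agree in decision
behaviour at stringent thresholds rather than digit-for-digit; the dating
model is a point estimate of a window, not a posterior (no gene-tree /
species-tree reconciliation, no molecular-clock estimation — ages are
inputs); protein-space search, ML codon models and bootstrap support are
out of scope.  Loci mapping is collapsed per donor subject gene: when
multiple host isoforms hit the same donor gene they date as one
candidate, and the per-gene summary records the ambiguity rather than
resolving it.
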