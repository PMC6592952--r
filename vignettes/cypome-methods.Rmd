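---
title: "Methods: CYPome discovery and RT-qPCR relative quantification"
author: "cypome package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CYPome discovery and RT-qPCR relative quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypome)
```

# Scope

`cypome` implements two connected analyses for fungal cytochrome P450
(CYP) biology: (i) mining a predicted proteome for its CYP complement by
homology plus signature-motif validation, and (ii) relative
quantification of gene expression from RT-qPCR quantification cycles
(Cq) in the efficiency-corrected, multi-reference model. Both arms are
exercised end-to-end against seeded synthetic generators with known
ground truth. Out of scope by design: *ab initio* gene prediction,
transmembrane/solubility prediction, official nomenclature assignment
(we emit tiers, not names — naming is a committee act), local-alignment
statistics (E-values), and any wet-lab modelling.

# Discovery arm

## Homology screen

Every proteome entry is aligned to every reference CYP by exact global
Needleman–Wunsch alignment with affine gap penalties, computed by
`Biostrings::pairwiseAlignment()` behind `globalAlign()`. Default
scoring is BLOSUM62 with gap opening 10 and gap extension 0.5, the
defaults of the EMBOSS Needle tool that is this field's standard for
pairwise protein alignment. Under the alignment engine's bookkeeping a
gap run of length $L$ costs $\mathrm{open} + L \cdot \mathrm{ext}$.
Percent identity is counted over *all* alignment columns, terminal gaps
included (the Needle convention), so fragments aligned into long
references are penalised — which is what makes the identity usable as a
nomenclature statistic.

Exact alignment of every pair replaces the heuristic database search a
genome-scale study would use. At desk scale (up to $\sim 10^4$ proteins
versus a handful of references) this is tractable, removes an external
binary, and is deterministic. A shared $k$-mer prefilter ($k = 4$, at
least 2 shared distinct $k$-mers, on by default) prunes obviously
unrelated pairs before alignment. A consequence accepted up front:
hit counts produced by heuristic search tools on real proteomes are not
expected to be reproduced by this screen.

The first-pass retention rule — identity $\ge 20\%$ over an alignment
covering $\ge 40\%$ of the reference — is deliberately permissive. Its
job is to pass every plausible homolog to the motif filter, which does
the real discrimination. Both thresholds are configuration
(`discoveryConfig()`).

## Signature grammar

Three degenerate motifs diagnose a P450, in fixed N→C order: the K-helix
`EXXR`, the PERF domain `PXRX`, and the haem-binding decapeptide
`FXXGXRXCXG` whose conserved cysteine ligates the haem iron. The motif
grammar is literal-plus-wildcard only: `X` matches exactly one of the 20
standard residues, and ambiguity codes (B, Z, J), selenocysteine,
stops and `X` itself *fail* a wildcard position. Rationale: a signature
should never be claimed on a residue the upstream predictor could not
call. Position-specific scoring and HMMs are non-goals; the grammar is
the published diagnostic, not a sensitivity-optimised model.

`findSignature()` anchors the triplet deterministically: rightmost haem
hit, then rightmost PERF hit strictly upstream of it, then rightmost
K-helix hit strictly upstream of that; absence of any anchor means no
signature. The haem motif is C-terminal-proximal in every
coordinate-consistent annotated CYP, so rightmost selection matches the
observed architecture while being order-independent and reproducible. No
maximum inter-motif distance is imposed: annotated spans vary enormously
(one 1211-aa protein carries its haem motif at 40% of its length).

## Partial filter and tiers

Proteins shorter than 300 aa are flagged partial and excluded from
classification but retained in every report — dropping them silently
would hide exactly the gene models a curator needs to revisit.
Full-length, signatured candidates are classified by identity to their
best reference: $\ge 55\%$ same subfamily, $\ge 40\%$ same family, else
new family, boundaries classifying upward. These are the CYP
nomenclature convention's thresholds; they stay configurable because
committee judgement occasionally overrides them (the packaged annotation
table itself contains a 39% ortholog kept in-family).

## Table-validation mode

The packaged annotation table of the 32-gene *Cunninghamella elegans*
CYPome (motif strings, 1-based start coordinates, lengths, closest
orthologs with integer percent identity) is a first-class pipeline
input: `validateCypomeTable()` runs the same conformance, ordering,
coordinate-consistency and partial checks on annotation rows that the
sequence pipeline runs on sequences. One transcribed row places its haem
motif start (304) beyond its stated length (302); the package treats
this as data to be flagged, never corrected, and the validity report is
where it surfaces. Coordinates are 1-based inclusive everywhere;
thousands separators in transcribed numbers are stripped at parse time.

## Redox partners

Class II CYPs need electron delivery, typically from NADPH–cytochrome
P450 reductase (CPR), a diflavin enzyme. `screenRedoxPartners()` buckets
proteins by best labelled reference homology, but a CPR call additionally
requires both a FAD- and an FMN-domain fingerprint in the query —
homology alone is not accepted for a diflavin claim, and incomplete
evidence downgrades the call to `none` with the evidence recorded. The
shipped FAD/FMN fingerprints (`GXGXXG`, `TXTGXT`) are simplified
dinucleotide/flavodoxin-style patterns intended for the synthetic
benchmarks; real-proteome work should substitute curated patterns via
configuration.

# Expression arm

## Model

For gene $g$ with amplification factor $E_g \in (1, 2]$ and
technical-replicate-averaged cycle $Cq_{s,g}$ in sample $s$:

$$RQ_{s,g} = E_g^{\,\overline{Cq}_g - Cq_{s,g}}, \qquad
NF_s = \Big(\prod_{r \in \mathrm{refs}} RQ_{s,r}\Big)^{1/f}, \qquad
NRQ_{s,g} = RQ_{s,g} / NF_s,$$

with $\overline{Cq}_g$ the gene's mean Cq across samples — any per-gene
constant cancels in the calibrated quantity, and the mean keeps
intermediate RQs near 1 for numerical readability. CNRQ rescales NRQ per
gene so the geometric mean over the calibrator group's samples is
exactly 1; by construction this identity holds to machine precision in
every run, and a group's fold change versus the calibrator is simply its
geometric-mean CNRQ. A gene reported as "$k$ times down-regulated" has
fold $1/k$.

Amplification factors come from dilution-series standard curves: OLS of
Cq on $\log_{10}$ concentration, $E = 10^{-1/\mathrm{slope}}$, with at
least three distinct concentrations required and non-negative slopes
flagged invalid rather than silently used. When no curve is available,
$E = 2$ is assumed per gene with a logged warning. Per-gene (not pooled)
efficiencies are used throughout.

## Error propagation

Relative standard errors propagate by the delta method on logs: the
relative SE of a product or quotient is the root sum of squared relative
SEs, and a geometric mean over $f$ references contributes each
reference's squared relative SE divided by $f^2$. Per-sample CNRQ SEs
combine the target RQ term (technical-replicate SE of the mean Cq scaled
by $\ln E$), the normalisation-factor term and the calibrator term,
treated as independent. Group-level SEs use the spread of log CNRQ
across biological replicates — biological replication, not technical,
is the unit of inference.

## geNorm

Reference stability follows geNorm: $M_j$ is the mean over partners $k$
of the SD (n−1 denominator) across samples of $\log_2(q_j/q_k)$;
ranking removes the highest-M gene iteratively (ties broken by gene
name, the alphabetically later gene leaving first, so results are
reproducible); pairwise variation $V(n/n{+}1)$ is the SD of
$\log_2(NF_n/NF_{n+1})$ over samples with $NF_n$ built from the $n$ most
stable genes. The recommended number of references is the smallest $n$
with $V < 0.15$ (the field's conventional cutoff, configurable), else
the $n$ minimising $V$, and never fewer than two. The final pair cannot
be separated by M alone; it is ordered by M in the last three-gene
round, ties again by name.

## Testing

Group differences are tested by two-sided Welch (unequal-variance)
t-tests on $\log_2$ CNRQ of biological replicates — the log scale
matches the multiplicative model, and Welch avoids assuming equal
variance between conditions whose biology differs. Commercial qPCR
suites do not document their test; this choice is the package's own,
stated rather than claimed equivalent. Multiplicity correction is off by
default (typical panels here are a handful of genes) with
Benjamini–Hochberg available via `p_adjust_method = "BH"`. Degenerate
zero-variance identical groups return p = 1. Missing Cq values drop the
affected technical replicate with a warning; a sample missing a
reference gene entirely is a hard error, because its NF is undefined.

# Synthetic generators

`simulateProteome()` builds reference CYPs as uniform-random sequences
over the 20 standard residues carrying one concrete instance of each
signature motif at controlled 1-based starts (default layout: K-helix at
$L-141$, PERF at $L-85$, haem at $L-66$, mirroring annotated fungal
CYPs); derived CYPs are mutated to a target ungapped identity with motif
positions protected, and partials are C-terminal 250-aa fragments
treated the same way. Rejection sampling enforces the ground truth
exactly: backgrounds contain no full ordered signature triplet, and
implanted sequences scan to exactly the implanted coordinates (no decoy
occurrences). Uniform residue frequencies are the conservative choice
for false-positive testing, since wildcard-heavy patterns hit uniform
backgrounds at least as often as biased ones of equal length. The
default scenario — 50 background proteins (150–600 aa), 8 full CYPs and
3 partials from 3 references at 60% identity — is the package's standard
recovery benchmark.

`simulateCq()` draws
$Cq = \mathrm{baseline} - \log_E(\mathrm{fold}) + b_s + u_{s,g} + \varepsilon$
with one biological effect $b_s \sim N(0, 0.3)$ per sample shared across
genes, an extra $u_{s,g} \sim N(0, 0.8)$ for planted unstable
references, and technical noise $\varepsilon \sim N(0, 0.2)$ per
replicate (all SDs in Cq units, all defaults configurable). The default
design has four groups (two media × two timepoints), one target 20-fold
induced in one group, two stable and one unstable reference, 3
biological × 2 technical replicates. Dilution series are generated
noise-free by default so efficiency recovery is exact.

What the generators do *not* emulate — and hence what passing tests do
not show about real data: proteome backgrounds have no homologous
non-CYP families, no compositional bias and no sequencing/gene-model
artefacts other than truncation; Cq tables have Gaussian noise, no
plate/batch effects, no inter-gene biological correlation beyond the
shared per-sample effect (which cancels through normalisation like a
loading difference), and no amplification failure. Recovery of planted
signal here validates the arithmetic and the pipeline plumbing, not
robustness to real-world artefacts.

# Numerical choices and problem sizes

Identity ties in reference selection break by byte-order name
comparison; all name sorting uses radix (C-locale) order for platform
independence. Printed-table identity comparisons use half-up integer
rounding. Generator rejection loops are capped (1000 draws for
sequence construction, 200 for mutation) and error loudly rather than
degrade. Seeds fully determine every generator through one isolated RNG
stream per call, restored afterwards.

Test and acceptance workloads are sized for a desk machine: exhaustive
alignment-enumeration oracles run on sequences up to 8 residues
(hundreds of random pairs), motif-scan oracles on 200 sequences up to
60 aa, discovery benchmarks on 61-protein proteomes against 3
references, and the stochastic fold-recovery study over 20 seeds of the
default Cq design. These sizes keep the whole suite under a minute
while leaving every code path exercised.

# Known limitations

- Tier assignment uses identity to the *screening* best reference; with
  very sparse reference panels the nearest reference may be a poor
  proxy for the true nearest family.
- The per-sample CNRQ SE treats RQ, NF and calibrator terms as
  independent, ignoring the covariance introduced when a reference gene
  is also the target (the group-level SEs, used for inference, do not
  have this issue).
- The motif grammar is exact-match; genuinely divergent P450s with
  non-canonical signatures (they exist) will be screened in by homology
  but rejected by the signature filter, which is the intended,
  conservative behaviour.
- Percent identity from global alignment depends on the gap model;
  values are comparable within this package's convention, not across
  tools.
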