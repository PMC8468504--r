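---
title: "Mining transcriptomes for antimicrobial peptide precursors: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining transcriptomes for antimicrobial peptide precursors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AMPminer)
```

## The problem

Antimicrobial peptides (AMPs) are short, mostly cationic effectors of innate
immunity. In fish they fall into two broad structural groups: cysteine-rich
peptides with conserved disulfide scaffolds (beta-defensins, hepcidins,
LEAP-2, NK-lysins) and cysteine-free amphipathic alpha-helical peptides, the
fish-specific piscidins. Piscidin precursors diverge rapidly in their mature
region, so BLAST-style annotation misses them; what stays conserved is the
*signal peptide*, which carries short diagnostic blocks (here the anchors
`FLVL` and `MAEPG`). AMPminer implements the in-silico arm of a discovery
workflow built on that observation: translate a transcript pool in six
frames, anchor on signal-peptide motifs, classify the cysteine-rich scaffold
families by rule, cut candidate peptides at convertase and monobasic sites,
and profile the candidates physicochemically to choose synthesis candidates.

## Pipeline model, stage by stage

### ORF discovery

`findOrfs()` enumerates every ATG-initiated ORF in all six frames, closed by
an in-frame stop or by the transcript end (flagged `partial`). Only ATG
starts are considered — precursor biology here always begins with an
initiator methionine — and this is a documented limitation for non-canonical
starts. The default `min_aa = 50` keeps the smallest full precursor in scope
(22-residue signal + 42-residue defensin = 64) while suppressing decoy
micro-ORFs. Nested ORFs (internal methionines) are deliberately kept: the
mining stage, not the ORF finder, decides what is a plausible precursor, and
downstream evaluations key on the coordinates of the full-length ORF.

### Signal-peptide heuristic

External signal-peptide predictors are deliberately out of scope; in their
place `predictSignalPeptide()` uses a transparent von Heijne-style score.
For every candidate cleavage position $c \in [15, 30]$ the score is

$$S(c) = \max_{w \in [8,12]} \; \overline{KD}(\text{best } w\text{-window in } 1..c) \;+\; \mathbf{1}[\,\text{res}_{c-2}, \text{res}_{c} \in \{A,G,S,C,T\}\,]$$

i.e. the mean Kyte–Doolittle hydropathy of the best hydrophobic core window
plus a +1 bonus when the $-3$ and $-1$ residues are small (the classical
(-3,-1) rule). The highest-scoring $c$ wins, ties to the smallest $c$, and
the call is withheld below a threshold $\theta$.

**Choice of $\theta$ (default 4.0).** A canonical secretory h-region is an
almost purely aliphatic stretch: on the Kyte–Doolittle scale an 8–12-residue
window of L/I/V/F averages 3.4–4.5, and a genuine cleavage site adds the
+1 small-residue bonus, so real signals score about 4.4 and above. The
N-termini of globular (non-secreted) proteins rarely sustain such a window:
across random protein starts the score almost never exceeds ~3.8. The
default threshold 4.0 sits between the two regimes, which is what makes the
cysteine-rich track selective (an AMP-free pool yields empty candidate
tables). It is configuration (`miningConfig(spThreshold = )`): for real
data with degenerate or divergent signal sequences a lower value (2.0–2.5)
trades precision for recall.

### Motif-anchored mining

`minePrecursors()` populates two tracks. The *piscidin-like* track requires
the anchor motifs within the first 30 residues (both, by default), a
precursor length in [60, 120], and a cysteine-free mature region — piscidins
carry no cysteines, and the cysteine count is taken after the predicted
cleavage (or after the anchor window when no cleavage is called) so that the
signal itself is not penalised. The *cysteine-rich* track requires a
predicted signal peptide and at least four cysteines after it; no motif
policy applies, since the disulfide scaffolds, not the signal, are the
diagnostic there. Motif matching is exact: no mismatch tolerance is defined
for the anchors, and exactness keeps results reproducible.

### Family rules

`classifyFamily()` applies, in fixed precedence order
(hepcidin > LEAP-2 > defensin > NK-lysin > piscidin-like):

* **hepcidin** — an `R-x-[K/R]-R` propeptide-convertase site whose
  downstream region carries exactly 8 cysteines in a 20–32-residue mature
  (canonical 26); the `QSHL` N-terminal block, which in hepcidins governs
  ferroportin binding, is recorded as corroborating evidence;
* **LEAP-2** — an `R-x-x-R` site releasing a 4-cysteine mature of about 46
  residues;
* **defensin** — no prodomain at all: the post-signal region itself is a
  6-cysteine peptide of about 42 residues;
* **NK-lysin** — at least 6 cysteines inside a 70–80-residue internal block,
  a deliberately transparent proxy for a saposin-B domain (no HMM
  dependence);
* **piscidin-like** — the anchors plus a cysteine-free mature region.

The precedence order resolves ties from most to least constrained rule; the
underlying biology never needs it, but determinism requires it. Exact
inter-cysteine spacing grammars are not enforced — they are family-variable
— but `cysSignature()` exposes the spacing for rule authors, and the rule
table is an editable TSV.

### Peptide derivation

For a cysteine-free precursor whose native mature form is unknown, the
design rule is: the first 20 residues after the signal cleavage are the
*parent peptide*, and candidate shorter forms are obtained by truncating at
potential monobasic processing sites. `truncationSeries()` generalises
this: every strict prefix ending in K or R is a candidate and the three
longest are kept. Applied to a 20-mer parent this yields the 17/13/10
series of the published synthesis panel for both precursor families, and it
extends to parents with differently placed basic residues. Convertase
families instead get the released mature via `convertaseMature()`.
C-terminal amidation is carried as a flag only (it adds +1 in the pH charge
model and −0.98 Da in mass when set); no amidation is asserted by default.

## Physicochemical descriptors

Two charge conventions coexist and are kept strictly separate:

* the **table convention** `formalCharge()`: $z = (\#K + \#R) - (\#D + \#E)$,
  histidine and the termini excluded. This integer convention is what
  peptide-design tables print (a His-containing 10-mer with 2 K + 1 R is
  +3, not +4);
* the **pH model** `phCharge()`: a Henderson–Hasselbalch sum over N-terminus,
  C-terminus (unless amidated) and the D/E/C/Y/H/K/R side chains with a
  single-pKa-per-group (Expasy-style) set, exposed via `defaultPka()`. The
  curve is strictly decreasing in pH, so `isoelectricPoint()` can bisect it
  on [0, 14] to 1e-3. Fractional charges (e.g. a defensin at +1.7) belong to
  this model.

The **hydrophobic ratio** counts residues in {A, C, F, I, L, M, V, W}; G, Y,
P and H are excluded from the set. Its table view truncates the percentage
toward zero (9/17 = 52.94% prints as 52%) — both the set and the truncation
are fixed so that the table view matches design-table conventions exactly;
the full-precision fraction is always available.

**Mean hydrophobicity** `meanHydrophobicity()` averages the
Fauchère–Pliska scale (as used by Heliquest: F 1.79, L 1.70, W 2.25,
K −0.99, ...) over the whole sequence. The **hydrophobic moment**
`hydrophobicMoment()` is Eisenberg's vector sum at $\delta = 100^\circ$ per
residue (ideal alpha-helix), normalised by length:

$$\mu_H = \frac{1}{N}\sqrt{\Big(\sum_n h_n \sin n\delta\Big)^2 + \Big(\sum_n h_n \cos n\delta\Big)^2}$$

A homopolymer of 18 residues (five full turns) has $\mu_H = 0$ by symmetry,
which is one of the invariants under test. `helicalWheel()` reports the
per-residue azimuths $(100 n) \bmod 360$ and the smallest arcs containing
all cationic and all hydrophobic azimuths. These face angles are a declared
geometric proxy for the "subtended angle" quantity of helical-wheel servers,
whose exact definition is not public; they are therefore never asserted
against external numbers.

Masses are average (isotope-weighted) and monoisotopic residue-mass sums
plus one water; `monoisotopicMass()` optionally applies fixed
carbamidomethyl-Cys (+57.02146 Da), matching an iodoacetamide-alkylated MS
workflow, and `trypticDigest()` attaches those alkylated masses to its
products (cleave after K/R, not before P, up to a configurable number of
missed cleavages).

## The synthetic transcriptome

Real discovery ran on a sequenced fin/spine transcriptome; the package
instead ships a seeded generator so every stage is testable offline.
`generateTranscriptome()` plants family-faithful precursor ORFs — each a
structural mimic, not a copy of any deposited sequence — among decoys:

* signal template: M + 2 basic + 16-residue aliphatic core + A-x-A
  (22 residues), agreeing with the (-3,-1)/h-core heuristic *by
  construction*; piscidin signals begin with `MAEPG` and carry `FLVL`
  inside the core;
* family scaffolds: 42-aa 6-Cys defensin directly after the signal; 36-aa
  prodomain + `RSKR` + 26-aa 8-Cys `QSHL...` hepcidin; 30-aa prodomain +
  `RSPR` + 46-aa 4-Cys LEAP-2; a 153-residue NK-lysin with a 75-residue
  6-Cys saposin-like block; piscidin matures of 38–58 cysteine-free,
  cationic-leaning residues;
* filler alphabets exclude C and R, so no spurious cysteine signatures or
  convertase motifs can arise in prodomains and matures;
* decoys (about 95% of the default pool, mirroring a realistic
  minority-positive setting) are random-codon ORFs or non-coding sequence,
  rejection-sampled so that no six-frame translation contains an anchor
  motif; plants sit on a random strand behind random UTRs;
* codons are drawn uniformly among synonymous options under the standard
  code; one seed drives everything, and equal seeds give byte-identical
  output.

`mutatePlants()` adds substitutions outside a protected mask (initiator,
anchor/convertase/N-terminal blocks, cysteines, the −3..−1 cleavage
residues), modelling the observation that piscidin variability concentrates
in signal/prodomain filler. Substitutions never introduce C or R.

What the generator does **not** emulate: read-level noise, assembly
artefacts, alternative starts, real codon-usage bias, realistic expression
levels, and real inter-family sequence homology. Passing the end-to-end
tests therefore demonstrates that the pipeline's logic is correct under its
own assumptions — perfect recall and high precision on generated pools — not
that these precision figures transfer to a real assembly, where signal
peptides are more variable and the threshold discussion above applies.

## Numerical and degeneracy choices

* Codons containing `N` translate to `X`; `X` is neutral (0) in the
  Kyte–Doolittle score and is a mass/scale error where a defined value is
  required.
* Bisection for pI runs to 1e-3 on [0, 14]; when the charge never crosses
  zero (no acidic group with an amidated C-terminus) the boundary is
  returned with a `boundary` attribute instead of a fabricated value.
* Helix descriptors are undefined for single residues: the profile reports
  `NA` there, while the low-level operations keep their length-≥-2
  contracts.
* Ties in the signal score resolve to the smallest cleavage position;
  mining output is sorted by (transcript, start, strand, end, frame) so it
  is invariant to input order.
* All tabular output is TSV with '.' decimals; manifests carry the config,
  seed, package version and input checksums so a run can be reproduced
  exactly.

## Problem sizes used in the test suite

The suite validates oracle equivalences on generated cases: 100 random
transcripts (300–600 nt) against an exhaustive six-frame ORF scan, 100
random peptides against a 0.001-pH grid scan for pI, 200 random proteins
against a split-then-merge digestion oracle, 100 random 20-mers against a
1-degree rotation scan for face angles, and an end-to-end pool of 200
transcripts carrying 26 planted precursors. These sizes give the
property-style tests dense coverage of boundary cases while keeping the
default check fast on a laptop.

## Worked example

```{r example}
tab <- peptideDesignTable(c(`b-Pte` = "FFKRLKNAFKSARQAWRDYK",
                            `g-Pte` = "FFRHLKSLWKGAKAAFRGAR"))
tab
```

```{r example2}
peptideProfile("FFRHLKSLWKGAKAAFR")
```

## Known limitations

* Only ATG starts; no coding-potential model; no homology search.
* The signal heuristic is a two-feature score, not a full predictor;
  its default threshold is calibrated for clearly hydrophobic h-cores.
* Saposin detection is a cysteine-count proxy, not a domain model.
* Cysteine spacing grammars are reported but not enforced.
* No disulfide connectivity, pyroglutamate, or dibasic processing.
* Expression support is the FPKM formula on a provided counts table; read
  mapping is out of scope.
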