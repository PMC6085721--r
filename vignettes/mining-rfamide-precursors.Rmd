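---
title: "Mining RFamide precursors: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining RFamide precursors: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfamine)
```

## The screening model

RFamide neuropeptides are released from prohormone precursors by a
stereotyped maturation path: the precursor is translocated via an N-terminal
signal peptide, cut by prohormone convertases at basic residue sites
(canonically Arg/Lys pairs), and a C-terminal Gly left on a cleaved peptide
is converted into the terminal amide. A peptide whose mature terminus is
...Arg-Phe-NH2 therefore appears in the coding sequence as
Arg-Phe-Gly-(Arg/Lys)-(Arg/Lys). `rfamine` screens conceptual translations
of assembled contigs for exactly this signature, then annotates surviving
ORFs as prohormones.

The screen's assumptions are worth stating plainly:

* **Cleavage is modelled positionally, not enzymatically.** Any maximal run
  of two or more R/K residues is a site; runs of three or more are treated
  as a single site (cutting KRR twice would manufacture a spurious
  single-residue product). Monobasic processing exists in mollusks but is
  noisier to predict, so it is off by default; when enabled, an isolated
  R/K counts only if another basic residue sits 2, 4 or 6 positions
  upstream, a standard processing-likelihood convention.
* **Amidation requires convertase context.** A segment's trailing Gly is
  consumed only when the segment abuts a downstream cleavage site. A Gly at
  the extreme C-terminus of the precursor is retained: with no site behind
  it there is no processing event to expose it.
* **Ambiguity never creates evidence.** Codons containing N translate to X,
  and X never matches any motif position.

## Parameters and defaults

| parameter | default | rationale |
|---|---|---|
| `mode` | `sense3` | assemblies are usually orientation-biased; the antisense strand can be swept with `both6`, and the synthetic tests show exactly what sense-only scanning misses |
| `min_aa` | 21 | "longer than 20 residues": the shortest plausible precursor (signal + one cassette) exceeds this; shorter hits are overwhelmingly chance matches |
| motif | `RFG(R/K)(R/K)` | the RFamide fingerprint; the core is data so related families (e.g. other amidated peptides) can be screened, while FxRIamide-type cassettes do not match the default core |
| `cleavage_rules` | `dibasic_only` | dibasic sites dominate annotated molluscan prohormones; monobasic calling is a sensitivity option, and enabling it only ever refines the dibasic segmentation (a tested invariant) |
| `min_peptide_aa` | 3 | inter-site scraps of 1–2 residues are processing debris, not peptides; they are kept as linker fragments so the precursor still reconstructs exactly, but are not counted |
| alignment | BLOSUM62, gap open 10, extend 0.5, identity over all columns | the customary global-protein-alignment setting; identity is always exact-match counts, never similarity, and the denominator is configurable (`columns`/`shorter`/`longer`) because published identity figures rarely state theirs |

Peptide classification is a total function of (sequence, amidation):
amidated and ending ...RF is `RFamide`; amidated and matching the
Phe-X-Arg-Ile terminal pattern is `excluded_FxRIamide` — labelled, not
dropped, so the family exclusion is auditable in reports; amidated otherwise
is `other_amide`; everything else `non_amide`.

## The signal-peptide caller

Dedicated signal-peptide predictors are trained models; re-deriving one is
neither desirable nor necessary here. The built-in caller is a transparent
rule-based implementation of the classical tripartite architecture:

* an n-region with at least one basic residue in the first 6 positions;
* an h-region: some 7-residue window in the first 45 residues with mean
  Kyte–Doolittle hydropathy ≥ 1.6 (the best window is taken, earliest on
  ties);
* a cleavage context with small neutral residues (A/G/S/C) at the −1 and −3
  positions, searched downstream of the h-region; among valid positions the
  one closest to 4 residues past the h-region end wins, ties to the earlier
  position.

All three components must be present for a call; the score combines them
(0.25 n-region + 0.25 context + 0.5 scaled hydrophobicity) into `[0, 1]`.
This caller is deliberately conservative and approximately placed; when
exact boundaries matter (e.g. reproducing a published annotation), a call
from any external predictor can be attached per sequence
(`signal_mode = "external"`) and is used verbatim. Sequences under 15
residues are refused rather than guessed.

## What the synthetic generator emulates — and what it does not

`generate_transcriptome()` plants precursors built as
signal + (peptide [+ Gly] + convertase run [+ spacer])* inside random
contigs: a 5' UTR with an in-frame stop immediately before the start codon,
uniform-synonymous reverse translation of the protein, a stop codon, a 3'
UTR, reverse-complemented whole for minus-strand plants. Ground truth
records every planted protein and its expected products, computed
structurally from the layout (a non-empty inter-cassette spacer is recorded
as fused to the following product, which is exactly how the annotation
rules will report it). Build-time validation re-scans the finished protein
and refuses specs whose cassette residues would create spurious or merged
cleavage sites, so truth and rules cannot silently drift apart.

Planted signals are generated to be detectable by the default heuristic
(Met + basic + hydrophobic core + S-x-A cleavage context); recovery
statistics therefore do not depend on external calls, though exact
peptide-boundary agreement is asserted with the planted boundaries attached
as external calls, since the heuristic's cleavage point may sit a few
residues off the planted one.

Real data differ in ways the generator does not model: codon usage bias,
sequencing/assembly errors (indels that shift frames), chimeric and
fragmented contigs, isoform redundancy beyond exact containment, and
compositional structure in UTRs. Passing the recovery tests therefore shows
the pipeline's logic is sound on well-formed input, not that recall on a
real assembly is 1; the sense-only/six-frame contrast and the
chance-hit calibration (observed signature rate on pure noise within 3
binomial standard errors of the composition-derived expectation) bound the
obvious failure modes.

## Numerical and degenerate-input choices

* ORFs are maximal stop-free runs; an initiator Met is not required by
  default because assembly fragments routinely truncate the 5' end.
  Coordinates are 1-based inclusive on the forward strand everywhere,
  including all reports.
* Candidate ordering is fully deterministic (signature count, then contig
  id, strand, frame, start); de-duplication keeps the longer of two nested
  proteins and the lexicographically lower contig id on exact ties.
* A precursor with no cleavage sites yields one peptide: the whole mature
  region, un-amidated.
* Alignment tie-breaking among co-optimal alignments follows the dynamic
  programming traceback of the underlying aligner; identity is invariant
  across co-optimal alignments in all tested cases, and the suite checks
  optimal scores against exhaustive enumeration rather than a fixed
  traceback.
* Reports are written atomically (stage-and-rename), and identical inputs
  and configuration produce byte-identical TSV/JSON/FASTA output;
  timestamps live only in the run manifest.

## Problem sizes used by the test suite

The suite checks the signature scanner against a position-by-position
oracle on 1,000 random 300-mers, the aligner against exhaustive alignment
enumeration on 200 random pairs of up to 8 residues, the reconstruction
invariant on 1,000 random synthetic precursors, and screen recovery on a
50-contig transcriptome with 10 planted precursors (two on the minus
strand). These sizes give the property tests real coverage while keeping a
full run comfortably on one CPU core.

## Known limitations

* The signal heuristic is rule-based; its cleavage boundary is approximate
  and its false-negative rate on atypical signals (e.g. very long or weakly
  hydrophobic h-regions) is higher than a trained predictor's. Use external
  calls when boundaries matter.
* Monobasic site calling, even gated by the upstream-basic convention,
  over-segments Arg-rich linkers; it is a sensitivity tool, not a default.
* Homology naming is explicit pairwise scoring against a user-supplied
  reference FASTA — there is no database search, no E-values, and no
  orthology inference; a best match at 25% identity names a candidate
  without implying orthology.
* The screen presumes intact reading frames. Frameshifted assemblies
  produce truncated ORFs that may fall under `min_aa`; lowering the
  threshold trades recall against chance hits, whose rate can be estimated
  with `expected_signature_rate()`.
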