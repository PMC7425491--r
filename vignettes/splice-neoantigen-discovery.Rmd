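---
title: "Discovering MHC-I neoantigens from tumor splice junctions"
author: "spliceneo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering MHC-I neoantigens from tumor splice junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceneo)
```

## The problem

Tumors frequently mis-splice. A splice junction observed in tumor RNA-seq
but absent from normal tissue can join exonic sequence that no annotated
transcript joins, and the protein translated across that junction can
contain peptides the immune system has never seen. If such a peptide is
processed, transported and presented by the patient's MHC class I
molecules, it is a candidate neoantigen — a potential vaccine target that
does not require any somatic mutation.

`spliceneo` turns a splice-junction table (the aligner's `SJ.out.tab`
dialect or a BED-like TSV), a genome, a transcript annotation, a
panel-of-normals junction matrix, the patient's HLA-I alleles and a known
epitope library into a ranked table of candidate neoantigens. Every stage
is a documented, separately testable function; the full pipeline is
`run_pipeline()` over a validated `spliceneo_config()`.

## Pipeline model

**1. Junction filtering.** Three gates, all strict inequalities:

* *read support*: unique junction reads must exceed 10;
* *relative usage*: psi5 and psi3 must exceed 0.1. psi5 is the fraction of
  a donor site's total junction reads carried by this junction (psi3
  analogously for the acceptor). psi is computed on the full unfiltered
  table so that denominators reflect all observed junctions — filtering
  first would inflate psi. Within each splice-site group psi sums to 1;
* *panel of normals*: junctions seen with at least 2 reads in at least 1%
  (ceiling, `>=` at both boundaries) of normal panel samples, and all
  annotation introns, form a normal-junction database; members are
  discarded as immune-tolerated. Both boundaries are parameters because
  the convention at the exact threshold is not universal.

Strand-unknown junctions (aligner strand code 0) are kept: they form
their own psi group, match the normal database on either strand, and are
tested against transcript models of both strands. Removal reasons are
assigned with fixed precedence (reads, then psi, then normal), so stage
counts always partition the input.

**2. Isoform construction.** Each surviving junction is mapped onto every
transcript whose span contains it on a compatible strand and classified:
tag 0 (an existing intron — annotated in context, no novel isoform), tag 1
(both sites are annotated exon boundaries: exon skipping), tag 2 (one
novel site: alternative donor/acceptor), tag 3 (both novel: exon split).
Among placements the smallest tag wins, then hosts need RPKM > 1
(`reads * 1e9 / (total_mapped * exonic_length)`), computed from a
per-transcript count table. Insertion applies the structural bounds used
by splice-event callers: a tag-2 boundary shift must change the exon
length by 2–250 bp inclusive; a tag-3 split must create an intron longer
than 50 bp. The junction's intron must intersect the host's CDS span —
a junction that cannot perturb the protein is rejected as non-coding.
Novel sites inside host introns, and tag-3 site pairs in two different
exons, are rejected with distinct reasons rather than modeled: intron
retention and multi-exon rearrangements are out of scope.

**3. Translation.** One-frame translation only: the spliced novel
transcript is translated from the *annotated* start codon in its original
frame to the first stop (or transcript end, recorded as `ran_off_end`).
Three- or six-frame translation would multiply false positives; a
frameshifting junction is still captured because translation simply runs
into novel sequence after the junction codon. Insertions that excise the
start codon are rejected (`start_lost`); proteins must exceed 30 residues.
Codons containing ambiguous bases translate to `X`, and any peptide
containing `X` is dropped before membership testing, since binding
predictors cannot score it.

**4. Peptides.** Retained proteins are chopped into 8–11-mers (a
`lengths` parameter reproduces 9-mer-only evaluation). k-mers found
verbatim in the *normal peptide index* are subtracted. The normal index
is built over the reference proteome **plus** the proteins obtained by
running the same insertion/translation machinery on panel-supported
normal junctions: commonly spliced non-annotated products are presumably
tolerated and must not be called tumor-specific. For each surviving
candidate the nearest normal peptide is the equal-length window of any
normal protein minimizing Hamming distance (ungapped, per the mismatch
count's definition), ties broken by lexicographically smallest window in
the C locale so results are platform-stable.

**5. Scoring.** Candidates are scored per allele. With L the logistic
transform `L(x) = 1/(1 + exp(5 (x - 2)))` centred on the conventional 2%
binder threshold:

$$S = C \cdot L(R_m)\,\bigl(1 - L(R_n)/2^{M}\bigr) \cdot H \cdot R$$

* `Rm`, `Rn` — binding percentile ranks of the candidate and of its
  nearest normal peptide on the same allele (the subtraction term is only
  meaningful per allele); pairs with `Rm < 2` (strict) are the putative
  neopeptides;
* `M` — Hamming mismatches to the nearest normal peptide; the factor
  `1 - L(Rn)/2^M` discounts candidates whose well-presented normal
  counterpart differs at few positions, and saturates to 1 as M grows;
* `C` — combined processing score (binding + proteasomal C-terminal
  cleavage + TAP transport);
* `H` — hydrophobicity-based presentation propensity;
* `R` — T-cell recognition probability from similarity to known epitopes.

Scores above 1e-8 (strict) are flagged as high-immunogenicity
neopeptides (HIN).

## Predictor surrogates

Binding, processing, hydrophobicity and recognition sit behind a small
predictor interface. Recorded-output parsers for the standard external
binding/processing tools are provided (`parse_netmhcpan_output()`,
`parse_netctlpan_output()`); the built-in surrogates are deterministic
pure functions so the pipeline runs and is testable fully offline:

* **Binding** (`surrogate_binding_predictor()`): an allele-keyed
  position-specific scoring matrix (anchor positions 2 and the C-terminus
  up-weighted 3x) derived deterministically from the allele name and a
  seed; a peptide's %rank is its score's percentile against a fixed
  seeded background of 2000 random peptides of the same length. Ranks are
  approximately uniform on random peptides, so the strict `< 2` gate
  passes about 2% of background — the behavior the threshold was designed
  around.
* **Processing** `C = (w_b (1 - \min(R_m,10)/10) + w_c\,\mathrm{cle} +
  w_t\,\mathrm{tap}) / \sum w` with binding-dominant default weights
  (1, 0.225, 0.025) and documented per-residue C-terminal cleavage/TAP
  propensity tables (hydrophobic and basic C-termini favored, proline
  strongly disfavored).
* **Hydrophobicity** `H = plogis(0.09 + 0.5 * meanKD)` over the
  TCR-contact positions 3..k-1 (Kyte–Doolittle scale); the coefficients
  put poly-alanine near 0.73. Positions 1, 2 and k are anchors and do not
  contribute.
* **Recognition** `R = Z/(1+Z)` with
  `Z = sum_e exp(k (|s,e| - a))` over the epitope library, `|s,e|` the
  best gapless BLOSUM62 alignment (sliding the shorter sequence along the
  longer), defaults `a = 26`, `k = 4.87` from the published fitness
  model. The sum is evaluated in log space: self-similar 11-mers
  otherwise overflow `exp`.

The surrogate hydrophobicity and binding models are explicitly *not*
re-implementations of any external tool's numerics; they are documented
stand-ins with the same interface, ranges and decision behavior, and are
swappable for adapters.

## The synthetic study

`generate_fixture(seed, dir)` writes a complete miniature study: a 17 kb
genome, five protein-coding genes (one minus-strand), all annotated
junctions plus twelve planted novel junctions, a 50-sample normal panel,
transcript counts, an epitope library and a ground-truth manifest.
Reference CDSs are random stop-free codons ending in a stop, and every
planted retained event excises a codon-aligned segment, so expected novel
proteins are exactly computable by the generator independently of the
pipeline's splicing code. Planted junctions sit on the decision
boundaries: 10 reads (fails the strict gate), psi 15/215 ≈ 0.07, a 1 bp
tag-2 shift, a 50 bp tag-3 intron, a 25-residue novel protein, a
UTR-confined junction, a start-codon-excising skip, a panel-supported
junction, and (optionally) a host at RPKM 0.77. Read counts (50 vs 100 on
shared donors), a panel detection rate of 60% of samples and transcript
counts of 1000 against a 1e7 library are chosen as typical magnitudes for
a well-expressed gene in bulk RNA-seq.

Epitope libraries contain twelve random peptides plus 9-mers of the
expected novel proteins centred on each junction codon, so the
recognition term sees epitopes resembling true junction peptides — the
situation the fitness model describes.

What the fixture does *not* emulate: read-level noise, junction
mis-mapping, multi-isoform genes (each planted junction has a single
candidate host), intron retention, expression uncertainty, and real
binding-motif biology. Passing tests therefore demonstrate the
correctness of the decision logic and arithmetic, not predictive
performance on patient data.

## Numerical and design choices

* All coordinates are 0-based half-open on the forward strand; aligner
  rows (1-based inclusive) and GTF (1-based inclusive) are converted at
  parse time. A junction key is `(chrom, strand, intron_start,
  intron_end)`.
* All biological thresholds are strict (`>`), following their usual
  phrasing ("greater than 10", "%rank < 2", "score > 1e-8"); the panel
  rule uses `>=` at both boundaries per "at least", with
  `ceiling(frac * n)` samples.
* Exon-boundary matching is exact (0 bp tolerance): junction coordinates
  from an aligner are base-exact.
* The tag-2 exon-modification bound applies only to tag-2 shifts; tag-3
  splits are governed by the intron-length bound. The RPKM gate uses the
  host's reference expression — the only quantity available before the
  novel isoform exists.
* When several same-tag hosts survive, one novel isoform per host is
  produced and peptides are deduplicated by sequence with merged
  provenance.
* Work is partitioned by junction; results are gathered and canonically
  sorted before scoring and writing, so `threads` never changes output.
  All user-visible orderings use radix (C-locale) sorting.
* Test and acceptance runs use the five-gene / twelve-junction study with
  a two-allele HLA set; the nearest-normal and psi property checks use
  500 and 100 randomized cases respectively — sizes at which brute-force
  oracles remain exact and fast.

## Limitations

Single junctions only (no combinatorial isoforms), no intron retention,
no MHC-II, no expression quantification beyond the RPKM gate, and
surrogate predictors whose absolute scores are not comparable to the
licensed tools they stand in for. The score's components beyond `Rm`,
`Rn` and `M` are peptide-intrinsic, so identical peptides from different
junctions receive identical `C`, `H`, `R`.
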