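# spliceneo

Identification and prioritization of MHC class I neoantigen candidates
arising from tumor-specific **alternative splicing**.

Tumors mis-splice: junctions observed in tumor RNA-seq but absent from
normal tissue can join coding sequence that no annotated transcript
joins. The proteins translated across such junctions contain peptides
the immune system has never tolerized against, and those presented by
the patient's HLA-I molecules are candidate neoantigens — vaccine
targets that require no somatic mutation. `spliceneo` takes an aligner
junction table and turns it into a ranked candidate table, entirely
offline.

## Pipeline

1. **Junction filters** (strict thresholds): unique reads > 10;
   psi5 and psi3 > 0.1 (percent-spliced-in, the junction's share of its
   donor/acceptor site's total reads, computed on the unfiltered table);
   removal of *normal junctions* — those detected with ≥ 2 reads in
   ≥ 1% of normal panel samples, plus all annotation introns.
2. **Isoform construction**: each junction is mapped onto covering
   transcripts and classified — tag 0 (existing intron), 1 (both sites
   annotated boundaries: exon skip), 2 (one novel site), 3 (both novel).
   Smallest tag wins; hosts need RPKM > 1; insertion enforces a 2–250 bp
   exon modification (tag 2), a > 50 bp novel intron (tag 3), and overlap
   with the CDS.
3. **One-frame translation** from the annotated start codon to the first
   stop; proteins must exceed 30 residues; `start_lost` insertions are
   rejected.
4. **Peptides**: 8–11-mers, minus every k-mer of the *normal proteome*
   (reference proteins plus proteins the same machinery derives from
   panel-supported normal junctions). Each survivor gets its
   nearest normal peptide (minimum Hamming distance, ungapped) and
   mismatch count M.
5. **Binding and scoring**: peptide × allele %ranks (pluggable
   predictor; deterministic surrogate built in); pairs with %rank < 2
   are putative neopeptides, scored

   S = C · L(R<sub>m</sub>) · (1 − L(R<sub>n</sub>)/2<sup>M</sup>) · H · R,  L(x) = 1 / (1 + e<sup>5(x−2)</sup>)

   with C the combined processing (binding/cleavage/TAP) score, H a
   hydrophobicity term, R the epitope-similarity (fitness-model)
   recognition probability with BLOSUM62 gapless alignment (a = 26,
   k = 4.87). Scores > 1e-8 are flagged HIN (high-immunogenicity
   neopeptides).

A synthetic-study generator (`generate_fixture()`) produces a complete
five-gene genome/annotation/junction/panel/epitope bundle with twelve
planted junctions and a ground-truth manifest of their expected fates.

## Worked example

```r
library(spliceneo)

fx  <- generate_fixture(1, "fixture")          # synthetic study, seed 1
m   <- fx$manifest
cfg <- spliceneo_config(
  genome = fx$paths$genome, annotation = fx$paths$annotation,
  junctions = fx$paths$junctions, panel = fx$paths$panel,
  counts = fx$paths$counts, total_mapped_reads = m$total_mapped_reads,
  epitopes = fx$paths$epitopes, hla = unlist(m$alleles),
  out_dir = "out")
res <- run_pipeline(cfg)
table(res$junction_fates$fate)
#>      exon_mod intron_length       low_psi     low_reads    non_coding
#>             1             1             1             1             1
#>        normal      retained short_protein    start_lost
#>            16             4             1             1
res$records[, c("peptide","allele","Rm","normal_peptide","Rn","M","S","HIN")]
#>      peptide      allele   Rm normal_peptide    Rn M        S   HIN
#>   SPRRPCLLLQ HLA-A*02:01 0.65     AAPRPCLLLQ  6.40 3 4.87e-01  TRUE
#>  TRPPGTLYDAR HLA-A*02:01 1.05    TRPPGTALQCL  4.15 5 3.99e-01  TRUE
#>     NTNTELIE HLA-B*07:02 1.25       ATNTELIE  0.85 1 1.00e-43 FALSE
#>     KTSKIRVR HLA-B*07:02 1.20       VRSKIRVR  5.20 2 1.64e-45 FALSE
#>   HVPPKTSKIR HLA-B*07:02 0.70     HVPPKTTFIP 10.15 3 5.93e-52 FALSE
```

Of 27 input junctions, 16 are annotated or panel-normal, five fail one
structural or expression gate each, and four survive to translation.
Their junction-spanning k-mers yield five peptide/allele pairs binding
below 2%. The two HINs are strong binders, several mismatches away from
any normal peptide, and similar to a library epitope; `NTNTELIE` binds
well but differs from a strongly-binding normal peptide at a single
position (M = 1, R<sub>n</sub> = 0.85), so the self-similarity factor
1 − L(R<sub>n</sub>)/2<sup>M</sup> collapses its score — exactly the
tolerance logic the score encodes. Outputs land in `out/`:
`score_table.tsv` (sorted by S), `neopeptides.fa`, `junctions.tsv`
(psi + per-junction fate), `novel_isoforms.gtf`, `summary.json`.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/spliceneo.R fixture --seed 1 --out fixture
Rscript inst/cli/spliceneo.R run --junctions fixture/SJ.out.tab \
  --genome fixture/genome.fa --annotation fixture/annotation.refGene.txt \
  --panel fixture/panel.tsv --counts fixture/counts.tsv \
  --epitopes fixture/epitopes.fa --hla "HLA-A*02:01,HLA-B*07:02" --out out
```

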