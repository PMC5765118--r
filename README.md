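# plateletIR

Platelets inherit partially spliced pre-mRNAs from megakaryocytes, and
activation (collagen/COLL, thrombin-receptor activating peptide/TRAP)
can trigger cytoplasmic removal of the retained introns followed by
translation of the matured message. `plateletIR` is an R package for the
full computational chain behind that biology:

1. **Intron retention (IR) quantification** from stranded, gapped RNA-seq
   alignments. Per intron *i* and sample *s*,

   IR_is = a_is / (a_is + j_is)

   where *a* is the intronic abundance (median per-base depth over the
   intron's measurable region, excluding positions covered by exons or by
   nested miRNA/snoRNA features) and *j* is the exon splice abundance
   (reads whose CIGAR-N gap matches the intron exactly).
2. **Retention filtering**: an intron is retained in a condition when its
   IR ratio exceeds the per-sample first quartile in at least 2 of 3
   replicates.
3. **Permutation differential testing** (pooled two-sample t with an s0
   stabilization term; 10000 sampled permutations): introns at BH-FDR
   0.01 ("removed" = significant, negative IR change), proteins at
   Bonferroni alpha 0.01 plus a linear |1.2| fold-change cutoff,
   transcripts at |1.5| fold-change and BH-FDR 0.05.
4. **Proteogenomic junction database**: for every intron retained at
   rest, +/-75 exonic nt of spliced exon-exon context translated in three
   reading frames, written as FASTA.
5. **Peptide-to-junction mapping** with junction-spanning calls (the
   peptide's coding span must straddle the junction offset) and
   per-junction quantification of spanning-peptide abundance.
6. **Integration**: stimulus-specific vs shared responder sets,
   protein-vs-mRNA concordance, and a per-gene validation table classing
   genes as `validated` (significant intron removal plus significant
   protein or junction-peptide accumulation), `partial`, or
   `not_significant`.

A deterministic synthetic-data generator (`simulate_study()`,
`simulate_ir_matrix()`) emulates the 3 CTRL + 3 COLL + 3 TRAP design with
planted intron-removal, protein and junction-peptide effects, so every
stage is testable against known ground truth.

## Worked example

```r
library(plateletIR)

res <- run_all(sim_config(seed = 1), out_dir = "pipeline_out", quiet = TRUE)

length(res$retained$CTRL)                 # introns retained at rest
#> [1] 44
sum(res$ir_diff$COLL$removed)             # introns removed after COLL
#> [1] 16
sum(res$protein_diff$TRAP$significant)    # proteins responding to TRAP
#> [1] 14
res$partition                             # stimulus-specific vs shared proteins
#> <stimulus_partition> COLL only: 4; TRAP only: 7; common: 7 (down 0, up 7, discordant 0)
table(res$validation$class, res$validation$stimulus)
#>                   COLL TRAP
#>   not_significant   20   15
#>   partial            1    3
#>   validated          9   12
```

Here 44 of ~60 simulated introns pass the retention filter in resting
samples; 16 are called removed after COLL stimulation at BH-FDR 0.01; and
the validation table recovers the planted "spliced and translated" genes
— significant intron removal coupled to junction-peptide/protein
accumulation — as `validated`. All stage outputs (IR matrix, differential
tables, junction FASTA, peptide matches, partition, validation) are
written as TSV/FASTA under `out_dir` with an md5 manifest; reruns with the
same seed are byte-identical.

A thin CLI over the same functions is installed at
`inst/scripts/plateletIR-cli.R` (subcommands `simulate`, `run-all`,
`ir-quant`, `junction-db`, `match-peptides`, `diff-protein`, `diff-ir`).

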