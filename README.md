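# tlr7scan

Screen a transcriptome for sex-biased, UU-rich, abundant self-RNA
transcripts — candidate endogenous sources of TLR7 ligands.

TLR7 is an endosomal receptor for single-stranded RNA whose minimal
stimulatory unit is the UU dinucleotide; an extended 9-mer,
5'-GUCCUUCAA-3', is a well characterized ligand. TLR7-driven autoimmunity
(notably lupus) is strongly female-biased, so the transcripts most likely
to feed the receptor in vivo are those that are at once UU-rich, highly
expressed, and female-biased — the profile of XIST, the ~19 kb lncRNA of
X-chromosome inactivation. `tlr7scan` is for computational immunologists
and genomics analysts who want to run that screen on their own counts and
sequences, or to study its behavior on simulated data with known ground
truth.

## The score

For each gene *g* in a tissue, four criteria are ranked ascending over the
N analyzed genes (ties averaged):

- r₁(g): total UU count of the gene's longest transcript variant
  (nonoverlapping by default),
- r₂(g): maximum UU richness — the largest UU count in any 500-nt window,
- r₃(g): sex bias log₂((TPM̄_F + c)/(TPM̄_M + c)), strongest male bias
  ranked 1,
- r₄(g): expression level (mean female TPM).

The **TLR7 ligation score** is S(g) = r₁ + r₂ + r₃ + r₄ (so 4 ≤ S ≤ 4N);
per tissue it is normalized by max S, and the cross-tissue summary is the
mean normalized score over tissues where the gene was analyzed. Supporting
stages: a low-count filter (genes with < 25 reads in ≥ 10% of samples are
dropped), TPM from counts and variant lengths, a moderated-t sex
differential-expression test with Benjamini–Yekutieli correction
(α = 0.05), a bin-matched-control single-cell module score with a
per-patient Pearson screen, and qPCR/reporter assay formulas (ΔΔCt,
2^ΔCt × R, fold induction).

## Worked example

Simulate a 500-gene transcriptome with a planted XIST-like transcript
(U-dense block, embedded GUCCUUCAA, 472× female bias, abundant), then run
the full pipeline:

```r
library(tlr7scan)

tx   <- simulateTranscriptome(seed = 42)
bulk <- simulateCounts(tx$transcripts, tx$truth, seed = 42)

d <- tempfile(); dir.create(d)
writeTranscriptomeFASTA(tx$transcripts, file.path(d, "tx.fa"))
writeCountsTSV(bulk$counts, file.path(d, "counts.tsv"))
writeSampleMetaTSV(bulk$sampleMeta, file.path(d, "samples.tsv"))

res <- runScorePipeline(scoreConfig(
    file.path(d, "tx.fa"), file.path(d, "counts.tsv"),
    file.path(d, "samples.tsv"), file.path(d, "out")))

head(res$combined, 5)
#>  gene_symbol mean_normalized_score n_tissues top_percent
#>        XISTL             1.0000000         3        0.21
#>        G0405             0.8297276         1        0.42
#>        G0220             0.8054078         1        0.63
#>        G0052             0.7867162         1        0.84
#>        G0095             0.7702403         3        1.05
```

The planted gene (`XISTL`) tops the cross-tissue normalized ligation score
in all 3 tissues (top 0.21% of 468 analyzed genes). Its sequence profile
shows why — the U-dense block planted at nt 181 carries the densest
window, and the motif sits at its recorded position:

```r
res$profile[res$profile$gene_symbol == "XISTL", ]
#>  gene_symbol length uu_count max_window_uu max_window_start motif_hits
#>        XISTL   3000      405           185              181       2500
```

and the moderated test calls its sex bias at `log2fc = 8.46`
(≈ 350-fold; the exact 472× simulated ratio is slightly attenuated in TPM
because the transcript is a large fraction of this small simulated
library), `q_by = 1.5e-113`.

The per-cell module score and patient screen run the single-cell stage:

```r
sc     <- simulateSingleCell(seed = 1)
scores <- moduleScore(sc$expr, sc$geneSet, seed = 7)
scr    <- patientScreen(sc$expr, scores, sc$cellMeta)  # 15 of 16 patients retained
```

A command-line front-end with `simulate` / `profile` / `score` /
`sc-score` / `assay` subcommands is at `inst/scripts/tlr7scan.R`.

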