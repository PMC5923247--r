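# spliceHDP

Discovery and per-sample quantification of mRNA isoforms from
short-read RNA-seq across many samples, without a reference
transcriptome.

Short reads rarely span whole transcripts, so the isoforms present in a
cohort — and their per-sample proportions — must be inferred jointly
from junction evidence scattered over samples. spliceHDP summarises
each mapped read as a *read term* `(start, end, covered-exon set)` and
models a gene's term counts `X ∈ N^{V×m}` with a hierarchical
Dirichlet process admixture: global isoforms (binary exon compositions
`b ∈ {0,1}^E`, encoded as integers MSB-first, so `(1,0,1) → 5`) are
atoms of a DP with concentration ω; each sample's isoform distribution
is a DP with concentration α sharing those atoms; and given its
isoform, a read term is multinomial with the isoform's
compatible-term simplex (η-weighted, with an ε noise floor). Sharing
atoms across samples gives power to find low-abundance isoforms, and
the nonparametric prior lets the catalog grow with the data.

The posterior is fitted by stochastic variational inference with
merge-propose-reduce catalog moves every 30 iterations (merge fuses
redundant isoforms when the penalised, re-optimised data likelihood
does not decrease; propose builds novel compositions from the exon
union of poorly mapped reads; reduce deletes isoforms no read supports
above probability 0.01), with the best of several random restarts
returned. Downstream, transcript expression is
`RPKM_t = 10^9 X_t / (L_t N)` with `X_t` the reads allocated by the
per-sample proportions; inferred sets are scored against truth by
maximum-cardinality minimum-weight Hamming matching
(p-partial precision/recall); and group-specific splicing is tested by
a Dirichlet likelihood-ratio test on transcript ratios plus a
hypergeometric test for population-specific allele enrichment.

The package also ships the evaluation simulators: a multi-isoform gene
read simulator (Dirichlet(1) per-sample proportions, 5′-biased starts)
and a long-read fragmenter (short reads separated by Normal(10, 40²) bp
inserts up to a target span).

## Worked example

```r
library(spliceHDP)
gene <- gene_model("demo", exon_starts = 1 + (0:4) * 300,
                   exon_ends = 1 + (0:4) * 300 + 200)
iso <- rbind(full = c(1, 1, 1, 1, 1), skip = c(1, 0, 1, 0, 1))
sim <- sample_dataset(gene, iso, m = 30, reads_per_sample = 40, seed = 7)
sim$rtm
#> read_term_matrix: 22 read terms x 30 samples, 1200 reads (demo)

f <- fit(sim$rtm, gene, cfg = fit_config(seed = 2, restarts = 3))
f
#> svi_fit: 2 isoforms over 30 samples (converged, restart 1)
#> codes: 31, 21
```

Codes 31 and 21 are the binary encodings of `(1,1,1,1,1)` and
`(1,0,1,0,1)` — both true compositions, recovered exactly:

```r
precision_recall(match_isoforms(f$isoforms, iso), p = 0)
#> precision    recall
#>         1         1

head(quantify(f, sim$rtm), 2)
#>   gene_id transcript_code sample_id reads length   rpkm ratio
#> 1    demo              31   sample1 30.33   1000 758158 0.758
#> 2    demo              21   sample1  9.67    600 403070 0.242
```

Sample 1 allocates 30.3 of its 40 reads (ratio 0.758) to the
full-length isoform; RPKM is per kilobase of that isoform's 1000
exonic bp per million mapped reads. Across samples the fitted
proportions track each sample's realised read composition with mean
absolute error 0.06 at this depth.

For shell pipelines, `exec/splicehdp` exposes the same steps as
`splicehdp extract | fit | quantify | evaluate | simulate | stats`
subcommands over GTF/SAM/TSV files.

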