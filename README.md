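# lineagetx

Lineage-resolved transcriptome analysis for the first, asymmetric
division of the plant zygote. The division yields an apical cell (AC),
founder of most of the embryo proper, and a basal cell (BC), founder of
the suspensor; profiling the egg cell, zygote (Zy14, Zy24), both
daughters and the 32-cell embryo proper / suspensor (32E / 32S) makes it
possible to ask *when* the two lineage programs diverge and *how* each
daughter acquired its transcripts. `lineagetx` implements the downstream
statistics of that analysis, starting from gene-level count matrices and
transcript models:

* **Differential expression** between cell types by a negative-binomial
  Wald test (median-of-ratios size factors, method-of-moments dispersion
  with trend moderation), calling DEGs at fold change ≥ 2 and
  FDR < 0.01.
* **Lineage-maintained genes**: up(AC:BC) ∩ up(32E:32S) for the apical
  lineage (ACL), down ∩ down for the basal lineage (BCL), with temporal
  profile grouping.
* **Transcript fate** of each daughter-cell DEG from its mean FPKM
  profile: `inherited_asymmetric` (zygote-deposited, partitioned into
  one daughter, gone by the 32-cell stage), `de_novo` (absent in the
  zygote, newly transcribed in one daughter), `selective_deletion`
  (zygote-deposited, retained in one daughter and degraded in the
  other).
* **Global structure**: Pearson correlation of samples, unsupervised
  hierarchical clustering, PCA.
* **Hypergeometric enrichment** (Benjamini–Hochberg adjusted) for
  annotation terms and for TF binding motifs.
* **TF regulatory networks**: PWM scans of the −500..+100 promoter
  window, motif enrichment in DEG sets, and a coexpression filter
  (Pearson r > 0.87); an edge requires all three.
* **lncRNAs and splicing**: candidate filtering (≥ 200 nt; single-exon
  same-strand overlaps removed), sense/antisense/intergenic context,
  consensus coding-potential voting (≥ 4 of 5 scorers), and pairwise
  classification of splice events (exon skipping, alt donor, alt
  acceptor, intron retention, complex).
* A **synthetic-data generator** that emulates the whole
  zygote → (AC, BC) → (32E, 32S) study with planted ground truth, so
  every module is validated end to end without any external data.

The statistical core in brief: counts are modeled as
K ~ NB(μ, α) with Var(K) = μ + αμ²; the Wald statistic is
z = log2((m_A + c)/(m_B + c)) / SE with a delta-method SE and pseudo-mean
c = 0.5; enrichment p-values are upper-tail hypergeometric,
p = Σᵢ C(K,i) C(N−K, n−i) / C(N,n) for i = k..min(K,n). See the methods
vignette (`vignettes/lineage-transcriptomics.Rmd`) for every rule,
threshold and design choice.

## Worked example

Run the whole pipeline on the default synthetic study (3000 genes,
7 cell types × 3 replicates):

```r
library(lineagetx)
cfg <- pipeline_config(outdir = "run1",
                       synthetic = list(design = study_design(seed = 1)))
s <- run_pipeline(cfg)

str(s$deg_counts[["AC:BC"]])
#> List of 2
#>  $ up  : int 210
#>  $ down: int 180
str(s$lineage)
#> List of 2
#>  $ ACL_maintained: int 120
#>  $ BCL_maintained: int 90
```

210 genes are upregulated in the apical cell relative to the basal cell
and 180 downregulated; 120 and 90 of them stay differential at the
32-cell stage and are therefore called ACL- and BCL-maintained. The
strongest AC:BC calls are the planted daughter-specific genes:

```r
de <- attr(s, "stages")$de[["AC:BC"]]$results
head(de[order(de$FDR), ], 3)
#>     gene_id baseMeanA baseMeanB log2FC         p       FDR call
#> 214   G0214         0       248  -8.96  0.00e+00  0.00e+00 down
#> 234   G0234         0       157  -8.30  0.00e+00  0.00e+00 down
#> 235   G0235       160         0   8.33  0.00e+00  0.00e+00   up
```

Because the data are synthetic, the summary also scores recovery of the
planted truth:

```r
str(s$recovery[c("jaccard_ACL", "jaccard_BCL", "fate_accuracy", "uhc_ari")])
#> List of 4
#>  $ jaccard_ACL  : num 1
#>  $ jaccard_BCL  : num 1
#>  $ fate_accuracy: num 1
#>  $ uhc_ari      : num 1
```

i.e. the maintained sets match the planted ones exactly, every planted
fate-class gene is labeled with the correct mechanism, and the 15
samples of the five contrasted cell types cluster perfectly by cell
type. All per-stage tables (DE results, fate labels, correlation
matrix, dendrogram, PCA, enrichment, TF edges, lncRNA calls, splice
events) are written under `outdir`, alongside a machine-readable
`summary.json`.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/run_pipeline.R --outdir run1 --seed 1
```

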