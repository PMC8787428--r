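# phosflow

Downstream analysis of mass-spectrometry phosphoproteomics data, from a
phosphosite intensity table to biological interpretation — entirely
offline, driven by a config file, and reproducible to the byte.

Large-scale phosphoproteome profiling quantifies tens of thousands of
phosphorylation sites, but turning a MaxQuant `Phospho (STY)Sites` table
into biology usually means stitching together many tools: clean-up and
normalization, differential statistics, translating site coordinates to
reviewed or human-ortholog accessions so annotation databases apply,
inferring which kinases drive the changes, set- and signature-level
enrichment, and interaction-network analysis. phosflow implements that
whole chain as one R package for analysts who want scripted, auditable
runs rather than interactive dialogs.

## What it computes

* **Ingestion** — the MaxQuant dialect (reverse/contaminant removal,
  per-site multiplicity summing or Perseus-style expansion by
  phosphocount) and a generic schema-mapped format; sectioned CSV design
  files. Fold-change sign convention: the higher-numbered group is the
  numerator.
* **Preprocessing** — missingness filtering (rows, then columns), median
  or quantile normalization on the log2 scale, and iterative
  truncated-SVD low-rank imputation (requires ≥ 4 observed values per
  row; otherwise the run falls back to normalization only).
* **Overview** — log2 display transform (missing → intensity 1),
  Euclidean/complete-linkage heatmap clustering in two variants, PCA
  with k-means at k = reference group count + 1.
* **Differential statistics** — Welch/Student and paired t, exact or
  approximate Wilcoxon, a reproducibility-optimized test statistic
  (bootstrap top-list optimization of the stabilized statistic
  |m₁−m₂|/(α₁+α₂·s), permutation p), and a rank product test (geometric
  mean of per-pair fold-change ranks, sample-wise permutation null);
  multi-group ANOVA + Tukey HSD, or blocked repeated-measures ANOVA for
  paired designs; BH FDR; significance lists; volcano tables with the
  ≤ 60-point labelling rule.
* **Site mapping** — global pairwise alignment (BLOSUM62, affine gaps)
  with per-site coordinate translation, conservation classes
  (exact / phospho-compatible / mismatch / unmapped) and identity
  scores, for unreviewed→reviewed and cross-species transfers.
* **Kinase activity** — position weight matrices from a substrate-window
  library, log-odds peptide scoring, resampled match p-values, and the
  swing score `log2((pos+1)/(neg+1))·√(pos+neg)` with joint-permutation
  z and p; top-250 kinase–substrate edge tables.
* **Enrichment** — hypergeometric over-representation against dual
  (universal and dataset) backgrounds; direction-tagged phosphosite
  signature enrichment (weighted-KS on the full dataset's signed site
  statistic) with GCT v1.3 conversion.
* **Network hubs** — STRING-style confidence-filtered networks
  (strictly > 0.4), hub rules (top 10% or mean + 1 SD), and hub
  interaction enrichment against 1000 equal-sized control networks drawn
  from the measured proteins.
* **Synthetic data** — generators for every input format with planted
  ground truth (differential sites, kinase motifs, signatures, a network
  hub), used throughout the tests.

All randomized stages are seeded; rerunning a pipeline config reproduces
every CSV byte-for-byte.

## Worked example

Simulate a 150-site, 6 + 6 study with planted regulation and kinase
motifs, then run the core chain:

```r
library(phosflow)

dir  <- file.path(tempdir(), "demo")
kf   <- simulateKnowledgeFiles(simSpec(nSites = 150), dir, seed = 1)
sim  <- kf$sim
sim$set
#> PhosphoSet: 150 phosphosites x 12 samples
#>   proteins: 50 | missing: 5.1% | multiplicity-expanded: no
#>   samples: S1, S2, S3, S4, S5, S6 ...

pp  <- preprocess(sim$set, mode = "normalize")
st  <- compareGroups(pp$set, sim$design, 1, tests = c("t", "rankprod"),
                     seed = 1)
sig <- selectSignificant(st, metric = "fdr", threshold = 0.05,
                         fcMin = 2, test = "t")
nrow(sig)
#> [1] 20
head(sig[, c("site_id", "log2fc", "p_t", "fdr_t")], 3)
#>          site_id    log2fc          p_t        fdr_t
#> 7   SYNP007;67;T  2.209586 8.791065e-07 0.0001125546
#> 12  SYNP012;56;T -2.270986 1.500728e-06 0.0001125546
#> 16 SYNP016;102;S -2.061315 2.656737e-06 0.0001328368
```

All 20 planted differential sites are recovered at FDR ≤ 0.05 with
fold change ≥ 2, at their planted ±2 log2 effect sizes. Kinase activity
from the same statistics:

```r
pwms <- buildPWM(readKinaseLibrary(kf$paths$kinase_library))
info <- siteInfo(pp$set)
mp   <- pwmPValues(pwms, setNames(info$window, info$site_id), seed = 1)
sw   <- swingScores(mp$p, setNames(st$log2fc, st$site_id),
                    setNames(st$p_t, st$site_id), seed = 1)
sw[order(sw$p_greater),
   c("kinase", "pos", "neg", "swing_raw", "z", "p_greater", "p_less")]
#>            kinase pos neg swing_raw         z   p_greater      p_less
#> KIN_UP     KIN_UP   9   1  7.342581  4.834318 0.000999001 1.000000000
#> DECOY_A   DECOY_A   2   0  2.241475  1.571873 0.125874126 0.969030969
#> DECOY_B   DECOY_B   1   0  1.000000  0.731532 0.373626374 0.894105894
#> KIN_DOWN KIN_DOWN   0   9 -9.965784 -6.473104 1.000000000 0.000999001
```

The planted up-kinase gets a large positive swing z with permutation
p ≈ 0.001 for increased activity (9 of its predicted substrates
up-regulated, 1 down); the planted down-kinase mirrors it; the decoys
stay null. `runPipeline(readRunConfig("run.yaml"))` executes the same
chain — plus annotation, enrichment and network stages — and writes the
standard output folders (Group Information, Overview Figure, Statistical
Analysis, Enrichment, Kinase Analysis, Network, Annotation). A thin CLI
wrapper lives at `inst/scripts/phosflow` (`run` / `validate` /
`simulate` subcommands).

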