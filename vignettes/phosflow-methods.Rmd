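---
title: "phosflow: models and methods for downstream phosphoproteomics"
author: "phosflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phosflow: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phosflow takes a phosphosite intensity table — typically a MaxQuant
`Phospho (STY)Sites` file — and carries it through the downstream analyses
a phosphoproteomics study needs: clean-up, normalization and imputation,
data overview, differential statistics, cross-species site mapping, kinase
activity inference, protein- and site-level enrichment, and network hub
analysis. This vignette explains the models behind each stage, the
parameters that matter, and the choices made where the design was open.

# Data model

The central container is the `PhosphoSet`, a `SummarizedExperiment` whose
rows are phosphosites and whose single assay holds non-negative raw (or,
after preprocessing, log2) intensities with `NA` for missing values. Each
site carries its protein accession, 1-based acceptor position, residue
(S/T/Y), a 15-mer sequence window centred on the acceptor and padded with
`_` at protein termini, and a multiplicity: the phosphocount of the
peptides supporting the quantification (1–3), or 0 for rows summed over
multiplicities. Site identity throughout the pipeline is
`accession;position;residue`, with the multiplicity appended for expanded
rows; the MaxQuant `id` column is kept only as provenance.

A `GroupDesign` maps samples to integer group labels under one or more
classifications and lists the comparisons to run. One sign convention
matters everywhere downstream: **in a two-group comparison the group with
the larger number is the numerator**, so positive log2 fold changes mean
"up in the higher-numbered group". Group numbering should be chosen with
this in mind.

# Ingestion

`parseMaxQuantSites()` removes decoy ("reverse") rows always, and
potential contaminants unless `keep_contaminants` is requested. MaxQuant
reports one intensity column per sample and multiplicity
(`Intensity X___1/2/3`). In the default *summed* mode the three channels
are added per sample, with missing channels treated as zero — but a site
missing in all three channels stays missing, which preserves the
missingness information the filtering and imputation stages rely on. The
*expanded* mode instead emits one row per (site, multiplicity), dropping
channels absent everywhere; the summed intensity of a site always equals
the sum of its expanded rows. Intensities of exactly 0 are read as
missing, following MaxQuant's convention for unquantified entries.

`parseGenericSites()` ingests preprocessed tables from other platforms
(Progenesis, Spectronaut, openMS, PEAKS) through a small column-mapping
schema rather than interactive prompts, for reproducibility. No clean-up
is applied; rows whose window is not a 15-mer centred on the stated
residue are rejected with a warning.

# Preprocessing

`filterMissing()` drops rows, then columns, whose missing fraction
*strictly exceeds* the thresholds; the column pass is computed after the
row pass, so a column can be rescued by the removal of bad rows. The
row-then-column order is a fixed convention.

Three modes mirror the usual practice:

* **none** — log2 transform only;
* **normalize** — median normalization on the log2 scale: each column is
  shifted so all medians equal the mean of the original column medians,
  preserving the global intensity level;
* **normalize_impute** — quantile normalization (via
  `limma::normalizeQuantiles`, ties sharing the mean of their spanned
  quantile values, missing entries excluded from ranking and left
  missing) followed by low-rank imputation.

`lowRankImpute()` treats the log2 matrix as approximately low-rank, as
intensity data with a few dominant sample-level factors typically is:
missing cells are initialised with row means, then the rank-*r* truncated
SVD of the completed matrix is computed and its reconstruction overwrites
only the missing cells, iterating until the largest relative change drops
below `tol` (default rank 2, tol 1e-5, at most 500 iterations). Observed
cells are never modified. Imputation requires at least four observed
values per row; when any row fails this, the run is forced into a
normalization-only mode and the fallback is reported. Whether quantile
normalization averages ties exactly as other implementations do is
documented rather than claimed; our rule is the one stated above.

# Overview figures

Overview computations operate on a display transform: missing values are
assigned intensity 1 so they map to log2 = 0. An observed intensity of
exactly 1 is then indistinguishable from missing; this is acceptable for
figures and is never used for statistics. Heatmaps use Euclidean distance
with complete linkage, in two variants (samples only; samples and sites).
PCA is computed on centred sample profiles over all sites (no
most-variable pre-selection), and k-means on the score space uses
**k = number of groups in the reference classification + 1**, with a
fixed seed and 10 restarts recorded in the run log. The 3D PCA view is
simply the first three components of the same decomposition.

# Differential statistics

Fold changes are ratios of group means of raw-scale intensities over
observed values; tests run on the log2 scale.

* **t** — Welch's t by default (a pooled-variance flag is available),
  paired t for paired comparisons. Zero-variance sites with equal means
  give p = 1.
* **Wilcoxon** — rank-sum when unpaired, signed-rank when paired (a
  signed-rank test is undefined for unpaired unequal groups); exact
  p-values for group sizes up to 25 without ties, otherwise the
  continuity-corrected normal approximation. Note that at very small
  group sizes the exact test is intrinsically discrete: with 4 vs 4
  samples the smallest attainable two-sided p is 2/70, so its realized
  type-I error at 0.05 is 0.0286, not 0.05.
* **ROTS-style reproducibility-optimized statistic** — the family
  d = |mean difference| / (a1 + a2 · s), with s the pooled standard error.
  The pair (a1, a2) is chosen to maximize the reproducibility z-score
  Z = (R − R0) / sd0 of top-k lists between bootstrap resamples (B pairs,
  resampling within groups), against the same quantity under group-label
  permutation; the candidate grid is a1 ∈ {0, 0.01, …, 5} with a2 = 1,
  plus the fold-change-ranking family a2 = 0 (all a1 > 0 give the same
  ranking, so it is evaluated once) — the ordinary t corresponds to
  a1 = 0, a2 = 1. Top-list sizes k run over a log-spaced grid up to half
  the number of sites (capped at 2000). p-values come from group-label
  permutation of the selected statistic, pooled across sites so that
  small designs (35 distinct 4v4 splits) still yield fine-grained p.
* **rank product** — per-pair fold changes (all between-group sample
  pairs when unpaired, matched pairs when paired), ranks within each
  pair (rank 1 = most up, resp. most down), and the geometric mean of a
  site's ranks. The null permutes site labels within every sample and
  recomputes the pair ranks. This choice is deliberate: the textbook
  null of independent uniform rank columns ignores that unpaired pairs
  share samples, and is anti-conservative for all-pairs designs (we
  measured type-I error near 0.27 at nominal 0.05 on 4v4 data); the
  sample-wise permutation preserves the shared-sample correlation and is
  calibrated, while reducing exactly to the independent-rank null when
  pair columns are independent, as in paired designs. Tail probabilities
  are pooled across sites; the percentage-false-prediction estimate is
  the usual expected-count/rank. Because observed tied fold changes
  produce fractional average ranks, exact integer-rank enumeration
  checks are run on continuous (tie-free) instances.

Multi-group comparisons use one-way ANOVA with Tukey HSD when unpaired.
For paired designs the linear mixed model is fitted as its exact
compound-symmetry equivalent, a fixed-block ANOVA `y ~ subject + group`,
with Tukey HSD on the group term; for two paired groups this reproduces
F = t² of the paired t exactly, which the tests verify. All permutation
p-values use the (1 + exceedances)/(1 + draws) estimator, so p > 0
always; FDR is Benjamini–Hochberg, with missing p-values excluded from
the family size.

Significance lists apply a p- or FDR-threshold for a chosen test plus an
optional raw-scale fold-change magnitude cutoff, ordered by metric with
site-id tie-breaks. Volcano figures plot up to four comparisons; points
are labelled only when the figure's total number of significant points is
at most 60 (the operational reading of the labelling rule).

# Cross-species and reviewed-accession site mapping

Site-hosting databases key on reviewed accessions, while measured data —
especially from non-human organisms — often carry unreviewed ones, and
human-ortholog coordinates are needed to exploit human-centric resources.
`globalAlign()` performs Needleman–Wunsch global alignment with affine
gaps (BLOSUM62, gap open 10, extend 0.5 per residue — exposed as
configuration, since no canonical values exist for this step) through
`Biostrings::pairwiseAlignment`, and derives a strictly increasing
query-to-target coordinate map. `mapSite()` classifies each mapped site
as *exact* (same residue), *phospho_compatible* (target residue S/T/Y),
*mismatch*, or *unmapped* when the acceptor aligns to a gap.
`translateSites()` applies this across a whole table with per-pair
alignment caching, recomputes the target-side 15-mer (so mapped sites can
feed kinase scoring directly), and reports the identity score — matches
divided by alignment length, gap columns included — because mappings
should only be trusted in proportion to that identity. Accession pairing
(unreviewed to reviewed, or query to ortholog) comes from a user-supplied
table, the offline stand-in for a live database lookup.

# Kinase activity inference

Known substrate 15-mers per kinase define a position weight matrix with
additive smoothing: `PWM[p, a] = (count + pseudocount) /
(n_p + 20 · pseudocount)`, where pads are excluded from counts; a
position seen only as pad is uniform. Data windows are scored by the
log2 odds sum against a background (uniform 1/20 by default), pads
contributing zero; the acceptor position is included (an excluded-centre
mode exists). Match significance for every (kinase, window) pair comes
from null windows resampled column-wise from the data windows' positional
letter pools — preserving positional composition — with the +1-corrected
tail (whole-window shuffling is available as an alternative null).

For a comparison, the predicted substrates of kinase k are the sites with
match p ≤ `alphaPWM` (default 0.05). With `pos`/`neg` the counts of
substrates significantly up/down at `alphaSite` (default 0.05), the raw
swing is

```
swing_raw = log2((pos + pseudo) / (neg + pseudo)) * sqrt(pos + neg)
```

with pseudo = 1 — a signed, count-weighted log odds of directional
substrate regulation. The (fold-change sign, site p) rows are permuted
jointly across sites, preserving each kinase's substrate set, to give a
z-score and one-sided p-values. Substrates are thresholded rather than
weighted by −log10 p (a flag could switch this; thresholding matches the
counting formula above). Under a global null the test is somewhat
conservative because many kinases have pos = neg = 0 both observed and
permuted, tying the statistic at zero. The kinase–substrate network keeps
the significant matched sites, ranked by site p with deterministic
site-id tie-breaks, capped at the top 250, grouped by substrate protein
for circos-style display.

# Enrichment

Protein-level over-representation uses the hypergeometric upper tail,
run twice per significant list: against a universal background (a
supplied list, or the union of gene-set members and the dataset) and
against the dataset background (all measured proteins). Both full and
significant-only (overlap ≥ 1, FDR ≤ 0.05) tables are written.

Site-level signature enrichment scores direction-tagged signatures
(members suffixed `;u`/`;d`) against the full dataset — never just the
significant list — using the signed statistic sign(log2fc) · (−log10 p)
of the chosen test (the ranking metric is our choice; site keys use
`accession;position;residue`, with flanking-sequence keying available).
The score is a weighted Kolmogorov–Smirnov running sum: hits climb by
|s|^weight shares, misses fall by 1/(N − |hits|). Direction is handled
per subset: `u` members are scored on the list ranked by s descending,
`d` members on the list ranked by −s descending (equivalently, their
statistic is negated before ranking), and the two subset scores are
combined weighted by matched member counts. This makes the score exactly
invariant under negating every statistic while swapping all tags — the
property a sign-convention-free directional score must have; scoring the
jointly adjusted vector on a single ranking does not satisfy it, because
non-member ranks flip. Normalization and significance use site-label
permutations stratified by ES sign, as in standard GSEA practice; our
normalization across directional subsets is documented here, not claimed
identical to any particular external implementation. Reported coverages
`pct_up`/`pct_down` are the percentages of matched members observed up-
or down-regulated. Inputs are also converted to GCT v1.3, whose strict
reader/writer round-trips byte-for-byte.

# Network hubs

The interaction network of a significant list is the induced subgraph of
a confidence-scored edge table (STRING-style, scores in [0, 1]) on the
significant proteins, keeping only edges with confidence strictly greater
than 0.4; isolated query proteins stay in the network with degree 0.
Hubs are defined either as the top 10% by degree (boundary ties
included — a documented convention) or as degree > mean + 1 sample SD.
Hub interaction enrichment draws, for each hub, 1000 control protein sets
of the same size from the measured dataset's proteins (the "total data"
universe, not an external one), hub forced in, sampling without
replacement; the p-value is the +1-corrected fraction of control networks
in which the hub's degree reaches its observed degree, with BH FDR across
hubs. Control sets resample protein membership only; they do not preserve
degree structure beyond set size.

# Synthetic data

The generator exists so that every stage is testable offline with known
truth. Protein sequences are generated first and sites are placed on
them, so windows, FASTA, ortholog sequences (+10-residue N-terminal
extensions) and kinase motifs are mutually consistent. Intensities follow
a log-normal model: per-site baseline N(20, 2) on the log2 scale,
within-group noise SD 0.5, MCAR missingness at 5%; the defaults plant a
two-group 6 + 6 design with 20 differential sites shifted ±2 log2 units
(half up, half down), two kinases with 3-letter consensus motifs and 10
substrates each among the regulated sites (plus two decoy kinases), an
up- and a down-signature drawn from the planted regulation, one gene set
collecting the regulated proteins, and an interaction table with a
planted degree-8 hub. These sizes are deliberate desk-scale stand-ins for
a real study (tens of samples, 10⁴ sites): large enough for the planted
signals to be unambiguous, small enough that the full pipeline and its
permutation tests run in seconds. What the generator does **not**
emulate: intensity-dependent (MNAR) missingness (a flag exists for
stress tests), correlated peptides from shared proteins, batch effects,
or realistic kinase motif redundancy — so green tests demonstrate
correctness of the computations, not robustness to every pathology of
real data.

# Numerical and degenerate-input conventions

* Permutation p-values are never 0: (1 + exceedances)/(1 + draws).
* Zero-variance rows: t-type statistics return p = 1 at equal means and
  p = 0 otherwise; constant multi-group rows return F = 0, p = 1; the
  ROTS statistic defines 0/0 as 0, so constant rows never outrank
  signal.
* BH is applied per test family, missing p excluded from the family
  size.
* Ties: quantile normalization averages spanned quantiles; rank product
  uses average ranks; top-k and top-250 selections break ties by site
  id; the top-10% hub rule includes boundary ties.
* All stage seeds derive from the single run seed and are written to the
  run log, making every CSV byte-reproducible; figure files are
  regenerated but not byte-compared.
* Intensity 0 in MaxQuant input is read as missing.

# Pipeline and scope

`runPipeline()` drives everything from a declarative YAML config — the
replacement for the original interactive dialogs — and writes the
documented folder layout (Group Information, Overview Figure,
Statistical Analysis, Enrichment with a PhosphoSite-enrichment subfolder
per comparison, Kinase Analysis, Network, Annotation) plus a run log of
parameters and seeds. Stage gating by organism: kinase and site-signature
stages run for human, mouse and rat only; the shipped 18-organism list
affects gating, never computation, and is user-editable. Everything runs
offline against flat-file knowledge inputs (FASTA, pairing table, kinase
library, GMT gene sets, signature file, edge table); live database
queries, disease-ontology enrichment, interactive 3D rendering and
upstream spectral processing are out of scope.

# Known limitations

* The ROTS grid search is the dominant cost; B and the grid are
  parameters, and the defaults target desk-scale data.
* The swing permutation test is conservative for kinases with very few
  substrates (heavily tied statistic).
* Quantile normalization with missing data uses per-column interpolated
  ranks; columns with extreme missingness are normalized on little
  information.
* Site mapping quality degrades with alignment identity; the identity
  column is reported precisely so users can cut on it.
* The exact Wilcoxon test is discrete at small n; its realized type-I
  error sits below the nominal level (see above).
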