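# circadetox

Circadian analysis of insect detoxification gene expression and promoter
E-box architecture.

Nocturnally feeding lepidopteran larvae (e.g. *Spodoptera litura*) express
much of their xenobiotic-metabolizing machinery — P450s, GSTs,
carboxylesterases, aminopeptidases N — rhythmically, peaking in the
**daytime**, in antiphase to night feeding, and day-peaking genes carry more
E-box enhancer elements (canonical CACGTG, non-canonical CANNTG) in their
3 kb upstream promoters. `circadetox` implements the full computational
chain behind such claims as a tested R package plus a numbered analysis
workflow, with a synthetic-data module that plants every signal with known
ground truth so each stage is verified by parameter recovery.

## What it computes

* **Rhythm detection** — a JTK-style nonparametric test: Kendall's
  $S = C - D$ between each gene's series and rank-transformed cosine
  references over periods $P \in [12, 24]$ h and a 3 h phase grid, with the
  *exact* tied-reference null obtained by Gaussian-multinomial convolution
  ($S = M - 2D$, $D$ the inversion count of a random multiset permutation),
  Bonferroni correction over distinct references and BH q-values.
* **Soft clustering** — log10 homogenization + per-gene standardization,
  then fuzzy c-means ($c = 12$, $m = 1.25$):
  $v_i = \sum_j u_{ij}^m x_j / \sum_j u_{ij}^m$,
  $u_{ij} = 1/\sum_k (d_{ij}/d_{kj})^{2/(m-1)}$.
* **Phase classes** — peak bin of the cycle-averaged profile;
  DAY = rhythmic with acrophase in ZT[0,12), NIGHT = [12,24),
  else ARRHYTHMIC; DEG filter at FDR < 0.01 with ratio > 2 / < 0.5.
* **Promoter E-boxes** — strand-aware 3 kb upstream extraction from
  FASTA + GFF3, overlap-aware CANNTG scanning, per-class densities
  ("E-box per gene"), TSS-distance histograms with the 300–1800 bp mass
  fraction, label-permutation enrichment, and in-silico CACGTG→TGTACA
  mutant construction.
* **Behavior** — percent-active summaries (strict >12 crossings / 20 min),
  acrophase/trough of entrained series, and free-running period by
  chi-square periodogram with least-squares cosinor refinement over
  20–28 h.
* **Synthetic study** — cosinor expression with multiplicative log-normal
  noise, promoters with Poisson-planted class-dependent E-box counts
  (optionally background-masked so scans recover planted hits exactly),
  and sinusoidal behavioral series under LD/DD.

## Worked example

```r
library(circadetox)
cfg <- pipeline_config()            # study defaults; seed = 1
rep <- run_pipeline(cfg, "results/run")
```

`results/run/report.txt` from that call:

```
genes analysed:            300
rhythmic fraction:         0.923
class fractions:           DAY 0.663 / NIGHT 0.260 / ARRHYTHMIC 0.077
E-box per gene:            DAY 2.68 / NIGHT 2.10 / ARRHYTHMIC 0.30
E-box mass in 300-1800 bp: 0.487
feeding acrophase/trough:  ZT18 / ZT6
defecation acrophase:      ZT9
tau locomotion (DD):       25.00 h (> 24)
tau feeding (DD):          23.00 h (< 24)
```

Reading it: the study planted 64.5/25.9/9.6% day/night/arrhythmic genes
with per-class promoter densities 2.54/1.77/0.57 E-boxes per gene, an LD
feeding rhythm peaking at ZT18, a defecation peak at ZT9, and free-running
periods of 25 h (locomotion) and 23 h (feeding). The recovered class
fractions sit within binomial error of the planted simplex, the scan
recovers the planted E-box counts exactly (background masking is on), the
behavioral acrophases are exact, and both free-running periods are
recovered on the 0.1 h grid with the correct "shorter/longer than 24 h"
classification. Planted distances are uniform over the promoter, so about
half the hit mass falls in 300–1800 bp (1500/2995 ≈ 0.50).

The same chain runs step by step with narrative output via the numbered
drivers:

```sh
Rscript analysis/01_simulate.R   # plants the study under results/data/
Rscript analysis/02_rhythm.R     # rhythm calls (writes results/rhythm_calls.tsv)
Rscript analysis/03_cluster.R    # fuzzy c-means, c=12, m=1.25
Rscript analysis/04_classify.R   # peak bins, DAY/NIGHT/ARRHYTHMIC
Rscript analysis/05_ebox.R       # promoter scan, densities, enrichment
Rscript analysis/06_behavior.R   # acrophases and free-running periods
Rscript analysis/07_report.R     # headline numbers + truth-table closure
```

User-supplied data (expression TSV with ZT/CT columns, genome FASTA, gene
GFF3) replaces the simulation through
`pipeline_config(expression_tsv =, genome_fasta =, annotation_gff =)`.

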