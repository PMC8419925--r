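# haplocall

Haplotype-aware SNP and small-indel calling from long-read sequencing
data, in R.

Long reads (ONT, PacBio) have high per-base error rates, so single-column
base counts are a weak variant signal — but one read spans dozens of
heterozygous sites, and every base on it comes from one parental
haplotype. `haplocall` turns that linkage into the primary feature for
SNP calling, and uses read phasing plus per-haplotype multiple sequence
alignment for indels:

* **SNPs** — for each candidate site *b*, up to 40 *likely heterozygous*
  sites sharing a read with *b* (within 50 kb for ONT, chosen either
  nearest-first or from fixed distance bands) form a 41-column window.
  Reads covering *b* are grouped by the base they carry there, and the
  window is summarised as a 5 × 41 × 5 tensor of signed counts
  F<sup>t</sup><sub>BD</sub> = C<sup>t</sup><sub>BD</sub> · g(D), with
  g(D) = −1 when D is the reference base at site *t* and +1 otherwise,
  plus a reference channel and a reference row. A small convolutional
  network maps the tensor to four independent per-base presence
  probabilities; ≥ 2 bases above 0.5 ⇒ heterozygous (including
  multiallelic 1/2), otherwise the best base gives a homozygous call or
  no call. QUAL = −100·log₁₀(1 − P(B)).
* **Phasing** — SNP calls phase the reads (built-in greedy read-linkage
  phaser, or an external WhatsHap-style phaser via a subprocess
  contract).
* **Indels** — candidates are gated on per-haplotype depth and windowed
  insertion/deletion frequencies (dual windows: ≥ 3 bp events in a 10 bp
  window, ≤ 10 bp events in a 4 bp window). The 160 bp reference window
  and read windows are MSA-realigned per read set (all / phase 1 /
  phase 2); each set yields a 5 × 128 symbol-frequency matrix M and
  one-hot reference matrix Q, stacked as [M − Q, Q] into a
  15 × 128 × 2 tensor for a 4-class zygosity network. Alleles come from
  the MSA consensus aligned back to the reference with affine gaps.

A deterministic diploid read simulator (exact alignments by
construction, homopolymer-aware error model), an exact genotype-level
comparator with precision/recall/F1, and a four-mode pipeline
(`snps_unphased`, `snps`, `indels`, `both`) complete the toolkit, so the
whole method can be trained and verified at desk scale with no external
data.

## A worked example

```r
library(haplocall)

cfg   <- simulation_config(region_length = 50000, seed = 7)
truth <- simulate_diploid(cfg)
sim   <- simulate_reads(truth, cfg, dir = "demo_sim")

reads <- read_alignments(sim$bam, "chrSim", 0, 50000)
ref   <- read_reference(sim$fasta, "chrSim", 0, 50000)
cand  <- select_snp_candidates(reads, "chrSim", 0, 50000, ref)
head(cand, 3)
#>   chrom  pos ref_base depth       aaf top_alt
#>  chrSim   40        G    29 0.4827586       C
#>  chrSim 1486        T    31 0.5483871       C
#>  chrSim 2547        A    28 0.4642857       T

het <- select_het_sites(cand)
nbr <- choose_neighbor_sites(cand$pos[5], cand$ref_base[5], het, reads)
tns <- build_snp_feature_tensor(nbr, reads)
dim(tns)          # 5 41 5     (rows R_A,R_G,R_T,R_C + reference row)
nbr$n_sites       # 17         (likely-het neighbours sharing a read)

blocks <- phase_internal(
  variant_calls(cand$chrom, cand$pos + 1, cand$ref_base, cand$top_alt,
                rep("0/1", nrow(cand)), 50)[cand$aaf < 0.8, ],
  reads)
reads <- assign_read_phases(reads, blocks)
#> phase blocks: 1 | tagged reads: 114 / 114
```

The simulated 50 kb genome carries 60 truth variants under 114 reads
(30.6×); all SNP candidates above are true heterozygous sites (AAF near
0.5), every read is assigned to its haplotype in a single phase block,
and the exhaustive error-free indel sweep recovers every allele exactly:

```r
indel_recovery_sweep(seed = 1, lengths = c(1, 5, 15, 30))$recovery_rate
#> [1] 1
```

Training and cross-genome evaluation of the SNP network are packaged as
one call (about 13 minutes on one CPU: a 1.2 Mb training genome, 100
epochs, then calling an independent 200 kb genome):

```r
exp <- snp_recovery_experiment(seed = 1)
exp$metrics
#> precision    recall        F1
#>         1         1         1
exp$counts
#> TP=173 FP=0 FN=0  precision=1.0000 recall=1.0000 F1=1.0000
```

A thin command-line front end over the same functions is installed at
`inst/cli/haplocall.R` (subcommands `call`, `train`, `simulate`,
`evaluate`).

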