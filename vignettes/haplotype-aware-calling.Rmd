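---
title: "Haplotype-aware SNP and indel calling from long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-aware SNP and indel calling from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Long reads (Oxford Nanopore, PacBio) span tens of kilobases but carry
per-base error rates that are orders of magnitude above short-read data.
Base counts at a single pileup column are therefore a weak signal: at 30x
coverage and a few percent error, a heterozygous site (expected
alternative allele fraction 0.5) and a noisy homozygous site can look
alike. What long reads uniquely offer is *linkage*: a 20 kb read covers
on the order of 20 heterozygous SNPs, and all bases on one read come from
one parental haplotype. `haplocall` exploits exactly that: each SNP
candidate is classified from a pileup image built over *distant likely
heterozygous sites that share reads with the candidate*, so the network
can see whether the candidate's allele split is consistent with the
haplotype structure of its neighbourhood — the signature of a true
heterozygous variant — or uncorrelated with it, the signature of noise.

Indels are harder still, because alignment errors smear them across
columns. Here the reads are first phased using the SNP calls; each
candidate region is then *re-aligned* per haplotype with a multiple
sequence alignment (MSA), and a small classifier decides zygosity from
the resulting per-column symbol frequencies. The actual allele sequence
is taken from the MSA consensus, aligned back against the reference.

# The SNP model

## Candidate selection

For a genomic site $b$ with reference base $R$, the alternative allele
frequency is

$$\mathrm{AAF}(b) = \frac{\max_{B \in \{A,G,T,C\}\setminus R}
\#\{\text{reads supporting } B \text{ at } b\}}
{\text{total read depth at } b}.$$

A site is a candidate when depth and AAF reach their thresholds; the
defaults are depth $\ge 8$ and AAF $\ge 15\%$. Comparisons are inclusive
at the stated bound, one convention applied everywhere. Deletion-spanning
reads count toward depth but never toward an alternative base.

## The feature tensor

A subset $V$ of candidates is marked *likely heterozygous*: AAF within a
band around 50% (0.4–0.6 for ONT; 0.3–0.7 for CCS, 0.3–0.6 for CLR,
where shorter reads force a more permissive band). During training the
truth heterozygous SNPs play the role of $V$, so the network learns from
correct anchors.

For each candidate $b$, up to 20 sites of $V$ are chosen per flank among
those that share at least one read with $b$ and lie within the platform
distance limit (50 kb ONT, 20 kb PacBio). Two strategies are available:

* `nearest` — the 20 nearest qualifying sites per flank;
* `banded` (ONT default) — per flank, up to 2, 3, 4, 5 and 6 sites from
  the distance bands (0,2], (2,5], (5,10], (10,20] and (20,50] kb. This
  spreads the anchors along the read length, so a dense cluster of false
  candidates (which would corroborate each other) cannot monopolise the
  window, while true SNPs inside dense clusters are still usable.

The window $Z$ (41 columns, $b$ at the centre, genomic order, zero
padding at the outer edges) is crossed with the read groups
$R_B = \{\text{reads with base } B \text{ at } b\}$, $B \in \{A,G,T,C\}$.
For each group row, window column $t$ and base channel $D$ the tensor
holds the signed count

$$F^{t}_{BD} = C^{t}_{BD}\, g(D), \qquad
g(D) = \begin{cases}-1 & D = \text{reference base at } t\\
+1 & \text{otherwise,}\end{cases}$$

where $C^{t}_{BD}$ is the number of reads of $R_B$ carrying base $D$ at
$t$. A fifth channel carries a row of ones marking the reference base at
$b$, and a fifth row one-hot encodes the reference base of every site in
$Z$. The final image is $5 \times 41 \times 5$. At a true heterozygous
site the two populated rows show anti-correlated signed patterns across
the linked columns; at an error-driven candidate the split is random.
Padded columns are all-zero in every channel, including the reference
channel, so that absent neighbours carry no signal.

To transfer between datasets of different depth, the counts are rescaled
by (training coverage)/(testing coverage) before prediction; the
reference channel and reference row are left untouched.

## Network, decision rule, quality

The network has three convolutional layers. The first layer runs three
parallel kernels — a $1\times k$ row kernel, a $k\times 1$ column kernel
and a 2D kernel — whose outputs (projected to a common filter count) are
summed; layers two and three use $2\times 3$ kernels. The flattened
output feeds a fully connected layer with dropout 0.5. Head A emits four
*independent* per-base presence probabilities (sigmoid, not softmax), so
multiallelic sites are representable. Head B receives head A's logits
concatenated with the hidden layer and classifies zygosity; it exists
only to inject a training signal for miscalled zygosity and is ignored at
calling time.

Calling uses head A alone: if at least two bases exceed probability 0.5
the site is heterozygous on the two highest-probability bases (`0/1` if
one is the reference, `1/2` otherwise); otherwise the single best base is
taken — reference means no call, anything else a homozygous `1/1`. The
QUAL score is $-100\log_{10}(1-P(B))$ with $B$ the alternative allele
(for multiallelic calls, the one with the *smaller* probability), capped
at 999.

Training minimises the sum of the four per-base binary cross-entropies
and the zygosity cross-entropy, with Xavier initialisation, Adam at
learning rate $10^{-3}$, L2 coefficient $10^{-3}$, dropout 0.5, 100
epochs. The spatial kernel sizes and the loss are part of the method; the
filter counts (16/32), hidden width (48) and batch size (32) are this
package's own choices sized for CPU training, all exposed in
`snp_network_config()`. Head B's gradient flows into the shared trunk by
default (`zygosity_into_trunk = FALSE` confines it to its own layers).
Inputs are multiplied by a fixed `input_scale` (default 1/30, the
reciprocal of the default training coverage) so that signed counts enter
the first layer near unit scale; this is a numerical choice, not a
per-tensor normalisation, and it preserves the coverage information in
the features.

# Phasing

SNP calls are phased and reads assigned to haplotypes. The production
contract is an external read-based phaser (WhatsHap-style) invoked as a
subprocess; by default its genotype-altering options
(`--distrust-genotypes`, `--include-homozygous`) are off, so phasing
never changes a genotype. Because tests and small installations should
not depend on an external binary, `phase_internal()` implements greedy
read-linkage phasing: heterozygous sites connected by shared reads form a
block (reads are contiguous intervals, so left-to-right linkage is
exact), and each site's allele orientation is chosen to maximise
agreement with the reads covering it and the already-phased sites. Output
is correct up to a global swap per block, which is all downstream indel
calling needs. Reads are then tagged by majority vote over the phased
alleles they carry; ties and uninformative reads stay unassigned — they
are excluded from the per-phase read sets but still contribute to the
all-reads set.

# The indel model

For site $b$ and phase $i$, two sliding windows starting at $b$ count
reads containing qualifying events: the large window (10 bp) counts
indels of at least 3 bp — the length floor exists to stop runs of 1–2 bp
sequencing errors from accumulating into a high frequency — and the
small window (4 bp) counts indels of at most 10 bp. A site is a
candidate when both per-phase depths reach the threshold (default 8) and
the insertion frequency reaches 0.4 or the deletion frequency 0.6 (ONT
defaults). The per-phase frequencies are combined with `max` by default:
a heterozygous indel lives on one haplotype only, and heterozygous is an
output class of the model, so candidates must be discoverable from a
single phase. The printed alternative — `min` across phases — is
available as `phase_combine = "min"` for strictly biallelic-homozygous
screening, but it suppresses heterozygous indels and is not the default.

For each candidate, the reference window of 160 bp (260 bp for PacBio
profiles, whose pileups are less gappy) starting at $b$ and the
corresponding read subsequences are realigned by MSA, separately for all
reads, phase-1 reads and phase-2 reads. The alignment is truncated to its
first 128 columns (and padded with gap columns when shorter, which keeps
every column's symbol frequencies summing to one). Per set, $M$ holds the
per-column symbol frequencies over $\{A,G,T,C,-\}$, $Q$ one-hot encodes
the realigned reference, and the set's block is the two-channel matrix
$[M-Q, Q]$; the three blocks stack to $15 \times 128 \times 2$. A
convolutional classifier with the same trunk design (column stride 2 in
layers 2–3 to walk the wide input) and two hidden layers outputs four
zygosity probabilities: homozygous-reference, homozygous-alternative,
heterozygous-reference, heterozygous-alternative. Training uses Adam at
$10^{-4}$, L2 $10^{-5}$; because heterozygous-alternative sites are rare,
each epoch resamples examples with inverse-class-frequency weights by
default.

Calling: hom-ref wins — no call. Hom-alt — consensus of the all-reads
MSA (per column the majority read symbol; ties prefer the reference
symbol, then the first symbol in A,G,T,C,- order; gaps removed), aligned
globally (affine gaps) against the reference window; the first gap run
gives a left-anchored REF/ALT pair; genotype `1/1`. Het — the same per
phase, combined: same allele on both phases is `1|1`, one phase `1|0` or
`0|1`, two different alleles a multiallelic `1|2` (with the shorter
reference allele extended so both alternatives share one REF). The QUAL
convention extends the SNP formula to $-100\log_{10}(1-P)$ of the winning
class.

## MSA backends

The default backend is a built-in centre-star MSA: every read window is
aligned to the reference window by affine-gap overlap alignment (match
+2, mismatch −4, gap open 8, gap extension 1 — the algorithm family is
part of the method, the scores are package defaults), and the pairwise
alignments are merged on the shared centre with the once-a-gap-always-a-
gap rule. Because the two phase sets are subsets of the all-reads set,
the pairwise alignments are computed once per candidate and each set's
alignment is assembled from the shared results. An external backend
(`msa_backend = "mafft"`) runs mafft as a subprocess; on error-free read
sets the two backends produce identical consensus sequences (gap
placement may differ; the consensus after gap removal may not), which the
test suite asserts.

# The simulator

`simulate_diploid()` and `simulate_reads()` generate the hermetic test
bed: a uniform-random reference, phased SNPs and indels on two
haplotypes, and error-bearing reads with alignments that are exact by
construction (composed from the haplotype-to-reference edit list), so no
external aligner is involved and every test is deterministic in one
seed. Defaults emulate a human-like 30x ONT sample: one SNP per 1000 bp,
one indel per 5000 bp (lengths 1 + geometric, truncated at 30 bp), two
thirds of variants heterozygous, 2% of heterozygous variants
multiallelic, 20 kb mean read length (SD 5 kb), 1% substitution and 0.5%
insertion/deletion errors, with deletion errors multiplied by 3 inside
homopolymer runs of length at least 4 — mimicking the dominant nanopore
failure mode. Variant anchors keep a minimum spacing of 50 bp so truth
records never overlap. An optional mode (`realign = TRUE`) writes reads
to FASTQ and maps them with minimap2 instead, for integration tests
against a real aligner.

What the simulator does *not* emulate: context-dependent substitution
spectra, systematic strand effects, mapping ambiguity in repeats,
chimeric reads, and coverage waves. Tests passing on this simulator
therefore demonstrate that the implementation is faithful and that the
method's machinery works at realistic rates — not that real-genome
benchmark accuracy is reproduced.

# Training-data construction

Labelled SNP examples pair each candidate tensor with per-base presence
labels read off the truth genotype (both alleles of a heterozygote are
"present") and a het/hom zygosity label. Candidates absent from the
truth become homozygous-reference negatives. At realistic error rates
almost no site passes the 15% gate without being a real variant, so
negatives are harvested by lowering the candidate AAF floor to 5% during
training-example collection only, and downsampled to two negatives per
positive. Similarly, because clean data produces almost no false indel
candidates, homozygous-reference indel windows are drawn at random
positions far from any truth variant. Both are package design choices
documented here; the calling-time gates are never altered.

# Numerical and design notes

* Internal coordinates are 0-based half-open everywhere; the single
  conversion to 1-based happens in the VCF writer/reader.
* Strand is ignored; pileups use aligned (already reverse-complemented)
  sequences. Secondary, supplementary and duplicate alignments are
  excluded; the default mapping-quality floor is 0.
* Tie-breaks: nearest-site selection prefers smaller distance, then
  smaller coordinate; MSA consensus ties prefer the reference symbol,
  then symbol order; read-phase votes tie to unassigned.
* The candidate positions produced by the indel gates form runs of
  consecutive sites around one event; the pipeline clusters each run and
  evaluates its first position, and identical records emitted by
  overlapping windows are collapsed after calling.
* Indels sitting within a few bases of the MSA window edge can be
  clipped by the ends-free overlap alignment; windows start at the
  candidate site precisely so the event sits comfortably inside.
* Degenerate inputs: empty pileups error in `alt_allele_frequency`;
  candidates whose neighbor count falls below `min_neighbor_sites`
  (default 1) are emitted as no-calls without prediction; a read set
  that supports no base at a candidate raises an uncallable-site error
  that the pipeline converts to a skip.
* Chunked execution pads each chunk by the neighbor distance limit so
  feature windows are chunk-invariant; phasing and indel calling run per
  contig, so block boundaries do not depend on the chunk size either.

# Problem sizes used by the shipped experiments

The cross-genome SNP experiment (`snp_recovery_experiment()`) trains on
a 1.2 Mb simulated genome (about 1200 SNPs; roughly 3200 labelled
examples including negatives) for 100 epochs at batch 64, and calls an
independently simulated 200 kb genome at the same 30x coverage and 1%
substitution error. These sizes were chosen so that held-out F1 clears
0.95 with margin across seeds (typical runs reach 0.97–0.995 with
precision near 1; smaller training genomes measurably lose accuracy —
150 kb trains to F1 about 0.6, 800 kb to about 0.93–0.98); they are the
package's scaled stand-in for whole-genome training. The exhaustive indel sweep
(`indel_recovery_sweep()`) covers lengths 1–30, both types and both
zygosities at depth 8 per haplotype, error-free, and must recover every
allele exactly.

# Known limitations

* The internal phaser is greedy; on error-free data it makes no switch
  errors, but it is not an MEC optimiser and the external-phaser
  contract exists for production use.
* The centre-star MSA inherits the reference-bias of its centre choice;
  complex nested events in one window may be summarised by a single gap
  run (only the first gap run becomes an allele).
* Homopolymer indel errors are the dominant residual failure mode, as
  expected for nanopore data; no length-based indel filtering is applied
  downstream.
* The models shipped by the experiments are trained on simulated data;
  calling real data requires training on real benchmark genomes.
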