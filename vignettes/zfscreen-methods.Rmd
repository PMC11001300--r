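---
title: "Methods: zinc-finger motif prediction, flank scanning and target screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zinc-finger motif prediction, flank scanning and target screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfscreen)
```

`zfscreen` nominates candidate direct targets of a C2H2 zinc-finger
transcription factor. The motivating system is the silkworm BTB-ZF
repressor Bm-mamo, whose short isoform carries three tandem C2H2
fingers and whose predicted 9-bp binding site (consensus `GTGCGTGGC`,
containing the EMSA-validated *Drosophila* mamo core `TGCGT`) was
scanned against the 2-kb flanks of every annotated silkworm gene and
intersected with differential expression between pigmentation
genotypes. The package implements each of those stages as a reusable,
separately testable unit, together with a selection-scan module
(nucleotide diversity and F~ST~ between wild and domesticated
populations), a qPCR relative-expression module, a distance-based
phylogeny module, and seeded simulators that give every stage inputs
with known ground truth.

## Finger detection and the canonical binding model

`find_zf_domains()` matches the classical Cys2His2 spacing
`C-x(1,4)-C-x(12)-H-x(3,5)-H` with lazy quantifiers on the variable
regions, so each coordinating pair binds the nearest compatible
partner, and matches never overlap. The recognition helix is numbered
the classical way: position 1 is the first helix residue, 7 residues
after the second coordinating cysteine; position −1 immediately
precedes it; position 6 immediately precedes the first histidine. On
the Zif268-derived fixture finger `FQCRICMRNFSRSDHLTTHIRTHT` this
yields helix residues −1=R, 1=S, 2=D, 3=H, 4=L, 5=T, 6=T — the worked
anchor for the numbering. The per-finger `confidence` is a small
structural feature count (pattern match, canonical CXXC spacing,
hydrophobic helix position 4) on a 1–3 scale; the default
`min_confidence = 0` keeps every pattern match because this scale is
not comparable with external prediction-server scores.

`predict_pwm()` applies the canonical binding model: each finger reads
a 3-bp sense-strand triplet, with the residue at helix position 6
specifying base 1, position 3 base 2 and position −1 base 3; fingers
bind antiparallel to the DNA, so the C-terminal finger's triplet sits
at the 5′ end of the motif. Residue 2 contacts the complementary
strand of the base 3′-adjacent to the triplet; that contact is exposed
as an optional fourth column per finger (`cross_strand_pos2`), off by
default because a three-finger protein with a printed 9-bp site
implies 3 bp per finger.

Residue-to-base preferences come from a plain-text
`RecognitionCodeTable` (position, residue, pA..pT). The shipped
default is a deliberately compact canonical code distilled from
classical C2H2 recognition studies (e.g. arginine at −1/6 → G,
glutamate/aspartate at 3 → C), with 0.85 on the preferred base and a
uniform fallback for residues it does not cover. It is not a
reimplementation of any trained specificity model, and it is fully
user-replaceable via `read_recognition_code()`. Because the numeric
PWM behind the published logo is not recoverable from printed
material, the package also ships `mamo_pwm()` — a width-9 PWM built
from the printed consensus at 0.97 per-column probability — so all
downstream stages have a fixture anchored to the printed site and
independent of the code table.

## Scanning statistics

`scan_pwm()` is a FIMO-style scanner. Probabilities and the background
are both pseudocount-adjusted, `p' = (p + c)/(1 + 4c)` with `c = 0.25`
by default, before log2-odds scoring; this avoids infinite scores and
mirrors common scanner practice. The background model is 0-order and,
by default, estimated from the scanned sequence set (uniform
fallback); a fixed vector can be supplied, which is what the simulated
tests do (the generating background is known) and what the worked
example does for the printed site (the silkworm genome is AT-rich,
GC ≈ 0.375, and a 9-bp query carries too little sequence to estimate
its own background). Windows containing N are skipped, never scored.

P-values are exact: the null score distribution of a random width-W
word under the background is built by dynamic-programming convolution
of the per-column score distributions. Scores equal to within 1e−9
bits are merged, so the support is the exact set of achievable scores
for any motif of practical width (at most 4^W values; a coarsening to
`granularity` bins per column only engages beyond 5×10^5 support
values). The resulting p-value function is right-continuous,
non-increasing, and equals exhaustive enumeration to 1e−12 — a
property the test suite checks against an independent enumerator for
widths up to 6 under arbitrary backgrounds. One consequence of exact
discrete p-values is worth noting: for a near-consensus motif the null
is coarse (scores essentially count mismatches), so the largest
achievable p-value below a nominal threshold can be much smaller than
the threshold itself; calibration statements of the form "false-positive
count ≈ 2·L·p" are meaningful only for motifs whose null is
fine-grained, and the calibration test uses such a motif. Default
reporting threshold is p ≤ 1e−4, the common FIMO default. Hits carry
Benjamini–Hochberg q-values computed over all scanned windows
(`bh_fdr()` wraps `stats::p.adjust`).

Both strands are scanned by default; minus-strand hits are reported in
forward coordinates at the leftmost base, with `matched_seq` giving
the hit's own strand. Scanning the reverse complement of a sequence
yields the mirrored hit set — a property test.

## Flanks, ORFs and target nomination

Gene models come from GFF3 `gene` records (1-based inclusive),
converted internally to 0-based half-open intervals; malformed records
are skipped with a per-line warning rather than aborting a whole
annotation. "2-kb upstream and downstream" is interpreted relative to
the annotated gene span, not per-transcript TSSs, because the screen
operates on predicted gene loci; flanks are not trimmed where they
overlap neighbouring genes, matching a per-gene site-presence
analysis. Minus-strand flank sequences are reverse-complemented so
they read 5′→3′ relative to the gene; intervals are clipped at contig
edges and flagged `truncated`.

`longest_orf()` searches the three forward frames for ATG-initiated,
stop-terminated reading frames (length includes the stop codon, ties
to the smallest start), the convention under which the two deposited
mamo transcripts have 2397- and 1824-bp ORFs. The deposited mRNAs
themselves are a network download, so the offline suite verifies the
operation against an exhaustive per-ATG enumerator on random
sequences and on synthetic transcripts carrying maximal ORFs of
exactly those lengths; a user with the GenBank FASTA can run
`longest_orf()` on it directly.

A gene is nominated by `nominate_targets()` iff it has ≥ 1 flank hit
and is a significant DEG. The DEG thresholds default to |log2FC| ≥ 1
and FDR ≤ 0.05 — the screen's own defaults, configurable, since the
thresholds behind the published 191-gene table live in a prior study.
Genes absent from the DEG table are carried but never nominated
(conservative). Nomination is exactly the intersection of the two
gene sets and is monotone in both thresholds; both are property
tests.

## Selection scan

Nucleotide diversity is the sum over window sites of the unbiased
per-site heterozygosity `2·p̂·q̂·n/(n−1)` divided by the window length
in bp, with missing calls excluded per site. F~ST~ is Hudson's
estimator as a ratio of averages, `1 − mean(H_w)/mean(H_b)`, with
`H_w` the mean of the two unbiased within-population heterozygosities
and `H_b = p̂_A(1−p̂_B) + p̂_B(1−p̂_A)`; sites monomorphic in both
populations are excluded. Hudson's form was chosen over
Weir–Cockerham for its robustness to the very unequal panel sizes of
the motivating data (51 wild vs 171 domestic haplotypes); the
published analysis names no estimator. Because `H_w` is unbiased while
two samples that happen to share identical frequencies still differ by
the `n/(n−1)` factor, single-window estimates can be slightly negative
under the null — the estimator's known behaviour, bounded in tests at
−0.1.

Windows tile the region at a default 5-kb window and 1-kb step — the
published figure resolves a roughly 1-kb upstream signal, so the step
must be ≤ 1 kb; both are exposed. Empty windows carry `n_sites = 0`
with absent statistics, distinct from monomorphic windows with π = 0.
Outliers are called at the empirical top quantile (default top 5%)
using the type-7 linear-interpolation quantile.

## qPCR

Relative expression uses the classical `R = 2^−ΔΔCt` with a reference
gene (RpL3 in the motivating assays) and a calibrator group.
Technical replicates are averaged per (sample, gene); significance is
tested on the ΔCt scale, which is approximately normal, rather than on
fold changes — standard ΔΔCt practice; the source protocol does not
state the tested scale. The default is the equal-variance Student's t
test (that is the test the figure legends name), with Welch and paired
variants available; the paired mode pairs samples by sorted id and
reduces to the textbook mean/SEM-of-differences statistic. Degenerate
noise-free inputs are handled explicitly: identical ΔCt sets give
t = 0, p = 1.

## Phylogeny

`p_distance()` computes protein p-distances with pairwise gap deletion
(columns with a gap or X in either sequence of a pair are dropped for
that pair only — retains more signal than complete deletion), with the
Poisson correction `−ln(1 − p)` applied by default. The published
methods name a "Pearson model", which does not exist in MEGA7's
distance menu; the package reads it as the Poisson amino-acid model
and leaves `correction = "none"` available.

`neighbor_joining()` is the classical Saitou–Nei algorithm with two
determinism guarantees the generic library implementations do not
make: Q-criterion ties break to the smallest index pair in the current
ordering, and a negative limb is clamped to 0 with its deficit moved
to the sibling limb, preserving path lengths through the new node. On
additive matrices NJ provably recovers the generating tree; the suite
checks topology and all path lengths on random additive matrices, and
cross-checks topologies against `ape::nj` on noisy ones. Bootstrap
support resamples alignment columns with replacement; replicate r
draws from a substream seeded `seed + r`, so supports are reproducible
bit-for-bit and invariant to taxon input order (taxa are sorted before
resampling). The motivating analysis used 2000 replicates, the
default here.

## What the simulators emulate — and what they do not

Every generator is a pure function of its parameters and seed, and
emits its truth table so tests never re-derive ground truth.

* `simulate_genome()` plants one binding site per designated true
  target at a uniform offset in a random 2-kb flank (avoiding the
  outer 10 bp so no site is clipped), on a random strand, in i.i.d.
  background sequence (default GC 0.5, configurable). Defaults — 20
  genes, 200-kb contig, 7 true targets, exact-consensus planting —
  are the toy-scale stand-in for the genome-wide screen. The
  background has no repeats, composition heterogeneity or chromatin
  structure, so passing recovery tests show correctness of the
  scan-and-intersect logic, not robustness to genomic artefacts.
* `simulate_deg_table()` draws per-group replicate means (default 3
  replicates, 0.2 log2-units noise, 3 log2-units effect) and computes
  t-test p-values with BH correction. It models no count overdispersion
  or normalization error.
* `simulate_haplotypes()` uses the motivating panel sizes (51 vs 171
  haplotypes) over a 100-kb region at 2 SNPs/kb, with shared
  background frequencies and a planted 10-kb window in which the two
  population frequencies are separated by `divergence_level` (default
  0.8; 1 gives fixed differences). Divergence is planted, not
  evolved: there is no coalescent, recombination or demography, so
  the recovery property speaks to the window statistics, not to
  detecting real selective sweeps.
* `simulate_ct_table()` gives the reference gene a constant mean Ct,
  shifts targets by −log2(fold change) and adds independent Gaussian
  measurement noise (default 0.1 cycles, triplicate measurements,
  3 samples per group — the scale of the motivating assays).

## Numerical choices and degenerate inputs

* Score merging at 1e−9 bits; scanned window scores are rounded the
  same way before p-value lookup, so scanner and null agree.
* Pseudocount 0 with any zero probability raises an invalid-
  configuration error instead of producing infinite scores.
* Consensus ties break alphabetically (A < C < G < T).
* Empty hit lists, empty windows, saturated protein distances
  (p ≥ 1 under Poisson), fewer than 3 taxa, and < 2 replicates per
  group are all explicit, tested edge cases.
* Test and acceptance problem sizes: 200-kb simulated contigs,
  100 popgen replicates of 222 haplotypes × ~200 sites, exhaustive
  enumeration up to 4^9 words, 1000-sequence ORF oracle runs — sizes
  chosen so the full suite exercises every oracle in a few minutes on
  one CPU.

## Known limitations

* The genome-wide counts of the motivating study (14,623 annotated
  genes, 10,622 genes with flank sites, 191 DEGs, 18 cuticular-protein
  targets, the chromosome-9 diversity curves) depend on the external
  genome assembly, resequencing panel, transcriptome and unstated tool
  settings; they are context, not desk-scale test targets. The
  property and recovery suite stands in for them.
* The recognition code is a coarse canonical table, not a trained
  model; predictions for fingers outside its residue coverage fall
  back to uniform columns with a warning.
* The scanner's 0-order background cannot model CpG islands or other
  local composition structure.
* Only biallelic SNPs enter the selection scan; multi-allelic VCF
  records are skipped with a warning, and genotypes are treated as
  allele counts (no phasing).
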