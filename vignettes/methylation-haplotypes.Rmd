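---
title: "Methylation haplotypes of homologous chromosomes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation haplotypes of homologous chromosomes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methaplotype)
```

## The problem

Whole-genome bisulfite sequencing (WGBS) reports, for every cytosine on
every read, whether it was methylated. Standard analyses collapse this to a
per-site methylation level, averaging reads from the two homologous
chromosomes. When the homologs disagree — X inactivation in females,
imprinting, allele-specific methylation, epigenetic mosaicism in tumours —
the average hides the structure: a site that is 100% methylated on one
homolog and 0% on the other looks identical to a site that is 50%
methylated on both.

This package reconstructs the *pair* of methylation haplotypes — one 0/1
string per homolog over the CpG sites of a small region — using only the
co-occurrence of methylation statuses on individual reads. No SNPs are
needed: the phasing signal is methylation heterozygosity itself. Each
reconstructed pair is summarised by a coarse *methylation haplotype mode*
(MHM), and modes are compared across samples to call differentially
methylated regions (DMRs) at haplotype resolution.

## Candidate regions

Reads are short and CpGs unevenly spaced, so complete chromosome-scale
haplotypes are unattainable; instead the method works on CpG-dense
candidate regions defined from the genome alone (sample-independent):

* **CpG islands** are split into `floor(n / 7)` consecutive blocks of
  near-equal size (each with at least 7 CpGs), so that long islands do not
  average away local signal. The annotation itself is consumed as given
  (BED); no island prediction is done.
* **Dense CpG clusters outside islands**: maximal runs of CpGs whose
  neighbor distances (between the C coordinates) are at most 20 bp, kept
  when they hold at least 7 CpGs. Runs longer than 14 CpGs are split like
  islands, which keeps the region-length distribution near the ~90 bp
  typical of the island-derived blocks.

The balanced-block splitting scheme is a design choice: any partition into
consecutive blocks of at least 7 CpGs would satisfy the definition, and the
balanced one yields per-region CpG counts in the 7–13 range, matching the
~10.5 CpGs per region typical of genome-wide annotation. Coordinates are
0-based half-open (BED convention) throughout, with a region spanning its
first to last CpG dinucleotide.

## From reads to site classes

Per-read CpG calls come from Bismark-style `XM` tags (`Z`/`z` in CpG
context), mapped through the CIGAR to reference coordinates, or from a
plain TSV (`read_id`, `chrom`, `cpg_position`, `status`). Two policies are
deliberate:

* **Strand collapsing.** Evidence from either strand of a CpG (the C at
  position p, the G at p + 1) is merged into one site. Hemimethylation is
  out of scope; a CpG is treated as one unit per homolog.
* **Mate overlap.** When both mates of a pair report the same CpG, the
  first encountered call wins and disagreements are counted (the
  `n_conflicts` field), never double-counted as depth — double counting
  would distort the depth threshold below.

Each site in a region is then classified. With depth threshold `th_dp`
(default 10):

* depth < `th_dp`: **filtered** (uncovered);
* one status only: **homozygous** for it;
* both statuses, each with at least `th_dp / 2` observations: **candidate
  heterozygous site (CHS)**;
* both statuses but the minority below `th_dp / 2`: **homozygous** for the
  majority — the minority is attributed to sequencing error or incomplete
  bisulfite conversion. This resolution of the two-status/low-minority case
  is a package decision; it treats the minority exactly like the noise that
  motivates the CHS rule. The default `th_dp = 10` makes the CHS rule
  demand at least 5 reads per status, ordinary WGBS practice.

A CHS can still be a false positive. The discriminating evidence is
*joint*: over reads covering two neighboring CHSs, the ordered status
patterns 00/01/10/11 are counted. Patterns seen fewer than twice are
dropped; then

* if a unique top pattern holds more than 0.6 of the surviving total, it is
  the single true pattern (both sites homozygous along it);
* otherwise, if an identifiable top pair exists and the second/first
  frequency ratio is at least 0.4, both are true patterns;
* otherwise — including three-way ties for the maximum and ties for second
  place, where the rules presuppose an identifiable top one or two — the
  pair is ambiguous.

The boundary semantics (strict `>` for 0.6, `>=` for 0.4) follow the rule
statements. A site is heterozygous iff both statuses appear at its position
across the true patterns.

Successive CHS pairs share a middle site, and unbalanced joint depths can
make the two pairs disagree about it. The conflict is resolved by a
confidence score: the total true-pattern frequency of a pair divided by the
maximum depth among the three sites of the conflict. The sweep is strictly
left to right; the earlier pair wins ties, and a revised middle site does
not trigger re-evaluation of the pair before it (no back-propagation —
the sweep is deterministic and single-pass). At a region's first pair there
is no third site yet, and the denominator uses the two sites available.
Isolated CHSs, with no neighbor to corroborate them, stay ambiguous.

## Haplotype pairs, modes and consistency

Final heterozygous sites are chained into two complementary *skeletons*.
The phase link between neighboring heterozygous sites is decided by
majority between the same-status pattern mass (f(00) + f(11)) and the
cross-status mass (f(01) + f(10)) on co-covering reads — a deliberately
robust reduction: when a region is genuinely heterozygous both linking
patterns are frequent, and a majority vote survives undersampling of one
pattern better than re-running the 0.6/0.4 selection would. Ties and
uncovered pairs break the chain; the longest prefix chain is kept and the
remaining heterozygous sites become uncovered. Homolog naming is arbitrary
but deterministic (haplotype 1 carries status 0 at the first chained site);
every downstream quantity is invariant under swapping the homologs.

Homozygous sites are padded into both strings. Filtered and ambiguous sites
are simply *uncovered* — excluded from the strings rather than encoded as a
third symbol — so the methylation level of a haplotype,
`MH(s) = (number of 1s) / len(s)`, is always computed over covered sites
only. A pair covering more than 3 CpGs is a *valid methylation haplotype*
(VMH); smaller fragments are too short to label meaningfully.

Each string gets a label from its MH level: `L` (MH <= 0.25), `N`
(<= 0.5), `M` (<= 0.75), `H` (otherwise), boundaries inclusive downward.
The unordered label pair is the region's MHM, written with the higher-MH
label first (`HL`, `NL`, ...); since the label is a function of MH, equal
levels give equal labels and the ordering is well defined.

*Methylation consistency* is the CpG-weighted fraction of valid pairs whose
MHM is `HH` or `LL` — both homologs simultaneously hyper- or
hypomethylated; *hypomethylation consistency* counts `LL` only, so it can
never exceed the former. CpG weighting (each pair contributes its covered
CpG count) follows from defining the ratio over CpGs in VMHs rather than
over regions. On autosomes of normal cells most regions are consistent;
a female X chromosome, with one inactive hypermethylated homolog, drives
consistency down — the simulator's `x_inactivation` scenario reproduces
this contrast exactly.

## DMRs at haplotype resolution

For a region with valid pairs in two samples (or groups; multi-sample
groups average the higher- and lower-MH levels across their samples):

* identical MHMs make the region a non-DMR outright, with no test;
* otherwise the *methylation haplotype difference* is
  `MHD = max(|hi_i - hi_j|, |lo_i - lo_j|)` — higher-MH haplotype aligned
  with higher, lower with lower. When the two levels tie within a group
  either alignment gives the same value. Among more than two groups the
  region's difference is the maximum pairwise MHD.
* a region is a DMR iff `MHD > 0.5` and `p < 0.05`.

The significance procedure is a package design decision: a read-label
permutation test. Reads of the two samples are pooled and reassigned to
pseudo-samples of the original sizes; each permutation rebuilds both
haplotype pairs from scratch and recomputes the MHD; the p-value is
`(1 + #{perm MHD >= observed}) / (1 + n_perm)` with `n_perm = 200` by
default. Permutation respects the haplotype-level statistic being tested —
under the null of no sample difference, mixing reads reconstructs the same
pooled pair structure and permuted MHDs collapse toward 0. Permutations
whose pseudo-samples yield no valid pair contribute MHD 0 (no evidence of
difference) and are counted. Because the DMR rule conjoins both thresholds,
the test is run only for regions passing the MHD gate; regions below it are
reported untested (`p = NA`) and are non-DMRs either way. Raw p-values are
compared with 0.05 by default; an optional Benjamini–Hochberg flag
(`bh_fdr = TRUE`) is provided for users who want FDR control across many
regions.

DMRs are classified by their mode pair, with precedence 1 > 2 > 3 > 4 to
make the typing total (e.g. `HL` vs `HH` surface-matches both rule 1 and
rule 3 and is Type 1):

1. hypomethylation mode (MHM containing `L`) vs. non-hypomethylation mode;
2. consistent `LL` vs. an inconsistent mode containing `L`;
3. consistent `HH` vs. an inconsistent mode containing `H`;
4. any other differing pair.

The subtype string (`"LL vs HH"`, `"HL vs HH"`, ...) records the ordered
mode pair and exposes the direction of methylation change of each homolog.

## The simulator

`make_scenario()` + `emit_reads()` generate paired-homolog call data with
known truth. Defaults are the package's study conditions, chosen once:
regions of 7–13 CpGs (gaps of 2–18 bp), read depth 30 per homolog, per-call
error rate 0.01, and reads spanning the whole region — realistic because
candidate regions average ~90 bp, shorter than a WGBS read. Reads are
simulated at the CpG-call level (with an optional SAM rendering carrying
XM-style tags) because the pipeline consumes calls; nucleotide-level
realism would add nothing testable. Each region receives exactly `depth`
reads per homolog, in random order: balanced per-homolog depth is the
stated condition of the validation scenarios, and it matters — see the
limitations below.

Scenario kinds map to the phenomena of interest: `consistent` (identical
homologs, all-hypo or all-hyper per region), `x_inactivation` (one homolog
fully methylated, the other fully unmethylated — mode `HL` everywhere),
`differentiation_shift` (identical homologs with per-CpG Bernoulli
methylation, i.e. partially methylated but consistent regions),
`cancer_like` (a 30% fraction of fully heterozygous, allele-specific
regions with random complementary templates, mixed with consistent ones),
and `dmr_panel` (two samples; 20% of regions planted as `LL` vs `HH` with
MHD 1).

What the simulator does **not** emulate: partially heterozygous regions
(single discordant CpGs inside an otherwise concordant region), depth
variation along a region, PCR duplicates, mapping error, bisulfite
non-conversion beyond the symmetric flip rate, and read pairs. Passing the
planted-truth validations therefore shows the machinery is correct under
the model's own assumptions; it does not certify recall on real data, where
isolated heterozygous CpGs (which have no corroborating CHS neighbor and
stay ambiguous by design) and uneven coverage will lower it.

## Validation sizes and numerical choices

The test-suite and acceptance-script problem sizes are the package's
chosen validation conditions: 200 regions per single-sample scenario and a
500-region panel with 100 planted DMRs at 200 permutations — large enough
for stable rates, small enough to run in minutes on one core. All
randomness is seed-pinned; every command-line run with a fixed seed is
byte-reproducible. Permutation seeds are derived per region from the base
seed by fixed offsets, so region results are independent of processing
order.

Degenerate inputs are defined rather than erroneous: an empty genome or a
region with no reads yields empty catalogs/pairs; a region with no
heterozygous sites yields two identical strings; zero valid pairs make the
consistency ratio NA ("missing"), not 0; all-zero depths give confidence 0
with a warning.

## Known limitations

* **Homolog sampling skew.** The 0.6 single-pattern rule reads a >60/40
  read imbalance between homologs at a heterozygous pair as a single true
  pattern. Under binomial homolog sampling at total depth 60 this happens
  in roughly 9% of regions, collapsing them to homozygous. This is a
  property of the ratio thresholds, not of the implementation; it is why
  the simulator fixes per-homolog depth.
* **Prefix-chain policy.** When a phase link breaks, the chain after the
  break is discarded even if longer than the prefix.
* Isolated heterozygous CpGs are systematically unphaseable and end up
  uncovered; regions dominated by them will rarely form VMHs.
* Haplotypes are not linked across regions, and homolog identity is not
  assigned to parental origin.
* The permutation test conditions on the observed read set; with very few
  reads it is conservative (reported with a flag).
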