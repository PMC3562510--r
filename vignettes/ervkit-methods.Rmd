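---
title: "ervkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ervkit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters with their
defaults and rationale, what the synthetic-data generator does and does
not emulate, the numerical conventions, and the design choices that were
genuinely open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The biological setting

A murine leukemia virus-type endogenous retrovirus (MuLV-ERV) is the
integrated DNA form of an ancient retroviral infection: two long terminal
repeats (LTRs) flanking gag, pol and env coding regions. The LTRs are
created identical by reverse transcription, so sequence differences
between the two copies of one provirus accumulate only after integration
— terminal-LTR identity is therefore a usable signal of provirus
integrity, and a lone LTR (the relic of LTR–LTR recombination) must never
be reported as a provirus. The U3 region of the 5' LTR is the proviral
promoter; its direct-repeat architecture (repeats 1/1\*, 4/4\*, 5/5\*,
6/6\*, a unique region 2, the TATA box, and an optional 190-nt enhancer
insertion) differs between xenotropic and polytropic host-range classes,
which is what makes a feature profile of U3 informative about tropism.
The 18 nt immediately downstream of the 5' LTR form the primer binding
site (PBS), complementary to the tRNA that primes reverse transcription
(glutamine or proline tRNA for the elements handled here).

## The synthetic-data generator

Everything downstream is exercised on data from `synthdata`, so its
defaults define the study conditions.

**Genomes.** Background sequence is i.i.d. uniform A/C/G/T — no claim
about mouse genome composition is tested, so none is modelled. Each
planted provirus is `LTR + PBS(18 nt) + leader(60 nt) + gag + spacer(15)
+ pol + spacer(15) + env + padding + LTR`, with the LTR drawn from one of
seven founder U3 templates (346–615 nt, below) and coordinates recorded
1-based inclusive so that `size = end − start + 1` holds row by row; the
BED export converts to 0-based half-open. Minus-strand proviruses are
stored as the reverse complement with the strand recorded in the truth
table.

**Gene cassette.** Reference peptide lengths default to the canonical
full-length MuLV polyproteins (gag 538 aa, pol 1196 aa, env 665 aa).
Partial and defective genes are modelled by planted premature stop
codons — one stop at 50% of the peptide for "partial", stops every 10%
for "defective" — which preserves cassette length and keeps the gene
windows at fixed offsets. A consequence is that default planted provirus
sizes fall in roughly 8.0–9.1 kb, the dominant size class of real
full-cassette MuLV-ERVs; loci shortened by large internal deletions
(down to ~5.3 kb in real data) are represented in the bundled coordinate
table rather than by the generator, whose deletion-free geometry is what
makes zero-noise recovery exactly checkable. `provirus_length_range`
remains configurable.

**Founder U3 templates.** The seven class templates (615, 556, 440, 433,
392, 361, 346 nt) are built from the bundled feature library so that each
carries its branch's repeat/unique/insertion copy layout by construction,
with fixed pseudo-random filler. The real repeat and insertion sequences
are defined in the literature the decision table derives from but are not
printed here, so the bundled library is an explicitly synthetic stand-in
(`u3_features_synthetic.tsv`) and user-replaceable; the same applies to
the tRNA-Gln PBS entry (the tRNA-Pro entry uses the canonical MoMLV
sequence). Tests are closed-loop: the simulator and the annotator share
the library, so passing feature-recovery tests show the machinery is
correct, not that the shipped sequences are the biological ones.

**Clone libraries.** Clones are founders plus per-base substitution
errors. The default library has 260 clones in six condition × cell-type
groups, with `clone_error_rate = 0.001`/bp chosen so that the expected
unique count after exact deduplication is ~100 at U3 lengths of
346–615 nt (at 0.004/bp nearly every clone would carry an error and
~220 uniques would survive, which contradicts the 260 → 100 collapse the
library is meant to emulate). Burn-24h groups draw from 2–3 founders with
skewed weights versus 4–8 founders elsewhere, and B-cell groups draw from
fewer founders than T-cell groups; these choices produce the diversity
orderings the statistics are tested against (lower π at burn-24h, B less
diverse than T). Per-condition clone counts are not constrained by
anything quantitative, so the 260 total is split 90/90/80.

What the generator deliberately does **not** emulate: real repeat
landscapes, recombination, indel errors, within-LTR divergence structure,
or any phylogenetic signal beyond the founder classes. Passing tests
therefore demonstrate algorithmic correctness on data with the assumed
structure, not performance on real genomes.

## U3 analysis

**Deduplication** is exact string identity after uppercasing.
Near-duplicates are kept apart on purpose: single-base differences among
clones are the diversity signal measured downstream, and collapsing them
would bias π toward zero.

**Grouping** replaces a specific alignment+tree program with k-mer count
distances (Euclidean, k = 6) and average-linkage clustering cut at
k = 7 groups, labelled I…VII by descending median length. The claim being
reproduced is size-driven seven-way branching, not a particular tree
topology, and k-mer distances make group membership a deterministic,
order-invariant function of the sequence multiset. The dendrogram is
still exported as newick for inspection.

**Feature annotation** counts non-overlapping ungapped matches of each
library query at identity ≥ 0.85 (greedy left-to-right selection, copy
number capped at 2). The threshold is permissive enough to tolerate the
simulator's clone errors on 20–30-nt repeats (one mismatch) yet strict
enough that random filler essentially never matches.

**Tropism** is a lookup against the seven reference branch profiles.
Two reference branches share an identical feature profile while carrying
different sub-class calls, so exact-match ties are broken by nearest
reference U3 size when the caller supplies a length, and abstain
otherwise; no rule for sub-class I vs II is invented. Profiles without an
exact match use the nearest reference at Hamming distance 1 when it is
unique; anything farther, tied, or inconsistent with the 190-nt insertion
(the P/X discriminator) returns `none` — abstention is the documented
behaviour for unclassifiable branches, not a failure mode.

## Diversity statistics

Groups are aligned progressively: guide tree from k-mer distances,
profile–profile global alignment with sum-of-pairs scoring (match +1,
mismatch −1, residue-vs-gap −2, gap-gap 0; ties prefer the diagonal).
For two sequences this is an optimal Needleman–Wunsch alignment under the
same scoring, which is what the oracle tests check. Identical sequences
are collapsed before alignment and re-expanded after, so clone
multiplicities weight the statistics (the default analysis uses all
clones, not unique sequences — an `unique_only` switch provides the other
reading).

Statistics use complete deletion: any column containing a gap or
ambiguous base is removed before counting, so an all-gap column can never
change a result. With n sequences, L retained sites, S segregating sites
and Π the mean pairwise difference count: π = Π/L, θ_W = S/(a₁L), and
Tajima's D = (Π − S/a₁)/√(e₁S + e₂S(S−1)) with the standard
a₁,a₂,b₁,b₂,c₁,c₂,e₁,e₂ constants. Π enters D as a total, not per site.
At S = 0, D is reported as `NA` rather than 0 — no neutrality score is
fabricated for an invariant sample. No Jukes–Cantor correction is
applied: the quantities compared are orderings and oracle equalities, and
raw difference counts are the simplest defensible reading of "nucleotide
diversity" here.

## Motif scanning

Weight-matrix scanners are proprietary where this motif library
originates, but the library itself prints consensus strings with a marked
core — exactly enough information for consensus scanning. A window is a
hit when every core position matches its IUPAC letter exactly and the
overall position-wise match fraction is ≥ `min_similarity` (default
0.75); both strands are scanned and positions are reported on forward
coordinates, non-redundantly per (motif, position, strand). The
occurrence table defaults to counting total hits (printed occurrence
totals exceed the number of sequences, so presence-per-sequence cannot be
what such totals mean), with a `count = "sequences"` mode whose column
sums can never exceed group sizes.

## Provirus mining

BLAST is replaced by an internal seed-and-extend scanner so that the
98%-identity semantics are explicit: exact 11-mer seeds sampled every
4 nt (plus the final offset) locate candidates, seed diagonals within
30 bp cluster into one candidate, and the full probe is then aligned
global-local (probe global) against the candidate window ±15 bp.
Identity is aligned matches / probe length; a hit must also span ≥ 90%
of the probe (near-full-LTR promoter probes make partial hits a source of
false pairs, so they are excluded). Overlapping hits keep the best
identity with leftmost/probe-order tie-breaks.

Pairing accepts same-chromosome, same-strand hit pairs whose outer span
lies in 5–12 kb, resolved greedily by mean identity with deterministic
leftmost tie-break and each hit used once. The locus span is the outer
span of the two LTR hits — provirus sizes include both LTRs. PBS typing
tolerates 1 mismatch in 18 (single-substitution drift is common in
ERVs; configurable). ORF integrity thresholds — intact ≥ 95% of the
reference peptide, partial 30–95%, defective below — are package
conventions for the printed `+`/`P`/`−` classes, configurable in the
reference model. Probe provenance tags condense the metadata of the
probes that located a locus: `U/U` (both conditions / both cell types)
through `B/B` (burn-only, B-cell-only).

## Neighbor genes

Genes within 100 kb (nearest-edge distance, 0 when overlapping — the
source convention does not define the measure, so it is documented here)
are reported per locus. A locus wholly inside a gene span that touches no
exon is `intronic`; touching an exon is `exonic_overlap`; otherwise
upstream/downstream is resolved relative to the provirus strand by
default (the retroviral convention), with a forward-coordinates switch.
Both unique (locus, gene) pairs and unique genes are countable from the
output, since it is not specified whether a published gene total would
deduplicate genes shared by two loci.

## Densitometry and purity

Relative intensity is band density / beta-actin density per lane; fold
change is the ratio of arm means and significance a two-sided two-sample
Student's t-test on relative intensities across the four experiments
(equal-variance by default — "Student's t-test" is read classically —
with a Welch switch, and an alternative mode that tests per-experiment
fold ratios against 1, since which variant was used is not stated).
Degenerate cases follow fixed conventions: equal zero-variance arms give
p = 1, differing zero-variance arms p = 0, and a zero control mean leaves
the fold undefined and flagged. Purity assumes a two-population mixture
with exclusive markers: purity_B = CD20/(CD20+Thy1), so the B and T
purities sum to exactly 1 by construction; marker levels come from
ΔCt quantification `efficiency^−(Ct_target − Ct_actin)` with efficiency
2 by default (configurable, as the amplification math is not otherwise
pinned down).

## Problem sizes and determinism

The test suite runs entirely on simulated data sized for interactive use:
planted-recovery checks use a 2 Mb genome with 10 proviruses plus solo-LTR
decoys; diversity-oracle checks enumerate alignments up to n = 6, L = 20
over 200 seeds; the motif-scan oracle covers 100 random 2-kb sequences
against the full 28-motif library; neighbor-gene oracles use 20 random
layouts. Every stochastic step is seeded, and the pipeline manifest
records seed, version and md5 checksums — reruns under one seed are
bit-identical. The spec-style command-line entry point is intentionally
absent: the package's functions and `run_pipeline()` are the interface.

## Known limitations

* Feature and PBS default sequences are synthetic stand-ins; results on
  real data require curated libraries.
* The miner's ungapped seeding tolerates substitutions well but large
  indels inside an LTR can split a hit below the coverage threshold.
* ORF classification assumes the cassette geometry of the reference
  model; exotic rearrangements would need a permissive model.
* Tajima's D is reported as a score, not a test — no significance
  thresholds are attached.

## A minimal session

```{r example}
library(ervkit)
cfg    <- synthetic_config(seed = 1)
clones <- build_clone_library(cfg)
uniq   <- dedup(clones)$unique
branches <- group_u3(uniq, k = 7)
profile  <- annotate_features(uniq[1, ], cfg$feature_library)
call_tropism(profile, u3_length = uniq$length[1])
compare_groups(diversity_by_group(clones, "condition"))

sim    <- build_genome(cfg)
probes <- u3_records(names(cfg$founder_templates),
                     unname(cfg$founder_templates))
report <- mine(sim$genome, probes, pbs_library = cfg$pbs_library,
               reference_model = cfg$reference_model)
ann <- build_gene_annotation(sim$truth, cfg$chrom_length, seed = 2)
neighbors(report, ann)
```
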