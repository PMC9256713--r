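---
title: "Characterizing transgene integration from paired-end WGS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing transgene integration from paired-end WGS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdnaseek)
```

This vignette explains the models and procedures behind `tdnaseek`, the
assumptions they rest on, the parameters that matter, and the design
decisions taken where the problem is genuinely open. It states no
empirical result that the package's test suite and acceptance script do
not themselves compute.

## The problem

A transformation event inserts one or more copies of a vector's T-DNA
into the host genome, usually with a small host deletion at the
breakpoint, sometimes with plasmid backbone dragged along. Paired-end
WGS sees the event as *chimeric read pairs*: fragments straddling a
junction leave one end mapping to the host and the other to the
plasmid. Two complications make naive chimeric-pair counting fail:

* **Host homology in the construct.** Modern constructs carry native
  promoters and RNAi cassettes targeting endogenous genes. Fragments
  from those *native* loci also produce host+plasmid pairs — in real
  data they outnumber true junction pairs several-fold — and in a
  cisgenic event the entire insert is host-derived.
* **Sporadic noise.** Library chimeras, contamination and alignment
  jitter produce isolated host–plasmid pairs scattered over the genome.

The pipeline answers both with an explicit homology blacklist and a
depth-proportional support filter, then reads the event structure off
assembled junctions plus calibrated depth.

## Read mapping

Reads are placed by exact 31-mer seeding at three offsets per strand
(start, middle, end) with full-length ungapped extension; a read maps if
its best placement has at most a 10% mismatch fraction. Two consequences
are intentional:

* Reads containing an indel or a junction fail to map. Junctions are
  recovered by assembly, not CIGAR parsing, so gapped alignment buys
  nothing here; the unmapped junction reads are recollected later via
  their mapped mates.
* With at most two substitution errors a read always retains one intact
  seed, which is why the mapper provably agrees with an exhaustive
  aligner on such reads (a property the test suite checks against a
  brute-force oracle).

Equal-best placements are all reported (`unique = FALSE`). The *primary*
placement prefers a plasmid reference over a host reference. This
tie-break is load-bearing for copy number: reads from sequence present
both in the construct and in the genome accumulate on the plasmid copy
in both the event sample and the control, so the wild-type subtraction
(below) removes the homologous contribution exactly. A random tie split
would halve those depths and break the subtraction's structure.

## Homology blacklist

A word-seeded (16-mer), ungapped X-drop extension search — BLAST-like,
both plasmid strands, the plasmid treated as circular — finds
plasmid↔host homologous blocks with at least 90% identity over at least
50 bp. Defaults are chosen so that any 100 bp read from a homologous
element necessarily lies within a detected block. Each block is expanded
by the `margin` (default 500 bp = the library insert size) on both
sides: every physical fragment end of a native-sequence pair must fall
within one insert of the homologous segment, so the expanded interval
catches all of them.

Filtering is applied to the **host side** of each chimeric pair: a pair
is discarded when its host end's footprint overlaps a blacklisted host
interval. A stricter both-sides mode (`blacklist_side = "both"`) exists
but is not the default, because it is structurally incompatible with
cisgenic events — there the whole donor is plasmid-side homologous and
both-side filtering would remove the true junction pairs at the new
locus along with the background. Host-side filtering removes the same
native-locus pairs (their host ends are always within one insert of the
homologous segment) while keeping junction pairs at any locus away from
the homology blocks.

## Candidate clusters and noise suppression

Kept chimeric pairs are clustered per chromosome by single linkage with
a 500 bp gap — the insert size, which is the physical scale over which
junction-spanning fragments spread. Clusters are *not* split by junction
side: for a head-to-head event both flanks present the same plasmid
element, so side-splitting on plasmid position is unreliable; both
junctions of one event merge into a single cluster and are separated
later by the split-aligner.

A cluster survives if its support is at least `max(3, 0.1 × D)` pairs
(`D` = genome sequencing depth) with at least 3 members whose host end
maps uniquely. True junctions accumulate roughly
`D × (insert − read)/read` pairs; one- and two-pair clusters at ~29× are
noise. A consistency check then rejects clusters whose members cannot
describe one physical junction: host-end spread beyond 3 inserts,
forward/reverse geometry violations, per-flank plasmid-side scatter, or
no uniquely mapped member at all.

## Junction assembly and the split-aligner

The assembly read set is the members' both ends plus the unmapped mates
of `one_unmapped` pairs whose mapped end lies near the cluster (host
side) or near a T-DNA terminus (plasmid side) — those unmapped mates are
exactly the reads that physically contain the junction. A deterministic
greedy overlap-layout assembler merges the pair with the longest
suffix–prefix overlap (≥ 30 bp at ≥ 95% identity, both orientations)
first, breaking ties by the lexicographically smallest merged sequence.

Each contig is split-aligned: candidate host and plasmid diagonals come
from shared 16-mers; for every breakpoint position the score is the best
host prefix-match count plus the best plasmid suffix-match count (and
the mirrored form for 3′ flanks), with per-side maxima over diagonals so
a haplotype indel away from the junction cannot drag the breakpoint. A
call requires 30 anchored bases at ≥ 90% identity immediately on each
side, and must beat the best *single-reference* explanation of the
contig — which is what prevents pure cisgene-donor contigs (host- and
plasmid-identical) from fabricating junctions.

Two tie-breaks deserve note:

* **Micro-homology.** When the bases at the junction match both
  references, every split inside the shared run scores identically.
  Among exact ties the caller prefers the split whose plasmid-side
  breakpoint lies exactly on a T-DNA terminus — integration proceeds
  from the borders, so that is the correct biological prior — then the
  maximal-host split. This makes locus recovery exact rather than
  off-by-microhomology.
* **Voting.** Junction calls are pooled from merged contigs *and* from
  each raw junction-spanning read (capped at 60), and the per-flank
  breakpoint is the modal value. A single sequencing error adjacent to
  the breakpoint in one contig is outvoted by the independent reads.

With 5′-flank breakpoint `L` (0-based exclusive end of retained host)
and 3′-flank breakpoint `R` (first resumed host base), the reported
locus is `L` as a 1-based coordinate of the last retained host base, and
the deletion is `R − L`; a genome built with deletion `d` returns
exactly `d`. Single-flank evidence reports the deletion as missing, not
zero.

## Copy number

Two depth-based forms are implemented:

* raw: `ADT_gm/(D_gm·R_gm) − ADT_wt/(D_wt·R_wt)`, with `D` computed
  from total trimmed pairs (before mapping) and `R` = host-mapped /
  total pairs correcting for unmapped data;
* calibrated (default): `ADT_t,gm/ADT_SPS,gm − ADT_t,wt/ADT_SPS,wt`,
  normalizing by a single-copy endogenous reference gene within each
  sample, so all sample-level factors cancel exactly.

The two are not equivalent on real data; the calibrated form is the
default because within-sample normalization absorbs residual library
and mapping bias that `D·R` does not capture, and because only it
reproduces published event tables. The wild-type term subtracts the
native-copy coverage of host-homologous elements (which the
plasmid-preferring tie-break concentrated on the plasmid reference in
both samples).

Per-element estimates over sub-kilobase elements at ~29× scatter with a
standard deviation near 0.15–0.2 — comparable to the spread visible in
published per-element tables — and elements abutting a junction lose
coverage to unmapped junction-spanning reads. The *event-level* estimate
therefore calibrates the depth of the whole T-DNA interior (terminal
150 bp trimmed), which averages over ~8 kb and is steady to a few
percent. ddPCR replicate counts give the orthogonal estimate
(mean target / mean reference), with replicate dispersion reported as
the n−1 relative standard deviation in percent.

## Arrangement inference

With `copies` = rounded copy number and the flank geometry from the
junction calls: one copy with flanks on opposite termini, same strand →
`single`; two copies, same terminus, opposite strands → `head_to_head`
(the insert is an inverted repeat, so both host flanks meet the same
T-DNA end); two copies, opposite termini, same strand →
`tandem_head_to_tail`; anything else `unresolved`. Whole-insert
reconstruction across two copies from 100 bp reads is not attempted —
short reads cannot traverse an 8 kb repeat — the structure is composed
from junction calls plus copy number.

## Backbone scan

Coverage over the plasmid from uniquely mapped ends only (multi-mapped
ends would let homology blocks inflate the track), restricted to the
backbone (the circular complement of the T-DNA). Maximal intervals of
length ≥ 200 bp with coverage ≥ 0.3 × D are flagged; shorter
super-threshold stretches are logged as sporadic. The rationale: a real
single-copy residue is covered at about 1 × D over its whole length,
while stray pairs at ~29× produce isolated sub-span hits; 0.3 × D over
200 bp separates the two with a wide margin. Both thresholds are
exposed.

## The simulator: what it emulates, and what it does not

`simulate_reads()` emulates an Illumina paired-end run at the study
conditions used throughout: 100 bp pairs; insert length Normal(500, 10)
truncated to `[2 × read, chromosome]`; substitution probability linear
from 0.1% at cycle 1 to 4% at cycle 100 (the ramp's endpoints are
standard for the platform; linear interpolation is the simplest model
matching both); a 5% chance that one end of a pair is replaced by
uniform random bases (one end per draw, keeping pair bookkeeping
simple); at most one N call per read (injected with probability 0.01 —
the cap is the platform's behaviour, the rate a modest choice since
qualities are ignored downstream); and a sample haplotype derived from
the reference by mutations at rate 0.001, of which 10% are indels
(geometric extension 0.3, minimum 1 bp), applied before fragment
sampling so reads are internally consistent with one haplotype.
Qualities are written as the Phred transform of the ramp; no downstream
stage reads them. The pair count is exactly
`round(depth × genome / (2 × read))` and everything is deterministic
given the seed.

Event genomes are built with known truth: `copies ∈ {0, 1, 2}` T-DNA
copies at a chosen site with a chosen host deletion, as a single copy,
a direct tandem, or a head-to-head inverted repeat; cisgenic genomes
insert a native host fragment with no deletion (and refuse donors
within one insert of the insertion site, where junctions would be
indistinguishable). The synthetic plasmid generator plants verbatim
host segments *inside* the T-DNA, ≥ 1.7 kb from either border — the
interior-cassette configuration — so that blacklist margins cannot
swallow true junction pairs; constructs with homology directly at a
border are exactly the configuration in which real analyses lose some
true junction pairs to filtering.

Not emulated: PCR duplicates, GC bias, quality miscalibration,
multi-locus insertions, insertions of more than two copies, and real
repeat structure of plant genomes (hosts are uniform-random, so host
multi-mapping is rarer than in real data). Passing tests on simulated
data therefore demonstrate the pipeline's logic and calibration, not
robustness to genome repeat content.

## Numerical choices and degenerate inputs

Coordinates are 0-based half-open internally, converted to 1-based only
in reports. N bases never seed and always count as mismatches. A T-DNA
covering the whole plasmid yields an empty backbone and a trivially
clean scan. Negative calibrated copy numbers (control deeper than the
event sample, under noise) are clipped to zero with a warning. Zero
totals, zero-length intervals and missing calibrator rows are errors,
not silent zeros. All assembly and calling is deterministic; the only
randomness in the package is the simulator's, and it is seed-driven.

## Problem sizes

The validation suite exercises the full pipeline at the study's own
conditions — a 200 kb host carrying two head-to-head copies of an 8 kb
T-DNA with two planted homologous elements, ~29× coverage, with a
matched wild-type run — and the property suites (mapper vs exhaustive
aligner, assembler vs merge oracle, 20-seed locus/deletion recovery)
at 5–80 kb scales, sizes at which every oracle can be recomputed
exactly in seconds.

## Known limitations

* Single-locus events only: one integration site per genome is assumed
  by the arrangement logic (multiple surviving clusters are each
  called, but copy number is genome-wide, not per-locus).
* Internal rearrangements or truncations within a T-DNA copy are not
  resolved; flank elements and copy number cannot distinguish, e.g., a
  head-to-head pair of truncated copies from complete ones.
* Backbone residues are detected on the plasmid axis only; their host
  location would need a second junction pass keyed to backbone
  intervals.
* The mapper is ungapped; highly diverged events (many indels near
  junctions) would lose mapped support earlier than a gapped aligner
  would.
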