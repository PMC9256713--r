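# tdnaseek

Molecular characterization of transgene (and cisgene) integration from
paired-end whole-genome sequencing (PE-WGS).

When a plant line is transformed with a binary vector, regulators and
developers need the full picture of what actually landed in the genome:
the integration locus and its flanking host sequence, how much host DNA
was deleted at the junction, how many T-DNA copies went in and in what
arrangement, and whether any plasmid backbone was dragged along. Getting
this from short-read WGS is hard precisely when the construct carries
host-derived parts — native promoters, RNAi cassettes targeting
endogenous genes — because reads from the native loci masquerade as
junction evidence. `tdnaseek` implements a complete, self-contained
pipeline for this problem, aimed at people analyzing transformation
events (including cisgenesis/intragenesis, where *everything* in the
insert is host-derived) without wiring together an aligner, BLAST, an
assembler and ad-hoc scripts.

## What it computes

Given a host reference, the transformation plasmid with an annotated
T-DNA and element map, and paired-end reads for the event (plus,
strongly recommended, its untransformed recipient line as control):

1. **Chimeric-pair discovery.** Reads are mapped against host + plasmid
   with a seed-and-extend mapper (31-mer seeds, ungapped extension);
   pairs with one end on the host and one on the plasmid are junction
   evidence.
2. **Homology blacklist.** A BLAST-like search finds plasmid↔host
   homologous blocks; each block, expanded by one library insert
   (±500 bp), defines host regions whose chimeric pairs are native-
   sequence artifacts and are removed — with reason codes, so the audit
   table always balances.
3. **Clustering and noise suppression.** Kept pairs are single-linkage
   clustered on the host genome; clusters are dropped if their support
   is out of proportion to sequencing depth (sporadic reads / alignment
   jitter) or internally contradictory.
4. **Junction assembly.** Cluster reads plus the junction-spanning
   unmapped mates are assembled by a deterministic greedy
   overlap-layout assembler; each contig (and each spanning read) is
   split-aligned into a host part and a plasmid part, giving the
   breakpoints, the host deletion length, and the plasmid element at
   each flank.
5. **Copy number.** From depth:
   `CN = ADT_t,gm / ADT_SPS,gm − ADT_t,wt / ADT_SPS,wt`, the average
   target-element depth calibrated by a single-copy endogenous
   reference gene (SPS) per sample; the wild-type term cancels
   host-homologous coverage. The uncalibrated form
   `ADT_gm/(D_gm·R_gm) − ADT_wt/(D_wt·R_wt)` (general depth `D`,
   coverage calibrator `R` = mapped/total pairs) is also reported.
   ddPCR replicate counts give the orthogonal estimate
   `CN = transgene amount / reference-gene amount` with replicate RSDs.
6. **Arrangement.** Rounded copy number plus the flank geometry decide
   the structure: both flanks on the same T-DNA terminus on opposite
   strands at two copies = head-to-head inverted repeat; opposite
   termini on one strand = single copy or tandem.
7. **Backbone scan.** Unique-read coverage over the non-T-DNA plasmid
   region flags any residue covered at ≥ 0.3× genome depth over
   ≥ 200 bp; isolated sub-threshold hits are logged as sporadic.

A built-in simulator generates ground-truthed transgenic or cisgenic
genomes and Illumina-like paired reads (100 bp pairs, 500 ± 10 bp
inserts, 0.1%→4% position-ramped errors, 5% random-read contamination,
mutated sample haplotype), so the entire pipeline is testable end to end
with no downloads.

## Worked example

Validated arithmetic on the published characterization of a real GM rice
event (G281 vs its recipient Xiushui 110), from the printed per-element
depths:

```r
library(tdnaseek)
tb  <- g281_depth_table()
sps <- tb[tb$element == "SPS", ]
tr  <- tb[tb$element != "SPS", ]
round(copy_number_calibrated(tr$adt_gm, sps$adt_gm,
                             tr$adt_wt, sps$adt_wt), 2)
#> [1] 1.95 2.14 2.02 2.00 1.72 1.75
```

— two copies of every element (hLF, EPSPS, Gt1, CYP81A6-RNAi,
Ubiquitin, PEPC). The ddPCR route agrees:

```r
dd  <- g281_ddpcr_counts()
ref <- as.numeric(dd[dd$element == "SPS", -1])
copy_number_ddpcr(as.numeric(dd[dd$element == "hLF", -1]), ref)
#> # A tibble: 1 × 5
#>   ratio rsd_target_pct rsd_ref_pct n_target n_ref
#>   <dbl>          <dbl>       <dbl>    <int> <int>
#> 1  1.96          0.935       0.338        3     3
```

And a full simulated event, recovered end to end:

```r
host <- synth_host(c(chr1 = 200000L), seed = 11)
hom  <- tibble::tibble(chrom = "chr1",
                       start = c(40000L, 120000L),
                       end   = c(40800L, 121000L),
                       name  = c("Gt1p_like", "CYP_like"))
pmap <- synth_plasmid(host, hom, seed = 12)
ev   <- build_event_genome(host, pmap, "chr1", site = 80000L,
                           copies = 2, arrangement = "head_to_head",
                           deletion_len = 36L)
gm <- simulate_reads(ev$genome, sim_config(depth = 29, seed = 101))
wt <- simulate_reads(host,      sim_config(depth = 29, seed = 202))
res <- characterize(gm, host, pmap, wt,
                    sps = list(chrom = "chr1", start = 150000L,
                               end = 160000L))
glance(res)[, c("locus", "deletion_len", "arrangement", "copy_number")]
#> # A tibble: 1 × 4
#>   locus deletion_len arrangement  copy_number
#>   <int>        <int> <chr>              <dbl>
#> 1 80000           36 head_to_head        2.01
```

The call lands exactly on the simulated truth: one insertion at host
position 80,000 with a 36 bp deletion, two T-DNA copies head-to-head,
clean backbone, and zero surviving candidate clusters in the wild-type
control. `tidy(res)` returns the per-element copy-number table,
`print(res)` the full report, `write_report(res, dir)` the JSON/BED/
FASTA artifacts, and `exec/tdnaseek` wraps `simulate`/`characterize`
for shell use.

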