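---
title: "Designing gel-resolvable InDel markers from assembled contigs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing gel-resolvable InDel markers from assembled contigs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(indelmine)
```

## The problem

Commercial market classes of common bean (pinto, navy, black, kidney, ...)
are bred largely in isolation, so the genetic diversity *within* a class is
narrow and most genome-wide SNP panels discriminate poorly there. Length
polymorphisms — insertions and deletions of 8 bp and more — have two
practical advantages: they can be assayed as simple PCR product-size
differences on a 3% agarose gel with no sequencing or fluorescent chemistry,
and a small number of well-placed markers suffices for variety
identification, mapping and diversity studies in low-resource labs.

`indelmine` implements the full development path for such markers from
per-genotype de novo contigs: within-class contig alignment, InDel
extraction and filtering, uniqueness screening against a reference genome,
consensus building, tightly constrained primer design, position-encoded
naming, and the downstream in-silico genotyping and diversity analyses. A
synthetic-genome generator with recorded ground truth makes every stage
verifiable at desk scale.

## The procedure and its assumptions

1. **Discovery.** Contigs of one genotype are aligned against the contigs
   of the other genotypes of the same market class, either *three-way* (one
   genotype as query against a database pooling the other two, best two
   hits kept) or *pairwise* (all ordered genotype pairs, best hit only).
   Alignment is exact Smith–Waterman–Gotoh with affine gaps
   (match +2, mismatch −4, gap cost 5 + 5·length — megablast's
   1/−2/2.5/2.5 doubled to stay integral) on both strands, with a
   Karlin–Altschul expectation value `E = K·m·n·exp(−λ·score)`
   (λ = 1.28, K = 0.46, cutoff 1e−50) used for ordering and cutoff only.
   Each maximal gap run in a passing alignment is an InDel candidate; runs
   are left-aligned through identical bases so the same event always gets
   the same coordinates.
2. **Filtering.** Candidates below 8 bp are dropped (below the resolution
   of a 3% agarose gel); query contigs containing more than four
   consecutive Ns are excluded (ambiguity can fake an InDel or mis-size
   it); contigs are then screened against the reference genome and kept
   only when they align to exactly one locus at the E-cutoff — zero hits
   leave nothing to name a marker by, two or more indicate repetitive
   sequence and a multi-band assay.
3. **Consensus.** The 2–3 InDel-bearing contigs are aligned onto the
   long-allele scaffold; positions where any non-gap member disagrees
   become N, the InDel interval itself is carried as long-allele sequence,
   and the region is trimmed to the stretch covered by all members. Regions
   with ≥10% ambiguity or without full flank coverage are rejected.
4. **Primer design.** All windows of length 22–32 strictly left (forward)
   and right (reverse, reverse-complemented) of the InDel interval are
   enumerated; windows must be N-free, have GC between 35 and 60%, a
   nearest-neighbor melting temperature between 67 and 69 °C, and no
   3′ self-complementary run of 5+ bases. Pairs must differ by at most
   2 °C, be free of 3′ cross-dimers, and yield a long-allele product inside
   the schedule window: minimum from a fixed size table
   (8–9 bp → 70, 10–11 → 80, 12–14 → 90, 15–17 → 100, 18–22 → 110,
   23–26 → 120, 27–29 → 130, 30–36 → 150), optimum 10× the InDel size,
   maximum 10× + 10. The returned pair minimizes a weighted penalty
   (weights 1, 0.5, 3, 0.1 for length, GC, Tm and product deviation from
   26 bp / 50% / 68 °C / optimum). The stringent envelope is the point:
   every marker amplifies under one PCR program with no per-marker
   optimization.
5. **Naming.** `NDSU_IND_NN_XX.XXXX`: zero-padded chromosome number and the
   physical position in Mbp, truncated (never rounded) to four decimals.
6. **Reference pileup scan.** Independently of marker design, alignments of
   reads against the reference (SAM, consumed not produced) are walked
   CIGAR-by-CIGAR; insertion/deletion events are left-aligned against the
   reference and grouped, and a call is emitted when at least five reads
   span the site and at least 80% of them support the event. Density
   summaries report calls per Mbp and calls per 1× coverage.
7. **Genotyping and diversity.** In-silico PCR (exact primer matching, both
   orientations, products up to 2 kb) produces band sizes per genotype;
   bands within the gel resolution (8 bp) collapse into one size class;
   markers with ≥2 classes are polymorphic. Inbred lines are scored as
   haploid — one band class per genotype per locus — so the shared-allele
   distance reduces to the mismatch fraction over co-scored loci.
   Neighbor-joining (Saitou–Nei Q-criterion, lexicographic tie-breaks,
   negative branches clamped to 0) builds the tree; bootstrap over markers
   gives per-edge support; Fst is the heterozygosity-based (Nei-style)
   `(Ht − mean Hs)/Ht` with allele frequencies averaged unweighted across
   groups.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `min_indel_size` | 8 | bp | smallest length difference separable on 3% agarose |
| `n_run_max` | 4 | bases | longer N runs can fake or mis-size an InDel |
| `e_cutoff` | 1e−50 | — | hit acceptance for discovery and uniqueness |
| `uniqueness_max_hits` | 20 | hits | counting cap; ≥2 hits excludes either way |
| primer length | 22/26/32 | bp | min/opt/max window sizes |
| primer GC | 35/50/60 | % | amplification robustness |
| primer Tm | 67/68/69 | °C | narrow window ⇒ one PCR program for all markers |
| ΔTm | ≤2 | °C | forward/reverse balance |
| product size | table / 10× / 10×+10 | bp | both alleles resolvable and scorable |
| `min_depth` | 5 | reads | pileup call support |
| `min_vaf` | 0.80 | fraction | homozygous-call stringency |
| `gel_resolution` | 8 | bp | bands closer than this co-migrate |

## The melting-temperature model

Primer Tm uses the Breslauer nearest-neighbor tables with the classic salt
and concentration correction,
`Tm = ΔH / (ΔS + R·ln(C/4)) − 273.15 + 16.6·log10([Na+])`, with initiation
entropy −10.8 cal mol⁻¹ K⁻¹, 50 nM annealing oligo and 50 mM monovalent
salt. This is the legacy model of the batch primer-design tools for which
the 67–69 °C window was expressed; a modern unified model would shift all
values several degrees and make the window meaningless. The bench annealing
temperature (55 °C for all markers) is a protocol constant, not a computed
quantity. On uniform-random 50% GC sequence roughly one in eight windows
that pass the GC filter also falls in the Tm window, which is why the
narrow envelope still leaves designable pairs in almost every region.

## What the synthetic generator emulates — and what it does not

`generate_reference()` builds uniform-random ACGT chromosomes with exact
2 kb segmental duplications covering a chosen fraction of the genome;
`plant_variants()` derives genotypes carrying private (or deliberately
shared) InDels and random SNPs, recording every event;
`fragment_to_contigs()` cuts genotypes into contigs with truncated-normal
lengths (sd = mean/4, floor 120 bp — so the 120 bp statistics filter is
exercised) and optional injected N-runs of 3–8 bases. Anchored contigs
guarantee each planted event ≥200 bp of flank in at least one contig of
*every* genotype, since primer products reach 370 bp.

Default study conditions, chosen once to mirror a desk-scale version of a
low-coverage resequencing study of three related genotypes: two 50 kb
chromosomes, 8% duplicated sequence, 20 private InDels per genotype
(60 events) with sizes uniform on 8–36 bp, SNP rate 1e−3 (narrow
within-class diversity), contig length ~N(700, 175²), 1.3× contig
coverage, 5% N-run injection. Planted events keep a global minimum
separation of 600 bp; placement samples from an explicit free-interval set
because naive rejection sampling jams well below this packing density.

The generator does **not** model sequencing errors, realistic repeat
families, assembly chimeras or heterozygosity. Passing tests therefore
demonstrate the correctness of the pipeline's logic and bookkeeping on
clean data — recall on real contigs will be lower in repeat-rich or
low-coverage regions, exactly the regions the uniqueness screen is designed
to drop.

## Numerical and design choices

* **Alignment engine.** Discovery-scale alignment is exact dynamic
  programming (no heuristic seeding losses); a 16-mer shared-seed prefilter
  skips pairs that cannot align, and cannot change the best hit for any
  pair sharing a seed. K-mers are packed two bits per base into doubles for
  fast hashing.
* **E-values** use fixed ungapped nucleotide constants; they are not
  BLAST-calibrated and only ordering plus a configurable cutoff is ever
  relied on.
* **Left-alignment everywhere.** Both the contig-alignment extractor and
  the pileup caller shift gaps leftward through identical bases, so
  positions are canonical and merging/dedup is deterministic.
* **One locus, two views.** A deletion in genotype A surfaces as a
  deletion when A is the query and as an insertion when A is the subject.
  The pipeline canonicalizes the reference anchor (the base left of the
  junction, plus one) so both views get identical coordinates and dedup
  collapses them regardless of kind.
* **Consensus by unanimity.** Disagreements become N rather than IUPAC
  codes; primer windows simply refuse N. Multalin-style weighted consensus
  thresholds are not emulated.
* **No-hit contigs are excluded** at the uniqueness screen: without a
  placement no position-encoded name is possible.
* **InDels larger than 36 bp** extrapolate the product-size table as
  `150 + 10·ceil((size − 36)/5)` and are flagged; the published table ends
  at 36.
* **Fst estimator** is the heterozygosity-based form, recorded as such in
  the output; Weir–Cockerham θ would differ on unbalanced groups.
* **Ties.** NJ joins break ties lexicographically on the clusters'
  smallest leaf labels (input-order invariant); primer pairs of equal
  penalty prefer the leftmost forward, then leftmost reverse window.

## Problem sizes used by the test suite

The suite runs the full pipeline on the 100 kb / 60-event study fixture
(about three minutes), checks the primer envelope on 500 independent
consensus regions, verifies aligner scores against a brute-force
full-dynamic-programming oracle on 200 random pairs up to 500 bp, and
validates NJ against additive tree metrics of 4–8 taxa — sizes at which
every expected value can be computed exactly and independently.

## Known limitations

* Heterozygotes (two bands per lane) are not modeled; F2-style mapping
  populations need a diploid scoring extension.
* The uniqueness screen counts one hit per seed-cluster window; two tandem
  copies closer than a contig length can merge into one window and escape
  the multi-hit exclusion. Fixture duplications are placed apart.
* In-silico PCR is exact-match by default; primer-site SNPs in real
  material cause null alleles the simulation does not produce.
* E-values, and therefore the practical meaning of the 1e−50 cutoff,
  differ from gapped BLAST calibration.

## A worked example

```{r example}
sim <- simulate_marker_study(seed = 11)
res <- run_marker_pipeline(sim$contig_sets, sim$reference$sequences,
                           market_class = "pinto", mode = "three_way")
res$counts                 # per-filter accounting
head(res$markers)          # named markers with primers and product sizes

sc <- score_markers(res$markers, sim$variants$genotypes)
sc$polymorphism_rate
D <- shared_allele_distance(sc$classes)
tr <- nj_tree(D)
```
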