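---
title: "Closing Target Trimming: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closing Target Trimming: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Gene superfamilies — F-box (PF00646), BTB (PF00651), protein kinases
(PF00069) and their kind — expand by whole-genome and tandem duplication,
and genome annotation projects routinely miss members: some lack the clean
gene signals that ab initio predictors rely on, and some sit so close to a
paralog that a homology-based predictor, which reports only the *best*
match for a template in a region, never looks at them. The second failure
mode is the one this package exists to fix.

`ctt` implements the Closing Target Trimming strategy: anchor a candidate
region with a translated homology search of the family's domain
signature, then *iteratively remove the footprints of neighbouring
homologous loci* from the candidate window until the predicted gene model
contains the anchor — at which point the anchor locus itself, not its
better-scoring neighbours, is what the spliced aligner sees.

## The pipeline

Seven steps run per genome from a three-column manifest (genome FASTA,
GFF3, proteome FASTA per row):

1. **Prior members** — family seeds are aligned to every annotated protein
   (Smith–Waterman, BLOSUM62, affine gaps, Karlin–Altschul E-values); a
   protein is a member when some seed reaches E ≤ 1e-5 *and* a
   position-specific profile built from the seed alignment finds the
   domain at E ≤ 1. Both cutoffs are exposed in `pipeline_config()`.
2. **Reference sets** — members are clustered at 0.9 global identity
   (greedy, longest-first) into a non-redundant reference set (RefPep);
   the best domain slice of each member joins the original seeds, likewise
   clustered, as the combined search queries.
3. **Anchoring** — the combined seeds are searched against all six reading
   frames of each contig (E ≤ 1e-5). Hits are deduplicated by a mutual
   midpoint rule (a hit is dropped when its midpoint lies inside a
   retained hit or vice versa; the higher bit score wins) and discarded
   when contained in an annotated gene span. Each survivor becomes a
   candidate window of `flank_head` + `flank_tail` + 1 nucleotides
   (default 5,000 + 5,000) around the anchor start, clamped to the contig.
4. **Closing target trimming** — repeat up to `max_iterations` (6) times:
   rank RefPep against the remaining segment (translated in six frames,
   best hit per protein), predict a gene model from the top template, and
   either (a) the model's span contains the anchor on the same strand —
   window exposed — or (b) the model footprint is cut out and the
   contiguous remainder holding the anchor midpoint is kept. The loop
   stops early when no template hit is found (E ≤ 10) or the model score
   drops below `genewise_min_score` (50).
5. **Consensus model** — the top three templates each predict and classify
   the exposed locus (`coding`, `pseudogene_stop` for models with internal
   stops or frameshifts, `pseudogene_no_transcript` when no model clears
   the score threshold); a class needs two agreeing templates. For coding
   loci the agreeing model with the highest score is kept. With a single
   available template the call is accepted but flagged low-confidence.
6. **Coordinates** — exon intervals are mapped through the window offset
   back to the genome and verified by re-extraction: splicing the genomic
   exons must reproduce the model CDS byte for byte.
7. **Domain confirmation** — accepted coding proteins must carry the
   family domain (profile scan, E < 1); pseudogene candidates bypass this
   check and are catalogued as pseudogenes.

## The spliced aligner

GeneWise-style prediction is re-implemented as a dynamic program over
(template residue, genomic position) with:

* codon matches scored by BLOSUM62 (configurable through
  `scoring_scheme()`); codons containing N translate to X and score as a
  mismatch;
* affine template-residue deletions and codon insertions
  (`gap_open` −11, `gap_extend` −1; a gap of length L costs
  `gap_open + (L−1)·gap_extend`);
* introns permitted only between codons, across GT..AG pairs at least
  `min_intron` (40) nt apart, at `intron_open_penalty` (−15). Phase-1/2
  introns and non-canonical splice sites are out of scope;
* single-base insertions or deletions inside a codon at
  `frameshift_penalty` (−20), each recorded as a frameshift lesion;
* read-through of in-frame stops at `stop_codon_penalty` (−15), each
  recorded as an internal-stop lesion.

Both strands are tried; ties break toward `+`, then leftmost. The score
is reported in raw DP units, and the stop rule's threshold of 50 is
interpreted in that unit: the role of the rule (drop windows whose best
model is no better than noise) is preserved, while the original
GeneWise-specific calibration is not portable. Segments are capped at
200,000 nt. The Karlin–Altschul constants (λ = 0.267, K = 0.041, the
ungapped BLOSUM62 approximation) are applied to raw scores everywhere an
E-value is needed, including profile scores; this is a declared
calibration, configurable per scheme, not a fitted one.

Penalty rationale: a frameshift (−20) must cost more than an intron
(−15), or real introns would be absorbed as chains of frameshifts; a
stop (−15) must cost less than truncating a long downstream match, or
pseudogene lesions would be silently clipped off the alignment; all three
must be small relative to the ~5/residue match reward so that one lesion
never outweighs an otherwise solid model.

## The synthetic study design

`make_family()` draws an ancestral protein with a fixed architecture —
20-residue N-flank, signature domain (48/108/267 residues for the
fbox/btb/pkinase presets), 160-residue C-flank — and diversifies members:
domain positions mutate at `divergence_rate` (default 0.15), flanks at
`flank_divergence` (0.30). Members therefore remain alignable over their
full length, as paralogs within a subfamily are, while the domain is the
clearly conserved signature. Seeds are the (equal-length, hence aligned)
member domains.

`plant_genome()` lays loci on one contig: annotated members (emitted to
GFF3 + proteome), hidden coding loci (emitted to neither), tandem pairs
(one annotated + one hidden copy 200–2,000 nt apart — the case the
trimming loop exists for), and pseudogenized hidden loci (a premature
stop or a 1-nt deletion in the middle third of the CDS, alternating).
Standalone loci sit 3,000–9,000 nt apart; intergenic space is i.i.d.
uniform ACGT. Loci carry 1–2 introns (60–200 nt, GT..AG) with
probability `intron_rate` (0.5); introns are placed downstream of the
domain-coding span so that a domain anchor is a contiguous translated
hit, which mirrors the common case the anchoring step is designed for.
Reverse translation uses uniform synonymous codon choice — codon bias is
irrelevant to the algorithms under test. Everything is deterministic per
`rng_seed`.

The acceptance-scale design is one ~500 kb contig with 30 annotated
members, 20 hidden coding loci (8 tandem-paired) and 10 hidden
pseudogenes — large enough that windows overlap neighbouring loci and
the trimming loop is genuinely exercised, small enough to run on one CPU
in minutes. What passing on this fixture does *not* show: robustness to
repeats, GC skew, non-canonical splicing, fragmented assemblies, or
domain families whose members share nothing outside the domain — real
data has all of these, so recovery rates on real genomes sit well below
the near-perfect recovery seen on clean synthetic contigs.

## Numerical and design choices

* **Coordinates** are 1-based inclusive everywhere (GFF3 convention);
  half-open arithmetic appears only at slicing boundaries, never in an
  interface.
* **"Encompasses"** is read strictly: the anchor interval must be fully
  contained in the model span on the same strand
  (`encompass = "containment"`); a config flag relaxes this to midpoint
  containment.
* **Trimming keeps one piece.** Removing a footprint never re-concatenates
  the flanking pieces — that would create chimeric sequence; only the
  piece containing the anchor midpoint survives. If a footprint overlaps
  the anchor without containing it (a rare antisense or partial-overlap
  model), the window is rejected rather than trimmed into an invalid
  state.
* **Step 4 uses one template per iteration; step 5 re-ranks with three
  and a quorum of two.** Both counts are configurable; the defaults
  satisfy the "top hit to expose, at least two to agree" reading.
* **Dedup tie-breaks** at equal bit score: longer hit, then leftmost,
  then seed id — determinism is a hard requirement, the order itself is
  not meaningful.
* **Gene-containment filtering** uses `gene`-type spans, strand-agnostic:
  an anchor inside an annotated gene on either strand is not a new locus.
* **Rounding** of reported percentages is half-up to one decimal, the
  printed-table convention (banker's rounding would turn 78.15 into
  78.1).
* **Known limitation:** a frameshift lesion that lands within a few
  codons of a splice junction can be absorbed into an alternative
  GT..AG splice of nearly equal score, and the locus is then classified
  coding. This ambiguity is intrinsic to score-based spliced alignment
  (the original tooling shares it) and is visible in the synthetic runs
  as occasional frameshift pseudogenes reported as coding.

## Reproducibility

All randomness flows through explicit `rng_seed` arguments
(`withr::with_seed`); the pipeline itself is deterministic given inputs
and configuration, which the test suite asserts by re-running it. The
test suite builds every fixture in code at run time — no binary data
ships with the package.
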