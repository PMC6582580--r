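---
title: "Detecting GULO orthologs in raw assemblies: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting GULO orthologs in raw assemblies: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gulotrace)
```

## The problem

Most vertebrates synthesise vitamin C (L-ascorbate); species that cannot
have invariably lost *GULO*, the gene for L-gulonolactone oxidase, the
enzyme catalysing the last step of the pathway. Whether the many
non-deuterostome animal lineages carry a *GULO* ortholog is hard to read
off public annotation: many genomes of interest are unannotated
assemblies, existing annotations are sometimes truncated, and apparent
hits can be bacterial contamination. `gulotrace` implements, as a tested
and reusable pipeline, the screening procedure such a survey needs:

1.  a six-frame translated homology search of a reference GULO protein
    against raw nucleotide scaffolds (tblastn-style);
2.  retrieval of hit regions with generous flanks and merging of regions
    that share a long exact overlap ("grow sequences");
3.  reconstruction of a spliced CDS by similarity-guided exon chaining
    under the canonical GT-AG splice rule;
4.  classification of the reconstructed protein by its His-Trp-x-Lys
    (HWxK) motif — in animals, true GULO orthologs carry HWAK, while
    related VAO-family flavoproteins carry other variants, typically
    HWGK;
5.  per-species presence/absence calls with contamination screening,
    per-lineage calls, and a minimum-loss (Dollo) mapping of independent
    gene-loss events onto a species cladogram.

A companion module quantifies L-ascorbate from HPLC chromatograms via a
linear calibration curve, with ascorbate-oxidase (AO) confirmation of
peak identity and unpaired two-tailed *t* comparisons between groups —
the biochemical half of the same study design (does the organism *have*
vitamin C even without *GULO*?).

Because the original survey ran against dozens of GenBank assemblies that
this package deliberately does not download, every stage is exercised on
*synthetic* data with planted ground truth (`synth_genome()`,
`fragment_assembly()`, `contaminate()`, `synth_chromatogram()`,
`make_gulo_family()`). The generators are first-class, seeded, tested
code: they define the study conditions under which the pipeline's
guarantees are asserted.

## The translated search

`search_genome()` seeds word matches between the query protein and all
six translation frames of every scaffold, and extends each seed into a
gapped HSP with an X-drop criterion.

* **Scoring.** BLOSUM62 with affine gaps; a gap of length $L$ costs
  $11 + L$. These are the standard protein-search costs.
* **Statistics.** Bit score $(\lambda S - \ln K)/\ln 2$ and E-value
  $K\,m\,n\,e^{-\lambda S}$ with the gapped Karlin–Altschul constants
  $\lambda = 0.267$, $K = 0.041$, $m$ the query length in residues and
  $n$ the searched nucleotide length divided by 3. Effective-length
  corrections and composition-based statistics are out of scope: the
  quantity the pipeline consumes is the **0.05 E-value cutoff**, whose
  filter semantics (not exact NCBI parity) are what the tests pin down.
* **Seeding.** Word size 3 with neighbourhood threshold T = 11 for
  discovery; word size 2 with T = 8 for the annotation-guide search.
  The discovery word size is a package default (the original protocol
  only fixes word size 2 for the guide stage); both are configurable in
  `search_params()`. Extension is anchored at the best-scoring residue
  pair of the seed word — anchoring on the whole word would force a
  negative edge pair into the HSP and cap the attainable score, which
  would break the equivalence, asserted in the tests, between the top
  HSP score and a full six-frame Smith–Waterman maximum on small
  fixtures.
* **Flanks.** `extract_flanked_regions()` retrieves 5000 nt on both
  sides of each HSP (clipped at scaffold ends) and merges overlapping
  regions; `grow_sequences()` then merges regions across HSPs that share
  an exact suffix/prefix overlap of at least 2500 nt. Overlap detection
  is exact string matching (regions come from a single assembly), with a
  KMP prefix function so growing stays linear in region length.
  Reverse-complement overlaps are not merged; orientation is handled
  downstream by the exon chainer, which explores both strands.

## Spliced CDS reconstruction

The original procedure annotated genes *by hand* under the assumption
that introns follow the canonical GT-AG rule. `annotate_region()`
replaces the human with a two-stage algorithm:

1.  **Candidate exons** (`candidate_exons()`): ungapped similarity cores
    between the query and all six frames of the region (word size 2
    guide search) are extended along their diagonals; cores sharing a
    diagonal are additionally merged into spans, which rescues diverged
    matches whose extension breaks into pieces. Candidate boundaries are
    then placed at the region ends, at the implied CDS start/end, or
    adjacent to AG (acceptor) / GT (donor) dinucleotides within a window
    of the core ends (18 nt outward, 60 nt inward — an ungapped
    extension is a random walk and can overshoot an exon end by a fair
    excursion before the score decays). Each core span contributes its
    best twelve boundary combinations, which always include the true
    pair (true boundaries maximise the number of matched codons) while
    keeping the chaining DP small. A candidate records the
    query-anchored CDS coordinates of its span; its interior never
    contains an in-frame stop.
2.  **Chaining** (`chain_exons()`): a dynamic program over candidates
    maximises total similarity minus an intron penalty (default 5 per
    intron), subject to colinearity in region and query coordinates,
    GT...AG introns of at least 20 nt, and splice-phase compatibility —
    a codon split across an intron must reconstitute a valid, non-stop
    codon, which is what makes the `translate(cds) == protein` invariant
    hold exactly. Query codons skipped between consecutive exons are a
    deletion and pay the affine gap cost (11 + 1 per codon); without
    that cost the DP would happily bypass weakly scoring codons across
    every intron. Ties break toward fewer exons, then the leftmost
    start. The DP is verified against exhaustive enumeration over all
    candidate subsets on small fixtures.

`exon_min_score` (15) and `chain_min_score` (25) are package inventions
— the by-hand step they automate had no numeric thresholds — and are
flagged as such in `genemodel_params()`.

Real GULO genes often have a first coding exon that encodes *only* the
ATG start codon. The generator can plant such genes, and the chainer
admits lone-ATG candidates; in practice the DP drops an isolated ATG
exon (its score equals the intron penalty it costs), so reconstructed
models of such genes lack a start codon — exactly the situation reported
for real de novo annotations, which is why `validate_model()` does not
hold a missing start codon against a model. Acceptability requires no
internal stop, an HWxK motif, and at least 50% aligned query coverage
(`coverage_min`, configurable; the original survey reports a coverage
column without fixing a threshold).

## Calls, contamination, losses

`call_species()` applies a fixed precedence:

| Evidence | Call |
|---|---|
| acceptable HWAK model, not contaminated | PRESENT |
| only contaminated model(s) | CONTAMINATION |
| HSPs on ≥ 3 scaffolds, no single-scaffold motif model | INCONCLUSIVE ("scattered") |
| no HSPs, or query coverage < 0.25 | ABSENT |
| anything else | INCONCLUSIVE |

"Scattered" (≥ 3 scaffolds) and "residual" (< 0.25 coverage)
operationalise wordings that the original criteria leave qualitative;
both are exposed as arguments. `screen_contamination()` calls a model
contaminated when its best translated-alignment bit score against a
labelled reference panel is bacterial *and* exceeds the best animal
reference by ≥ 10% — mirroring the published tick case whose apparent
GULO was a near-identical copy of a bacterial CDS. CONTAMINATION counts
as neither present nor absent at lineage level.

`call_lineage()` declares a lineage ABSENT only when at least three
member species are ABSENT and none is PRESENT; one PRESENT species makes
the lineage PRESENT (a recent species-level loss inside a
gene-bearing lineage does not flip the lineage call); anything else is
INCONCLUSIVE.

`dollo_losses()` maps losses under Dollo parsimony: the ancestral animal
state is gene-present, regain is disallowed, and the minimum set of loss
edges is placed canonically — each loss pushed rootward to the deepest
edge whose clade contains no present tip. Unknown tips are
unconstrained. The count is verified against brute-force enumeration on
small trees, and the bundled Protostomia lineage matrix reproduces the
four independent losses (Pancrustacea, Nematoda, Platyhelminthes,
Bivalvia).

## The phylogenetic stand-in

The original study confirmed orthology with a Bayesian codon-model tree.
Desk-scale re-analysis does not need MCMC: the classification rule the
pipeline implements is *topological* (a query is GULO-like iff it
attaches inside the animal-reference clade of a tree rooted on a
two-sequence fungal outgroup), so `codonphylo` provides:

* `align_codons()` — translate, progressively align at the protein level
  (guide tree from pairwise identities, sum-of-pairs profile DP with
  affine gaps), thread codons back. Degapping any record returns its
  input CDS exactly; gaps come in whole codons.
* `column_support()` — a 0–9 per-column support score,
  `round(9 × f)` with `f` the fraction of record pairs whose residues are
  identical or score positively under BLOSUM62. Columns with support
  ≥ 3 ("above two") are kept. The original support values came from an
  alignment-pipeline tool whose formula is unpublished; this score is an
  explicit stand-in, while the ≥ 3 cutoff is taken as stated.
* `nj_tree()` — neighbour joining on protein p-distances over filtered
  columns (recovers additive matrices exactly), and
  `place_and_classify()` for the rooted placement verdict.
* `burnin_count()` and `psrf()` — the run arithmetic (5,000,000
  generations sampled every 100 with 25% burn-in discard exactly 12,500
  samples) and the Gelman–Rubin potential scale reduction factor
  $\sqrt{(n-1)/n + B/(nW)}$, defined as 1 when both variance components
  vanish. These are generic utilities: they diagnose any pair of chains,
  not a bundled MCMC.

## HPLC quantitation

`synth_chromatogram()` emulates a reversed-phase trace at 265 nm:
polynomial baseline drift, Gaussian peaks of fixed width (4 s sd), iid
trace noise, and a realised peak area of `response × conc` jittered by a
1% relative error (replicate injections scatter around the calibration
line). `detect_peaks()` subtracts a rolling-minimum baseline (window
201 samples, much wider than a peak), finds prominence-filtered local
maxima and integrates trapezoidally between the points where the
corrected signal decays to 0.2% of the peak height.
`fit_calibration()` is ordinary least squares of area on concentration
at the published standard levels 25/50/100 uM; `quantify()` inverts the
line for the largest peak in a retention-time window, clipping at zero.
`confirm_identity_ao()` requires a ≥ 90% area drop after
ascorbate-oxidase treatment — the published criterion is "extinction" of
the peak, which 90% operationalises conservatively.
`per_individual_amount()` converts uM in a homogenate of 25 individuals
per ml to ug per individual (molar mass 176.12 g/mol), exposing an
extraction-recovery factor that defaults to naive dimensional analysis.
`compare_groups()` is the two-tailed unpaired *t*-test (pooled variance
by default, Welch behind a flag), matching the published per-comparison
reporting with no multiplicity correction.

Quantitation in tests follows the published protocol's three technical
replicate injections per sample; single-injection quantitation at the
low end of the calibration carries a few percent of intercept-driven
uncertainty that replicate averaging removes.

## What the synthetic data does and does not emulate

`make_gulo_family()` evolves one ancestral 120-residue HWAK protein into
a query (5% divergence), animal references (10%), a fungal outgroup
(25%) and bacterial decoys (35%), each protected at the motif site and
guaranteed a single HWxK occurrence. Planted genomes embed a
back-translated, exon-split copy of a species protein in iid background
of given GC (default 0.4), with introns drawn uniformly from a
configurable range (defaults 50–300 nt; real intron-length distributions
for the surveyed taxa are unknown, so this is an explicit modelling
choice). Fragmentation cuts inside introns so exons scatter across ≥ 3
scaffolds with no scaffold retaining a dominant share of the CDS;
contamination appends a scaffold carrying a synonymously-mutated (≥ 98%
identity, identical protein) copy of a bacterial reference.

Deliberately *not* modelled: repeat landscapes, sequencing error,
assembly-graph artefacts, non-canonical splice sites (GC-AG and AT-AC
are rejected by design, as the original annotation assumed GT-AG),
alternative genetic codes, paralogous gene families beyond the decoy
panel, and real intron-length and codon-usage distributions. Passing
tests therefore demonstrate the pipeline's *algorithmic* correctness and
its decision semantics under controlled homology structure — not
performance on real assemblies, where masking, repeats and deeper
divergence would matter.

Problem sizes used throughout the suite — 120-residue proteins, ~3-kb
backgrounds, 50-genome recovery corpora, 10 genomes per mode for the
call confusion matrix, 200 chromatograms for quantitation error — are
the package's desk-scale choices: large enough for the ≥ 95% recovery
and call-accuracy guarantees to be meaningful, small enough that the
whole suite runs in minutes on one CPU.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open internally; GFF3 output is 1-based
  inclusive with phase computed from cumulative CDS length.
* Codons containing N translate to X, and X never matches the motif
  wildcard — motif calls on low-quality regions are conservative.
* All generators take an explicit seed and restore the caller's RNG
  state; identical seeds give byte-identical FASTA/GFF3.
* Chains must start and end on codon boundaries; candidate interiors are
  stop-free by construction; the junction codon of a phase-split intron
  is checked at chain time.
* `psrf()` of two identical constant chains is defined as 1.0; a
  degenerate between-chain variance with zero within-chain variance is
  Inf.
* Empty FASTA input parses to an empty set; a sequence character outside
  the declared alphabet is an error naming the record and position.

## Known limitations

* The search reports HSPs with default Karlin–Altschul constants and no
  effective-length correction, so E-values differ from NCBI BLAST by a
  modest factor; the 0.05 cutoff semantics, not the exact values, are
  contractual.
* The exon chainer assumes the gene lies on one grown region and one
  strand; trans-scaffold models are out of scope (such evidence
  surfaces as a "scattered" INCONCLUSIVE call instead).
* Neighbour joining is a stand-in for Bayesian inference; topologies for
  deeply diverged, rate-heterogeneous real data would be less reliable
  than for the synthetic families tested here.
* The HWxK pattern is a four-residue motif; on real data a match is
  necessary but not sufficient evidence, which is why the pipeline also
  demands alignment coverage and placement inside the animal clade.
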