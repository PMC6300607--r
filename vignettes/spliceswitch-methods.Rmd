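---
title: "Models and methods behind spliceswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spliceswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceswitch)
```

This vignette explains what the package computes, the assumptions
behind each stage, the parameters that matter, and the design choices
made where more than one reasonable definition exists. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## Coordinates and the splice-site convention

Junctions are stored as intron intervals `[start, end]` — the first and
last intronic base, 1-based inclusive, the convention of STAR's
`SJ.out.tab`. Annotated splice sites, by contrast, are exon-boundary
coordinates, so a junction's left boundary is `start - 1` and its right
boundary `end + 1`. For the three-exon gene with exons 1–100, 201–300
and 401–500 on the + strand, the donors are {100, 300}, the acceptors
{201, 401}, and the introns (101,200) and (301,400). All rule matching
("a junction end overlaps a splice site") is **exact coordinate
equality** after this boundary shift, strand-aware for donor/acceptor
roles. Exact equality was chosen because junction ends *are* splice
sites by construction; interval overlap is ill-defined for point sites.
A windowed-proximity variant was considered and rejected as
experimental; the tolerance is fixed at 0.

## Differential junction usage

The unit of inference is a junction's *relative usage*: its count
divided by the total junction count of its gene in that sample. The
denominator is the sum over the gene's tested junctions, not an
external gene-expression count — this keeps the test self-contained and
at junction-level granularity, and makes it insensitive to overall
expression changes.

The test is a beta-binomial likelihood-ratio test. Per gene, an
intra-class correlation $\rho_g$ (the beta-binomial overdispersion) is
estimated by a method of moments on Pearson-style dispersion statistics
accumulated over junction × condition cells, using condition-specific
proportion estimates so genuine usage shifts do not inflate the
estimate. At three samples per condition such per-gene estimates are
very noisy, so they are shrunk toward the dataset-wide pooled estimate
with a prior weight of 30 dispersion cells — the same moderation logic
limma and edgeR apply to variance and dispersion estimation. The floor
is 0, where the model reduces to a binomial LRT. Given $\rho_g$, the
proportion under null and alternative is profiled out by 1-D
golden-section likelihood maximisation (tolerance 1e-8; the
beta-binomial likelihood in one proportion is unimodal in practice),
and twice the log-likelihood ratio is referred to $\chi^2_1$.

Choices a user can change:

* `treated` — which condition level is the FC numerator
  (default `"treated"` when present). FC is treated/control.
* Filtering: `filter_junctions()` defaults to count ≥ 5 in at least
  (smaller condition size) samples; upstream tools filter comparably,
  and the exact values are not critical for the test's validity.
* Count source: column 7 of `SJ.out.tab` (uniquely mapping reads);
  multi-mapped reads are excluded, the standard practice for usage
  testing.

Single-junction genes are skipped (relative usage is degenerate at 1),
as are genes with zero counts throughout one condition; both are
recorded with reasons on the result's `skipped` attribute.

Gene-level aggregation uses the Bonferroni-adjusted minimum junction
p-value, $p_g = \min(1, n_g \min_j p_j)$, then BH across genes. The
minimum-based statistic matches the question "does this gene contain at
least one differentially used junction"; it is conservative but exact
under independence-free assumptions.

The default significance gates are junction FDR ≤ 0.001 for event
classification and gene FDR ≤ 0.0005 for differential-splicing calls.
The FDR procedure is Benjamini–Hochberg.

## Event classification

Classification applies the first matching rule:

1. **IR** — either junction boundary equals a splice site owned by a
   transcript of biotype `retained_intron` or
   `nonsense_mediated_decay` (biotype strings are normalised to
   lower-case/underscores).
2. **ES/EI** — an annotated *internal* exon lies strictly inside the
   junction interval; with $M$ the arithmetic mean fold change of the
   junctions sharing a splice site with it: $M>1$ and FC < 1 gives ES,
   $M<1$ and FC > 1 gives EI. If the direction pattern matches
   neither, or the partner set is empty (making $M$ undefined), the
   junction falls through to the later rules with the reason recorded
   in its evidence.
3. **A5SS/A3SS** — the strand-aware donor boundary is unannotated
   while the acceptor boundary is annotated (A5SS), or conversely
   (A3SS).
4. **ATE** — a boundary equals a terminal-exon site: a coordinate on
   some transcript's first or last exon that is never an internal-exon
   boundary in any transcript of the gene. No principled rule exists
   for alternative transcript ends at junction level; this heuristic
   flags junctions into alternative first/last exons and is labelled
   as a heuristic in the documentation. Its literal form also flags
   first-intron junctions whose donor sits on every transcript's first
   exon; such junctions can only reach rule 4 after failing rules 1–3.
5. **UNCLASSIFIED**.

Rules 1 and 2 are given priority because they are the two rules with
explicit published definitions for this kind of analysis; 3 and 4 are
documented heuristics, in the order the categories are conventionally
listed. The partner set is *all tested* junctions of the gene sharing
an end — not only significant ones — because sharing a splice site is
an annotation property, not a significance property. The partner mean
is arithmetic by default (`partner_mean = "geometric"` is available).
Each significant junction receives exactly one category, so category
frequencies partition the significant set.

The classifier is verified two ways: hand-worked toy cases, and
exhaustive agreement with an independently written brute-force
interpreter of the same rules (plain loops over raw exon tables) on
hundreds of randomised toy loci covering skip variants,
retained-intron/NMD companions and novel-end junctions.

## Isoform-switch score

With per-condition summed long/short marker abundances and pseudocount
0.5 per isoform–condition cell, the score is the log2 ratio of ratios.
The pseudocount guarantees finiteness at zero counts and biases the
score toward 0 by a bounded, computable amount (about 0.05 at the
worked example's counts); the total-abundance fold change is reported
alongside so that "switch without total change" is directly visible.
Marker abundances may be isoform-exclusive junction counts (obtained
with `isoform_marker_junctions()`, the set difference of the two
transcripts' intron sets) or externally measured per-isoform
quantities; the formula is agnostic to the source. Optional
library-size normalisation rescales each sample to counts-per-million
before summation, which makes the score exactly invariant to
per-sample rescaling.

## Overlap and enrichment statistics

The hypergeometric overlap p-value is the exact upper tail
$P(X \ge k)$ including the observed $k$, by direct summation of the
hypergeometric mass — no normal approximation. The universe for
overlap questions should be the intersection of genes actually tested
in both analyses; the package requires the universe explicitly rather
than assuming a genome-wide background. Fisher's exact test is
two-sided by the probability-mass convention (sum of all
margin-compatible tables no more probable than the observed one).
Both are cross-checked in the tests against exhaustive enumeration
(all subset draws for universes up to 12; all 2×2 tables with margins
up to 15).

## Bliss synergy

Viability grids are normalised to the untreated control well and
converted to effects $E = \mathrm{clip}(1 - v, 0, 1)$; viability above
1 (growth stimulation) clips to zero effect and is flagged rather than
allowed to produce negative effects. Single-agent effects are read off
the zero-dose margins, so both dose vectors must include 0. No scalar
"synergy score" is canonical, so the package reports the whole excess
grid plus two summaries: the mean excess over combination wells (the
primary summary; 0 under independence) and the maximum excess with its
well. Replicates are averaged before effect computation.

## The synthetic-data generator

The generator is the ground-truth source for every end-to-end check,
so its defaults *are* the study conditions: biological triplicates
(3 vs 3), mean depth 100 reads per junction, a 4-fold usage-odds
effect on programmed junctions, Dirichlet concentration 50 for
between-sample usage variability, and NB dispersion 0.05 for
expression noise.

*Annotation.* Each gene gets a canonical multi-exon transcript
(4–8 exons, exon lengths 80–300 bp, introns 200–2000 bp). Event genes
additionally get the geometry their category needs: a skip-variant
transcript (so an in-between exon exists) for ES/EI; a retained-intron
companion for IR, retaining the intron *adjacent* to the programmed
junction so the programmed junction's own boundaries remain splice
sites of the companion — the only geometry under which the IR rule can
recognise it; an alternative-last-exon transcript for ATE. A5SS/A3SS
events use junctions at a *novel* donor or acceptor inside an exon
paired with an annotated partner site; the alternative site is
deliberately left out of the emitted annotation, because an annotated
alternative site could never satisfy the unannotated-donor/acceptor
rule — the event would be undetectable by construction.

*Counts.* Per gene, expression is log-normal around depth × junctions
(shared across samples); per sample, usage proportions are Dirichlet
around the gene's base usage; the per-sample gene total is negative
binomial and junction counts are multinomial given that total. Each
junction count is therefore marginally NB(depth × proportion) while
within-gene usage noise is exactly Dirichlet-multinomial — the model
family the usage test assumes, so calibration checks are meaningful.
Programmed usage shifts are exchanged *locally*: the programmed
junction trades mass with the junctions sharing one of its splice
sites (splice-site choice is a local competition), with the block
carrying 50–70% of the gene's junction output. A junction programmed
to gain usage starts as the minority choice of its block (15–35%); one
programmed to lose starts as the majority (40–60%) — the baseline a
gained alternative site realistically has. Shift directions follow
each category's definition: usage falls for ES and IR, rises for
EI/A5SS/A3SS/ATE. Per-gene random substreams are derived from the
master seed by stable string hashing of the gene id, so enlarging a
simulation leaves existing genes' data untouched.

*Dose matrices.* Single-agent effects follow Hill curves on an 8 × 6
dose grid (2-fold series plus zero-dose margins); combination effects
are the Bliss expectation plus a configured constant interaction,
observed through Gaussian replicate noise and renormalised to the
control well exactly as a measured plate would be. Default Hill
maxima (0.5 and 0.4) keep programmed interactions away from the
effect ceiling so recovery is unbiased.

*What the generator does not emulate:* mapping artefacts and alignment
uncertainty, GC/length biases, correlated dispersion across genes,
unbalanced library sizes, isoform-level coupling of junctions beyond
the local block, and multi-factor designs. Passing recovery and
calibration checks therefore demonstrates correctness of the
statistics and rules under a faithful but idealised sampling model,
not robustness to real-data artefacts.

## Problem sizes used by the checks

The calibration check runs 20 null datasets of ≥1000 junctions
(250 genes) each; recovery uses 100 programmed events (50 ES, 30 IR,
20 A5SS) across 110 genes; classifier–oracle agreement uses 200
random toy loci; exact-test enumeration covers all hypergeometric
configurations to N = 12 and all Fisher tables with margins to 15;
Bliss recovery averages 50 replicate plates. These sizes give stable
Monte-Carlo estimates while keeping the whole suite comfortably fast
on a single CPU.

## Known limitations

* The usage test conditions on gene totals and assumes a common
  intra-class correlation within a gene; junction-specific dispersion
  is not modelled.
* The ES/EI rule depends on the sign of a noisy partner mean; at weak
  effects junctions fall through to the site-annotation rules, which
  is visible in the evidence records.
* The ATE rule is a heuristic; alternative promoters and terminal
  exons are better resolved with dedicated end-sequencing data.
* Gene assignment of junctions is span + strand based with
  deterministic tie-breaks (splice-site match, then smaller span, then
  lexicographic id); overlapping same-strand genes can still be
  ambiguous in dense loci.
* The isoform-switch score quantifies relative enrichment; it does not
  model qPCR efficiencies or protein-level differences.
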