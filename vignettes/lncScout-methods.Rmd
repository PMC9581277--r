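---
title: "lncScout: models, parameters, and design of the lncRNA pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncScout: models, parameters, and design of the lncRNA pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

lncScout implements the standard desk-scale workflow for cataloguing long
non-coding RNAs (lncRNAs) from a merged, multi-tissue transcriptome
assembly: a filter cascade that separates lncRNAs from coding and artifact
transcripts, positional classification against the coding annotation,
comparative characterization, a tissue-specificity score, and
guilt-by-association function inference. This vignette explains each model,
the tunable parameters and why their defaults are what they are, the
synthetic-data generator used to validate the pipeline, and the numerical
and design choices that were genuinely open.

## The identification cascade

Input is a `TranscriptSet` (exon-resolved transcript models; coordinates
are 1-based and closed throughout the package — half-open conversions are
confined to the I/O layer) plus the genome sequence and a raw count matrix.
Four filters run in a fixed order, each recording its removals:

1. **Structure** — keep multi-exon transcripts at least `minLen = 200` nt
   long (inclusive) with known strand. 200 nt is the defining length bound
   of the lncRNA class; single-exon and strandless models from merged
   assemblies are predominantly fragments and are removed as one class
   each. Strand `"."` and absent strand are both treated as unknown.
2. **Exonic overlap** — remove candidates with ≥ 1 bp exonic overlap with a
   coding-gene exon *on the same strand*. The strand restriction is forced
   by internal consistency: an appreciable fraction of genuine lncRNAs is
   antisense to coding genes, and a strand-blind overlap filter would
   delete that whole class before classification. A `strandMode = "both"`
   flag exposes the stricter reading.
3. **Coding potential** — remove candidates whose longest *complete* ORF is
   ≥ `maxOrfAa = 100` amino acids (strict `< 100` retained). An ORF here is
   ATG through the first in-frame stop, scanned in the three forward frames
   of the spliced, strand-resolved sequence; 5'/3'-partial ORFs are not
   counted (unlike some TransDecoder modes) because the complete-ORF
   definition is reproducible and oracle-checkable, and only forward frames
   are scanned because splicing already resolves the strand. Codons
   containing `N` never match a start or stop. External
   coding-potential/homology tools are never invoked; their verdicts are
   importable TSVs. Where no imported verdict exists, a built-in
   ORF-coverage score `(3·aa + 3) / length` (clipped to [0, 1], 0 with no
   ORF) flags candidates above `builtinThreshold = 0.5` — a deliberately
   transparent stand-in heuristic, replaceable by real tool output.
4. **Read support** — keep candidates with at least `minReads = 6` raw
   reads. The sum over all samples is used: with per-sample or per-tissue
   readings being stricter, the total is the weakest sufficient reading of
   "supported by at least six reads", and the alternative is one argument
   away.

The funnel (step, `n_in`, `n_out`, removed ids, reasons) is the audit
trail; survivors are relabeled `biotype = "lncRNA"`.

## Positional classification

Classes are assigned by an explicit priority so that every transcript gets
exactly one deterministic label:

1. no overlap of the lncRNA span with any coding-gene span → **intergenic**;
2. exonic overlap with an opposite-strand gene's exons → **antisense**;
3. span contained in a single intron of a same-strand gene → **intronic**;
4. anything else → **other**.

Overlap is measured on gene spans for rule 1, exons for rule 2, introns for
rule 3 — matching each class's verbal definition. Antisense is tested
before intronic so that an intron-contained transcript that still touches
an exon on the opposite strand is called antisense. "Other" deliberately
absorbs same-strand intron-overlapping-but-not-contained and
opposite-strand intron-contained cases; published catalogues report such an
"other" bucket without defining it, and this absorption rule is the
smallest one that keeps the first three classes crisp. The partner gene is
the gene with maximal overlap under the deciding rule, ties broken by
smallest gene id.

## Normalization and characterization

Between-sample normalization is the trimmed mean of M-values (TMM),
implemented in the package: reference = sample whose library-size-scaled
upper quartile is closest to the mean; per sample, gene-wise log2 ratios
(M) and average log abundances (A) against the reference over
double-nonzero genes; two-sided trims of 30 % on M and 5 % on A; factor =
2 to the precision-weighted mean of the surviving M values; factors
rescaled to geometric mean 1. The 30/5 trims are the only published
parameterization of the method. The test suite cross-checks the
implementation against edgeR's `calcNormFactors` on random matrices — the
library is the oracle there, never the implementation.

FPKM is `counts · 1e9 / (length · libsize · factor)`; tissue-level
expression is the arithmetic mean of replicate FPKM (median available via
`tissueStat`), the simplest unbiased aggregate. GC content is
`(G + C) / (A + C + G + T)` with `N` excluded from the denominator (all-`N`
returns missing). Genome density uses fixed 50-kb bins from position 1;
each transcript is counted once, in the bin of its leftmost coordinate —
overlap-weighted assignment would double-count spliced transcripts for a
question ("where do lncRNAs cluster?") that only needs locations. Because
per-strand displays are common, bin tables carry pooled and per-strand
counts; correlations are reported per scaffold and pooled. Feature
summaries report group deciles, means and Wilcoxon rank statistics;
`log2(FPKM + 0.01)` uses a pseudocount to keep zero-expression transcripts
finite.

## Tissue specificity

For transcript *i* and tissue *j* of *n*, `F[i, j] = E[i, j] / Σ_j E[i, j]`
and the score is `max_j F[i, j]`, bounded by 1/*n* (uniform) and 1
(single-tissue). `n` comes from the design table (six tissues in the
motivating setting; the formula generalizes). Transcripts with all-zero
expression are excluded rather than scored — the formula is 0/0 there, and
a fabricated 0 would silently dilute group comparisons; they are counted
separately. The screen is strict: specific ⇔ score > 0.6; a score of
exactly 0.6 is not specific. Argmax ties break by lexicographic tissue
name for determinism. Whether `E` should be tissue means or pooled samples
is genuinely open; tissue means are used (replicate-count independent),
and the threshold-sweep table makes the choice inspectable.

## Function inference

Co-expression uses Pearson correlation over per-sample FPKM — not tissue
means, because with six tissues the t test on n − 2 = 4 degrees of freedom
makes adjusted p < 0.05 nearly unattainable even at r = 0.8, which would
turn the screen into a dead letter. P-values come from the t transform
`t = r·sqrt(m − 2)/sqrt(1 − r²)`; |r| = 1 maps to p = 0; zero-variance
profiles are excluded (undefined r) with a logged count. The
Benjamini–Hochberg family is per-lncRNA across all tested mRNAs (a
`family = "global"` option exists): the method is framed per lncRNA
("which partners does this lncRNA have?"), so the error rate is controlled
within that question. Edges require r strictly above 0.8 *and* adjusted p
strictly below 0.05.

Enrichment is the upper-tail hypergeometric test per (lncRNA, term):
background `N` = expressed mRNAs annotated in the namespace (the standard
universe — unannotated or unexpressed genes cannot be drawn), `K` = those
with the term, `n` = the lncRNA's selected partners in the background,
`k` = partners with the term; BH across terms within each lncRNA and
namespace; significant ⇔ adjusted p strictly below 0.1. Terms absent from
the selection (k = 0) score p = 1 rather than being skipped, so reported
families are comparable across lncRNAs. Profile reports count significant
lncRNAs per term within each tissue-specific group (and the non-specific
pool) and keep the top 20 by count.

## The synthetic-data generator

The generator exists to make every stage falsifiable: it plants known
truth and the tests ask whether the pipeline recovers exactly that truth.

*Genome and annotation.* Six scaffolds of 600 kb carry 100 coding genes
(4–8 exons, planted in-frame ORFs of 110–300 aa) and 100 lncRNAs in the
planted composition 70 intergenic / 19 antisense / 5 intronic / 6 other —
the composition reported for plant lncRNA catalogues of this kind. lncRNA
sequences are made non-coding *constructively*: a stop-bearing 12-mer
(`TTAATTAATTAA`, one stop per frame) is woven in at least every 45 nt, so
no reading frame can run 100 aa regardless of chance ATGs — a guarantee by
construction, verified again at generation, rather than rejection
sampling. Antisense lncRNAs share exactly 150 bp of exon with an
opposite-strand host gene (the inherited bases are the host's, so the
guarantee there is the arithmetic one: ≤ 50 inherited codons plus
frame-broken flanks stay under 100 aa, and the generated object is
re-verified). Five decoys per class each violate exactly one filter:
short (< 200 nt), single-exon, strandless, long-ORF (120–200 aa), and
low-support (total counts ≤ 5 planted directly). lncRNAs are built
shorter (280–800 nt), with fewer exons and AT-richer (GC 0.33 vs 0.45)
than mRNAs, reproducing the comparative signatures the characterization
stage is meant to detect. Truth labels never leak: the annotation exposes
only `coding`/`candidate` biotypes.

*Counts.* Negative binomial, mean = baseline × biotype ratio ×
(length/1 kb) × tissue multiplier × block factor × library factor.
Defaults: baseline 200 (deep libraries), lncRNA ratio 0.25 (lncRNAs are
lowly expressed), dispersion 0.04 — a biological CV of 0.2, the standard
figure for replicate libraries of near-isogenic material such as a clonal
cultivar; dispersion 0 degenerates to Poisson. Library sizes are
log-uniform over a 4× range so TMM has real work to do. 40 % of lncRNAs
and 10 % of mRNAs get a planted specific tissue with fold 25, putting the
expected max fraction at 25/(25 + 5) ≈ 0.83 — clearly above the 0.6
screen while leaving a tunable hard regime. Three co-expression blocks of
8 coding + 2 lncRNA members share a per-sample log-normal latent factor
with sdlog 2. Two design constraints fix that value and shape. First, with
multiplicative noise of squared CV `v = 1/μ + φ`, the raw-scale Pearson
correlation between two members is bounded by `1/sqrt((1+v₁)(1+v₂))` no
matter how strong the shared factor, so recovering blocks through an
r > 0.8 screen requires both a dominant factor and modest residual noise —
hence sdlog 2 together with the dispersion and baseline above. Second, the
factor is rebalanced to mean 1 within each tissue's replicates, keeping
the co-expression axis orthogonal to the tissue axis: without this, block
spikes concentrate in single tissues and fake tissue specificity.
Emulating co-regulated modules as tissue-balanced is the generator's
choice for clean separability of the two planted structures; real modules
are often themselves tissue-driven, which is one reason real-data
performance is not implied by these recovery tests (see Limitations).

*Term map.* Coding genes draw 3 background GO-BP and 2 KEGG terms
uniformly; each block's planted BP and KEGG terms attach to its coding
members with probability 1 and to outsiders at the 2 % background rate.
Setting the planted fraction equal to the background rate produces a null
map for type-I checks.

## Numerical choices and degenerate inputs

- Exons overlapping within one transcript are merged with a warning
  (tolerant of assembler artifacts) rather than rejected.
- `N` bases: complement of `N` is `N`; `N` counts as neither G nor C; codons
  with `N` never start or stop an ORF.
- TMM: all-zero rows are dropped; two libraries with no common nonzero gene
  get factor 1 with a warning; an all-zero library is an error.
- Correlation p-values at |r| = 1 are set to 0 exactly rather than left to
  the singular t transform.
- The hypergeometric tail is computed in log space via `phyper`; BH via
  `p.adjust` behind a validating wrapper.
- All generator randomness flows from one integer seed; the same seed gives
  byte-identical FASTA/GTF/TSV outputs, and the pipeline itself is
  deterministic given its inputs.

## Problem sizes used in validation

The default validation dataset is 225 transcripts (100 coding, 100 lncRNA,
25 decoys) on 3.6 Mb of genome with 18 libraries — large enough that every
planted structure is statistically resolvable, small enough to iterate on.
The test suite checks the ORF finder against a brute-force enumeration on
200 random sequences, overlap/classification against naive all-pairs
oracles on 20 random 500-transcript annotations, specificity algebra on
10,000 random vectors, the hypergeometric tail exhaustively for all N ≤ 12,
specificity recovery over 10 seeded count replicates, and co-expression /
enrichment recovery over 20.

## Limitations

- The generator plants clean, separable structure; passing its recovery
  tests demonstrates correctness of the computations, not performance on
  real assemblies, where fragmentation, isoform overlap, positional class
  ambiguity and tissue-driven co-expression are all harsher.
- Read-level artifacts (alignment, assembly, quantification) are upstream
  of this package and are not simulated; counts are an input.
- The built-in coding score is a stand-in; real studies should import
  verdicts from dedicated coding-potential and homology tools.
- GO graph structure is ignored (no term propagation); enrichment treats
  terms as flat labels.
- Sense-overlapping exonic lncRNAs are removed upstream by design, and
  bidirectional-promoter classes are not modeled.
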