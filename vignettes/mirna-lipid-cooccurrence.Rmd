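---
title: "Methods: literature co-occurrence mining of miRNA-lipid disease associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: literature co-occurrence mining of miRNA-lipid disease associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirlipidnet)
```

## The model

The pipeline rests on the co-occurrence assumption of literature mining: two
entities mentioned in the same abstract are taken to be associated, and the
abstract is the unit of counting. For a miRNA $m$ and a disease/identifier
group $g$, the corpus of $n$ abstracts partitions into a 2×2 table

|            | $g$ mentioned | $g$ not mentioned |
|------------|---------------|-------------------|
| $m$ mentioned | $a$ | $b$ |
| $m$ not mentioned | $c$ | $d$ |

Under the null hypothesis that $m$ and $g$ are mentioned independently, and
conditioning on both margins, $a$ follows the hypergeometric distribution
with point probability

$$P(a) = \frac{(a+b)!\,(c+d)!\,(a+c)!\,(b+d)!}{a!\,b!\,c!\,d!\,n!}.$$

The association statistic is the one-sided (enrichment-tail) Fisher exact
p-value $P(A \ge a)$ — one-sided because the question is specifically
whether the pair co-occurs *more* than independence predicts; a deficit of
co-mentions is not evidence of association. Pairs with $a = 0$ are not
scored: under the co-occurrence assumption there is no observation to test,
and emitting them would only pad the output with $p = 1$ rows. No
multiple-testing correction is applied at this stage (the raw $p \le
\alpha$ rule is the stage's published convention; an optional
Benjamini–Hochberg flag exists but is off by default). Correction does
appear in the GO stage, where the tested family is well defined.

Ranking uses ascending p-value with ties broken by descending
supporting-paper count ($a$) and then lexicographic miRNA name in the C
locale. The tie-break is our choice — the source convention is silent — and
it is the one that reproduces the published ordering of top-20 tables in
which many pairs share one p-value.

### Numerical choices

* All tail sums are computed in log space (`lgamma`) with max-subtraction,
  stable for corpora up to $n \approx 10^5$.
* Exactness is enforced by tests against an independent enumeration oracle
  (direct `choose()` products, exact in double precision for $n \le 25$) at
  relative tolerance $10^{-10}$, and against `stats::fisher.test` /
  `stats::phyper` as independent library routes.
* Strict monotonicity of the tail in $a$ is asserted wherever the removed
  point probability is resolvable above the tail's accumulated rounding
  (relative $10^{-12}$); below that the two tails coincide in double
  precision and no floating-point implementation can distinguish them.
* A formula for this test that circulates in the applied literature
  duplicates the $(c+d)!$ factor; that version does not normalize to 1 over
  the admissible range of $a$. We use the standard numerator
  $(a+b)!(c+d)!(a+c)!(b+d)!$, and the normalization test (sum of point
  probabilities $= 1 \pm 10^{-12}$) guards the choice.

## Entity recognition

Recognition is deterministic dictionary-plus-pattern matching rather than
statistical NER: the variant families of miRNA nomenclature are finite and
documented, and determinism is what makes the corpus → scores path
reproducible. The recognizer handles, case-insensitively and word-boundary
anchored: stem spellings (`miR`, `miRNA`, `MiRNA`, `MicroRNA`), species
prefixes (`hsa-`), precursor prefixes (`pre-`), loci/variant suffixes
(`miR-1a-1`), the historical names `lin-4` and `let-7`, and compound
abbreviations (`miR-221/222`, `miR-33a/b`, `miR-15 & –16`). En-dashes are
canonicalized to ASCII hyphens before matching, since published text mixes
them. Offsets are 0-based half-open into `title + "\n" + body`, and every
span's `matched_text` equals the text slice — a property the tests verify on
generated corpora.

Two deliberate policies:

* **Longest match wins.** `HDL` and `HDL-Cholesterol` are distinct
  identifier groups; an abstract containing only the longer form counts
  only toward the longer group. A group is counted at most once per
  abstract.
* **Compound mentions are their own pair key by default.** Published
  association tables list `miRNA-33a/b` alongside `miRNA-33a` and
  `miRNA-33b` as separate rows, so crediting policy is genuinely ambiguous.
  `normalize_mirna_mention()` always returns the expanded member ids (with
  the compound key as an attribute); `annotate_corpus(expand_compounds =
  FALSE)` (default) counts the compound as one key, `TRUE` credits the
  members. Ground-truth round-trip tests run with expansion on, matching
  how the generator records intent.

Tokens that match the pattern but resolve to no lexicon entry are returned
with an `unnormalized` flag — never silently dropped — so lexicon gaps are
visible in the mention TSV.

## The synthetic world

`generate_corpus()` emulates the corpus this kind of study works from, with
defaults chosen once as the stated world of the validation suite: 300
abstracts, planted pairs with co-mention probability 0.6, background
mention probability 0.05 per entity. Each abstract is dedicated round-robin
to one planted pair; with probability `p_comention` both of its entities
are mentioned there; every configured entity additionally appears with its
background probability. Each intended miRNA is rendered exactly once, in a
surface form drawn from the documented variant families; each intended
group via one of its synonyms. Filler text comes from a fixed vocabulary
that is checked against both recognizers at generation time, so corpus
noise cannot masquerade as an entity. If sampling leaves a planted pair
with zero co-mentions, the pair is forced into its first dedicated abstract
and the intervention is recorded in the ground truth (`forced_pairs`) —
coverage is guaranteed without quietly re-rolling the dice.

What the generator does **not** emulate: real linguistic structure,
negation or hedging ("miR-122 was *not* associated with..."), cross-sentence
anaphora, mention-frequency effects within an abstract, and the skewed
disease marginals of a real retrieval query. A green round-trip therefore
establishes that recognition is exact on well-formed mentions of every
variant family — not that recall on real prose is 100%. Likewise the
planted-recovery test establishes the scoring chain's sensitivity and the
null calibration its specificity *under independence*, not robustness to
topical correlation between diseases.

The null-calibration check reads "type-I error at most $\alpha$" over all
candidate miRNA × group pairs, counting never-co-occurring (untested) pairs
as non-significant. Fisher's exact test is conservative by construction, so
the observed fraction is compared against the upper 95% binomial bound at
$\alpha = 0.05$; a two-sided band around $\alpha$ would wrongly fail the
test for being conservative.

The miRNA lexicon shipped in `inst/extdata` is likewise synthetic: it
contains every miRNA named in the published tables this pipeline's output
schema mirrors, topped up with generated miRBase-style names and MIMAT-style
accessions to reach the documented 148-entry floor. It is a stand-in, not a
miRBase excerpt.

## Network extension and the overlap threshold

RegINs (regulatory interaction networks) are directed regulator → target
edge lists, one per source database, read from XGMML or TSV.
`extend_network()` unions the seeds' interactions across sources and
annotates each edge with its supporting source set; `overlap_threshold(k)`
keeps edges with $\ge k$ distinct supporting sources ("or more", so with
three loaded sources $k = 3$ coincides with per-seed set intersection — an
identity the tests verify independently); `hide_sources()` is
non-destructive (support is recomputed over visible sources; unhiding
restores the network exactly). Three laws are enforced as properties:
threshold composition (applying $k_1$ then $k_2$ equals $\max(k_1,k_2)$),
monotone shrinkage in $k$, and hide/unhide round-trip.

Gene identifiers are treated as opaque symbols; no cross-database gene-ID
harmonization is attempted (real databases disagree; the synthetic fixtures
use one namespace). Seed miRNAs enter as miRBase-style accessions; the
lexicon's name ↔ accession mapping bridges the association stage's
canonical names, expanding compound keys into their members first. The
four-way seed-set split used by published accounting tables is a
configuration option (`seed_sets`), not a constant.

## GO overrepresentation

Annotations are closed under `is_a` ancestry (the true-path rule) before
counting — the standard behavior of GO enrichment tools; a
`propagate_annotations = FALSE` escape hatch preserves raw-annotation
counting since the source convention does not state propagation explicitly.
For each term with at least one annotated query gene, the right-sided
hypergeometric p-value $P(X \ge k)$ is computed with $N$ = background
universe size (default: all genes in the annotation table), $K$ = universe
genes annotated to the term, $n$ = query size, $k$ = annotated query genes.
Terms with $k = 0$ are not tested and do not enter the BH family — this
changes the family size $m$ and hence the adjusted values, and is
documented for that reason. Significance is flagged on the BH-adjusted
p-value at $\alpha$ by default (`correct = "raw"` restores raw-p
filtering). Published "total genes" columns in comparable tables are not
reconstructible as per-term background counts; this package defines
`total_genes` as the propagated per-term universe count and documents the
divergence.

## Pipeline and determinism

`run_pipeline()` executes the five stages over files, logging per-stage
input/output counts to the console and aborting with the stage name on any
failure. Every artifact is listed in a manifest with its MD5 hash; numeric
output is formatted to fixed precision (`%.2E` in tables, `%.12g` in graph
attributes) and file lists are sorted in the C locale, so identical inputs
and seed give byte-identical output across platforms and locales. The one
random component is fixture simulation; all randomness flows from its
single integer seed (sub-seeds `seed + 1..3` for the RegIN overlap design,
RegIN sampling and the GO fixture).

## Known limitations

* Abstract-level counting cannot distinguish co-mention from asserted
  association; negated findings count as co-occurrences.
* The recognizer's compound expansion assumes the member-id conventions of
  miRNA nomenclature (`/222` → same stem, `/b` → letter-suffix swap);
  unconventional compounds resolve to flagged, unnormalized spans.
* With very small corpora the exact test is strongly discrete: the
  attainable p-values jump, and calibration statements only hold in the
  conservative direction.
* The package deliberately stops at standard graph files (GraphML, SIF,
  XGMML, TSV); layout and interactive visualization belong to downstream
  viewers.
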