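---
title: "The host-gene method: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The host-gene method: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirhost)
```

## The method in one paragraph

Intragenic miRNAs — precursors embedded on the sense strand within introns
or exons of protein-coding genes — share transcriptional context with their
host genes and are frequently co-expressed and co-dysregulated with them.
`mirhost` turns a miRNA differential-expression table into (i) a host-gene
list for the dysregulated miRNAs, built under explicit cluster and
sequence-family rules, (ii) a co-dysregulation statistic linking miRNA and
host-gene dysregulation, and (iii) a hypergeometric over-representation
analysis of the host-gene list. The key premise is specificity: a miRNA has
exactly one genomic host (possibly several only through sequence-identical
paralogs), whereas it has hundreds of noisy predicted targets, so the
host-gene route yields compact queries and sharp hypotheses.

## Host assignment

**Containment, not overlap.** A precursor is intragenic only when a gene
span fully contains it. Partial overlap at a gene edge is called
intergenic: half-in cases are ambiguous about shared transcription, and a
hard rule keeps the classification a partition (each precursor gets exactly
one of `intragenic_sense`, `intragenic_antisense`, `intergenic`).

**Precursor-level classification.** The precursor interval drives the call;
matures are sub-intervals, so their context could differ only at exon/intron
boundaries, and the hairpin is the transcriptional unit that actually sits
in the host.

**Sense strand only.** Only same-strand protein-coding containers confer a
host. Opposite-strand containment is reported as `intragenic_antisense`
(no host), and containment by non-coding genes is retained in an audit
column but never assigns a host.

**Nested and overlapping genes.** When several same-strand coding genes
contain a precursor, the smallest span wins (the most specific container),
with lexicographic gene-id tie-breaks so output is deterministic; the
remaining containers are reported as alternates rather than dropped.

**Sublocation.** Against the chosen container's transcripts, a precursor is
`exonic` if fully inside an exon of any transcript, else `intronic` if
fully inside an intron of any transcript, else `junction`. Two open choices
are resolved here. First, a precursor exonic in one isoform and intronic in
another is called exonic — the presence of *any* exonic isoform means the
mature can derive from spliced message — and the disagreement is flagged
(`isoform_disagreement`) instead of silently coerced. Second, `junction`
is kept as its own label: boundary-straddling cases are rare and a user
should see them, not receive a coerced intron/exon call. Genes with no
annotated exon structure are usable through a flagged pseudo-exon spanning
the gene; host calls against them carry `confidence_flag =
"pseudo_exon_gene"`.

**Clusters.** Polycistronic clusters are detected by single-linkage
chaining of same-chromosome, same-strand precursors with gaps of at most
`max_gap` (default 10,000 bp — the conventional polycistron window; no
value is fixed by the method itself, so it is a flag). Clusters are
reported for audit; the "count a cluster's host once" rule needs no special
code because the host-gene list is a set union.

## Families and the expansion rule

Distinct precursors can produce byte-identical mature sequences
(miR-103a-1-3p and miR-103a-2-3p are the canonical example); sequencing
cannot attribute such a read to one precursor, so a detected dysregulation
must be credited to the host genes of *every* precursor in the family.
"Indistinguishable" is exact full-length mature-sequence identity after
normalisation (uppercase, U→T): seed-level families would over-expand far
beyond what the detection ambiguity justifies. The -5p and -3p products of
one precursor are never merged — they are distinct molecules with distinct
sequences. Without a sequence table, matures fall back to id-keyed
singleton groups, which reduces expansion to direct host lookup (and still
groups matures that share a detection id, as identical miRBase matures do).

## Selection and co-dysregulation

Selection is a strict `padj < 0.1` by default, with no fold-change filter
(`min_abs_log2fc = 0`): the adjusted-p criterion alone defines
dysregulation, both directions kept and labelled. The boundary is strict —
`padj = 0.1` exactly does not pass.

Co-dysregulation counts **miRNAs, not genes**: a dysregulated host carrying
two dysregulated miRNAs contributes two, which is what makes a statement
like "12 of 71 intragenic dysregulated miRNAs (16.9%) sit in dysregulated
hosts" well-defined. The denominator is the number of distinct selected
matures with at least one sense-strand host; a family-expanded mature
counts once and is co-dysregulated if *any* of its hosts is in the
dysregulated-gene list. The dysregulated-gene list is an explicit input (a
gene DE table or flat list) — in the motivating literature it came from
manual curation, which is not implementable, and an explicit input keeps
the statistic recomputable. The attached hypergeometric overlap p-value is
an audit statistic added by this package (not part of the original method);
it is computed at the gene level (distinct co-dysregulated hosts among
distinct hosts drawn from a universe of stated size) because gene draws,
unlike miRNA counts, are exchangeable under the null.

## Enrichment

One-sided over-representation only: the question is which pathways the
host genes point to, not depletion. `p = P(X ≥ k)` for
`X ~ Hypergeom(N, K, n)` is evaluated through the log-space hypergeometric
CDF so extreme tails do not underflow, and BH (step-up) FDR is the default
correction (Bonferroni by flag). Terms with in-universe size outside
`[min_term_size = 3, max_term_size = 2000]` are not tested — degenerate
terms produce unstable p-values. Ties in p break lexicographically by term
id, and results are invariant to input ordering.

**The universe matters.** The default background is every protein-coding
gene of the annotation that appears in at least one collection term. The
`host-capable` option restricts to genes hosting at least one annotated
miRNA, which controls host-selection bias (only ~half of miRNAs have hosts,
and hostable genes are not a random sample of pathways); `gmt-union` uses
the whole collection vocabulary, which is the right choice for simulated
collections whose filler genes are not in the annotation. The choice
materially shifts p-values, so it is an explicit argument, never implicit.

## The synthetic generator

The generator emulates the *statistical structure* of a host-gene study,
not genomic realism. Defaults mirror the motivating study's conditions:
240 precursors of which ~45% are sense-intragenic, 71 dysregulated
intragenic detection ids, a co-dysregulation rate of 12/71, three
sequence-identical families across distinct hosts, two intronic clusters,
two nested gene pairs, and one planted 100-gene term holding half of the
dysregulated host genes against a 5000-gene universe. Geometry is
schematic: genes sit on a regular two-chromosome lattice (4 × 1200 bp exons,
8 kb introns, 25 kb spacing) so that every planted context is unambiguous
and the pipeline can be held to exact truth recovery. Dysregulated
intragenic ids are chosen with pairwise-disjoint host sets, which makes the
generated co-dysregulation count exactly `Binomial(71, 12/71)` — without
that constraint, shared hosts (clusters, families, both arms of one
precursor) would inflate the count beyond the configured rate. DE tables
are generated at the summary level (padj placed strictly below/above the
0.1 threshold), not from read counts; expression modelling is out of scope.

What passing closed-loop tests therefore shows: the geometry, family,
selection, set-construction and enrichment machinery is exact under clean
annotations. What it does not show: robustness to messy real annotations
(isoform soups, fragmented assemblies, biotype vocabulary drift) beyond the
specific edge cases unit-tested (nested genes, junction straddles,
pseudo-exon genes, antisense containment, orphan records).

One config field differs from a naive reading of "number of dysregulated
miRNAs": the count is split into intragenic and intergenic components
(`n_dysregulated_intragenic`, `n_dysregulated_intergenic`) because the
co-dysregulation statistic conditions on the intragenic count and the
generator must pin it exactly.

The packaged `dmd_example_bundle()` preserves only containment, strand,
intron/exon and sequence-identity relations from the DMD literature
(PANK1/2/3 hosting miR-107/-103a-2/-103a-1; USMG5 hosting miR-1307, all
arms down); its coordinates are invented placeholders and are documented as
such.

## Numerical and testing choices

- **Coordinates** are 0-based half-open everywhere internally; GFF3 (1-based
  inclusive) converts exactly once at the I/O boundary, and BED export is
  the internal convention verbatim. This gives a single conversion site and
  uniform interval arithmetic.
- **Determinism.** All randomness flows from one seed through the
  generator; writers emit fixed attribute orders, so identical seeds give
  byte-identical bundles and pipeline outputs.
- **Discreteness-aware calibration.** Hypergeometric p-values are discrete,
  so `P(p < 0.05)` under the null is at most, and typically below, 0.05.
  Validating type-I behaviour against a ±binomial band around 0.05 is only
  meaningful for term/query sizes whose *achievable* level sits near the
  nominal one; the calibration suite therefore uses a universe of 5000, a
  query of 150 and nine disjoint terms (sizes 67, 89, 210, 236, 262, 315,
  370, 397, 425) chosen analytically from the exact null so each achievable
  level is ≥ 0.049. With arbitrary sizes, the test would flag conservatism
  as miscalibration.
- **Problem sizes in the suite** (a deliberate trade of breadth for depth):
  oracle equivalence runs exhaustive subset enumeration for all
  hypergeometric configurations with N ≤ 12 and an all-pairs containment
  scan over 200 randomised annotations; calibration uses 500 replicates;
  planted-term recovery 100 replicates at the full default configuration;
  the binomial co-dysregulation check 200 seeds at a reduced lattice.
- **Degenerate inputs** have defined behaviour rather than errors where a
  valid interpretation exists: empty gene list → all intergenic (warned);
  empty selection → empty host set (warned); zero intragenic miRNAs →
  co-dysregulation rendered `NA`; queries outside the universe → dropped
  before testing; unmapped miRNAs → reported lists, not failures.

## Known limitations

- Only ~half of a typical miRNA complement is interpretable by the
  host-gene route at all; the intergenic half is untouched by design.
- Host assignment is purely geometric; it does not use expression evidence
  to decide whether a miRNA is actually co-transcribed with its host.
- The enrichment engine is a generic ORA; network/upstream-regulator
  analyses of the kind offered by proprietary platforms are out of scope,
  as is miRNA target prediction (targets are consumed as a precomputed
  mapping) and any non-canonical (nuclear/promoter-level) miRNA activity.
- GTF input and genome-sequence handling are not supported in this version.
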