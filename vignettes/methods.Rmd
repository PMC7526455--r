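---
title: "Methods: prioritizing functional noncoding variants and their target genes"
author: "funsnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prioritizing functional noncoding variants and their target genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

funsnp chains six analysis stages, each a filter that conjoins
independent lines of evidence: variant curation, epigenetic functional
scoring, allele-specific regulatory evidence, target-gene prediction, TF
network assignment, and drug-target prediction. The design principle
throughout is *conjunction of orthogonal evidence with explicit
thresholds*: no stage learns weights from labels, so every decision is
auditable and the whole chain can be validated against planted ground
truth.

# Variant curation

Tag SNPs (genome-wide significant, noncoding) are expanded through
linkage disequilibrium: any SNP with r² > 0.8 to a tag joins the
*positive* set and inherits the union of the tags' disease labels. r² is
the standard haplotype-frequency formula
(p_AB − p_A p_B)² / (p_A(1−p_A) p_B(1−p_B)), equal to the squared
Pearson correlation of the 0/1 allele indicators; unphased genotypes are
not supported — users supply precomputed LD tables, which avoids
re-implementing EM phasing. Loci are the merged ±1 Mb windows around
tags with any MHC overlap cut out (default MHC chr6:25–35 Mb, hg19-style
and configurable, since no canonical boundary exists; truncation may
split a locus). Noncoding SNPs inside loci are *background*; noncoding
SNPs outside loci and the MHC with r² < 0.1 to every GWAS-catalog SNP
are *negative*. Classes obey the precedence positive > background >
negative, which resolves tags that are their own proxies; anything left
(coding SNPs outside loci, catalog-linked SNPs) is `excluded` and
reported. The background set deliberately includes the positives when
enrichment denominators are formed — the fold-change formula uses *total*
background counts, and at realistic scales the positives are a
vanishing fraction of the background.

Coordinate conventions: SNP positions are 1-based (VCF), interval files
0-based half-open (BED), and the conversion lives in exactly one
function (`overlap_annotate()`: annotated iff pos−1 ∈ [start, end)), so
off-by-one drift cannot accumulate.

# Epigenetic scoring

One *feature* is one annotation in one cell type, in one of four
categories (chromatin states, histone marks, DHS, TFBS). Enrichment of
positives over background uses the Pearson χ² statistic without
continuity correction; when any expected cell drops below 5 the exact
test substitutes, recorded in the result's `method` field. The Bonferroni
denominator is the *total* feature count across categories, not
per-category — matching a single family-wise error budget over the whole
feature screen. Selection requires FC > 1 *and* p < α/N; the two-sided
exact p is direction-blind, so the FC > 1 conjunct supplies the
direction.

The category score S = Σ FC·B is a weighted count, hence monotone:
gaining an overlap can never lower a score. Support calls use the
empirical null of the negative set: the threshold is the nearest-rank
95th percentile (the ⌈0.95·n⌉-th order statistic — no interpolation, so
the guarantee "at most 5% of nulls exceed it" holds exactly on any
distribution, including heavily tied ones), and support requires a
*strictly* greater score, so ties at the threshold fail. Scoring
streams SNPs in chunks (default 50,000) so genome-scale negative sets
never materialise a full incidence matrix.

# Allele-specific evidence

The motif scanner scores log2 odds of a pseudocounted probability matrix
(p′ = (p + c)/(1 + 4c), default c = 0.001) against a background base
distribution, on both strands. **Numerical choice:** the window score is
the sum of per-cell log-odds *discretized at 1e-3 log2 units*, and the
null distribution of that integer-valued score is computed exactly by
dynamic programming over the same lattice. P-values are therefore exact
for the score actually used and reproducible bit-for-bit given the
configuration; the tie rule includes masses up to a 1+1e-7 relative
factor. The reverse strand gets its own null, which differs from the
forward one only under a skewed background.

A motif call is allele-specific when exactly one allele's best
SNP-overlapping hit passes p < 1e-4 — a presence/absence criterion
(gain = alternate allele passes, loss = reference passes). A score-delta
criterion was the alternative; presence/absence was chosen because it
needs no second threshold and composes cleanly with the ≥ 2-database
consensus rule (same uppercased TF name, same direction). The TF
expression filter (RPKM > 1 in ≥ 1 configured immune cell type) is
applied from a user table and bypassed with a warning when absent.

Molecular QTLs count only when *local* (SNP inside the molecular peak)
and FDR < 0.1, with Benjamini–Hochberg applied within dataset when a
precomputed FDR is absent. The functional call is the conjunction:
≥ 1 supported epigenetic category AND ≥ 1 allelic evidence.

# Target genes

cis-QTL support requires FDR < 0.05 and ≥ 2 distinct datasets per
SNP-gene pair. Chromatin-interaction support counts datasets whose
contact has the SNP in one anchor and a promoter window of the gene in
the *other* anchor (both orientations); promoter windows default to
±1,000 bp per TSS — "1 kb surrounding TSS" is read as ±1 kb, exposed as
a 0.5–10 kb configuration because published robustness checks across
1–10 kb definitions show the choice is not load-bearing.

Colocalization follows the single-causal-variant Bayesian framework:
per-SNP Wakefield log approximate Bayes factors
0.5·(log(1−r) + r·z²) with r = W/(V+W), prior effect s.d. √W = 0.15
(quantitative) or 0.2 (case-control) — the conventional defaults of the
cited framework, since no values are stated — and priors p1 = p2 = 1e-4,
p12 = 1e-5, combined in log space with a log-sum-exp guard. When only
p-values are available, |z| is recovered from the two-sided p (signed by
beta when present) and V approximated from sample size and allele
frequency.

The PICS variant assigns each locus SNP a causal probability
proportional to the Normal density of the observed lead association
(−log10 p = S) under causality of that SNP: mean r²·S, s.d.
√(1−|r|^3.2)·√S/2. The exponent 3.2 and scale 1/2 come from the cited
fine-mapping literature, not measured here, and are isolated behind
function arguments. Perfect proxies (|r| = 1) have a degenerate spike
density and share the point mass equally — the natural limit of the
formula. PICS-based colocalization conditions on both traits having a
fine-mapped signal (a credible set presupposes an observed association),
so PP0–PP2 carry no mass and PP3/PP4 normalise the distinct mass
Σ_{i≠j} g_i q_j weighted by p1·p2 against the shared mass Σ g_i q_i
weighted by p12; disjoint SNP universes give PP4 = 0 with a warning.
This conditioning makes the PICS PP4 systematically more liberal than
the ABF PP4; it agrees with it in *rank* (shared loci above distinct
loci), which is what the pipeline uses it for.

A pair is predicted iff SNP functional ∧ ≥ 2 QTL datasets ∧ max PP4 >
0.8 ∧ (local ∨ ≥ 2 interaction datasets) — a monotone conjunction:
removing any evidence table can only shrink the prediction set. A gene
is *local* iff every predicted pair is local, else *distal*;
`exclusively_distal` additionally marks genes with no local pair.

# TF networks

TF enrichment compares, per allele-specific motif TF, functional SNPs
with predicted targets against all positive SNPs (Fisher exact, FC > 1,
Bonferroni over the TFs tested; the two groups are nested, as in the
source comparison). Direct edges inherit the pair class (local/distal);
indirect edges traverse exactly one mediating enriched TF whose encoding
gene is a direct target — one hop only, which excludes cycles and keeps
the model identifiable. Whether indirect targets already reached
directly should be dropped is genuinely ambiguous, so both tallies are
reported and a `dedup_indirect` flag controls it (default off). The
covering-TF report uses a greedy set cover (largest remaining coverage,
ties by TF name, hence deterministic); exact minimality is verified by
enumeration only on small instances in the tests.

# Drug targets

Tiers: *high* immune relevance = pathway, mouse-knockout (IMPC) or
Mendelian (OMIM) support; *suggestive* = blood expression (RPKM > 1),
tissue-specific expression (pSI < 0.01), DisGeNET association or SMR
causality (consumed as an input already filtered at FDR < 0.05 with
heterogeneity p > 0.05); else *none*. The over-representation test is
one-sided hypergeometric with BH correction, ties broken by pathway id
for reproducibility. Druggability needs ≥ 2 curated resources; strong
PPI means score strictly > 0.9. A new drug-target prediction (A, B, C)
requires (a) strong PPI between A and drug gene C indicated for
autoimmune disease B, (b) both A and C regulated by functional SNPs
predisposing to B — implemented as exact disease-label equality, with no
ontology expansion, per the rule's literal wording — and (c) A druggable
or already drugged; A ≠ C, predictions deduplicated per (A, B), with a
repurposing flag when A's existing drugs treat some other disease.

# The synthetic-data generator

`generate_fixture()` emulates the structure of every input family:
tag/proxy LD structure, class-defining loci with an MHC-straddling tag,
epigenetic peak sets with planted fold enrichment, motif libraries in
two database formats with consensus matches destroyed by alternate
alleles, molecular and cis-QTL tables, BEDPE contacts, per-gene
GWAS/QTL summary statistics, function/drug/PPI tables — with a JSON
truth manifest. Signals are planted *constructively* (e.g. every planted
functional SNP is covered by every enriched feature and carries a
two-database motif whose consensus the alternate allele breaks) and
decoys miss exactly one evidence leg (single-dataset QTL pairs,
single-dataset contacts, null-colocalization loci, non-functional SNPs,
sub-threshold PPI, single-resource druggability, unregulated partners).
Randomness uses one labelled sub-seeded stream per output family, so
adding an output never perturbs the others and a fixed seed reproduces
the bundle byte-for-byte.

Default conditions: 2 chromosomes × 10 Mb; 20 tags over 3 diseases, 4
strong proxies (r² 0.85–0.99) and 2 weak decoys per tag; 4,000
background and 4,000 negative SNPs; 16 enriched features (4 per
category) at target FC 3 over a 10% background annotation rate among 24
nulls; 30 planted functional SNPs and 10 epigenetic-support-only decoys;
3 local and 6 distal planted genes (distal TSS offsets 80 kb; two SNPs
per distal gene); colocalization loci of 60 SNPs at n = 5,000 with 0.6
s.d. causal effects; 2 planted enriched TFs (one seeding an indirect
edge through the gene encoding the other) and 2 drug triples. These
sizes make the full pipeline run in well under a minute on one CPU while
keeping every statistical decision (Bonferroni margins, null
percentiles, Fisher enrichment) comfortably away from its threshold —
they were chosen from power arithmetic, e.g. the planted TF splits give
Fisher p ≈ 0.002–0.003 against a 0.025 Bonferroni bar.

What the generator does **not** emulate: realistic human LD maps (block
LD only), realistic motif databases (a handful of near-consensus PWMs),
overlapping loci between diseases, allele-frequency spectra, winner's
curse in tag selection, or correlated epigenetic features. Passing the
end-to-end test therefore demonstrates that the evidence chain is wired
correctly and recovers constructively planted signals at designed
strengths — not that the thresholds are optimal for real data.

The colocalization simulator draws z ~ MVN(Rλ, R) with block LD
(20-SNP blocks, r = 0.95^|i−j|) and non-centrality
effect·√n·√(2f(1−f)) at the causal SNP; a Cholesky failure triggers a
1e-6 diagonal jitter with a message.

# Numerical choices and degenerate inputs

* Fisher two-sided p: point-probability rule over dhyper masses with the
  customary 1+1e-7 tie tolerance, clamped at 1; zero-margin tables are
  degenerate (statistic 0, p 1, flagged).
* Fold change: annotated background of zero returns +Inf (flagged)
  rather than an error, so an all-positive feature is visible.
* Percentages round half away from zero, 1 decimal for headline
  summaries and 2 in tables; pair distances are measured to the nearest
  TSS of the target gene, since no anchor is canonically defined.
* Empty inputs (no proxies, no contacts, zero planted signals)
  propagate as empty results, not errors — verified by a zero-signal
  fixture run.
* Monomorphic SNPs have undefined r² (NA), not 0.

# Problem sizes used in the test suite

Oracle checks run at: 1,000 SNPs × 100 features (scoring vs brute-force
sum), all 635,376 2×2 tables with total ≤ 60 (Fisher vs margin-grouped
hypergeometric enumeration), all 4^L words for motif lengths 4–6 under
uniform and skewed backgrounds (DP vs enumeration), 50 simulated loci
per colocalization scenario at n = 5,000 with 200 SNPs, 20-seed null
calibration draws, and the full default fixture end-to-end. The complete
suite runs in about a minute on one CPU.

# Known limitations

* Single-causal-variant colocalization only; multi-signal loci dilute
  PP4.
* LD handling is table-driven; no phasing, imputation or multi-ancestry
  support.
* The PICS constants are literature-fixed, not estimated, and the PICS
  colocalization conditions away PP0–PP2 (rank use only).
* Indel variants and dinucleotide background models are out of scope for
  the motif scanner.
* Disease matching in drug rules is exact-label; synonymous disease
  names must be harmonised upstream.
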