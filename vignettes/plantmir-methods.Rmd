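---
title: "Methods: homology-guided plant pre-miRNA prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology-guided plant pre-miRNA prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Plant microRNAs are ~21-nt guides excised from stem-loop precursors
(pre-miRNAs) by DCL enzymes, which leave a characteristic two-nucleotide 3'
overhang on each strand of the miRNA/miRNA* duplex. Because mature miRNAs
are strongly conserved across plants, a genome of an understudied species
can be scanned with the catalogue of known matures: wherever a close
homolog sits inside a sequence that folds into a qualifying hairpin, a
conserved miRNA locus is likely. plantmir implements that programme end to
end: homology search, genomic windowing, protein-coding and rRNA/tRNA
screening, secondary-structure prediction, structural qualification, a
170-feature description of each candidate, a dense neural discriminator
against decoys, and a final rule-based validation.

# Homology search and the dissimilarity measure

Each mature reference miRNA is aligned against both strands of the input.
Every local alignment is scored by its *level of dissimilarity*

$$\mathrm{LD} = Q - Q_a + G + M,$$

where $Q$ is the query length, $Q_a$ the aligned query span, $G$ the
number of gap columns and $M$ the number of mismatches. LD counts, in
nucleotides, everything that separates the hit from a perfect full-length
match. Three selection modes use it:

* **prediction**: $E \le 0.001$ and $\mathrm{LD} \le 3$ (the case-study
  configuration) — candidates close enough to a known mature;
* **positive compilation**: perfect full-length matches only
  ($\mathrm{LD} = 0$, no gaps or mismatches);
* **decoy compilation**: $E \le 0.001$ and $5 \le \mathrm{LD} \le 6$ —
  similar enough to fold like a precursor, dissimilar enough that a
  functional miRNA is unlikely (hits below the band may be real miRNAs;
  above it, significance collapses).

Two aligner backends implement one contract: a BLASTn adapter
(`blastn-short`, word size 7) and a built-in exhaustive affine-gap local
aligner (match +1, mismatch −2, gap open −5, gap extend −2) whose
expectation values come from the ungapped Karlin–Altschul formula
$E = K m n e^{-\lambda S}$ with $\lambda = 1.28$, $K = 0.46$ for this
scoring system. The internal engine is the default: on the short queries
this pipeline uses it is exhaustive (hence its own oracle), deterministic,
and recovers multiple hits per subject by greedy masking of previous hit
footprints. A consequence of combining the significance gate with the
decoy band is worth noting: for a ~21-nt query, an alignment carrying five
substitutions can never reach $E \le 0.001$; the band is populated by hits
whose dissimilarity comes mostly from unaligned query ends (for example, a
19-nt exact core of a 24-nt mature gives $\mathrm{LD} = 5$ at
$E \approx 10^{-4}$ against 100 kb).

Windows extend each selected hit by a flank per side — 200 nt for
prediction (an $n + 400$ window), 20 nt for dataset compilation, where the
structural signal adjacent to the duplex is known to be concentrated
within ~15 bp — clipped at sequence boundaries; minus-strand windows are
reverse-complemented so the hit always reads 5'→3'. Redundant windows are
removed by greedy longest-first clustering (representatives at ≥ 0.9
identity, defined as matches over the global alignment of the shorter
sequence onto the longer, ties broken lexicographically).

# Annotation screening

Genuine pre-miRNAs do not overlap protein-coding exons, and coding overlap
is exactly what makes a decoy provably non-functional. Windows are
six-frame translated; peptides of ≥ 20 aa between stops are locally
aligned (BLOSUM62, gap open 11, extend 1) against the protein set, with
$E$-values from the gapped BLOSUM62 Karlin–Altschul constants
($\lambda = 0.267$, $K = 0.041$). A window is *flagged* when its best
$E \le 10^{-3}$; prediction and positive compilation drop flagged windows,
decoy compilation keeps only them. The 20-aa floor and the thresholds are
configuration, not biology: no canonical value exists for this step, so
the nucleotide significance threshold is mirrored.
Windows resembling rRNA/tRNA family sequences (local identity ≥ 0.85 over
≥ 80% of the family record) are removed; both thresholds are exposed in
the configuration for the same reason.

# Secondary structure

Folding is pluggable. The production engine is RNAfold when present on the
PATH (`fold_all(engine = "auto")`); the built-in reference folder is a
deterministic maximum-weight nested-pairing dynamic programme (GC = 3,
AU = 2, GU = 1, minimum hairpin loop 3 nt) with traceback enumeration of
co-optimal structures capped at 20. It is a test-grade engine: exact,
seedless and fast, but blind to stacking thermodynamics, which is why the
planted-genome runs use the thermodynamic folder. Every engine's output is
validated against the pair-table invariants (symmetry, irreflexivity,
minimum loop, nestedness) before anything downstream sees it; T is always
converted to U.

Free energies of sub-structures (whole window, main branch, presumed
precursor) come from a deliberately simple nearest-neighbour model: a
stack of two pairs contributes $-((s_1+s_2)/2 + 0.5)$ kcal/mol with
$s_{GC} = 3$, $s_{AU} = 2$, $s_{GU} = 1$; hairpin loops cost
$4.5 + 1.1\log(n/3)$, bulges $3.5 + 1.1\log n$, internal loops
$2.0 + 1.1\log(n/2)$, multiloops $3.4 + 0.4b + 0.1u$. The model is
documented, monotone in stacking, and zero on open chains — sufficient for
the comparative energy features (MFE, AMFE = MFE/L·100,
MFEI = AMFE/GC%); it does not reproduce experimental folding energies.

# Qualification and the rule engine

A folded window is first screened by six structural disqualification
rules on the hit region: (i) not involved in a double-stranded stem,
(ii) only a few residues in complementarity (< 60% of hit positions
paired), (iii) no continuous complementary region (an unpaired run > 5
nt), (iv) inner branches inside the hit, (v) a branched complementary
region, (vi) the hit not located entirely on one side of its terminal
loop. A primary filter then requires a simple terminal region — at most 3
terminal structures (hairpin loops distal to the hit on its branch) and no
internal loop with a side > 5 nt touching the hit. The 60%/5-nt/5-nt
thresholds make precise what "near-perfect" and "large" mean; they are
configurable and stated here because the source description is
qualitative. Violations accumulate — a candidate reports every broken
rule, not just the first.

The star strand is inferred from DCL geometry: the star 3' end is the
partner of the mature 5' end offset +2; the star 5' end is the partner of
mature position $e-2$; unpaired mature ends are resolved by scanning
inward to the nearest paired position and re-applying the offset. Duplex
statistics walk the region between the spans: a gap with $l$ unpaired
guide and $r$ unpaired star nucleotides contributes $\max(l, r)$
mismatched positions and $|l - r|$ asymmetric-bulge nucleotides; G:U
wobbles count as pairs by default (folding engines pair them; the flag
`wobble_as_pair = FALSE` demotes them). The final rule engine enforces the
five generally accepted criteria for plant miRNAs — 2-nt 3' overhangs at
both duplex ends, no secondary stems, at most 6 mismatched positions with
at most 3 in asymmetric bulges, precursor ≤ 300 nt, mature 20–24 nt — plus
an optional ban on mismatches at chosen mature positions (e.g. 9–11, the
cleavage-site-facing region). In prediction mode the star is inferred
assuming the overhang geometry, so the overhang rule bites mainly when
spans come from annotation or planted truth; the remaining rules are
always discriminative.

# The 170-feature record

The extractor reports eight families with fixed sizes — primary (7),
reference query (4), genomic positions (5), nucleotide composition (4),
energy (8), linear sequence (23), pair composition (36), major structural
(83) — 170 features in a stable order, with −1 as the documented sentinel
for undefined members (absent stems, fewer than eight mismatches, and so
on). The family sizes and row descriptions are the binding contract; the
exact membership is this package's schema, published machine-readably in
`inst/extdata/feature_schema.tsv` and from `feature_schema()`. Two
interpretation notes. First, a literal tetranucleotide frequency table
(256 values) cannot fit a 4-feature family; the nucleotide-composition
family therefore holds the GC content of the four segments the description
names (whole window, main branch, precursor, mature). Second, "crucial
positions" for the pair-composition family are fixed as mature positions
1–11 (5'-cut-adjacent 1–2, seed 2–8, central 9–11) plus the 3'-terminal
position — twelve positions × (pair state, base, partner base). Energy
features cover {FE, AMFE, MFEI} for the main branch and the precursor and
{FE, MFEI} for the whole structure.

# The classifier

The discriminator is a dense network of seven SELU hidden layers with
widths geometric from 256 down to 8, batch normalisation, alpha-dropout
0.1, a 2-way softmax head, cross-entropy loss and Adam (10⁻³), trained
with early stopping (patience 8) on a stratified 10% validation split. It
is written in plain matrix numerics: deterministic given its seed,
dependency-free, and easily fast enough at this scale (170 inputs, a few
thousand rows). Features are z-scored with training-fold statistics only,
so no information leaks from evaluation folds. Every width, rate and
epoch count is overridable through `model_spec()`.

Evaluation implements the three protocols: stratified 10-fold
cross-validation (positives and negatives partitioned separately, the
paired subsets held out together), pooled cross-validation, and
leave-one-group-out versatility analysis in which each species-like group
is predicted by a model trained on all the others. Seven metrics are
reported per fold and as mean ± sd: accuracy, sensitivity, specificity,
precision, F1, Matthews correlation, and AUC computed from the midrank
(Mann–Whitney) statistic, which handles ties exactly.

# Synthetic data: what it does and does not emulate

All tests run on generated inputs with planted truth. `make_hairpin`
emits a precursor *and its intended structure directly* — no folding — so
duplex statistics, the rule engine and the feature extractor can be
checked against planted mismatch counts, bulge sizes and overhangs
exactly. `make_genome` plants, in a uniform-random background: clean
hairpin loci (the emitted matures form the reference set), ORF-structured
coding regions whose six-frame peptides form the protein set, decoy loci
(hairpins whose guide is an 18–19-nt exact substring of a 24-nt mature —
the dissimilarity band by construction) embedded inside coding regions,
and tRNA-like records. `make_feature_table` draws two Gaussian clusters
over the schema, separated by `class_sep` standard deviations along a
random direction; the default 6 makes the Bayes error ~0.1%, i.e.
"separable by construction", and `class_sep = 0` gives an exchangeable
null with AUC 0.5.

Because planted hairpins sit in thermodynamically random flanks, the
production folder occasionally prefers a slightly different register than
the planted one (for example, zipping an overhang base into the adjacent
helix when it happens to complement it). The generator forbids the
specific complementarities that enable the common shifts (overhang bases
zipping into the adjacent helix, and register slips across the flush
stem junctions), which keeps planted-locus recall at 5 of 5 across the
seeds exercised; any residual case would be a genuine property of
thermodynamic refolding, not of the pipeline. What
synthetic data cannot show: real genomes have repeat structure,
composition bias, paralogous families and imperfectly conserved matures,
so passing these suites demonstrates correctness of the machinery, not
field sensitivity/specificity on real species.

# Numerical choices and problem sizes

Coordinates are BED-style 0-based half-open for genomic intervals and
1-based inclusive on folded sequences (the CT convention); the conversions
are inverses and both are exercised by round-trip tests. CT files accept
`dG =` and `ENERGY =` headers and emit `dG`. Ambiguity codes other than N
are rejected loudly; lowercase (soft-masked) residues are kept as normal
bases by default, with `mask_lowercase = "n"` to ignore them — the choice
is surfaced because upstream practice varies. Ties in clustering are
broken lexicographically; co-optimal structures are capped at 20; all
violated rules are reported. The test and acceptance runs use a 100-kb
genome with 5 clean, 5 coding-embedded and 5 decoy loci, 2 000-row
feature tables for the classifier checks, 500 hairpin parameterisations
for the duplex oracle, 500 random structures for the decomposition
oracle, and 1 000 draws for the metric oracle — sizes chosen so the whole
suite completes in minutes on one CPU while every boundary in the rule
engine is swept exhaustively.

# Interface notes and limitations

Overlapping accepted candidates from different reference queries are all
reported, grouped by window and flagged (`overlapping_in_window`) rather
than merged — merging policy is a downstream decision. `run_pipeline`
accepts `model = NULL`, running the structural pipeline and rule engine
without a classifier stage; that is how the planted-recovery checks
isolate the structure machinery. The command-line front end
(`inst/scripts/plantmir`) is a thin wrapper over the same functions with
subcommands `predict`, `build-datasets`, `train`, `evaluate` and
`simulate`. Known limitations: the reference folder ignores stacking
thermodynamics; the built-in energy table is comparative, not
experimental; the internal aligner is exhaustive and therefore quadratic
(fine for ~21-nt queries, wrong tool for megabase queries); and no attempt
is made to call mature strands de novo without a homology anchor.
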