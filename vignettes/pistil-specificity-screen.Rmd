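---
title: "Screening for pistil-specific genes and secreted cysteine-rich peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for pistil-specific genes and secreted cysteine-rich peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pistilscreen)
library(dplyr)
```

## The problem

Fruit set in tomato begins when the quiescent ovary inside the pistil
commits to becoming a fruit. Genes expressed *only* in the pistil are prime
candidates for regulators of this transition and for tissue-specific
promoters in breeding, but calling a gene "pistil-specific" from a single
expression survey is fragile: one tissue panel, one replicate per tissue,
and arbitrary detection thresholds all leave false positives. The approach
implemented here hardens the call by intersecting evidence across
independent datasets: an in-house multi-tissue RNA-seq panel, a public
multi-tissue compendium with a large vegetative block, a pistil cell-type
expression atlas, and (as annotation only) a two-tissue ovary dataset from
a second cultivar.

`pistilscreen` implements that cascade as a tested, reusable pipeline, plus
the two satellite analyses that typically follow it: GO-term
over-representation of the resulting gene set, and a sequence-level screen
of the encoded proteins for small secreted cysteine-rich peptides (CRPs),
the hallmark anatomy of plant peptide hormones.

## Quantification and normalization

Counts are converted with the classical length- and depth-normalized
measures:

$$\mathrm{RPKM}_{g,s} = \frac{10^9\, c_{g,s}}{L_g N_s}, \qquad
  \mathrm{RPM}_{g,s} = \frac{10^6\, c_{g,s}}{N_s},$$

where $c_{g,s}$ is the read count of gene $g$ in sample $s$, $L_g$ the
exon-union gene length in bp, and $N_s$ the mapped-read depth of the
sample. Two choices here were genuinely open:

* **The depth denominator.** The "million mapped reads" of an aligner
  includes reads outside annotated gene models, which a gene-level count
  matrix cannot see. `compute_rpkm()` defaults to the column sum of the
  count matrix and accepts an explicit `depths` vector whenever the true
  mapped totals are known. Filters in this package compare both sides of a
  threshold computed the same way, so the choice moves absolute values
  slightly but is consistent within a run.
* **Gene length.** `gene_lengths_from_gff()` uses the union of all exon
  intervals over all isoforms (1-based inclusive coordinates, so
  $[a,b]$ contributes $b-a+1$ bp), the standard RPKM convention when no
  isoform-level quantification is attempted. Genes without exons are
  dropped with a warning rather than silently given length zero.

`quantile_normalize()` forces all samples onto the common reference
distribution (the mean of the sorted columns). The tie rule is explicit:
tied values within a column receive the mean of the reference values over
their rank span. This makes the operation deterministic and idempotent on
tie-free data; when a column contains ties, the tie-averaged values are no
longer exactly a permutation of the reference, so a second application can
shift values by the tie-averaging amount — a property of every
tie-averaging quantile scheme, not of this implementation.
`log2p1()` applies $x \mapsto \log_2(x+1)$ so that zeros map to zero.

Normalized log2 values feed *inspection* only (heatmaps, `pca_qc()`); the
screening filters below always run on raw RPKM/RPM/FPKM. Published
descriptions of such screens rarely state the order; applying thresholds
to the un-renormalized values keeps the stated cutoffs interpretable in
their original units.

## The specificity cascade

`run_screen()` composes four filters, each with an explicit, strict
threshold (defaults in `screen_thresholds()`):

1. **Candidates** — RPKM > 0.5 in at least one pistil sample *and*
   RPKM < 0.5 in every non-pistil sample of the in-house panel.
2. **Detected** — expression above `public_detect` (default 0, i.e. any
   positive value) in at least one sample of the public compendium. A gene
   whose id does not occur in the external matrix is treated as not
   detected; cross-dataset id drop-out is the realistic failure mode, and
   the provenance trace records it.
3. **Floral organ-specific** — excluded if RPKM > 1 in *any* vegetative
   sample of the compendium.
4. **Pistil expressed** — in parallel from the candidates, RPM > 2 in at
   least one pistil cell-type sample.

The final set is the intersection of branches 3 and 4. All comparisons
are strict because the verbal definitions are of the form "greater
than" / "higher than"; a gene sitting exactly on a cutoff therefore fails
the keep side, and every cutoff is a parameter. Two invariants hold by
construction and are enforced in the test suite: nestedness
(final ⊆ floral-specific ⊆ detected ⊆ candidates; final ⊆ pistil-expressed
⊆ candidates) and threshold monotonicity (loosening an "off" bound never
shrinks the surviving set).

A secondary two-tissue dataset, when supplied, only *annotates* each final
gene with detected / not detected at FPKM > 0.5 — in the study design this
comparison came after the final call, so it must not feed back into it.

Gene ids are matched across datasets after stripping trailing `.N` version
suffixes (`strip_gene_version()`), optional but on by default, because
ITAG identifiers circulate in both forms.

Downstream helpers formalize what is otherwise done by eye on heatmaps:
`classify_celltype_preference()` labels a gene with the cell-type group of
maximal mean RPM (all-zero profiles are `"unclassified"`, ties go to the
first group in a documented fixed order), and `rank_top_genes()` ranks
genes within a sample or group mean with lexicographic tie-breaking.
`pca_qc()` is deliberately minimal: row-centered PCA via SVD, returning
per-component variance fractions that sum to 1.

## GO-term over-representation

`enrich()` tests each GO term carried by at least one study gene with the
one-sided hypergeometric tail

$$p = P(X \ge k), \quad X \sim \mathrm{Hypergeom}(N, K, n),$$

where $N$ is the population size, $K$ the population genes carrying the
term, $n$ the study size and $k$ the study hits. Benjamini–Hochberg
adjustment runs across exactly the tested terms (the family is the number
of terms with ≥ 1 study hit). Three policies were open and are fixed as
follows:

* **No ontology-graph propagation.** The test uses direct annotations as
  given. Web tools propagate gene–term links up the GO graph internally;
  replicating the graph is out of scope here, and pre-propagated
  annotation tables are accepted as input unchanged.
* **Population default** is every gene in the annotation table, and can be
  overridden (e.g. to "all expressed genes") via `population=`.
* **Study genes outside the population** are dropped with a warning and
  counted in `attr(result, "n_dropped")` rather than silently shrinking
  $n$.

Because published enrichment results depend on the web tool's unpublished
background universe and propagation policy, this module does not attempt
to reproduce any specific published p-value; its correctness anchors are
exhaustive enumeration (all populations up to $N = 25$) and the empirical
type-I error of the test under uniform null draws.

## The CRP screen

Plant peptide hormones of the CRP family share a three-part anatomy: a
small precursor (here, strictly fewer than 200 amino acids, the
conventional small-protein bound), an N-terminal secretion signal, and a
conserved set of cysteines — four, six, or eight — in the C-terminal
region. `classify_crp()` requires all three.

The secretion-signal predictor is a deliberately transparent heuristic
over the canonical signal-peptide anatomy, not a reimplementation of a
neural predictor: (a) at least one K/R within the first 5 residues (the
charged n-region) and (b) an 8-residue window entirely within the first 30
residues with mean Kyte–Doolittle hydropathy ≥ 1.6 (the hydrophobic
h-region). All four numbers are parameters. When published predictions
exist, `import_signal_calls()` ingests them verbatim (`"a-b"` spans or
`"-"`), and they take precedence over the heuristic.

Remaining conventions: the "C-terminal region" is the trailing 50 % of the
*mature* sequence (after signal cleavage; with a heuristic call the mature
start is one past the hydrophobic window, since the heuristic has no
cleavage-site model), configurable via `cterm_frac`; the cysteine rule is
the literal set {4, 6, 8} by default with a `min_cys` relaxation flag;
`pairwise_identity()` is plain Needleman–Wunsch with hand-checkable scores
(match 1, mismatch 0, gap −1) and a fixed traceback tie order
(diagonal > up > left), intended for reproducing identity-percentage
columns, not for sensitive homology search.

The packaged `table2_lengths()` fixture transcribes the published table of
45 pistil-specific small-protein entries (id, length, reported signal
span). Note one internal tension preserved as-is: the surrounding text
says roughly half of these proteins carry a secretion signal, while the
table's signal column marks fewer than half. The fixture reproduces the
table verbatim and takes no side.

## What the synthetic data emulates — and what it does not

`synth_config()` fixes the study conditions the generator emulates:

* four dataset designs — 17 in-house samples (6 pistil stages, 3 anther +
  sepal + petal, 4 vegetative, 2 fruit), a 26-sample public compendium
  containing 9 vegetative samples, a 7-sample pistil cell-type atlas
  (ovule, embryo, endosperm, seed coat, pericarp, placenta, septum), and a
  2-tissue ovule/ovary-wall dataset;
* five gene classes with largest-remainder allocation (deterministic
  counts; ties by index): `pistil_specific` 5 %, `floral_nonpistil` 15 %,
  `vegetative` 20 %, `ubiquitous` 50 %, `silent` 10 %;
* counts drawn as Poisson with rate proportional to
  depth × length × concentration, normalized per sample; "on"
  concentrations are log-normal (meanlog $\log 50$, sdlog 1), "off" states
  leak at `expr_off_level * leak` (0 by default), and pistil-specific
  genes carry a planted preferred cell type expressed 10× above the other
  cell-type samples;
* depth $10^7$ reads per sample, in the range of typical bulk RNA-seq
  libraries;
* optional dropout: each count is zeroed independently with probability
  `dropout` after the draw, modelling cross-dataset detection failure.

The Poisson–log-normal model is the *minimal* generative model under which
RPKM/RPM thresholds behave the way the cascade assumes. It deliberately
omits biological replicates and overdispersion, batch effects, isoform
structure, partially-on intermediate expression states and correlated
dropout. Consequently, a perfect precision/recall on noiseless synthetic
data demonstrates that the cascade's logic and thresholds are implemented
correctly — not that the thresholds are optimal for real data, where
class boundaries are soft. The dropout knob probes one direction of that
softness: dropout in the public matrix can only remove true positives at
the detection stage, so precision stays 1 while recall falls.

The synthetic proteome plants four protein classes (¼ each of 500 records
by default): true CRPs, and three decoy classes each violating exactly one
CRP property (too long; no signal — hydrophilic, K/R-free N terminus; 2,
3, 5 or 7 cysteines). All cysteines are confined to the C-terminal tail
and the rest of each sequence is drawn from a cysteine-free alphabet, so
the planted count is exactly what the classifier measures. Real proteomes
scatter cysteines everywhere; the generator validates the classifier's
logic, not its false-positive rate on real sequences.

All generation is seed-deterministic: the gene universe derives from the
configuration seed, each dataset's count draw from a fixed per-dataset
offset of it, so one configuration yields bit-identical data everywhere.

## Numerical and scale choices

Problem sizes in the tests and acceptance script — 200–2,000 genes, 500
proteins, 100 fuzzed screen instances, 10,000 null draws for the
enrichment calibration, exhaustive hypergeometric enumeration to
$N \le 25$ — were chosen so that every oracle comparison is exact and the
whole suite runs in about a minute, while still exercising each filter on
both sides of its threshold. The screen itself is linear in genes ×
samples and runs comfortably at genome scale (tens of thousands of genes).

## A worked run

```{r screen}
cfg <- synth_config(n_genes = 1000, seed = 42)
sim <- simulate_screen_inputs(cfg)
res <- run_screen(sim$counts, sim$lengths, sim$annotations,
                  sim$public_rpkm, sim$celltype_rpm, sim$secondary_fpkm)
res
glance(res)

planted <- sim$truth$gene_id[sim$truth$class == "pistil_specific"]
setequal(res$stage_sets$psg, planted)
```

```{r celltype}
classify_celltype_preference(res$stage_sets$psg, sim$celltype_rpm) |>
  count(celltype)
```

```{r crp}
prot <- generate_proteome(cfg)
calls <- classify_crp(prot$proteins)
table(planted = prot$truth$class, called_crp = calls$is_crp)
```

```{r plots, fig.width = 6, fig.height = 4}
autoplot(res)
autoplot(pca_qc(log2p1(compute_rpkm(sim$counts, sim$lengths))),
         annotations = sim$annotations)
```

## Known limitations

* Published headline gene counts from any specific study are not
  reproducible without that study's raw sequencing archives and mapping
  software; this package validates the *method* on generated data with
  known truth.
* The enrichment module tests direct annotations only; users wanting
  graph-aware enrichment should propagate annotations upstream.
* The signal-peptide heuristic trades sensitivity for transparency; for
  publication-grade secretome calls, import predictions from a dedicated
  predictor.
* One replicate per tissue is assumed, as in the emulated design; the
  cascade has no variance model and should be read as a deterministic
  filter, not a statistical test.
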