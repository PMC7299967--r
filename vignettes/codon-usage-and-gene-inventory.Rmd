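---
title: "Codon usage bias and sex-gene inventories: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias and sex-gene inventories: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(dinocodon)
```

## The scientific setting

Dinoflagellates of the family Symbiodiniaceae — the photosynthetic symbionts
of reef corals — are suspected of sexual reproduction on genomic grounds,
although meiosis and gamete fusion have never been observed cytologically in
these taxa. Two complementary genomic arguments are in play. First, a
*gene inventory*: screening genome- and transcriptome-derived protein sets
for the meiotic toolkit (synaptonemal-complex components, ZMM proteins,
recombination, cohesin, crossover-resolution, mismatch-repair and syngamy
genes) shows which parts of the machinery are retained and which were lost.
Second, *codon usage*: meiotic recombination is one of the forces proposed
to drive GC-content and codon-usage patterns in these genomes, so per-gene
codon statistics and the contrast between genes under selection for codon
preference and genes evolving neutrally carry information about the forces
shaping the genome.

This package implements both analyses, the GO-term enrichment that connects
them, and synthetic-data generators that plant known truth for every stage.

## Codon usage statistics

All statistics are computed per coding sequence (CDS) from codon counts in
frame 0, excluding the terminal stop codon; codons containing non-ACGT
characters are skipped and tallied; genes with internal stop codons are
excluded by default (their presence signals a frame error upstream; the
behaviour is configurable). For transcriptome inputs one transcript is
treated as one CDS.

**Positional GC.** `gc1`, `gc2`, `gc3` are the percentages of G+C at each
codon position; `gc12` is the mean of the first two; `gc_overall` averages
all three. All GC quantities are percentages in [0, 100], so the two
classification thresholds below ("25 Nc units", "5 percentage points") are
on the natural axis scales.

**GC3s.** The G+C fraction at third positions restricted to codons of amino
acids with at least two synonymous codons (Met, Trp and stops excluded),
i.e. the positions free to vary without changing the protein.

**Effective number of codons (Nc).** Wright's estimator. For one
synonymous family with counts \(n_1, \dots, n_k\), \(n = \sum n_i\) and
\(p_i = n_i/n\), the codon homozygosity is

\[ \hat F \;=\; \frac{n \sum_i p_i^2 - 1}{n - 1}, \]

computed only for families with \(n \ge 2\). Families are grouped by
degeneracy; under the standard genetic code

\[ N_c \;=\; 2 \;+\; \frac{9}{\bar F_2} \;+\; \frac{1}{\bar F_3}
   \;+\; \frac{5}{\bar F_4} \;+\; \frac{3}{\bar F_6}, \]

where \(\bar F_k\) is the mean homozygosity of the degeneracy-\(k\) class.
Nc runs from 20 (one codon per amino acid, maximal bias) to 61 (uniform
synonymous usage). Conventions for degenerate inputs follow Wright's
published estimator: a missing 3-fold class (no Ile observed) is imputed
as \((\bar F_2 + \bar F_4)/2\); any other missing class leaves Nc
undefined with a `missing_family` flag; Nc is capped at 61. One edge case
the published description leaves open is a class mean of exactly zero
(possible in very short genes, e.g. a single family with counts (1, 1));
here Nc is reported undefined with a `zero_homozygosity` flag rather than
capped, since the estimate is uninformative. Genes with fewer than
`min_codons = 100` codons are flagged `short` but not excluded — no length
filter is imposed by default.

**The neutral expectation.** Under mutation pressure alone, Nc is expected
to track GC3s (as a fraction \(s\)):

\[ N_c^{exp}(s) \;=\; 2 + s + \frac{29}{s^2 + (1-s)^2}. \]

The anchor values are 31.0 at \(s = 0\), 32.0 at \(s = 1\) and 60.5 at
\(s = 0.5\). Note that because of the linear \(+s\) term the curve's true
maximum is not exactly at \(s = 0.5\): the derivative there is \(+1\), and
the maximum (60.5011) sits at \(s \approx 0.502\). This is a property of
the standard formula, not an implementation artefact, and the tests assert
it as such.

**Classification.** A gene shows *strong codon-usage preference* when its
Nc falls strictly more than 25 units below \(N_c^{exp}\) at its GC3s.
Otherwise it is *neutral* when its vertical distance from the
GC12 = GC3 diagonal is strictly less than 5 percentage points; otherwise
*other*. Genes with undefined Nc or GC3s are *other*. Both thresholds are
parameters. Two design points were genuinely open:

* *Distance from the diagonal* is the vertical distance |GC12 − GC3|, the
  simplest reading; a perpendicular-distance variant would differ by a
  constant factor \(\sqrt 2\) and can be emulated by rescaling the
  threshold.
* Undefined-Nc genes could arguably still be called neutral from their GC
  values alone; they are classed *other* so that the strong/neutral
  contrast is always based on the same defined statistics.

**Neutrality fit.** `neutrality_analysis()` fits GC12 on GC3 by ordinary
least squares. A slope near 1 is the neutral (mutation-driven) signature; a
shallow slope indicates third-position GC evolving away from the first and
second positions, i.e. selection or biased gene conversion on GC3.
Quadrant occupancy splits the plane at 50% on each axis; a value of exactly
50% counts as "low" (a tie-break that matters only for points on the
boundary).

**RSCU and correspondence analysis.** Relative synonymous codon usage of
codon \(j\) in a \(k\)-fold family with family total \(m\) is
\(\mathrm{RSCU}_j = n_j / (m/k)\); unobserved families contribute 0 for all
their codons (no row renormalisation, keeping row sums comparable across
genes). The gene × codon matrix over the 59 synonymous sense codons is
decomposed by standard chi-square-metric correspondence analysis: with
proportions \(P\), row masses \(r\) and column masses \(c\), the SVD of
\(S = D_r^{-1/2}(P - rc^{\top})D_c^{-1/2}\) yields axis inertias (squared
singular values) and principal coordinates. Relative inertia — the
fraction of total variation per axis — is the quantity usually quoted when
the first axis is interpreted as the GC3s gradient. Axes whose singular
value falls below \(10^{-8}\) of the leading one are treated as numerical
noise and dropped; their inertia contribution is below \(10^{-16}\) of the
total, so reported relative inertias still sum to 1 within \(10^{-9}\).

## The gene inventory

**Search.** `search_homologs()` aligns every catalog query protein against
every subject protein with Smith–Waterman local alignment (BLOSUM62, gap
open 11, gap extend 1 — the defaults of the common search tools, for
comparability). The built-in aligner reports raw scores only; it makes no
attempt at e-value statistics, which would require Karlin–Altschul
calibration that is out of scope. Pre-computed tabular hits (the
12-column "outfmt 6" dialect, or a 14-column variant appending query and
subject lengths) can be imported instead and carry e-values.

**Filters.** A hit survives when it is significant — e-value strictly
below \(10^{-3}\) when present, otherwise raw score at least `score_min` —
and covers at least 25% of *both* query and subject (inclusive). "Mutual
coverage" is read as both-sided; because the phrase is ambiguous in common
usage, the subject-side requirement can be disabled
(`require_subject_cov = FALSE`), which makes the filter strictly more
permissive. The default `score_min = 100` (about 30 bits under
BLOSUM62 11/1) is a conservative conventional cutoff: local alignments
between unrelated proteins of a few hundred residues reach raw scores of
60–70 by chance at this search-space size, so a floor well above that
noise ceiling — yet far below genuine-homolog scores, which exceed 1000 at
20% divergence over 300 residues — separates the two regimes without fine
tuning.

**Presence/absence.** A catalog gene is present in an isolate when at
least one surviving hit links one of its queries to a protein of that
isolate; supporting hits are retained per cell. Completeness of a
reference ortholog set (BUSCO-style) counts complete plus fragmented
orthologs, as a percentage; the complete/fragmented distinction is taken
from the input status file, not re-derived.

**Tree validation.** Candidates are verified on single-gene trees by two
criteria: (a) the candidate branches with the ingroup — operationalised as
the nearest non-candidate tip by patristic distance belonging to the
ingroup or to the queries, with ties broken by fewest intervening edges
then label; a stricter monophyly mode (candidate + ingroup + queries form
a clade under the given rooting) is available by flag; and (b) the
candidate's terminal branch length is comparable to the queries' —
operationalised as a ratio to the median query terminal branch of at most
2.0 (inclusive). The similarity criterion has no published cutoff; 2.0 is
this package's default and is deliberately prominent as a parameter
(`ratio_max`), since divergent-but-genuine homologs (the MER3 situation)
sit exactly on this boundary of judgement. Verdicts are invariant under
tip rotation and under re-rooting away from the candidate's terminal
branch, because patristic distances and terminal branch lengths are.

## GO enrichment

One-sided (upper-tail) Fisher exact p-values from the hypergeometric
distribution: \(p = P(X \ge k)\) for \(k\) of \(n\) annotated test
proteins carrying a term that \(K\) of \(N\) background proteins carry.
Raw p-values are reported and rank the output, following the convention of
enrichment tables in comparative surveys; a Benjamini–Hochberg column is
emitted additionally but unused for ranking. Annotations are direct by
default; optional ancestor propagation uses supplied child–parent term
edges (checked acyclic). Ontology-graph down-weighting algorithms
("elim", "weight") are deliberately out of scope, so p-values from such
tools are not expected to reproduce exactly.

## The synthetic generators

Each generator emits exactly the formats the readers consume and a truth
table naming what was planted.

* **CDS sets** (`generate_cds_set`): amino acids are drawn i.i.d. (uniform
  over the 20 by default), then synonymous codons from per-gene,
  per-family symmetric Dirichlet-multinomial distributions. Concentration
  `alpha` is the bias dial in the statistical sense — `alpha = 0.01`
  effectively commits each family to one codon (planting strong
  preference, Nc near 20), `alpha = 1000` approaches uniform usage
  (planting neutrality, Nc near 61); `gc3_bias` multiplies the probability
  of G/C-ending codons within each family, tilting GC3/GC3s without
  touching first and second positions. The parameter-recovery suites run
  200 genes of 3000 codons per condition — long genes, so the Nc estimator
  operates in its low-variance regime where the ±3-unit recovery band is
  meaningful. Note a consequence of tilting only third positions: across a
  gc3_bias gradient, GC12 stays flat while GC3 varies, so the fitted
  neutrality slope on such fixtures is near 0 — a fully decoupled,
  selection-like pattern, not the mixed slopes of real data.
* **Homology fixtures** (`generate_homology_fixture`): presence is planted
  per cell with probability `presence_prob`; present subjects are queries
  mutated by point substitutions at the stated divergence; decoys are
  composition-matched shuffles of query proteins (rather than unrelated
  natural sequences), keeping the specificity test self-contained.
  No indels are simulated, so coverage of true homologs is near 1; real
  fragmentary transcripts would lower it.
* **Annotation fixtures** (`generate_annotation_fixture`): term
  frequencies uniform on [0.01, 0.2] over 40 terms and 1000 proteins by
  default; the planted term's frequency is multiplied by
  `enrichment_factor` inside the test set. With `enrichment_factor = 1`
  the planted term behaves as null; the discreteness of the
  hypergeometric makes the null test conservative (observed fraction of
  p < 0.05 near 0.03-0.04 rather than 0.05), which the calibration check
  allows for.
* **Tree fixtures** (`generate_tree_fixture`): ingroup + query tips form
  one random coalescent clade, outgroups another; the candidate is grafted
  onto a terminal edge of the requested group with terminal length equal
  to `terminal_length_ratio` times the median query terminal length. By
  construction, ingroup placements at ratio 1 validate and outgroup
  placements fail the clade check.

Every generator is bit-reproducible under an integer seed; the pipeline
stages derive their stream seeds from one master seed by fixed offsets so
stages can be regenerated independently.

What passing these fixtures does **not** show: the generators have no
expression-dependent transcript capture (so the false-negative problem of
transcriptome-only isolates is discussed, not modelled), no indel
evolution, no codon autocorrelation along genes, and decoys are
composition-matched noise rather than distant paralogs. Results on real
data depend on those factors.

## Numerical choices and limitations

* GC thresholds and distances are strict inequalities where classification
  is involved (`> 25`, `< 5`) and inclusive where the filters are
  (`>= 25%` coverage, `<= 2.0` ratio), matching the stated contracts.
* The CA axis-noise cutoff (`1e-8` relative singular value) and the
  reconstruction tolerance (`1e-9`) are well inside double precision for
  matrices of the sizes used here (hundreds of genes × 59 codons).
* `fisher_exact_upper` sums `dhyper` terms directly; for the cell sizes of
  GO tables this is exact to double precision and matches
  `fisher.test(alternative = "greater")`.
* The package does not run external search/alignment/tree tools; it
  consumes their tabular and Newick outputs. Alignment trimming, model
  selection and bootstrap support are upstream concerns.
* Reported runtimes in the test-suite are minutes on one CPU: the largest
  fixtures are 200 × 3000-codon genes for codon statistics and a
  10 × 5-isolate protein panel (300-residue proteins) for the inventory.

## A worked end-to-end run

```{r, eval = FALSE}
# plant a biased and a neutral population, analyse, and enrich
biased <- generate_cds_set(100, 1000, alpha = 0.05, seed = 1,
                           prefix = "bias")
neutral <- generate_cds_set(100, 1000, alpha = 1000, seed = 2,
                            prefix = "neut")
run <- run_codon_pipeline(rbind(biased$records, neutral$records),
                          out_dir = "codon_out")
print(run)
plot(run$usage, which = 1)   # Nc vs GC3s with the neutral curve

# inventory on a planted fixture
fx <- generate_homology_fixture(seed = 1)
inv <- run_inventory_pipeline(queries = fx$queries,
                              subjects = fx$subjects,
                              catalog = fx$catalog,
                              isolate_map = fx$isolate_map)
print(inv)
```
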