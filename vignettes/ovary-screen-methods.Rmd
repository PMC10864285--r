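---
title: "Methods: from tissue expression to nondisjunction screen calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from tissue expression to nondisjunction screen calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovascreen)
```

## The screening problem

Most genes required for female meiosis and oocyte development in
*Drosophila* are up-regulated in the ovary, so a transcriptome-guided screen
proceeds in stages: select genes enriched in meiotically active tissues
(ovary, with testis and larval CNS as companion meiotic/mitotic tissues),
prioritize the uncharacterized ones that have RNAi reagents, knock each down
in the female germline with two GAL4 drivers of different temporal onset,
and score each cross for sterility, elevated X-chromosome nondisjunction
(NDJ), or a small brood. This package implements each stage as a tested,
configurable function, and ships a generator that fabricates every input
with planted ground truth so the whole pipeline can be exercised end to end
without any external download.

## Expression selection model

For a probe set with replicate intensities $x_1,\dots,x_{n_t}$ in tissue $t$
and $y_1,\dots,y_{n_w}$ in the whole-body reference, the enrichment value is
$E_t = \bar x / \bar y$ and significance comes from a two-tailed two-sample
t test. The direction call is **up** when $E_t > 1$ (strictly) and
$p \le 0.05$ (inclusive), **down** when $E_t < 1$ and $p \le 0.05$, and
**others** otherwise — so the three directions partition every gene × tissue
pair. Defaults live in `screen_thresholds()` and are recorded in every run
manifest.

Numerical choices, made once:

* **t-test variant.** Classic pooled-variance Student's t
  ($\mathrm{df} = n_1 + n_2 - 2$) is the default; Welch's unequal-variance
  form is available via `screen_thresholds(var_equal = FALSE)`. On
  four-replicate microarray groups the two rarely disagree at $p = 0.05$,
  but the choice can move genes near the boundary.
* **Degenerate inputs.** Fewer than two replicates on a side means no
  t-test: the call is forced to `"others"` and flagged rather than failing.
  Two constant samples give the degenerate t limit ($p = 1$ for equal
  means, $p = 0$ otherwise). A non-positive whole-body mean is a hard
  error, since the enrichment ratio is then meaningless.
* **Probe collapsing.** Each gene keeps the probe set with the most
  replicate present calls across ovary/testis/CNS, then the most "up" calls
  among those tissues; exact ties go to the lexicographically smallest
  probe id so the funnel is deterministic.
* **Detection filter.** A probe set with no present call in any replicate of
  ovary, testis and larval CNS is removed; one present replicate anywhere
  among the three is a sufficient witness. Missing detection columns are
  treated as all-absent by default (configurable to an error).

Selected genes are classified by their up pattern: ovary up-regulation is
mandatory; testis and larval CNS are the only other tissues allowed to be
up (giving `ovary_only`, `ovary_cns`, `ovary_testis`, `ovary_cns_testis`);
an up call in any other panel tissue disqualifies the gene. The tissue
panel is data-driven — tissues are whatever column groups the matrix
provides — with the special tissue names passed as arguments, and
cultured-cell columns can be excluded at read time.

Symbol-based scope filters drop unknown genes (`---`), annotated
non-coding `CR` genes, RNA genes and ribosomal proteins before any
statistics. The RNA and ribosomal patterns are matched case-insensitively
(`rna` as a substring, to catch `snRNA:`/`tRNA:`/`rRNA` naming dialects;
`RpS`/`RpL` as prefixes); the exact dialect is configurable only by editing
the filter, a deliberate simplification since these families are unambiguous
in practice.

## The nondisjunction estimator

In the X-NDJ test cross, females are mated to `y w / Y, B^S` males and four
progeny classes are scored: normal X/X females, Bar X/B$^S$Y males, and the
exceptional X/O males and X/X/B$^S$Y females that arise from nullo-X and
diplo-X ova. The reciprocal exceptional zygotes (XXX and YO) die, so every
surviving exceptional fly stands for two nondisjunction ova. The frequency
is therefore estimated as

$$\widehat{\mathrm{NDJ}} = \frac{2(XO + XXY)}{2(XO + XXY) + XX + XY}.$$

Screen tables serialize a cross as "`total, k NDJ`", where `total` is the
estimator's *adjusted* denominator $2(XO+XXY)+XX+XY$ and `k = XO+XXY`; the
frequency is recovered as $2k/\mathrm{total}$. This reading is fixed by the
worked example in the packaged table — the CG3430/HMC06551 mat$\alpha$ cell
`226, 18 NDJ` gives $2\cdot18/226 = 15.9\%$, the screen's reported value —
whereas the alternative reading $2k/(2k+\mathrm{total})$ does not.

The generator's `simulate_cross()` works at the egg level precisely so that
the $\times 2$ correction is *tested against mechanism* rather than assumed:
eggs are Poisson with the brood mean, each egg is NDJ-derived with
probability $d$, NDJ ova split equally between diplo-X and nullo-X, sperm
are X or B$^S$Y with equal probability, and the two inviable classes are
discarded before tallying. Under this model the expected surviving fraction
is $1-d/2$ and $\widehat{\mathrm{NDJ}}$ is a consistent estimator of $d$;
the test suite verifies both, the latter at $d \in \{0.01, 0.05, 0.15\}$
with 2000 broods of mean 300 against a two-Monte-Carlo-SE band.

## Positivity rules and their conventions

A line (gene × shRNA stock) is positive when, in either germline driver,
the cross was **sterile**, had an **NDJ frequency ≥ 1.7%**, or produced a
**small brood (≤ 100)**. A gene is positive when at least one of its lines
is; its category set is the union over positive lines, and the Venn region
is that exact subset. `ND` (not determined) cells carry no evidence: a line
with only `ND` entries is *untested*, never negative. Somatic-driver and
oocyte-morphology columns are annotation only.

Three conventions deserve explanation, all configurable through
`screen_thresholds()` and recorded in the run manifest:

* **Rounding before thresholding** (`ndj_rounding_decimals = 1`). Screen
  tables print frequencies to one decimal in percent, and several published
  calls (e.g. `119, 1 NDJ`: $2/119 = 1.68\%$) are positive only if the
  comparison happens after rounding to that precision. The default
  therefore rounds to one decimal before comparing against 1.7%; raw
  comparison is available with `ndj_rounding_decimals = NULL`.
* **Brood boundary** (`brood_max = 100`, `brood_inclusive = TRUE`). The
  small-brood criterion is stated both as "≤ 100" and "< 100" in different
  places in the screen literature; the inclusive reading is the default and
  the strict one a flag. The adjusted total is used as the brood measure,
  matching what the tables print.
* **Sterile is not small.** A sterile cross trivially has fewer than 100
  progeny, but sterility and small brood are distinct evidence classes; a
  `STERILE` cell contributes only the Sterile category, keeping the Venn
  regions disjoint in meaning.

With these defaults, scoring the packaged table of 110 positive lines
reproduces the published gene-level summary: 94 positive genes, exclusive
Venn counts 29 (Sterile), 24 (NDJ), 18 (Small_brood), and 23 genes in
overlap regions. The duplicated CG8435/GL00696 rows in the source table are
kept as printed; gene-level counting is by distinct symbol, so the
duplication is harmless.

## Prioritization annotations

Uncharacterized genes are those whose symbol is a bare `CG` number
(case-sensitive, digits only); multi-gene probe-set symbols joined by
`///` count if any component matches, since such probe sets were screened
as units. Stock filtering is a pure join against an availability table.
The published screen applied an additional manual review that is not
reproducible from stated criteria; `prioritize_candidates()` exposes
explicit `include`/`exclude` lists instead of guessing at it. Single-cell
germline bias summarizes stage-level expression as per-cluster medians
(midpoint convention for even counts) and calls a gene germline-biased only
when the germ-cell cluster strictly exceeds both somatic clusters — a tie
is not "higher".

## Overrepresentation and network filters

Term enrichment uses the upper-tail hypergeometric probability
$P(X \ge k)$ for an overlap of $k$ input genes with a $K$-gene term, an
$n$-gene input and an $N$-gene background. Terms with fewer than two input
genes are dropped *before* testing, and Benjamini–Hochberg adjustment runs
across the retained terms only, mirroring how pathway servers report
filtered term lists. The background defaults to the union of all term
members because database-internal universes are rarely published; supply
the assay universe when known, since $N$ directly scales every p-value.
Published q-values from specific database versions are therefore not
comparable run-for-run and are not targets of this package. (A note on a
tempting invariant: BH is *not* idempotent — re-adjusting q-values inflates
them — so the tests assert monotonicity and the hand-computed step-up
values instead.)

PPI subnetworks keep edges at combined score ≥ 0.4 ("medium confidence"),
deduplicate repeated pairs by maximum score, drop self-loops, induce the
graph on the positive gene set, and report connected components by size.
Raising the threshold can only remove edges, which the tests assert as a
monotonicity property.

## What the generator emulates — and what it does not

`sim_config()` fixes the synthetic study conditions once: 200 genes, five
panel tissues plus whole body, four replicates per tissue, lognormal
intensities with sd 0.25 on the log scale around a base mean of 100,
planted 4-fold effects for 20 genes (half ovary-only, the rest spread over
the companion-tissue groups), a detection floor equal to the base mean, and
a screen truth of 6 sterile, 8 elevated-NDJ ($d = 0.10$) and 6 small-brood
genes over broods of mean 300 (60 for small-brood genes), with a background
NDJ egg fraction of 0.004. These magnitudes are typical of replicate
Affymetrix tissue panels and of published NDJ assays; at 4-fold effects the
per-gene detection power is essentially 1 and losses come almost entirely
from spurious up calls in bystander tissues (about 2.5 percent per
bystander tissue per gene at the 0.05 cutoff, by construction of the
two-sided test), which is what the recovery tests' sensitivity and
false-positive bands check.

The generator deliberately does not emulate: probe-level sequence effects
or cross-hybridization (one probe set per gene by default), correlated
replicate noise or batch structure, partial RNAi knockdown (sterility is
binary truth), meiosis-II or autosomal nondisjunction (only X diplo/nullo
ova, matching the assay's readout), or driver expression windows. Passing
the recovery tests therefore demonstrates that the *rules and estimators*
are implemented correctly under the stated noise model, not that the
thresholds are optimal for real arrays.

Problem sizes in the test suite — 100–200 simulated genes, 2000 simulated
broods, exhaustive hypergeometric checks to $N = 40$, 100-case t-test
oracle comparisons — were chosen as the smallest sizes at which the
Monte-Carlo bands in the corresponding checks are decisive.

## Known limitations

* Reproducing the original microarray funnel exactly (1118 selected genes,
  611 ovary-only) requires the historical FlyAtlas 1 export and depends on
  unstated details of the original t-test and zero-variance handling; the
  package exposes both variants but ships no third-party expression data.
* The `rna`/ribosomal symbol filters are pattern heuristics; curated gene
  lists would be stricter.
* Brood size is measured by the adjusted total, which exceeds the raw
  progeny count by the number of exceptional flies; at the 100-progeny
  boundary the two can differ by a few flies in high-NDJ crosses.
* The positivity rules are thresholds, not hypothesis tests; no multiple
  testing correction is applied across crosses, matching screen practice of
  treating calls as candidates for cytological follow-up.
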