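---
title: "Methods: exact differential expression for two sequencing libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact differential expression for two sequencing libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgepair)
```

## The setting

Early de novo transcriptome studies — typically a non-model organism with
two contrasted conditions or cultivars, one cDNA library each, no
biological replicates — quantify expression by counting reads mapped to
assembled unigenes. With a single library per condition, replicate-based
tests (negative-binomial GLMs as in DESeq2 or edgeR) are not applicable;
the field's standard is the Audic–Claverie exact test, which treats the
pair of counts for one gene as the only data and asks whether they are
compatible with equal underlying expression given the two sequencing
depths. `dgepair` implements that complete analysis: RPKM quantification,
the exact test, Benjamini–Hochberg FDR control, joint FDR/fold-change DEG
calling, hypergeometric term enrichment, homology-based candidate
screening, and a ground-truth simulator that makes every stage testable
at desk scale.

## The model

### RPKM

For a gene of length $\ell$ bp with $c$ mapped reads in a library of $N$
total reads,

$$\mathrm{RPKM} = \frac{10^9\, c}{\ell\, N},$$

reads per kilobase of transcript per million mapped reads. RPKM is used
for *reporting* expression and for the fold change; the test itself works
on raw counts, where the discreteness matters.

### Fold change with zero substitution

The fold change is $\log_2(\mathrm{RPKM}_S / \mathrm{RPKM}_L)$. When
either RPKM is zero the ratio is undefined, so zero operands are replaced
by a small constant (default 0.01 RPKM) before forming the ratio. The
substitute is a tunable of consequence: it caps the magnitude reportable
for genes detected in only one library. 0.01 is the conventional choice
and sits well below the smallest nonzero RPKM observable at these depths.

### The exact test

Condition on the count $x$ observed in library L (depth $N_1$). Under
equal expression, the count $y$ in library S (depth $N_2$) follows

$$p(y \mid x) = r^y \, \frac{(x+y)!}{x!\, y!\, (1+r)^{x+y+1}},
  \qquad r = N_2/N_1,$$

the two-depth generalisation of the Audic–Claverie distribution (a
negative binomial with size $x+1$ and success probability $1/(1+r)$,
which is the route the test-suite oracle uses). The two-sided p-value
doubles the smaller tail and caps at one:

$$p = \min\!\big(1,\; 2 \min\{P(Y \le y \mid x),\, P(Y \ge y \mid x)\}\big).$$

Two-sidedness is a package decision: DEGs are called in both directions,
so a one-sided test would be incoherent with the reporting. Note the
doubled-tail construction is *not* exactly symmetric under exchanging
$(x, N_1) \leftrightarrow (y, N_2)$: the swapped lower tail equals the
original strict upper tail, so the two p-values differ by terms involving
the point mass $p(y\mid x)$. The construction identity that does hold,
$p(x \mid y;\, r^{-1}) = r\, p(y \mid x;\, r)$, is what the tests assert.

### Numerics

All factorials are evaluated through `lgamma`. The lower tail is a finite
sum accumulated by log-sum-exp. The upper tail is computed by whichever
route is accurate where it is needed: at or below the pmf mode the tail
is large and the complement $1 - P(Y \le y-1)$ is safe; above the mode
the terms decay geometrically (ratio $\to r/(1+r) < 1$) and the tail is
summed directly in chunks until a chunk no longer moves the accumulator
at double precision. Summing the small tail directly keeps full relative
accuracy down to probabilities near the double-precision floor, which the
complement cannot do — tail probabilities of order $10^{-30}$ occur
already for counts of a few dozen.

### FDR and the DEG call

`bh_fdr()` is the textbook Benjamini–Hochberg step-up
($q_{(i)} = \min_{j \ge i} p_{(j)} m / j$, capped at 1, input order
restored), applied over all testable genes jointly. A gene is a DEG when
$\mathrm{FDR} \le 0.001$ **and** $|\log_2 \text{ratio}| \ge 1$, both
thresholds inclusive. Genes with zero reads in both libraries are
untestable (the ratio would be substitute/substitute and the test
degenerate) and are dropped before adjustment, with their ids logged.

The default totals are *clean-read* totals. The worked-example catalogue
shipped with the package shows why the choice matters: recomputing its
printed log2 ratios from clean-read totals shifts every one of the 106
values by the same constant, about $+0.051$ — the signature of ratios
originally computed with slightly smaller (mapped-read, unprinted)
totals. The per-row differences have standard deviation below $10^{-2}$,
which is what validates the formula while exposing the totals ambiguity.
`call_degs()` therefore takes the totals explicitly and the pipeline logs
them.

### Enrichment

For a term carried by $M$ of $N$ annotated background genes, observed on
$m$ of $n$ annotated DEGs, the over-representation p-value is the
hypergeometric upper tail $P(X \ge m)$, computed in log space via
`lchoose`. The background defaults to every annotated gene in the
experiment (configurable). Correction is Bonferroni by default for GO
terms and BH for pathways (`correction = "bh"`), with significance at
adjusted $p \le 0.05$. Terms are taken as annotated — no GO-graph
ancestor propagation, since no ontology file is consumed.

### Candidate screening

Flowering-related candidates are DEGs with at least one homology hit at
e-value $\le 10^{-5}$ (inclusive). The filter is *any-hit*; the single
best hit (lowest e-value, ties by bit score, then lexicographic subject
accession) merely decorates the record. The flowering-time report groups
catalogue genes by the six pathway categories (circadian clock &
photoperiod, vernalization, autonomous, GA, age-related, floral pathway
integrators), in that order, and reports the log2 RPKM ratio to four
decimals plus the raw read fold $y/x$ truncated — not rounded — to one
decimal (`"inf"` when $x = 0$), matching how such folds are quoted.

## The simulator: what it emulates, and what it does not

`generate_counts()` draws per-gene baseline proportions from a log-normal
(sdlog 1.5, i.e. expression spread over roughly four decades, as in real
tag-count tables), normalises them, applies $2^{\pm\text{effect}}$ to a
`de_fraction` of genes on the S side (even up/down split, odd remainder
up), renormalises, and draws Poisson counts at mean
$\text{proportion} \times \text{total}$ — negative binomial with
`size = 1/dispersion` when overdispersion is requested. Defaults emulate
two libraries of 25,603,968 and 27,723,240 reads over 20,000 genes of
200–3000 bp.

Deliberate simplifications: no gene-length bias in counts beyond the
RPKM denominator, no mapping ambiguity, no assembly artefacts, and
independence across genes apart from the shared normalisation. A green
recovery test therefore establishes that the *statistics* behave as
claimed under the stated generative world — not that the pipeline is
robust to misassembly or multi-mapping, which are upstream concerns out
of scope here.

`min_mean_count` deserves a note. Power statements about count-based
tests are statements about adequately expressed genes: with an unbounded
log-normal baseline, a material fraction of genes has expected counts in
the single digits where a 4-fold change is undetectable at
$\mathrm{FDR} \le 10^{-3}$, and no threshold choice changes that. The
floor (clip-and-renormalise so every gene's expected count in the
shallower library is at least $k$) lets a simulation state "every gene
has mean count at least 50" exactly, which is the world in which the
package's sensitivity $\ge 0.90$ property is asserted. It defaults to
off.

The Poisson default also means the exact test is *correctly calibrated*
by construction in the null simulations; with `dispersion > 0` the test
is anti-conservative, which is documented behaviour (the test models
technical, not biological, variation — the reason replicate-based methods
superseded it), not a defect.

Each generator call uses its own explicitly seeded stream (seed plus a
fixed per-generator offset), so counts, annotations and hits are
individually reproducible and jointly independent.

## Design choices where the design was open

* **Sidedness**: two-sided by tail doubling, as argued above. The exact
  exchange-symmetry that a naive reading would expect does not hold for
  any doubled-tail construction; the package documents the identity that
  does.
* **Enrichment correction default**: Bonferroni for GO-style use, BH
  available and recommended for pathway sets; both exposed.
* **Untestable genes**: dropped, not assigned p = 1 — assigning 1 would
  deflate the BH adjustment of real tests for no informational gain.
* **Serialisation**: expression-scale reals at fixed four decimals
  (matching the catalogue's printed precision); probabilities at four
  significant digits, since fixed decimals would collapse small p-values
  to zero. Written tables round-trip exactly at rendered precision.
* **Table dialects**: the counts/annotation/results TSVs are this
  package's own (documented in the readers); homology hits use the
  ubiquitous 12-column tabular alignment format. Typographic minus signs
  (U+2212) in pasted tables are normalised to ASCII on input.

## Known limitations

* No replicate-aware testing; the exact test is the method implemented,
  not a recommendation for designs that have replicates.
* Enrichment treats annotations as flat labels; no GO DAG or pathway
  topology.
* The flowering catalogue is an input fixture, not re-derived: deriving
  it requires homology search against external databases, out of scope.
* P-values below roughly $10^{-300}$ underflow to 0 in the results table;
  calls are unaffected.
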