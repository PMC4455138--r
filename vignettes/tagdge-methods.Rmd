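---
title: "Methods: tag-based DGE analysis in tagdge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag-based DGE analysis in tagdge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope and model

`tagdge` analyses restriction-anchored digital gene expression (DGE)
data: each transcript copy contributes (ideally) one sequenced 21-nt tag
— the NlaIII site `CATG` plus the adjacent 17 nt — and expression is the
count of a gene's tags in a library. The package covers the whole desk
side of such an experiment: read cleaning, exact tag mapping, TPM
normalization, a two-library exact test with FDR control, fold-change
summaries, hypergeometric term enrichment, and 2^−ΔΔCt qPCR
concordance, plus a synthetic generator that emulates the data-producing
process.

The experimental design the pipeline targets has **one library per
condition** — no biological replicates. That constrains the statistics
fundamentally: no dispersion can be estimated, so the test must be an
exact conditional test on the two counts themselves, and all inference
is about sampling variation only, not biological variation. This is why
the package deliberately does not offer negative-binomial/shrinkage
machinery (edgeR/DESeq2 territory): with n = 1 per group those models
are not identifiable, and the classical exact test is the honest choice.

# The exact two-library test

For a gene with `x` tags in library A (clean total `N1`) and `y` in
library B (clean total `N2`), under the null of equal relative abundance
the conditional law of `y` given `x` is

    P(Y = y | x) = r^y (x+y)! / ( x! y! (1+r)^(x+y+1) ),  r = N2/N1.

This is exactly the negative binomial `NB(size = x+1, prob = 1/(1+r))`,
an identity the implementation exploits: tails are computed with
`stats::pnbinom`, which evaluates the regularized incomplete beta
function in log space — numerically equivalent to (and more carefully
implemented than) a hand-rolled log-gamma summation. The test suite
keeps an *independent* brute-force log-space summation oracle and checks
agreement to 1e-10 relative over a grid of counts up to 200 and library
ratios 0.5–2.

**Two-sidedness.** The p-value is `min(1, 2 · min(P(Y ≤ y), P(Y ≥ y)))`
— twice the smaller tail, capped. For discrete counts this is
conservative (at `x = y`, equal libraries, p = 1 exactly). The null
calibration tests therefore assert type-I error `≤ α + 3·SE`, not `≈ α`.

**Orientation.** The test conditions on the first library's count, so it
is *not* exactly symmetric under exchanging the two libraries: swapping
`(x, N₁) ↔ (y, N₂)` shifts one argument of the underlying incomplete
beta function by one (equal libraries, `x=0, y=5` gives p = 1/16 while
`x=5, y=0` gives 1/32). This discreteness effect vanishes for
non-extreme counts. The pipeline always conditions on the control
library, so every comparison uses one consistent, well-defined
orientation.

**Multiple testing.** Benjamini–Hochberg step-up, implemented directly
(the step-up rule is three lines and is itself a specified operation),
cross-checked against `stats::p.adjust(method = "BH")`. Which FDR
variant the original DGE pipelines used is generally unstated; BH is
this package's documented choice. BH runs across exactly the tested set:
genes with a nonzero count in at least one library.

**Zero flooring.** A gene absent from one library has TPM 0 and an
infinite ratio. Its TPM is floored at the TPM of a *single tag* in that
library (`1e6/N`), which keeps ratios finite and makes the floor
depth-aware: the deeper the library, the stronger the evidence that the
gene is really absent, and the larger the reported |log2 ratio|.

**DEG thresholds.** Defaults are FDR < 0.001 and |log2 ratio| ≥ 1, the
conventional cutoffs for this assay. Fold-change summaries bin
|log2 ratio| into [1,2), [2,3), [3,4), [4,12), ≥12 and also report the
aggregate [1,4) share — "one- to four-fold" is interpreted on the log2
ratio scale, consistent with how such distributions are plotted.

**Correlation.** Pearson r between libraries is computed on
`log2(TPM + 1)` over genes detected in at least one library. Raw TPM,
log TPM or counts are all defensible; the log scale with a pseudocount
is the documented choice because expression is log-normal-ish and zeros
must stay finite.

# Tag mapping

The index enumerates every `CATG`-anchored 21-nt window of every gene on
**both strands** by default. De novo transcriptome contigs have unknown
orientation, so sense-only indexing would silently halve sensitivity on
antisense-assembled contigs; a `both_strands = FALSE` mode exists for
oriented references, and the choice is recorded in the index object.
Mapping is exact — no mismatches — and a tag matching more than one
*gene* is ambiguous and dropped from quantification, while multiple
positions within one gene stay unambiguous (gene identity is what
matters). Offsets are 0-based, windows half-open, on the scanned strand.

The three distinct-tag classes (unambiguous / ambiguous / unmapped)
always partition the library's distinct tags; mapping statistics report
the Table-1-style percentages with **half-up rounding to 2 decimals**
(base R's round-half-even cannot reproduce conventionally printed
percentages; `round_half_up()` is exported).

# Cleaning rules

"Low quality" is not standardized for this assay; the package defines it
as any base with Phred < 10, or any ambiguous base, both configurable.
Reads equal to or containing the adaptor are removed; longer reads are
first trimmed at the adaptor and truncated to 21 nt (a read whose insert
is shorter than a full tag is dropped). No copy-number filter is applied
by default — cleaning removes artifacts, not rare tags — but a
`min_copies` option exists for protocol variants that drop singletons.

# The synthetic generator: what it emulates, and what not

`sim_config()` defaults state the generator's world:

| parameter | default | rationale |
|---|---|---|
| `library_depth` | 6e6 | raw tags per library at study scale (tests scale down) |
| `baseline_sdlog2` | 1.5 | log-normal baselines, heavy tail like real expression |
| `de_fraction` | 0.05 | between the ~2% and ~6% DEG rates seen in the two-species comparisons |
| `frac_up` | 0.5 | neutral; `simulate_study()` uses 0.8 / 0.17 per species to mirror the asymmetric up/down regulation |
| `lfc_magnitude_range` | [1, 4] | the dominant fold-change bin of such comparisons |
| `error_rate` | 0.01 | per-base substitution; yields a large unmapped distinct-tag class, as in real libraries |
| `adaptor_fraction` | 0.02 | concrete removable artifact class for the cleaner |
| `low_quality_fraction` | 0.01 | reads written with quality `#` |

`low_quality_fraction` is an addition beyond the core parameter list:
the generator must emit low-quality reads for the cleaner to remove, and
there was no stated knob for their rate.

Each gene gets one *planted* `CATG + 17` site (plus chance sites);
informative reads are the gene's **canonical tag** — the window at the
3'-most CATG site of the sense strand, matching the enzyme chemistry
that cuts at the 3'-most site. Sampling is multinomial with
probabilities ∝ `baseline × 2^lfc` (fold change applied in condition B),
errors are i.i.d. substitutions (no indels — exact-match mapping makes
substitutions sufficient to create unmapped tags), and every operation
draws from its own seeded stream derived from `config$seed`, so outputs
are byte-identical given (config, seed).

What the generator does **not** emulate: positional/sequence-composition
bias, PCR duplication structure, quality-score realism beyond a binary
high/low flag, partial digestion (multiple tags per transcript copy),
and cross-gene homology beyond chance 21-mer collisions. A green
recovery test therefore establishes that the pipeline's arithmetic and
statistics behave as designed under clean multinomial sampling — not
that real libraries meet those assumptions.

One library per condition is the default (mirroring the target design);
replicate libraries can be drawn from the same truth via the `seed`
argument of `sample_tag_library()`.

# Enrichment

Upper-tail hypergeometric over-representation per term, with the
background defined as genes carrying ≥ 1 annotation in the tested
category — not the whole transcriptome. That matches the convention in
which the "Ref" column counts pathway-annotated genes, and it is the
statistically coherent universe when annotation coverage is partial.
Raw p ≤ 0.05 is the significance filter (as conventional for this
analysis); BH-adjusted values are reported alongside for readers who
want them. GO is treated as flat term sets; DAG propagation is out of
scope. Ties in (dif, ref) sort stably by term id.

# qPCR concordance

2^−ΔΔCt with replicates averaged on the Ct scale and no
primer-efficiency correction — the plain textbook estimator. Direction
concordance with DGE uses sign agreement of log2 fold changes with an
exact-zero fold counted as non-concordant (conservative boundary rule).

# Numerical and design notes

- Percentages: half-up rounding, 2 decimals for library statistics,
  1 decimal for DEG summaries, matching conventional table formatting.
- All factorial-like quantities are evaluated in log space (via
  `pnbinom`/`phyper` internals); nothing overflows at counts ~1e3.
- Determinism: `withr::with_seed` isolates every generator call; the
  pipeline's report bundle contains no timestamps, so a rerun is
  byte-identical — and `verify_run()` recomputes every report number
  from the serialized intermediates and diffs them.
- Empty inputs are legal where a sensible value exists (empty library →
  zeroed statistics; empty DEG table → zero counts with an `empty`
  flag) and errors where none does (`clean_total = 0` normalization,
  empty enrichment background, no shared genes in concordance).

# Known limitations

- No replicate-aware dispersion modeling; sampling-noise inference only.
- Exact-match mapping cannot rescue tags with sequencing errors; at 1%
  per-base error ~19% of reads carry ≥ 1 error and become (mostly)
  unmapped, which the TPM denominator choice (clean total, not mapped
  total) deliberately reflects.
- Enrichment treats terms as independent flat sets.
- The qPCR module assumes 100% amplification efficiency.
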