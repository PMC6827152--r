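---
title: "Genome survey analysis from k-mer spectra: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome survey analysis from k-mer spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the methods it
implements: the statistical model behind each estimator, the defaults
and why they were chosen, what the synthetic-data generator does and
does not emulate, and the numerical conventions that matter when
results are compared across tools.

## The k-mer spectrum model

For reads with per-base coverage $c$, read length $L$ and k-mer length
$k$, a position of a haploid genome is the start of an error-free
k-mer window in an expected
$\lambda_0 = c\,(L - k + 1)/L$ reads. The depth of a *distinct*
canonical k-mer is approximately Poisson, and the depth histogram
$h(d)$ (distinct k-mers seen exactly $d$ times) decomposes into:

- an **error spike** at depth $\approx 1$: a substitution error turns
  up to $k$ windows into near-unique novel k-mers;
- a **heterozygous component** near $\lambda/2$: at a heterozygous
  site each allele is carried by one haplotype, so each variant k-mer
  receives half the diploid coverage;
- the **homozygous peak** at $\lambda$;
- **repeat harmonics** at $m\lambda$ for sequence present in $m$
  copies.

Note $\lambda < \lambda_0$ in the presence of errors: a window
survives error-free with probability $(1-\varepsilon)^k$, so
$\lambda = \lambda_0 (1-\varepsilon)^k$. The volume diverted into the
error spike is what the revision step removes; the two effects cancel
to first order, which is why the *revised* genome size is the
estimator of record.

### Genome size and revision

`estimate_genome_size()` is the classical identity $G = N/\lambda$
with $N$ the total k-mer volume $\sum_d d\,h(d)$ and $\lambda$ the
homozygous peak depth. `revise_genome_size()` multiplies by
$(1 - e)$ where $e$ is the *error k-mer volume fraction*: the share of
$N$ at depths at or below the error valley. The error rate entering
the revision is deliberately this spectrum-derived fraction, not the
per-base error rate implied by Phred scores — the spectrum fraction is
the quantity that actually inflates $N$ (a per-base rate of 0.03%
produces a k-mer volume fraction an order of magnitude larger, since
each error contaminates up to $k$ windows).

### Error valley and peak detection

Extremum detection runs on a centred 3-bin moving average of the dense
histogram (edges replicated); ties in the argmax break toward the
lower depth. The **valley** is the smallest depth $d \ge 2$ with
$\tilde h(d) < \tilde h(d-1)$ and $\tilde h(d) \le \tilde h(d+1)$.
Two guards make this robust on clean data:

- An error spike, when present, is by far the modal bin of the
  spectrum (millions of depth-1 k-mers against thousands at the
  coverage peak). If the depth-1 smoothed bin is *not* the modal bin,
  the spectrum is declared error-free (`no_error`), the valley is 1
  and no volume is attributed to error. Without this rule, the handful
  of genuinely low-depth k-mers near linear-genome ends (coverage
  ramps down over one insert length) triggers spurious valleys and a
  sub-basepair-scale "revision" of error-free data.
- A monotone spectrum with no local minimum likewise yields
  `no_error`.

The **peak** is the smoothed argmax above the valley, with a
heterozygous-peak guard: in a strongly heterozygous genome the
$\lambda/2$ component can be taller than the $\lambda$ peak (it is
narrower, and its distinct-k-mer weight doubles — two variants per
site). If a local maximum at least half the candidate's height exists
near twice the candidate depth (window $[1.7p,\,2.3p]$), that
full-depth maximum is returned. The height threshold of 0.5 separates
the two confusable cases cleanly: when the candidate is the true
$\lambda$ peak, the structure near $2\lambda$ is a repeat harmonic
whose height is an order of magnitude lower; when the candidate is the
$\lambda/2$ het peak, the true peak near $2p$ has comparable height.

### Heterozygosity

Counts in $(\text{valley},\,1.5\lambda]$ are fitted by least squares
with two Poisson-shaped columns centred at $\lambda$ and $\lambda/2$;
negative weights are clamped to zero with a warning (this occurs
legitimately for heterozygosity-free genomes, where the true het
weight is zero and noise makes the fitted one slightly negative). With
$a$ the fitted heterozygous share of distinct non-error k-mers, the
per-base rate is reported as
$100\,(1 - (1 - a/2)^{1/k})$.
This inversion treats $a/2$ as the probability that a genome k-mer
overlaps a heterozygous site; it is exact in the small-rate limit and
biased low by roughly 10–15% relative at $k r \approx 0.16$ (e.g.
$k = 17$, $r = 0.9\%$). The package keeps the simple closed form —
its recovery accuracy is asserted by the test suite at 25% relative
tolerance against simulator ground truth — rather than the exact
inversion $q = (2-2a)/(2-a)$, whose extra precision is far below the
fit noise on real spectra.

### Repeat ratio

Reported as the k-mer-volume share at depths beyond the homozygous
peak's reach, $d > 2\lambda - \text{valley}$, relative to all
non-error volume ($d > \text{valley}$). The threshold mirrors the
valley's distance below $\lambda$ on the other side of the two-copy
harmonic: everything the homozygous Poisson can plausibly produce is
excluded. The estimator is deliberately conservative — the lower tail
of the two-copy harmonic below the threshold is forfeited — so it
approaches the true repeat fraction from below (a planted 20% is
recovered around 16–18%); the suite asserts recovery within 5
percentage points and strict monotonicity in the planted fraction.

## The synthetic-data generator

The generator exists so every estimator above can be checked by
*parameter recovery* on data whose truth is stored, not inferred.

- **Genome**: i.i.d. bases at the requested GC fraction. Default study
  conditions mimic a small teleost-scale survey: GC 45%,
  heterozygosity ~0.9%, repeat fraction ~21%.
- **Repeats**: families of fixed-length segments
  (`repeat_unit_length`, default 500 bp) duplicated *exactly* —
  no divergence — so repeat k-mers sit at exact integer multiples of
  $\lambda$ and recovery is assertable. Copy number per family is
  geometric with minimum 2 and mean 3, reflecting the heavy-tailed
  copy-number spectra of real repeat families rather than a uniform
  "everything exactly twice" model. Placement is block-aligned and
  non-overlapping; `repeat_intervals` records donors and copies, so
  the covered fraction is the ground-truth repeat ratio.
- **Heterozygosity**: biallelic substitutions only (no indels) at
  Bernoulli(`het_rate`) positions; this keeps the k-mer theory exact
  (an indel would shift every downstream window).
- **Reads**: fragments drawn uniformly from the two haplotypes with
  equal probability; insert length Normal(350, 35) — the 10% SD is a
  free choice in the absence of a stated library SD — truncated to
  $[2L_{\text{read}}, G]$ unless overlapping mates are explicitly
  allowed; per-base substitution errors at `error_rate`; a two-valued
  quality model (`quality_high` = 36 for correct bases,
  `quality_low` = 2 for erroneous ones), sufficient for exact
  Q20/Q30/error-rate accounting without an empirical quality-profile
  model.
- **Determinism**: every stochastic step is governed by the spec seed
  and restores the caller's RNG state; identical specs give
  byte-identical FASTQ/FASTA.

What the generator does **not** emulate — and hence what passing
recovery tests do *not* establish about real data: position- and
context-dependent error profiles, indels and structural variation,
PCR duplicates and optical artifacts, adapter read-through (adapters
are only injected explicitly by QC test fixtures), diverged repeat
copies (real repeat families mutate; diverged copies leak out of the
$2\lambda$ harmonic and the repeat ratio of real genomes is
underestimated more strongly than the synthetic recovery gap
suggests), GC-coverage bias, and microsatellite mutational dynamics
(i.i.d. sequence yields mostly long-unit chance SSRs, unlike the
dinucleotide-dominated catalogues of real genomes — SSR correctness
is therefore established by brute-force oracle equivalence, not by
class-proportion realism).

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `k` | 17 | bases | Standard survey choice: $4^{17} \gg$ genome size (specificity) while windows per read stay plentiful; must be odd so no k-mer is its own reverse complement. |
| `max_depth_tracked` | 10000 | depth | Histogram truncation; deeper k-mers collapse into the last bin with their volume preserved exactly, so size estimates are unaffected. |
| QC `max_n_frac` | 0.1 | fraction | Common survey practice; pairs are dropped jointly, never orphaned, to keep k-mer coverage unbiased. |
| QC `min_q` / `max_lowq_frac` | 5 / 0.5 | Phred / fraction | A read with half its bases below Q5 contributes mostly error k-mers. |
| GC-depth `window` | 500 | bases | Small enough to resolve compositional heterogeneity, large enough (~30 GC percentage-point resolution at 1 base) for stable per-window depth means; trailing windows under half a window merge into their predecessor so no under-sampled fragment windows are reported. |
| SSR `min_total_len` | 12 | bases | Complete copies only; implies minimum copy numbers 6/4/3/3/2 for unit lengths 2–6 (two pentamer copies are 10 bp < 12, so pentamers need three). |

## Numerical conventions and degenerate inputs

- Coordinates are 0-based half-open everywhere (records, intervals,
  windows).
- Canonical k-mers are 2-bit encoded (A<C<G<T matches lexicographic
  order) and counted exactly in a hash table — no sketches; codes fit
  a double exactly for $k \le 26$.
- `estimate_genome_size()` is real division; rounding to Mbp happens
  only at the reporting layer.
- N50/N90 "reaches" means $\ge$; ties among equal lengths are then
  harmless. Scaffold lengths include N gaps by default (toggleable).
- SSR maximality: within one periodic region whose length is not an
  exact unit multiple, the leftmost-phased complete-copy run is
  reported; records of the same unit length never overlap; a span
  expressible with several unit lengths belongs to the shortest
  primitive unit.
- Degenerate inputs fail loudly: empty read batches, empty sequence
  sets, zero peak depth and infeasible generator specs raise errors;
  zero-length sequences and sub-k sequences are skipped with warnings;
  a coverage so low that zero pairs would be drawn is an error, not an
  empty file.

## Problem sizes used for validation

The suite validates parameter recovery on a 1 Mb diploid genome at
~70× k-mer depth (0.9% heterozygosity, 20% repeats, 45% GC, 0.3%
error), a scale at which peak location is stable to ±1–2 depth units
and recovery tolerances (5% on revised size, 25% relative on
heterozygosity, 5 points on repeat percent, 1 point on GC) are
comfortably discriminating; oracle-equivalence checks run the SSR
scanner against exhaustive enumeration on 1,000 random kilobase
sequences and the N50/N90 code against literal accumulation on 1,000
random length multisets.

## Known limitations

- The two-component heterozygosity fit ignores the repeat series; a
  joint nonlinear fit over a copy-number ladder (GenomeScope-style)
  would be more accurate on repeat-rich genomes but is out of scope.
- Ploidy is assumed 2 throughout.
- The repeat-ratio rule counts volume, not sequence classes; nested
  and diverged repeats are not resolved.
- GC–depth uses k-mer depth as a proxy for mapped-read depth; the two
  differ near assembly gaps and in high-error regions.
- The QC stage drops whole pairs; it never trims, so adapter-bearing
  reads cost their full pair.
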