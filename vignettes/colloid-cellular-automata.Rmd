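---
title: "Colloid cellular automata: model, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colloid cellular automata: model, measures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colloidca)
```

## The model

Boolean functions can be mined from colloidal substrates — ZnO
nanoparticle suspensions, proteinoid microspheres, and their mixture —
by driving electrode pairs with all combinations of 2-, 4- or 8-bit
voltage-encoded strings and inferring, from the recorded responses,
which sum-of-products (SOP) function the substrate implements.
`colloidca` starts where that mining ends: it ships the catalogue of 46
such functions (plus the degenerate constant-false response), compiles
each into a cellular-automaton transition rule, and asks how complex the
dynamics of the resulting automata are.

The automaton is a one-dimensional array of binary cells updated
synchronously. A rule of arity $k \in \{2, 4, 8\}$ reads the $k$ nearest
neighbours of a cell — never the cell itself — with the fixed layout

* $k = 2$: offsets $(-1, +1) \mapsto (A, B)$,
* $k = 4$: offsets $(-2, -1, +1, +2) \mapsto (A, B, C, D)$,
* $k = 8$: offsets $(-4, \dots, -1, +1, \dots, +4) \mapsto (A, \dots, H)$,

so for example the four-input rule
$(A \cdot B \cdot D \cdot \bar C) + (C \cdot D \cdot \bar A \cdot \bar B)$
reads $x^{t+1}_i = (x_{i-2} x_{i-1} x_{i+2} \bar x_{i+1}) +
(x_{i+1} x_{i+2} \bar x_{i-2} \bar x_{i-1})$. Compilation enumerates all
$2^k$ neighbour assignments into a lookup table (`truth_table()`), with
variable $A$ as the most significant index bit — one documented
convention, fixed once, since the SOP notation itself never needs one.

```{r}
get_rule("f7")$outputs   # the two-input XOR
```

The canonical study scale is 500 cells evolved for 500 synchronous
updates; a run is stored as the full space-time diagram, a binary matrix
with 501 rows (the initial configuration is row 0 and is included in all
measures — "space-time configuration" naturally includes $t = 0$, and
the convention is stated so results are comparable).

## Boundaries and initial conditions

The default boundary is absorbing (fixed zero): cells beyond the array
are read as permanent 0s. This choice reproduces the reflection
phenomenology of single-seed XOR runs, where the Sierpinski cone meets
the array edge and reflects; a periodic boundary is available by flag
and is the natural setting for shift-equivariance properties.

Three initial conditions cover the package's experiments:

* `init_single_seed(n)` — one cell in state 1 at the centre
  $\lceil n/2 \rceil$; under the XOR rule this produces Pascal's
  triangle mod 2 (the Sierpinski gasket), which doubles as an exact
  oracle in the test suite.
* `init_two_seeds(n, offset)` — seeds at centre $\pm$ offset (default
  200 on 500 cells, i.e. cells 50 and 450); the two fractal cones
  collide and the collision region is measurably denser than either
  parent cone.
* `init_random(n, p, seed)` — i.i.d. Bernoulli($p$) cells.

The original study never states the initial conditions behind its
measured complexity table. For measurement runs the package therefore
**declares** a protocol rather than inheriting one:
`init_random(n, 0.5, seed)` with the seed recorded in every output
record. Density 0.5 is the maximum-entropy, assumption-free choice for
a binary lattice and exercises every rule's full transition table from
step one. The consequence is spelled out below: per-function absolute
measure values are not comparable with the printed ones, while
structural findings (hierarchy tops, class assignments, correlations on
the printed table itself) are.

## The five measures

Let $L$ be the space-time matrix. For every position whose full
$3 \times 3$ space-time neighbourhood lies inside $L$ (no padding — no
padding convention is documented in the source material, and
completeness keeps the census identity exact), the census
`block_census()` records which of
the $512$ binary window configurations occurs. A position is
*non-quiescent* when any of its nine cells is 1; their number is
$\eta$, and the counts $\nu(w)$ of non-all-zero configurations sum to
$\eta$ exactly. Two readings of the 9-cell window were possible (a
Moore neighbourhood in space-time, or nine cells within a row); the
space-time Moore window is adopted, being the natural neighbourhood of
a *matrix* position.

* **Shannon entropy** $H = -\sum_w \frac{\nu(w)}{\eta}
  \ln \frac{\nu(w)}{\eta}$, in nats (a base option exists; the study
  convention is $\ln$). The all-zero configuration is excluded — the
  only reading under which $\nu/\eta$ is a probability distribution.
  $H = 0$ when $\eta = 0$.
* **Simpson index** $S = \sum_w (\nu(w)/\eta)^2$, the concentration of
  the census: 1 when a single configuration dominates, $1/m$ under
  uniformity over $m$ configurations. A convention caveat: the
  *published values and hierarchies* for this measure behave as the
  ecological diversity index $1 - \sum p^2$ (diverse chaotic rules
  score high). `simpson_diversity()` implements the printed
  $\sum p^2$ formula; wherever the package ranks functions "by Simpson
  diversity" it ranks by $1 - S$, so that more diverse censuses rank
  higher. Both facts are documented here once and applied consistently.
* **Space filling** $D$: the fraction of 1s in the whole matrix.
* **Expressiveness** $E = H / D$, the "economy of diversity"; defined
  as 0 (with a warning) when $D = 0$.
* **LZ complexity**: the byte size of the diagram under a
  deflate-family (LZ77-derivative) codec, plus $LZ/n$ normalised by the
  input-string size $n$. Two codecs are reported because the historical
  descriptions disagree (PNG file size in one place, ZIP in another)
  and PNG byte size varies across encoders: `raw-deflate` compresses
  the row-major bit-packed matrix with zlib and is the pinned,
  cross-platform-stable codec used for hierarchies; `png-fixed` is the
  size of the package's own deterministic 1-bit PNG (filter 0, single
  IDAT, no ancillary chunks), so a saved PNG's file size *is* its
  reported measure.

```{r}
m <- matrix(0L, 10, 10); m[5, 5] <- 1L
h <- block_census(m)
c(eta = h$eta, H = shannon_entropy(h), S = simpson_diversity(h))
```

## Hierarchies, fits and classes

`rank_hierarchy()` sorts functions by a measure and groups adjacent
values into one level when they differ by less than 10% of the
measure's range over the input, marking a boundary `>>` when the jump
is at least 30% of range. No numeric rule for "slightly lower" versus
"significantly lower" exists in the source material, so these two
thresholds are explicit, configurable, and — being range-relative —
invariant under positive affine rescaling of the measure.

`linear_fit()` / `cross_measure_stats()` are ordinary least squares with the
product-moment correlation; $R^2 = r^2$ holds identically for the
simple regression. Fitted on the packaged printed measure table
(`printed_measures()`), they recover the published regression lines and
correlations; two typographically ambiguous rows of that table are
stored under the unique reading consistent with $E = H/D$ and with the
published fit coefficients (f20: $D = 0.32$, $E = 3.4$; f37: $D = 0.1$,
$E = 12.0$).

`classify_wolfram()` operationalises the qualitative behaviour classes
on the last $\max(2P, 50)$ rows of a run (transients are dynamics, but
class labels describe asymptotics): Class I is a homogeneous fixed
point, Class II any detected period $\le P = 16$ including frozen
heterogeneous states, Class III everything else. Class IV (interacting
gliders) is never auto-assigned: glider detection is out of scope and
none of the catalogued rules shows it.

```{r}
classify_wolfram(ca_evolve("f2", init_random(500, 0.5, seed = 1), 500))
```

## Numerical and degenerate-input choices

* Tie-breaks in ranking are stable: equal values keep input order.
* `detect_period()` verifies a candidate period over a window of
  `max_period` rows, so a "period" is never certified from a single
  repeat.
* Degenerate conventions — $H = S = 0$ at $\eta = 0$, $E = 0$ at
  $D = 0$ — are the limits that keep records well-defined for the
  constant-false rule, which is a genuine catalogue member.
* The catalogue stores one row per (id, source-table) occurrence; an id
  recurring across substrates is verified on load to denote one and the
  same Boolean function. The long 41-term eight-input entry carries a
  term-count audit enforced by the loader. Two entries whose printed
  source is typographically mangled (f38, split across lines; f46, an
  unbalanced parenthesis) are transcribed conservatively and flagged
  `uncertain` rather than silently repaired.

## What the synthetic protocol does and does not show

Everything measured here is measured on simulations the package itself
generates; there is no hidden data. The declared random-0.5 protocol
reproduces the *structure* of the published findings — XOR/XNOR
(f7/f8) top every two-argument hierarchy; OR-like saturating rules
land at the bottom by compressibility; f2/const0 are Class I and f7/f8
Class III — and the regression statistics are reproduced exactly from
the printed table. It does **not** reproduce per-function absolute
measure values, for three stacked reasons: the source's initial
conditions are unknown, its census variant is under-specified, and its
LZ units are unstated. One printed row (f11: $H = 0.07$, $D = 0.98$) is
provably unreachable for the catalogued f11 under *any* protocol — the
all-ones configuration maps to all-zeros under that rule, so no run can
fill 98% of space-time with 1s — and accordingly f11's position at the
bottom of the entropy and diversity hierarchies is not reproduced: its
slow decay to quiescence leaves a long, census-diverse transient.
Passing tests therefore certify the engine, the measures and the
statistics, not the unknown protocol behind the printed per-function
values.

Problem sizes: simulations in the package's tests run at the full
500-cell, 500-step study scale (the complete 47-rule measurement sweep
takes well under a minute on a desktop CPU); property tests that need
many repetitions use smaller lattices (40–300 cells) chosen to keep the
checked property non-trivial — e.g. long enough runs for light cones to
spread and for transients to die out.

## Limitations

Only one-dimensional, synchronous, deterministic binary automata are in
scope; no asynchronous updating, probabilistic rules or 2D/3D lattices.
No Boolean minimisation is performed on the catalogue expressions. The
complexity suite is the five measures above — fractal dimension,
Lyapunov exponents and network measures are out of scope, as is formal
Class IV (glider) detection.
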