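---
title: "Exact brain-network identification numbers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact brain-network identification numbers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubnin)
```

## The representation

A subject's binary brain network is a symmetric $T \times T$ adjacency
matrix $A$ with $A_{ij} \in \{0, 1\}$, $A_{ii} = 0$: node $i$ is a brain
region in a fixed parcellation, and $A_{ij} = 1$ records a connection. Since
$A$ is symmetric with a zero diagonal, all its information sits in the
strict upper triangle. Column $i$ of that triangle holds $i - 1$ bits
(rows $1 \dots i-1$); read bottom-to-top with the bottom row as the most
significant bit, it is one binary number whose base-10 value this package
calls the column code
$$\mathrm{DEC}(i) \;=\; \sum_{r=1}^{i-1} A_{ri}\, 2^{\,r-1},
\qquad 0 \le \mathrm{DEC}(i) \le 2^{\,i-1} - 1 ,$$
with $\mathrm{DEC}(1) = 0$ always. The vector
$\mathrm{DEC}(1 \dots T)$ determines $A$ exactly
(`column_code()` / `matrix_from_column_code()`).

The *principal node* of one network is its highest-degree node
(`principal_node()`). Across a cohort, the node that is most often the
principal node is the *maximally occurring principal node* MN
(`maximally_occurring_principal_node()`); it can also be fixed from the
literature, e.g. the parcel containing a disease-relevant region, via
`mn_override` / `--mn`.

## The modified encoding and its field layout

`encode_modified()` packs the whole code vector into a single rational
number. $\mathrm{DEC}(\mathrm{MN})$ becomes the integer part. The remaining
codes, in ascending node order $s_1 < s_2 < \dots < s_{T-1}$ (node MN
removed), are nested into the fraction by the recurrence
$$V \leftarrow V \cdot 2^{-w(s_{k-1})} + \mathrm{DEC}(s_k),
\qquad k = 2, \dots, T-1,$$
followed by a final wrap
$\mathrm{UBNIN\text{-}M}_{T,\mathrm{MN}} = V \cdot 2^{-T} +
\mathrm{DEC}(\mathrm{MN})$, where $w(i)$ is the bit width allotted to node
$i$'s column:
$$w(i) = (i - 1) + [\, i = \mathrm{MN} + 1 \,].$$

Unrolled, every column occupies its own disjoint bit field of the binary
fraction, in descending node order below the binary point: the top node
gets $T$ bits from the wrap, every other node gets exactly its
strict-upper width $i - 1$, and the node immediately following the skipped
MN carries one spare (always zero) bit. Three properties follow directly
from the disjoint fields:

* **Integer-part law** — the fraction is below 1, so
  $\lfloor \mathrm{UBNIN\text{-}M} \rfloor = \mathrm{DEC}(\mathrm{MN})$.
* **Bounded fraction** — the top field holds
  $\mathrm{DEC}(s_{T-1}) < 2^{T-1}$ in $T$ bits, so the bit at $2^{-1}$ is
  always clear and the fractional part is below $1/2$.
* **Injectivity and exact decodability** — distinct matrices occupy
  distinct field patterns; `decode_modified()` peels the fields back off,
  and rejects (never rounds) any value that is not exactly a valid code
  for its $(T, \mathrm{MN})$.

The layout, including the spare bit at node $\mathrm{MN}+1$, is pinned
character-for-character to the published 66-fractional-digit worked value
of the canonical 12-node example (`make_worked_example()`, MN = 3): that
constant is the normative definition of the scheme here, which is why the
codec identifier is `"worked-example"`. The closed-form display that
circulates alongside that constant is not internally consistent with it —
evaluated exactly, it yields a different number — so this package follows
the constant, the only artifact precise to the last digit. The test suite
asserts the encoder reproduces it exactly and that decoding it returns the
original network.

`encode_classic()` is the unskipped variant (recurrence
$V \leftarrow V \cdot 2^{-(k-1)} + \mathrm{DEC}(k)$ over all columns,
integer part $\mathrm{DEC}(T)$). The original formulation it aligns with is
not restated in the material the modified scheme comes from, and the one
published classic value belongs to a matrix that is not available, so the
function is documented as best-effort; its field layout is disjoint in the
same way, hence it is injective and is the default encoder of the
uniqueness experiment.

## Why exact rational arithmetic

A 12-node value already needs 67 significant bits; a 64-bit double carries
53. Worse, rounding silently destroys the low-order fields — exactly the
columns of the low-index nodes — so a floating-point implementation can
encode two different networks to the same double. The codec therefore runs
entirely on hand-written arbitrary-precision naturals (limb vectors in base
$10^7$, `R/bignum.R`) wrapped as dyadic rationals, reduced to lowest terms.
Encoded values are serialized by `to_decimal_string()` as full terminating
decimals (a dyadic rational always terminates; the digit count equals the
exponent of 2 in the reduced denominator) and re-enter via
`parse_decimal_string()`, which accepts only plain decimal numerals —
floats are refused at every program boundary. The arithmetic layer is
property-tested against double arithmetic below $2^{50}$, where doubles are
themselves exact, and on decimal/shift round trips far beyond it.

Base $10^7$ was chosen so that every limb product and carry stays below
$2^{53}$ (keeping plain double arithmetic on limbs exact) while decimal
serialization is a straight concatenation of limbs.

## Tunable parameters

| parameter | where | default | meaning |
|---|---|---|---|
| `mn` / `mn_override` | encoders, cohort, CLI | cohort mode per group | principal node whose code becomes the integer part |
| `p` | `random_adjacency()`, experiment | 0.5 | Bernoulli edge probability; 0.5 = uniform over all networks, i.e. no sparsity constraint |
| `n_nodes` | experiment, generator | 10 | network size of the simulation |
| `n_iter` | experiment | — | number of random networks |
| `seed` | generator, experiment, CLI | none | RNG seed; recorded in the result object and the CLI log |
| `--display-digits` | CLI | off | lossy display truncation only; stored output is always exact |

Tie rules are deliberately deterministic and documented rather than
configurable: the principal node takes the smallest index among
highest-degree nodes, and the cohort mode takes the smallest index among
equally frequent principal nodes. The source material never states a tie
rule; smallest-index is this package's choice, made because it reproduces
the canonical example's designation of node 3 (whose maximum degree 8 is
shared with nodes 7 and 11) and because any stable rule keeps cohort
encodings reproducible.

## The random-network generator and what the experiment shows

`random_adjacency()` draws each strict-upper cell as an independent
Bernoulli($p$) bit from R's seeded RNG and mirrors it; the diagonal stays
zero. `uniqueness_experiment()` draws the same stream in vectorized chunks
(a regression test pins the equivalence to sequential generation), encodes
every network with the exact codec, and counts pairwise-distinct values.
The default conditions — 100,000 iterations, $10 \times 10$ matrices,
$p = 0.5$ — mirror the published uniqueness run. Because the decoder exists,
the map is injective for fixed $(T, \mathrm{MN})$; a collision can only
mean two identical matrices were drawn (probability
$\approx \binom{10^5}{2} 2^{-45} \approx 1.4 \times 10^{-4}$ across the
whole run), and any colliding pair is reported with its matrices.

What the generator does *not* emulate: real grey-matter-derived networks
are not Bernoulli — their edges are correlated, degree distributions are
heavy-tailed, and cohort matrices share structure. Passing the uniqueness
experiment therefore demonstrates the codec's injectivity under the stated
random model, not that two patients' empirical networks must differ;
identical (or identically thresholded) connectomes encode identically by
design.

## Numerical and degenerate-input choices

* Node count is capped at 54: column $i$ carries $i - 1$ bits and codes
  are exchanged as R doubles, exact up to $2^{53}$. Inputs beyond the cap
  are rejected with an explicit error. Encoded values themselves have no
  such cap internally.
* Validation is strict: non-binary entries, asymmetry and self-loops are
  errors with coordinates, not coercions (`symmetrize = TRUE` opts into
  OR-symmetrization).
* `decode_modified()` is strict: non-dyadic denominators, any recovered
  code above its $2^{i-1}-1$ bound (this includes a set spare bit), and
  non-zero residuals are rejected.
* Degenerate cases: $T = 1$ encodes only classically (value 0); an
  all-zero network encodes to 0 under both schemes; $p = 0$ and $p = 1$
  give the empty and complete graphs.
* Cohorts must be homogeneous in node count and node order — the codes are
  only comparable when node $i$ means the same region for every subject.

## Problem sizes used by the shipped checks

The test suite verifies the worked 12-node example exactly; round-trip
identity on 1,000 random 10-node networks and exhaustively on all
$2^{10} = 1024$ five-node networks; injectivity exhaustively at five nodes
for every choice of MN (and for the classic scheme); and the full
100,000-iteration uniqueness experiment at $10 \times 10$, $p = 0.5$.
`scripts/acceptance.R` re-runs the worked example, the decode round trip
and the full experiment from scratch.

## Known limitations

* Weighted or directed networks are out of scope; so is constructing the
  binary networks from MRI volumes in the first place.
* The classic encoder is a best-effort alignment (see above) and has no
  decoder here; decoding is defined for the modified scheme.
* Values encoded with different MN live on different layouts; comparability
  across MN choices is not claimed, which is why cohort encoding forces one
  MN per group (or one global override).
* The 54-node cap excludes some whole-brain parcellations; within the
  supported range the codec is exact end to end.
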