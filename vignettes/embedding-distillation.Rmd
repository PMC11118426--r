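---
title: "Embedding distillation: counting and fixing gauge freedoms in equivariant sequence-function models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedding distillation: counting and fixing gauge freedoms in equivariant sequence-function models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqgauge)
```

## The model class

A linear model of a sequence-function relationship assigns to each sequence
$s$ over an alphabet of size $\alpha$ (length $L$) the value
$f(s;\theta) = \theta^\top x(s)$, where $x(\cdot)$ is an $M$-dimensional
feature embedding. `seqgauge` works with embeddings built as direct sums of
Kronecker products of *single-position* embeddings over position sets
$A_1,\dots,A_J \subseteq \{1,\dots,L\}$:

* **one-hot** flavor: each position contributes the $\alpha$-dimensional
  indicator of its character, so block $j$ has dimension $\alpha^{|A_j|}$
  and features are indicators of character combinations ("generalized
  one-hot models" — this covers constant, additive, pairwise,
  nearest-neighbor and all higher-order interaction models);
* **simplex** flavor: each position contributes the zero-centered
  $(\alpha-1)$-dimensional encoding in which characters
  $c_1,\dots,c_{\alpha-1}$ map to standard basis vectors and the *last*
  alphabet character maps to the all\-$(-1)$ vector.

A `sfr_model()` records the alphabet (whose order is contractual: it fixes
feature indexing and designates the simplex reference character), $L$, the
flavor, and the ordered list of position sets. `sfr_preset()` provides the
standard families. Within a block, Kronecker factors are ordered by
ascending position with earlier positions varying slowest; blocks appear in
the listed order. These conventions fix the meaning of every feature label
(`theta_0`, `theta_1,2:AB`, `theta_1,2:1,2`, …) bit-exactly, which matters
because parameter TSVs and the CLI round-trip through those labels.
Duplicate position sets are legal (they produce duplicated blocks and a
`#2`-style label suffix); the empty set denotes the constant feature. The
degenerate empty model ($J=0$, $M=0$) is accepted so that the class
enumeration below can include it.

## Gauge freedoms and the symmetry group

A gauge freedom is a vector $g$ with $g^\top x(s) = 0$ for all sequences —
the null space $G$ of the $\alpha^L \times M$ design matrix. The brute-force
route to $\gamma = \dim G$ (enumerate, SVD) is implemented in
`nullspace_dim()`/`nullspace_basis()` and kept deliberately independent of
everything else: it is the oracle against which the fast path is certified.

The fast path uses the group $H$ of position-specific character
permutations (PSCP): an element applies an arbitrary character permutation
at each position independently, preserving Hamming distances. Both flavors
are *equivariant*: $x(hs) = R(h)\,x(s)$ where $R(h)$ is the direct sum of
Kronecker products of single-position representation matrices — permutation
matrices for one-hot, the integer "standard representation" matrices for
simplex. `simplex_rep_single()` is assembled by solving against the simplex
embedding vectors themselves (whose first $\alpha-1$ members are the
standard basis), *not* by conjugating the permutation representation, so the
Maschke identity checked by `check_maschke_single()` remains a genuine
cross-check rather than a tautology.

Equivariance implies the compensation identity
$f(s;\theta) = f(hs; (R(h)^{-1})^\top\theta)$, implemented as
`transform_parameters()` with the inverse taken exactly as the
representation of $h^{-1}$ (all matrices stay integral). One consequence
worth spelling out because it is easy to get backwards: for the simplex
flavor at $\alpha = 3$, the swap $A \leftrightarrow C$ has
$R = \bigl(\begin{smallmatrix}-1&0\\-1&1\end{smallmatrix}\bigr)$, an
involution, so the compensating parameter map is $\theta \mapsto R^\top
\theta$: $\theta^1 \mapsto -\theta^1 - \theta^2$, $\theta^2 \mapsto
\theta^2$. Applying $R$ itself to $\theta$ does *not* preserve predictions;
the test suite pins the $R^\top$ form by solving the compensation identity
over the full sequence space.

## The distillation

The single-position one-hot embedding splits as trivial $\oplus$ simplex
under the similarity matrix $T$ (`similarity_T()`): first row all ones, row
$i{+}1$ has $+1$ in column $i$ and $-1$ in the last column; its inverse has
entries in $\frac{1}{\alpha}\mathbb{Z}$ and is written in closed form.
Distillation is the composition of three sparse similarity transformations
of feature space:

1. **`build_Tdecom()`** applies $\bigotimes_{l \in A_j} T$ to each block
   and then permutes coordinates *within* the block so that, for every
   subset $B \subseteq A_j$, the coordinates transforming as
   $\bigotimes_{l\in B}(\text{simplex})$ are contiguous. The within-block
   grouping order is ours to choose (any choice differing by a permutation
   satisfies the same contracts): sub-blocks are ordered by $|B|$ ascending,
   then lexicographically by positions; inside a sub-block the natural
   Kronecker order is kept, which makes the sub-block coincide exactly with
   the simplex Kronecker embedding of $B$. Applied to $x(s)$, block $j$
   becomes the stack of $\prod_{l\in B} x^{\mathrm{sim}}_l(s)$ over all
   $B \subseteq A_j$ — so equal subsets appearing under different $A_j$
   yield *equal* (not merely proportional) coordinate runs. The
   implementation relies on that equality with constant $+1$ and the test
   suite asserts it exhaustively.
2. **`build_Tthin()`** replaces every non-first copy of each subset's
   sub-block by (copy − kept copy), which vanishes on every sequence
   embedding. The kept copy is the first in scan order (smallest $j$, then
   the within-block order above). Since distinct copies live in disjoint
   column ranges, entries stay in $\{-1,0,+1\}$, and the inverse simply
   re-adds the kept copy.
3. **`build_Tsort()`** is the permutation moving the kept sub-blocks to the
   top (ordered by $|B|$, then lexicographically) and the zeroed
   coordinates to the bottom.

`distill()` returns $T_{\mathrm{dist}} = T_{\mathrm{sort}} T_{\mathrm{thin}}
T_{\mathrm{decom}}$ with its inverse assembled from the factors' closed-form
inverses (never by numerical inversion), the distinct subsets $B_k$ with
multiplicities $Q_k$ (the number of $A_j$ containing $B_k$), and the
distilled model: the simplex-flavor model over the distinct $B_k$. For
every sequence, $T_{\mathrm{dist}}\,x(s)$ equals the distilled model's
embedding stacked on $\gamma$ zeros, where

$$\gamma = M - \sum_k (\alpha-1)^{|B_k|} = \sum_k (Q_k-1)(\alpha-1)^{|B_k|}.$$

`count_gauge()` evaluates both expressions combinatorially (they must
agree; disagreement is an internal error, not a warning) with no matrix
construction, so it works for pairwise models at $L$ in the thousands.
Simplex-flavor models enter the same pipeline with
$T_{\mathrm{decom}} = I$: their blocks are already irreducible, and only
duplicated position sets produce thinning (a mild generalization of the
"distinct subsets" case, at no extra cost).

Because all three factors have $\{-1,0,+1\}$ entries and the composition
introduces no cancellation across blocks, every nonzero entry of
$T_{\mathrm{dist}}$ is $\pm 1$; its last $\gamma$ rows are a sparse signed
basis of the gauge space (`gauge_basis()`).

## Gauge fixing

`projection_matrix()` returns
$P = T_{\mathrm{dist}}^\top D\, (T_{\mathrm{dist}}^{-1})^\top$ with $D$ the
diagonal selector of the first $M-\gamma$ coordinates: idempotent,
prediction-preserving, annihilating the gauge basis, of rank $M-\gamma$.
Its image — the "distilled gauge" — is *one* valid linear gauge; no claim
is made that it coincides with the classical zero-sum gauge.
`zero_sum_check()` tests zero-sum membership separately (pairwise one-hot
models only, where that gauge is conventionally defined), and the
relationship between the two is left empirical.

## Numerical choices

* All embeddings, representations, $T_{\mathrm{dist}}$ and the gauge basis
  are integer-valued; certificates on them ("last $\gamma$ coordinates are
  zero", "basis annihilates the design matrix") are asserted *exactly*
  (`== 0`), since products of small integers are exact in doubles.
* Quantities passing through $T^{-1}$ (entries in
  $\frac{1}{\alpha}\mathbb{Z}$) or through random parameters use an
  absolute tolerance of $10^{-9}$.
* The oracle's rank uses a $10^{-9}$ relative singular-value cutoff;
  design-matrix entries are in $\{-1,0,1\}$ and the spectra at certified
  sizes are well separated, so the rank is not fragile.
* Sequence enumeration is capped (default $10^6$) and exceeding the cap is
  an explicit error; the analytic path has no cap.
* Prediction TSVs are written with 12 significant digits so that
  gauge-equivalent parameter files produce byte-identical outputs.

## Class enumeration

Each irreducible embedding is determined by a subset of positions (simplex
factors on the subset, trivial elsewhere), giving $2^L$ irreducibles and
$2^{2^L}$ inequivalent distilled embeddings — i.e. equivalence classes of
equivariant linear models by expressivity. `enumerate_model_classes()`
materializes each class as a simplex model over a family of distinct
subsets (including the empty family), every one of which is gauge-free;
it refuses $L > 4$.

## What the tests do and do not establish

The certification suite is exhaustive but small: every preset at
$(\alpha, L) \in \{2,3,4\} \times \{2,3\}$ (with all valid $K$), plus
hand-picked duplicate-set and degenerate models. Within that suite the
package proves, sequence-by-sequence, that distillation is exact and that
analytic counts equal design-matrix rank deficits. For larger models the
counts and $T_{\mathrm{dist}}$ are produced by the same code paths but the
exhaustive certificate is no longer run — correctness there rests on the
structure of the construction, not on re-verification. The sparsity claim
is likewise checked only as a bounded nonzero-count ratio on pairwise
models at $L = 4, 8, 16$, not as an asymptotic statement.

There is no data fitting anywhere in the package: models are specified, not
estimated, and the "synthetic data" used by the tests are the enumerated
sequence spaces, seeded random group elements, and seeded random parameter
vectors — real measurement noise, missing sequences and fitted-parameter
uncertainty are outside its scope.

## Known limitations

* Only the PSCP symmetry group is treated; global character permutations,
  position permutations and the full Hamming group have different (or
  failing) distillation theory and are not implemented.
* Wild-type models, physicochemical-property embeddings and parametric
  gauge families (zero-sum, wild-type gauges as projections) are out of
  scope; `zero_sum_check()` only tests membership for pairwise one-hot
  models.
* The brute-force oracle is exponential in $L$ by design; it exists to
  certify, not to scale.
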