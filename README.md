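# seqgauge

Gauge freedoms of linear sequence-function models, analyzed through the
symmetry group of sequence space.

## The problem

Quantitative models of sequence-function relationships — additive, pairwise
and higher-order interaction models over DNA, RNA or protein alphabets, the
workhorses of deep mutational scanning and massively parallel reporter
analyses — are almost always over-parameterized. There are directions **g**
in parameter space with

    f(s; θ + g) = f(s; θ)   for every sequence s,

so individual parameter values (e.g. Potts couplings) are meaningless until
a *gauge* is fixed. These gauge freedoms form the null space **G** of the
design matrix, but computing that null space by elimination or SVD requires
enumerating sequences and is hopeless beyond small L.

`seqgauge` exploits symmetry instead. Linear models built from one-hot
embeddings are *equivariant* under the group of position-specific character
permutations (PSCP): `x(hs) = R(h) x(s)` for a matrix representation `R`.
By Maschke's theorem `R` decomposes into irreducible representations, and
gauge freedoms arise exactly from the *redundant* irreducible components.
An **embedding distillation** — a sparse similarity transformation

    T_dist = T_sort · T_thin · T_decom

— maps the embedding of a generalized one-hot model (position sets
A_1, …, A_J, M = Σ_j α^|A_j| parameters) onto a full-rank simplex embedding
over the distinct position subsets B_1, …, B_K stacked on a γ-dimensional
zero block, where

    γ = M − Σ_k (α−1)^|B_k| = Σ_k (Q_k − 1)(α−1)^|B_k|,

with Q_k the number of A_j containing B_k. This yields:

* `count_params()` / `count_gauge()` — closed-form parameter and gauge
  counts, pure integer combinatorics, usable at L in the thousands;
* `distill()` — the sparse `T_dist` (all nonzero entries ±1) whose last γ
  rows are a sparse signed basis of **G** (`gauge_basis()`);
* `projection_matrix()` / `project_parameters()` — an idempotent
  gauge-fixing projection that never changes a prediction;
* a brute-force SVD oracle (`nullspace_dim()`, `nullspace_basis()`,
  `span_equal()`, `verify_model()`) that certifies all of the above on
  small sequence spaces.

## Worked example

The all-order interaction model on three-letter sequences over the alphabet
{A,B,C} (every subset of positions interacts):

```r
library(seqgauge)
model <- sfr_preset("all-order", "ABC", 3)
model
#> Linear one-hot model on {A,B,C}^3
#>   J = 8 position sets, M = 64 parameters
#>   sets: {} {1} {2} {3} {1,2} {1,3} {2,3} {1,2,3}

d <- distill(model)
d
#> Embedding distillation: M = 64, gamma = 37, K = 8 distinct subsets
#>   nonzeros in Tdist: 603 (all +/-1)
#>   redundant subsets (Q_k > 1): 7
```

Of the 64 parameters, 37 directions are gauge freedoms: the model's 8
Kronecker blocks expand into 27 irreducible simplex components (dimension
Σ_k (α−1)^|B_k| = 27 = α^L), and everything beyond one copy of each is
redundant. The last 37 rows of `T_dist` are a sparse ±1 basis of the gauge
space, certified exhaustively:

```r
B <- gauge_basis(d)                       # 37 x 64, entries in {-1,0,+1}
is_gauge_vector(model, as.numeric(B[1, ]))
#> TRUE
nullspace_dim(model)                      # independent SVD oracle
#> 37
```

The same machinery counts without building anything — e.g. the pairwise
one-hot model on 10-mers over ACGT:

```r
mp <- sfr_preset("pairwise", "ACGT", 10)
count_params(mp)   # 761
count_gauge(mp)    # 325  ( = L + choose(L,2)(2*alpha - 1) )
```

## Command line

`inst/cli/seqgauge.R` wraps the package for shell use (JSON model configs,
MatrixMarket matrices, TSV parameters, FASTA sequences):

```sh
Rscript inst/cli/seqgauge.R count   --config model.json
Rscript inst/cli/seqgauge.R distill --config model.json --out run.json
Rscript inst/cli/seqgauge.R verify  --config model.json
Rscript inst/cli/seqgauge.R evaluate --config model.json \
    --theta theta.tsv --fasta seqs.fasta --out predictions.tsv
```

## Acceptance script

`scripts/acceptance.R` rebuilds the all-order model on {A,B,C}^3 from
scratch, measures its embedding dimension, runs the distillation with the
exhaustive certificate enabled, cross-checks the gauge count against the
design-matrix rank, and writes the results as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope

Presets cover the standard families (constant, additive, pairwise,
nearest-neighbor, all-order, all-adjacent, K-order, hierarchical-K-order,
K-adjacent, hierarchical-K-adjacent); arbitrary position-set families —
including duplicates — are supported via `sfr_model()`. Out of scope:
other symmetry groups of sequence space (global character permutations,
position permutations, the full Hamming group), wild-type and
physicochemical-property models, and parametric families of gauges beyond
the distilled gauge implemented here. See `vignettes/embedding-distillation.Rmd`
for the methods account.
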