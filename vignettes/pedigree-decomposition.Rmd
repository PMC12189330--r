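---
title: "Decomposing pedigree inbreeding and coancestry into ancestral contributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing pedigree inbreeding and coancestry into ancestral contributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedloops)
```

## The problem

In a closed livestock population, the mean inbreeding coefficient $\bar F$ and
the mean coancestry $\bar f$ summarize how much identity by descent has
accumulated, but they do not say *who* put it there or *when*. This package
dissects those statistics into per-ancestor pieces at three nested levels:

1. **Mendelian sampling variance (MSV) contributions** $m$ — one weight per
   ancestor, summing exactly to the target statistic;
2. **nodal common ancestor (NCA) contributions** $u$ — the marginal share of
   each ancestor that actually closes an inbreeding loop;
3. **founder contributions** $v$ — the same mass pushed back onto the founder
   genomes.

The per-ancestor profiles then feed a canonical discriminant analysis (CDA) of
the ancestors' birth origins, asking whether geography structured the build-up
of inbreeding — the situation of regional cattle nuclei historically connected
by transhumant droving routes.

## The decomposition model

All computations rest on the factorization of the numerator relationship
matrix,
$$A = U^{-1} B \,(U^{-1})^\top,$$
where $U$ carries $1$ on the diagonal and $-\tfrac12$ from each animal to each
recorded parent, and $B$ is diagonal with the Mendelian sampling variances

* $b = 1$ for founders,
* $b = \tfrac12 - \tfrac14(F_s + F_d)$ with both parents recorded,
* $b = \tfrac34 - \tfrac14 F_{\text{known}}$ with one parent recorded.

The one-known-parent rule is the standard unknown-parent convention; it is what
keeps the factorization exact on incomplete pedigrees. Products $A x$ never
form $A$: one upward sweep (solve with $U^\top$), a diagonal scaling, one
downward sweep (solve with $U$), each a single pedigree pass. For a group $G$
of size $n$ with indicator $x$, $\bar f_G$ on the relationship scale is
$\frac{1}{n^2} x^\top A x$ — self terms included — and the coancestry scale is
half of that. The package exposes **both scales everywhere** and the
relationship-scale numbers are exactly twice the coancestry-scale numbers; the
herdbook software this field uses has historically mixed the two silently.

Individual inbreeding decomposes as $F_j = \tfrac12 \sum_k b_k\,
c_k(s)\,c_k(d)$, where $c_k(\cdot)$ is ancestor $k$'s genetic contribution
(the corresponding row of $U^{-1}$) to the sire and dam. Every weight is
nonnegative and the sum is exact, which the tests assert at $10^{-10}$ on
every fixture and on simulated pedigrees.

### From MSV weights to nodal common ancestors

NCAs are the ancestors appearing on both the paternal and maternal sides of a
pedigree. Wright's path counting assigns
$(\tfrac12)^{n_1+n_2+1}(1+F_A)$ to the ancestor $A$ at the apex of each
non-self-intersecting loop; when one NCA descends from another, the younger
one captures the older one's genes, leaving the older only a marginal (often
zero) contribution.

The package converts MSV weights into these marginal contributions with a
*first-coalescence pair elimination* (the upward-exploration tabular method):
a table of gene-lineage pair frequencies seeded at the target is propagated
to older generations, each animal's weight splitting half-and-half to its
recorded parents, and a pair that coincides at animal $h$ contributes its
frequency times $(1 + F_h)$ to $u_h$ and stops. This attribution rule is
*exactly* Wright's marginal accounting: the tests verify elementwise equality
of the two routes on every inbred animal of one hundred random 50-animal
pedigrees. We deliberately implement the NCA conversion through this engine
rather than through a literal triangular-matrix product: published recipes
for the conversion matrix are ambiguous about indexing and sign, whereas the
path-counting equality is an unambiguous contract.

Founder contributions push $u$ up the pedigree: each animal's founder profile
is half its sire's plus half its dam's. The half genome behind an unknown
parent of a non-founder is assigned to a flagged *phantom founder*
(`"<id>/sire"`, `"<id>/dam>"`), so $\sum v = \sum u$ holds exactly instead of
leaking mass on incomplete pedigrees.

### Rates and non-random mating

Two scalar summaries accompany the decomposition: the individual rate of
coancestry $\Delta C = 1 - (1 - C)^{2/(t_b + t_a)}$, standardized by the
pair's equivalent complete generations $t = \sum_{\text{known ancestors}}
(\tfrac12)^{\text{depth}}$, and the non-random mating coefficient $\alpha$
from $(1-\bar F) = (1-\bar f)(1-\alpha)$. The $\Delta C$ literature formula is
typeset ambiguously in several places; we use the individual-rate form above,
which is the construction of the method it cites. Because it is unstated
whether upstream software averages $\Delta C$ over all pairs or over cohort
pairs, the package exposes the pairwise primitive (`rate_of_coancestry`) and
a mean-over-pairs convenience (`mean_rate_of_coancestry`) separately.

## The feature table and its identities

`assemble_ancestor_features()` builds one row per *identified ancestor*
(an animal with recorded offspring) with five variables: the loop
contribution, the two founder-contribution columns, a coancestry-scale copy
of the loop contribution, and a per-record $\alpha$. Three choices here were
genuinely open:

* **Rows are ancestors**, not all reference animals: the reported group sizes
  in this literature are counts of identified ancestors, and only ancestors
  can carry loop or founder contributions.
* **The loop/C columns target the mean inbreeding coefficient.** The defining
  description of the loop variable is the proportion of the *inbreeding*
  coefficient attributable to nodal ancestors via closed loops, and the
  descriptive tables in this literature print the same numbers twice — once
  on the relationship scale ("through inbreeding loops") and once halved
  ("Coancestry (C)"). We therefore compute the marginal NCA contribution to
  the reference population's $\bar F$ and print it on both scales, making
  `loop_contribution = 2 * coancestry_C` an exact per-row identity. Under
  this definition only loop-closing ancestors carry weight, which is what
  makes the variable informative about regional isolation.
* **Per-record $\alpha = 1 - 1/(1 - C)$**: the population identity with the
  record's own inbreeding term zeroed. It reproduces the published extreme
  values of $\alpha$ from the published extremes of $C$ exactly, which is the
  only internal consistency check available for this column.

Group NCA contributions are per-ancestor sums over member pairs (not
per-individual maxima); with the mean-coancestry target the self pairs of
group members are part of the statistic and are attributed to the members
themselves.

## The discriminant pipeline

The CDA stage follows the conventional nine-step protocol: collinearity
screen, stepwise selection, canonical fit, significance tests, leave-one-out
validation, and a Mahalanobis dendrogram.

* **VIF screen** (threshold 5): iteratively removes the largest-VIF column;
  exact dependence reports an infinite VIF. Because the feature table makes
  `loop = 2 * C` exact by construction, one of the pair *must* fall here; ties
  at the maximum drop the rightmost column, so the relationship-scale column
  survives deterministically. The $\alpha$ column, a near-affine function of
  $C$, falls to the same screen — mirroring the exclusions reported for this
  variable set.
* **Stepwise selection**: forward selection on a ridge-penalized multinomial
  log-likelihood (decay $10^{-4}$) with BIC stopping. The qualifier
  "regularized" in the protocol gives no penalty or criterion; a small ridge
  with BIC is the conservative reading. On weakly separated groups the
  procedure legitimately selects nothing, in which case the pipeline falls
  back to the screened set.
* **Canonical fit**: eigen-solution of $W^{-1}B$ via Cholesky; scores are
  scaled to unit pooled within-group variance; signs are fixed by making the
  largest raw coefficient positive. A singular $W$ is ridge-inflated by
  $10^{-8}\,\mathrm{tr}(W)/p$ with a warning (exactly dependent columns are
  expected to have been dropped by the screen first). The
  observation-to-variable ratio is checked against the conventional 4:1
  floor with a warning, not an error.
* **Tests**: Wilks $\Lambda = \prod (1+\lambda_i)^{-1}$ with Rao's F;
  Bartlett residual $\chi^2 = -[n - 1 - (p+g)/2]\ln\Lambda_k$ with
  $(p-k)(g-1-k)$ df; Pillai $V = \sum \lambda_i/(1+\lambda_i)$ with its F
  approximation; univariate one-way tests per variable. The identities
  $\Lambda \prod(1+\lambda_i) = 1$ and $V = \sum\lambda_i/(1+\lambda_i)$ are
  asserted at $10^{-12}$ on every fit.
* **LOOCV** refits the classification functions for every held-out row (true
  cross-validation, not resubstitution scoring), classifies by Mahalanobis
  distance to the centroid penalized by $-2\ln(\text{prior})$, and reports
  the confusion matrix, hit ratios, Press's $Q = (N - nK)^2/(N(K-1))$ against
  the 6.63 critical value, and the proportional- and maximum-chance criteria
  with the 1.25 rule. Priors default to group-size proportional, with a
  uniform option.
* **Dendrogram**: linkage is not prescribed by the protocol; UPGMA is the
  default, with single and complete linkage exposed. Output is Newick with
  branch lengths.

## What the generator emulates — and what it does not

`generate_structured_pedigree()` produces discrete, non-overlapping
generations: regional founder pools, per-region matings with each mating
leaving one male and one female (so the loop policy always finds full sibs),
sires drawn from the dam's relatives with probability `loop_intensity`, from
another region with probability `migration_rate`, otherwise at random within
the region; offspring inherit the dam's municipality; parent links of
first-generation animals are masked with probability `unknown_parent_rate`.

Defaults — 3 regions, 12 founders each, 6 generations, 12 matings (24
offspring) per region and generation, migration 0.1, loop intensity 0.1,
masking 0.2 — describe a small endangered breed fragmented into regional
nuclei with incomplete early records. They were fixed once, on that
rationale. Discrete generations are a deliberate simplification: the
decomposition is generation-agnostic, and discrete cohorts make closed-form
checks (full-sib floors, depth-$d$ loop values) possible. Sexes alternate
rather than being sampled, guaranteeing feasible matings at small sizes.

What the generator does *not* emulate: overlapping generations and age
structure, unequal family sizes under selection, herd-level (as opposed to
municipality-level) structure, and real herdbook error patterns (identity
recycling, impossible dates beyond the simple masking used here). Passing
tests on synthetic data therefore demonstrate the *mathematics* — exactness,
conservation, cross-backend agreement, and qualitative isolation effects —
not calibration to any real herdbook.

## Numerical choices and degenerate inputs

* Conservation tolerance $10^{-10}$ throughout; hard assertions in tests,
  soft warnings in the pipeline.
* Topological ordering breaks ties by (birth date, id), so all downstream
  vectors are bit-reproducible for a given input.
* Unknown-parent sentinels default to `"", "0", "NA", "UNKNOWN"` and are
  configurable; referenced-but-undeclared parents become flagged founder
  stubs; a child born before its recorded parent warns rather than fails
  (herdbooks with three decades of records contain such entries, and
  rejecting them would reject the dataset).
* Wright path enumeration is exponential and capped (default $10^6$ paths)
  with an error that points to the MSV route; the pair-elimination engine is
  quadratic in memory and capped at 2 GiB.
* Non-inbred focal animals yield empty contribution vectors with zero totals;
  zero-coancestry groups are valid inputs everywhere.

## Problem sizes

The test suite exercises pedigrees of up to 2,016 animals for conservation,
200 animals for dense-oracle equality, 100 random 50-animal pedigrees for the
Wright triangle, 200 label permutations for the size of the Wilks test, and
ten 3-region replicates for the isolation contrast. These sizes were chosen
to make every closed-form and brute-force oracle affordable while remaining
an order of magnitude above the regime where the algorithms change behavior.

## Known limitations

* Founder genome equivalents, effective numbers of founders/ancestors, and
  genomic (marker-based) relationship matrices are out of scope.
* The per-ancestor feature table is a *view* of the decomposition: its row
  filter (identified ancestors) intentionally drops the self-term mass of
  non-parents, so column sums of the table are not the population statistics;
  the conservation identities live at the decomposition level.
* LOOCV refitting is $O(n)$ model fits; for tables beyond a few thousand
  ancestors a rank-one downdate would be the natural optimization.
* The pair-elimination engine holds a dense $n \times n$ table; pedigrees
  beyond roughly 15,000 animals need the MSV route instead.

## A worked example

```{r example}
fix <- reference_fixtures()
chain <- fix[["FIX-CHAIN"]]
compute_inbreeding(chain)[["X"]]
m <- msv_decomposition_individual(chain, "X")
m$weights
u <- nca_contributions(chain, m)
u$weights
founder_contributions(chain, u)$v
```

The MSV weights spread over A, B and M; the marginal NCA conversion
concentrates everything in M (the loop-closing ancestor), and the founder
conversion splits M's share equally between its parents.
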