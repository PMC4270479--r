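---
title: "Decomposing epistatic adaptation on a mutational hypercube"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing epistatic adaptation on a mutational hypercube}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lambdascape)
```

## The problem

Visual pigments tune their wavelength of maximal absorbance (λ_max, in nm)
through a small number of amino-acid replacements. When the adaptation of
interest required L replacements, engineering the reconstructed ancestral
pigment and all 2^L combinations of the derived states gives a complete
genotype–phenotype map on the subset lattice (the L-dimensional hypercube).
`lambdascape` answers three questions from such a map: how the phenotypic
change decomposes into main effects and higher-order epistasis; which of the
L! mutational orderings were evolutionarily accessible; and in what order
the substitutions accumulated on a particular lineage.

## The effect model and its solve

Each genotype g (a subset of the L derived states) satisfies

$$\lambda(g) = \lambda_{anc} + \sum_{\emptyset \ne T \subseteq g} \theta_T,$$

one equation per genotype — 2^L equations in 2^L unknowns (λ_anc plus the
127 θ when L = 7). The incidence matrix C with C[g, T] = 1 iff T ⊆ g is unit
lower-triangular once rows and columns are sorted by subset size and then by
bitmask, so `decompose()` solves the system by forward substitution in that
order. For integer-valued λ (pigment assays report whole nm) every
intermediate quantity is an exactly representable integer, so the solution
carries no floating-point error; `mobius_decompose()` computes the same
quantities by direct inclusion–exclusion,
$\theta_S = \sum_{T \subseteq S} (-1)^{|S|-|T|} \lambda(T)$, and the two
routes agree bit-for-bit on integer data. We keep both because they are
algebraically independent: one is an oracle for the other in the test suite.

### Nonfunctional genotypes and imputation

Some combinations fail to form a pigment at all (no absorbance peak). A
nonfunctional genotype carries no λ, so its own, highest-order term is not
estimable. Processing subsets in increasing size, `decompose()` pins that
term to exactly 0, flags it imputed, and records the genotype's λ as the sum
of the already-estimated lower-order terms. The logic cascades: a
nonfunctional genotype nested above another one uses the earlier imputations.
The companion routine `decompose_stable_only()` runs the same recursion using
functional genotypes only; every θ it can estimate equals the full imputed
analysis exactly, which is both a consistency check and the honest statement
of what the data determine without the imputation convention.

Two consequences of the convention are worth keeping in mind. First, an
imputed λ is a model value, not a measurement: trajectory profiles therefore
never use imputed phenotypes, and accessibility depends only on the
functional flag. Second, imputation forces θ = 0 for the nonfunctional
subset itself but *propagates* into the θ of its supersets, which absorb any
true effect the missing measurement carried.

### Uncertainty

The estimates are linear in the observations, X = C⁻¹Y, so
cov(X) = C⁻¹V(C⁻¹)ᵀ. We adopt the convention that each λ_max is measured
with unit variance, independently (V = I); then SE(θ_S) = 2^{|S|/2} exactly,
because θ_S is a ±1-signed sum over the 2^{|S|} subsets of S. The ancestral
observation is part of the system, so it, too, is treated as noisy.
`significance()` applies a two-sided z-test per term with 0.05/0.01 star
flags; no multiple-testing correction is applied by default (the effect
table reports one test per term, as effect plots in this field conventionally
do), with Benjamini–Hochberg available via `adjust = "BH"`.

## Trajectories

A trajectory is an ordering of all L mutations. It is *accessible* when
every intermediate genotype and the endpoint are functional — we adopt the
stricter reading that includes the endpoint, which costs nothing when the
full mutant is functional and is the scientifically sensible rule when it is
not. `enumerate_trajectories()` walks all L! orderings explicitly (refusing
L > 10); `count_accessible()` computes the same counts by dynamic
programming over the functional sub-lattice in O(2^L·L), and the suite
cross-checks the two on hundreds of random lethality patterns.

Two classification thresholds are exposed as parameters with literal
strictness: paths whose every per-step shift satisfies |Δλ| < 25 nm (strict
`<`) separate gradual tuning from jumpy paths, and the per-path step
variance distribution is split by whether any step exceeds 30 nm (strict
signed `>`). The variance denominator is n−1 by default with a
population-variance option, since either convention is defensible for a
fixed path of L steps; the trajectory driver reports both.

## Ordering substitutions on a lineage

Given a rooted tree (as read from Newick, used as rooted — no re-rooting)
and single-letter states per taxon and site, `fitch_parsimony()` runs the
standard two-pass Fitch reconstruction with full set arithmetic (multi-state
sites are not binarized; multifurcations use the state-frequency
generalisation of the intersection rule). `place_substitutions()` then walks
the root-to-focal-tip path and assigns each site that must change to the
branch(es) where the derived state can arise under the reconstruction. When
the resolution is ambiguous, every candidate branch is reported and
`partial_orders()` expands all consistent branch-wise partial orders — the
package never silently picks an accelerated or delayed resolution. Node ages
are carried as annotations only; the ordering uses topology and parsimony
alone. The consistent complete orderings are the linear extensions of the
partial order (the product of group-size factorials), and
`constrained_paths()` profiles each against the landscape together with an
epistasis-only prediction (`reconstruct()` with `min_order = 2`), which
isolates how much of the phenotype trajectory interactions alone explain.

## Synthetic data

`generate_landscape()` draws a ground-truth effect table and emits a noisy
landscape: main effects N(0, 2 nm); each interaction nonzero with
probability 0.175 with magnitude 5 nm plus an exponential excess of mean
5 nm and random sign; additive i.i.d. Gaussian noise with SD 1 nm (matching
the V = I convention — the ancestor is noisy too unless `fix_anchor`); and
an optional nonfunctional rule (explicit list, or i.i.d. by genotype).
The defaults mirror the motivating system's scale: singles of a couple of
nm, roughly one interaction in six at or above 5 nm, an ancestor near
357 nm. Draws occur in a fixed documented order under a mandatory seed, so
outputs are reproducible byte-for-byte.

What the generator deliberately does not emulate: correlated measurement
error between genotypes, order-dependent interaction sparsity, and —
importantly — *structured* lethality. The calibration driver
(`analysis/04_simulation_calibration.R`) shows that placing ~47% of
genotypes nonfunctional i.i.d. leaves a median of zero accessible paths,
whereas concentrating lethality on genotypes sharing a single
incompatibility (as a steric clash like the motivating system's
T52F-without-F46T would) leaves many more. Real systems' accessibility
fractions in the tens of percent imply strongly clustered lethality, so
passing tests on i.i.d.-lethal synthetic data says nothing about the
lethality structure of real data — only about the counting machinery.

Two fixed fixtures ship with the package. `human_m_fixture()` is the
three-site landscape of the ancestral long-wavelength pigment (560 nm; known
effect terms −5, −10, −17, 0, −2, 1, 4 summing to −29 nm).
`s1_like_fixture()` is a *synthetic* seven-site instance shaped like the
short-wavelength system: the printed-scale main effects (−2, −3, 0, 0, 2, 1,
1), four interactions (20, 20, 8, 7 nm) chosen so the phylogeny-consistent
ordering climbs 357 → 380 → 400 → 411 nm, a lethal-if-first mutation and one
additional nonfunctional double, plus a 15-taxon tree and character matrix
whose Fitch placement yields four branch groups of sizes (2, 1, 2, 2) — and
hence exactly 8 consistent orderings. It exercises every pipeline stage
end-to-end; its census numbers (e.g. 4,080 of 5,040 accessible) describe the
fixture, not any measured landscape.

## Numerical and design choices

* Subset processing order is size-then-bitmask everywhere; it makes C unit
  lower-triangular and the decomposition exact on integer data.
* λ values are stored as doubles; file output rounds to 0.1 nm by default
  (a formatting choice; assays report whole nm).
* Landscape files must list every genotype for `decompose()` (absent rows
  are a hard error naming the missing genotypes); only
  `decompose_stable_only()` tolerates absent nonfunctional rows.
* Zero SE with nonzero θ yields p = 0 with a warning rather than an error.
* The dense design matrix is limited to L ≤ 12; exhaustive path enumeration
  to L ≤ 10 (the DP has no such limit below the bitmask width).
* Unicode minus signs are normalised on input; "NF" and blank both mark
  nonfunctional λ.
* Problem sizes in the test suite — 1,000 random landscapes for the dual-
  route check, 500 lethality patterns at L ≤ 7 for DP-vs-enumeration, 2,000
  replicates for the SE calibration — were chosen to bound Monte-Carlo error
  well inside the asserted tolerances while keeping the default run fast.

## Limitations

The factorial decomposition is exact but saturated: it has no residual
degrees of freedom, so "significance" rests entirely on the assumed V = I
error model rather than on replication. Imputation is a convention, not an
inference — it is the unique choice consistent with "a mutation that cannot
form a pigment cannot shift λ_max", but other conventions would shift
higher-order terms. Trajectory counting weights all accessible orderings
equally; no population-genetic weighting (selection coefficients, fixation
probabilities) is attempted. Parsimony ordering inherits parsimony's
assumptions; with rampant homoplasy at the focal sites the branch groups
widen into ambiguity rather than failing loudly.
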