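---
title: "A weighted similarity index for read-across: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A weighted similarity index for read-across: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

simdex computes a blended chemical similarity index between two molecules
A and B:

$$ SI_{A,B} \;=\; S_b(FP_A, FP_B)^{\,w_{fp}} \cdot
   S_{nb}(CD_A, CD_B)^{\,w_{cd}} \cdot
   S_{nb}(HD_A, HD_B)^{\,w_{hd}} \cdot
   S_{nb}(FG_A, FG_B)^{\,w_{fg}}, \qquad
   w_{fp}+w_{cd}+w_{hd}+w_{fg}=1 $$

where $S_b$ is a binary similarity coefficient applied to a bit
fingerprint, and $S_{nb}$ a non-binary coefficient applied to three
real-valued structural keys: 35 constitutional descriptors (CD), 11
hetero-atom counters (HD, a deliberate subset of CD that can be weighted
independently), and per-pattern occurrence counts over a functional-group
catalog (FG). The FG key counts *occurrences*, not presence: two hydroxyls
score 2. This is the motivating repair of plain fingerprints, which
encode a fragment once no matter how often it occurs.

The exponent form is a weighted geometric mean. The product formula with
adjacent weights admits two readings (exponentiation or plain scaling);
we adopt the geometric reading because the identically typeset
desirability function used for ranking (DES, below) is unambiguously a
geometric mean with exponents 0.25, and because only the geometric
reading makes $SI$ a mean of the component similarities. An arithmetic
mode ($SI = \sum_k w_k s_k$) is available as a configuration switch for
sensitivity analysis. A component with weight 0 contributes a factor of 1
(the $0^0 = 1$ convention), so zero-weight keys are genuinely inert.

The shipped default configuration is the best scheme of the index's
original two-dataset calibration: Extended fingerprint, Maxwell–Pilliner
binary coefficient (id 37), Bray/Curtis non-binary coefficient (id 3),
weights $(w_{fp}, w_{cd}, w_{hd}, w_{fg}) = (0.4, 0.35, 0.1, 0.15)$.

```{r}
library(simdex)
cfg <- similarity_config()   # the calibrated default
cfg
```

## Molecule handling

Structure parsing, hydrogen perception, ring/aromaticity detection and
all genuine SMARTS matching are delegated to Open Babel through
ChemmineOB/ChemmineR. The package's own molecule representation is an
H-depleted graph: heavy atoms carry element, formal charge, aromatic
flag and implicit-hydrogen count; bonds carry Kekulé order plus an
aromatic flag. Dot-disconnected inputs are reduced to the largest
fragment by heavy-atom count (with a warning), the common QSAR
convention. Stereochemistry is accepted but ignored: no descriptor or
fingerprint downstream is stereo-aware.

## Fingerprint families

Nine families are registered. Four are hashed path fingerprints in the
classic Daylight style: all simple linear paths of 0–7 bonds are
enumerated, written as canonical element/bond-symbol strings (the
lexicographic minimum of the two reading directions), and hashed into the
bit vector with a fixed 32-bit FNV-1a hash (`bit = hash mod length`,
default length 1024, configurable). The variants differ only in the path
alphabet:

* `default` — aromatic-aware symbols (`c`, `:`) and bond orders;
* `extended` — `default` plus a fixed 16-bit ring-feature block
  (presence of ring sizes 3–8, a ring-count thermometer up to 8 rings
  from the cyclomatic number, any-aromatic and any-ring flags);
* `graph_only` — element skeleton only, no bond orders, no aromatic
  distinction (benzene and cyclohexane coincide by design);
* `hybridization` — bond orders without aromaticity perception
  (pure Kekulé paths).

The other five (`estate` 79, `maccs` 166, `substructure` 307, `pubchem`
881, `klekota_roth` 4860) are structural keys: ordered pattern catalogs
where bit *i* is set iff pattern *i* matches. The published definitions
of these key sets are proprietary or far too large to redistribute, and
bit-exact reproduction of any particular toolkit is a non-goal; the
shipped catalogs are therefore **synthetic**: deterministically generated
pattern sets at the published lengths, written in a SMARTS-compatible
dialect (single-atom environments and linear bond paths) that the
package's own path engine evaluates directly. Because every entry is
valid SMARTS, the test suite cross-checks sampled entries of every family
against Open Babel's independent SMARTS engine. User catalogs in full
SMARTS can be substituted via `read_catalog()`; entries outside the
linear dialect fall back to Open Babel matching.

## Descriptor keys and atomic constants

The CD key holds molecular weight, average weight, carbon-scaled sums
and heavy-atom means of van der Waals volume, polarizability and
Sanderson electronegativity, atom/bond/element counts, bond-order sums
and composition percentages. Conventions worth stating explicitly:

* hydrogens are implicit; `nAt = nSk + nH` uses perceived H counts;
* `SCBO` sums conventional bond orders over the H-depleted graph with
  aromatic bonds counted 1.5;
* `Sv`, `Sp`, `Se` sum over heavy atoms only and `Mv`, `Mp`, `Me` divide
  by the heavy-atom count (the divide-by convention is not fixed by the
  descriptor names; heavy-atom division is adopted and tested);
* the constants table (Bondi-derived volumes, Sanderson 1983
  electronegativities, Miller 1990 polarizabilities, all carbon-scaled)
  ships as a reviewable TSV and can be replaced per call.

The FG catalog is the package's own curated, openly redistributable set
of 154 organic functional-group SMARTS (the proprietary Dragon list is
not reproduced); matches are counted with symmetry-equivalent duplicates
removed.

## Similarity coefficients

The binary registry implements the 44 coefficients of the standard
roster (Todeschini et al. 2012, J Chem Inf Model 52:2884), under that
numbering; the non-binary registry the six continuous coefficients of
Holliday, Hu & Willett (2002). Three details are design choices rather
than transcription:

* **Range normalisation.** The index contract requires every coefficient
  in $[0,1]$. Naturally unit-range forms pass through; correlation-type
  forms in $[-1,1]$ are rescaled $(s+1)/2$; the few forms with unbounded
  or count-dependent ranges get fixed documented maps — $s/(1+s)$ for
  Forbes, Mountford and Sokal–Sneath 3, $s/n$ for Fossum and
  Harris–Lahey, a linear map of $s/\sqrt n$ for Dennis, $2s + 1/2$ for
  Dispersion, clamping to $[-1,1]$ for the Cole pair. The registry's
  `rescale` column records the rule per entry.
* **Degenerate denominators.** Identical fingerprints score 1 for
  reflexive coefficients (this is the analytic limit); otherwise an
  undefined correlation form returns the rescaled raw 0 (i.e. 0.5) and
  any other undefined form returns 0. Per-term 0/0 policies
  (Rogot–Goldberg, Hawkins–Dotson, Sokal–Sneath 4, Harris–Lahey) are
  baked into the formulas and unit-tested.
* **Reflexivity and symmetry are properties, not assumptions.** Nine
  coefficients (e.g. Russel–Rao $a/n$, Faith, CT3) have self-similarity
  below 1 whenever unset bits exist — by definition, not by defect — and
  six are directional and exist as transpose pairs (Cole 1/2, Dice 1/2,
  Peirce 1/2). The registry flags both (`reflexive`, `symmetric`), the
  self-similarity and symmetry test suites key on the flags, and the
  transpose-pair identity is asserted for the asymmetric entries.

Non-binary distance forms (Mean Canberra, Divergence, Bray/Curtis) are
returned as complements of the normalised distance, with 0/0 component
terms contributing 0; Divergence uses
$1 - \tfrac1n\sum ((x_i-y_i)/(x_i+y_i))^2$ and the continuous
Sokal/Sneath uses $C/(2A+2B-3C)$ with $A=\sum x^2$, $B=\sum y^2$,
$C=\sum xy$ (the standard continuous analogues; the source tables give
these forms only by name). Descriptor vectors enter **raw** — no
per-descriptor scaling — matching the index's original definition; an
optional min–max flag is deliberately absent from the default path.

## Read-across and validation

A query's endpoint is predicted as the SI-weighted mean of the
experimental values of its $k=3$ most similar compounds; if all three
similarities are zero the unweighted mean is used and the prediction is
flagged low-confidence. Ties are broken by ascending compound id, making
every run bit-reproducible. Leave-one-out validation computes keys once,
reuses them across folds, and reports
$R^2 = 1 - SS_{res}/SS_{tot}$ (the coefficient-of-determination reading
of "R squared"; the squared Pearson correlation is emitted alongside in
`glance()` because the two conventions differ for biased predictors and
published tables rarely say which was used). A zero-variance dataset is
reported as $R^2 = 1$, RMSE 0, with a `degenerate_variance` flag.

## Two-stage evaluation and ranking

Stage 1 sweeps fingerprint family × binary coefficient with a
fingerprint-only index (weights $(1,0,0,0)$ — the stage-1 description
mentions only fingerprints and binary coefficients, so stage 1 is read
as a pure fingerprint benchmark). Stage 2 fixes the winning pair and
sweeps weight schemes × non-binary coefficient. The weight lattice is
$w_{fp} \in [0.3, 1]$ step 0.1, $w_{cd} \in [0, 0.4]$ step 0.05,
$w_{hd}, w_{fg} \in [0, 1]$ step 0.05 under the unit-sum constraint,
enumerated in exact integer arithmetic (338 schemes; the enumeration is
validated against a brute-force oracle rather than against any reported
approximate count, whose basis is unclear).

Each batch is ranked by scaling every quality metric to $[0,1]$ by
min–max across the batch (the only self-contained choice of scaling
population), replacing scaled RMSEs by their complements, then scoring

$$ DES = \prod_j p_j^{1/m}, \qquad UTI = \tfrac1m \sum_j p_j $$

over the $m = 2 \times$ (number of datasets) parameters. DES uses
$0^{1/m} = 0$: a run worst on any single parameter is maximally
undesirable, the intended geometric-mean semantics. A metric with zero
spread is set to 1 for all runs, with a warning. Both rank columns are
deterministic (score, then input order).

```{r}
fx_a <- build_fixture(n = 30, beta = c(MW = 0.01, nHet = -0.5), seed = 42,
                      endpoint_name = "bcf_like")
fx_b <- build_fixture(n = 30, beta = c(nC = 0.25, nHet = -0.3), seed = 43,
                      endpoint_name = "logp_like")
g1 <- stage1_grid(list(bcf = fx_a, logp = fx_b))
g2 <- stage2_grid(list(bcf = fx_a, logp = fx_b),
                  fp_type = g1$fingerprint[g1$rank_des == 1],
                  binary_id = g1$binary_id[g1$rank_des == 1])
autoplot(g2)
```

## The synthetic fixture generator

`fixture_library()` is a hand-curated set of 74 small organic molecules
and `build_fixture()` attaches a synthetic endpoint
$y = \sum_d \beta_d \, CD_d + \mathcal N(0, \sigma^2)$, by default
$y = 0.01\,MW - 0.5\,nHet + \varepsilon$ with $\sigma = 0.1$ and seed 42.
The property is built *from descriptors the index itself uses* — on
purpose, so that leave-one-out recovery is a meaningful end-to-end check
of the whole machinery rather than a claim about any real endpoint.

Two design points matter for interpreting results:

* **The library is organised as dense homologous ladders** (alkanes,
  alcohols, acids, amines, per-halogen alkyl halides, phosphate and
  borate ester series, ...), every class with at least three members at
  single-CH2 steps, and series listed consecutively. Sampling is
  stratified along that order, so every seeded sample keeps every series
  represented. Without this, random subsets orphan entire compound
  classes and read-across error reflects sampling accidents instead of
  index quality.
* **What recovery can and cannot reach.** Even with perfect similarity
  ranking, the 3-nearest-neighbour weighted mean has structural bias:
  ladder-end compounds have one-sided neighbourhoods, and halogen-swap
  near-twins (chloro- vs bromopropane) are maximally similar yet differ
  in $y$ through the mass term. On this fixture the observed ceiling is
  a leave-one-out $R^2$ around 0.85 (noisy) to 0.88 (noise-free) with
  RMSE near 0.25 — substantially above chance, close to the best the
  estimator class admits here, and an overestimate of nothing: a
  value-oracle that cheats by picking neighbours on the endpoint itself
  reaches RMSE 0.05, which read-across by construction cannot.

Passing fixtures therefore demonstrate that parsing, keys, coefficients,
the index, and the prediction/validation loop compose correctly and
deterministically. They do not show that the default weights are optimal
for any real endpoint, nor that synthetic key catalogs match the
published key sets bit for bit (explicitly out of scope).

## Numerical and procedural choices

* Path hashing is FNV-1a/32 on UTF-8 bytes, implemented on 16-bit halves
  so results are exactly reproducible across platforms; one bit per
  path.
* Confusion counts and binary similarities in the grid engines are
  computed from dense 0/1 matrices with `tcrossprod`, evaluated
  vectorised per coefficient; component similarity matrices are cached
  per dataset and recombined per weight scheme, so a full stage-2 sweep
  (338 × 6 = 2028 runs on two 30-compound datasets) takes under two
  minutes on one CPU.
* Problem sizes used in the shipped tests and acceptance script — 30-
  and 50-compound fixtures, full 9 × 44 stage 1, full 338 × 6 stage 2 —
  were chosen so the complete suite exercises every stage end to end at
  desk scale.
* LOO tie-breaks, rank tie-breaks and CSV writers are all deterministic;
  the test suite asserts byte-identical outputs across repeated runs.

## Known limitations

* The synthetic key catalogs share family *semantics* (ordered pattern
  catalogs at the published lengths), not the published patterns;
  absolute bit densities differ from CDK/MACCS/PubChem implementations.
* Aromaticity follows Open Babel's model via ring perception; exotic
  systems perceived differently by other toolkits will key differently.
* Descriptor vectors are compared raw, so CD similarity is dominated by
  the large-magnitude fields (MW, sums); that matches the index's
  original definition but means CD similarity is primarily a size
  similarity.
* The read-across model has no applicability-domain guard beyond the SI
  itself and no uncertainty estimates; both are out of scope.
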