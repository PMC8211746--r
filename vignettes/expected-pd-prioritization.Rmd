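---
title: "Expected phylogenetic diversity: models, scores and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expected phylogenetic diversity: models, scores and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdgain)
library(dplyr)
```

## The model

Phylogenetic diversity (PD, Faith's measure) of a species set is the summed
branch length, in millions of years (Ma), of the minimal rooted subtree
spanning the set. Given a per-species probability of extinction $p_i$ over a
fixed time horizon, and treating extinctions as independent, a branch $b$
with descendant leaf set $L(b)$ survives with probability
$1 - \prod_{i \in L(b)} p_i$, so the PD expected to survive is

$$\mathrm{expPD}(p) \;=\; \sum_b \ell_b \Bigl(1 - \prod_{i \in L(b)} p_i\Bigr).$$

Every score in this package is a functional of this quantity:

* **HEDGE** of species $i$: the gain in expPD if $i$ is secured,
  $\mathrm{expPD}(p \mid p_i{=}0) - \mathrm{expPD}(p)
  = \sum_{b \ni i} \ell_b \prod_{j \in L(b)} p_j$.
  High for threatened, evolutionarily distinctive species; a secured species
  ($p_i = 0$) scores exactly 0.
* **LEDGE** of species $i$: the loss in expPD if $i$ goes extinct,
  $\mathrm{expPD}(p) - \mathrm{expPD}(p \mid p_i{=}1)
  = \sum_{b \ni i} \ell_b (1 - p_i) \prod_{j \neq i} p_j$.
  High for secure, distinctive species (or species whose close relatives are
  highly threatened); a species with $p_i = 1$ scores 0.
* **ED** (fair proportion): $\sum_{b \ni i} \ell_b / |L(b)|$, a partition of
  PD ($\sum_i \mathrm{ED}_i$ equals the tree length, an identity the test
  suite asserts to $10^{-10}$).
* **EDGE**: $\ln(1 + \mathrm{ED}) + \mathrm{GE}\,\ln 2$ with the Red List
  weight GE (LC 0, NT 1, VU 2, EN 3, CR 4).
* **GexpPD / LexpPD** of a grid cell: the same two counterfactuals applied
  jointly to *all* species present in the cell — the best outcome of perfect
  local protection and the worst outcome of total local loss. A cell holding
  one species collapses to that species' HEDGE/LEDGE. Joint securing is
  subadditive ($\max_i \mathrm{HEDGE}_i \le \mathrm{GexpPD} \le \sum_i
  \mathrm{HEDGE}_i$) while joint loss is superadditive
  ($\mathrm{LexpPD} \ge \sum_i \mathrm{LEDGE}_i$); both bounds are
  property-tested on random instances.

The per-branch forms are the implementation; the two-evaluation definitions
are kept as independent oracles in the tests (500 random trees with random
probability vectors, agreement to $10^{-10}$ Ma), so the fast path can never
silently drift from the definition.

### Conventions

* **Rooted PD.** PD of a subset includes the path to the root of the full
  tree, matching the behaviour of the classical `pd` implementations this
  field uses: a single species then has a well-defined PD (its root-path
  length) and the fair-proportion EDs sum exactly to total PD. A root edge
  above the basal split, if present in a Newick string, is ignored.
* **Polytomies and zero-length branches** are accepted as-is; nothing is
  arbitrarily resolved.
* **Zero probabilities** are handled exactly (no log-of-zero shortcuts): the
  engine tracks zero counts separately from log-products, so a secured
  sister species correctly shields shared branches.

## Extinction-probability model

Red List categories are converted to 50-year extinction probabilities with
the widely used "IUCN50" projection (LC 0.00005, NT 0.004, VU 0.05, EN 0.42,
CR 0.97). These numbers are a modelling choice, not data: `extinction_model()`
takes any strictly increasing mapping in $[0,1]$ and a horizon, and every
expected-PD statistic is conditional on that choice. All scores in Ma refer
to the horizon of the active model (50 years by default).

Data-deficient (DD) species must be imputed before scoring. The default rule
in `impute_dd()` is a range-size quantile-bracket match: categories are
ordered CR < EN < VU < NT < LC by increasing typical range size (small range
is itself a Red List criterion), bracket widths equal the category shares
among assessed species, and a DD species is assigned the bracket its
range-size quantile falls into. The rule is deliberately simple — monotone
(smaller range never yields a less threatened imputation), idempotent,
calibration-free beyond the assessed species — and pluggable: it stands in
for richer imputation models without pretending to be one. Imputed species
may receive any category, including LC or NT.

## The reference grid

Cell scores live on a cylindrical equal-area grid (Behrmann when the
standard parallel is 30°). `build_reference_grid()` uses the WGS84
*ellipsoidal* equal-area forward equations — with
$k_0 = \cos\varphi_s / \sqrt{1 - e^2\sin^2\varphi_s}$, world width
$2\pi a k_0$ and band height from the authalic-latitude auxiliary — and
rounds width and height to integer cell counts. With the package defaults
(96.5 km cells, parallel 30°, 90°N–60°S) this reproduces the 360 × 142 =
51,120-cell raster used by the gridded mammal range maps the analysis was
designed around; a spherical approximation would round to 359 columns and
miss the reference raster, which is why the ellipsoidal form was chosen.
All cells have identical area (cell size squared), so area-weighted and
unweighted cell means coincide — the protection overlay relies on this.

Twelve cell scores are computed: SR, TSR (threatened = VU/EN/CR), RSR
("rare" = range size *strictly below* the median range over all species,
mid-point median for even counts), SWR (sum of inverse range sizes), their
phylogenetic analogues PD, TPD, RPD, PWR (phylogenetic endemism: branch
length divided by the branch's occupied-cell count), richness in the top
HEDGE and top LEDGE species, and GexpPD / LexpPD. Two conservation
identities pin the rarity-weighted maps: summed over cells, SWR equals the
number of occurring species and PWR equals the total PD of occurring
branches; both are asserted at full grid scale in the tests.

Proportion maps (e.g. TSR/SR, TPD/PD) mask cells with a zero denominator as
undefined (`NA`) rather than zeroing them, so empty ocean cells never
masquerade as measured zeros.

## Selection rules

* **Top species sets**: the `floor(fraction × n)` highest-scoring species
  (default fraction 0.25). With 5477 species this yields exactly 1369 — the
  floor rule is what makes that count reproducible.
* **Hotspots**: the `floor(fraction × n_defined)` highest-valued cells
  (default 0.025); undefined cells never enter the ranking.
* **Ties** at either boundary are broken deterministically — score
  descending, then label/cell-id ascending — so set sizes are exact and
  reruns are byte-identical; a tie crossing the hotspot cut additionally
  warns, since count-valued scores tie often at coarse resolution.
* **Medians across trees**: every phylogeny-based score is computed per tree
  and median-aggregated per species or cell (mean of the central pair for
  even ensemble sizes), never computed on a consensus tree. EDGE applies its
  transform once to the median ED, since the GE weight is tree-independent
  and the transform is monotone.

## Protected-area processing

Records mimic a simplified WDPA-style layer. Filtering drops records whose
status is "Not Reported" or "Proposed", "UNESCO-MAB Biosphere Reserve"
designations, and point records without a reported area; points *with* a
reported area are buffered into regular 64-gons whose area equals the
reported value exactly (the circumradius is inflated to cancel the polygon's
area deficit). Buffers are built in the projected equal-area plane, where
area is preserved on the globe — the quantity a geodesic buffer fixes.

Dissolving and per-cell coverage use an exact event-driven scanline for the
area of a union of simple polygon rings: between consecutive event
abscissae (vertices, pairwise edge crossings, cell walls) the union's
vertical extent is linear in $x$, so a midpoint evaluation integrates
exactly. No external geometry engine is involved; the identity "sum of
per-cell covered areas = dissolved area clipped to the frame" is tested to
0.1%. Rings must be simple and hole-free; degenerate rings are repaired by
dropping duplicate vertices or rejected by name.

The overlay classifies hotspot cells as *not protected* (exactly 0%
coverage), *heavily protected* (≥ 50% by default — the threshold is an
argument), and *slightly protected* in between, and reports the overall
protected share of the hotspot surface as the plain mean over its
equal-area cells.

## Synthetic study conditions

The generators produce inputs with the statistical shape the analysis
assumes, at desk scale, and are pure functions of a config seed (fixed
per-generator offsets, caller's RNG state restored):

* **Trees**: pure-birth (Yule) trees conditioned on $n$ tips, built by the
  package's own simulator so the depth oracle is exact by construction:
  root-to-tip depth is $\sum_{k=2}^{n} \mathrm{Exp}(k\lambda)$, with mean
  $(1/\lambda)\sum_{k=2}^{n} 1/k$, which the tests verify by Monte Carlo
  (200 replicates at $n = 50$). Default speciation rate 0.05/Ma puts root
  depths for 1000 species near 130 Ma, the order of the mammal crown.
  Extinction in the tree model is deliberately omitted — a Yule tree is the
  simplest ultrametric shape that exercises every score; the model is
  pluggable.
* **Statuses**: multinomial draws from a profile with 56.8% LC, 8% NT,
  9% VU, 8% EN, 4% CR and a 14.2% DD fraction — the rounded shape of the
  mammal Red List, including the DD share that forces the imputation path.
* **Ranges**: log-normal target sizes (median 10 cells, log-sd 1.5 — a
  heavy tail reaching from single-cell endemics to quasi-cosmopolitan
  ranges) grown as 4-connected spreading-dye blobs from uniform seed cells,
  with no wrap-around (raster semantics at the grid edge).
* **Protection**: random rectangles and area-true circles rasterized
  through the exact coverage engine, then calibrated multiplicatively (with
  clipping) to a target global mean of 15%, the order of the terrestrial
  protected estate.

What the generators do *not* emulate: phylogenetic signal in range
placement or threat status, range cohesion, latitudinal richness gradients,
realistic protected-area size-frequency or spatial clustering. Green tests
on synthetic data therefore certify the *mechanics* — formulas, identities,
determinism, selection arithmetic — not any biogeographic conclusion drawn
from real data.

## Problem sizes and determinism

The shipped tests run the engine oracles on 500 random trees of up to 12
leaves, the conservation identities on 1000 species over the full 51,120-
cell grid with a single tree, and the end-to-end pipeline on a 160-cell
grid with 40 species and 4 trees; the acceptance script runs 300 species,
10 trees and a 2880-cell grid. These sizes were chosen so a complete run
stays comfortably interactive while still crossing every code path at full
grid resolution at least once. Larger runs scale linearly in trees and in
presence-matrix occupancy (all cell scores reduce to one sparse
branch-by-cell product per tree).

Every simulation and analysis is reproducible: rerunning any command with
the same config and seed produces byte-identical CSV outputs (asserted via
checksums in the tests), and each written table carries its config hash,
seed and tree count as `#` header lines.

## Limitations

* Extinction independence: expected PD multiplies survival probabilities
  across species, ignoring correlated threats (shared ranges, shared
  drivers) — inherited from the expected-PD framework itself.
* Scores rank species and cells *individually*; no complementarity or
  optimal-subset selection is attempted, so the top-$k$ set is not the set
  that jointly maximises expected PD.
* The DD imputation default is a coarse stand-in; real analyses should
  plug in a fitted imputation model.
* The geometry engine handles simple, hole-free rings; true WDPA layers
  with holes and self-intersections need repair upstream.
* GeoTIFF raster I/O is not provided; gridded inputs and outputs travel as
  plain CSV (triplets or per-cell tables) in the grid's row-major cell
  indexing.
```{r example, eval = FALSE}
# a complete synthetic run
cfg  <- synth_config(n_species = 300, seed = 1)
grid <- custom_grid(40, 72, 96.5)
ens  <- simulate_trees(cfg, 10)
pm   <- simulate_ranges(cfg, grid)
st   <- simulate_statuses(cfg)
rs   <- range_sizes(pm)
risk <- species_risk_table(st$species, st$category,
                           rs$range_size[match(st$species, rs$species)])
sa <- run_species_analysis(ens, risk)
sp <- run_spatial_analysis(pm, ens, risk, species = sa)
pa <- run_protection_analysis(simulate_protection(cfg, grid), sp)
glance(sa); glance(sp); tidy(pa)
```
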