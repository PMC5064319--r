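---
title: "Dynamic protein structure networks and allosteric pathway analysis"
author: "psnpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic protein structure networks and allosteric pathway analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psnpath)
```

## The model

`psnpath` implements the dynamic protein-structure-network (PSN) view of a
molecular dynamics (MD) ensemble.  Residues (plus bound ions and acyl
groups such as an N-terminal myristoyl) are nodes; an edge is drawn
between two nodes when a noncovalent interaction between them *persists*
along the trajectory.  Persistence of an interaction is the fraction of
frames in which its geometric criterion holds:

* **salt bridges** — oppositely charged side-chain groups whose centres
  of mass lie within 4.5 Å (ions count as single-atom charged groups);
* **hydrogen bonds** — donor-to-acceptor heavy-atom distance ≤ 3.5 Å
  *and* donor–hydrogen–acceptor angle ≥ 120°, which requires explicit
  polar hydrogens;
* **hydrophobic contacts** — mass-weighted side-chain centre-of-mass
  distance ≤ 5.5 Å for residues in {Ala, Val, Leu, Ile, Met, Phe, Pro,
  Trp}, extensible to acyl groups through the residue-template config.

Contacts between sequence neighbours (|Δresno| < 2 in one chain) are
excluded uniformly across classes; the separation is configurable.
Multiple simultaneous contacts of one class between a residue pair in
one frame count once, and pairs are stored symmetrically with the
lower-numbered residue first.

### The significance threshold p~T~

Transient contacts are noise for communication analysis.  The threshold
p~T~ below which an interaction is discarded is estimated from the data:
the size of the largest connected component of the *hydrophobic* graph
is scanned over a persistence grid (0–100 % in 5 % steps — the
hydrophobic component is the most restrictive constraint on PSN
construction).  That curve falls from a plateau that includes transient
noise to a persistent core.  `estimate_pt()` fits a four-parameter
decreasing logistic and reports the inflection abscissa; if the fit
fails, the midpoint of the steepest single-step drop is used.  Both the
continuous fit value and its nearest grid value are reported, since
rounding conventions differ between published analyses.  A curve with no
drop has no inflection and the user must supply p~T~ explicitly.  p~T~
is estimated on the hydrophobic class but applied to all three classes:
the per-class graphs are filtered at p~T~ and joined into one PSN, each
edge keeping its maximum persistence and the set of contributing
classes.

### Hubs

A *hub* is a PSN node with at least `min_degree` neighbours (default 3);
nodes of degree ≥ 7 carry a highest-degree flag.  Ties in the hub table
are broken by residue number so output is deterministic.

### Communication robustness and selective betweenness

For a source A and sink B (for a calcium sensor: an EF-hand bidentate
glutamate and a target-interface residue), communication is scored on
*unweighted shortest paths* in the PSN — persistence shapes the network
only through the p~T~ filter.  With σ~AB~ the number of distinct
shortest paths and *l* their length in edges, the communication
robustness index is

$$\mathrm{CR} = \frac{\sigma_{AB}\, p_T}{l},$$

increasing in the number of parallel shortest routes and in the
persistence level those routes survive, and decreasing in length
(parsimony).  This is a design decision of this package: the index is
the simplest function of exactly these three quantities with the
required monotonicities; it is implemented as one pure function
(`cr_index()`) so that alternative algebraic forms can be swapped, and
the variant identifier (`cr-v1: sigma*pT/l`) is stamped into every graph
attribute and manifest.  A disconnected pair has CR = 0 exactly.

Selective betweenness restricts betweenness to one endpoint pair:
σ~AB~(v) is the number of A–B shortest paths through v, computed by the
two-sided BFS product σ~A~(v)·σ~B~(v) for nodes with
d~A~(v) + d~B~(v) = l, and SB(v) = σ~AB~(v)/σ~AB~.  Endpoints carry
SB = 1 by convention and are excluded from path scores.  The
conservation identity Σ~internal~ σ~AB~(v) = σ~AB~(l − 1) is asserted at
runtime on every computed map.  `max_sb_path()` returns, among all
shortest paths, the one maximizing the summed SB of its internal nodes,
with lexicographic node-id tie-breaking.  Explicit path enumeration is
capped (default 10⁶) against combinatorial blow-up; the *count* σ~AB~ is
always exact because it comes from the BFS recursion, not the
enumeration.

### Sampling-convergence diagnostics

Because network statistics are only meaningful on a well-sampled
ensemble, the package carries the standard essential-dynamics
diagnostics: the covariance matrix of Cα positional fluctuations about
the trajectory mean (population divisor, optional mass weighting — a
no-op on an all-Cα selection), its eigendecomposition
(`pca_subspace()`, default S = 20 modes, warning when the captured
variance falls below 80 %), per-frame projections on single components,
the cosine content

$$c_i = \frac{2}{T}\,
  \frac{\left(\int_0^T p_i(t)\cos(i\pi t/T)\,dt\right)^2}
       {\int_0^T p_i(t)^2\,dt},$$

and the root-mean-square inner product between two essential subspaces

$$\mathrm{RMSIP} = \sqrt{\frac{1}{S}\sum_{i=1}^{S}\sum_{j=1}^{S}
  (\mathbf{n}^A_i\cdot\mathbf{n}^B_j)^2}.$$

A c₁ near 1 indicates random-diffusion-like, unconverged sampling; a
c₁ of the concatenated trajectory below the per-replica average, and
RMSIP values well above chance between replicas, support pooling
replicas into one concatenated ensemble for the network analysis.

### Conformational clustering

The clustering cutoff is data-driven: the mean best-fit Cα RMSD of all
frames to their average structure (`derive_cutoff()`).  Pairwise RMSD
matrices are computed on strided frames (default every 4th).  Two
algorithms are provided: GROMOS greedy neighbour counting (the frame
with most neighbours within the cutoff becomes a center, it and its
neighbours are removed, repeat) and single-linkage agglomeration cut at
the cutoff.  Single linkage chains through gradual drifts and therefore
reports no more clusters than GROMOS on chained data — the qualitative
relation the two algorithms are expected to show on long protein
trajectories.  Cluster centers are the greedy centers (GROMOS) or
medoids (linkage); ties everywhere break on the lowest frame index.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| salt-bridge cutoff | 4.5 | Å | charged-group COM distance |
| H-bond distance / angle | 3.5 / 120 | Å / deg | donor–acceptor / D–H–A |
| hydrophobic cutoff | 5.5 | Å | side-chain COM distance |
| sequence separation | 2 | residues | excludes i, i±1 contacts |
| scan step | 5 | % | p~T~ grid resolution |
| PSN p~T~ | estimated | fraction | persistence filter |
| hub min degree / highest | 3 / 7 | neighbours | hub classes |
| PCA modes S | 20 | — | essential-subspace dimension |
| trajectory stride / cluster stride | 1 / 4 | frames | frame thinning |
| enumeration cap | 10⁶ | paths | explicit path lists only |

## The synthetic-data generator

No MD data ship with the package; every test fixture is generated in
code.  `make_polymer()` builds an extended toy chain (Cα every 3.8 Å
with a mild y zig-zag so the Cα trace is never collinear — a degenerate
configuration for least-squares fitting) with side-chain pseudo-atoms,
polar hydrogens on donors, and optional ion/acyl residues.
`make_trajectory()` adds seeded harmonic collective modes (random
orthonormal directions; an optional separate direction seed lets several
trajectories share one mode model, emulating replicas of one system),
isotropic Gaussian noise, and *geometrically realized* contacts: for
each planted contact the partner group is placed at 0.9 × cutoff on
"on" frames and 1.6 × cutoff on "off" frames, so the detectors
themselves are exercised and the realized persistence equals the
recorded on-count exactly.  Temporal models are independent Bernoulli
(for exact-count tests) and a two-state telegraph chain (because
persistence in MD is autocorrelated).

`make_pathway_scenario()` plants an allosteric chain: chain residues'
side chains live in a lane offset from the backbone and successive
contacts are chained along +x, so non-consecutive chain nodes are always
≥ 1.8 × cutoff apart and the chain is the *unique* shortest source–sink
route under the planted p~T~ by construction.  Decoy contacts (default
persistence 0.05, below any reasonable p~T~) occupy vertex-disjoint
residue blocks dropped below the backbone plane, so they can never
create shortcuts or corrupt the planted bookkeeping.  Scenario defaults
(5-node chains at persistence 0.9, five decoys at 0.05, 200 frames,
thermal noise 0.02 Å) keep every inter-group margin above the largest
detector cutoff; larger noise would be realistic for MD but would turn
planted counts into approximate ones.

What the generator does *not* emulate: force-field energetics,
Boltzmann-weighted sampling, solvent, correlated side-chain rotamer
dynamics, or realistic secondary structure.  Passing tests therefore
demonstrate the correctness of the detectors, network construction and
pathway arithmetic on known ground truth — not that any particular
biological system is well sampled.

## Numerical choices and degenerate inputs

* Time integrals in the cosine content use the trapezoid rule on uniform
  frame times with T = (n − 1)·dt; rectangle vs trapezoid differs at
  O(1/n) and is immaterial at MD frame counts.
* Eigenvector signs are fixed by making the largest-magnitude component
  positive, so projections are reproducible across platforms.
* Best-fit RMSD of numerically identical frames can yield the square
  root of a tiny negative residual; it is clamped to zero.
* The PCA reference frame is a required input (config field) rather than
  a hard-coded choice, since the equilibrated conformation used as
  reference is a property of the study, not of the method.
* `estimate_pt()` reports both the continuous logistic inflection and
  its nearest grid value; a constant largest-component curve raises an
  error instead of guessing.
* All tabular outputs are written as plain TSV with fixed column order;
  reruns on identical inputs are bit-identical (graph files exclude the
  writer's timestamp for the same reason).

## Scope and limitations

* Trajectory input: multi-model PDB and DCD (plus PDB/GRO topologies).
* Paths are unweighted; no flow-, current- or energy-weighted
  centralities, and no all-pairs global betweenness.
* The interaction classes are the three above — no π-stacking, cation-π
  or water-mediated interactions.
* Ion charge assignments and acyl hydrophobic atom sets are configurable
  templates, not force-field derived.
* Validation problem sizes: path oracles on 200 random graphs of ≤ 12
  nodes against exhaustive enumeration; 50 planted-chain scenarios of
  200 frames; clustering against brute-force reimplementations on ≤ 30
  frames.  These sizes make every expected value checkable by an
  independent oracle.

## A worked example

```{r example, eval = FALSE}
sc <- make_pathway_scenario(chain_spec(5), n_decoys = 5,
                            n_frames = 200, seed = 1)
tab  <- persistence_table(sc$trajectory)
scan <- threshold_scan(tab)
psn  <- build_psn(tab, sc$truth$p_T)
path_set(psn, sc$truth$source, sc$truth$sink)
max_sb_path(psn, sc$truth$source, sc$truth$sink)
cr_matrix(psn, sc$truth$source, sc$truth$sink)
```

The same steps run against real data via `run_state_analysis()` with a
YAML config naming topologies, trajectory replicas, source/sink residue
selectors (`"A:GLU:75"` syntax) and cutoff overrides; outputs are TSV
tables, GML graphs and a YAML manifest recording every parameter, seed
and formula variant.
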