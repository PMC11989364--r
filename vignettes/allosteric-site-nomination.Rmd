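---
title: "Nominating allosteric pockets from coarse-grained network models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nominating allosteric pockets from coarse-grained network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allopocket)
```

## The problem

Allosteric sites are binding cavities away from a protein's functional site
whose occupation nonetheless modulates activity. Two inexpensive, structure-
only signals correlate with allostery: (i) residues whose local crowding
perturbs the protein's slowest collective motions, and (ii) residues that act
as bottlenecks of the intramolecular contact network. `allopocket` computes
both signals for a protein complex, intersects them, and maps the shared,
solvent-accessible residues onto detected surface pockets; pockets containing
such residues are nominated as putative allosteric sites. Everything runs on
an ordinary PDB file; no dynamics, docking, or proprietary software.

## Model 1: essential-site scanning on a Gaussian network

The structure is coarse-grained to one node per residue at its C-alpha;
nodes within a cutoff $r_c$ (default 10 Å, the conventional scalar-network
choice) are joined by identical springs. The Kirchhoff (graph Laplacian)
matrix $\Gamma$ has $\Gamma_{ij} = -1$ for contacts, node degrees on the
diagonal, and a spectrum $0 = \lambda_0 < \lambda_1 \le \dots$ whose smallest
nonzero eigenvalues describe the softest global motions.

Each residue $i$ is then perturbed in turn by inserting one extra node per
side-chain heavy atom — a proxy for the steric crowding a bound ligand would
cause — and the spectrum is recomputed at the same cutoff. The response is
the percent shift per mode,
$$\Delta\lambda_k(i)\% \;=\; 100\,\frac{\lambda_k(i) - \lambda_k}{\lambda_k},$$
averaged over the ten slowest nonzero modes (ten modes typically carry the
bulk of the global dynamics; fewer makes the score noisy, more dilutes it).
Mean shifts are z-scored across residues,
$z_i = (\langle\Delta\lambda_{1\text{–}10}(i)\rangle - \mu)/\sigma$, and
residues in the top quartile of $z$ (threshold by linear-interpolation
percentile, ties included) are flagged *essential*. Such residues
concentrate at global hinges and at orthosteric/allosteric sites.

Numerical choices worth knowing:

* **Mode pairing.** Reference and perturbed eigenvalues are paired by rank
  among nonzero eigenvalues. The perturbed network is larger, but the
  inserted nodes are few and peripheral, so rank pairing is stable;
  eigenvector-overlap mode tracking is deliberately not attempted.
* **Spring constant.** Uniform and set to 1: the percent shift is a ratio
  and provably invariant to any uniform rescaling (tested at 0.1×, 1×, 10×).
* **Glycine.** Residues without side-chain heavy atoms cannot be perturbed.
  They are kept in the output with mean shift 0 and flagged `skipped`;
  $\mu$ and $\sigma$ (population form — no Bessel correction) are computed
  over non-skipped residues only, and skipped residues can never be
  essential. This keeps the profile length equal to the residue count.
* **Connectivity.** A disconnected elastic network makes z-scores
  meaningless across components, so it is a hard error
  (`allo_disconnected_error`, reporting component sizes), never a warning.
* **Eigensolvers.** The default path is a dense LAPACK decomposition (the
  per-residue scans re-factorize small matrices anyway); an ARPACK
  shift-invert path over a sparse Cholesky factor is available for large
  single decompositions, and the two agree to better than $10^{-6}$
  relative on the slow modes (tested on 200 random connected networks).

## Model 2: residue interaction network

Residues are nodes; an edge joins every residue pair with at least one
heavy-atom pair within 4.5 Å (boundary included). The interaction strength
is the normalized contact count
$$a_{ij} = \frac{N_{ij}}{N_i\,N_j},$$
with $N_i$ the heavy-atom count of residue $i$ and $N_{ij}$ the number of
contacting heavy-atom pairs; the shortest-path distance of the edge is
$1/a_{ij} \ge 1$. Sequence-adjacent residues are *not* excluded: the
normalization already down-weights the otherwise dominant covalent contacts.
Weighted shortest-path betweenness (Brandes, endpoints excluded, equal
fractional credit across tied paths, normalized by $2/((n-1)(n-2))$ so
scores are size-comparable) identifies communication bottlenecks; nodes in
the top 5% (same percentile/tie conventions as above) are *hub* residues.
Closeness and degree are reported alongside but drive no selection. Unlike
the elastic network, a disconnected interaction graph is legal: betweenness
is computed per component and the quantile taken over all nodes.

## Pockets and consensus

Pockets come from either source:

* **Fpocket ingestion** — the standard `*_out` directory layout is parsed;
  each pocket's residues come from `pockets/pocket<N>_atm.pdb` and its
  druggability score and total SASA are read verbatim from the info file.
  These descriptors are external tool outputs and are never recomputed.
* **Built-in grid detector** — a deterministic stand-in when Fpocket output
  is not at hand: cubic lattice points (1.0 Å spacing) over the padded
  bounding box are kept when at least 2.2 Å from every heavy atom yet with
  at least 18 heavy atoms within 8 Å, clustered by 6-connected flood fill;
  clusters of ≥ 15 points become pockets whose residues lie within 5 Å of a
  cluster point.

Each pocket receives the median and the maximum z-score of its residues
(the ranking key defaults to the median; both are always reported, since
either aggregate is a defensible pocket score). The consensus stage takes
`essential ∩ hubs`, keeps residues with at least `sasa_min` (default 5 Å²)
of solvent-accessible surface — computed by deterministic golden-spiral
sphere sampling (960 points/atom, 1.4 Å probe, Bondi-style radii, fallback
1.7 Å for unknown elements) — and marks any pocket containing at least one
such mutual residue as a consensus candidate. Candidates are ranked by
(mutual count, pocket z aggregate), and pocket pairs sharing residues are
reported as back-to-back neighbours, a configuration of practical interest
because paired pockets can share a druggable rim.

The one-mutual-residue consensus threshold and the 5 Å² accessibility floor
are deliberate knobs: the mutual count is always reported so stricter
cutoffs can be applied downstream.

## Synthetic ground truth

The package ships generators, not data files; every structure is rebuilt
from a seed at test time and generation leaves the caller's RNG state
untouched.

* `generate_two_domain()` packs two 25-residue C-alpha clusters (rejection
  sampling in 9 Å spheres, 3.8 Å minimum separation — about one residue per
  115 Å³, ordinary protein density) and joins them by a 4-residue collinear
  linker at 3.8 Å spacing, with an anchor residue pinned at each domain pole
  and a buttress residue wiring each anchor into its domain at contact
  distance. The axial chain (buttress–anchor–linker–anchor–buttress) carries
  every inter-domain contact, so it is simultaneously the elastic-network
  hinge and the interaction-network bottleneck: shared ground truth for both
  methods. Pseudo side chains are one C-beta at 1.5 Å (`cbeta`, default),
  three atoms (`triplet`), or none (`none`, glycine-like — useful for
  exercising the no-perturbable-residue contract).
* `generate_cleft_structure()` builds a spherical C-alpha cage (7.5 Å
  radius, 3.3 Å wall spacing, seeded tangential jitter) with a ~6.4 Å
  aperture cone left open: a cavity whose lining residues are known exactly.
  With `filled = TRUE` the cage collapses into a compact convex lattice
  cluster as a negative control.

What the synthetic structures do *not* emulate: real side-chain rotamers,
backbone connectivity beyond the C-alpha trace, heterogeneous residue
sizes, crystallographic artifacts (altlocs, missing density), and real
protein packing density above ~1 heavy atom per 60 Å³. Passing tests
therefore demonstrate the contracts and the mechanics of hinge/bottleneck
recovery, not predictive performance on crystal structures.

On the detector constants: with the clearance/burial values above, the
burial count separates cavity interior from exterior only at the synthetic
C-alpha cage density. At full atomic density every point in the first
solvent shell of a convex protein also satisfies the burial test, so for
real structures the Fpocket ingestion path is the appropriate source and
the grid detector should be treated as a coarse-grained stand-in. The
`filled` negative control exploits the converse: a compact cluster with
fewer than 18 heavy atoms in total cannot satisfy the burial test anywhere,
guaranteeing a clean zero.

## Parameters at a glance

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `enm_cutoff` | 10.0 | Å | C-alpha spring cutoff of the elastic network |
| `n_modes` | 10 | — | slowest nonzero modes averaged in the scan |
| `essa_quantile` | 0.75 | — | essentiality threshold (top 25% of z) |
| `contact_cutoff` | 4.5 | Å | heavy-atom contact distance (closed boundary) |
| `rin_quantile` | 0.95 | — | hub threshold (top 5% of betweenness) |
| `sasa_min` | 5 | Å² | per-residue accessibility floor for consensus |
| `probe` | 1.4 | Å | solvent probe radius |
| `zero_tol` | 1e-8 | relative | zero-mode tolerance of the eigensolver |

The 10 Å elastic-network cutoff is the conventional default of the scalar
network model and is recorded as an assumption; results for compact
structures are insensitive to ±1 Å.

## Degenerate inputs and tie-breaks

Alternate locations keep the highest-occupancy copy (ties: first in file).
Residues lacking a C-alpha are dropped at curation with a logged warning —
network nodes require one (retained hetero residues without a C-alpha are
placed at their heavy-atom centroid instead). All-equal score vectors
select every residue (the percentile of a constant vector is that
constant, and ties at the threshold are included by definition). A pocket
none of whose residues appear in the scan profile has no defined aggregate;
it is flagged and ranked last rather than silently scored.

## Scale of the validation runs

The bundled checks run on 54-residue two-domain structures (10 seeds),
random connected networks of 20–200 nodes (200 instances for the
Laplacian/eigensolver properties), exhaustively enumerable weighted graphs
of ≤ 7 nodes (50 instances) for the betweenness oracle, and ~60-residue
cavity cages. These sizes keep the full suite to well under a minute while
leaving every property dependent on the same code paths a full-size complex
would use; a 1,000-residue complex runs the per-residue scan in minutes
because each perturbation re-decomposes an $n{+}s$ matrix.

## Known limitations

* Missing side chains are used as-is; no rebuilding or protonation is
  attempted, so scan scores for truncated residues underestimate crowding.
* Rank pairing of eigenvalues can mislabel shifts if a perturbation
  reorders near-degenerate modes; averaging over ten modes damps this.
* The grid detector is density-limited as described above.
* Whether a given study retained nucleotides/ions in the network is often
  unstated; curation defaults to removing all hetero residues, with
  `drop_hetero = FALSE` available to keep them as extra nodes.
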