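---
title: "Dynamical network analysis and hapten cross-reactivity classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical network analysis and hapten cross-reactivity classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fqcross)
```

## The problem

Monoclonal antibodies raised against a small-molecule hapten usually bind a
family of structural analogues with cross-reactivities spanning orders of
magnitude. For the fluoroquinolone (FQ) antibiotics — which share a quinolone
bicyclic core with a C3 carboxyl, C4 carbonyl and usually a C6 fluorine, and
differ in N1/C5/C7/C8 substituents — predicting which analogues an
anti-FQ antibody will recognise is hard precisely because the shared core
makes static descriptors uninformative: docking binding energies of
cross-reactive and non-cross-reactive FQs overlap, so no energy threshold can
separate them (the packaged docking table reproduces this:
`descriptor_overlap(reference_docking(), "lowest_energy_kcal")`).

What does separate the classes is a *dynamic* property: a hapten that forms a
stable complex moves in a correlated way with the residues of the
antigen-binding site and thereby becomes part of the antibody's internal
communication network. fqcross implements the trajectory-based pipeline that
quantifies this: coarse-grained node partitioning, a contact-restricted
correlation network, edge betweenness centrality, and the scalar
quinolone-ring betweenness sum $S_q$ used as a binary classifier, together
with the competitive-ELISA arithmetic (4PL fits, IC50, cross-reactivity) that
provides the experimental labels.

## The network model

Given a coordinate trajectory of the complex:

1. **Partitioning.** One node per amino-acid residue and 3–4 user-defined
   nodes per ligand, one of which — the *ring node* — holds all non-hydrogen
   atoms of the quinolone ring (including ring-attached halogen or amino
   substituents; the assignment ships as a TSV, never guessed from
   structure). Residue nodes are represented by their C$\alpha$ atom, ligand
   nodes by the unweighted centroid of their member heavy atoms. The C$\alpha$
   convention is the established choice of the dynamical-network method;
   the centroid is its natural analogue for extended ring/substituent
   fragments. An alternative `first_atom` convention is available; nothing
   downstream depends on it.
2. **Superposition.** Frames are least-squares superposed (rotation +
   translation, fitted on protein nodes only, ligand carried along) onto the
   mean structure, removing global rigid motion.
3. **Correlation.** The scalar (dot-product) normalized cross-correlation of
   node displacement vectors,
   $C_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
   \sqrt{\langle |\Delta r_i|^2\rangle \langle |\Delta r_j|^2\rangle}$,
   with time averages over frames. Per-component correlation and linear
   mutual information are out of scope.
4. **Contacts.** Nodes are edge-eligible only if any heavy-atom pair is
   within 4.5 Å in at least 75% of frames (both bounds inclusive; atom-level,
   because fragment nodes are spatially extended). Covalently adjacent pairs
   (sequence neighbours, bonded ligand fragments) are always eligible so the
   graph stays connected along chains. Both parameters are configurable; the
   defaults are the standard ones of the network methodology.
5. **Weights.** $w_{ij} = -\ln |C_{ij}|$ (natural logarithm; only the
   ordering of path costs matters for betweenness). A contact pair with
   exactly zero correlation would have infinite weight; the edge is dropped
   with a warning.
6. **Betweenness.** Edge betweenness by Brandes' algorithm: each unordered
   node pair contributes one unit of credit, split equally over its
   equal-cost shortest paths (raw counts, unnormalized — the descriptor's
   published magnitudes are raw counts over all pairs). Path-cost ties are
   decided with a $10^{-12}$ relative tolerance because $-\ln|C|$ weights
   are floats and exact ties arise in symmetric toys. An `all_paths` counting
   mode (full credit per equal-cost path) is provided for diagnostics on
   small graphs.
7. **The descriptor.** $S_q$ is the sum of the betweenness of the edges
   joining the ring node to protein residue nodes. "Betweenness between the
   ring node and residue $k$" is interpreted at the *edge* level (not
   path-endpoint level): published per-residue profiles are non-zero only
   for binding-site residues adjacent to the ligand node, which matches edge
   semantics; a ligand that left the site has no ring–protein edges and
   $S_q = 0$ exactly. This is the single most consequential interpretation
   in the package.

### The classifier

A hapten is called cross-reactive when $S_q \ge 4000$ (inclusive: the lowest
published cross-reactive score is 4169, so the 4169 system must classify
positive; behaviour exactly at 4000 is unobserved and simply documented).
The threshold is a configuration value, not a fitted quantity, and its
published magnitude is calibrated for Fab-scale systems (~220 residues,
tens of thousands of node pairs). For the package's small synthetic systems
the same pipeline produces proportionally smaller sums, so toy runs should
pass a commensurate threshold; the packaged reference table is the 4000-scale
input. On that table the classifier yields exactly two false positives (DIF,
ORB) and no false negatives.

## Competitive-ELISA module

Calibration curves are fitted with the four-parameter logistic
$\mathrm{OD}(x) = d + (a - d)/(1 + (x/c)^b)$ by bounded Levenberg–Marquardt
least squares on log concentration (starting values $a$ = zero-dose/maximum
OD, $d$ = minimum OD, $c$ = geometric-mean concentration, $b = 1$; bounds
$c, b > 0$). IC50 is the inflection $c$, the concentration halving the
signal between the asymptotes — the symmetric 4PL places the inflection at
$c$ exactly, which is why 4PL (not 5PL) is used. Cross-reactivity is
$\mathrm{CR} = \mathrm{IC50}_{\mathrm{ref}} / \mathrm{IC50}_x \times 100\%$.

Curves whose dynamic range is below three times the replicate noise (or
essentially flat) are *censored*, not force-fitted: the IC50 is reported as
"greater than the highest tested concentration" and CR as an upper bound
(displayed `<0.01` when the bound falls below 0.01%, mirroring the assay
convention). Replicate uncertainty is propagated as the standard deviation
of per-replicate CRs, pairing replicate $r$ of the analyte with replicate
$r$ of the reference; the propagation method behind published CR
uncertainties is not specified anywhere, so this simple convention is
documented rather than reverse-engineered.

## The synthetic generator

MD trajectories of an antibody Fab at the hundreds-of-nanoseconds scale are
out of reach for a test suite, and the analysis consumes only *correlations*
and *contact persistence*. The generator therefore controls exactly those
statistics:

* **Geometry.** A solenoid of coarse residues (C$\alpha$ + two side atoms,
  10 residues per turn) whose interior is the pocket. The ligand mimics a
  fluoroquinolone's shape: the ring node is the large central fragment
  dominating the pocket contacts, with small terminal substituent nodes near
  the pocket mouth. This shape matters: with three equally-contacting
  fragments the descriptor's credit splits arbitrarily among them, while the
  real molecule concentrates contacts (and hence network flow) on the ring.
  A `detached` geometry places the ligand >10 Å from the protein, emulating
  a ligand that left the binding site.
* **Dynamics.** Per-frame node displacements are zero-mean multivariate
  Gaussian, drawn independently per Cartesian axis so the dot-product
  correlation equals the target matrix; atoms move rigidly with their node.
  The target correlation is 0.3 between covalently *or spatially* adjacent
  nodes and `coupling_rho` (default 0.8 for a binder, 0 for a non-binder)
  within the coupled block of ligand nodes plus the `n_site_residues`
  nearest residues.

Two deliberate design choices in the target matrix deserve explanation.
First, the coupled block is *equicorrelated* — ligand–ligand and site–site
pairs inside the block share the same $\rho$ as ligand–site pairs — because
a "star" target (ligand correlated with each site residue but site residues
mutually uncorrelated) is not positive semidefinite at $\rho = 0.8$
(a star is PSD only for $\rho \le 1/\sqrt{k}$), and projecting such a target
to the nearest PSD matrix would silently destroy the very coupling the
generator is supposed to deliver. An equicorrelated block is PSD for any
$\rho \ge 0$ and is also the natural one-factor model of a collectively
breathing binding site. Second, spatially contacting residue pairs get the
same 0.3 as sequence neighbours: real contacting residues do move together,
and without those correlated cross-links the toy protein's only
communication routes run along the chain, making *any* pocket ligand a
purely geometric bottleneck — which would hand the classifier its answer
for free. Correlations between block members and outside neighbours are
damped by $\sqrt{1-\rho^2}$ (nodes dominated by the shared binding mode
retain only that much residual freedom), after which remaining negative
eigenvalues are tiny and clipped at $10^{-10}$, with the applied adjustment
recorded in the ground truth.

Defaults (30 residues, 3 ligand nodes, 5 site residues, displacement SD
0.5 Å, 1500 frames) are the package's study conditions: 0.5 Å is a typical
C$\alpha$ fluctuation scale, and 1500 frames keeps the finite-sampling
correlation noise floor ($|r| \approx 1/\sqrt{3F} \approx 0.015$) low enough
that noise edges (weight $-\ln|r| \approx 4$) never compete with genuine
coupling edges (weight $-\ln 0.8 \approx 0.22$), in the same way long MD
sampling does.

What the generator does *not* emulate: anisotropic and amplitude-varying
fluctuations, solvent, conformational transitions, contact making/breaking
dynamics, and any force-field physics. Passing tests therefore demonstrate
that the *pipeline* measures imposed correlation/contact structure
correctly and that the descriptor separates coupled from uncoupled ligands
under Gaussian statistics — not that the method's published absolute
magnitudes are recoverable, which is exactly why the published betweenness
table ships as an input fixture rather than a recomputation target.

The ELISA generator samples OD from the 4PL with multiplicative Gaussian
noise (`noise_cv`, default 3%, the scale of a well-run plate) on an 8-level
log-serial dilution from 0.001 to 167 ng/mL (the reference calibration
design), three replicates; `NA` IC50s yield flat curves for non-binding
analytes.

## Numerical choices, in one place

* Correlation: exact symmetrisation, unit diagonal, values clamped to
  $[-1, 1]$; a node with zero total fluctuation is an error naming the node.
* Superposition: two-pass (first frame, then mean); near-collinear protein
  node sets are refused. Degenerate rotations cannot occur afterwards.
* Contact test: inclusive at both the 4.5 Å cutoff and the 75% frame
  fraction, with a $10^{-12}$ relative guard against float equality.
* Dijkstra/Brandes: $O(n^2)$ node selection (networks here have tens to a
  few hundred nodes), unordered pairs counted once, credit halved after
  summing over sources.
* 4PL: fitted in $\log c$ for conditioning; zero-dose wells anchor the
  starting $a$ only; an `a ≤ d` (non-decreasing) fit is treated as
  censored.
* JSON reports: keys sorted recursively, six significant digits — reruns on
  identical inputs are byte-identical.
* Correlation-recovery checks in the tests run on the raw generator frames
  (no superposition): the generator emits frames in a common laboratory
  frame, and least-squares centring on 30 protein nodes of which 5 are
  ligand-coupled shrinks ligand–site correlations by $O(k/n)$ — a property
  of the superposition step, tested separately, not of the estimator under
  test.

## Scale of the shipped checks

The test suite and the acceptance script size their simulations to run on a
single CPU in minutes: 500 random graphs (≤ 8 nodes) against brute-force
path enumeration, one 5000-frame system for correlation recovery, 50
binder/non-binder pairs at the default 1500 frames for the separation
property, 5 detached systems, and 100 noisy ELISA panels for IC50 recovery.

## Known limitations

* The pipeline reproduces the *qualitative* structure of the published
  betweenness results (integer-scale profiles concentrated on binding-site
  residues, zero for detached ligands, binder ≫ non-binder); absolute
  published magnitudes depend on the original long MD trajectories and the
  exact conventions of the original network tool, which are not fully
  specified (normalization, pair ordering, edge vs path-endpoint
  semantics — see the edge-level interpretation above).
* The 4000 cut-off is meaningful at Fab scale only; applying the package to
  other systems requires re-anchoring the threshold on systems of known
  label, as any screening use would.
* Insertion codes, altLoc fields, multi-ligand systems and nucleic acids
  are rejected rather than handled.
* DCD support is CHARMM-style little-endian, fixed atom count, no unit-cell
  records; XYZ is whitespace multi-frame text. Nothing else is parsed.
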