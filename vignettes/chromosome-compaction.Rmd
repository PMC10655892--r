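---
title: "Modelling mitotic chromosome compaction with looping and bridging condensins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mitotic chromosome compaction with looping and bridging condensins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`condensac` simulates a coarse-grained prophase chromosome as a bead-spring
polymer. One bead of diameter $\sigma$ represents 20 nm of chromatin fiber
holding 2 kbp (an intermediate choice between a 10-nm and a 30-nm fiber
mapping). Two condensin activities are modelled as distinct species:

* **Looping condensins** are not particles at all: they are static harmonic
  springs that close consecutive chromatin loops. A loop of length $L$
  starting at anchor bead $i$ is closed by a spring from $i$ to bead
  $j = i + L - 1$, the bead immediately preceding the next anchor, so loops
  tile the chain back-to-back with no linker beads. The ordered anchors form
  the chromosome backbone, and the result is a bottlebrush polymer (BBP)
  whose bristle repulsion confers a large effective stiffness.
* **Bridging condensins** are diffusing beads that bind chromatin
  multivalently. They interact with the polymer purely sterically during an
  initial equilibration and then attractively — weakly with generic
  chromatin ($\epsilon = 3\,k_BT$), strongly with loop anchors
  ($\epsilon = 8\,k_BT$). No bridge–bridge attraction exists; clustering
  emerges from the bridging-induced attraction feedback (bridges raise the
  local binding-site concentration, which recruits more bridges).

The potential-energy terms are:

* Soft non-bonded repulsion between polymer beads,
  $U_{soft}(r) = A\,[1 + \cos(\pi r/r_c)]$ with $r_c = 2^{1/6}\sigma$.
  The barrier is bounded by $2A$, so chains can pass through one another;
  this is the in-model representation of topoisomerase II. $A = 1\,k_BT$
  corresponds to high topoisomerase activity, $A = 100\,k_BT$ to strongly
  suppressed strand passage.
* Harmonic chain bonds $U = K(r - r_0)^2$, $K = 100\,k_BT/\sigma^2$,
  $r_0 = 1.1\sigma$ (note the stiffness convention carries no factor
  $1/2$).
* Kratky–Porod bending $U = K_{BEND}(1 + \cos\phi)$ at every interior
  chain bead, $K_{BEND} = 3\,k_BT$, giving a bare-fiber persistence length
  of roughly $3\sigma \approx 60$ nm.
* Loop-closure springs $U = K_{backbone}(r - r_1)^2$ with
  $K_{backbone} = 100\,k_BT/\sigma^2$ and rest length $r_1 = 1.8\sigma$.
* Truncated Lennard-Jones interactions between bridges and the polymer.

### The attraction cutoff

A Lennard-Jones potential truncated at $2^{1/6}\sigma$ is the purely
repulsive WCA form: it exerts no attractive force whatever $\epsilon$ is,
so quoting that cutoff together with distinct attraction strengths of 3 and
8 $k_BT$ would make bridging inoperative. `condensac` therefore truncates
the two attractive pairs (bridge–chromatin, bridge–anchor) at $1.8\sigma$
with the energy shifted to zero at the cutoff — the standard convention in
bridging/binder polymer models — while bridge–bridge contacts keep the WCA
form with $\epsilon = 1\,k_BT$. The cutoff is exposed as the
`attr_cutoff` argument of `forceField()`; changing it rescales absolute
binding energies but not the qualitative phase behaviour.

## Dynamics and units

The equation of motion is underdamped Langevin,
$m\,\ddot r_i = -\nabla_i U - \gamma \dot r_i + \sqrt{2k_BT\gamma}\,\eta_i$,
integrated with velocity-Verlet in which friction and noise enter the force
evaluation (time step $dt = 0.01\tau$). With $m = k_BT = \sigma = 1$ and
$\gamma = 1$, the inertial, decorrelation and Brownian times coincide,
$\tau_{LJ} = \tau_{dec} = \tau_B = 1$. Setting `gamma = 0` yields plain
energy-conserving velocity-Verlet, which the test-suite uses to verify the
integrator.

Physical units come from `unitSystem()`: with $\sigma = 20$ nm,
$T = 300$ K and a nucleoplasm-like viscosity of 150 cP, the Brownian time
$\tau_B = 3\pi\sigma^3\eta/k_BT$ evaluates to about 2.73 ms (commonly
rounded to $\sim$3 ms; the package returns the unrounded value so that
step-count conversions do not compound rounding), and the force unit
$k_BT/\sigma$ to about 0.207 pN. Micromanipulation-scale forces of
2–9 pN therefore map to roughly 10–43 simulation force units.

The noise stream is a counter-based generator keyed by
`(seed, step, particle)`: trajectories are bit-reproducible from the seed
and independent of how a run is split into chunks.

### Periodic box

The box is cubic and periodic with minimum-image interactions; coordinates
are stored and written unwrapped, so every shape observable can ignore
images. The default side is 1.5 times the initial backbone extent. A much
larger box (several times the polymer length) would be equally valid
physically but makes bridge capture a slow diffusion-limited search; the
1.5 factor keeps the polymer clear of its periodic image while keeping the
approach kinetics inside a desk-scale budget. Bridges start uniformly
distributed in the polymer's bounding box inflated by 8$\sigma$ (condensin
I is chromatin-loaded when bridging begins), with placements rejected
within $1\sigma$ of an existing particle so no initial force diverges.

## Protocols

`runCompaction()` implements the two-phase experiment: (1) equilibrate the
bottlebrush with sterically inert bridges; (2) at $t = 0$ switch on the
attractive interactions and follow the collapse into the self-assembled
cylinder (SAC). Gyration radius $R_g$, acylindricity
$Ac = \lambda_2 - \lambda_1$ and bridge cluster statistics are recorded
throughout. A plateau is declared when the windowed mean $R_g$ changes by
less than 1% between consecutive windows; if the budgeted duration ends
before that, the run warns and returns the partial result rather than
silently extending itself.

`runExtensionRetraction()` reproduces in-silico micromanipulation: equal
and opposite constant forces on the two terminal backbone anchors
(constant-force, not constant-velocity — the two coincide only in the
thermodynamic limit), then release. `runScenario()` wires the perturbation
experiments: condensin I knockout (loops $\times 2$, bridges halved),
condensin II knockout (loops $\times 0.5$, bridges doubled), fragile-site
removal (two adjacent loop springs deleted) and merge (three loops fused
into one), and centromere-linked sister chromatids. The knockout
loop-length factors of 2 and 0.5 are a package choice: the biology fixes
the direction (longer loops after condensin I loss, shorter after
condensin II loss) but not the magnitude, and a symmetric factor keeps the
two perturbations comparable.

## Observables

* `gyrationTensorShape()` reports the principal axis lengths as the square
  roots of the gyration-tensor eigenvalues, so
  $R_g^2 = \lambda_1^2 + \lambda_2^2 + \lambda_3^2$ and the acylindricity
  carries length units. The raw-eigenvalue convention is available via
  `eigenvalue_axes = TRUE`; the two are monotone-equivalent for every
  comparison made here.
* `tangentCorrelation()` coarse-grains the anchor backbone by 5 or 10
  points before correlating tangents, which suppresses the local crumpling
  that bridging induces; `fitPersistenceLength()` extracts the exponential
  decay length.
* `contactProbability()` uses a contact cutoff of $3.5\sigma$ (above the
  attraction range of $1.8\sigma$, standard for bead contact maps) and
  fits the power-law exponent of $P(s)$ over an intermediate decade,
  by default 100 kbp up to one tenth of the polymer length — below that
  window bonded/loop structure dominates, above it chain-end depletion
  bends the curve. Both choices are exposed as arguments.
* `clusterBridges()` uses single-linkage components at $1.3\sigma$,
  slightly beyond the WCA contact distance $2^{1/6}\sigma \approx 1.12\sigma$.
* `bridgeValence()` counts polymer beads within $1.1\sigma$ (22 nm) of a
  bridge.
* `bristleRepulsion()` evaluates the scaling estimate
  $F \propto (T/\lambda)\sqrt{Na/(\pi\lambda)}$ for the repulsion per unit
  axial length between bottlebrush bristles. Because $\sqrt{N}$ is
  concave, Poisson-distributed loop lengths lower the mean repulsion at
  equal mean loop size — the mechanism behind the extra compaction of
  variable-loop chromosomes.

## What the generator emulates, and what it does not

Topologies built by `buildUniformBottlebrush()` /
`buildPoissonBottlebrush()` represent the study conditions: 300–400 loops
of mean size 80–120 kbp (40–60 beads) at full scale, soft amplitude
$A \in \{1, 10, 100\}\,k_BT$, and 500 bridges per 350 loops (halved or
doubled under the knockout scenarios, scaled proportionally with loop
count at reduced scale). Loops are strictly consecutive and static: no
nested or overlapping loops, no loop extrusion dynamics, no
bridging/looping interconversion, no explicit helical winding of the
backbone, and no hydrodynamic interactions.

Test-suite and acceptance runs use reduced systems, chosen once and kept
fixed:

* contact scaling and bridge valence: 100 Poisson loops of mean 80 kbp
  (about 4,000 beads) at $A = 1\,k_BT$ — the strongest-topoisomerase
  condition, which compacts deepest and fastest — with a 50 $\tau_B$
  steric equilibration and a 2,600–3,000 $\tau_B$ bridging phase,
  measured over the late third of the run. These durations do not reach a
  strict plateau (the protocol says so via its plateau warning); the
  measured contact exponent approaches the steady-state value from below.
* elasticity: a 40-loop chromosome, whose full extension–retraction cycle
  (pull at ~9 pN for 800 $\tau_B$, relax for 2,400 $\tau_B$) completes at
  desk scale; the 100-loop cycle's recovery spans the several mapped
  minutes seen in micromanipulation and exceeds a test budget.
* replicated trend comparisons (loop length, topoisomerase strength,
  knockout widths, fragile-site probes): 10–20 loops, ten replicate seeds,
  one-sided rank tests.

These runs probe the same mechanisms at smaller size and shorter times;
passing them demonstrates the model's qualitative physics, not
quantitative agreement with any particular chromosome. Simulated FISH
probes for the fragile-site scenarios are placed with one probe inside the
perturbed region and one on the first intact loops downstream: the merged
loop is expelled from the cylinder body, so this pair separates most
clearly, while probes flanking the locus on both sides move closer
together along the shortened backbone.

## Numerical choices

* Time step $0.01\tau$ with bond stiffness 100 gives
  $\omega\,dt \approx 0.14$, comfortably stable for velocity-Verlet.
* Neighbour lists are Verlet lists (skin $0.4\sigma$) built from a cell
  grid and rebuilt when any displacement exceeds half the skin; bonded
  pairs are excluded at build time.
* Directly bonded pairs (chain, loop spring, centromere) are excluded from
  non-bonded interactions.
* Initial bottlebrush coordinates stack the loop rings along a straight
  backbone with golden-angle azimuths; residual overlaps are bounded by
  the soft potential ($\le 2A$) and relax within a few $\tau_B$.
* Degenerate inputs: zero-length tangent segments are dropped from
  correlation and stiffness estimates; empty $P(s)$ bins are excluded
  from the exponent fit; `n = 0` bridges and zero-spring sister builds are
  legal degenerate cases.
* The equilibration plateau criterion (1% relative change of windowed mean
  $R_g$) is a package choice; no published criterion exists for these
  runs.

## Known limitations

* Reduced-scale SACs compact less deeply than full-scale ones; observables
  that depend on the degree of compaction (absolute width, cluster sizes)
  are meaningful in comparisons, not in absolute value.
* The extra compaction of Poisson-distributed loops relative to uniform
  loops at matched mean — predicted by the concavity of the
  bristle-repulsion estimate and seen in full-scale ensembles — does not
  resolve above seed noise in reduced replicas (tens of loops, hundreds to
  a thousand $\tau_B$): paired comparisons across several desk-scale
  configurations show no significant ordering. The mechanism itself is
  exercised analytically through `bristleRepulsion()`; the corresponding
  simulation-level test documents this scale limitation rather than
  confirming the ordering.
* Constant-force pulling differs from the constant-velocity protocol of
  real micromanipulation experiments.
* The model contains no chromosome periphery proteins, no histone-scale
  detail, and no ATP-driven loop extrusion; it addresses prometaphase
  compaction given a pre-formed loop architecture.
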