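---
title: "Folding trajectories by optimal control: the model behind lqrfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Folding trajectories by optimal control: the model behind lqrfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lqrfold)
```

## The problem and the model

lqrfold generates folding pathways that connect an unfolded protein
conformation to its native state, at coarse-grained resolution, by treating
folding as an optimal-control problem. Each residue is a bead at its
C$\alpha$ position. In the overdamped (massless) limit the chain obeys

$$\gamma\,\frac{d\Delta R}{dt} = -k_{bond}\,L_{chain}\,\Delta R + F,$$

per Cartesian coordinate, where $\Delta R = R - R^N$ is the deviation of the
bead positions from the native state, $L_{chain}$ is the path-graph
Laplacian of the covalent backbone, $\gamma$ is a friction constant and $F$
is the force field we are free to design. Writing
$A = -(k_{bond}/\gamma)L_{chain}$, the system matrix is symmetric negative
semidefinite with exactly one zero eigenvalue — rigid translation — which
the controller must stabilise.

The force field is chosen by the infinite-horizon Linear Quadratic
Regulator: minimise

$$J = \int_0^\infty \left( \Delta R^T Q\, \Delta R + \lambda\,\|F\|^2 \right) dt$$

subject to the dynamics. The first term is an elastic-network (harmonic
pair) potential centred at the native state: $Q = L_{nb} + \epsilon I$,
where $L_{nb}$ is the graph Laplacian of the *noncovalent* contact map of
the **current** conformation (pairs within `cutoff_q` of each other,
sequence separation $\ge 2$; covalent neighbours already live in
$L_{chain}$). The ridge $\epsilon I$ makes $Q$ positive definite so the
translational zero mode is stabilised. The second term penalises large
forces — trajectories that fold "infinitely fast" would be entropically
unrealistic, and $\lambda$ sets how strongly they are penalised.

With control matrix $B = I/\gamma$ and control weight $R = \lambda I$, the
stabilising solution $P$ of the continuous algebraic Riccati equation

$$A^T P + P A - \tfrac{1}{\lambda\gamma^2} P^2 + Q = 0$$

gives the optimal feedback $F^* = -K\,\Delta R$ with
$K = P/(\lambda\gamma)$. Because $A\mathbf{1} = 0$ and
$Q\mathbf{1} = \epsilon\mathbf{1}$, the gain inherits a clean structure:
every row of $K$ sums to $\alpha = \sqrt{\epsilon/\lambda}$, so

$$K = \Gamma^* + \alpha I,$$

where $\Gamma^*$ has zero row sums and is read as an optimally assigned
inter-residue spring-constant matrix, while $\alpha I$ are uniform springs
anchoring each bead directly to its native position — exactly the term that
tames the translation mode. The controller has effectively synthesised the
harmonic potential $U(\Delta R) = \tfrac12 \sum_{c\in\{x,y,z\}}
\Delta R_c^T K \Delta R_c$ (the normalisation $\tfrac12$ is our convention,
chosen so that $-\nabla U = F^*$).

## The iterative loop

A single harmonic well around the native state is a poor global model: the
true landscape is rugged, and contacts form and break during folding. The
pipeline therefore alternates:

1. superpose the current conformation onto the native frame and rebuild
   $Q$ from the *current* contact map — nonnative contacts enter the
   potential for as long as they persist, with no native-only (Gō) filter
   by default;
2. solve the LQR and propagate the closed loop
   $d\Delta R/dt = (A - K/\gamma)\Delta R$, recording `samples_per_traj`
   (default 50) equally spaced frames;
3. pick one frame as the refinement target (scheduling, below);
4. refine toward that target — either the built-in mock refiner or
   exported targeted-MD inputs for an external engine;
5. recompute metrics and loop until the RMSD to native drops below
   `converge_rmsd` or `max_steps` is hit.

Deviations are always taken from the *final* native structure, while the
contact map always comes from the *current* conformation. This asymmetry is
deliberate and is preserved exactly: the target of folding never moves, but
the model of the energy surface is refreshed every cycle.

### Scheduling

Early in folding the closed-loop trajectory moves fast, so targeting its
first frame already gives a useful hop; late in folding consecutive frames
are nearly identical, so the target must be taken from deeper into the
trajectory or refinement would keep returning the same structure. Table
mode encodes this as an explicit step-range lookup
(`default_schedule_table()`: steps 1–4 target frame 1, …, 45–50 target
frame 47, beyond 51 frame 50), sized for 36-residue chains with 50 frames
per trajectory. Adaptive mode operationalises the same rule quantitatively:
the earliest frame at least `delta_min` (default 0.5) away from the current
conformation. The table is the default; the adaptive rule is our
interpretation of "as small as possible but large enough" and is labelled
as such.

### Refinement backends

The package never integrates all-atom molecular dynamics. In `export` mode
it writes, per step, a reference PDB whose C$\alpha$ atoms carry occupancy
1 and the target coordinates (the NAMD targeted-MD convention), a config
fragment with the restraint constant (default 2000) and durations (defaults
0.01 ns TMD + 0.05 ns equilibration), and a manifest naming the artifact it
expects back; `resume_folding()` then continues from the returned
structure. The targeted-MD bias itself is
$U = \frac{k}{2N}(\rho - \rho^*)^2$ with $\rho$ the RMSD *from the native
structure* (not from the target — the target enters through $\rho^*$).

`mock` mode keeps the loop self-contained: the refined structure moves
a fraction `attain_fraction` (default 0.6) of the way to the target and
receives Gaussian jitter of scale `noise_sigma` (default 0.05), emulating
imperfect attainment and the strain-relieving equilibration of a real MD
cycle. Every draw is seeded deterministically from the run seed and the
step number, which is what makes interrupted-and-resumed runs reproduce
uninterrupted ones record-for-record.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `cutoff_q` | 7 | contact cutoff (length units) feeding $Q$; inclusive test, sequence separation $\ge 2$ |
| `cutoff_contacts` | 6.5 | strict cutoff of the native-like contact *metric*, separation $> 2$ |
| `epsilon` | 0.04 | ridge of $Q$; sets the native-anchor stiffness $\alpha=\sqrt{\epsilon/\lambda}$ |
| `lambda` | 1 | control (entropy-loss) penalty; larger values give gentler forces |
| `gamma`, `k_bond` | 1, 1 | friction and covalent spring constant; the CG stage is dimensionless by default |
| `samples_per_traj` | 50 | frames recorded per CG trajectory |
| `converge_rmsd` | 0.5 | stopping threshold (toy units; ~1.5 is a reasonable Å-scale choice) |
| `max_steps` | 200 | folding-step budget |

The two cutoffs coexist on purpose: 7 defines the contacts that shape the
potential, 6.5 with separation $> 2$ defines the reported contact count.
The boundary conventions differ too ($\le$ for the former, $<$ for the
latter); boundary-equal distances are measure-zero in practice.

## Numerical choices

* **Riccati solver.** All matrices here are symmetric, so the package uses
  Newton–Kleinman iteration started from the stabilising $P_0 = \beta I$
  ($\beta = \gamma\sqrt{\lambda\,\max_i Q_{ii}}$), with each Lyapunov step
  solved through the eigendecomposition of the symmetric, stable
  closed-loop matrix. Convergence is quadratic; solves are rejected unless
  the max-abs ARE residual is $\le 10^{-8}$ (typically $10^{-12}$ or
  better). One $n \times n$ solve is shared by x, y and z, since $A$ and
  $Q$ are coordinate-independent — solving a $3n \times 3n$ problem would
  triple the work for an identical answer.
* **Propagation.** Noiseless closed-loop propagation is exact (spectral
  matrix exponential); the `"auto"` horizon runs until the slowest
  closed-loop mode has decayed to 1%. Langevin noise, when requested, uses
  seeded Euler–Maruyama with step `horizon/(100 * samples)`. The default is
  noiseless: the feedback law stays optimal in expectation under white
  noise, but no noise amplitude is part of the standard conditions.
* **Superposition.** RMSD is computed after Kabsch superposition (the
  community convention for folding trajectories), implemented via SVD with
  a determinant sign correction so rank-deficient (collinear or planar)
  conformations are handled exactly; a flag gives the raw unsuperposed RMSD
  used by the targeted-MD $\rho$ bookkeeping.
* **Degenerate inputs.** Repeated eigenvalues are handled by the dense
  symmetric eigensolver with no reliance on eigenvector ordering; a
  conformation already at the native state returns a one-record converged
  trajectory; empty trajectories, mismatched bead counts and non-positive
  parameters are rejected with informative errors.

## What the synthetic generators emulate — and what they do not

`make_extended()` is the geometric stand-in for an unfolded start: a
straight chain at 3.8-unit bond spacing with zero noncovalent contacts.
`make_collapsed()` is the stand-in for a compact native state: a
seed-deterministic self-avoiding walk with exact bond lengths confined to a
sphere of radius $1.2 \cdot 3.8 \cdot n^{1/3}$ (globule scaling), with
nonconsecutive beads kept $\ge 0.9$ bond lengths apart. `make_helix()`
provides ideal $\alpha$-helical geometry (rise 1.5, radius 2.3,
100°/residue) for contact-pattern tests. The standard end-to-end pair is
`make_extended(36)` against `make_collapsed(36, seed = 7)` — 36 beads so
the default schedule table is exercised meaningfully at villin-headpiece
scale.

These fixtures are geometric, not thermodynamic. A passing end-to-end run
shows that the control loop, contact feedback, scheduling and refinement
interact correctly and contract to the target under noise; it does not show
that a real protein's energy landscape is well approximated, which is
precisely the part a real MD engine supplies in export mode.
The mock pseudo-energy column (synthesised harmonic potential plus seeded
jitter) exists so the fluctuation metrics have something to chew on in
self-contained runs; internal energies of real runs must come from the
engine's own log, and the package never computes force-field energies
itself.

## Problem sizes used by the tests

The test suite and the acceptance script run entirely on generated
fixtures: Riccati ensembles over chains of 2–50 beads, oracle comparisons
(modal closed form; backward Riccati ODE) up to 10 beads, 100-structure
contact-count cross-checks, and the standard 36-bead end-to-end run, which
converges in roughly 20 folding steps. These sizes keep a full suite run in
the tens of seconds while covering every code path; nothing in the method
limits it to chains this small, and the solver remains interactive well
beyond hundreds of residues (the ARE solve is $O(n^3)$ per step).

## Known limitations

* The CG stage is linear: anharmonicity enters only through the iterative
  contact-map updates, never within a single LQR solve.
* Folding "steps" are algorithmic cycles, not physical times; no kinetic or
  timescale claims can be made from them.
* The exact scaling of the control-penalty term ($\lambda\|F\|^2$ here) is
  a convention; a reparametrisation $\lambda \to 1/\lambda$ gives the same
  family of solutions.
* Export mode targets C$\alpha$ atoms only; whether to target all heavy
  atoms is left to the user's engine configuration.
* In adaptive scheduling the monotonicity of RMSD-to-frame along the
  trajectory is guaranteed only for noiseless propagation.
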