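---
title: "Numerical methods behind mmcg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Numerical methods behind mmcg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the functional forms, construction rules and
numerical schemes implemented by `mmcg`. Units are nm, ps, kJ/mol, amu and
K throughout; `kB()` returns 0.008314462618 kJ mol⁻¹ K⁻¹.

## 1. Energy decomposition

The hybrid potential is

$$E_{\mathrm{total}} = E_{MM} + E_I + E_{MM/I} + E_{CG} + E_{CG/I} + E_{wall},$$

and the solvent term is realised dynamically as Langevin friction and noise
rather than as a potential. `total_energy()` reports every term separately
and their sum; the per-frame energy table written by `run_simulation()`
carries the same decomposition (`e_mm`, `e_i`, `e_mmi`, `e_cg`, `e_cgi`,
`e_wall`, `e_pot`).

### Atomistic terms ($E_{MM}$, $E_I$, $E_{MM/I}$)

Harmonic bonds $\tfrac12 k (r-r_0)^2$ and angles
$\tfrac12 k (\theta-\theta_0)^2$, periodic dihedrals
$k\,[1+\cos(n\phi-\phi_0)]$, and nonbonded Lennard-Jones 12-6 plus Coulomb
($f = 138.935458$ kJ mol⁻¹ nm e⁻²) terms. Nonbonded interactions use a
plain atom-based cutoff with an *energy shift* so that $V$ is continuous at
the cutoff; 1–2 and 1–3 pairs and all intramolecular water pairs are
excluded. The split into $E_{MM}$, $E_I$ and $E_{MM/I}$ is by the region
membership of the interacting pair.

Because the energy-shifted plain cutoff leaves a force discontinuity, runs
with charged water are not exactly microcanonical; energy-conservation
guarantees are stated for the charge-free Go/wall system (see §6). Water
runs are always thermostatted.

### Go model ($E_{CG}$, $E_{CG/I}$)

One bead per residue at the Cα position. Sequence-adjacent beads:
$\tfrac12 K_b (r - b_{ij})^2$ with $K_b = 1000$ and $b_{ij}$ the *native*
distance. All other pairs with native separation below 1.2 nm form Morse
contacts

$$V(r) = V_0\left[(1 - e^{-B_{ij}(r-b_{ij})})^2 - 1\right],
\qquad V_0 = 5.3\ \mathrm{kJ/mol},$$

whose well depth (dissociated limit minus minimum) is exactly $V_0$ and
whose width follows $B_{ij} = B_{\mathrm{const}} + 6/b_{ij}$
($B_{\mathrm{const}} = 5$ nm⁻¹ for membrane systems, 0 for soluble ones).
The CG/I coupling applies the same bonded term across the CG–I boundary and
Morse contacts between CG beads and interface Cα/Cβ atoms. Since every
equilibrium parameter is measured from the input structure, the native
configuration is a stationary point of $E_{CG} + E_{CG/I}$ — this is
asserted to $10^{-9}$ in the test suite.

## 2. Wall construction

`build_walls()` derives five level sets from the initial structure:

1–2. **Slab faces**: $\varphi_1 = z_{hi} - z$ and $\varphi_2 = z - z_{lo}$,
with the 3.1 nm slab centred on the protein centre of mass.

3–4. **Hemisphere caps**: $\varphi_{3,4} = r_{3,4} - |r - \chi_{3,4}|$,
where $\chi$ is the COM projected onto the corresponding slab face and the
radius is the largest distance from $\chi$ to any protein atom outside the
slab plus a 2.0 nm water margin. A structure that never leaves the slab
cannot define the caps and is rejected.

5. **Membrane surface**: $\varphi_5 = r_p - \mathrm{softmin}_j |r - c_j|$
over the initial Cα positions $c_j$, with
$\mathrm{softmin}(d) = -\beta^{-1}\log\sum_j e^{-\beta d_j}$, $\beta = 50$
nm⁻¹ and $r_p = 0.2$ nm. The softmin makes $\varphi_5$ smooth, bounded
between $\min d - \log(n)/\beta$ and $\min d$, and converging to the hard
minimum as $\beta \to \infty$.

Walls are *gated*: the planar walls act inside the membrane-radius
cylinder, cap 3 (4) acts above (below) the slab, and $\varphi_5$ acts
inside the slab, so each particle sees the wall relevant to its position
and `wall_distance()` returns the gated minimum (with a brute-force oracle
test). Two coupling modes exist: water atoms couple to the gated minimum
over all walls; protein Cα atoms couple to $\varphi_5$ only (they anchor
the membrane surface and start exactly at its minimum $d = r_p$). Aromatic
(TRP/TYR) side-chain atoms couple to $\varphi_5$ only if they start inside
its attractive zone.

## 3. Wall potentials, shifting and capping

With $d$ the level-set value:

* **Repulsive planar walls (1–2)**:
  $V(d) = \varepsilon (\sigma/d)^6$, energy-shifted and force-shifted so
  that both $V$ and $F$ go to zero continuously at $d_{\mathrm{rep}} = 0.7$
  nm, beyond which the term is *identically* zero (compact support).
* **Attractive walls (3–5)**: a softened Lennard-Jones
  $V(d) = 4\varepsilon\left[x^{12} - x^{6}\right]$, $x = \sigma'/(d+\Delta)$
  with $\Delta = (r_p - 2^{1/6}\sigma)/(2^{1/6}-1)$ and
  $\sigma' = \sigma + \Delta$, which places the minimum exactly at
  $d = r_p$ with depth $\varepsilon$ and the zero at $d = \sigma$. The term
  is shifted and cut at $1.5\,r_p$.
* **Force cap**: the applied scalar force is clamped at
  $F_{\max} = 1000$ kJ mol⁻¹ nm⁻¹; for $d \le 0$ the force is exactly
  $F_{\max}$, so penetrating particles are pushed back with a finite,
  constant force. The cap onset is found in closed form for the repulsive
  branch and by bisection for the attractive one.

Two energy flavours are kept deliberately: `wall_potential()` is the
energy-shifted potential (used for reporting and for locating the minimum),
while dynamics accounts `e_wall` with the exact antiderivative of the
*applied* (force-shifted, capped) force — linear with slope $F_{\max}$
inside the cap region and zero at the cutoff. Using the antiderivative
makes the reported total energy a true first integral of the equations of
motion, which is what the NVE drift test measures.

## 4. Stochastic dynamics

`run_simulation()` integrates Langevin dynamics with the OBABO splitting of
velocity Verlet: a friction/noise half-step ($v \leftarrow a v +
\sqrt{(1-a^2) k_B T/m}\,\xi$, $a = e^{-\Delta t/2\tau}$), a velocity
half-kick, a full position drift with SHAKE, the second half-kick, and the
closing friction/noise half-step. For a free particle the velocity decays
as $e^{-t/\tau}$ *exactly*, which the tests verify to $10^{-10}$. Setting
`tau = 0` disables friction and noise and yields symplectic NVE dynamics.

Constraints (rigid SPC water: O–H 0.1 nm, H–H 0.16330 nm) are enforced by
SHAKE after the position update and by RATTLE velocity projection after
velocity changes, so constrained bond lengths drift by less than $10^{-5}$
relative over thermostatted runs. The kinetic temperature uses
$N_{dof} = 3N - N_{\mathrm{constraints}}$ (minus 3 more for the conserved
COM momentum when friction is off).

Nonbonded forces use a Verlet neighbour list with skin, rebuilt when any
atom moves half the skin; the test suite checks the listed dynamics against
a fresh exact pair list to $10^{-9}$. All randomness flows from the single
`seed` in `mmcg_config`, making trajectories bitwise reproducible.

A steepest-descent minimiser (`minimize_sd()`) relaxes initial contacts
before dynamics; plain-text checkpoints (`save_checkpoint()` /
`load_checkpoint()`) restart runs exactly.

## 5. Analysis

* `kabsch()` — SVD superposition with the proper-rotation correction.
* `rmsd()` / `rmsf()` — per-frame deviation and per-residue fluctuation
  after optional fitting (RMSF fits to the iterated mean structure).
* `vacf()` — normalised velocity autocorrelation
  $C(t) = \langle v(0)\cdot v(t)\rangle / \langle v^2\rangle$ averaged over
  atoms and time origins, with the decorrelation time defined as the first
  lag where $|C(t)|$ drops below a configurable threshold (default 0.05),
  linearly interpolated.
* `rdf_oo()` — water O–O radial distribution function normalised with the
  accessible droplet volume, which `mc_region_volume()` estimates by Monte
  Carlo integration of the positive-$\varphi$ region (the droplet is not
  periodic). For a bounded region the ideal-gas $g(r)$ itself falls below 1
  at large $r$; comparisons should use a matched ideal-gas reference.
* `pair_distances()` — atom–atom distance time series.

## 6. Validation summary

The test suite (`tests/testthat/`) asserts, among ~300 checks: analytic
forces equal finite differences of every energy term to $10^{-5}$ relative;
NVE total-energy drift below $10^{-4}$ over 10 ps at a 0.5 fs step on the
charge-free hybrid system with walls active; thermostat accuracy at 300 K;
SHAKE drift below $10^{-5}$; zero wall-energy support outside the stated
cutoffs (exact); the force cap exact at contact; containment of all waters
in the positive level-set region over dynamics; stationarity of the native
Go configuration; lower CG-region than MM-region RMSF in hybrid runs; and
bitwise reproducibility for equal seeds. `scripts/acceptance.R` recomputes
the headline constants (Morse depth, wall minimum location, compact-support
boundary, hemisphere margin, water VACF decorrelation) from scratch.
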