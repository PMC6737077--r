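---
title: "Electrostatically steered ligand association: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrostatically steered ligand association: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A charged ligand approaching a charged receptor from tens of Angstroms away
is guided almost entirely by long-range electrostatics through water and
salt. Implicit-solvent MD engines truncate exactly this interaction: with
the customary 16--18 A switching cutoffs (applied both to pairwise terms and
to the effective-Born-radius sums of Generalized-Born models), a ligand
placed 60 A out feels *nothing* and diffuses aimlessly. `pbsteer`
implements the complementary protocol: a finite-difference
Poisson--Boltzmann (PB) solver supplies the missing long-range forces on
every ligand atom, those forces are rescaled into a window an MD engine can
act on, and a Langevin dynamics engine advances the ligand with the
steering force held constant for a cycle (500 steps by default) before the
field is re-solved at the new pose.

# The electrostatic model

The solver discretizes the linearized PB equation

$$\nabla\cdot\big(\varepsilon(\mathbf r)\,\nabla\varphi\big)
  - \varepsilon_s\,\kappa^2(\mathbf r)\,\varphi = -4\pi C \rho$$

on a uniform cubic lattice with the 7-point stencil, where $C =
332.0636$ kcal A/(mol e$^2$), so that $\varphi$ is in kcal/(mol e) and
$-q\nabla\varphi$ is directly a steering force in kcal/mol/A. Modelling
choices, all standard for this class of solver:

* **Two-dielectric model.** The solute interior (union of atomic vdW
  spheres; $\varepsilon_\text{in}=2$) is carved into edge-centred
  dielectric maps; everything else is solvent ($\varepsilon_s=80$). A
  probe-traced molecular surface is deliberately not used: at the
  separations where steering matters the forces are insensitive to the
  fine dielectric boundary, and the vdW union keeps the map construction
  exactly testable.
* **Salt.** A 1:1 ion atmosphere at 0.15 M enters through
  $\kappa^2$ (Debye), zeroed inside the solute plus a 2 A Stern layer.
  The Stern thickness is a convention, not a measurement; it is exposed in
  `solverConfig()`.
* **Sources.** Receptor partial charges are spread to the eight
  surrounding nodes with trilinear weights. The ligand enters the solve
  *uncharged*: it contributes its cavity shape only, so the solved field
  is the receptor's field in the presence of the ligand body, and
  multiplying by the known ligand charges afterwards gives the force
  without self-interaction artifacts.
* **Boundary condition.** Each boundary node is set to the sum of
  per-source-atom screened-Coulomb (Debye--Hueckel) potentials. This
  "Coulombic" condition is accurate for off-centre probes at long range,
  where a monopole approximation would bias the force direction.
* **Grid sizing.** The cubic box edge is the maximal solute extent divided
  by perfil/100 (default 70), with spacing 1/scale; dimensions are forced
  odd so the centre is a node. The default 2 grids/A reproduces the
  conventional ~300^3 mesh for a 105 A system; production force runs in
  this package use 0.5--1 grids/A, which the refinement tests show changes
  long-range forces by under a few percent.
* **Relaxation.** Red--black SOR ($\omega = 1.8$) iterated until the max
  per-sweep change falls below 1e-4 kcal/(mol e) (default; chosen so force
  errors are well below the 0.01 kcal/mol/A steering floor). Checkerboard
  ordering makes each half-sweep order-independent, which is why the
  mirror-symmetry test can demand agreement at rounding level.

The solver is validated against closed forms: Coulomb's law in uniform
dielectric (within 5% for probe distances of 5 A to a third of the box) and
the Yukawa-screened potential at 0.15 M (within 7%), plus exactness
properties (superposition, mirror symmetry, monotone screening).

# Steering forces and the force window

Forces are the negative gradient of the trilinearly interpolated potential,
evaluated by central differences with step = spacing/2 (differentiating the
interpolant analytically would inherit node-level noise; the half-spacing
step smooths it). Two window rules then apply, preserving every force
direction exactly:

* if the maximum per-atom magnitude $F_\max$ is below $F_\text{lower}$
  (default 0.01 kcal/mol/A, i.e. ~0.7 pN -- the conventional smallest
  steering force an MD engine registers), all forces are multiplied by
  $F_\text{lower}/F_\max$;
* if $F_\max$ exceeds $F_\text{upper}$ (default 10 kcal/mol/A, the scale at
  which constant-force overshoot starts causing clashes), all are
  multiplied by $F_\text{upper}/F_\max$.

A identically-zero field cannot be normalized; the rule is skipped with a
warning. Rescaling is idempotent and direction-preserving by construction,
and both properties are tested.

# The Generalized-Born comparison arm

`gbForces()` implements the simplest standard GB: HCT pairwise-descreening
Born radii and Still's interaction function, plus direct Coulomb
($\varepsilon=1$) inside the cutoff, all switched smoothly to zero between
16 and 18 A. Design notes:

* The descreening sum is *switched with the same function* as the pair
  terms rather than hard-truncated, so energy and force are continuous at
  the cutoff (tested to 1e-8) while the model remains strictly blind
  beyond it -- which is the point: the cutoff-blindness is the artifact
  the PB arm exposes.
* Forces are fully analytic, including the chain rule through the Born
  radii, and are verified against central-difference energy derivatives to
  1e-4 kcal/mol/A on random systems.
* The GB flavour is not load-bearing: any standard flavour shows the same
  cutoff behaviour. HCT+Still was chosen as the simplest to verify against
  a quadrature oracle.
* The "scaled" steering mode computes steering = PB force − GB force.
  The protocol's correction of steering forces "for the forces calculated
  via GB" is not spelled out as a formula anywhere we could follow; the
  difference is the interpretation that exactly cancels the double count
  when the local model is GB-like.

The two-ion toy system makes the contrast concrete: a +1 e source and a
+1 e receiver 60 A apart, with a neutral low-dielectric body either midway
between them (20 A from each ion, outside every 18 A cutoff) or displaced
far off-axis. PB forces on the receiver differ by well over 20% between the
two placements; GB forces are identical (zero, in fact -- the ions are
beyond each other's cutoff). The supplementary material this re-creates is
available only as a description, not as numbers, so the comparison is
encoded as inequalities rather than magnitudes.

# The dynamics engine

The ligand is flexible (harmonic bonds k = 100 kcal/mol/A^2, harmonic
angles k = 10 kcal/mol/rad^2 about 180 deg), the receptor rigid. Ligand and
receptor beads repel through a WCA (truncated-shifted Lennard-Jones)
potential, and inside the 18 A cutoff the engine carries the native
electrostatics an implicit-solvent MD engine would: direct Coulomb
($\varepsilon=1$) plus the Still GB polarization term, switched at
16--18 A, with HCT Born radii recomputed once per steering cycle and held
fixed inside it (consistent with the constant-force-per-cycle convention;
at bead scale the radii change negligibly within a cycle). At long range
this term reduces to $\sim q_iq_j/(\varepsilon_s r)$; at contact it is
several-fold stronger than solvent-screened Coulomb, which is what makes a
bound pose thermally stable -- and it is exactly the model whose
truncation artifact the steering corrects. The local term is on in
**every** mode: steering is added *on top* of the engine's own force
field, which is precisely why the scaled mode exists (to remove the double
count). The unsteered control in the capture experiment removes the
electrostatic guidance entirely (both the steering and its short-range
tail), isolating what guidance contributes over excluded-volume diffusion.

Integration is BAOAB-discretized underdamped Langevin dynamics at 300 K.
BAOAB was picked for its configurational accuracy at large timesteps; its
RNG (splitmix64-seeded xoshiro256++ with Box--Muller normals) is
implemented in the package so trajectories are bit-reproducible from the
seed across platforms and compilers. Thermostat calibration is tested
against closed forms: harmonic-well variance $k_BT/k$ within 5% and the
free-particle Einstein relation MSD $= 6k_BT t/(m\gamma)$ within 10%.

The steering loop solves the PB problem once per cycle (default 500 steps,
i.e. re-solving every 1--2.5 ps) and holds the force constant in between,
matching constant-pulling-force steering conventions. The ligand cavity is
re-carved at each new pose by default (`freezeCavity` disables this; the
protocol description leaves open whether the cavity or only the forces are
refreshed, and re-carving is the physically consistent choice). With a
rigid receptor the receptor maps and the boundary condition are built once
and cached; only the small ligand cavity is re-carved, and the previous
potential is the SOR initial guess, which cuts a cycle's solve to a few
sweeps. In mode "cutoff" the gate re-opens if the ligand diffuses back out
beyond the cutoff; the symmetric rule is the less surprising one and every
gate decision is logged in the per-cycle event table.

If the ligand diffuses outside the solved box, the cycle's steering force
falls back to the analytic Debye--Hueckel gradient of the receptor charges
-- outside the box that expression *is* the boundary condition the grid
was solved against, so the fallback is seamless, and the event log records
which source supplied each cycle's force.

# The synthetic systems

Fixtures are bead-level, not atomistic: the steering physics under test is
monopole-driven and scale-free, and beads keep PB grids desk-sized.

* **Funnel receptor** (default 60 beads, net −10 e): a spherical shell of
  neutral beads with an open 60 deg mouth cone and a recessed ring of six
  charged beads. The negative charge buried in a low-dielectric shell with
  a single aperture is the minimal geometry that produces an
  electrostatic funnel through the mouth. −10 e was chosen once as strong
  enough to steer a +3 e ligand from 60 A on a coarse desk-scale grid.
  The annotated pocket centre is the centroid of the charged pocket
  beads -- the binding site is where its charges are.
* **Ligands**: a 7-bead chain, bond length 1.5 A, bead mass 20.75 amu
  (one seventh of spermidine's 145 amu). The spermidine-like default puts
  +1 e on beads 1, 4 and 7 (net +3 e); the AdoMet-like variant carries a
  single +1 e; a neutral variant serves as a control.
* **Two-ion system**: described above.

What the fixtures do *not* emulate: atomistic shape complementarity,
desolvation barriers, rotamer entropy, or any chemistry of real
polyamines. A passing capture test shows the steering loop turns a correct
long-range field into reliable pocket finding at desk scale; it says
nothing about binding poses of real ligands.

# The capture experiment

Ten independent runs place the spermidine-like ligand 60 A from the
receptor centre along the mouth axis with a random seeded orientation, and
count a run as captured when the final ligand-centre to pocket-centre
distance is below 5 A (echoing the usual 5 A RMSD binding-success
criterion). Protocol choices, fixed before the replicate experiment was
run and stated here as the package's own:

* grid scale 0.5 grids/A (the refinement tests justify coarse grids for
  long-range forces), SOR tolerance 1e-3 for per-cycle solves;
* timestep 5 fs -- a 137 fs bond period gives ~27 steps per period, well
  inside BAOAB's stability margin for this toy force field;
* Langevin damping 0.5 ps^-1: the damping coefficient is the knob that
  controls effective diffusion, and light damping shortens the diffusive
  approach without changing the steering physics;
* steering window (0.01, 1) kcal/mol/A: the lower bound is the standard
  floor; the upper bound is tightened below the conventional 10 because a
  constant 10 kcal/mol/A per-atom force held for 500 steps slams a
  20 amu bead into the repulsive wall -- window ranges are explicitly a
  per-study choice in steered protocols, and (0.01, 1) is this study's;
* 320,000 steps (1.6 ns) per run: the drift speed under the window floor
  (~0.17 A/ps for the +3 e chain) covers the 60 A approach in ~350 ps, but
  the approach is a biased random walk, and the run must be several times
  the mean first-passage time for capture counts to reflect steering
  efficacy rather than truncation of unfinished walks.

The unsteered arm runs the identical protocol with all electrostatic
guidance off. Expected behaviour, which the acceptance tests assert: at
least 8/10 steered runs end captured; at most 1/10 unsteered runs do.

# Titration fitting

The single-site quadratic isotherm gives the bound-protein concentration

$$P_b = \tfrac12\Big[(K_d + P_t + L_t) - \sqrt{(K_d + P_t + L_t)^2
      - 4 P_t L_t}\Big],$$

the physical root, clamped to $[0, \min(P_t, L_t)]$ against floating-point
underflow, and the corrected fluorescence is $F_c = f_p(P_t - P_b) +
f_{pb}P_b$. The fitter runs nonlinear least squares over
$(\log_{10}K_d, f_p, f_{pb})$ -- the log parameterization enforces
positivity and handles the decade-scale dynamic range -- with a multi-start
over $K_d$ decades around $P_t$ when no guess is supplied, per-replicate
fluorescence coefficients with a shared $K_d$ (titrations are typically
measured in at least three repeats), and standard errors from the
Gauss--Newton curvature. The synthetic generator adds multiplicative
Gaussian noise, the natural first model for fluorescence readings; the
inner-filter correction is an experimental step upstream of this package,
which consumes already-corrected $F_c$. Recovery is tested noiselessly
(0.1%), under 2% noise (10%, median of 20 seeds), and for a planted 5x
apparent-$K_d$ shift -- the readout by which competitive inhibition is
read from titrations.

# Numerical edge cases and limitations

* Nonlinear PB, focusing/multigrid, membrane slabs and periodic
  electrostatics are out of scope; so is receptor flexibility.
* The linearized equation is accurate in the weak-field long-range regime
  the protocol targets; potentials inside the charged pocket are outside
  that regime and are used only qualitatively (funnel-ness checks).
* Charges closer than one spacing to the box face cannot be spread
  (error); force interpolation requires atoms 2 spacings inside.
* The HCT descreening integral is evaluated in closed form including the
  enclosing-neighbour branch; identical atom positions are rejected.
* `fitKd` on a constant-fluorescence series has no information about
  $K_d$ and errors out rather than returning an arbitrary number.
* Problem sizes throughout the test-suite (65^3--107^3 grids, 10 x 160k-step
  capture runs, 20-seed Monte-Carlo recoveries) were chosen as the
  smallest at which each check is physically meaningful.
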