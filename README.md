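# bivmech — biventricular cardiac mechanics on idealized geometries

`bivmech` is an R package for quasi-static finite-element simulation and
passive personalisation of biventricular heart mechanics, aimed at
researchers building image-driven ("digital twin") cardiac models. It
implements the full modelling chain that in a clinical pipeline sits
between segmented cine-MR images and reported biomechanical parameters:

* **Constitutive laws** — the reduced Holzapfel–Ogden passive model
  P<sub>p</sub> = a₀ e^{b₀(Ī₁−3)} J^{−2/3}(F − I₁/3 F^{−T}) +
  2a_f (I_f−1)₊ e^{b_f(I_f−1)₊²} f⊗f₀ in a nearly-incompressible u/p
  framework (P<sub>vol</sub> = p J F^{−T}, bulk equation
  K[(J−1)+k ln J] = p), chamber-wise active stress
  (α_lv φ + α_rv(1−φ)) tanh(2(I_f−0.8)₊)(f⊗f₀ + F/3), and an exponential
  valve-annulus collagen stress resisting ring dilation.
* **FE solver** — P1/P1 tetrahedral displacement/pressure elements with
  follower pressure loads, truncated cavity-volume constraints and
  valve-ring motion constraints enforced by Lagrange multipliers. Three
  modes: passive inflation (chamber pressures as multipliers), the active
  cycle (activations α_lv(t), α_rv(t) as multipliers making the model
  follow measured volume traces at prescribed pressures), and a forward
  mode for twin experiments.
* **Rule-based fibres** — Laplace–Dirichlet transmural and apex-base
  coordinates, helix angles −60°→+60° (LV and septum) and −25°→+90° (RV)
  from epicardium to endocardium, with configurable valve-ring angles.
* **Personalisation** — the anisotropy ratio γ = a₀/a_f by sweeping γ over
  1.0…0.1 under fixed end-diastolic volumes and minimising the RMS
  point-to-surface distance to end-diastolic contours, then scaling to
  absolute stiffnesses with sample-size-weighted literature pressures:
  a_f = a_f^sim · EDP_g / p^ED_sim, a₀ = γ a_f.
* **Image QC** — connected-component filtering (strict <50 px), hole
  filling, dice-based slice rejection along slice intersection lines,
  landmark outlier repair with zero-phase periodic smoothing, contour
  extraction with the 3 mm RV-epicardial offset.
* **Reporting** — cavity volumes, ejection fraction, wall thickness,
  17/16-segment AHA division, fibre stretch and active fibre stress
  traces, group statistics.
* **Synthetic study conditions** — an idealized two-ellipsoid biventricular
  mesh generator (healthy / dilated / hypertrophic presets at the
  end-systolic reference), physiologically shaped volume/pressure/
  valve-motion traces warped to the cycle events, and corrupted label
  image / landmark fixtures with recorded ground truth, so the entire
  pipeline runs and is testable without patient data.

## Worked example

```r
library(bivmech)

# literature-based group pressures (sample-size-weighted means)
hcm <- assign_group_pressures("hcm")
# HCM group pressures: EDP 24.2 mmHg (3.2 kPa), ESP 183.1 mmHg (24.4 kPa)

# idealized biventricle at the end-systolic reference + rule-based fibres
mesh <- generate_idealised_biventricle("healthy", h = 5)
# biv_mesh: 1738 nodes, 4953 tets, 3548 boundary facets
fib <- fibre_field(mesh)
surface_helix_angle(mesh, fib, "epi")$mean_deg
# mean LV free-wall epicardial helix angle: -60.0 deg (n = 243)
cavity_volume(mesh, chamber = "lv")
# LV cavity volume: 70.9 mL (analytic truncated-ellipsoid value 72.0 mL)

# passive inflation of both chambers to +15% volume: the chamber pressures
# are the Lagrange multipliers of the cavity-volume constraints
prob <- fe_problem(mesh, fib, material_params(a0 = 0.5, af = 1))
V0 <- c(lv = cavity_volume(prob, chamber = "lv"),
        rv = cavity_volume(prob, chamber = "rv"))
infl <- solve_diastolic_inflation(prob, V_target = as.list(1.15 * V0))
infl$P
# simulated pressures at +15% volume: LV 0.09 kPa, RV 0.05 kPa
```

The simulated end-diastolic pressure is what the personalisation step
scales against the assigned group pressure to obtain absolute stiffnesses
(`sweep_gamma()`, `scale_parameters()`); `solve_active_cycle()` then
recovers the activation traces over the cycle. A thin command-line front
end over these functions (subcommands `synth`, `qc`, `inflate`, `cycle`,
`personalise`, `metrics`) ships in `inst/cli/bivmech.R`.

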