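---
title: "Modelling foliar uptake of a deliquescent ionic solute through isolated cuticles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling foliar uptake of a deliquescent ionic solute through isolated cuticles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuticleflux)
```

## The problem

Hydrophilic ionic agrochemicals — calcium chloride is the canonical example —
cannot dissolve in the waxy matrix of the plant cuticle.  Their only route
into the leaf is through *aqueous pores*: nanometre-scale, water-filled
pathways that form and swell when the cuticle is hydrated.  Uptake from a
spray droplet sitting on the cuticle surface is therefore controlled by an
unusually entangled set of mechanisms:

* **Evaporation.** A sessile droplet on a partially wetting surface loses
  water first with a pinned contact line (shrinking contact angle, constant
  contact radius — "CCR" mode), then, once the angle reaches its receding
  value, with a constant angle and a shrinking radius ("CCA" mode).  As the
  footprint shrinks, fewer pores sit under the droplet.
* **Deliquescence.** An ionic solution above its point of deliquescence
  (POD) pulls water out of humid air.  For CaCl2 (POD 32 %RH) at field
  humidities this hygroscopic absorption nearly balances evaporation and
  keeps a concentrated brine film on the surface for hours after a plain
  water droplet would have vanished.
* **Surfactants.** An adjuvant such as the ethoxylated rapeseed-oil
  surfactant RSO 5 flattens the droplet (larger footprint, more pores
  underneath) and shifts the POD of the solution, extending water
  absorption to lower humidities.
* **Pore swelling.** Water adsorbs as a monolayer to the pore walls; the
  adsorbed density sets the open pore radius, the radius sets the areal
  porosity, and porosity (with tortuosity) sets the effective diffusivity
  of both solute and water.
* **Ion binding.** A fraction of the ions is irreversibly trapped at the
  cuticle surface, capping total penetration below 100 %.

`cuticleflux` couples all of these in one quasi-one-dimensional mechanistic
model and reproduces penetration experiments on isolated astomatous tomato
fruit cuticles, where droplets of known concentration are applied to the
outer surface and the receiver bath below the inner surface is assayed over
48 h.

## Model structure

### Transport through the cuticle

Solute and water concentrations $c_{AI}(x,t)$, $c_{H_2O}(x,t)$ are defined
on $0 \le x \le b$ ($x = 0$ the droplet surface, $x = b$ the bath;
$b = 18.7\,\mu m$).  Both obey nonlinear diffusion in conserved form,

$$\frac{\partial(\varepsilon c_i)}{\partial t} =
  \frac{\partial}{\partial x}\!\left[D_i
  \frac{\partial(\varepsilon c_i)}{\partial x}\right],$$

with the water equation carrying an additional sink
$-\tfrac{2}{r_p}(1-\varepsilon)\,\partial\Gamma/\partial t$ for monolayer
adsorption to the pore walls.  The local closure chain is: a Langmuir
isotherm $\Gamma(c_{H_2O}) = \Gamma_S \beta c / (1 + \beta c)$; a geometric
relation $r_p(\Gamma) = r_{H_2O}\,[1 + 1/\sin(1/(\Gamma r_{H_2O}^2 N_A))]$
whose saturation value is exactly the maximum pore radius
($\Gamma_S = 9.6832\times10^{-4}\,mol/m^2$ gives $r_p = 2.12\,nm$); areal
porosity $\varepsilon = (n_0+1)\pi r_p^2/L^2$ with $n_0 = \eta_{pore}L^2$
evenly distributed circular pores; and a fractal-tortuosity diffusivity
$D_i = D_i^{bulk}\,\varepsilon^{F_s/(2-F_s)}$, which degenerates to the
classical $\varepsilon$-scaling as $F_s \to 1$.

Boundary conditions: the bath is well stirred ($c_{AI}(b,t)=0$,
$c_{H_2O}(b,t)$ pure water); at the droplet the water concentration is
displaced by the dissolved solute's partial molar volume,
$c_{H_2O}(0,t) = (1 - \bar v_{AI} c_{AI}(0,t))/\bar v_{H_2O}$, and the
solute boundary value is the droplet concentration itself, governed by the
surface balance below.

### The droplet

During CCR mode ($t \le t_{rec}$) the contact angle and volume follow the
quasi-steady diffusion-limited evaporation model for a pinned spherical
cap,

$$\frac{d\theta}{dt} = -\frac{\Lambda (1+\cos\theta)^2 f(\theta)}{r_{drop,0}^2},
\qquad
\frac{dV}{dt} = -\pi \Lambda r_{drop,0} f(\theta),$$

where $f(\theta)$ is the angular evaporation kernel (a semi-infinite
integral with closed forms $f\to 4/\pi$ at $0$ and $f(\pi/2)=2$) and
$\Lambda = D_{evap}\psi/\rho_{H_2O}$ with
$\psi = M_{w,H_2O}P_v(1-H)/(RT)$ the vapour concentration deficit.  The
receding angle is a fixed 12.64 % reduction of the initial angle; initial
angles are back-calculated from measured droplet footprint areas by
inverting the spherical-cap relation
$A = \pi^{1/3}(3\,g(\theta)V)^{2/3}$.

During CCA mode, above the POD the bare evaporation rate is modulated by a
logistic deliquescence factor and a crystallisation cap:

$$\frac{dV}{dt} = -\pi\Lambda f(\theta_{rec})
  \left(\frac{3 g(\theta_{rec}) V}{\pi}\right)^{1/3}
  \left[\frac{\bar\chi}{V_0}V\left(\frac{V}{V_{Del}}-1\right)\right]
  \left(1-\frac{c_{AI}(0,t)}{c_{POD}}\right) + W(t),$$

where $V_{Del} = m_\infty(\Phi)\,M_{w,AI}\,c_{AI}(0,t)\,V/\rho_{H_2O}$ is
the deliquescent volume (the equilibrium water content of the brine; note
it depends only on the *moles* of solute in the drop), $\bar\chi = \chi
c_{AI,0}^2$ (with $c_{AI,0}$ in g/L), $c_{POD}$ the saturation
concentration at the shifted humidity, and $W(t)$ a small diffusive
water-exchange term with the cuticle surface that closes the water
balance.  Evaporation stalls as $V \to V_{Del}$ and reverses (absorption)
below it.  Below the POD the logistic and cap factors are absent.

The empirical deliquescence inputs for CaCl2 are two-exponential fits to
published moisture-absorption data: the saturated solution weight percent
$c_{mass\%}(\Phi) = -0.8307 e^{3.618\Phi} + 55.44 e^{-0.612\Phi}$ and the
equilibrium water-to-solute mass ratio
$m_\infty(\Phi) = 0.307 e^{2.763\Phi} + 1.218\times10^{-9} e^{24\Phi}$
(14 g/g at 95 %RH).  Both are evaluated at the shifted humidity
$\Phi = \min(H + \xi,\ 0.97)$ when $H + \xi$ exceeds the solute POD; the
adjuvant shift $\xi$ (5 %RH for RSO 5) is an assumption exposed as a plain
configuration parameter, and a `hygro_material` object lets a different
salt supply its own $(POD, c_{mass\%}, m_\infty)$ triple.

Solute in the droplet obeys

$$\frac{d}{dt}\bigl(V c_{AI}(0,t)\bigr) = -k\,c_{AI}(0,t) +
  \eta_{pore} A_{drop}(t) A_\Pi \left[D_{AI}
  \frac{\partial(\varepsilon c_{AI})}{\partial x}\right]_{x=0},$$

with irreversible first-order ion binding ($k$) and the pore-weighted
diffusive exchange with the cuticle.  Penetration is the time integral of
the bath-face flux weighted by the same factor
$\eta_{pore}A_{drop}(t)A_\Pi$, converted to micrograms and to percent of
the applied mass.

### Parameters that matter

| symbol | meaning | default | unit |
|---|---|---|---|
| `b` | cuticle thickness | 1.87e-5 | m |
| `r_p_max` | maximum pore radius (tomato fruit) | 2.12e-9 | m |
| `gamma` | initial pore radius / maximum | 0.97 | — |
| `eta_pore` | pore density (fitted) | 2.18e15 | m^-2 |
| `F_s` | fractal tortuosity dimension (fitted) | 1.203 | — |
| `k` | ion-binding rate (fitted) | 8.68e-16 | m^3/s |
| `chi` | logistic evaporation constant (fitted) | 0.043 | L^2/g^2 |
| `xi` | POD shift from RSO 5 | 0.05 | RH fraction |
| `H` | relative humidity | 0.70 | fraction |
| `V_0` | droplet volume | 1e-9 | m^3 |
| `theta_0` | initial contact angle | per measured footprint | rad |

The four fitted constants were calibrated against penetration curves at
1–30 g/L with and without surfactant; one shared set serves all ten
scenarios.  An alternative set (`preset = "cacl2_rso5_alt"`: `F_s` 1.138,
`k` 3.74e-15, `eta_pore` 1.99e15, `chi` 0.0023) improves the
surfactant-only fit at the highest applied mass but degrades the joint
fit, so it is not the default.

## Numerical formulation

**Spatial discretisation.** Node-centred finite volumes, uniform grid,
`N_x = 100` cells by default; second-order central differences on the
conserved variable $q_i = \varepsilon c_i$, arithmetic averaging of the
diffusivity at cell faces, Dirichlet values imposed through boundary faces
at half-cell distance.  With frozen coefficients the scheme annihilates
the linear steady profile to round-off, which the test suite asserts at
1e-10.

**Time integration.** Rather than a DAE residual form, the adsorption
sink is folded into a chain-rule capacity: with every local quantity a
function of $c_{H_2O}$,
$$C(c_{H_2O})\frac{\partial c_{H_2O}}{\partial t} =
  \text{flux divergence}, \qquad
C = \varepsilon + c_{H_2O}\frac{d\varepsilon}{dc_{H_2O}}
  + \frac{2}{r_p}(1-\varepsilon)\frac{d\Gamma}{dc_{H_2O}},$$
while the solute equation is integrated directly in conserved form.  The
state vector (droplet volume, angle, drop solute moles, three inventory
quadratures, and the two fields) is nondimensionalised to order one so
uniform tolerances (`rtol = 1e-8`, `atol = 1e-12`) are meaningful.  The
stiff coupled system is solved monolithically with `deSolve::lsodar`;
stage transitions (CCR→CCA at $\theta = \theta_{rec}$; droplet dry-out;
solute exhaustion; crystallisation) are located by root functions, and the
angle event is cross-checked against the independent quadrature
$t_{rec} = \int_{\theta_{rec}}^{\theta_0} r_{drop,0}^2 /
[\Lambda(1+\cos\theta)^2 f(\theta)]\,d\theta$ (they agree to 0.1 %).
After the droplet is gone the cuticle interior continues to relax to
`t_final` with a BDF integrator (`deSolve::vode`; the lsoda family's
method-switching interpolation misbehaves on the near-steady tail).

**Evaporation kernel.** $f(\theta)$ is evaluated by adaptive quadrature on
a numerically stable exponential form of the integrand (the naive
$\cosh^2$/$\operatorname{csch}$ product overflows), validated against the
two closed-form limits and a brute-force truncated-domain oracle, then
tabulated on a 0.1° grid with cubic-spline interpolation for use inside
the ODE right-hand side (interpolation error below 1e-6).  The kernel is
validated for contact angles up to 150°; calls beyond that warn.

**Mass audit.** The cuticle and bath solute inventories are integrated as
quadrature states with the same footprint weighting
$S(t) = \eta_{pore}A_{drop}(t)A_\Pi$ applied to both boundary fluxes, so
applied = drop + bound + cuticle + bath holds to integrator accuracy
(observed ~1e-15 relative) at every output time; an independent
trapezoidal quadrature of the stored bath-flux series
(`penetration_mass()`) reproduces the integrated mass on the output grid.

**Numerical guards and tie-breaks.**
$V_{Del}$ is floored at 1e-18 m^3 (its natural limit as the solute is
depleted is zero, where the logistic bracket would divide by zero); the
droplet is declared dry when its volume or solute content falls below
1e-6 of the initial value; below the POD, where no crystallisation cap
exists in the evaporation law, integration stops when the droplet
concentration reaches the saturation concentration at the POD
(≈ 8355 mol/m^3 for CaCl2) — the point where the brine solidifies.  With
the default scenario this stop differs from a bare volume-zero stop by
seconds.  Penetration accrual uses the droplet footprint weighting, so
penetration ceases at droplet death, matching the observed plateaus.

### Open choices made here

* **Porosity reading.** The porosity expression is taken as the areal
  pore fraction $(n_0+1)\pi r_p^2/L^2 \approx \eta_{pore}\pi r_p^2$
  (≈ 0.029 initially), the only dimensionally consistent reading of the
  evenly-distributed-circular-pores picture.  The function is pluggable.
* **Control-volume area.** $A_\Pi$ defaults to $L^2/(n_0+1) \approx
  1/\eta_{pore}$, so the flux weight $\eta_{pore}A_{drop}A_\Pi \approx
  A_{drop}$: porosity-weighted transport through the whole droplet
  footprint, independent of the arbitrary control-volume size.  It is
  configurable.
* **Langmuir parameter.** $\beta_{H_2O}$ is computed at startup from the
  initial condition (isotherm at pure water must return the adsorbed
  density of a pore at $\gamma\,r_{p max}$), giving 5.3987e-4 m^3/mol;
  the alternative tabulated value 3.77e-5 is inconsistent with
  $\gamma = 0.97$ (it corresponds to $\gamma \approx 0.70$) and is
  available as `beta_H2O_override`.
* **Stage semantics.** Evaporation starts at $t = 0$ (the brief initial
  spreading phase is outside the model; measured footprints are treated
  as the post-spreading state), CCR carries no hygroscopic correction,
  and the final short mixed stage of sessile evaporation is neglected.
* **Binding is surface-only and irreversible**; remobilisation or
  in-pore binding are not modelled.

## What the synthetic generator emulates — and what it does not

`make_fixture()` samples the model's own percent-penetration curve at a
typical assay cadence (0.5–48 h), adds seeded Gaussian noise and clamps
to [0, 100].  It emulates assay noise of a few percent points — about the
scatter of replicate cuticle assays — and yields exactly reproducible
datasets for parameter-recovery experiments (`fit_parameters()` recovers
`k` and `eta_pore` within 20 % at noise SD 3).  It does **not** emulate
the structure of real residuals: between-cuticle biological variability
(pore density and thickness vary between specimens), correlated errors
within a time course, heteroscedastic assay error, or model discrepancy.
Passing recovery tests therefore demonstrates identifiability of the
parameters under the model's own dynamics, not that real data would
constrain them equally well.

## Problem sizes

Defaults are `N_x = 100` cells over 48 h.  Grid refinement changes the
final percent penetration by less than 0.5 % between 100 and 200 cells,
and halving the tolerances changes it below 0.1 %.  The fast unit and
property tests run the same physics at `N_x` 24–50 and, for the
parameter-recovery experiment, `N_x = 30` with a 9-point assay cadence —
coarse enough to iterate quickly, fine enough that every qualitative
conclusion carries over to the default resolution, which the acceptance
suite exercises end to end.

## Known limitations

* Strictly quasi-1-D: no lateral transport, no pore-size distribution,
  no explicit lamellae; one representative pore radius per depth.
* Deliquescence is a sharp threshold; efflorescence hysteresis and
  temperature dependence of the POD are not modelled.
* All physical constants are fixed at 20 °C.
* The droplet footprint weighting ties penetration to droplet life;
  solute still inside the cuticle when the droplet dies is not delivered
  to the bath (a few tenths of a percent in the default scenario, since
  the cuticle transit time ~90 s is far below the droplet lifetime).
* Multiple droplets are assumed identical and non-interacting
  (`n_drops` is a pure multiplier).
* Lipophilic actives, pore-dehydrating chelates, stomatous cuticles and
  whole-leaf transport are outside the model's scope.
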