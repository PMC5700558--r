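---
title: "Pulsed immunotherapy in a tumor-CD4-cytokine model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulsed immunotherapy in a tumor-CD4-cytokine model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsetim)
```

## The model

`pulsetim` analyses a three-compartment model of the interaction between
a solid tumor, tumor-specific CD4+ T cells, and a tumor-suppressing
cytokine such as IL-4, secreted by the T cells. Writing $x$, $y$, $z$
for the tumor, CD4+ T cell and cytokine volumes (all in cm$^3$; time in
days), the autonomous dynamics are

$$
\begin{aligned}
\dot x &= r x \left(1 - \frac{x}{K}\right) - \frac{\delta x z}{m + x},\\
\dot y &= \frac{\beta x y}{k + x} - a y + l_1(t),\\
\dot z &= \frac{\alpha x y}{b + x} - \mu z + l_2(t).
\end{aligned}
$$

The tumor grows logistically and is killed by the cytokine through
saturating (Michaelis–Menten) kinetics; the tumor stimulates CD4+
proliferation and, through the T cells, cytokine production, both also
saturating; T cells die at rate $a$ and the cytokine is cleared at rate
$\mu$. The model deliberately contains no direct T cell cytotoxicity:
tumor killing is mediated entirely by the cytokine, which is the
mechanism attributed to Th2-type CD4+ responses against MHC-II-negative
tumors. $l_1$ and $l_2$ are therapy terms (CD4+ T cell transfer and
cytokine injection).

All ten constants are strictly positive; `tim_params()` enforces this.
Three literature-derived parameter sets ship as presets
(`tim_preset()`):

* `"baseline"` — the baseline estimate-derived set
  ($\alpha=0.1$, $a=0.03$, $b=0.1$, $\delta=0.1$, $k=10$, $\mu=50$,
  $m=1$, $K=1000$, $r=0.027$);
* `"therapy"` — the same set with the CD4+ death rate lowered to
  $a=0.02$, which is the variant actually used in the pulsed-therapy
  analysis (the antigenicity threshold $0.0202 = 0.02\,(10+1000)/1000$
  is only consistent with $a = 0.02$); and
* `"nontreatment"` — the set used for the nontreatment bifurcation study
  ($\alpha=0.01$, $a=0.03$, $b=100$, $\delta=0.1$, $k=1000$, $\mu=50$,
  $m=100$, $K=1000$, $r=0.01$).

The antigenicity $\beta$ — how strongly the tumor drives T cell
proliferation — is the biological bifurcation parameter and is supplied
by the caller (default 0.1, the "immunogenic tumor" case; 0.015 is the
"weakly immunogenic" case).

## Equilibria and the slow-manifold reduction

Without treatment the system always has the trivial state $E_0=(0,0,0)$
(a saddle) and the tumor-at-capacity state $E_1=(K,0,0)$. $E_1$ is
stable exactly when $\beta < \beta_c = a(k+K)/K$ (`beta_crit()`): a
tumor that is insufficiently antigenic wins outright. Above $\beta_c$ a
unique interior equilibrium exists, with

$$x^* = \frac{ka}{\beta - a},\qquad
  z^* = \frac{r(1 - x^*/K)(m + x^*)}{\delta},\qquad
  y^* = \frac{z^*\mu(b + x^*)}{\alpha x^*},$$

always with $x^* < K$. `equilibria()` returns all of these as a tibble
with eigenvalue-based stability verdicts, reporting degenerate cases
($\beta \le a$, $\beta \le \beta_c$) as structured "absent" rows rather
than errors, because parameter sweeps cross those values routinely.

Because $\mu = 50$/day makes the cytokine far faster than the other two
compartments, trajectories collapse quickly onto the slow manifold
$S(x,y) = \alpha x y / (\mu(b+x))$ (`slow_manifold()`); substituting
$z = S(x,y)$ gives a planar reduced system whose interior equilibrium
shares $x^*$ and has
$\bar y = r\mu(m+x)(b+x)(K-x)/(K\alpha\delta x)$. The second component
is stated here in the form forced by $\dot x = 0$ together with
$z = S(x,y)$; the package verifies it by a residual check rather than
trusting any printed rendering of the formula. The reduced Jacobian
(`reduced_jacobian()`) has positive determinant, so stability is
decided by its trace,

$$\operatorname{tr} =
  -\frac{r x}{K}\left[1 + \frac{b(K-x)}{x(b+x)} -
  \frac{K-x}{m+x}\right],$$

and a Hopf bifurcation occurs exactly where the bracket vanishes
(`hopf_residual()`, `reduced_trace()`). Solving the bracket for $b$
yields the Hopf surface $b(m,\beta) = x^2(K-m-2x)/(x^2+mK)$
(`hopf_surface_b()`); the denominator follows from the algebra of the
trace condition (with the `"nontreatment"` values $k = K$, so the distinction
between $mk$ and $mK$ is invisible there), and every returned value is
checked by substitution back into the trace condition. With the
`"nontreatment"` set at $m = b = 100$ the two Hopf points bracket a limit-cycle
band:

```{r hopf}
p <- tim_preset("nontreatment", m = 100, b = 100)
locate_hopf(p, c(0.05, 0.15))$value
locate_hopf(p, c(0.15, 0.35))$value
```

## Pulsed therapy and the stroboscopic map

Therapy is modelled as instantaneous additions: every $\tau$ days
(default 7, a weekly cycle, with the first dose at $t = 0$) the state
jumps by $(0, d_{CD4}, d_{IL4})$. Between pulses the autonomous flow
applies. The natural object is the stroboscopic Poincaré map $F$
advancing a pre-pulse state across one cycle
(`stroboscopic_map()`); its fixed points are the $\tau$-periodic
solutions. The pre-pulse section is the canonical convention throughout
(the post-pulse value is always pre-pulse + dose, and
`tumor_free_fixed_point()` reports both).

On the invariant tumor-free plane everything is linear, giving closed
forms: the pre-pulse fixed point has $y_0 = d_{CD4}/(e^{a\tau}-1)$,
$z_0 = d_{IL4}/(e^{\mu\tau}-1)$, and an infinitesimal tumor grows per
cycle by the Floquet factor

$$\exp\!\left(r\tau - \frac{\delta\, d_{IL4}}{m\mu}\right)$$

(`tumor_free_multiplier()`). The tumor-free state is therefore stable
exactly when $d_{IL4} > r\tau\mu m/\delta$
(`il4_clearance_threshold()`; 94.5 cm$^3$ per week for the
`"therapy"` set), *independently of the CD4+ dose* — and with no
cytokine the factor is $e^{r\tau} > 1$, so pulsed T cells alone can
never hold a cleared tumor down. These closed forms are used both as
results and as exacting oracles for the numerical machinery.

## Numerical choices

**Integration.** $\mu = 50$ makes the system stiff in $z$, so the
default integrator is `deSolve`'s `lsoda` with the analytic Jacobian,
at `rtol = 1e-9`, `atol = 1e-12` (`sim_control()`). These tight
defaults are what bifurcation localisation near $|\text{multiplier}|=1$
needs; they are configurable. Negative undershoot within $10^{-9}$ of
zero is clipped; anything larger is treated as solver failure rather
than masked. Because `lsoda` can inject harmless but nonzero noise
($\sim 10^{-30}$) into a compartment that is exactly zero — which the
tumor's exponential growth would then amplify over hundreds of cycles —
the exactly invariant tumor-free plane is pinned: if $x(0)=0$ the
integrated $x$ is set to 0. This is the mathematical invariance, not a
smoothing.

**Floquet multipliers.** The monodromy matrix is obtained by
integrating the variational equations
$\dot\Phi = J(x(t))\,\Phi$ alongside the state — never by finite
differences of $F$, which lose exactly the accuracy needed near a
bifurcation (finite differences are retained as a test oracle). The
pulse jump is an additive translation, so its Jacobian is the identity
and $\Phi(\tau)$ is the full map Jacobian. At zero dose the multipliers
of an ODE equilibrium must equal $e^{\tau\lambda_i}$; the test suite
asserts this spectral mapping to $10^{-6}$ relative, using a short
$\tau$ so that even the fast cytokine direction ($\lambda \approx
-\mu$) stays numerically comparable — at $\tau = 7$ that direction
underflows toward $0$ and only its magnitude ordering is meaningful.

**Fixed points.** `solve_map_fixed_point()` is a damped Newton
iteration on $F(s)-s$ using the monodromy Jacobian, with
non-convergence reported as a result (multi-start searches must survive
bad seeds). `find_fixed_points()` seeds Newton from the tumor-free
closed form, a ladder of small-tumor states placed on the pulsed CD4+
level with the slow-manifold cytokine height, a near-capacity state,
and the no-dose interior equilibrium. Branches are labelled by the
region nomenclature: `tumor_free`, the small-tumor stable branch
`E1_star`, its saddle companion `E2_star`, and the large-tumor branch
`E3_star`.

**Fold location.** The fold of interest is the birth of the small-tumor
node/saddle pair. Below the fold (at high antigenicity) the attractor
is a closed invariant curve surrounding an unstable *focus* — a
nontrivial fixed point with a complex multiplier pair — so "a
nontrivial fixed point exists" is the wrong bisection predicate.
`locate_fold()` instead bisects on the existence of a small-branch
fixed point ($x < K/2$) whose leading multiplier pair is *real*, which
is precisely the pair created at the fold. This also captures the
fold-homoclinic scenario, where the pair appears on the closed curve
itself. Bisection keeps the fold bracketed at every step; the default
stopping width is $10^{-3}$ of the initial bracket.
`locate_neimark_sacker()` handles the complementary oscillatory
transition: it tracks the small-branch focus and bisects on its complex
multiplier pair crossing the unit circle — the map analogue of a Hopf
bifurcation, at which the invariant closed curve (tumor
regression–relapse cycling) is born or absorbed. In keeping with the
regime nomenclature, outputs label this crossing `neimark_sacker`; in
the dosing diagrams it is the boundary at which oscillation gives way
to a stable small-tumor spiral as the CD4+ dose grows.

**Attractor classification.** `classify_attractor()` iterates the
strobe map (default budget 2000 cycles) and labels a `fixed_point` on
relative convergence below $10^{-7}$ for 10 consecutive iterates, or a
`closed_curve` when the orbit is bounded, non-convergent, and its
strobe points recur near earlier points (median nearest-neighbour
distance below 5% of the orbit diameter over a 100-point window).
Orbits exceeding $10K$ are flagged `unresolved` rather than erroring.
These policies are conservative and fully configurable
(`attractor_policy()`); the analyses here do not need spectral
diagnostics, and none are attempted.

**Region maps.** `region_map()` classifies grid points by the signature
of coexisting fixed points (branch + stability) and adaptively refines
cells whose corners disagree — no continuation, no normal forms. The
refinement scheme (default 17×17 grid, depth 5, corner-disagreement
splitting) is this package's own; any scheme reaching the same labels
would do. With the `"therapy"` set at $\beta = 0.015$ it recovers the
three dosing regimes: tumor escape only; bistability of a small dormant
tumor ($E_1^*$) with near-capacity escape ($E_3^*$) beyond the fold at
$d_{CD4} \approx 32$; and, above $d_{IL4} = 94.5$, a stable tumor-free
state coexisting with $E_3^*$, so clearance depends on the initial
burden.

## What the checks do and do not show

The test suite freezes hand-derived values (vector-field arithmetic,
closed-form equilibria, pulsed fixed points), asserts structural
invariants on randomly drawn parameter sets (tumor-free plane
invariance, pulse-jump exactness, nonnegativity, $x^* < K$, the
trace/residual identity, the stability predicate against reduced-system
eigenvalues on 1000 draws), and cross-checks every numerical route
against an independent one: analytic Jacobian vs central differences,
`lsoda` vs high-accuracy `radau`, variational multipliers vs
$e^{\tau\lambda}$ and vs the tumor-free closed form, the Hopf surface
vs substitution into the trace condition, and the closed-form
transcritical dose vs the monodromy crossing. Published bifurcation
values are recovered end to end: $\beta_c = 0.0202$, the weekly
clearance dose 94.5 cm$^3$, Hopf points near $\beta = 0.113$ and
$0.247$, the IL-4 fold near 76.23 cm$^3$ (at $\beta=0.1$, $d_{CD4} =
10$) and the CD4+ fold near 32 cm$^3$ (at $\beta=0.015$).

Everything here concerns this deterministic, well-mixed,
three-compartment caricature. The model has no spatial structure, no
pharmacokinetics beyond instantaneous pulses and first-order clearance,
no Th1/Th2 split, no immunosuppressive feedback, and its parameters are
literature-scale estimates with wide uncertainty. Agreement with the
published thresholds validates the implementation, not the therapy:
dose numbers such as "94.5 cm$^3$ per week" are statements about the
model. Test problem sizes (horizons of a few hundred to a few thousand
days, cycle budgets of several hundred, coarse region-map grids) were
chosen as the smallest runs that exercise each qualitative regime
cleanly; the locators themselves are run at their full default
tolerances.

## Reproducing the headline numbers

```{r acceptance, eval = FALSE}
# from the repository root
# Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The script recomputes, from scratch: the antigenicity threshold, the
weekly IL-4 clearance dose (with its monodromy cross-check), both Hopf
points of the reduced system, and both folds of the weekly stroboscopic
map.
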