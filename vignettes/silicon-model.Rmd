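---
title: "Modelling silicon bioavailability and uptake in greenhouse tomato"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling silicon bioavailability and uptake in greenhouse tomato}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silicrop)
```

## The problem

Tomato takes up silicon passively: orthosilicic acid, Si(OH)₄, dissolved
in the root-zone water is swept into the plant with the transpiration
stream and precipitates in tissue as amorphous silica (SiO₂), where it
stays for the life of the plant. Two quantities therefore decide the
silicon status of a crop: the Si(OH)₄ concentration the roots see, and
the volume of water the crop transpires. `silicrop` models both, for
soil-grown and soilless (hydroponic) tomato, at the season scale.

The model is valid for unstressed crops only: growth is treated as a
direct function of irradiance, temperature and CO₂, which breaks down
under salinity, drought or disease pressure. The simulator will run on
any inputs, but results outside the no-stress envelope should not be
trusted.

## Soil availability

The soil solution can hold at most `SiP = 192.18` mg L⁻¹ Si(OH)₄ (2 mM);
above that threshold silicic acid condenses into hydrated amorphous
polymers that roots cannot absorb (`polymerization_status()` classifies
concentrations against the 1.8 and 2.0 mM marks). How much of that
potential is realised is modelled multiplicatively:

$$\mathrm{SiAv} = (\mathrm{SiP} - \mathrm{SiWater})\cdot
  E_T(T)\, E_{OM}(OM)\, E_{pH}(pH) + \mathrm{SiWater}$$

* $E_T$ — cubic in soil temperature, coefficients
  $(-0.0003, 0.0127, -0.1093, 0.1674)$;
* $E_{OM} = OM/(2.5 + OM)$ — Michaelis–Menten in organic matter (% w/w),
  half-saturated at 2.5 %, i.e. at the conventional threshold of an
  organically rich soil the factor is exactly one half;
* $E_{pH}$ — cubic in pH, coefficients
  $(-0.0235, 0.325, -1.1563, 1.2262)$.

`SiWater` (mg L⁻¹ Si(OH)₄ in the irrigation water) enters both as the
floor of the availability and as the sole source in soilless mode.

**Clamping.** The fitted cubics are only meaningful over roughly 8–35 °C
and pH 2–9. Outside those ranges the raw polynomials go negative (no
availability — clamped to 0) or exceed 1 ($E_{pH}$ slightly, near its
maximum at pH ≈ 6.8; $E_T$ wildly, at deeply sub-zero temperatures far
outside validity). Both factors are clamped to $[0, 1]$, which together
with the multiplicative form guarantees
$\mathrm{SiWater} \le \mathrm{SiAv} \le \mathrm{SiP}$ for every input —
a property the test suite checks on a thousand random soils. Note a
small discrepancy between the fitted curves and the usual narrative:
the cubics actually peak at ≈ 23 °C and pH ≈ 6.8, not at 25 °C and 7.0.
We implement the printed coefficients verbatim; the numbers win over the
prose.

**Areal availability.** To express availability per unit ground area the
concentration is multiplied by the soil water volume
`profile_depth × bulk_density × moisture` (90 L m⁻² for the default
30 cm, 1200 kg m⁻³, 25 % w/w). Bulk density is not part of the published
scenario description; 1200 kg m⁻³ is a typical loam value, chosen once
and exposed in `soil_state()`. Under the reference fertile soil (pH 7,
OM 6 %, SiWater 5) this gives ≈ 4870 mg m⁻² at 15 °C and ≈ 8570 mg m⁻²
at 25 °C, above the published `> 4,500` / `> 8,300` bounds.
`areal_availability(..., include_irrigation = FALSE)` exposes the
soil-derived term alone: the published low-end figures (tens of mg m⁻²)
are only reachable without the irrigation floor, since 5 mg L⁻¹ × 90 L
already contributes 450 mg m⁻²; we expose both terms and assert neither
low-end figure.

## Crop growth and transpiration

The original work drives transpiration from a six-state greenhouse
tomato model whose coefficients are not published. Rather than guess at
it, `silicrop` defines a **GrowthDriver** contract — any function
`(biomass, env_sample, dt, params) → increment` — and ships a reduced
default:

$$\frac{dB}{dt} = \mathrm{RUE}\cdot \mathrm{PAR}\cdot
  \frac{C}{C + K_C}\cdot f_T(T_{air})\cdot\left(1 - \frac{B}{B_{max}}\right)$$

active during the photoperiod only. $f_T$ is a beta-type cardinal
temperature function with $T_{min} = 8$, $T_{opt} = 30$,
$T_{max} = 40$ °C; $K_C = 300$ µL L⁻¹; $B_{max} = 9000$ g m⁻² (a
3000 g/plant ceiling at 3 plants m⁻², matching the highest published
biomass); transplant biomass 6 g m⁻² (2 g/plant). RUE is frozen at
`4.66682277422e-06` g µmol⁻¹, the value that makes the reference season
(PAR 400 µmol m⁻² s⁻¹ for 12 h/day, CO₂ 400, air 30 °C, 10 279 801 s at
Δt = 1800 s) end at exactly 1370 g dry matter per plant — the anchor
implied by the published saturation value of 13.7 g SiO₂ per plant at
the 1 % cap. Only this anchor and the qualitative orderings (more
biomass at 30 °C than 20 °C, increasing in PAR and CO₂) are calibrated;
absolute biomass under other scenarios is *not* a validated output of
the reduced driver.

**Transpiration** is linear in biomass,
`Transpiration = Biomass · plm / tcg` with `plm = 8.5714` and
`tcg = 10 279 801 s`, with biomass in g dry m⁻². The published relation
carries no units; we read the result as L m⁻² s⁻¹ (per ground area).
This makes seasonal transpired volumes large, which matters little for
accumulation *at* the 1 % cap (the cap, not the volume, decides) but
means sub-cap accumulations should be read comparatively, not as litre
budgets. Transpiration runs day and night; growth only under light.

**Organ partitioning.** Dry mass fractions interpolate linearly between
two anchor canopies: at 30 °C fruit 60 %, leaf 9 %, stem 25 %, root 6 %;
at 20 °C fruit 33 %, leaf 33 %, stem 27 %, root 7 % (stem and root
values are our completion of the published leaf/fruit anchors, chosen to
sum to one with a small root share typical of indeterminate tomato).
Fractions are constant outside 20–30 °C.

**Leaf-share transpiration weighting.** Because leaves account for ~90 %
of transpiration, a cool-grown, leafy canopy (33 % leaf) transpires more
water per gram of biomass than a warm, fruit-dominated one (9 % leaf).
With transpiration strictly proportional to *total* biomass that
mechanism — and with it the observed higher Si concentration of
cool-grown plants — is unreproducible: the warm crop always accumulates
at least as much Si per unit biomass. The simulator therefore scales
transpiration by `leaf_fraction(T) / leaf_fraction(30 °C)` (a factor of
1 at the 30 °C reference, so the calibration anchor is untouched; ~3.7
at 20 °C). Set `growth_params(leaf_weighting = FALSE)` to recover the
strictly linear relation. `transpiration_rate()` itself always returns
the unweighted linear value.

## Silicon uptake and the 1 % cap

Per timestep, the uptake increment is
`SiAv · transpired volume · SiSi`, converted from mg Si(OH)₄ to g SiO₂
(× 60.08/96.11), where `SiSi ∈ [0, 1]` is the retained fraction of
transpiration-stream silicon. No value for `SiSi` is published; the
default is 1, the only value under which the published maximal
accumulations are reachable. The running total is truncated at
`MSiT = 1 %` of the *current* dry biomass (the cap grows with the crop),
and each increment — including a truncated one — is split over organs by
transpiration share (leaf 0.90 / stem 0.05 / fruit 0.025 / root 0.025),
so organ totals conserve the whole-plant total exactly and organ shares
equal the transpiration shares in any run with non-zero uptake. There is
no remobilization: deposited silica never leaves an organ.

The published capacity relation (`biomass/100 × planting density`) is
dimensionally ambiguous; we read its biomass as per-plant dry mass, so
the cap per unit area is 1 % of per-area dry biomass and the per-plant
figure divides by planting density — this reproduces 13.7 g per plant at
1370 g dry biomass.

**Saturation masks orderings.** Under the volume scale above, any
irrigation source ≳ 3 mg L⁻¹ saturates the cap by season's end at either
air temperature. At the cap, concentration is exactly 1 % regardless of
temperature or source strength, so comparisons such as "cooler crops
concentrate more Si" or "28 mg L⁻¹ beats 5 mg L⁻¹" hold *strictly* only
in the transport-limited (sub-cap) regime; at saturation they hold
weakly (equality). The acceptance tests probe the strict orderings at
0.5–2 mg L⁻¹ and verify weak monotonicity elsewhere.

## Synthetic environments

`generate_environment()` produces the scenario inputs used throughout:
square-wave PAR (constant `par_day` during a `photoperiod_h` light
block starting at midnight, 0 at night — the published scenarios specify
constant PAR for fixed hours; a half-sine option exists), day/night air
temperature levels (the reference scenarios use one average temperature,
so night defaults to day), and constant CO₂. Optional Gaussian noise is
drawn from a private seeded stream that never touches the global RNG,
with PAR clamped at 0. This generator emulates *setpoint greenhouse
climates*, not weather: no seasonal trend, no cloud autocorrelation, no
humidity or VPD. A green test therefore establishes correctness of the
model mechanics under controlled forcing, not predictive skill against
field data; user-recorded climates can be supplied as CSV
(`read_environment_csv()`).

## Numerical choices

* **Integration**: explicit Euler at Δt = 1800 s (default). The dynamics
  are mild (growth rates ≪ B_max per step); halving Δt moves final Si by
  ~4 × 10⁻⁵ relative, far inside the 0.5 % robustness requirement the
  tests enforce.
* **Season/step mismatch**: the canonical season length 10 279 801 s is
  not a multiple of any round timestep. Rather than reject the published
  value, `run_simulation()` truncates to ⌊season/Δt⌋ whole steps (1 s
  dropped at Δt = 1800) and records the effective season in the summary.
* **Cap enforcement**: applied per step against the capacity of the
  *updated* biomass; a cap momentarily below the accumulated total (only
  possible via exotic drivers) freezes the account rather than clawing
  anything back.
* **Order within a step**: grow → partition → transpire → uptake, so
  uptake in a step uses that step's transpired volume and end-of-step
  capacity; the brute-force replay oracle in the tests pins this
  convention.
* **Soil Si is non-depleting by default** (re-evaluated from the static
  soil state each step), reflecting the assumption of unlimited mineral
  replenishment; `soil_reservoir` enables a finite areal pool for
  sensitivity work.
* **Ties and degenerate inputs**: zero-length seasons, empty sweep axes,
  environments shorter than the season, organ fractions not summing to
  one, and irrigation Si above `SiP` all raise typed validation errors
  rather than producing numbers.

## Tunable parameters at a glance

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `si_p` | 192.18 | mg L⁻¹ | polymerization ceiling of Si(OH)₄ |
| `km` | 2.5 | % w/w | OM half-saturation |
| `profile_depth` | 0.30 | m | rooted profile |
| `moisture` | 0.25 | w/w | gravimetric soil moisture |
| `bulk_density` | 1200 | kg m⁻³ | dry bulk density (our choice) |
| `plm / tcg` | 8.5714 / 10 279 801 | – / s | transpiration slope / season |
| `pd` | 3 | plants m⁻² | planting density |
| `rue` | 4.667 × 10⁻⁶ | g µmol⁻¹ | calibrated light-use slope |
| `biomass_max` | 9000 | g m⁻² | growth asymptote |
| `si_si` | 1 | – | retained fraction of stream Si |
| `max_si_fraction` | 0.01 | – | SiO₂ cap as share of dry mass |
| `mulch_offset` | 0 (0–4) | °C | soil warming by plastic mulch |

## Known limitations

* The growth driver is a calibrated stand-in; outside the anchor
  scenario its absolute biomass (and hence absolute sub-cap Si) is
  indicative only.
* No stress physiology, no transporter-level (Lsi) mechanism, no
  distinction between soluble and biogenic tissue silicon, no soil
  adsorption kinetics on Fe/Al phases.
* Transpired volumes inherit the unit ambiguity of the published linear
  relation; treat them as a forcing for Si transport, not as an
  irrigation budget.
* Organ silicon follows transpiration shares, not organ biomass — the
  two conflict for fruit (heavy, barely transpiring), and transpiration
  is the physiologically supported choice for silica deposition.
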