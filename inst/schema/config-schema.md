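# Configuration file layout

All configuration is JSON. The time axis is years CE (negative = BC).
Every time-varying quantity is a breakpointed series `{"t": [...], "y":
[...]}` with strictly increasing `t`; values are interpolated linearly and
held constant beyond the ends. Validation is performed by
`load_landscape()` / `load_nuclides()` / `load_and_validate()`, which
aggregate all violations into one report.

## Nuclide library (`nuclides.json`)

Array of records:

| field | type | constraint |
|---|---|---|
| `name` | string | unique |
| `half_life` | number, years | > 0 |
| `parent` | string or absent | must name another record; parent graph acyclic; branching out of one parent sums to <= 1 |
| `branching_fraction` | number | in (0, 1], default 1 |
| `element.kd` | object: medium -> m3/kg dw | >= 0; keys `regolith_low`, `regolith_mid`, `regolith_up`, `water` all required (0 allowed) |
| `element.cr` | object: biota -> CR | >= 0; `ter_producer`, `aqu_producer`, `crops`, `aquatic_food` required for dose runs |
| `element.degassing_rate` | number, /a | >= 0, default 0 |
| `dose_coefficients.ingestion` | Sv/Bq | >= 0 |
| `dose_coefficients.inhalation` | Sv/Bq | >= 0 |
| `dose_coefficients.external_soil` | (Sv/a)/(Bq/kg dw) | >= 0 |
| `dose_coefficients.external_water_immersion` | (Sv/a)/(Bq/m3) | >= 0 |

## Landscape (`landscape.json`)

```
{
  "objects": [ <object>, ... ],
  "downstream_edges": [ {"from": id, "to": id-or-outlet, "flux": series m3/a}, ... ],
  "sea_exchange":     [ {"object": id, "coast": id,
                         "flux_out": series, "flux_in": series}, ... ],
  "outlet": id
}
```

Downstream edges must form a DAG ending at the outlet. During an object's
sea stage only its sea exchange is active; after isolation only its
downstream edges (the blend follows the object's sea-stage weight).

Each `<object>`:

| field | content |
|---|---|
| `id` | unique string |
| `compartments` | per compartment id (`REGOLITH_LOW`, `AQU_REGOLITH_MID`, `AQU_REGOLITH_UP`, `TER_REGOLITH_MID`, `TER_REGOLITH_UP`, `LITTER`, `WATER`, `AQU_PP`, `TER_PP`, `ATMOSPHERE`): series `solid_mass` kg dw, `water_volume` m3, `area` m2, `thickness` m |
| `water_fluxes` | list of `{from, to, flux}` internal advective fluxes, m3/a |
| `diffusion` | list of `{pair: [i, j], diffusivity m2/a, area m2, length m}` |
| `sedimentation_flux`, `resuspension_flux` | series, kg dw/m2/a |
| `suspended_solids` | series, kg dw/m3 |
| `production`, `biomass` | `{terrestrial, aquatic}` series, kg C/m2/a and kg C/m2 |
| `litter_decomposition_rate`, `atmosphere_turnover` | scalars, /a |
| `aquatic_return_split` | fraction of aquatic producer turnover returned to WATER (rest to upper sediment) |
| `schedule` | succession schedule (below) |

Schedule: `submerged_until <= isolation_start < isolation_end <=
wetland_established`, optional `agricultural_from >= isolation_end`,
`agricultural_ramp` (years), and `climate_periods` rows
`{label, start, end}` with labels from `temperate`, `periglacial`,
`glacial`, `global_warming`.

## Monte Carlo distributions (`dists.json`)

Array of `param_dist()` argument objects, e.g.

```
[{"path": "library/Ra226syn/element/kd/regolith_low",
  "kind": "loguniform", "best_estimate": 2, "min": 0.2, "max": 20}]
```

`path` is a `/`-separated address into the configuration list
(`graph/...`, `library/...`, `habits/...`) and must resolve to a scalar.
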