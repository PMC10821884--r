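# fluxtrace

A desk-scale server for constraint-based metabolic models, built for teams
who probe a shared model — knocking out reactions, changing flux bounds,
re-running flux balance analysis — and need every alteration to stay
**traceable** and the model itself to stay **intact**.

The package keeps three kinds of files:

| file | format | role |
|---|---|---|
| model file | SBML L3 + fbc | the mathematical model; immutable once registered |
| view file | Cytoscape CyJson | a spatial projection of all or part of a model (≥ 1 per model) |
| modification file | YAML | author, date, root model, optional parent, ordered entries |

Modifications are layered over the model like image-editing layers. A file
can name a **parent** whose entries are prepended on load (temporal
traceability: every intermediate state is recoverable through the lineage),
states are diffable entry-by-entry (differential traceability), and when
several files are loaded together, **the last file loaded wins** on any
element both touch.

At its core is standard flux balance analysis: maximise the objective
`c'v` subject to steady-state mass balance `S v = 0` and bounds
`lb ≤ v ≤ ub`, with `S` the species × reactions stoichiometric matrix and
fluxes in mmol·gDW⁻¹·h⁻¹. A knockout pins a reaction's bounds to (0, 0).
The LP is solved by a bounded-variable two-phase simplex (Bland's rule,
pivot tolerance 1e-9), cross-checked in the test suite against an
independent vertex-enumeration oracle and the cobrapy/GLPK stack. The
solver reports one optimal vertex; the objective value is unique, but under
alternate optima individual fluxes (and hence the reported extrema) are
solver-dependent. Solutions also carry the display scalars used by
graphical clients: blue→red colour interpolation
`color_t = (v − v_min)/(v_max − v_min)`, edge widths clamped into
`[w_min, w_max]`, and a particle debit proportional to |flux|.

Everything is exposed over an HTTP query API
(`/listModels`, `/listViews/<model>`, `/importViewFile/<view>`,
`/listModificationFiles/<model>`, `/saveModificationFile`,
`/solveFBA/<model>[/<modFile>...]`, `/commands`) with an **action-schema
handshake**: a client module unlocks exactly when the commands it requires
are a subset of what the server publishes.

## Worked example

A bundled synthetic central-metabolism model (a deliberately small,
hand-built caricature of *E. coli* glucose import — not a genome-scale
reconstruction) shows the whole loop. Glucose enters with the conventional
default uptake bound of −10 mmol·gDW⁻¹·h⁻¹ and is imported either by the
PTS or by a less efficient ABC route:

```r
library(fluxtrace)
store <- store_open(tempfile("demo"))
syn <- synthetic_central_metabolism()
register_model(store, syn$sbml, "synthCentral", source_db = "synthetic")

sol <- fba(store, "synthCentral")
print(sol)
#> <flux_solution> status optimal, objective 16.6667, flux range [-10, 16.6667]
round(sol$fluxes, 3)
#>    EX_glc_e      GLCtex    GLCptspp    GLCabcpp        HEX1        GLYC
#>     -10.000      10.000      10.000       0.000       0.000       6.667
#>         PYK        OXID        CO2t    EX_co2_e BIOMASS_syn
#>       0.000       0.000       0.000       0.000      16.667
```

The optimum routes the entire uptake through the PTS reaction
(`GLCptspp = 10`, the uptake bound). Now knock it out — as a recorded,
attributable modification file, never by touching the model:

```r
put_modification_file(store, modification_file(
  "pts_ko", "ada", "synthCentral", list(mod_entry("GLCptspp", "knockout"))))
ko <- fba(store, "synthCentral", mod_files = list("pts_ko"))
round(ko$fluxes, 3)
#>    EX_glc_e      GLCtex    GLCptspp    GLCabcpp        HEX1        GLYC
#>         -10          10           0          10          10           6
#>         PYK        OXID        CO2t    EX_co2_e BIOMASS_syn
#>           9           0           0           0          15
```

The knocked-out flux is 0 and the full 10 units reroute through the ABC
branch at a lower objective (15 vs 16.67). Display scalars for a renderer:

```r
head(compute_visual_scalars(sol, w_min = 0.2, w_max = 2, rate_per_flux = 0.5), 4)
#>   reaction_id flux color_t width particle_rate
#> 1    EX_glc_e  -10   0.000  1.28             5
#> 2      GLCtex   10   0.750  1.28             5
#> 3    GLCptspp   10   0.750  1.28             5
#> 4    GLCabcpp    0   0.375  0.20             0
```

The same computations are one HTTP call away
(`serve_api(store, port = 8585)` then `GET /solveFBA/synthCentral/pts_ko`),
and a thin CLI wraps the package (`exec/fluxtrace`): `store add`,
`store list`, `store translate`, `view check`, `trace diff`, `trace save`,
`fba solve`, `fixtures make`, `serve`.

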