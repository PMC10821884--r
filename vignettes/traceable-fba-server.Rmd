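---
title: "Traceable metabolic-model management and flux balance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Traceable metabolic-model management and flux balance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxtrace)
```

## The problem this package addresses

Collaborative work on constraint-based metabolic models has a data-integrity
problem: several people probing the same genome-scale reconstruction — closing
reactions, changing bounds, re-running simulations — can easily end up with
divergent, untraceable copies of the model. fluxtrace organises the work
around one rule: **the model file is immutable**. Everything a user does is
recorded outside it, in small versioned *modification files*, and the model a
simulation actually sees is always "the stored model, plus an explicit,
replayable stack of modifications". Three file types carry the whole system:

* **Model files** (SBML Level 3 with the flux-balance-constraints package):
  species, reactions with stoichiometry, flux bounds in
  mmol·gDW⁻¹·h⁻¹, and the optimisation objective. Registered once, never
  rewritten; `model_bytes()` exposes the stored bytes so integrity is
  auditable, and the test suite asserts byte-identity after arbitrary
  operation sequences.
* **View files** (Cytoscape CyJson): spatial projections of all or part of a
  model — node positions plus edge source/target. Views are display
  artifacts; they carry no modelling content, and a model can have any number
  of them (every model gets at least a deterministic grid layout at
  registration, so "model without a view" cannot occur).
* **Modification files** (YAML): an author, an ISO-8601 UTC date, the root
  model, an optional parent file, and an ordered list of entries. Two
  operations exist in this version — `knockout` and `set_bounds (lower,
  upper)` — because these are the two model-altering actions the analysis
  layer consumes; a knockout is defined as bounds (0, 0) at analysis time.

## Temporal and differential traceability

A modification file may name a **parent**. Loading a child behaves as if
every ancestor had been loaded first: `resolve_lineage()` concatenates
entries ancestors-first (duplicate identical entries collapse, keeping the
first occurrence). Authorship, dates, and the parent chain give *temporal*
traceability: any intermediate state can be reconstituted by truncating the
chain. Because states are plain entry lists, `diff_modification_files()`
gives *differential* traceability: two lineage-expanded states partition
into `only_in_a` / `common` / `only_in_b`, with entry identity defined as
(target, operation, payload) — authorship and timestamps are bookkeeping,
not modifications.

When several files are loaded together, conflicts are resolved by **load
order**: the entry from the last-loaded file targeting an element wins, and
within one expanded file the later entry wins. `resolve_effective_state()`
reduces any load sequence to exactly one winning entry per target, with the
provenance (file, load index) that decided it.

### The save rule and its one subtlety

`save_modification_file()` checkpoints a session. The parent of the new file
is the last file loaded, so the parent's entries travel implicitly; the new
file records only (a) what the earlier-loaded files contributed and the
parent does not already carry, in load order, then (b) the session's own
entries. One design decision deserves a note: an entry from an
earlier-loaded file that was *overridden* by the parent on the same target
is **not** recorded. Recording it would place it after the parent's entries
in the saved file's expansion, where the within-file "later wins" rule would
resurrect it — the reloaded state would differ from the state the user
saved. With losers dropped, the package maintains the closure property that
the suite tests directly: loading only the saved file reproduces, exactly,
the effective state of the original load sequence plus the session.

## Flux balance analysis

The analysis layer implements standard FBA: find fluxes `v` maximising
`c'v` subject to steady-state mass balance `S v = 0` and bounds
`lb ≤ v ≤ ub`, where `S` is the species × reactions stoichiometric matrix
(negative coefficients = consumed). `build_fba_problem()` assembles the LP
from a model record and an effective state — knockouts pin bounds to (0, 0),
`set_bounds` replaces them — and applies every modification whether or not
any view displays the target. Reversible reactions are kept as single
signed-flux columns rather than being split, so reported fluxes keep their
sign.

`solve_fba()` uses a dense bounded-variable **two-phase primal simplex**
written for this package (R/lp.R), with Bland's rule for anti-cycling and a
pivot tolerance of 1e-9; a mass-balance residual above the feasibility
tolerance (default 1e-6) is refused rather than reported. The solver is
deliberately dense and simple: it targets desk-scale problems (tens to a few
hundred reactions), which is where all bundled fixtures live. It is **not**
sized for genome-scale reconstructions (thousands of reactions); driving
those requires a sparse LP backend, which is outside this version's scope.
Correctness is established by triangulation in the test suite: on seeded
random networks the objective agrees to 1e-6 relative with (a) an
independent vertex-enumeration brute force and (b) the cobrapy/GLPK stack
solving the very SBML files this package writes.

Two well-known FBA facts shape the reporting contract. The optimal
*objective value* is unique, but the optimal *flux vector* generally is not
(alternate optima); `solve_fba()` returns one optimal vertex and documents
that per-reaction fluxes — and hence the extrema `v_min`/`v_max` — are
solver-dependent. The extrema can optionally be restricted to the reactions
present in a given view (`view =`), since a display typically colours only
the mapped pathway.

### Visual scalars

`compute_visual_scalars()` turns a solution into the three per-reaction
display quantities used by graphical clients: `color_t = (v − v_min) /
(v_max − v_min)` (clamped to [0, 1]; defined as 0.5 when the extrema
coincide) interpolating blue→red; an edge `width` mapping |v| linearly onto
and clamped into `[w_min, w_max]`; and `particle_rate = rate_per_flux · |v|`
in particles·s⁻¹, so zero-flux edges emit nothing. `color_t` is invariant
under affine rescaling of the flux vector. With the endpoints −45/+55, a
flux of 10 maps to `color_t = 0.55`.

## The query API and the action-schema handshake

`handle_query()` is a pure router implementing the URL convention
`/<queryName>[/<param>...]`: `listModels`, `listViews/<model>`,
`importViewFile/<view>`, `listModificationFiles/<model>`,
`saveModificationFile` (POST, YAML body), and
`solveFBA/<model>[/<modFile>...]`, where extra path segments are
modification files **in load order** — the URL order is the
last-loaded-wins order. An infeasible FBA returns HTTP 200 with status
`"infeasible"`: it is a scientific result, not a transport failure.
`/commands` publishes the implemented command list; `check_action_schema()`
implements the client-side handshake (a module unlocks iff its required
command set is a subset of the published list, an empty requirement being
vacuously satisfied). A deliberately minimal serial HTTP/1.1 loop
(`serve_api()`) exposes the router on a socket for a single trusted client;
there is no TLS, authentication, or concurrency in this version, and every
request is appended to a JSONL query log for audit.

## Synthetic data: what it emulates, and what it does not

`generate_toy_model()` produces chain, parallel, branched and seeded-random
networks. Defaults follow the field's conventions: uptake exchanges carry a
lower bound of −10 mmol·gDW⁻¹·h⁻¹ (the customary default glucose-uptake
bound in *E. coli* reconstructions), internal reactions are irreversible
with generous capacity (100× the uptake scale, standing in for the usual
±1000 "unbounded" sentinel), and every topology guarantees an inlet, an
outlet, and a feasible zero vector, so generated problems are never
degenerate by construction. Random networks sprinkle compartments,
subsystems and reversibility to exercise grouping and signed fluxes.

`synthetic_central_metabolism()` is a hand-built ~11-reaction caricature of
*E. coli* central carbon metabolism, and is labelled synthetic everywhere:
it exists to exercise the demonstration workflow, not to approximate a
reconstruction. Its one carefully engineered property mirrors the real
system: glucose crosses the periplasm and is imported either by the PTS
(consuming phosphoenolpyruvate) or by a strictly less efficient ABC+kinase
branch, so the unique optimum routes the entire default uptake (10) through
`GLCptspp` — and knocking that reaction out reroutes all 10 units through
the ABC branch at a lower objective. Passing tests on these fixtures
demonstrate the machinery (store, lineage, LP, API) end to end; they do not
demonstrate numerical agreement with any genome-scale reconstruction, whose
size this solver deliberately does not target.

## Numerical and design choices

* LP pivot tolerance 1e-9, feasibility tolerance 1e-6, both surfaced as
  arguments; Bland's rule everywhere (slower, but termination-safe under the
  heavy degeneracy knockouts create).
* Variables with `lb == ub` (knockouts, pins) are eliminated before the
  simplex runs.
* ID translation tables are direction-specific two-column TSVs; a lookup of
  an absent identifier is a *not-found error*, distinct from an empty result
  — an empty mapping would silently propagate as "no counterpart exists",
  which is a claim the table cannot support.
* Views store coordinates exactly as read (Cytoscape screen convention);
  node classes are inferred from membership (species → metabolite, reaction
  → reaction), and a node matching neither is a consistency error.
* Serialisers (SBML, CyJson, YAML) are canonical: fixed field order and
  full-precision numbers, so parse∘serialize round trips are byte-stable and
  integrity checks are meaningful.
* Problem sizes in the test suite — random LPs of ≤ 8 reactions for oracle
  triangulation (the vertex-enumeration oracle is exponential), lineages of
  depth ≤ 5, 100-seed property loops — were chosen as the package's own
  testing budget: large enough to hit degenerate corners, small enough that
  the whole suite runs in a couple of minutes on one core.

## Known limitations

* Dense simplex: no genome-scale LPs; no FVA/pFBA/MOMA.
* One CyJson dialect; other view formats would need their own parser plugged
  in at the `parse_view()` boundary.
* The HTTP layer is serial and unauthenticated by design (single trusted
  client); real deployments would sit it behind a reverse proxy.
* Per-entry authorship is not recorded — author and date live at file level,
  which is the granularity the lineage and diff machinery needs.
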