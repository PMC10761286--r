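---
title: "Temporal social bubbles: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal social bubbles: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

bubblesim asks a policy question with a coupled simulation: can reorganizing
*who meets whom* — rather than cutting contacts — keep an epidemic under
control while still letting complex social processes (knowledge diffusion,
collaboration, norm formation) run? Two spreading processes share one
synthetic temporal contact network: a disease spreading by *simple*
contagion (one contact can infect) and knowledge spreading by *complex*
contagion (several reinforcing contacts are needed). Interventions that help
one generally hurt the other; the package quantifies that trade-off.

```{r, eval = FALSE}
library(bubblesim)
sc <- scenario(network_config(p = 199, pairing_period_days = 10),
               epi_params(eps_I = 0.1, eps_T = 0),
               knowledge_params(), n_runs = 50)
ens <- run_ensemble(sc)
ens$indicators
```

## The contact network: social bubbles under a fixed link budget

Layers are sampled independently per 2-hour step from a stochastic block
model: `N = 680` nodes in `N_c = 10` bubbles of 68 (contiguous index
blocks), within-bubble pair probability `p_intra`, between-bubble pair
probability `p_inter`. The population and density mimic a real proximity
study of about 700 students with an average of 400 simultaneous proximity
links, so conclusions are drawn at realistic contact densities, but no real
data are consumed or fitted.

The central constraint is the *link budget*: the expected number of links
per layer is held at `L = 400` whatever the modularity, so interventions
rearrange contacts instead of removing them. With bubble sizes \(n_i\),

\[
L \;=\; \sum_i \frac{n_i(n_i-1)}{2}\,p_{intra}
      \;+\; \sum_i \frac{n_i(N-n_i)}{2}\,p_{inter},
\]

and the package always solves one probability from the other
(`solve_p_inter()`, `network_config(p = ...)`). The single dial is the
modularity ratio \(p = p_{intra}/p_{inter}\): `p = 5` means within-bubble
contacts are only 5 times likelier than between-bubble ones (bubbles in name
only), `p = 199` means nearly self-contained bubbles.

*Temporal clustering* (`pairing_period_days = d > 0`) adds the package's
distinctive intervention: rather than spreading between-bubble contacts over
all bubble pairs, each bubble is matched with exactly one partner for `d`
days, and matchings rotate by a circle-method round robin so that every pair
of bubbles eventually meets (`round_robin_schedule()`). Matched pairs use a
boosted probability
\(p_{pair}(a,b) = p_{inter}\,[n_a(N-n_a)+n_b(N-n_b)]/(2 n_a n_b)\),
which preserves the expected inter-bubble link count — for equal sizes it
reduces to \(p_{inter}(N-n_c)/n_c\). With an odd number of bubbles one bubble
sits out per round (a bye), which slightly lowers that round's inter-bubble
contact mass; the tournament still covers every pair exactly once.

Layers are independent across steps: no contact persistence, day/night
rhythm, weekday structure, geographic clustering or degree heterogeneity.
That is deliberate — modularity is the *only* structure, so its effect is
not confounded — but it means passing tests say nothing about networks with
temporal correlation or hubs, where tracing in particular behaves
differently.

## Disease: non-Markovian SIR with isolation, tracing, quarantine

Infection histories are age-dependent rather than memoryless. An infected
node of infection age \(\tau\) (days) transmits per contact with probability
\(\beta\,\omega(\tau)\) and, if symptomatic-fated (80% of infections),
develops symptoms according to a CDF \(s(\tau)\). Infected nodes recover 10
days after infection. Once symptomatic, a node is isolated with daily
probability `eps_I`; isolation cuts all contacts for 10 days, after which
the node is recovered. On each isolation, the node's distinct contacts of
the trailing 7 days are traced and quarantined with per-contact probability
`eps_T` for 10 days; quarantined infected ("true positives") that turn
symptomatic are promoted to isolation and trigger their own tracing.
Confined nodes of either kind have all contacts cut — they neither transmit
disease nor exchange knowledge.

Two curves are only qualitatively constrained by the sources this model
follows, so the package makes explicit, configurable choices
(`infectivity_curve()`):

* \(\omega(\tau)\): gamma-shaped with mode at 5 days and shape 9 (standard
  deviation about 1.9 days, in line with COVID-19 generation-interval
  estimates), truncated at the 10-day infectious period and normalized to
  peak 1, so `beta` is the maximal per-contact transmission probability.
* \(s(\tau)\): log-normal with median 5.5 days and `sdlog` 0.45 (COVID-19
  incubation literature). Onset is simulated by the incremental hazard
  \([s(\tau+\Delta)-s(\tau)]/[1-s(\tau)]\) so that onset times follow
  \(s\) exactly regardless of step size.

Isolation is specified as a probability *per day*; each 2-hour step applies
the hazard \(1-(1-\varepsilon_I)^{1/12}\), making the daily probability
independent of the step size.

**Calibration of `beta`.** The reproduction number is measured empirically
(`estimate_R0()`): mean offspring of the index case, which is seeded — like
every scenario run — with a uniform 0–10-day initial infection age, so part
of its infectious period is already spent. `calibrate_beta()` adjusts `beta`
by damped proportional updates until this quantity hits the target 1.64 on
the baseline network (`p = 5`, `eps_I = 0.1`, `eps_T = 0`). The shipped
default `beta` is the result of that calibration; re-running it (or the
CLI's `calibrate-beta`) reproduces it to Monte-Carlo error. The index
seeding convention matters: observing a *fresh* infection instead
(`index_tau0 = 0`) roughly doubles the measured offspring mean, and
calibrating to that definition produces epidemics far too weak to match the
scenario peaks this model is meant to exhibit.

## Knowledge: multi-strain threshold contagion with memory

20 independent pieces of knowledge start on one uniformly chosen node each
(independent draws; a node may hold two pieces by chance — with
\(N = 680\) collisions are rare). A node acquires piece \(k\) after
accumulating `K` contacts with nodes holding \(k\); exposures never decay
and acquisition is irreversible (multi-strain SI). Contacts with the same
holder in different layers each count: the threshold is on *interactions*,
not distinct partners.

Cadence matters: exposures accumulate on every 2-hour layer, but acquisition
becomes *transmissible* only at the daily update — a node that crosses the
threshold at noon holds the piece, yet starts spreading it the next day.
This mirrors the different natural timescales of infection events and of
productive knowledge exchange.

**Choice of `K`.** The threshold is the one knowledge parameter with no
reported value, and the dynamics are extremely sensitive to it: because
exposures are cumulative, diffusion is explosive once a piece has a handful
of holders, and with `K = 3` at this contact density the whole 680-node
population acquires everything within about two weeks even without bubbles.
`K` is therefore calibrated once, the same way `beta` is: it is set to the
smallest value for which the bubble-knowledge milestone (mean knowledge
reaching one bubble's initial endowment, 2 pieces) in the
`p = 199`, `eps_T = 0` scenario lands at the reported day-43 timescale. The
calibrated default is stated in `knowledge_params()`; all milestone-based
results should be read as conditional on this choice.

## Coupling, indicators and ensembles

Each 2-hour step: sample the layer (honouring the active matching), strip
all edges touching confined nodes, log surviving contacts for tracing, run
transmission, run progression (isolations trace immediately), accumulate
knowledge exposures. Each simulated day ends with the knowledge update. The
indicator set (`indicators()`):

* **Peak simultaneous infected** — maximum over time of the *ensemble-mean*
  curve of active infected + isolated + true-positive quarantined (the
  epidemiologically meaningful load), as a count and % of `N`. Taking the
  peak of the mean curve (not the mean of per-run peaks) smooths over run
  asynchrony; per-run peaks are also reported for dispersion.
* **Knowledge milestones** — first days the population mean reaches 2, 10
  and 16 pieces (one bubble's endowment, 50%, 80%), at daily resolution
  without interpolation; never-crossed milestones are `NA`.
* **Collateral confinement** — % of the population confined at least once
  while never infected: the social cost of quarantining on suspicion.
* **Realized modularity** \(\hat p\) — realized intra-density over
  inter-density per window, with pair counts restricted to unconfined
  nodes; windows without inter-bubble links give `NA`, not `Inf`. This
  diagnostic verifies that confinement thins both link classes
  proportionally, so the configured `p` remains meaningful throughout a run.
  Under pairing, \(\hat p\) is computed against the uniform inter-pair
  denominator (the `p` the generator was configured with); the matched-pair
  density is `p_pair`-boosted by construction and is not separately
  reported.

Ensembles derive one sub-seed per run from `master_seed` (drawn once up
front), making every ensemble bit-reproducible; runs, layers, disease and
knowledge all share the run's stream. Runs stop early when no infected
remain and mean knowledge has passed 80%, after which the epidemic series is
exactly constant and the knowledge series is frozen at its last value (a
lower bound that cannot affect milestones at or below 80%).

## Numerical choices and degenerate inputs

* Infection ages advance by 1/12 day; natural recovery uses a `1e-9`
  tolerance so accumulated floating error cannot add a spurious
  transmission step.
* If several infectors succeed on one susceptible in the same step, the
  attributed infector is drawn at random (relevant only for offspring
  counting).
* Exposure counters freeze at `K`; within one layer, simultaneous exposures
  from several holders are aggregated, matching a per-contact sequential
  recount exactly because counters cap at the threshold.
* Single-bubble configurations are allowed (`p_inter = 0`); sampling guards
  the empty inter-pair table, and the realized-modularity ratio is `NA`.
* Matched-pair boosts failing `p_pair <= 1` raise an error rather than
  silently truncating the link budget.
* The tracing log is a rolling 84-step (7-day) ring buffer; contacts age
  out exactly at the window edge.

## Problem sizes

Shipped defaults run the full 680-node reference population. The test suite
and the acceptance script use 50-run ensembles for scenario indicators
(against 200 in the design they reproduce), 1000+ simulations for
reproduction-number estimates, and 15–25-run ensembles on reduced horizons
for monotonicity and sweep properties; these sizes give Monte-Carlo errors
comfortably below the tolerances being checked while keeping a full run of
the suite inexpensive. Sweep grids default to `p` in {5, 199} plus a
log-spaced range, `eps_I` in {0.1, 0.25, 0.4} and pairing periods
`d` in {5, 10, 20} days.

## Known limitations

* The infectiousness and onset curves are literature-shaped, not fitted;
  absolute peak heights inherit that uncertainty even after `beta`
  calibration.
* i.i.d. layers understate tracing efficacy relative to real contact
  networks, where repeated contacts make traced partners likelier to be the
  actual infectors.
* Knowledge milestone times are conditional on the calibrated `K`; only
  their *relative* behaviour across `p`, `d` and `eps_T` is robust.
* No reinfection, vaccination, testing delay, age or household structure;
  bubbles are the only population structure.
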