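---
title: "Modelling microbe-induced host altruism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling microbe-induced host altruism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microaltruism)
```

## The model

Hosts carry exactly one of two microbe types. Type $\alpha$ manipulates its
host into acting altruistically; type $\beta$ has no behavioural effect.
Hosts interact in pairs with a prisoner's-dilemma payoff: an altruist pays a
fitness cost $c$ and its partner receives a benefit $b > c$. All hosts may
additionally share a genetic baseline of altruism, paying $c_g$ and
conferring $b_g$ per interaction, so an $\alpha$-carrier pays $c_g + c$ and
confers $b_g + b$. During an interaction each microbe may transmit
horizontally to, and establish in, the partner host, replacing the resident
microbe: $\alpha$ with probability $T_\alpha$, $\beta$ with probability
$T_\beta$, independently; when both establish they do so simultaneously, so
the pair swaps microbes. At reproduction an offspring inherits its parent's
microbe with probability $VT$ (vertical transmission) and otherwise picks up
the microbe of a random member of the parent population (fully mixed model)
or of the parent's neighbourhood (lattice model).

Payoffs are always computed from the pair's states *before* any transmission
in the same interaction — behaviour is attributed to the microbe resident at
the moment of the act — and transmission is applied immediately afterwards,
so a convert behaves (and transmits) as an $\alpha$-carrier in its later
interactions of the same generation.

## The fully mixed recursion

With $p$ the proportion of newborn $\alpha$-carriers, random pairing gives
discordant pairs at frequency $2p(1-p)$, each contributing an expected
$1 + T_\alpha - T_\beta$ $\alpha$-carriers after the transmission lottery, so
the post-interaction proportion is
$\tilde p = p + p(1-p)(T_\alpha - T_\beta)$
(`post_interaction_proportion()`). Mean fitness is
$\bar w = 1 + b_g - c_g + p(b - c)$ (`mean_fitness()`). The next generation
combines fitness-weighted vertical transmission with random acquisition:

$$p' = VT \cdot \frac{p^2 f_{\alpha\alpha} + p(1-p)\,[\,f_{\alpha\beta}(1-T_\beta) + f_{\beta\alpha}T_\alpha\,]}{\bar w} + (1 - VT)\,\tilde p$$

with $f_{\alpha\alpha} = 1 + b_g + b - c_g - c$,
$f_{\alpha\beta} = 1 + b_g - c_g - c$ and
$f_{\beta\alpha} = 1 + b_g + b - c_g$ (`next_generation_proportion()`).
The non-vertical route draws uniformly from the post-interaction parent
population (proportion $\tilde p$), not fitness-weighted — a random microbe,
not a random successful parent.

Rearranging $p' > p$ gives the signed spread margin used by
`spread_condition()`:

$$p' - p = p(1-p)\left[ VT\,\frac{b T_\alpha - c(1 - T_\beta) - (1 + b_g - c_g)(T_\beta - T_\alpha)}{\bar w(p)} + (1 - VT)(T_\alpha - T_\beta) \right].$$

With $VT = 1$ the sign is independent of $p$: when the bracket is positive,
$\alpha$ sweeps to fixation even from rarity. With $b_g = c_g = 0$ it
reduces to $b\,T_\alpha > c(1 - T_\beta) + (T_\beta - T_\alpha)$, a
Hamilton-like rule in which $T_\alpha$ plays the role of relatedness: with
probability $T_\alpha$ the beneficiary of the act carries, after the
interaction, relatives of the manipulating microbe. With equal transmission
$T_\alpha = T_\beta = T$ the $(T_\beta - T_\alpha)$ terms cancel and the
threshold is $b/c > (1 - T)/T$, for every $VT > 0$ and every $p$ — so for
$T = 0.1, 0.01, 0.001$ the critical ratios are exactly $9, 99, 999$.
`critical_bc_ratio()` solves the rare-invader condition either in closed
form or by bisection on $b$ over the recursion itself; the two agree to
$10^{-6}$ and the bisection route is what the reproduction script uses.

Two conventions were genuinely open and are fixed as follows. The
rare-invader limit $p \to 0$ (where $\bar w \to 1 + b_g - c_g$) defines the
reported threshold; for $VT < 1$ and $T_\alpha \neq T_\beta$ the sign of
$p' - p$ can in principle depend on $p$ through $\bar w$, and
`spread_condition()` over a $p$ grid serves as the diagnostic. Fixed points
are found by iteration (`iterate_mixed()`), not root-finding: the map is
one-dimensional and cheap, and iteration also yields the approach rate —
imperfect vertical transmission slows the sweep without moving the
endpoint. Convergence is declared at $|p' - p| < 10^{-12}$.

The control in which altruism is encoded by a host allele (cost
$c_g$, benefit $b_g$, perfect inheritance, no horizontal transfer) follows
$p' = p(1 - c_g + p b_g)/(1 + p(b_g - c_g))$
(`genetic_next_generation()`), which declines for every $p \in (0,1)$
whenever the cost is positive: genetically encoded altruism cannot evolve
in a fully mixed population.

### Parameters

| parameter | meaning | typical values here |
|---|---|---|
| $b$, $c$ | benefit and cost of the act (fitness units per interaction) | $c = 0.05$; $b$ set via $b/c$ |
| $b_g$, $c_g$ | baseline benefit/cost paid by every host | 0 unless studying baselines |
| $T_\alpha$, $T_\beta$ | per-interaction horizontal transmission and establishment | $10^{-3}$–$1$ |
| $VT$ | vertical-transmission fidelity | $0.25$–$1$ |
| $K$ | interactions initiated per host per generation (lattice) | 1 or 8 |

$c = 0.05$ is the cost used throughout the simulation experiments; only
$b/c$ matters for the analytic threshold under equal transmission, while in
the lattice model the absolute scale of $c$ also sets the payoff noise per
interaction.

## The finite-population check

`mixed_population_step()` and `estimate_delta_p()` implement an
independent, stochastic realisation of the same generation at finite $N$:
a uniform random perfect matching, one interaction per pair, fitness
$1 + \text{payoff}$, Wright–Fisher (fitness-proportional, with replacement)
reproduction, then the vertical-transmission lottery. Nothing is shared
with the recursion except the parameter object, so agreement is evidence,
not tautology. The test suite compares the mean one-generation change at
$N = 10^5$ over 200 replicates with the recursion across a 20-point
parameter grid at three standard errors, and checks the threshold case
$b/c = 9$, $T = 0.1$ (mean change statistically zero) and the neutral case
$b = c = 0$ (a martingale). Fitness-proportional sampling is an oracle
convention: any scheme whose expected offspring share is proportional to
fitness converges to the same infinite-population limit.

## The lattice simulator

`run_lattice_sim()` places one host per site on a non-toroidal grid
(default $100 \times 100$). A generation consists of $K$ sweeps; each sweep
visits every site in a freshly randomised order, and the visited host
interacts with one uniformly chosen Moore neighbour (8 neighbours in the
interior, 5 on edges, 3 in corners). Both participants accumulate the
payoff and an interaction count; fitness is accumulated payoff divided by
interactions participated in. In microbe mode, horizontal transmission is
resolved immediately after each interaction's payoff, on current states.
Reproduction follows Nowak and May: every site of the new grid is a copy of
the fittest host among the site and its neighbours, ties broken uniformly
at random (ties are common — e.g. all-zero neighbourhoods — so the
tie-break is part of the documented RNG stream). The offspring takes the
parent's end-of-generation microbe; with probability $1 - VT$ it instead
takes the microbe of a uniformly chosen member of the old neighbourhood,
site included. Genetic mode is identical except that hosts carry alleles:
vertical transmission is perfect and nothing transmits horizontally.

Because no-op random draws are skipped (transmission draws when
$T_\alpha = T_\beta = 0$ or in genetic mode; vertical-transmission draws
when $VT = 1$), microbe mode with $T = 0, VT = 1$ and genetic mode consume
identical RNG streams: under a shared seed their trajectories are equal
site-for-site, which the suite asserts on a $50 \times 50$ grid over 20
seeds. The inner loop is C++ (via Rcpp) because within-generation state
updates make the interaction phase inherently sequential; all randomness
comes from R's generator, so `set.seed()` governs everything.

Initial conditions are an exact count of randomly placed altruist carriers
(`lattice_init_random()`: "5% occupancy" means exactly
$\mathrm{round}(0.05\,n)$ sites, removing initial-condition variance) or a
central $2 \times 2$ patch (`lattice_init_patch()`, $p_0 = 4 \times 10^{-4}$
on the default grid).

### Stopping

A run stops when $p$ hits an absorbing target (0 and 1, or 0 and 0.05 for
invasion experiments), stabilises, or reaches the generation cap of 10,000
(in which case the proportion at the cap is reported). Stabilisation
compares the two most recent non-overlapping 200-generation means of $p$
and declares stability when they differ by at most 0.01 (inclusive, fixed
for determinism), evaluated only after generation 400. The smoothed form
ignores fast oscillation but catches slow ramps: a drift of
0.001/generation shifts the window means by 0.2 and keeps the run alive.

## Experiments and verification scale

`threshold_table()` tabulates critical $b/c$ curves;
`sweep_lattice()` runs the final-proportion sweep over $(T, b/c)$ cells
with a genetic-control column, and `invasion_probability()` estimates the
chance a $2 \times 2$ patch reaches $p = 0.05$ before extinction, with
Wilson score intervals (appropriate in the small-probability regime; no
continuity correction). Per-replicate seeds derive deterministically from
(base seed, cell index, replicate index), so every cell is independently
reproducible; sweeps are bit-identical across runs.

Routine verification uses deliberately modest problem sizes: 30 replicates
per sweep cell on the full $100 \times 100$ grid and 5,000 invasion runs
for the neutral bound, against a one-sided binomial test at the neutral
fixation probability $4/10{,}000$ — the chance that a neutral 4-site patch
drifts to fixation in a population of $10^4$ sites. Full-scale studies (100+ replicates per cell, $\ge 15{,}000$
invasion runs per point) use the same functions with larger `replicates`.

The sweep cells checked routinely straddle the analytic boundary: the
genetic control dies at every $b/c$ at $K = 1$; microbe mode with $T = 0.1$
dies at $b/c = 2$ (below the threshold of 9) and persists at $b/c = 20$;
with $T = 0.3$ or $0.5$, $b/c$ well above $(1-T)/T$ gives fixation in
essentially all runs. Persistence above the boundary is not always
fixation: part of the parameter range yields a stable polymorphism, which
the stopping rule classifies as `stabilized` — the sweep's outcome tallies
expose this band directly.

## What the generator does and does not emulate

The synthetic inputs are the model's own study conditions — there is no
external data. The lattice emulates local interaction, local transmission,
drift and limited dispersal; it does not emulate host mortality schedules,
variable group sizes, multi-strain microbiomes, host recognition of
partners, or co-evolution of transmission rates (the microbe pair is
fixed). Passing tests therefore show internal consistency of the model and
agreement between three independent realisations of it (recursion,
finite-$N$ simulator, lattice in its mixing limits) — not that real
microbiomes induce altruism.

## Known limitations

* The critical-threshold convention for $VT < 1$ with unequal transmission
  is the rare-invader limit; thresholds at intermediate $p$ can differ and
  must be read off `spread_condition()` directly.
* The stabilisation rule can classify a very slow sweep (change below
  0.01 per 200 generations) as stable; the generation cap bounds the error.
* Lattice results near the boundary between extinction and polymorphism
  are sensitive to the replicate count; the sweep reports outcome tallies
  so that boundary cells can be re-run at higher replication.
* The two-type assumption (one microbe per host) excludes within-host
  competition; an equal carriage cost folds into $c_g$, a differential one
  into $c$.
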