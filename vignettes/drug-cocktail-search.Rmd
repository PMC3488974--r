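---
title: "Stochastic search for potent multi-drug combinations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic search for potent multi-drug combinations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aruopt)
```

## The optimization problem

Combination therapy searches for a *drug cocktail*: a vector
$\mathbf{x} = (x_1, \dots, x_N)$ where drug $n$ takes one of $M_n$
pre-specified concentrations $C_n = \{c_{n1} < \dots < c_{nM_n}\}$. The
search space $X = C_1 \times \dots \times C_N$ holds
$M = \prod_n M_n$ combinations — already 1.77 million for six drugs at
eleven levels each — while every tested combination costs a wet-lab
measurement. The normalized response $f(\mathbf{x}) \in [0, 1]$ scores
efficacy (0 = ineffective, 1 = grid optimum), and the goal is to find a
*potent* combination, one with $f(\mathbf{x}) \ge 0.95$, while testing as
few distinct combinations as possible.

`aruopt` implements this closed loop — measure, update the combination,
measure again — with three families of stochastic search rules, a
measurement channel with additive uniform noise, and a seeded Monte-Carlo
harness that scores success rates and testing effort.

## The search algorithms

All algorithms move one concentration level at a time, which keeps every
proposal inside the feasible grid and mirrors how a laboratory would titrate
doses.

**Gur Game automaton** (`gur_simultaneous`, `gur_sequential`). Each updated
drug draws $r_n \sim U[0,1]$ and is *rewarded* when the current observed
response exceeds $r_n$, *penalized* otherwise. Reward moves the drug one
level away from a fixed per-drug reference concentration (the median of
$C_n$; the lower middle for an even number of levels), clamped at the grid
edge; penalty moves it one level towards the reference. The simultaneous
variant updates all $N$ drugs from the same response in one iteration; the
sequential variant updates one drug per iteration in round-robin order. The
automaton never adapts to the response function, which produces its two
characteristic failure modes (both reproduced in the test suite): a response
below 0.5 everywhere concentrates the search at the reference, and a
response above 0.5 everywhere pushes it to the grid edges.

**Informed-guess baseline** (`enhanced`). For the round-robin drug $n$ the
algorithm remembers the last pair of combinations that differed only in drug
$n$ (by one level) together with their observed responses. The pair's
*virtual slope* predicts the beneficial direction — increase if the response
at the higher level was larger — and the drug moves in that direction with
the reward probability
$$g = \min\!\left(1, \tfrac{1}{2}\left(1 + \alpha \max(f_1, f_2)\right)\right) \ \ge\ 0.5,$$
and in the opposite direction otherwise. A drug with no memory yet makes a
uniformly random first probe. $\alpha \in [0,1]$ sets the randomness:
$\alpha = 0$ is a symmetric random walk, $\alpha = 1$ (the benchmark
setting) exploits past observations maximally.

**Adaptive reference update** (`aru`). Instead of the last single-level
pair, ARU compares the current combination with a *reference combination*
$\mathbf{x}^{\mathrm{ref}}$ — a previously visited point whose response
anchors a longer-range virtual slope
$\left(f(\mathbf{x}^{\mathrm{ref}}) - f(\mathbf{x}^c)\right) /
\left(x_n^{\mathrm{ref}} - x_n^c\right)$. The reference starts at the
trial's initial combination and is replaced whenever the trajectory passes a
local maximum: with observed responses $f_{t-2}, f_{t-1}, f_t$ along the
visit sequence, if $f_{t-1} > f_{t-2}$ and $f_{t-1} > f_t$ the reference
becomes the combination visited at $t-1$, keeping the response it had when
visited (it is not re-measured). Using the most recent local maximum — not
the best point ever seen — keeps the reference from freezing the search on
stale observations while still averaging over a wide concentration range,
which is what makes ARU robust to small response fluctuations. The move is
accepted in the beneficial direction with the same probability $g$ applied
to $(f(\mathbf{x}^c), f(\mathbf{x}^{\mathrm{ref}}))$.

## Design choices in under-determined cases

The per-step rules above leave several cases open; the package resolves them
as follows, and the test suite pins each choice down with enumerated
transition matrices.

* **Uninformative reference comparison (ARU).** When the updated drug's
  level equals the reference level, or the two responses are exactly equal,
  the virtual slope carries no direction. ARU then falls back to the drug's
  own last-move pair — the informed-guess comparison — and only moves
  uniformly at random when no informative pair exists either (for example at
  the start of a trial). Rationale: ARU generalizes the single-pair rule, so
  the pair is the natural recourse; discarding it would waste measurements
  the trial has already paid for, and on response plateaus (exact ties are
  common on surfaces with multiplicative zero factors) a random fallback
  turns the search into pure diffusion.
* **Grid edges.** A prescribed move off the grid leaves the drug in place
  (`edge = "clamp"`), the same convention the Gur automaton uses. The
  alternative `edge = "reflect"` (step one level inward) is available but
  measurably harms success on surfaces whose optima sit on the boundary,
  because it actively pushes the search off corner optima.
* **Gur reference ties.** The automaton's reward/penalty rules do not cover
  a drug sitting exactly at its reference level; the package moves it to a
  uniformly random feasible neighbor (deterministically inward at an edge).
* **Rosenbrock orientation.** The two-drug `dejong2` benchmark maximizes the
  min-max normalized saddle $100(x_1^2 - x_2)^2 + (1 - x_1)^2$ as-is, so the
  response optimum is the steep corner at $(-2, -2)$ and only 2 of 441
  combinations are potent — a genuinely hard instance for a
  non-adaptive automaton. `builtin_surface("dejong2", invert = TRUE)` flips
  the surface so the saddle's minimization optimum at $(1, 1)$ becomes the
  target; that variant is much easier (185 potent combinations) and is kept
  only for sensitivity checks.
* **Update order.** Sequential algorithms cycle drugs $1, \dots, N$ in
  strict round-robin order starting at drug 1. One iteration always means
  one proposed-and-observed combination, for all algorithms, so iteration
  budgets are comparable across them.

## The measurement channel

Observed responses follow $f_{\mathrm{obs}} = f_{\mathrm{true}} + \eta$ with
$\eta \sim U(-u, u)$ applied to the normalized response; benchmark noise
levels are $u \in \{0.02, 0.05, 0.08\}$. Observations are not clipped to
$[0, 1]$; the reward probability caps at 1 instead. Two revisit strategies
bracket the lab's options: type A never re-measures a combination (cheap,
but clings to a noisy first reading), type B re-measures every visit
(costly, but unbiased in the long run). Success is always judged on the
*true* response of a visited combination — the benchmark surfaces are known,
so the harness can score what an experimenter could only estimate — while
the algorithms see only the noisy observations. Each trial consumes a single
seeded RNG stream in a fixed draw order, which makes every trial bit-for-bit
reproducible from its seed; the compiled engine and the plain-R reference
engine consume that stream identically, and the test suite asserts their
bit-identity across algorithms, strategies and noise levels.

## Benchmark surfaces and what they exercise

Nine analytic response surfaces are built in (`builtin_surface()`), from the
21×21 Rosenbrock saddle to six-drug products of trigonometric and Gaussian
factors on $11^6$ grids. All are min-max normalized over their discrete
grid, so $f$ spans $[0, 1]$ exactly; normalization over the grid (not the
continuous domain) is the right choice because the algorithms only ever
visit grid points. Each surface is tabulated once into a lookup vector
(about 14 MB for the $11^6$ grids) and cached for the session, making
response evaluation O(1) during search.

These surfaces emulate specific hazards of real dose-response landscapes —
multiplicative zero plateaus, sign-changing factors, corner optima, narrow
Gaussian ridges — but not others: no biological replicate structure, no
heteroscedastic or multiplicative noise, no drug-drug interaction constraints,
and potency is a property of a single response scalar rather than an
efficacy/toxicity trade-off. Passing benchmarks here shows the search logic
is sound and efficient on hard landscapes; it does not certify performance
on any particular experimental system. For measured data, a complete-grid
CSV loads through `load_tabular_surface()` (concentration columns plus a
`response` column, one row per combination).

## Monte-Carlo settings

`run_benchmark()` repeats seeded trials from uniformly random starting
combinations. The reference setting is 5,000 trials per condition — the
binomial standard error of a success rate is then at most 0.7 points — with
iteration budgets of $2M$ for two drugs and 1,000/2,000/3,000/4,000 for
3/4/5/6 drugs. The shipped acceptance script uses the full 5,000 trials
(each benchmark takes on the order of a second through the compiled engine);
the test suite scales to 2,000 trials per benchmark and 800 per noise
condition, which keeps the whole suite near a minute while leaving
Monte-Carlo error well inside the tolerances it asserts (about ±1 point on
success rates at 2,000 trials).

Per-trial seeds are drawn once from the master seed, so any individual trial
can be replayed in isolation (`trial_seeds[k]`), and identical settings with
an identical master seed give bit-identical summaries.

## Known limitations

* The trajectory-based local-maximum rule is the one-dimensional notion
  applied along the multi-drug visit sequence; in higher dimensions
  consecutive observations differ in different drugs, so "local maximum"
  is a property of the path, not of the surface. This is the natural
  operationalization, but not the only conceivable one.
* On surfaces whose basins attract the search to the wrong edge
  (for instance `f4a`'s negative basin pushing drugs outward), success rates
  fall short of 100% under the standard budgets, and measurement noise can
  deepen this: at $u = 0.08$ several five- and six-drug surfaces lose more
  than 10 points of success rate. The noise-robustness property in the
  acceptance suite documents exactly which surfaces violate the
  graceful-degradation band.
* The α parameter is held fixed within a trial; adaptive schedules, larger
  jumps, and other metaheuristics are out of scope by design.
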