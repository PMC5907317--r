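---
title: "Coordinated Q-learning and norm emergence under limited communication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinated Q-learning and norm emergence under limited communication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coordnorm)
```

## The problem

Populations of interacting units — cells signalling their neighbours,
sensors sharing coverage duties, agents in a multi-agent system — often
need to settle on a *common convention* (a social norm) although no unit
sees the whole population and communication is expensive. `coordnorm`
simulates this process. Agents sit on the nodes of an undirected network
and repeatedly play a pairwise coordination game with each neighbour:
both endpoints of an edge receive `+1` when they choose the same action
and `-1` otherwise, so with `m` actions there are `m` equivalent optimal
conventions and the population has to break the symmetry collectively.
The global reward of a joint action decomposes over the edges of this
*coordination graph*,

$$R(\vec a) = \sum_{(i,j)\in E} r(a_i, a_j),$$

and a norm has emerged when the greedy joint policy attains the optimal
average edge payoff of 1 — every adjacent pair matched.

The built-in `sensor_fixture()` illustrates why coordination (rather than
independent greed) is needed: four sensors on a path can cover three
locations worth 30/50/40 when *two* sensors watch the same location.
Independent learners crowd the single best location (global reward 50),
while the optimal joint policy covers the two flanking locations for 70.

## The learning architecture

Three pieces work together each round:

1. **Edge-factored cooperative Q-learning.** One table
   $Q_{ij}(a_i, a_j)$ per undirected edge, shared by both endpoints,
   updated from the executed actions and the observed edge reward:
   $Q_{ij} \leftarrow (1-\alpha) Q_{ij} + \alpha\,[r + \gamma\,
   Q_{ij}(a_i^*, a_j^*)]$, where $(a_i^*, a_j^*)$ is the coordinated
   joint action selected this round, restricted to the edge.

2. **Max-plus action selection.** The coordinated joint action is found
   by message passing on the (active part of the) coordination graph:
   agent $i$ sends its neighbour $j$ a vector
   $\mu_{ij}(a_j) = \max_{a_i}\{Q_{ij}(a_i,a_j) + \sum_{k} \mu_{ki}(a_i)\}$
   (incoming messages from the other active neighbours), mean-centred to
   keep values bounded; after the sweeps each agent plays
   $\arg\max_{a_i} \sum_k \mu_{ki}(a_i)$. On trees this is exact; on
   loopy graphs it is a well-behaved heuristic. Exploration is
   $\varepsilon$-greedy on top of the coordinated choice, with
   $\varepsilon$ decaying linearly per round.

3. **Coordination-set selection.** To save communication each agent
   chooses, every round, the subset $CS(i) \subseteq \tau(i)$ of
   neighbours it exchanges messages with. An edge is active when either
   endpoint selected the other. Strategies:
   * `all` — full coordination;
   * `random` — keep each neighbour independently with probability
     $\delta$ (a *keep* fraction);
   * `decayed_random` — as `random`, with $\delta$ shrinking per round;
   * `loss_rate` — drop the neighbours whose loss of *potential value*
     stays within a budget. The potential value of action $a_i$ under a
     coordination set credits coordinated neighbours with their best
     response and predicted ones with the expected Q-value under the
     empirical conditional frequencies $P_k(a_k \mid a_i)$
     (Laplace-smoothed joint counts); the *potential loss* of a dropped
     set is the drop in the maximised potential value. Neighbours are
     removed greedily while $PL \le \delta \cdot PL(\tau(i))$, so here
     $\delta$ is an allowed *loss* fraction: 0 keeps everyone whenever
     dropping anyone would cost utility, 1 drops everyone. Note the
     deliberate semantics inversion between the two $\delta$s, preserved
     from their definitions.

Agents that end up with no active edge in a round act greedily on the
expected Q-value of all their edges under the empirical neighbour model —
they follow the locally prevailing convention rather than moving at
random, which is what makes very sparse coordination (small keep
fractions) viable.

Message cost accounting: every max-plus sweep sends two directed messages
per active edge; the distributed-value-function baseline (DVF) counts one
Q-vector exchange per directed neighbour pair per round; independent
learners (IL) communicate nothing.

## Design choices in the open corners

Several details matter empirically and were genuinely open; the package's
choices and the reasons:

* **Sweep schedule.** `run_maxplus()` supports synchronous (Jacobi)
  sweeps and sequential Gauss–Seidel sweeps in a fresh random order per
  iteration; the default is sequential. With a deadline of 5 sweeps,
  synchronous message passing on loopy graphs routinely freezes the
  population into a patchwork of two or three local conventions whose
  boundaries messages cannot move (five hops of influence are not enough
  once domains have self-reinforced). Sequential random-order sweeps both
  propagate information across the whole graph within a sweep and add a
  small stochastic relaxation that melts domain walls while exploration
  is still high; at 100 agents / 10 actions this is the difference
  between ~50% and ~100% of runs reaching the norm. The sequential
  schedule is also the natural reading of a per-agent, continuously
  communicating protocol.

* **Discount $\gamma$ (default 0).** The repeated game has a single
  state, and the experiment tables list no discount. With large
  $\gamma$ the bootstrap term $\gamma Q(a^*)$ drives *visited* cells
  towards $\pm 1/(1-\gamma)$ while rarely visited cross-convention cells
  stay near zero. A frozen two-convention split then literally becomes
  the argmax of the learned values — no optimizer can escape it, because
  the learned tables, not the true game, are what selection maximises.
  With $\gamma = 0$ the tables track recency-weighted empirical payoffs
  (the true $\pm 1$ structure), boundary regions remain contestable, and
  late mergers stay possible. $\gamma$ is config-exposed
  (`learning$gamma`) for study.

* **Sticky tie-breaking in the loop.** Early in a run all values tie, so
  a memoryless uniform tie-break would re-randomise every agent every
  round and delay symmetry breaking. In the experiment loop an agent
  keeps its previous coordinated choice while it is still within
  tolerance of the maximum, and only re-draws (uniformly) when strictly
  beaten. The stateless module surface `select_action()` keeps the plain
  uniform tie-break.

* **Message normalisation.** The centring constant is realised as
  subtracting each outgoing message's mean — bounded drift, argmax
  invariant (asserted by a shift-invariance test).

* **Selection uses all active neighbours.** Messages exist in both
  directions of every active edge (the active set is the symmetric union
  of one-sided selections), so an agent sums incoming messages over its
  *active* neighbours, including those that selected it one-sidedly;
  discarding that information would waste messages already paid for.

* **Warm-started messages** (`maxplus$warm_start`) are available but off
  by default: coordination sets change per round, and zero-initialised
  sweeps proved at least as reliable in every tested condition once the
  sequential schedule was in place.

* **Loss-rate search.** The best coordination set under a loss budget is
  found greedily (cheapest neighbour first); monotonicity of the
  potential loss under set inclusion makes the greedy order admissible,
  and an exhaustive subset-enumeration oracle validates it in the tests.
  The $\delta = 1$ endpoint unconditionally empties the set; at
  $\delta = 0$ the whole neighbourhood is kept whenever dropping anyone
  would lose utility.

* **Neighbour model.** Conditional joint counts with Laplace smoothing
  $\lambda = 1$ (uniform before any observation). The conditional form
  $P_k(a_k \mid a_i)$ is used as written in the loss-rate definitions.

## What the simulations emulate — and what they do not

The synthetic experiment generator reproduces the study conditions:
populations of 50–1000 agents on regular / Erdős–Rényi / Watts–Strogatz /
Barabási–Albert networks of mean degree 6 (rewiring 0.1 and attachment
parameter 3 where unstated), 2–10 actions, learning rate decaying
1.0 → 0.6 at 0.0005/round, exploration decaying from 1.0 at
0.003–0.004/round (0.04 for IL), max-plus deadline 5 and tolerance 1e-5.
A run is declared converged when the greedy evaluation (exploration
switched off) sits at the optimal average edge payoff for 10 consecutive
rounds; `early_stop` then ends the run.

These are stylised conditions: payoffs are noiseless and identical across
edges, actions are synchronous, the network is static, and every agent
observes its neighbours' actions perfectly. Passing tests therefore show
that the algorithms behave as described under the stated model — not that
real cell populations or sensor deployments will.

Problem sizes in the tests and the acceptance script are the study's own
(100 agents, 10 actions, 20 seeds, up to 2000 rounds; population scaling
up to 500 agents at fixed degree), with early stopping at confirmed
convergence.

## A worked run

```{r example}
cfg <- experiment_config(
  topology = list(kind = "small_world", n = 100, k = 6, beta = 0.1),
  game     = list(n_actions = 10),
  csselect = list(strategy = "loss_rate", delta = 0.7),
  learning = list(epsilon = list(init = 1, delta = 0.004, floor = 0)),
  rounds = 2000, seed = 1)
res <- run_experiment(cfg)
attr(res, "converged_round")
tail(res[, c("round", "greedy_payoff", "adoption_fraction", "messages_cum")], 3)
```

The run converges when all 100 agents share one action
(`adoption_fraction` 1, `greedy_payoff` 1); `messages_cum` counts every
directed max-plus message sent, the currency in which limited
communication is measured.

## Known limitations

* Loopy max-plus carries no optimality guarantee; exactness is only
  asserted (and tested) on trees.
* The engine's experiment loop requires one payoff table shared by all
  edges; heterogeneous per-edge tables (as in the sensor fixture) are
  supported by the module functions but not by `run_experiment()`.
* Convergence detection is an operationalisation (sustained greedy
  optimum over a window); the original study never defines its criterion.
* Multi-state problems, eligibility traces, damping, and exact
  junction-tree inference are out of scope.
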