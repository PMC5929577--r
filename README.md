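# compclust

Nonparametric Bayesian agents for studying *compositional* generalization
of task structure. In grid-world navigation, each context (an observable
cue) carries two separable pieces of a Markov decision process: a reward
function (a hidden goal worth +1) and a mapping function φ_c that assigns
eight primitive actions to the four cardinal movements. `compclust`
implements agents that transfer these pieces across contexts by
clustering contexts with a Chinese restaurant process (CRP) prior,

    Pr(c ∈ k) = N_k / (N + α)   for an existing cluster k,
                α  / (N + α)    for a new cluster,

combined with the likelihood of the observed movements and rewards,
Pr(c ∈ k | D) ∝ Pr(D | k) Pr(c ∈ k). The **independent** agent keeps two
partitions (one per function; compositional transfer), the **joint**
agent one partition carrying both (holistic transfer), and the **flat**
agent none. Planning is model-based: value iteration over the known
spatial kernel and the MAP reward estimate, softmax movement selection
Pr(A|x) ∝ exp(βQ(x,A)), and marginalization through the estimated mapping
Pr(a|x) ∝ Σ_A φ̂(A|a) Pr(A|x). Two meta-agents arbitrate between the
independent and joint strategies from reward-prediction evidence
(Thompson sampling on Pr(m|D) ≈ Z⁻¹ Π_t Pr(r_t|m) Pr(m), or a prediction-
error value learner Q_m ← Q_m + η(r_t − r̂_t)). An accompanying
information-theoretic module scores the CRP as a bare sequence predictor
under the information-gain loss −log₂ q to delimit when independent or
joint clustering generalizes better as a function of the mutual
information I(R;T) between the two functions and of observation noise.

Who this is for: computational cognitive scientists and RL researchers
who want a reproducible, tested reference implementation of
context-clustering agents, the "diabolical rooms" compounding-cost
benchmark, and the accompanying sequence-prediction analysis.

## Worked example

Four contexts crossing two goals with two mappings (so knowing one
function says nothing about the other), 16 trials, three agents:

```r
library(compclust)

dom <- make_sim1_domain(seed = 3)
dom
#> <task_domain sim1: 6x6 grid, 4 contexts (2 mappings x 2 goals), 16 trials>

for (agent in c("independent", "joint", "flat")) {
  rec <- run_episode(dom, agent, agent_config(), seed = 1)
  cat(sprintf("%-12s %4d total steps\n", agent, rec$total_steps))
}
#> independent  247 total steps
#> joint        278 total steps
#> flat         242 total steps
```

Fewer steps means faster learning-plus-transfer. Because reward and
mapping assignments are uncorrelated here, the independent agent can
reuse each goal across the two contexts sharing it and each mapping
across the two contexts sharing *that*, while the joint agent must treat
every (goal, mapping) combination as a new cluster. Single-domain totals
are noisy — on this particular domain and seed the flat agent happens to
edge out the independent one — so the orderings are claims about means:
averaged over 150 seeded domains (`scripts/acceptance.R` below) the
agents take ≈216 (independent), ≈260 (joint) and ≈262 (flat) steps. On
the dependent-statistics protocol (`make_sim2_domain()`, where the
mapping predicts the goal) the order reverses, with joint clustering
ahead.

The partition the independent agent inferred:

```r
rec <- run_episode(dom, "independent", agent_config(), seed = 1)
belief_partition(rec$final_models$independent$rew_belief)
#>   context_id cluster
#> 1         c2       1
#> 2         c1       2
#> 3         c3       2
#> 4         c4       1
```

Contexts c1/c3 share one goal and c2/c4 the other in this domain: the
reward partition is recovered exactly.

The sequence-prediction analysis runs in milliseconds:

```r
mi_sweep(n = 5)[, c("m", "mutual_information", "independent_advantage")]
#>   m mutual_information independent_advantage
#> 1 0         0.00000000              3.688117
#> 2 1         0.02904941              3.044261
#> 3 2         0.11870910              1.044261
#> 4 3         0.27807191             -2.570449
#> 5 4         0.53100441             -8.570449
#> 6 5         1.00000000            -16.910299
```

Positive advantage (in bits over the 20-item sequence): independent
clustering predicts the upcoming reward function more cheaply; the sign
flips once the mutual information between reward and transition labels
exceeds ≈0.2 bits.

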