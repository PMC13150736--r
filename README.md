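# nnmo — evolving recurrent neural-network model objects

`nnmo` is a heuristic, fully transparent model of an evolving biological
system, built to study two linked questions that are practically untestable
on real organisms: **are the outcomes of evolution reproducible**, and
**what does the set of all equally fit structures look like?**

The evolving agent is a small fully connected recurrent neural network — a
*neural network model object* (NNMO). Its synapse matrix
$x \in \mathbb{R}^{n\times n}$ is the heritable structure; its fitness is
performance on a stimulus-recognition task in a quasi-random event stream;
and its modification rule is a mirrored random search (mutation plus
selection, nothing else). The dynamics are

$$\alpha_i^k = \tanh\!\big(a\,\rho_i^k\big), \qquad
  \rho_i^k = \sum_j x_{ij}\,\alpha_j^{k-1} + A_i^k,$$

with two input neurons receiving the signal $A^k$ over the alphabet
pause $(0,0)$, A $(1,0)$, B $(0,1)$, C $(1,1)$, and two output neurons that
must produce a sustained $(1,1)$ whenever the most recent processed stimulus
was the task's "correct" one (tasks **A3**, **C4**: correct stimulus A or C,
3- or 4-tick processing window).

Because the activation is odd, the input–output function of a trained
network is exactly invariant under per-hidden-neuron sign changes and
hidden-neuron permutations. The functional-symmetry group for $K$ hidden
(associative) neurons has order

$$N = 2^K\,K!$$

(doubled by the input-neuron swap for tasks like C4 whose correct code is
symmetric), so an ensemble of independently evolved networks falls into $N$
structural clusters of identical fitness: equifinality in its sharpest
form. The package provides, per module:

* **net_core** — network dynamics, goal (loss) function, recognition-error
  counting (`nn_step()`, `run_stream()`, `goal_function()`,
  `recognition_errors()`);
* **event_stream** — seeded quasi-random task environments
  (`generate_stream()`, `task_spec()`, `swap_AB()`);
* **evolution** — the mirrored random-search trainer with restart protocol,
  ensembles and trajectory-divergence experiments (`evolve()`,
  `evolve_restarts()`, `train_ensemble()`, `trajectory_divergence()`);
* **symmetry** — the invariance group, cluster-count prediction, orbit
  canonicalisation, ensemble geometry (`enumerate_group()`,
  `predicted_cluster_count()`, `canonicalize()`, `pairwise_distances()`,
  `cluster_count()`, `distance_modality()`, `project3d()`);
* **reduction** — complexity reduction by smallest-synapse pruning with
  retraining, network compaction, the randomised-synapse negative control,
  and minimal-size search (`reduce_network()`, `compact_network()`,
  `randomize_control()`, `min_network_search()`);
* **experiments** — scripted, manifest-writing experiment driver and a
  command-line interface (`run_experiment()`, `inst/cli/nnmo.R`).

See `vignette("functional-symmetry")` for the full model description and
design rationale.

## Worked example

Train one 6-neuron network on A3, check the symmetry prediction, and reduce
the trained structure to its functional minimum:

```r
library(nnmo)

net  <- network_config(6)           # 2 input, 2 output, K = 2 hidden
task <- task_spec("A3")
cfg  <- train_config(max_generations = 20000)

res <- evolve_restarts(net, task, cfg, max_attempts = 10, base_seed = 42)
res
#> <nnmo_train_result> task A3: success after 16130 generations; final goal 16.46, 0 errors

# functional symmetry: sign-flipping a hidden neuron's row and column
# leaves every output tick unchanged
s  <- generate_stream(task, stream_config(rng_seed = 1))
tr <- invariant_transform(c(1, 2), c(-1, 1))
max(abs(run_stream(apply_transform(res$weights, tr, net), s, net) -
        run_stream(res$weights, s, net)))
#> [1] 0

predicted_cluster_count(K = 2)                       # A3 ensembles
#> [1] 8
predicted_cluster_count(K = 2, input_swap_allowed = TRUE)  # C4 ensembles
#> [1] 16

red <- reduce_network(res$weights, net, task, cfg,
                      retrain_budget = 10000, restarts = 5, base_seed = 99)
red$report
#> $functional_complexity
#> [1] 18
#>
#> $potential_complexity
#> [1] 36
#>
#> $redundancy
#> [1] 18

evaluate_network(red$weights, generate_stream(task, stream_config(rng_seed = 777)), net)
#>     goal   errors
#> 20.50265  0.00000
```

The trained network commits zero recognition errors (confirmed on 100
fresh validation fragments); the transformed network's output trace agrees
with the original's exactly (the computational content of "equal fitness
across the cluster structure"); and this particular replicate prunes the
36-synapse structure down to 18 non-zero synapses while still running
error-free on a fresh stream — reduction is a stochastic upper-bound
estimator, so the reproduction protocol takes the best over 10 independent
replicates, which reaches the functional minimum (typically around 13
synapses).

A command-line driver wraps the same experiments:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/nnmo.R", package = "nnmo"))') \
    ensemble --task A3 --runs 8 --seed 1 --out runs/a3
```

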