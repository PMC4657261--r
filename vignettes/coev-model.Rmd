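---
title: "The coupled-pair model of coevolving sites: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The coupled-pair model of coevolving sites: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Standard phylogenetic simulators and substitution models treat every
alignment column independently, which makes them useless for benchmarking
methods that look for *coevolving* positions — pairs of sites whose
substitutions are coordinated, as in Watson–Crick-paired RNA stems or
contacting residues in proteins. `coevolve` instead treats a pair of
positions as a single continuous-time Markov chain on the coupled
pair-state space: ordered pairs of letters from one alphabet, i.e. 16
states for nucleotides and 400 for the 20 amino acids.

The chain is parameterised by four strictly positive rates and one
discrete object, the *coevolution profile* $\phi$: a set of at least two
pair-states whose position-1 letters are all distinct and whose position-2
letters are all distinct (an injective matching — any two members therefore
differ at both positions). For states $i \neq j$ the generator is

$$
Q_{ij} = \begin{cases}
0 & i,j \text{ differ at both positions}\\
s & i \in \phi,\ j \notin \phi\\
d & i \notin \phi,\ j \in \phi\\
r_1 & i,j \notin \phi, \text{ differ at position 1}\\
r_2 & i,j \notin \phi, \text{ differ at position 2}
\end{cases}
$$

with the diagonal set so rows sum to zero. Because profile members differ
at both positions, the first rule also covers profile-to-profile moves;
we fix this rule precedence explicitly (double-difference first, then the
membership rules, then $r_1$/$r_2$). The ratio $d/s$ measures the strength
of coevolution: $d/s = 1$ means none, larger values mean the chain is
pulled into the profile faster than it leaks out.

A point that matters in practice: the number of *routes* out of a profile
state is $2(n-1)$ (every single-letter change leaves $\phi$), while
re-entry happens only from the few states adjacent to a member. Holding
occupancy therefore requires a much larger $d/s$ for amino acids
($n = 20$, 38 exit routes per state) than for nucleotides ($n = 4$,
6 routes). A nucleotide pair with $s = r_1 = r_2 = 1$, $d = 20$ spends
roughly 74% of its stationary time in a two-state profile; an amino-acid
pair needs $d$ in the several hundreds for comparable occupancy. The
examples and tests choose parameters per alphabet accordingly.

### Profile combinatorics

A profile of size $k$ chooses $k$ position-1 letters, $k$ position-2
letters and a bijection between them; dividing by the $k!$ orderings of
the set gives $\binom{n}{k}^2 k!$ profiles of size $k$ and

$$\sum_{k=2}^{n} \Big[\tfrac{n!}{(n-k)!}\Big]^2 \tfrac{1}{k!}$$

in total: 192 for $n = 4$ (72, 96 and 24 of sizes 2, 3, 4) and about
$1.7\times 10^{21}$ for $n = 20$. `count_profiles()` computes the sum in
exact integer arithmetic (a small built-in base-$10^7$ bignum, since the
$n = 20$ value overflows doubles) and returns the exact decimal string as
an attribute. `enumerate_profiles()` does the exhaustive enumeration and
refuses alphabets larger than 8 letters; `random_profile()` samples
uniformly over the *whole* profile space by first drawing the size from
the exact per-size counts. Uniformity over profiles is our choice — the
sampling distribution of the original platform is not documented.

## Likelihood and model comparison

Given a rooted binary tree with branch lengths (both assumed known, never
estimated) and the pair-states observed at the leaves, `prune_loglik()`
computes $\log \Pr(X \mid \phi, s, d, r_1, r_2, \tau, \nu)$ by
Felsenstein pruning: leaf partials are indicator vectors, each edge
applies $P(t) = e^{Qt}$, and the root sums against a root distribution
that defaults to the stationary distribution $\pi$ of the *model being
scored* (mirroring the simulator's root draw). `brute_force_loglik()` is
an independent oracle that enumerates all internal-node state assignments
explicitly (trees of up to 6 leaves) with each $P(t)$ computed by Padé
scaling-and-squaring; the test suite holds the two routes together at
1e-8 on hundreds of random instances.

The coevolution score is
$\Delta \mathrm{AIC} = \mathrm{AIC}_{\text{indep}} - \mathrm{AIC}_{\text{Coev}}$
with $\mathrm{AIC} = 2k - 2\log L$; positive values favour coevolution.
The independent null substitutes positions independently: single
position-1 changes at $r_1$, position-2 changes at $r_2$, no double
changes. We fit its two rates by ML but count $k_{\text{indep}} = 3$
(and $k_{\text{Coev}} = 4$) by default; the profile is treated as model
*structure* and not penalised. Both counts are arguments of
`delta_aic()` and of `evaluate_pair_ml()`'s config, because neither the
null's exact form nor the penalisation of a discrete structure is
settled — an alternative null is the product of two single-site chains,
which we deliberately did not guess at.

## Numerical choices

* **No rate normalisation.** $Q$ is *not* scaled to one expected
  substitution per unit time; branch lengths are read in $Q$'s natural
  time units. Simulator and evaluator share the convention, and the
  likelihood is exactly invariant under (double all branch lengths, halve
  all rates), so absolute rates are identified only relative to the
  branch-length unit while $d/s$ is scale-free.
* **Matrix exponentials.** The public `transition_matrix()` uses Padé
  scaling-and-squaring (`Matrix::expm`). The likelihood kernel instead
  eigendecomposes $Q$ once per parameter set and propagates each edge as
  $V\,(e^{\lambda t} \circ (V^{-1} L))$ — two small matrix–vector
  products per edge. If the eigenbasis fails to reconstruct $Q$ to 1e-9
  (defective or ill-conditioned cases) the kernel falls back to
  scaling-and-squaring per edge. Zero-length edges short-circuit to the
  identity exactly. Partials are rescaled per edge with the log scale
  accumulated, so trees with hundreds of leaves do not underflow.
* **Exact state lumping for amino acids.** For a given data set and
  profile, letters that are neither observed at any leaf nor part of the
  profile are exchangeable under the rates above, so the chain is
  strongly lumpable: they aggregate into one wildcard letter per position
  carrying a multiplicity weight on incoming rates. The lumped generator
  yields *identical* likelihoods (asserted against the full 400-state
  space in the tests) at a fraction of the cost; this is what makes
  amino-acid evaluation tractable.
* **Stationary distributions** solve the augmented least-squares system
  $[Q^\top; \mathbf{1}]\,\pi = [\mathbf{0}; 1]$, with a residual check
  that reports non-irreducibility.

## Maximum-likelihood fitting

Rates are optimised in log space by Nelder–Mead inside
$[10^{-4}, 10^3]^4$ (a soft penalty pushes proposals back into the box),
started from a fixed $3\times3$ grid over $(d/s, r_1)$ with $s = 1$ and
$r_2 = r_1$. `optimize_rates()` runs a local search from every grid point
("full" mode). The exhaustive nucleotide search fits all 192 profiles;
to keep 192 fits affordable its *ranking* phase starts a single search
from the best-scoring grid point per profile ("fast" mode, capped
iterations), after which the top-ranked profiles are refitted with the
full multi-start before the final ranking. On the simulations in the test
suite the two-phase scheme reproduces the single-phase ranking at about a
ninth of the cost. Everything is deterministic: no randomness enters the
ML path, so identical inputs give identical fits. Fits at the box
boundary or without optimiser convergence are flagged, not hidden — the
degenerate all-leaves-identical input (normally impossible after
curation, which drops constant columns) is the canonical flagged case.

The amino-acid profile space cannot be enumerated, and the original
platform's search strategy is undocumented; ours is an explicit
heuristic, not a reconstruction. Candidates are built from the
pair-states actually observed at the leaves: all injective subsets of the
(up to 12 most frequent) observed pairs of sizes 2 to `k_max` (default
6), prioritised by summed member frequency, capped at `max_candidates`
(default 500), then ranked like the nucleotide search. If no two observed
pairs are injective-compatible there is no valid candidate and the result
says so explicitly.

## Bayesian evaluation

`run_mcmc()` is a Metropolis–Hastings sampler over
$(s, d, r_1, r_2, \phi)$. All conventions below are our documented
choices; none are specified by the method's public description:

* **Priors:** independent Exponential(mean 10) on each rate — weakly
  informative and covering the 1–100 range the experiments use; uniform
  over all profiles (nucleotides) or over the observation-driven
  candidate set (amino acids).
* **Moves:** each iteration picks uniformly among five moves — a
  log-scale multiplier update of one of the four rates (factor
  $1.5^{U(-1,1)}$, Jacobian included in the acceptance ratio), or a
  profile move. Nucleotide profile moves propose uniformly from the
  neighbour set (swap one member's position-2 letter with an unused
  letter; add a member pair on unused letters; remove a member while
  keeping size $\ge 2$) with the $|N(\phi)|/|N(\phi')|$ Hastings
  correction; amino-acid moves are independence draws from the candidate
  set. These moves reach every profile (position-1 letters turn over
  through add/remove).
* **Schedule:** `burnin` counts iterations; the first recorded sample
  sits at `burnin + sample_freq`, then every `sample_freq` iterations.
  With 10,000 iterations, burn-in 1,000 and frequency 1,000 that is nine
  records at iterations 2,000–10,000. Recommended production settings
  are 1,000,000 / 1,000 / 1,000.

`write_tracer_log()` emits a tab-delimited log whose columns are all
numeric (`state`, posterior, likelihood, prior, the four rates, `d/s`) so
Tracer can read it; the profile chain goes to a `.profiles.tsv` sidecar.
Prior-only runs of the sampler reproduce the exponential prior
(batch-means and KS checks in the test suite), and on strongly coevolving
simulated data the posterior mass on $d/s > 1$ exceeds 0.9.

## The simulator

`simulate_pairs()` draws one shared profile for all pairs (matching the
"same coevolving profile" semantics of the original form), then for each
pair independently draws a root state from $\pi(Q)$ and walks the tree
pre-order. Whether the platform draws one root state for all pairs or one
per pair is not stated; we draw per pair, since pairs are independent
given the shared profile. Two branch samplers are provided and tested
against each other (two-sample chi-square on end-state laws):

* `"expm"`: child state drawn from the parent's row of $P(t)$ (the
  transition matrices are cached per edge);
* `"gillespie"` (default): exponential waiting times at rate $-Q_{ii}$
  and jumps from the embedded chain $Q_{ij}/(-Q_{ii})$.

Pair $i$ lands in columns $2i-1, 2i$ of a FASTA-writable alignment; the
CLI adds a JSON sidecar with the profile, parameters, seed and per-pair
root states.

## Data curation and coordinates

Evaluation filters the alignment first: a column is removed if it
contains a gap, any symbol outside the declared alphabet (ambiguity codes
such as N, R, Y or X count as outside — the strict reading of the
nucleotide alphabet {A, C, G, T}), or if it is fully conserved; the first
matching reason in the order gap, non-alphabet, conserved is recorded.
User-facing positions are 1-based on the *original* alignment (what a
user sees in their uploaded file) and are mapped through the curation
report; asking for a removed column is an error that names the reason,
never a silent shift. Alignment taxa must equal the tree's leaf set
exactly — extras are an error, not silently pruned, because silent
pruning hides upload mistakes.

## The scripted experiments

`subtree_swap_experiment()` rebuilds the co-inheritance control at desk
scale: two random subtrees of $m$ leaves joined at the root, one
pair-state combination (default AA) assigned to the first subtree's
leaves and another differing at both positions (default TT) to the
second, then leaves exchanged one pair per step. At each step it records
the number of lineages with double substitutions and the ML
$\Delta$AIC of the two synthetic columns. Two definitions were open and
are fixed here: "exchanging two combinations" means swapping one leaf
from each side per step (cyclically, so steps beyond $m$ begin undoing
earlier ones — the recorded (count, $\Delta$AIC) pairs remain valid
points); and the double-substitution count is the Fitch parsimony change
count of the two-colouring on the known leaf assignment (via
`phangorn::parsimony()`), which is 1 for the clean split. The package
ships the desk-scale default ($m = 10$, 20 swaps); the original design
used 50-leaf subtrees and 100 swaps and is available by argument.

`ds_sweep_experiment()` evolves the profile {AA, CC} along single
branches of length 0.1, 0.5, 1 and 5: per replicate $r_1, r_2 \sim
U(1, 100)$, $s = 1$, $d = $ ratio, root states drawn from $\pi(Q)$, 1000
end-state draws through $P(t)$, reporting the fraction of end states in
the profile. The median fraction is non-decreasing in $d/s$ at every
branch length.

`random_tree()` supplies the fixtures: random binary topology with branch
lengths from Normal(mean 0.5 by default, sd = mean/5, clamped at
$10^{-6}$) — the mean matches the published experimental design; the
standard deviation is unstated there, and sd = mean/5 is our choice,
exposed as an argument.

## What the generator does and does not emulate

Simulated data are exactly the model's own world: one pair, one profile,
homogeneous rates along the tree, no indels, no rate variation among
pairs, no mixture of coevolving and independent pairs within a call
(compose two calls for that). Passing recovery tests on these
simulations shows the estimator inverts the model, not that real
alignments satisfy the model; on real data, profile misspecification,
heterotachy and alignment error all bite and are out of scope here.

## Problem sizes and known limitations

The test suite runs at desk scale by design: oracle comparisons on trees
of 2–6 leaves, recovery and null calibration on 50-leaf trees with 20
replicates, swap experiments at 10 leaves per subtree, sweeps with 20
replicates of 1000 draws. Known limitations:

* absolute rates are only identified relative to branch-length units
  (see the scale invariance above); report $d/s$, not $\hat d$ alone;
* the amino-acid candidate heuristic can only find profiles whose
  members are observed at the leaves; a profile member that never
  reaches a leaf is invisible to it;
* AIC with a fitted discrete structure is optimistic under the null:
  choosing the best of 192 profiles is a selection over model structures
  that the default parameter counts do not penalise. In the package's
  null-calibration runs ($d = s$ simulation on 50-leaf trees) the
  selected Coev fit gains about 3–4 log-likelihood units over the
  independent fit, i.e. a mean $\Delta$AIC of roughly +5 rather than the
  $-2$ a fixed-structure comparison would give. Single-pair
  $\Delta$AIC values below ~10 should therefore not be over-read, and
  `evaluate_pair_ml()`'s `k_coev` config can be raised to penalise the
  profile explicitly;
* no multiple-testing machinery: the tool scores one pair per call.
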