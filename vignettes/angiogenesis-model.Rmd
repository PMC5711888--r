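---
title: "Methods: exact analysis of a synchronous Boolean model of endothelial cell behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact analysis of a synchronous Boolean model of endothelial cell behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model and its assumptions

angionet analyzes synchronous Boolean networks: each molecular species is a
binary variable (active/inactive), and all variables update simultaneously,
`x(t+1) = f(x(t))`, with one fixed Boolean rule per node.  The package's
centerpiece is a bundled 64-node model of a single endothelial cell (EC)
during sprouting angiogenesis, covering the ANG/TIE, HIF, AMPK/mTOR, VEGF,
IGF, FGF, PLC-gamma/Calcium, PI3K/AKT, NO, NOTCH, WNT and TGF-beta pathways
and a shear-stress mechanosensor.  Sixteen nodes describe the extracellular
micro-environment (ligand availability, oxygen, the AMP:ATP ratio, shear
stress); they carry identity self-loops, so they are constant along every
trajectory and a *micro-environment* is one of the 2^16 = 65,536 input
assignments.

The synchronous scheme is a deliberate simplification: it ignores kinetic
differences between reactions, so the *timing* of cyclic attractors is not
biologically meaningful, only their existence and composition.  Because the
state space is finite and the map deterministic, every trajectory ends in an
attractor — a fixed point (stationary activation pattern) or a cycle
(oscillating pattern).  Each attractor is read as an EC behavior via marker
signatures:

* **Tip** (migratory sprout leader): `NRP1+, DLL4a+, AKT-`
* **Stalk** (proliferative follower): `JAGa+, NRP1-`
* **Phalanx** (quiescent, stable vessel): `AKT+, JAGa-, NRP1-`

The three signatures are pairwise contradictory, so a state carries at most
one label.  An attractor inherits a label only if *all* of its states agree
on one signature; anything else — mixed cycles, or states matching no
signature — is *atypical*.  A micro-environment inherits a label only if all
its attractors agree; this is the environment-level classification the sweep
reports.  Proliferation follows cyclin-D1 logic: an attractor "divides" when
beta-catenin and LEF1 are both active in every state (a sustained growth
signal); environments are classed `all`/`some`/`none` by the share of their
attractors that divide.  The `any_state` variant of
`classify_proliferation()` exists as a documented toggle but the sustained
(`all_states`) reading is the default and is the one whose roll-up the
bundled analyses use.

## Exact attractor enumeration

All reported quantities rest on *exact* attractor sets, never on sampling.
The pipeline for one micro-environment is:

1. **Clamping**: input nodes become constants.
2. **Constant propagation**: any node whose rule evaluates to a constant
   under three-valued logic (0/1/unknown), given the constants found so far,
   is itself constant in every attractor state; this is iterated to a
   fixpoint.  The inference is sound because an attractor state is in the
   image of the update map: if `f_i` is forced to `c` by established
   constants, node `i` equals `c` in every recurrent state.  No rule in the
   bundled model repeats a variable, so per-rule three-valued evaluation is
   exact.
3. **Core enumeration**: the remaining *free core* (0-39 nodes, depending on
   the environment) is solved by one of two certified-complete backends:
   * cores of at most `brute_cap` (default 22) nodes: the full successor
     array is built 64 states at a time with bit-sliced rule evaluation, and
     the functional graph's cycles are extracted by path coloring;
   * larger cores: a reduced ordered BDD backend computes the set of
     recurrent states as the limit of the decreasing chain `f^t(full
     space)`, using partitioned transition relations with early
     quantification, then peels cycles off the fixpoint by concrete
     iteration.  Variable order is a dependency-graph DFS refined by a
     force-directed (barycenter) pass.  If the node budget
     (`bdd_node_budget`, default 3e7–6e7) is exceeded the call *fails*; a
     silent partial result is never returned.
4. **Re-embedding**: core attractors are completed with the propagated
   constants to full 64-node states.  Identical clamped cores are shared
   across environments through a memo keyed on the free-node set plus the
   constants their rules read, which collapses the 65,536 environments to
   about 1,200 distinct enumeration jobs.

Canonical attractor form: the cyclic state list rotated to start at its
minimum state under the fixed bit order (node 1 = least significant bit).
This makes attractor identity, ids and report order independent of the
discovery path.

The brute-force enumerator (`enumerate_attractors_bruteforce()`) doubles as
the oracle: the test suite checks the BDD path against it on 200 seeded
random networks (6-14 nodes, in-degrees 1-4, with and without clamped
inputs) and additionally checks the compiled brute-force path against a
plain-R evaluator on smaller fixtures, so the two production backends are
anchored to an implementation that shares no code with them.

## Sweep, mutations, transitions

`sweep_environments()` runs the pipeline above for every input assignment
and labels each environment; `mutation_scan()` repeats the sweep with one
node clamped to 0 (loss of function) or 1 (gain of function).  A mutated
input node overrides its environment bit, so the scan still reports all
65,536 codes.  Mutation effects are classified against the wild type:
`no_effect` (identical per-environment label vector), `behavior_lost` (some
signature appears in no attractor of any environment), else
`response_changed`.  The full 128-mutation scan is exact but costs several
CPU-hours; the bundled tests exercise the seven mutations with well-known
qualitative effects (loss of DLL4a/ETS/MEK/NRP1, gain of
VEGFAxxxP/VEGFC_Dp/NRP1) as a spot check, each of which reproduces its
expected outcome.

`behavior_transition()` models an environment shift around a settled cell:
starting from an attractor state, only the 16 input bits are overwritten and
the dynamics are iterated to the new attractor.  By default the start state
is verified to lie on an attractor of its own environment.

## Noise-robustness and sensitivity experiments

`robustness_experiment()` draws uniform random full 64-bit states (inputs
included), flips one uniformly chosen variable per state (inputs included —
so a quarter of perturbations change the micro-environment itself), and
iterates both copies to their attractors.  `mode = "attractor"` compares
canonical attractor identity; `mode = "behavior"` compares behavior labels.
Per-behavior fractions condition on the unperturbed trajectory's label
("relevant experiments").  Note that the two modes measure very different
things here: single-bit noise frequently moves a trajectory to a *different
attractor of the same behavior*, so behavior-level robustness (~98%) is far
higher than attractor-level robustness (~71%) under this definition of
attractor identity.

`rule_sensitivity()` estimates, for each rule, the probability that one
application of the rule differs between a random state and a one-flip copy.
Alongside the Monte-Carlo estimate the package computes the exact value — the
rule's summed Boolean influence divided by the network size — whenever the
rule's support is small (always true here; the largest support is 8).  The
estimate must sit within a few binomial standard errors of the exact value,
which the tests assert for every rule.

Randomness is deterministic: both engines use counter-based splitmix64
streams derived from the user's integer seed (one independent stream per
rule for the sensitivity scan), so identical `(n, seed)` reproduce results
bit for bit and the seed is recorded in every result object.  The trajectory
cache used by the robustness engine is a speed/memory knob only; results are
identical for any cache size, which is also tested.

## Network reduction operators

Three attractor-aware simplification operators are provided for working with
larger hand-built models: removal of inputs fixed to a constant (with
constant folding), iterative removal of out-degree-zero nodes, and edge
contraction of intermediary nodes (in- or out-degree one) that are not in a
protected set — the bundled workflow protects transcription factors.
Contraction substitutes a relay's (possibly negated) regulator, or inlines a
rule into its single reader.  Under synchronous update, inlining removes one
step of delay: fixed points are preserved exactly (tested against brute
force on seeded toys), while cyclic attractors keep their existence but may
change period, so contraction is a modeling aid rather than a
dynamics-preserving transform.  Every operator returns a replayable log;
replaying the log on the original network reproduces the reduced network
byte for byte.  Which nodes count as "transcription factors" is left to the
caller via `protected=` rather than guessed from node names.

## Random fixtures

`random_network()` generates the property-test fixtures: seed-deterministic
networks of up to 20 nodes with configurable in-degree distribution and
literal-negation probability (defaults: in-degrees 1-3 uniform, negation
0.4).  These fixtures emulate the *structural* features that matter for the
enumeration machinery — sparse rules, mixed AND/OR logic, negative
regulation, feedback — but not the biological organization of real signaling
networks (pathway modularity, input self-loops, canalizing rules), so green
property tests certify the algorithms, not the biology of any particular
model.

## Problem sizes and tolerances

The shipped test suite and the acceptance script use: the full 65,536
environment sweep (about 2 minutes); seven mutant sweeps (about 7 minutes
together); robustness at n = 10^6 replicates per mode (seconds); sensitivity
at 5 x 10^5 pairs per rule; 200 random fixtures for backend equivalence.
Monte-Carlo checks use 4-5 binomial standard errors as tolerance, never a
fitted constant.  Degenerate inputs are handled explicitly: environments
whose core propagates away completely yield the single propagated fixed
point; an empty satisfiable BDD never occurs (the recurrent set of a finite
deterministic map is nonempty); and enumeration failure (budget exhaustion)
is always an error, so downstream counts can never silently omit
environments.

## Known limitations

* The fast engine is fixed at 64 nodes (one machine word per state); larger
  networks fall back to a plain-R evaluator for stepping but not for the
  sweep machinery.
* Synchronous updating only; race conditions and update-order effects are
  out of scope, and cyclic-attractor periods should not be over-interpreted.
* The model describes a single cell; multicellular phenomena (lateral
  inhibition between neighbors, sprout geometry, lumen formation) are not
  represented.
* Attractor-level robustness depends on the identity convention for
  attractors (canonical state-set equality here); comparisons with numbers
  produced under other conventions require care.
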