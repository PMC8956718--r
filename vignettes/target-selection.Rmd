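---
title: "Selecting combination therapy targets from single-cell tumor data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting combination therapy targets from single-cell tumor data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncohit)
```

## The problem

Modular therapies — CAR-T constructs, antibody-drug conjugates, ligand-coated
nanoparticles — kill cells that display a chosen cell-surface receptor above
some recognition level. Because tumors are heterogeneous, a single target
rarely covers every malignant cell, so a *combination* of targets acting as a
logical OR is needed: a cell dies if any selected target can recognize it.
Given single-cell expression profiles of a patient's tumor and adjacent
non-tumor cells, oncohit answers two questions:

1. **Per patient** — what is the smallest set of targets that kills at least
   a fraction `lb` of the tumor cells while killing at most a fraction `ub`
   of the non-tumor cells (the *individual target set*, ITS)?
2. **Per cohort** — what is the smallest global basket of targets from which
   every patient can be treated almost individually-optimally (the *cohort
   target set*, CTS)?

## The model

Let `E(g, C)` be the expression of gene `g` in cell `C`, in whatever units
the data came in — we deliberately take measured values as is and apply no
library-size normalization or imputation, since zeros in single-cell data
mix dropouts with true silence. The reference expression of `g` is

> `E(g)` = arithmetic mean of the *non-zero* values of `g` across the
> patient's non-tumor cells,

zeros being ignored as likely dropouts. A targeted gene `g` kills cell `C`
when

> `E(g, C) > 0` and `E(g, C) >= r * E(g)`,

with `r` the expression-ratio threshold (baseline 2.0, the regime in which
superselective receptor-mediated uptake switches from no binding to near
complete binding). The comparison is inclusive. Each cell `C` thus induces
the set `S_C` of pool genes able to kill it, and a selection `H` of genes
kills `C` iff `H` intersects `S_C`: a hitting-set structure.

Two boundary rules deserve mention:

* **All-zero reference rows.** When a gene shows no non-zero expression in
  the non-tumor compartment, `E(g)` is undefined by the formula above. We
  set `E(g) = 0` and rely on the strict-positivity guard: such a gene kills
  exactly the cells that express it at all, and no measured non-tumor cell.
  This preserves the dropout logic without dividing by zero.
* **Presence mode.** With `mode = "presence"` a gene kills any cell
  expressing it above zero; this is exactly ratio mode with every reference
  forced to zero, and is the right mode for data without a non-tumor
  compartment (the suite asserts the equivalence).

### The individual problem

With `m` tumor cells and `q` non-tumor cells, `solve_its()` finds a
minimum-cardinality `H` with

* tumor cells killed `>= ceiling(lb * m)` and
* non-tumor cells killed `<= floor(ub * q)`.

The integer thresholds are what any integral formulation enforces; we apply
a `1e-9` guard so that, e.g., `lb = 0.7` with `m = 10` yields 7 and not 8
through floating-point noise. `require_full_coverage = TRUE` replaces the
first constraint with "every tumor cell is hit". Feasibility is never
guaranteed — with a small pool or strict bounds a patient may simply have no
admissible combination — and infeasibility is reported as data, not as an
error.

### The fair cohort problem

Let `H(i)` be patient `i`'s optimal ITS size computed in isolation. The
fair CTS problem minimizes the size of a global set `S*` such that every
patient can draw an assignment `A_i ⊆ S*` with `|A_i| <= H(i) + alpha`
meeting their own `lb`/`ub` bounds. The slack `alpha` is the number of
extra targets any patient may be asked to tolerate for the sake of a
smaller cohort basket; `alpha = 0` forces every patient to an
individually-optimal set, and increasing `alpha` can only shrink the
cohort set (a property the suite asserts). `alpha_sweep()` reports the
first `alpha` at which the minimum CTS size is reached. Patients with no
feasible ITS at all are dropped with a loud warning by default
(`drop_infeasible = TRUE`), mirroring the practice of omitting a patient
whose sample alone makes a whole cohort infeasible; setting it to `FALSE`
makes the cohort infeasible instead.

## The exact solver

Both problems are NP-hard set-cover relatives, but the instances arising
from a few hundred sampled cells and a receptor-restricted pool are small
enough to solve to proven optimality. oncohit ships a specialized
branch-and-bound search (C++, bitset cell masks) rather than delegating to
a general MIP library:

* **Iterative deepening** on solution cardinality `k = lb0, lb0+1, ...`,
  where `lb0` comes from the sorted single-gene coverages; the first
  feasible `k` is optimal by construction, and exhausting all `k` proves
  infeasibility.
* **Submodular coverage bound**: added coverage of any `t` further genes is
  at most the sum of the `t` largest single-gene residual gains, pruning a
  branch whose bound misses the target.
* **Monotone kill pruning**: non-tumor kills only grow along a branch, so a
  branch over budget is dead, and a gene whose own kills exceed the budget
  is excluded from the start.
* **Determinism**: genes are scanned in a fixed coverage-then-input order,
  so the same instance always returns the same optimal solution. Multiple
  optima are handled explicitly (below), not left to solver happenstance.
* **Node budget**: a configurable `node_limit` turns a runaway search into
  a distinct `"timeout"` status, never silently reported as infeasible.

The cohort search runs the same scheme over global candidate sets, with a
per-patient coverage bound at every node and, at each leaf, a per-patient
feasibility check that is itself a tiny ITS solve restricted to the
candidate set (which also yields each patient's minimum-size assignment).
One subtlety: the cohort search must *not* skip genes that add no marginal
coverage, because under the per-patient cardinality caps a "redundant" gene
can still be the only way a patient meets their cap; the individual search
can and does skip them at minimal cardinality.

Correctness is not taken on faith: the test suite compares the
branch-and-bound answers against deliberately independent brute-force
enumeration oracles (`brute_force_its()`, `brute_force_cts()`) on hundreds
of randomized instances, demanding exact agreement on both optimal size and
feasibility status.

A note on counted kills: a naive "kill indicator at least the max of its
genes" linearization lets a tumor cell be counted as killed without any
selected gene covering it, vacuously satisfying the `lb` constraint. The
solver counts a cell as killed only when a selected gene actually covers
it, i.e. kill indicators are tied to genuine coverage on the tumor side;
on the non-tumor side any cover must be counted. `kill_report()` verifies
every returned solution against its incidence directly.

## Multiple optima and summaries

Optimal solutions are typically not unique. `enumerate_optima()` first
proves the optimum size, then exhaustively enumerates the distinct optimal
solutions (capped at `max_distinct`) by the same pruned search without
early stopping, and finally draws `k_draws` (default 50) solutions
uniformly with replacement under a seed. Every draw is an exact optimum;
when few distinct optima exist, draws repeat. `gene_frequencies()` turns
the draws into per-gene and per-pair occurrence frequencies (the sum of
gene frequencies equals the mean solution size), and
`cooccurrence_report()` aggregates across replicates, counting for each
gene the number of replicates whose optima ever use it — both the
"fraction of sampled solutions" and the "replicates containing the gene"
views are reported because they answer different questions.

## The greedy baseline

`greedy_its()` is a control, not a recommendation: it adds, at each step,
the single gene (or in `pair_mode` also the gene pair) newly covering the
most tumor cells among candidates that keep cumulative non-tumor kills
within the allowance, breaking ties by fewer new kills, then fewer genes,
then lexicographic order. The exact scoring details of historical greedy
controls for this problem are not published, so this rule is our own
precise formulation; results are labelled `"feasible"` rather than
`"optimal"` since greedy carries no proof, and the suite asserts greedy
never undercuts the exact optimum.

## Sampling and preprocessing

* `filter_low_coverage_cells()` removes cells expressing fewer than 10% of
  the genes in the file (strict "fewer than"; raise to 20% for lightly
  filtered data). It runs before any gene-pool reduction, so the
  denominator is the full gene list.
* `sample_replicate()` draws `min(c, m)` cells without replacement from
  the union of a patient's tumor and non-tumor cells and re-partitions
  them; defaults are 20 replicates of `c = 500` cells. Sampling is per
  patient: the downstream solves are per patient, and a per-dataset pooled
  draw would let one patient's cell count perturb another's replicate.
  Reference expressions are recomputed from each replicate's own non-tumor
  cells, because sampling redefines the non-tumor compartment.
* Seeding: one base seed; the stream for (patient, replicate) is derived by
  a stable string hash, so adding a patient or replicate never changes any
  other draw, and identical configurations give byte-identical outputs.
* `filter_by_normal_tissue_expression()` restricts the pool to genes whose
  mean TPM across tissues is strictly below a threshold in *both* of two
  normal-tissue tables; genes missing from either table fail the filter —
  absence of evidence of low expression is not treated as evidence of
  safety. The retained pool grows monotonically with the threshold.

## Synthetic data

Two generators make every solver testable without any external download.

`make_demo_cohort()` builds the package's worked example: three patients,
two tumor cells each, five pool genes, where patient `i`'s cells are
killable by `{APP, Target i}` and `{MET, Target i}`. Each `H(i) = 1`; at
`alpha = 0` the optimal cohort set is the three private targets (size 3),
at `alpha = 1` it is `{APP, MET}` (size 2) with every patient one target
over their individual optimum.

`generate_planted_cohort()` draws log-normal background expression
(per-gene scale spread 0.25, `meanlog = 0`, `sdlog = 0.3`) with independent
dropout zeroing (default 0.3), then plants `k_star` genes: each tumor cell
is assigned one planted gene round-robin and expresses it at `rho` times
that gene's expected non-zero background mean. Defaults (5 patients,
100 genes, 150 + 150 cells per patient, `k_star = 4`, `rho = 4`) are chosen
so that at `r = 2, lb = 0.8, ub = 0.1` the planted set is feasible with a
wide margin (`rho = 2r`), each planted gene covers about a quarter of every
patient's tumor cells so no three genes reach the coverage target, and the
narrow background spread keeps non-planted genes weak decoys (chance
coverage well under 1% of cells, far below the 30% weak-decoy cap the
recovery tests assert). The ground truth ships alongside the matrices so
tests never re-derive it.

What the generator does *not* emulate: platform-specific depth differences
(SmartSeq2 vs droplet counts), doublets, batch effects, correlated gene
modules, or mean-variance relationships of real counts. Passing the
recovery tests therefore shows the optimization machinery finds planted
combinatorial structure under dropout noise — it does not certify
performance on any real tumor data set, where decoys can be strong and
reference expressions heavy-tailed.

## Problem sizes used by the test suite

The suite solves ~200 randomized individual instances (up to 12 genes,
40 cells) and 150 cohort instances (3 patients, up to 10 genes, slack 0–2)
against the brute-force oracles, and 20 seeded planted cohorts at the full
default scale above; these sizes give the oracles exhaustive coverage while
keeping a complete run around half a minute on one core.

## Known limitations

* Exactness is practical, not asymptotic: pools of thousands of genes with
  large optima can exhaust the node budget; the `"timeout"` status makes
  that explicit, and the replicate protocol (hundreds of cells, restricted
  receptor pools) is the intended operating regime.
* The model is logical OR only — no AND/NOT gating, no mutation-aware
  targeting, no per-gene costs.
* Killability is a hard threshold on a ratio of means; stochastic
  expression and measurement error are not modelled beyond the dropout
  convention in `E(g)`.

## A worked run

```{r example}
fix <- make_demo_cohort()
compute_h_values(fix$instances, fair_params(full_coverage = TRUE))
r1 <- solve_fair_cts(fix$instances, fair_params(alpha = 1, full_coverage = TRUE))
glance(r1)
sw <- alpha_sweep(fix$instances, fair_params(full_coverage = TRUE), alpha_max = 3)
sw
attr(sw, "best_alpha")
```
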