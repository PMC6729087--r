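---
title: "Incremental meta-docking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incremental meta-docking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r load}
library(incrdock)
```

# The problem

Docking predicts how a small molecule (the *ligand*) binds a rigid protein
receptor. The search space is the ligand's placement — three translations,
three rotations — plus one dihedral angle per rotatable bond. Stochastic
engines in the AutoDock Vina family handle up to roughly a dozen rotatable
bonds well; beyond that, a single run rarely finds poses near the true
binding mode, because the search volume grows exponentially with the number
of degrees of freedom (DoFs).

`incrdock` implements and compares three responses to that problem:

* **single** — one engine call, compensating with a high exhaustiveness;
* **multi** — many short independent engine calls with distinct seeds,
  pooling all returned binding modes;
* **incremental** — dock a small fragment of the ligand first, keep its
  best placements, grow the fragment by a few bonds, re-dock, and repeat
  until the whole ligand is reconstructed in the binding site.

The incremental strategy is the interesting one: every round searches a
low-dimensional space (a constant number of actively sampled bonds), and the
placement information found in early rounds — where the anchor fragment sits
in the pocket — is transmitted to later rounds. This is most valuable for
buried binding sites, where a whole-ligand run must thread a large flexible
molecule into a constricted cavity in one step.

# Torsion trees and fragments

A ligand is decomposed into a *torsion tree*: maximal rigid groups (atoms
connected by non-rotatable bonds) as nodes, rotatable bonds as edges. A bond
is rotatable when it is a non-ring single bond between two heavy atoms each
carrying at least one further heavy neighbour, and is not an amide-like
bond. The root is the largest rigid group (ties broken by lowest atom
serial), matching the convention of PDBQT tools.

```{r tree}
lig <- make_branched_ligand(6L, seed = 7L)
tree <- build_torsion_tree(lig)
count_dofs(lig)
count_heavy_atoms(lig)
```

The incremental schedule is plain algebra: with $N$ rotatable bonds, $r$
rounds and $b$ new bonds per round, the *fragment size* (number of actively
sampled bonds per round) is $k = N - (r-1)\,b$, and round $i$ has explored
$k + (i-1)b$ bonds. Only the $k$ most recently explored bonds are active;
older bonds are frozen at their docked dihedral values.

```{r schedule}
make_schedule(n_dofs = 6, rounds = 3, new_bonds = 2)
```

The initial fragment is the root group plus the first $k$ branches in
breadth-first order. `expand_fragment()` grows a docked fragment pose by the
next $b$ bonds, transplanting the reference internal geometry of the new
atoms into the current pose's local frame, so existing atoms do not move and
frozen torsions keep their values exactly (the reconstruction identity is
tested to $10^{-6}$ Å).

# The built-in engine

To keep everything offline and deterministic, the package ships a small
seeded stochastic engine with the output conventions of Vina-family tools.
The scoring function is a charge-free empirical contact score: every
receptor/ligand heavy-atom pair within 8 Å contributes a Gaussian well
$-0.05\,e^{-(s/0.5)^2}$ in the gap $s = d - (r_i + r_j)$, plus a repulsive
wall $0.8\,s^2$ when $s<0$; ligand-internal heavy pairs at graph distance
$\ge 3$ contribute the wall when $s < -0.5$. Lower is better.

An engine call performs `4 * exhaustiveness` independent runs. Each run
draws a random conformation (uniform active torsions, uniform orientation,
translation uniform in the box, hard clashes rejected) and refines it by
cyclic coordinate descent over translation, rotation and active torsions
with step halving. The refined poses are clustered at 1 Å heavy-atom RMSD
and filtered by `num_modes` and `energy_range` — the familiar multi-MODEL
output contract. Everything is a pure function of the seed.

```{r engine}
cplx <- plant_complex(n_dofs = 4L, seed = 104L, box_padding = 2)
pool <- dock(cplx, engine_config(exhaustiveness = 4, seed = 1L))
head(vapply(pool$poses, `[[`, 0, "score"), 3)
```

An adapter (`dock_external()`) drives any real Vina-compatible binary
through the conventional command-line contract instead, writing PDBQT
inputs and parsing multi-MODEL PDBQT output back into the same pose-pool
type.

# Planted complexes

Synthetic fixtures make the evaluation fully offline. `plant_complex()`
first embeds a random branched all-carbon ligand with the requested number
of rotatable bonds, then builds a snug concave receptor around a chosen
"planted" pose: a spherical-shell wall whose mouth narrows above the
ligand, plus lining atoms that give every heavy atom a near-contact
partner. Construction gates guarantee the planted pose is bound (score
$\le -1$), enclosed, and a local minimum of the score under small rigid and
torsional perturbations. The planted pose then plays the role a crystal
structure plays in redocking studies: the reference answer the protocols
must recover.

# Evaluation

Redocking quality is measured by all-atom, no-superposition, heavy-atom
RMSD to the reference pose. Two summaries matter:

* `top_scoring()` — the pose the scoring function ranks first (what a
  blind user would pick);
* `top_rmsd()` — the pool's best pose by RMSD (the *sampling power*: did
  the search produce anything near the answer at all?).

A pose is a success when its RMSD is strictly below 2 Å. Pooling obeys the
identity `top_rmsd(A ∪ B) = min(top_rmsd(A), top_rmsd(B))`, which makes the
multi protocol's value additive and monotone: with nested seed sets, more
instances can only improve the pooled top-RMSD.

```{r protocols}
cfg <- protocol_config("multi", instances = 4L,
                       engine = engine_config(exhaustiveness = 2),
                       master_seed = 11L)
top_rmsd(run_multi(cplx, cfg), cplx$ligand)$rmsd
```

# Protocol orchestration and budget accounting

One "thread" is one engine call per round, so incremental docking with $T$
threads and $r$ rounds costs $rT$ engine calls — directly comparable to a
multi protocol with $n = rT$ instances, or a single call with matched total
exhaustiveness. The run log carried by every pose pool (one row per engine
call: round, lineage, seed, exhaustiveness, internal runs, best score)
makes budget-matched comparisons auditable.

Round 1 of the incremental protocol docks the initial fragment with $T$
independent calls. Each later round selects `expansion_size` diverse
well-scored poses (greedy score-ordered selection with a 1 Å diversity
filter), grows each into its own lineage, and docks every lineage with
$\lceil T/m \rceil$ calls. Two mechanisms transmit placement information
between rounds:

* the docking box of a lineage adapts to its carried pose (fragment extent
  plus a 3 Å margin) instead of the full binding-site box;
* half of each call's runs start *anchored* at the carried pose — only the
  round's freshly added torsions are resampled, plus a small rigid-body
  perturbation — while the other half are randomized freely, so the search
  both exploits and re-examines what earlier rounds found.

Only the last round's full-ligand poses are returned.

```{r incremental}
inc <- protocol_config("incremental", threads = 4L, rounds = 2L,
                       new_bonds = 2L, expansion_size = 2L,
                       engine = engine_config(exhaustiveness = 2),
                       master_seed = 11L)
top_rmsd(run_incremental(cplx, inc), cplx$ligand)$rmsd
```

# What the test suite pins down

The acceptance tests assert, among other things: the RMSD metric axioms and
the pooling identity; the schedule algebra and the fragment reconstruction
identity; PDB/PDBQT round-trips; that the engine's best pose on a
single-atom spherical-shell fixture matches a brute-force 0.25 Å
grid-search oracle; that pooled success rates are monotone in the instance
count on nested seeds; and the headline stochastic ordering — on planted
complexes with 6–10 DoFs at an equal engine-call budget, the median
top-RMSD of multi is at least as good as single, and incremental at least
as good as multi.
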