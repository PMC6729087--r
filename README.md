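# incrdock

Parallelized incremental meta-docking of flexible ligands, as a
self-contained, fully offline R package.

## The science

Protein–ligand docking searches for the pose (placement plus internal
dihedral angles) of a small molecule in a rigid receptor that minimizes a
scoring function. Stochastic engines of the AutoDock Vina family are
effective up to roughly a dozen rotatable bonds; past that, a single run
rarely samples anything near the true binding mode, because the
conformational space grows exponentially with the number of degrees of
freedom. Large peptide-like ligands, and ligands binding buried,
constricted sites, are exactly where plain docking breaks down.

`incrdock` implements the *incremental meta-docking* answer to this
problem, alongside the two baselines it is measured against:

* **single** — one engine call with a high exhaustiveness;
* **multi** — many short independent engine calls with distinct seeds,
  whose pose pools are merged (meta-docking: pooling can only improve the
  pool's best pose);
* **incremental** — decompose the ligand into a torsion tree of rigid
  groups, dock a small initial fragment with only `k` actively sampled
  bonds, select diverse well-scored poses, grow each by `b` bonds
  (transplanting reference geometry into the docked pose, so frozen bonds
  keep their dihedral values), and re-dock — for `r` rounds, until the full
  ligand is reconstructed in the site. With `N` rotatable bonds the
  schedule keeps `k = N − (r−1)·b` bonds active per round, so every round
  is a low-dimensional search, and the placement found by early rounds is
  carried into later ones (adaptive boxes around the carried pose, and
  runs anchored at it).

Everything runs offline: a built-in seeded stochastic engine (randomize +
coordinate-descent refinement over an empirical contact score, Vina-style
multi-mode output, deterministic given its seed), a generator of synthetic
pocket/ligand complexes with *planted* reference poses playing the role of
crystal structures, and a redocking evaluation layer (all-atom
no-superposition RMSD, top-RMSD vs top-scoring poses, strict 2 Å success
calls, replicate statistics, benchmark tables). An adapter can drive any
real Vina-compatible binary through the standard CLI contract, and PDB /
torsion-tree PDBQT readers and writers connect the package to real
structure files.

## Worked example

A planted 7-bond complex; three protocols at an equal budget of 96
exhaustiveness-units (one E96 call vs. twelve E8 calls vs. 4 threads × 3
rounds at E8):

```r
library(incrdock)

# a synthetic buried-pocket complex: 7 rotatable bonds, planted reference pose
cplx <- plant_complex(n_dofs = 7L, seed = 101L, box_padding = 2)
cplx
#> <planted_complex> receptor 103 atoms | ligand 12 atoms, 7 rotatable bonds
#>   box center (1.0, -1.9, 2.7), size (14.6, 14.6, 14.6) A

single <- run_single(cplx, protocol_config("single",
            engine = engine_config(exhaustiveness = 96), master_seed = 1L))
multi <- run_multi(cplx, protocol_config("multi", instances = 12L,
            engine = engine_config(exhaustiveness = 8), master_seed = 1L))
inc <- run_incremental(cplx, protocol_config("incremental", threads = 4L,
            rounds = 3L, new_bonds = 2L, expansion_size = 2L,
            engine = engine_config(exhaustiveness = 8), master_seed = 1L))

# how close did each protocol's pool get to the planted pose? (top-RMSD, A)
sapply(list(single = single, multi = multi, incremental = inc),
       function(p) round(top_rmsd(p, cplx$ligand)$rmsd, 2))
#>      single       multi incremental
#>        5.43        5.66        0.94

# the run log makes the budget auditable (one row per engine call;
# the incremental pool carries its final round's calls)
head(inc$log, 4)
#>   round lineage instance       seed exhaustiveness n_runs n_failed best_score
#> 1     3       1        1 1740152555              8     32       13  -1.485459
#> 2     3       1        2 1573076427              8     32       14  -1.486458
#> 3     3       2        1  353075173              8     32       13   1.214602
#> 4     3       2        2  185999045              8     32       12   1.214921
```

The whole-ligand protocols cannot thread 7 flexible bonds into this
constricted pocket and stall above 5 Å; the incremental protocol docks the
small head fragment first and grows it in place, recovering the planted
pose to under 1 Å. On the package's full benchmark (10 planted complexes
with 6–10 rotatable bonds, 20 master seeds, same equal budget) the median
top-RMSDs order as incremental ≤ multi ≤ single, which is what the
acceptance tests assert.

The methods vignette (`vignettes/incremental-docking.Rmd`) walks through
the torsion-tree decomposition, the schedule algebra, the engine, the
planted fixtures and the evaluation conventions in detail.

## Reproduction

```sh
# install (from the package root)
R CMD INSTALL .

# run the full test suite against the installed package
Rscript -e 'testthat::test_dir("tests/testthat", package = "incrdock",
                               load_package = "installed")'

# acceptance report: all randomness derives from --seed
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

The test suite is fully offline and deterministic; the acceptance script
writes the headline quantities (grid-oracle deviation, protocol medians
and success rates, pooling monotonicity, prepared-fixture statistics) as
JSON.
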