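# netdiv

Phylogenetic diversity optimization on rooted phylogenetic networks.

Conservation planning often asks: *which m taxa preserve the most
evolutionary history?*  On a phylogenetic tree this is Faith's PD and a
simple greedy algorithm finds all optimal taxon sets.  Real evolutionary
histories, however, contain reticulate events (hybridization,
recombination, lateral transfer) and are modelled by rooted phylogenetic
networks — weighted rooted DAGs whose in-degree ≥ 2 nodes (reticulations)
have out-degree 1 and whose leaves are the taxa.  There the natural measure
is the **rooted Phylogenetic Subnet Diversity** (rPSD, a.k.a. AllPaths-PD):

    rPSD_N(X) = Σ { w(e) : arc e has a descendant leaf in X }

Maximizing rPSD over size-m leaf sets is NP-hard in general, and the
single-leaf exchange property behind the tree greedy fails on even the
simplest non-tree networks.  `netdiv` implements the machinery that repairs
it: exchange-pair families S_{k,d} parameterized by the network's level k
(max reticulations per biconnected blob) and arity d (max reticulation
in-degree), within which an improving leaf swap is always guaranteed, and
the exact greedy optimizers they license:

| class | algorithm |
|---|---|
| trees (level 0) | `greedy_tree()` — classical single-leaf greedy |
| galled trees (semibinary level 1) | `greedy_galled()` — add a leaf or swap 1-for-2 |
| semibinary level 2 / semi-3-ary level 1 | `greedy_level2()` — pools up to 1-for-3 swaps |
| anything harder | `brute_force_opt()` + `gap_scan()` empirical harness |

Around the core: eNewick (hybrid-node `#H` convention) and edge-list TSV
I/O, blob decomposition / level / arity classification, exhaustive checkers
for the monotonicity–subadditivity–submodularity of rPSD, improving-pair
search and verification, seeded random network generators, and a `netdiv`
command-line interface (`inst/cli/netdiv.R`).

## Worked example

The package ships the canonical four-leaf galled tree on which the naive
greedy breaks (`example1_fixture()`): leaves x1..x4, one reticulation H
reachable from both children of an internal node s.

```r
library(netdiv)
net <- example1_fixture()

rpsd(net, c("x2", "x4"))
#> [1] 10
rpsd(net, c("x1", "x3", "x4"))
#> [1] 13

# no single leaf can be moved from {x1,x3,x4} to {x2,x4} without loss ...
find_improving_pair(net, c("x1","x3","x4"), c("x2","x4"), swap_family("s0"))
#> NULL
# ... but the two-for-one swap ({x1,x3}, {x2}) restores the exchange
find_improving_pair(net, c("x1","x3","x4"), c("x2","x4"),
                    swap_family("skd", k = 1, d = 2))
#> $A
#> [1] "x1" "x3"
#> $B
#> [1] "x2"

optimize_rpsd(net)   # auto-routes to the galled-tree greedy
#> optimal sequence (greedy_galled):
#>   m=0 value=0 sets=1
#>   m=1 value=6 sets=1
#>   m=2 value=10 sets=1
#>   m=3 value=13 sets=1
#>   m=4 value=14 sets=1
```

The value column is the maximum rPSD among all leaf sets of size m (weight
units = branch-length units); the optimal pair {x2,x4} and optimal triple
{x1,x3,x4} are unique and do **not** nest, which is exactly why the greedy
must be allowed to swap leaves, not only add them.

Same computations from the shell:

```sh
Rscript inst/cli/netdiv.R score -n example1.enewick -X x2,x4        # 10
Rscript inst/cli/netdiv.R optimize -n example1.enewick --all-m
Rscript inst/cli/netdiv.R scan --class level3-semibinary --n-leaves 8 \
        --reps 200 --seed 1 --max-j 3
```

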