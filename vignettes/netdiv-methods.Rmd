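---
title: "Subnet diversity on rooted phylogenetic networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subnet diversity on rooted phylogenetic networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netdiv)
```

## The measure

Faith's phylogenetic diversity (PD) scores a set of taxa placed at the
leaves of a weighted phylogenetic tree by the total branch length of the
subtree spanning the root and those leaves.  Reticulate evolution —
hybridization, recombination, lateral transfer — is not representable in a
tree; on a rooted phylogenetic network (a rooted DAG whose in-degree-2-or-
more nodes, the *reticulations*, have out-degree 1 and whose leaves carry
taxon labels) the natural generalization is the *rooted Phylogenetic Subnet
Diversity*, also known as AllPaths-PD:

$$\mathrm{rPSD}_N(X) \;=\; \sum_{e \in \uparrow X} w(e),$$

the total weight of all arcs with some descendant leaf in $X$.  `rpsd()`
evaluates this by one reverse reachability sweep from $X$, in $O(|E|)$ per
query; `rpsd_table()` evaluates all $2^n$ subsets at once by adding each
arc's weight to every subset that intersects the cluster (descendant leaf
set) of the arc's head, with subsets encoded as bitmasks.

rPSD is monotone nondecreasing, subadditive and submodular on every
network; `check_monotone()`, `check_subadditive()` and `check_submodular()`
verify these inequalities exhaustively on small inputs and are themselves
validated in the test suite against deliberately broken value functions.

## Network structure

Structural queries reduce to the *blob decomposition*: a blob is a
biconnected component (of the underlying undirected graph) with more than
two nodes.  Each blob has a unique *split node* ancestral to all its nodes,
and its reticulations with no child inside the blob are its *exit
reticulations*.  The *level* of a network is the maximum number of
reticulations in one biconnected component (level 0 = tree), and the
*arity* is the maximum reticulation in-degree (semibinary = arity at most
2; a galled tree is a semibinary level-1 network).  Biconnectivity is
delegated to igraph; a brute-force node-removal characterization — two arcs
share a biconnected component exactly when no single vertex removal
separates them — serves as the independent cross-check in the tests.

## The exchange property and the swap families

On trees, PD satisfies the strong exchange property: for any two leaf sets
$X, X'$ with $|X'| < |X|$, some single leaf can be moved from $X$ to $X'$
without decreasing the summed value.  This is exactly what makes the
classical greedy algorithm exact.  On networks the property fails already
for galled trees: the package ships a four-leaf fixture
(`example1_fixture()`) where the pair $X = \{x_1,x_3,x_4\}$,
$X' = \{x_2,x_4\}$ sums to 23 but every single-leaf move sums to 21.

The remedy is to allow richer swaps.  A pair of disjoint sets $(A, B)$ with
$|B| < |A|$ is *improving* for $X, X'$ when

$$\mathrm{rPSD}(X) + \mathrm{rPSD}(X') \;\le\;
  \mathrm{rPSD}((X \setminus A) \cup B) +
  \mathrm{rPSD}((X' \setminus B) \cup A),$$

with $A \subseteq X \setminus X'$ and $B \subseteq X' \setminus X$.  The
inequality is deliberately non-strict, exactly as defined in the
literature; a consequence worth keeping in mind is that the *full swap*
$(X \setminus X',\; X' \setminus X)$ is always improving, so the property
only has content relative to a restricted family of candidate pairs.  On a
semi-$d$-ary level-$k$ network an improving pair always exists within the
family $\mathscr S_{k,d}$: all single moves $(\{x\}, \emptyset)$ plus, for
$k = 1$, all pairs with $1 \le |B| < |A| \le d$ and, for $k \ge 2$, all
pairs with $1 \le |B| < |A| < dk$ and $|A| - |B| \le (d-1)k$.  The family
sizes have closed forms (`family_size()`), with the inner summation index
clamped to $|B| \ge 1$ because the set definition requires nonempty $B$
outside the single moves.  `verify_exchange_property()` checks the
guarantee exhaustively; `example2_network(k)` realizes the extremal case, a
binary level-$k$ chain of reticulations for which the *only* improving pair
for $X = \{x_1..x_k\}$, $X' = \{y\}$ is the full swap with
$|A| - |B| = k - 1$.

On level-1 networks the family refines to $\mathscr S_d$: single moves plus
many-for-one swaps $(A, \{b\})$ with $|A| \le d$.  When such a swap is
genuinely needed (no single move improves), it is localized by a blob: some
blob with exit reticulation $H$ and split node $v$ has
$X \cap C(H) = \emptyset$, $b \in C(H)$ and $A \subseteq C(v)$
(`corollary1_witness()`).  Note the qualifier: a trivially improving full
swap on, say, a tree has no blob to point to, so the localization is only
meaningful for needed swaps; the test suite quantifies it accordingly.

## Greedy optimization

$\mathrm{Opt}_m$ denotes the family of *all* maximum-rPSD leaf sets of
cardinality $m$.  Maximizing rPSD over $m$-subsets is NP-hard on general
networks, but the exchange property yields exact greedy algorithms on the
lowest rungs of the level/arity ladder:

* **Trees** (`greedy_tree()`): $\mathrm{Opt}_m$ is the argmax over single-
  leaf extensions of $\mathrm{Opt}_{m-1}$.
* **Galled trees** (`greedy_galled()`): $\mathrm{Opt}_m$ is the argmax over
  extensions of members of $\mathrm{Opt}_{m-1}$ by adding one leaf or
  replacing one leaf by two.
* **Semibinary level-2 / semi-3-ary level-1** (`greedy_level2()`): the
  candidate pool combines, from $\mathrm{Opt}_{m-1}$, adding a leaf,
  replacing one leaf by two, and replacing two leaves by three, and, from
  $\mathrm{Opt}_{m-2}$, replacing one leaf by three.  The two-for-three
  pool is redundant on semi-3-ary level-1 networks (the refined level-1
  family never needs $|B| \ge 2$) and is skipped there.

A design point that matters for correctness: the containment results for
level-2 networks quantify over **all** members of the earlier optimal
families, so the algorithms propagate full families by default, guarded by
a configurable cap (`max_sets`, default 10,000) against adversarially tied
weights.  Tracking a single representative per cardinality is only sound on
galled trees, where any optimal expansion of any optimal set is again
optimal; `greedy_galled(mode = "representative")` exposes exactly that and
nothing more.  Optimal sets of consecutive sizes need not nest — on the
four-leaf fixture the unique optimal pair $\{x_2,x_4\}$ is not contained in
the unique optimal triple $\{x_1,x_3,x_4\}$ — which is why the greedy must
swap, not only add.

`optimize_rpsd()` routes automatically by class and otherwise falls back to
brute-force enumeration (`brute_force_opt()`, the oracle used throughout
the tests) with a warning.

## Exact arithmetic and ties

Optimal families are defined by exact maxima, and spurious tie-splitting
would silently corrupt family propagation.  When every arc weight is a
short decimal literal (at most six decimal places) all comparisons are
performed on integer-scaled sums, so equality of values is exact; weights
are parsed from eNewick/TSV text as decimal literals precisely to preserve
this.  With non-decimal (floating) weights the package groups near-ties
within a relative tolerance of `1e-9` and documents the result as
approximate.  Degenerate inputs are handled explicitly: the empty set has
rPSD 0, $\mathrm{Opt}_0 = \{\emptyset\}$, and elementary nodes (in-degree
at most 1, out-degree 1) are legal throughout.

Determinism: family enumeration is ordered by $(|A|, |B|,$ lexicographic$)$
on sorted labels, "first" results are therefore reproducible, leaf sets are
always returned sorted, and the eNewick writer visits children in
lexicographic order.

## Beyond the proven classes: the gap scan

For semibinary level-3 and semi-4-ary level-1 networks (and upward) no
greedy algorithm is proven; what is known is a weaker disjunction that does
not pin $\mathrm{Opt}_m$ to earlier families for every $m$.  `gap_scan()`
tests the operative containment
$\mathrm{Opt}_m \subseteq \bigcup_{j=1}^{J}
\mathrm{Opt}\text{-}\tau_{k,d,j}(\mathrm{Opt}_{m-j})$ entirely by brute
force — every $\mathrm{Opt}_m$ is recomputed by enumeration, never by the
greedy under test — and emits a certificate (network, $m$, escaping set)
for any violation.  `gap_scan_sample()` runs this over seeded random
networks.  The package's own scans (400 networks with 8 leaves per run of
the acceptance suite, $J = 3$) have found no violation, consistent with the
open conjecture that the greedy extends; a certificate, if one ever
appears, is a publishable counterexample rather than a bug.

## Synthetic networks: what they do and do not emulate

`random_tree()` grows rooted binary trees by sequential leaf attachment.
`random_level_k()` inserts blobs into tree arcs: each blob is a spine of
tree nodes under a split node plus a chain of $k$ reticulations with
in-degrees drawn from $2..d$, exited through the last reticulation, after
which some pendant leaves are re-attached onto spine nodes so that blob
nodes separate leaves (otherwise every blob node would have the same
cluster and swaps would never be needed).  The construction guarantees
level exactly $k$ and arity at most $d$, which `classify_network()`
re-asserts on every draw.  Weight models are unit, uniform integers in
[1, 10] (the default study condition), one-decimal values (to exercise
exact decimal arithmetic), and uniform reals (to exercise the tolerance
path).

These samplers are convenience generators: they are deterministic per seed
but not uniform over their class, they produce blobs of one structural
family (spine plus reticulation chain), and they do not model biological
processes (no coalescent, no hybridization rates, no clock).  Passing
property suites on them therefore demonstrates correctness of the
algorithms on their classes — each greedy is compared against brute force
on at least 100 seeded instances with up to 10 leaves, and the exchange
property is verified exhaustively over all subset pairs on networks with up
to 7 leaves — not calibration against empirical phylogenies.

Problem sizes used by the shipped suites: exhaustive exchange checks on
networks of 5–7 leaves; oracle-equivalence on 6–10 leaves; gap scans on 8
leaves with $J = 3$, 200 networks per class.  These sizes keep every
quantity exactly enumerable, which is what gives the oracle its authority;
the cost of all brute-force components grows exponentially in the leaf
count, and the guards (`rpsd_table` at 20 leaves, `gap_scan` at 12) mark
where enumeration stops being reasonable.

## Known limitations

* The eNewick dialect is the de-facto hybrid-node `#H` convention (first
  expanded occurrence carries the subtree; each occurrence's branch length
  is that parent's arc weight; missing lengths default to 1).  No Nexus,
  PhyloXML, split networks, or multi-statement files.
* Subset machinery is bitmask-based and capped at 30 leaves (tables at
  20); the greedy algorithms themselves are polynomial, but this package
  prioritizes verifiable exactness over scale.
* On level-3 / semi-4-ary networks and beyond, `optimize_rpsd()` is
  brute-force only; the gap scan is evidence, not proof, that a greedy
  would succeed there.
* The worked four-leaf fixture's weight split among the three arcs
  touching its reticulation is not identifiable from subset values (only
  their sum is); the fixture fixes 0.5/0.3/0.2 by convention.
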