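---
title: "Alignment-free sequence comparison with lwords: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free sequence comparison with lwords: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lwords)
```

## The method

`lwords` compares DNA sequences by their oligonucleotide composition
instead of by alignment. The assumption is that evolutionarily close
sequences share similar word-usage statistics, so a distance between
word-frequency profiles acts as a proxy for genetic distance. This holds
best for long sequences (tens of kilobases, e.g. complete mitochondrial
genomes) and for moderate divergence; it deliberately ignores positional
information, so rearrangements that preserve composition are invisible to
it — which is exactly what makes the method robust to the indel-heavy
regions that derail automated alignment.

The pipeline has four stages.

**Word length.** With $m = \max_i \mathrm{length}(S_i)$, the word length is
$L = \lceil \log_4 m \rceil$, the lower limit of the optimal resolution
range for word-composition comparison; any value in that range is equally
informative, and the lower limit is the cheapest. We compute $L$ in exact
integer arithmetic as the smallest $L$ with $4^L \ge m$ (never through
floating-point logarithms, whose rounding at exact powers of four would be
wrong: $m = 16$ must give $L = 2$). A user override is available in
`lword_compare(word_length =)` because any length in the resolution range
is legitimate; the guard $L \le 12$ protects memory ($4^{13}$ column labels
would be gigabytes).

**Counting.** All $4^L$ words are counted in all sequences with one
generalized suffix tree, built online in linear time (Ukkonen). Each
sequence is terminated by its own sentinel symbol drawn from an integer
code space disjoint from the IUPAC alphabet, so every suffix ends at a
leaf, sequences never merge spuriously, and sentinel collisions are
impossible by construction. A single depth-$L$ depth-first traversal
collects, at string depth exactly $L$ (possibly mid-edge), the aggregated
leaf annotations per sequence; this visits each node at most once, versus
$4^L$ root-to-depth-$L$ traversals for per-word queries. The equivalence of
the bulk traversal and per-word queries is a tested property, not an
assumption, and both are tested against an independent sliding-window
oracle (`oracle_counts()`), which scans the $m - L + 1$ overlapping windows
directly and never touches the tree.

**Profiles and distance.** Occurrence rows are normalized to relative
frequencies $f_{ij} = O_{ij} / \sum_j O_{ij}$, and sequences are compared
by the standard Euclidean distance
$\mathrm{SED}(X,Y) = \sqrt{\sum_{w}(f_{Xw}-f_{Yw})^2}$. For profiles that
each sum to one the sharp range of this distance is $[0, \sqrt 2]$ (the
maximum attained by disjoint compositions, e.g. poly-A versus poly-C at
$L=1$); values are reported exactly as computed — no clipping or rescaling
to $[0,1]$ — because any renormalization would silently change downstream
trees. Only the upper triangle is computed and mirrored, so the matrix is
exactly symmetric.

**Outputs.** The distance matrix feeds Saitou–Nei neighbor joining and/or
classical (Torgerson) multidimensional scaling. NJ is exact on additive
matrices, which is the basis of its acceptance test.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `word_length` | $\lceil \log_4 m \rceil$ | bases | lower limit of the resolution range; override allowed within 1..12 |
| `truncated` | `FALSE` | — | depth-$L$ truncated tree; identical counts, less memory |
| `sub_prob` (simulator) | 0.02 | per site per branch | moderate divergence: signal present, saturation absent |
| `root_length` (simulator) | 1000 (tests use up to 20000) | bases | mtDNA-scale validation uses 20 kb |
| `mds_dims` | 2 | — | planar map for display |

## Handling of ambiguity codes

Real GenBank mtDNA records contain IUPAC ambiguity letters (N, R, Y, ...).
The tree keeps them as ordinary symbols so the suffix structure stays
exact, but word queries are restricted to the {A,C,G,T} alphabet: any
window containing an ambiguous base is never counted, by the tree (a path
through a non-ACGT symbol is skipped) and by the sliding-window oracle (the
window is dropped) alike. This keeps the frequency denominator
$\sum_j O_{ij}$ self-consistent with the $4^L$-word universe. Consequence:
for a pure-ACGT sequence the row sum is exactly $m_i - L + 1$ (a tested
conservation law); for sequences with ambiguity codes it is smaller. A
sequence with no valid $L$-word at all (e.g. all N) is a hard error rather
than a silent zero profile. Only the forward strand is counted; there is no
reverse-complement folding, a documented limitation for comparing sequences
deposited in opposite orientations.

## Numerical and degenerate-case choices

* **Word-length ties.** Exact powers of four take the ceiling literally:
  $m = 16 \Rightarrow L = 2$.
* **NJ tie-breaking.** When several pairs minimize the $Q$ criterion, the
  lexicographically smallest (row, column) pair in the current cluster
  ordering is joined, making the output deterministic; a relative
  tolerance of $10^{-13}$ treats floating-point near-ties as ties.
* **Negative NJ branch lengths.** Estimated pendant lengths can be
  negative on non-additive input; they are clamped to zero with the
  deficit transferred to the sister branch, preserving the pair's summed
  length. Two taxa split their single edge evenly.
* **MDS.** Classical scaling (double-centering + eigendecomposition) was
  chosen over iterative stress majorization because it is deterministic
  and needs no seed. Negative retained eigenvalues (non-Euclidean input)
  are zeroed with a warning and the corresponding coordinates set to zero.
* **Zero distances.** Identical sequences give identical profiles, SED
  exactly 0, and NJ places them as zero-length siblings.
* **Serialization.** Distances and branch lengths are written with at
  least six significant digits (fixed notation, scientific below $10^{-4}$);
  full double precision is kept internally. PHYLIP output defaults to
  relaxed labels (full id + space) because accession ids exceed the
  classic 10-character field; `strict = TRUE` restores the classic
  dialect. Newick labels containing metacharacters are single-quoted.

## The simulator, and what passing tests do not show

`evolve_on_tree()` draws a uniform random root sequence and, along each
branch, substitutes each site independently with probability `sub_prob` to
a uniformly chosen different base — a Jukes–Cantor-like, substitution-only
model with one mutation round per branch and no indels. It emulates the
divergence structure that the pipeline is meant to recover, with fixed
seeds for bit-reproducibility. It does **not** emulate realistic base
composition, rate heterogeneity among sites, back-mutation saturation at
high divergence, or indels. Passing the end-to-end recovery test therefore
shows that the pipeline extracts the tree signal present in word
compositions under clean substitution-only evolution; it does not certify
accuracy on real genomes, where composition bias and rearrangements add
noise the simulator omits. (Indel robustness is precisely the method's
motivation, but an indel mode in the simulator is future work.)

Problem sizes in the test-suite were chosen to exercise the asymptotic
claims while staying desk-sized: the oracle-equivalence property runs 100
random instances with sequences up to 300 bp and words up to 8 bases; the
topology-recovery experiment uses ten replicates of six 20 kb genomes at
2% per-branch substitution, accepted when at least 8 of 10 replicates
reproduce the true topology (a stochastic threshold documented here, not
derived from a publication); tree-size linearity is asserted as a trend
(node count at most twice the sentinel-terminated text length) on doubling
inputs.

## Known limitations

* Forward strand only; no reverse-complement folding.
* Composition-based distances lose positional signal; very short
  sequences (comparable to $4^L$) give sparse, noisy profiles.
* The suffix tree lives in memory; genome-scale (hundreds of Mb) inputs
  would need the truncated tree or an external index.
* The distance is the plain Euclidean metric on frequency profiles;
  alternative dissimilarities (correlation, $d_2^*$, Jensen–Shannon) are
  out of scope.

## A compact session

```{r example}
sim <- evolve_on_tree(n_taxa = 6, root_length = 2000, sub_prob = 0.02, seed = 1)
fit <- lword_compare(sim$sequences)
fit
nj <- neighbor_joining(fit$distance)
write_newick(nj)
```
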