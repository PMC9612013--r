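---
title: "Methods: plastome structure, isoform phasing, variants and phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plastome structure, isoform phasing, variants and phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidkit)
```

## The biological problem

Land-plant plastomes are circular molecules with a quadripartite layout:
a long single-copy region (LSC, ~80–90 kb in grasses), a small
single-copy region (SSC, ~12–20 kb) and two inverted repeats (IR1/IRa,
IR2/IRb, ~20–25 kb each) that separate them. Recombination between the
two IR copies inverts the SSC, so each individual carries two structural
isoforms of its plastome differing only in SSC orientation. This
*structural heteroplasmy* is invisible to short reads and to assemblers,
which collapse the repeat: the telltale signs are an assembly graph with
three segments where the IR segment has about twice the read depth of the
single-copy segments, and — decisively — long reads that traverse one
whole IR and anchor in both neighbouring single-copy regions, each of
which supports exactly one of the two conformations. Rapid flip-flop
recombination is expected to equilibrate the isoforms at 1:1.

plastidkit implements this analysis — structure detection, spanning-read
phasing, ratio estimation — together with the comparative layer built on
top of it: SNV/indel classification of a whole-plastome multiple
alignment, coordinate lift-over and marker intersection, and a
distance-based phylogeny with bootstrap supports and monophyly queries.
A ground-truthed simulator generates every input the pipeline consumes,
so all claims are testable end to end without external data.

## Inverted-repeat detection and the partition

`find_inverted_repeats()` treats an inverted repeat as a pair of
intervals whose sequences are reverse complements. It finds exact k-mer
matches (k = 15 by default) between the sequence and its reverse
complement, groups them by diagonal into seed runs, and extends each run
outwards. Extension is X-drop: +1 per matching base, −3 per mismatch,
stop when the running score falls 6 below its maximum, then trim back to
the maximum. The mismatch budget `max_mismatch_frac` (default 0.01; real
IR copies are near-identical, commonly differing by a handful of bases)
caps the accepted mismatches per pair; with a budget of 0 the procedure
reduces to exact maximal extension. The X-drop rule matters at the IR
boundaries: a greedy "absorb mismatches while the budget allows" rule
creeps a few bases into the single-copy flanks whenever flanking bases
match by chance, whereas X-drop requires a net-positive continuation and
trims back, so detected boundaries coincide with the true repeat ends.
Circularity is handled by searching the doubled sequence and folding
coordinates; exact inverted palindromes (an interval matching itself
reversed, the signature of an adjacent pair) are split into their two
halves. Pairs are reported longest first with a deterministic tie order.

`partition_genome()` labels the two arcs between the IR copies LSC
(longer) and SSC (shorter), breaking ties toward the arc with the smaller
start, and returns the four regions in circular order from the LSC. IR
copies that leave a zero-length arc are an error, as are genomes without
a qualifying pair — plastomes lacking IRs are out of scope.

`canonicalize()` rotates the molecule to start at LSC position 1 in the
order LSC→IR1→SSC→IR2. The circle itself does not distinguish the two
global orientations (both read LSC→IR→SSC→IR), so the package fixes
orientation by content: of the two candidate canonical strings, the
lexicographically smaller is returned. This is arbitrary but
deterministic, idempotent, and invariant under any rotation or
reverse-complementation of the input — the properties multiple alignment
needs. "Canonical" vs "non-canonical" isoform is likewise purely
relative: `build_isoform(..., "noncanonical")` returns the molecule with
the SSC reverse-complemented in place, an involution, and which SSC
orientation is called canonical is defined by the reference as given.

## Read mapping and conformation calls

`map_read_segments()` defines the package's own mapping contract rather
than wrapping an external aligner. Per partition region and strand, exact
read k-mers are matched against a precomputed region index, clustered by
diagonal (tolerance 30 bp, enough for the diagonal drift that per-base
indel errors induce within a segment), and chained monotonically. A hit
records the read interval, the reference interval, the strand and an
identity estimate `(covered fraction)^(1/k)`, where *covered fraction* is
the share of hit positions covered by exact seed k-mers — for error rate
*e* per base, the expected k-mer survival is `(1−e)^k`, so this statistic
recovers `1−e` directly. The mapping-quality gate used with external
aligners is re-expressed as `identity >= 0.85` plus best-placement
conflict resolution (overlapping hits resolved by identity, then length,
then a fixed label/strand order). A read from either isoform on either
strand thus yields segment hits in read order, e.g. LSC(+), IR(+),
SSC(+).

`classify_spanning_read()` calls the conformation from the hit pattern: a
read is *spanning* iff some IR region is covered end to end by one hit
and the nearest single-copy hits on either side are one LSC and one SSC
anchor of at least `anchor_min` bp (default 500 — comfortably above any
alignment slop at the IR boundary). The call is **canonical** when the
two single-copy anchors share an orientation (collinear with the
canonical layout) and **noncanonical** when they differ (the SSC-flipped
layout). This rule is invariant to read strand and to which IR copy label
the middle hit carries — convenient, because a read's IR segment matches
IR1 on one strand and IR2 on the other indistinguishably. Reads spanning
both IRs must yield agreeing calls, else they are `unclassified`;
unclassified reads go to a third read set, never to both conformation
sets, preserving the mutual exclusivity the downstream isoform-specific
reassembly requires. Seed-anchored hit ends fall short of the true
segment boundary by a few bases per sequencing error, so full-IR coverage
is asserted with a `cover_slack` tolerance (100 bp): the requirement of
anchors on *both* sides already forces a true traversal of the repeat,
so the slack cannot admit non-spanning reads.

`estimate_ratio(n_canonical, n_noncanonical)` returns the non-canonical
fraction, its Wilson 95% score interval, and the exact two-sided binomial
test against ½ (summing the probabilities of all outcomes no more likely
than the one observed; `stats::binom.test` implements exactly this). On
counts of 9 vs 11 this gives a ratio of 0.55 with p = 0.8238 — no
evidence against the 1:1 flip-flop equilibrium.

`region_depth_ratio()` reproduces the collapsed-assembly depth signature:
mapping reads against the three-segment (LSC+IR+SSC) representation, the
IR's mean depth is expected at twice the single-copy depth, since both IR
copies' reads pile onto the one collapsed segment.

## Variant classification and coordinates

`classify_columns()` scans a whole-genome alignment column by column. An
**SNV** is a column with no gap character and ≥ 2 distinct alleles among
A/C/G/T with minor-allele count ≥ `min_minor_count`; the default of 1
deliberately keeps singletons (no low-frequency filter), which is why a
deeply sampled plastome alignment yields more SNVs than filtered studies.
`N` is missing data: it never counts as an allele, and a column whose
only variation involves N is invariant. Gap-containing columns belong to
**indel events**: maximal runs of adjacent columns with an identical,
non-trivial gap presence/absence pattern count as one event, on the view
that one biological insertion/deletion spans many columns. Whether an
indel tally of a published alignment counts events or columns is
ambiguous, so the column count is reported alongside
(`n_indel_columns`).

`build_coordinate_map()`/`liftover()` convert between alignment columns
and ungapped reference positions (1-based both ways; BED output is
0-based half-open); the round trip is the identity on non-gap columns and
reference-gap columns lift to `NA`. `intersect_markers()` lifts SNV
columns to reference coordinates and intersects them with two external
position lists; the SNVs found in both are the high-confidence marker
set. `write_variants()` emits the variant table as TSV and a minimal
VCFv4.2 whose REF allele is verified against the reference sequence.

## Distance phylogeny

`p_distance_matrix()` computes mismatch proportions under pairwise
deletion of gaps and N, over all columns or SNV columns only. `nj_tree()`
is standard neighbor joining — Q-criterion join selection with
Studier–Keppler branch lengths — with two policies worth stating:
ties in Q are broken by the lexicographically smallest pair of cluster
representatives, making output order-independent and reproducible, and
negative branch lengths (a known NJ artefact on noisy distances) are
clamped to zero with the total deficit recorded on the tree. On an
additive matrix NJ provably reconstructs the generating tree; the tests
assert exact recovery (to 1e-9) on a worked 4-taxon example and zero
Robinson–Foulds distance to the true tree on simulated 12-taxon
populations. A maximum-likelihood search is intentionally out of scope:
ML engines are existing tools, and at plastome-level divergence NJ on
p-distances recovers the same topology; the bootstrap (column resampling,
support = percent of replicate NJ trees containing the bipartition)
carries the uncertainty statement. 5000 replicates is a sensible
full-scale default; 100–200 saturate the clean splits at desk scale.

`root_tree()` verifies the outgroup is one side of a bipartition of the
unrooted tree (an error otherwise — never silently resolved) and places
the root at the midpoint of that edge. `clade_test()` answers monophyly
queries: the query is monophyletic iff some node's descendant-leaf set
equals it, and `min_clades` counts the maximal query-pure subtrees, which
on a tree is exactly the minimum number of clades covering the query —
`min_clades == 1` iff monophyletic, and a query straddling two sister
groups reports 2, the quantitative form of a polyphyly claim.

## The simulator: what it emulates, what it does not

`simulate_plastome()` draws i.i.d. bases at the requested GC (0.38
default, typical of grass plastomes) in the layout LSC+IR1+SSC+IR2 with
IR2 the exact reverse complement of IR1, and rejection-samples until the
only inverted repeat ≥ `ir_len` is the planted pair (the detector itself,
in exact mode, is the rejection check), keeping the structural truth
unambiguous. `simulate_reads()` draws each read from the canonical
isoform with probability `1 − mixture_ratio` (0.5 at equilibrium), a
uniform start on the circle (sampling from the doubled sequence), a
random strand, and a log-normal length truncated to [200 bp, genome
length] so that some reads always span an IR; per-base substitution,
insertion and deletion errors are applied at the given rates, and
constant Phred-20 qualities are written (qualities are not used
downstream). Every read carries a truth record (source isoform, origin,
strand, template length); `spanning_truth()` derives from it which reads
truly span an IR with given anchors.

`simulate_population()` evolves an ancestor along a rooted tree:
substitution counts are Poisson per branch with mean `branch length ×
rate scale × sequence length` under single-site Jukes–Cantor (every
substitution changes the base — the simplest model sufficient for
recovery testing), and indels are Poisson events of geometric length,
deletion or insertion with equal probability. The alignment is built on a
persistent column-key system — ancestral columns keep integer keys,
insertions get fractional keys between their neighbours — so the emitted
alignment is the *true* alignment and every planted variant column and
indel event is recoverable exactly, with no aligner in the loop.

Deliberate non-goals of the generator: no platform-specific error
profiles, no chimeric reads, no coverage bias, no rate heterogeneity
across sites, no selection. Passing tests therefore demonstrate
correctness of the algorithms under clean, known conditions — they bound,
but do not measure, performance on real reads, where error structure and
alignment ambiguity add noise the identity gate and anchor rule are
designed to absorb. One observation from real assemblies is intentionally
not modelled: reassembled non-canonical isoforms can come out ~10 bp
shorter than their canonical counterpart, which is an assembly artefact
rather than a structural property, so the simulator keeps both isoforms
the same length.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere in reports; BED is
  0-based half-open; VCF is 1-based.
* All generators consume an explicit integer seed and restore the
  caller's RNG state; identical seeds give byte-identical outputs, which
  the pipeline manifest verifies by checksums.
* X-drop parameters (+1/−3, drop 6) and the seed size k = 15 fit
  near-exact repeats; k also bounds the smallest detectable anchor.
* Degenerate inputs fail loudly with classed conditions
  (`plastidkit_param_error`, `plastidkit_structure_error`, ...): empty
  sequences, non-clade outgroups, pairs leaving no single-copy arc,
  distance pairs with zero comparable columns.
* `estimate_ratio` requires at least one classified spanning read; a
  phasing run with none reports an `NA` ratio rather than erroring.
* The pipeline config is strict: unknown keys are rejected, every
  stochastic stage must carry a seed.

Desk-scale problem sizes used by the test suite and the acceptance
script — 3–10 kb plastomes with 0.3–1 kb IRs, 100–200 reads per phasing
run, 100 calibration replicates, 12-taxon populations on 1.5–2 kb
ancestors, 100–200 bootstrap replicates — were chosen so the full suite
exercises every stage, including 50-seed sweeps, in a few minutes; all
algorithms scale to real plastome sizes (the detector and mapper are
linear in sequence length for fixed seed density).

## Known limitations

* Plastomes without inverted repeats, or with more than one qualifying
  repeat pair, are rejected rather than handled.
* The mapper is a k-mer chainer, not a full aligner: identities are
  estimates, and hit boundaries are seed-anchored (hence the documented
  `cover_slack`). It is not intended for reads with error rates far
  above ~10%.
* NJ with p-distances is the implemented tree method; model-based
  distances, ML and Bayesian inference are out of scope.
* Indel placement in the population simulator is uniform and
  length-geometric; real plastome indels cluster in repeats.
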