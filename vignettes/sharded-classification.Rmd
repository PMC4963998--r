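---
title: "Sharded exact-match 30-mer classification: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sharded exact-match 30-mer classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smartclassifier)
```

This vignette is the package's account of its method: what the classifier
assumes, which knobs matter, what the bundled simulator does and does not
emulate, and where the design was genuinely open and a choice had to be
made.

## The classification model

The classifier assigns shotgun metagenomic reads to taxa by exact k-mer
membership, not by alignment. Three modelling commitments follow from
that:

1. **The database is a set, not a tree.** Every reference genome is cut
   into non-overlapping 30-mers (offsets 0, 30, 60, …, forward strand
   only; the trailing remainder is discarded) and each 30-mer maps to the
   *full set* of species whose references contain it. Nothing is
   collapsed to a lowest common ancestor and no "discriminative k-mer"
   filtering is applied: non-unique k-mers simply carry multi-species
   sets and contribute multi-species votes. The step-30 cut keeps the
   database at 1/30 of the sliding-window k-mer space; sensitivity is
   recovered on the query side, where windows slide by 1, so every
   read of length ≥ 59 bp that lies within a single reference necessarily
   covers at least one database tile exactly.

2. **Votes, then rules.** Each deduplicated (window, strand, species)
   match event is one vote. Genus and class tallies are *derived* as
   lineage sums of the species tallies — with a single-lineage taxonomy
   the two are provably equivalent to tallying each level independently,
   and deriving avoids a redundant store (the equivalence is asserted in
   the test suite). Per level the verdict is the unique argmax,
   `AMBIGUOUS` on a tie, `UNMATCHED` with no votes. Two reads rules sit
   on top of the tallies: the mammalian override (any mammalian match ⇒
   category `mammalian`) and the tie rule, evaluated independently per
   level.

3. **Errors are substitutions.** Permuted mode queries all 3k one-base
   substitution variants of every window, accepting Hamming distance ≤ 1.
   Insertions and deletions are deliberately out of scope — a window with
   an indel is simply unmatched, and the read relies on its other
   windows.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `k` | 30 | bases | window and tile length; ≤ 32 so a k-mer fits one 64-bit word at 2 bits/base |
| `prefix_len` | 4 | bases | shard key length; 4^4 = 256 shards. Controls parallel grain and per-shard memory, not results |
| `mammalian_class` | `"Mammalia"` | label | class that triggers the host override; configurable so non-mammalian hosts can reuse the rule |
| `mode` | `"exact"` | — | `"permuted"` adds the 90-variant neighborhood per window (~an order of magnitude more lookups) |
| `workers` | 1 | count | shard groups searched concurrently; results are invariant by contract and by test |

`k = 30` balances specificity (a 30-mer is essentially unique among
random sequence) against error tolerance (a 100-bp read with one error
still has ≥ 40 error-free windows). `prefix_len` trades shard count
against shard size; any value with `0 < prefix_len < k` gives identical
classifications because the prefix only routes, never filters.

## What the simulator emulates — and what it does not

`simulate_community()` draws i.i.d. uniform-ACGT genomes. At 30-mer
scale, two random 3-kb genomes share a k-mer with probability ≈ 0
(500 tiles against 4^30 possible k-mers), so species-unique content holds
*by construction*; `shared_fraction` plants identical blocks in
designated species pairs to create multi-species k-mers and vote ties on
demand, and `host_fraction` adds a genome labeled with the mammalian
class and weights read sampling toward it. `simulate_reads()` draws
uniform positions and strands and injects i.i.d. substitutions (binomial
per read), recording truth in both the read names and a sidecar table.

The simulator deliberately does **not** model: realistic error profiles
(quality- or position-dependent, platform-specific), indels, chimeric
reads, GC bias, repeat structure or shared homology within real genomes,
or skewed abundance distributions. Passing tests therefore demonstrate
the *algorithmic* contracts — oracle equivalence of the sharded search,
correct vote arithmetic, override and tie semantics, determinism — not
field performance on real communities, where database completeness and
genuine inter-genome homology dominate accuracy. The near-perfect
sensitivity on synthetic data is a parameter-recovery check, not a claim
about real samples.

Default study conditions used by the test suite and the acceptance
script: 5 species × 3 kb, 10,000 reads × 100 bp, substitution rate 0.01,
host fraction 0.5 for the host-rich run. These sizes make every
brute-force oracle comparison exhaustive while each search completes in
seconds.

## Numerical and procedural choices

- **Non-ACGT handling.** Sequences are uppercased; any tile or window
  still containing a non-ACGT character (N, IUPAC codes) is skipped on
  both the database and the query side. This keeps the 2-bit encoding
  total and never fabricates matches from ambiguity codes.
- **Canonical ordering.** Shard suffixes, species sets, and match tables
  are sorted with C-locale (radix) byte order, making the serialized
  index and every intermediate file canonical: building from a permuted
  reference FASTA yields byte-identical output, which is also how
  order-independence is tested.
- **Permutation routing.** A variant whose substitution falls inside the
  4-bp prefix belongs to a *different* shard. Each shard therefore
  answers every variant query whose mutated prefix equals its own,
  regardless of the window's original prefix. The alternative —
  permuting only within a fixed shard — would silently drop
  3·prefix_len of the 3·k variants (≈ 13% at the defaults); the routing
  choice keeps the sharded search exactly equal to a global 1-edit
  search, and the equality is asserted against a brute-force scanner.
- **Exact beats permuted.** Within a window, a species matched both
  exactly and via a variant is recorded once, as exact; one vote per
  (window, strand, species) prevents the 90-variant neighborhood from
  swamping exact evidence while keeping permuted mode a strict superset
  of exact mode.
- **Reverse complement.** The whole read is reverse-complemented once and
  scanned with the same window logic (equivalent to per-window reverse
  complementation); a palindromic window matching on both strands yields
  two events, keeping strand symmetry exact.
- **Override precedence.** A read with a mammalian match *and* a
  species-level tie is categorized mammalian, not ambiguous: the override
  is stated unconditionally, and a conservative host filter is its
  purpose. The per-level verdicts are reported unchanged alongside, so
  the other convention can be recomputed from the per-read table.
- **Sample-category convention.** The mammalian / non-mammalian /
  ambiguous / unmatched partition uses the species-level verdict for
  "ambiguous"; per-level verdict columns are exposed for any other
  convention.
- **Precision denominator.** "Attempted" means a unique taxon verdict at
  the level scored; `AMBIGUOUS` reads count in the totals (hurting
  sensitivity) but not in the precision denominator. This is the reading
  under which precision can exceed sensitivity; the alternative
  (ambiguous = attempted and incorrect) is available via
  `ambiguous_as_attempted = TRUE`.
- **Confidence intervals.** Wilson score at 95%, with exact endpoints at
  boundary counts (0 or n successes) to avoid floating-point drift past
  the parameter space.
- **Depth normalization.** Host depth = host reads × read length / host
  genome length (mean coverage); zero depth refuses normalization
  explicitly rather than dividing by zero.
- **Degenerate inputs.** Empty taxonomy files load (an index build on
  them fails loudly); references shorter than k contribute nothing; reads
  shorter than k scan zero windows and report as unmatched.

## Implementation notes

The window scan is compiled (Rcpp): k-mers are 2-bit packed into 64-bit
words and rolled across each read, with a validity counter resetting at
non-ACGT characters; variants are generated by XOR-ing the packed word,
so permuted mode costs ~91 hashtable probes per window instead of 91
string allocations. The map step splits occupied shards into worker
groups; the reduce step concatenates, deduplicates, and canonically sorts
per-read match sets, so any grouping and any shard order reduce to the
same result. In-memory construction replaces the external merge sort that a build over
a full public reference database would need, with the same sorted-merge
semantics; an out-of-core builder is a non-goal at desk scale.

## Known limitations

- The whole index lives in memory during build and full-index search
  (piecewise single-shard search via `load_shard()` is the
  memory-bounded path).
- `k ≤ 32` (one 64-bit word). Larger k would need two-word keys.
- No paired-end awareness: mates are independent reads.
- No abundance re-estimation, no confidence scores, no LCA: verdicts are
  vote argmaxes with ties surfaced as `AMBIGUOUS`, and downstream
  smoothing is out of scope.
- Edit distance is capped at 1 substitution; two errors inside every
  window of a read leave it unmatched in either mode.
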