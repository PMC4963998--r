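# smartclassifier

Taxonomic classification of shotgun metagenomic reads by **exact 30-mer
matching against a prefix-sharded hashtable database**, with one-base
permutation matching for error tolerance and a conservative host
(mammalian) override. The package is aimed at microbiome analysts who need
a transparent, fully testable classifier for host-rich samples — where
reads of host origin easily masquerade as microbial hits — and at method
developers who want a desk-scale reference implementation of the
shard-and-vote search strategy with every stage (index, search, vote,
report, evaluation) exposed as an R function.

## The method

**Database.** Each reference genome is *virtually cut* into
non-overlapping 30-mers (tiles at offsets 0, 30, 60, …; forward strand
only), and every 30-mer is linked to the species/genus/class lineage of
its record. The deduplicated (30-mer, species) pairs are split into
4^4 = 256 **shards** keyed by the first 4 bases of the 30-mer
(A=0, C=1, G=2, T=3, first base most significant); within a shard the
remaining 26 bases are the hashtable key and the value is the sorted set
of species containing the full 30-mer. Shards serialize independently, so
the database can be searched or loaded piecewise in memory-bounded
settings.

**Search.** A 30-bp window slides in steps of 1 over every read and over
its reverse complement. Each window is routed by its 4-bp prefix to the
owning shard for an exact 26-bp suffix lookup (the *map* step; any number
of shard workers give identical results). In *permuted* mode, all
3×30 = 90 one-base substitution variants of each window are additionally
queried — substitutions are the error model; insertions and deletions are
out of scope — with each variant answered by the shard owning the
variant's (possibly mutated) prefix, so the sharded search is exactly
equivalent to a global Hamming-distance-1 search. Per-shard match lists
are merged (the *reduce* step) into per-read match sets; a species
supported by both an exact window and a variant counts once, as exact.

**Classification.** Every deduplicated (window, strand, species) match
event is one vote. Genus and class tallies are the lineage sums of the
species tallies. Per level the verdict is the unique argmax taxon,
`AMBIGUOUS` on a tie, or `UNMATCHED` with no votes; ties are evaluated per
level, so a species-level tie can still resolve at genus level. One rule
takes precedence over the tallies: **a read with even one mammalian match
is categorized as mammalian**, which is what makes the classifier robust
in host-rich samples. Sample reports partition reads into
mammalian / non-mammalian / ambiguous / unmatched and tabulate per-genus
read counts, optionally normalized by the host depth of coverage
(host reads × read length / host genome length).

**Evaluation.** Sensitivity = correct classifications / total reads;
precision = correct classifications / reads attempted (unique verdict at
the level in question), with Wilson 95% confidence intervals. A bundled
simulator generates reference communities and error-bearing reads with
known truth, so the whole pipeline is testable offline.

## Worked example

```r
library(smartclassifier)

community <- simulate_community(n_species = 5, genome_length = 3000,
                                host_fraction = 0.2, seed = 11)
readset   <- simulate_reads(community, n_reads = 2000, read_length = 100,
                            substitution_rate = 0.01, seed = 11)
index     <- build_index(community$sequences, community$taxonomy)

matches <- search_reads(index, readset$reads,
                        search_config("permuted", params = index$params))
cls     <- classify_reads(matches, community$taxonomy)
summarize_sample(cls)
#> Sample report: 2000 reads
#>   mammalian           393  (19.65%)
#>   non_mammalian      1606  (80.30%)
#>   ambiguous             0  (0.00%)
#>   unmatched             1  (0.05%)
#> Top genera:
#>   genus_01             659
#>   genus_02             645
#>   Homo                 393
#>   genus_03             302

metrics <- evaluate_classifications(cls, readset$truth)
metrics[, c("level", "n_total", "n_attempted", "n_correct",
            "sensitivity", "precision")]
#>     level n_total n_attempted n_correct sensitivity precision
#> 1 species    2000        1999      1999      0.9995         1
#> 2   genus    2000        1999      1999      0.9995         1
#> 3   class    2000        1999      1999      0.9995         1
```

About 20% of the reads come from the mammalian host genome and every one
of them carrying at least one host match is pulled into the `mammalian`
category by the override, regardless of its other votes. With a 1%
per-base error rate, permutation matching classifies 1999 of 2000 reads;
in exact mode roughly 5% of reads (those whose every 30-bp window carries
an error) would remain unmatched. All verdicts agree with the known truth
labels, so sensitivity ≈ precision ≈ 1 on this clean synthetic community.

The same pipeline is scriptable from a shell via the thin CLI wrapper
(`system.file("cli", "smart", package = "smartclassifier")`) with the
subcommands `simulate`, `build`, `search`, `report`, and `eval`.

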