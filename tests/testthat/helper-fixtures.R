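# Small hand-built fixtures used across test files.

# deterministic random ACGT string
rand_seq <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# two bacteria + one mammal taxonomy over three records
tiny_taxonomy <- function() {
  taxonomy_table(data.frame(
    record_id = c("refA", "refB", "refH"),
    species_id = c("E. coli", "B. subtilis", "H. sapiens"),
    genus_id = c("Escherichia", "Bacillus", "Homo"),
    class_id = c("Gammaproteobacteria", "Bacilli", "Mammalia"),
    stringsAsFactors = FALSE))
}

# two species whose genomes share one identical 30-base tile
shared_tile_fixture <- function(k = 30) {
  withr::with_seed(42, {
    shared <- rand_seq(k)
    seqs <- c(refA = paste0(shared, rand_seq(2 * k)),
              refB = paste0(shared, rand_seq(2 * k)))
    tax <- taxonomy_table(data.frame(
      record_id = c("refA", "refB"),
      species_id = c("spX", "spY"),
      genus_id = c("gX", "gY"),
      class_id = c("cX", "cY"),
      stringsAsFactors = FALSE))
    list(sequences = seqs, taxonomy = tax, shared_kmer = shared)
  })
}

# a standard small simulated dataset (built fresh, cached per session)
sim_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(n_species = 5, genome_length = 3000, shared_fraction = 0,
           host_fraction = 0, seed = 1, n_reads = 500, read_length = 100,
           substitution_rate = 0, read_seed = seed) {
    key <- paste(n_species, genome_length, shared_fraction, host_fraction,
                 seed, n_reads, read_length, substitution_rate, read_seed,
                 sep = "_")
    if (is.null(cache[[key]])) {
      community <- simulate_community(n_species, genome_length,
                                      shared_fraction, host_fraction, seed)
      readset <- simulate_reads(community, n_reads, read_length,
                                substitution_rate, read_seed)
      index <- build_index(community$sequences, community$taxonomy)
      cache[[key]] <- list(community = community, readset = readset,
                           index = index)
    }
    cache[[key]]
  }
})

# strip attributes and sort so two match tables can be compared exactly
plain_matches <- function(m) {
  dt <- data.table::data.table(read_id = m$read_id, offset = m$offset,
                               strand = m$strand, permuted = m$permuted,
                               species = m$species)
  data.table::setorder(dt, read_id, strand, offset, species)
  dt
}

expect_same_matches <- function(a, b) {
  pa <- plain_matches(a)
  pb <- plain_matches(b)
  expect_equal(nrow(pa), nrow(pb))
  for (col in names(pa)) expect_identical(pa[[col]], pb[[col]])
}
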