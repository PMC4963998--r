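test_that("reverse complement is the standard involution with N", {
  expect_equal(reverse_complement("ACGT"), "ACGT")  # palindrome
  expect_equal(reverse_complement("AAAC"), "GTTT")
  expect_equal(reverse_complement("ANGT"), "ACNT")
  expect_error(reverse_complement("ACGU"), "outside")

  withr::with_seed(21, {
    for (i in 1:20) {
      s <- rand_seq(sample(1:80, 1))
      expect_equal(reverse_complement(reverse_complement(s)), s)
    }
  })
})

test_that("sliding windows step by 1 and skip non-ACGT windows", {
  p <- index_params()
  expect_equal(sliding_windows(rand_seq(31, seed = 22), p)$offset, 0:1)
  expect_equal(nrow(sliding_windows(rand_seq(30, seed = 23), p)), 1)
  expect_equal(nrow(sliding_windows(rand_seq(29, seed = 24), p)), 0)

  s <- rand_seq(35, seed = 25)
  substr(s, 33, 33) <- "N"  # 0-based position 32
  expect_equal(sliding_windows(s, p)$offset, 0:2)
})

test_that("1-bp permutation yields exactly 3k distinct distance-1 variants", {
  expect_setequal(permute_1bp("AA"), c("CA", "GA", "TA", "AC", "AG", "AT"))

  km <- rand_seq(30, seed = 26)
  vars <- permute_1bp(km)
  expect_equal(length(vars), 90)
  expect_equal(length(unique(vars)), 90)
  expect_false(km %in% vars)
  hamming <- vapply(vars, function(v) {
    sum(strsplit(v, "")[[1]] != strsplit(km, "")[[1]])
  }, integer(1))
  expect_true(all(hamming == 1))
  expect_error(permute_1bp("ACNG"), "A/C/G/T")
})

test_that("a shard answers exact windows of its prefix on both strands", {
  fx <- shared_tile_fixture()
  p <- index_params()
  ix <- build_index(fx$sequences, fx$taxonomy, p)
  km <- substring(fx$sequences[["refA"]], 31, 60)  # unique to spX
  cfg <- search_config("exact", params = p)
  shard <- ix$shards[[encode_prefix(substr(km, 1, 4)) + 1L]]

  m <- search_shard(c(read1 = km), shard, cfg)
  expect_equal(nrow(m), 1)
  expect_equal(m$offset, 0L)
  expect_equal(m$strand, "forward")
  expect_false(m$permuted)
  expect_equal(m$species, "spX")

  m_rc <- search_shard(c(read1 = reverse_complement(km)), shard, cfg)
  expect_equal(m_rc$strand, "reverse")
  expect_equal(m_rc$species, "spX")
})

test_that("a single substitution is invisible to exact mode but found permuted", {
  fx <- shared_tile_fixture()
  p <- index_params()
  ix <- build_index(fx$sequences, fx$taxonomy, p)
  km <- substring(fx$sequences[["refA"]], 31, 60)
  mutated <- km
  orig <- substr(mutated, 11, 11)  # 0-based position 10
  substr(mutated, 11, 11) <- setdiff(c("A", "C", "G", "T"), orig)[1]

  m_exact <- search_reads(ix, c(read1 = mutated),
                          search_config("exact", params = p))
  expect_equal(nrow(m_exact), 0)

  m_perm <- search_reads(ix, c(read1 = mutated),
                         search_config("permuted", params = p))
  expect_equal(nrow(m_perm), 1)
  expect_true(m_perm$permuted)
  expect_equal(m_perm$species, "spX")

  # literal 90-variant brute force agrees
  dict <- oracle_dict(fx$sequences, fx$taxonomy)
  oracle <- oracle_scan(c(read1 = mutated), dict, permuted = "scan")
  expect_same_matches(m_perm, oracle)
})

test_that("permutations crossing the shard prefix are still found", {
  fx <- shared_tile_fixture()
  p <- index_params()
  ix <- build_index(fx$sequences, fx$taxonomy, p)
  km <- substring(fx$sequences[["refA"]], 31, 60)
  mutated <- km
  substr(mutated, 2, 2) <- setdiff(c("A", "C", "G", "T"),
                                   substr(km, 2, 2))[1]  # inside the prefix
  m_perm <- search_reads(ix, c(read1 = mutated),
                         search_config("permuted", params = p))
  expect_equal(m_perm$species[m_perm$strand == "forward"], "spX")

  # the owning shard is the one with the *original* prefix, which differs
  # from the mutated window's prefix
  owner <- ix$shards[[encode_prefix(substr(km, 1, 4)) + 1L]]
  m_shard <- search_shard(c(read1 = mutated), owner,
                          search_config("permuted", params = p))
  expect_true("spX" %in% m_shard$species)
})

test_that("reduce merges shard partials independently of order", {
  fx <- shared_tile_fixture()
  p <- index_params()
  ix <- build_index(fx$sequences, fx$taxonomy, p)
  kmA <- substring(fx$sequences[["refA"]], 31, 60)
  kmB <- substring(fx$sequences[["refB"]], 31, 60)
  read <- paste0(kmA, kmB)  # windows of both species' unique tiles
  cfg <- search_config("exact", params = p)

  occupied <- which(vapply(ix$shards, function(s) length(s$suffixes) > 0,
                           logical(1)))
  partials <- lapply(ix$shards[occupied], function(s) {
    search_shard(c(r1 = read), s, cfg)
  })
  merged <- reduce_matches(partials)
  merged_rev <- reduce_matches(rev(partials))
  expect_same_matches(merged, merged_rev)
  expect_same_matches(merged, search_reads(ix, c(r1 = read), cfg))

  # the same read id with conflicting metadata across partials is an error
  bad <- search_shard(c(r1 = substr(read, 1, 40)),
                      ix$shards[[occupied[1]]], cfg)
  expect_error(reduce_matches(c(partials, list(bad))),
               "conflicting read id")
})

test_that("map-reduce equals the naive full-table scan (exact and permuted)", {
  fix <- sim_fixture(n_reads = 120, substitution_rate = 0.02, seed = 3)
  dict <- oracle_dict(fix$community$sequences, fix$community$taxonomy)
  reads <- fix$readset$reads

  m_exact <- search_reads(fix$index, reads,
                          search_config("exact", params = fix$index$params))
  expect_same_matches(m_exact, oracle_scan(reads, dict, permuted = "none"))

  m_perm <- search_reads(fix$index, reads,
                         search_config("permuted",
                                       params = fix$index$params))
  expect_same_matches(m_perm, oracle_scan(reads, dict, permuted = "dict1"))

  # the expanded-dictionary oracle itself agrees with the literal
  # 90-variant scan on a subset
  sub <- reads[1:15]
  expect_same_matches(oracle_scan(sub, dict, permuted = "dict1"),
                      oracle_scan(sub, dict, permuted = "scan"))
})

test_that("results are invariant to workers and shard order", {
  fix <- sim_fixture(n_reads = 80, substitution_rate = 0.01, seed = 4)
  reads <- fix$readset$reads
  cfg1 <- search_config("permuted", workers = 1, params = fix$index$params)
  cfg4 <- search_config("permuted", workers = 4, params = fix$index$params)
  m1 <- search_reads(fix$index, reads, cfg1)
  m4 <- search_reads(fix$index, reads, cfg4)
  expect_same_matches(m1, m4)

  occupied <- which(vapply(fix$index$shards,
                           function(s) length(s$suffixes) > 0, logical(1)))
  shuffled <- withr::with_seed(5, sample(occupied))
  m_shuf <- search_reads(fix$index, reads, cfg1, shard_order = shuffled)
  expect_same_matches(m1, m_shuf)
})

test_that("strand symmetry: reverse-complemented reads match the same species", {
  fix <- sim_fixture(n_reads = 60, substitution_rate = 0.01, seed = 6)
  reads <- fix$readset$reads
  cfg <- search_config("exact", params = fix$index$params)
  m_fwd <- search_reads(fix$index, reads, cfg)
  m_rev <- search_reads(fix$index,
                        stats::setNames(reverse_complement(reads),
                                        names(reads)), cfg)
  sp_fwd <- split(m_fwd$species, m_fwd$read_id)
  sp_rev <- split(m_rev$species, m_rev$read_id)
  expect_identical(names(sp_fwd), names(sp_rev))
  for (id in names(sp_fwd)) {
    expect_identical(sort(sp_fwd[[id]]), sort(sp_rev[[id]]))
  }
  # strands flip, offsets are preserved on the scanned strand
  expect_equal(table(m_fwd$strand)[["forward"]],
               table(m_rev$strand)[["reverse"]])
})

test_that("windows containing non-ACGT bases never match", {
  fx <- shared_tile_fixture()
  p <- index_params()
  ix <- build_index(fx$sequences, fx$taxonomy, p)
  km <- substring(fx$sequences[["refA"]], 31, 60)
  broken <- km
  substr(broken, 15, 15) <- "N"
  m <- search_reads(ix, c(r1 = broken),
                    search_config("permuted", params = p))
  expect_equal(nrow(m), 0)
  expect_equal(attr(m, "reads")$windows_scanned, 0L)
})

test_that("config/index parameter mismatch is rejected", {
  fx <- shared_tile_fixture()
  ix <- build_index(fx$sequences, fx$taxonomy, index_params())
  cfg_bad <- search_config("exact", params = index_params(k = 20))
  expect_error(search_reads(ix, c(r1 = rand_seq(40, seed = 1)), cfg_bad),
               "do not match")
})

test_that("FASTA and FASTQ read files are auto-detected", {
  fx <- shared_tile_fixture()
  p <- index_params()
  ix <- build_index(fx$sequences, fx$taxonomy, p)
  km <- substring(fx$sequences[["refA"]], 31, 60)
  cfg <- search_config("exact", params = p)

  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">read1 some description", km), fa)
  fq <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@read1", km, "+", strrep("I", 30)), fq)
  m_fa <- search_reads(ix, fa, cfg)
  m_fq <- search_reads(ix, fq, cfg)
  expect_same_matches(m_fa, m_fq)
  expect_equal(unique(m_fa$read_id), "read1")
})

test_that("match TSV round trip preserves matches and unmatched reads", {
  fix <- sim_fixture(n_reads = 50, substitution_rate = 0.05, seed = 8)
  m <- search_reads(fix$index, fix$readset$reads,
                    search_config("exact", params = fix$index$params))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matches(m, path)
  m2 <- read_matches(path)
  expect_same_matches(m, m2)
  expect_equal(attr(m2, "reads"), attr(m, "reads"))
  expect_equal(attr(m2, "mode"), "exact")
})
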