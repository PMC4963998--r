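#' Simulate a reference community with known taxonomy
#'
#' Generates `n_species` i.i.d. uniform-ACGT genomes — at 30-mer scale two
#' random 3 kb genomes share a k-mer with probability essentially 0, so the
#' community has clean species-unique content by construction. Optionally a
#' fraction of each odd genome is copied into its pair partner
#' (`shared_fraction`, to create non-unique k-mers that exercise multi-taxon
#' votes and ties), and when `host_fraction > 0` an extra genome labeled
#' with the mammalian class is added as the host. Species are paired into
#' genera (two species per genus) and genera grouped four species per
#' class, so every taxonomy level is non-trivial.
#'
#' @param n_species number of (non-host) species.
#' @param genome_length genome length in bases (all genomes equal length).
#' @param shared_fraction fraction in `[0, 1)` of each designated pair's
#'   genome copied between the pair (0 = fully disjoint genomes).
#' @param host_fraction fraction in `[0, 1]` of reads later drawn from the
#'   host genome; a host genome is included iff this is positive.
#' @param seed RNG seed; the community is a pure function of its arguments.
#' @param params a `smart_params` (for `k` and the mammalian class label).
#' @return A `smart_community` list with `sequences` (named character),
#'   `taxonomy` (`smart_taxonomy`), `host_record` (or `NA`),
#'   `host_fraction`, `params`, `seed`.
#' @export
simulate_community <- function(n_species = 5, genome_length = 3000,
                               shared_fraction = 0, host_fraction = 0,
                               seed = 1, params = index_params()) {
  n_species <- as.integer(n_species)
  genome_length <- as.integer(genome_length)
  if (is.na(n_species) || n_species < 1) stop("n_species must be >= 1")
  if (is.na(genome_length) || genome_length < params$k) {
    stop("genome_length must be >= k")
  }
  if (shared_fraction < 0 || shared_fraction >= 1) {
    stop("shared_fraction must be in [0, 1)")
  }
  if (host_fraction < 0 || host_fraction > 1) {
    stop("host_fraction must be in [0, 1]")
  }

  withr::with_seed(as.integer(seed), {
    random_genome <- function() {
      paste(sample(.BASES, genome_length, replace = TRUE), collapse = "")
    }
    seqs <- vapply(seq_len(n_species), function(i) random_genome(),
                   character(1))
    names(seqs) <- sprintf("ref_%02d", seq_len(n_species))

    if (shared_fraction > 0) {
      block <- as.integer(round(shared_fraction * genome_length))
      if (block >= 1) {
        for (i in seq(1L, n_species - 1L, by = 2L)) {
          pos <- sample.int(genome_length - block + 1L, 1L)
          donor <- substr(seqs[[i]], pos, pos + block - 1L)
          s <- seqs[[i + 1L]]
          seqs[[i + 1L]] <- paste0(substr(s, 1L, pos - 1L), donor,
                                   substr(s, pos + block, genome_length))
        }
      }
    }

    entries <- data.frame(
      record_id = names(seqs),
      species_id = sprintf("species_%02d", seq_len(n_species)),
      genus_id = sprintf("genus_%02d", ceiling(seq_len(n_species) / 2)),
      class_id = sprintf("class_%02d", ceiling(seq_len(n_species) / 4)),
      stringsAsFactors = FALSE)

    host_record <- NA_character_
    if (host_fraction > 0) {
      host_record <- "ref_host"
      seqs <- c(seqs, ref_host = random_genome())
      entries <- rbind(entries, data.frame(
        record_id = host_record, species_id = "Homo sapiens",
        genus_id = "Homo", class_id = params$mammalian_class,
        stringsAsFactors = FALSE))
    }

    structure(list(sequences = seqs,
                   taxonomy = taxonomy_table(
                     entries, mammalian_class = params$mammalian_class),
                   host_record = host_record,
                   host_fraction = host_fraction,
                   params = params, seed = as.integer(seed)),
              class = "smart_community")
  })
}

#' Simulate reads from a community with truth tracking
#'
#' Draws reads uniformly over the non-host genomes (the host genome, when
#' present, receives probability `host_fraction`), from a random strand and
#' a uniform start position, then injects i.i.d. per-base substitutions —
#' no indels, matching the scope of the one-base permutation search. Truth
#' (source record, lineage, offset, strand, substitution count) is recorded
#' both in the colon-delimited read names and in an authoritative truth
#' table.
#'
#' @param community a `smart_community`.
#' @param n_reads number of reads.
#' @param read_length read length in bases (`k <= read_length <=`
#'   genome length).
#' @param substitution_rate per-base substitution probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return A `smart_readset` list with `reads` (named character), `truth`
#'   (`data.table`: `read_id`, `record_id`, `species_id`, `genus_id`,
#'   `class_id`, `offset`, `strand`, `n_subs`), `read_length`,
#'   `substitution_rate`, `seed`.
#' @export
simulate_reads <- function(community, n_reads, read_length = 100,
                           substitution_rate = 0.01, seed = 1) {
  stopifnot(inherits(community, "smart_community"))
  n_reads <- as.integer(n_reads)
  read_length <- as.integer(read_length)
  k <- community$params$k
  genome_length <- nchar(community$sequences[[1]])
  if (is.na(n_reads) || n_reads < 1) stop("n_reads must be >= 1")
  if (read_length < k) stop("read_length must be >= k = ", k)
  if (read_length > genome_length) {
    stop("read_length exceeds the genome length")
  }
  if (substitution_rate < 0 || substitution_rate > 1) {
    stop("substitution_rate must be in [0, 1]")
  }

  records <- names(community$sequences)
  is_host <- !is.na(community$host_record) &
    records == community$host_record
  probs <- if (any(is_host)) {
    p <- rep((1 - community$host_fraction) / sum(!is_host), length(records))
    p[is_host] <- community$host_fraction
    p
  } else {
    rep(1 / length(records), length(records))
  }

  withr::with_seed(as.integer(seed), {
    src <- sample(records, n_reads, replace = TRUE, prob = probs)
    start <- sample.int(genome_length - read_length + 1L, n_reads,
                        replace = TRUE)
    strand <- sample(c("F", "R"), n_reads, replace = TRUE)
    seqs <- substring(community$sequences[src], start,
                      start + read_length - 1L)
    rev_idx <- strand == "R"
    if (any(rev_idx)) seqs[rev_idx] <- reverse_complement(seqs[rev_idx])

    n_subs <- stats::rbinom(n_reads, read_length, substitution_rate)
    for (i in which(n_subs > 0)) {
      pos <- sample.int(read_length, n_subs[i])
      chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      for (p in pos) {
        chars[p] <- sample(setdiff(.BASES, chars[p]), 1L)
      }
      seqs[i] <- paste(chars, collapse = "")
    }

    ids <- sprintf("r%06d:%s:%d:%s:%d", seq_len(n_reads), src, start - 1L,
                   strand, n_subs)
    names(seqs) <- ids
    lin_idx <- match(src, community$taxonomy$record_id)
    truth <- data.table::data.table(
      read_id = ids,
      record_id = src,
      species_id = community$taxonomy$species_id[lin_idx],
      genus_id = community$taxonomy$genus_id[lin_idx],
      class_id = community$taxonomy$class_id[lin_idx],
      offset = start - 1L,
      strand = strand,
      n_subs = n_subs)

    structure(list(reads = seqs, truth = truth, read_length = read_length,
                   substitution_rate = substitution_rate,
                   seed = as.integer(seed)),
              class = "smart_readset")
  })
}

#' Write a simulation to disk
#'
#' Writes `refs.fa`, `tax.tsv`, `reads.fq` (constant quality, since
#' qualities are ignored downstream) and `truth.tsv` into a directory —
#' the self-contained inputs for an index build, search, and evaluation.
#'
#' @param community a `smart_community`.
#' @param readset a `smart_readset` from the same community (optional).
#' @param directory output directory (created if needed).
#' @return named list of the written paths, invisibly.
#' @export
write_simulation <- function(community, readset = NULL, directory) {
  stopifnot(inherits(community, "smart_community"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  refs <- file.path(directory, "refs.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(community$sequences), refs, width = 80L)
  tax <- file.path(directory, "tax.tsv")
  write_taxonomy(community$taxonomy, tax)
  paths <- list(refs = refs, tax = tax)
  if (!is.null(readset)) {
    stopifnot(inherits(readset, "smart_readset"))
    fq <- file.path(directory, "reads.fq")
    dss <- Biostrings::DNAStringSet(readset$reads)
    quals <- Biostrings::BStringSet(
      vapply(nchar(readset$reads), function(n) {
        paste(rep("I", n), collapse = "")
      }, character(1)))
    Biostrings::writeXStringSet(dss, fq, format = "fastq", qualities = quals)
    truth <- file.path(directory, "truth.tsv")
    data.table::fwrite(readset$truth, truth, sep = "\t")
    paths$reads <- fq
    paths$truth <- truth
  }
  invisible(paths)
}

#' Read a truth table written by [write_simulation()]
#'
#' @param path path to `truth.tsv`.
#' @return A `data.table`.
#' @export
read_truth <- function(path) {
  data.table::fread(path, sep = "\t", colClasses = list(
    character = c("read_id", "record_id", "species_id", "genus_id",
                  "class_id", "strand")))
}

#' @export
print.smart_community <- function(x, ...) {
  cat("Simulated community:", length(x$sequences), "genome(s) of",
      nchar(x$sequences[[1]]), "bp",
      if (!is.na(x$host_record)) "(incl. host)" else "", "\n")
  invisible(x)
}

#' @export
print.smart_readset <- function(x, ...) {
  cat("Simulated read set:", length(x$reads), "reads of", x$read_length,
      "bp, substitution rate", x$substitution_rate, "\n")
  invisible(x)
}
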