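#' Search configuration
#'
#' @param mode `"exact"` (only literal window matches) or `"permuted"`
#'   (additionally query every one-base substitution of each window, to
#'   tolerate SNPs and sequencing errors; indels are out of scope).
#' @param workers number of shard groups processed concurrently in the map
#'   step. Results are invariant to `workers` by contract.
#' @param params the `smart_params` of the index being searched.
#' @return A `smart_search_config` list.
#' @export
search_config <- function(mode = c("exact", "permuted"), workers = 1L,
                          params = index_params()) {
  mode <- match.arg(mode)
  workers <- as.integer(workers)
  if (is.na(workers) || workers < 1) stop("workers must be a positive integer")
  stopifnot(inherits(params, "smart_params"))
  structure(list(mode = mode, workers = workers, params = params),
            class = "smart_search_config")
}

#' Reverse complement of DNA sequences
#'
#' Watson-Crick complement, reversed; `N` is self-complementary. Input is
#' uppercased first; characters outside A/C/G/T/N are an error.
#'
#' @param seq character vector of sequences.
#' @return character vector of reverse complements (an involution).
#' @export
reverse_complement <- function(seq) {
  if (length(seq) == 0) return(character(0))
  seq <- toupper(seq)
  if (any(grepl("[^ACGTN]", seq))) {
    stop("sequence contains characters outside A/C/G/T/N")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Step-1 sliding windows over a read
#'
#' Windows of length `k` at every offset `0 .. length - k` (0-based,
#' half-open); windows containing a non-ACGT character are omitted and a
#' read shorter than `k` yields none. This is the read-side counterpart of
#' the database's step-k tiling ([tile_reference()]).
#'
#' @param read a single read sequence (character).
#' @param params a `smart_params` object.
#' @return data.frame with columns `offset` and `kmer`.
#' @export
sliding_windows <- function(read, params = index_params()) {
  stopifnot(is.character(read), length(read) == 1)
  read <- toupper(read)
  k <- params$k
  L <- nchar(read)
  if (L < k) {
    return(data.frame(offset = integer(0), kmer = character(0),
                      stringsAsFactors = FALSE))
  }
  starts <- seq_len(L - k + 1L)
  kmers <- substring(read, starts, starts + k - 1L)
  ok <- !grepl("[^ACGT]", kmers)
  data.frame(offset = starts[ok] - 1L, kmer = kmers[ok],
             stringsAsFactors = FALSE)
}

#' All one-base substitution variants of a k-mer
#'
#' Returns the `3 * nchar(kmer)` distinct strings at Hamming distance
#' exactly 1 from the input (90 for a 30-mer); the input itself is not
#' included.
#'
#' @param kmer an A/C/G/T string.
#' @return character vector of variants.
#' @export
permute_1bp <- function(kmer) {
  stopifnot(is.character(kmer), length(kmer) == 1)
  if (nchar(kmer) == 0 || grepl("[^ACGT]", kmer)) {
    stop("kmer must be a non-empty A/C/G/T string")
  }
  k <- nchar(kmer)
  chars <- strsplit(kmer, "", fixed = TRUE)[[1]]
  out <- character(3L * k)
  n <- 0L
  for (i in seq_len(k)) {
    for (b in setdiff(.BASES, chars[i])) {
      n <- n + 1L
      out[n] <- paste0(substr(kmer, 1L, i - 1L), b, substr(kmer, i + 1L, k))
    }
  }
  out
}

## read sequences from FASTA/FASTQ (auto-detected) or a named vector;
## returns uppercase named character vector
.as_read_sequences <- function(reads) {
  if (is.character(reads) && length(reads) == 1 && is.null(names(reads)) &&
      file.exists(reads)) {
    first <- substr(trimws(readLines(reads, n = 1L)), 1L, 1L)
    fmt <- if (identical(first, "@")) "fastq" else "fasta"
    ss <- Biostrings::readDNAStringSet(reads, format = fmt)
    out <- toupper(as.character(ss))
    names(out) <- sub("\\s.*$", "", names(ss))
  } else {
    if (is.null(names(reads)) || any(!nzchar(names(reads)))) {
      stop("reads must be named (read ids) or given as a FASTA/FASTQ path")
    }
    out <- toupper(as.character(reads))
    names(out) <- names(reads)
  }
  if (anyDuplicated(names(out))) {
    stop("duplicate read id(s): ",
         paste(utils::head(unique(names(out)[duplicated(names(out))]), 5),
               collapse = ", "))
  }
  out
}

## empty canonical match table
.empty_matches <- function() {
  data.table::data.table(read_id = character(0), offset = integer(0),
                         strand = character(0), permuted = logical(0),
                         species = character(0))
}

## run the compiled scanner for one group of shards; shards is a list of
## plain shard lists (prefix/suffixes/species), codes their 0-based indices
.search_group <- function(seqs, shards, codes, params, mode) {
  levels <- sort(unique(unlist(lapply(shards, `[[`, "species"),
                               use.names = FALSE)), method = "radix")
  payload_species <- lapply(shards, function(s) {
    lapply(s$species, function(sp) match(sp, levels))
  })
  res <- cpp_search(unname(seqs), params$k, params$prefix_len,
                    as.integer(codes),
                    lapply(shards, `[[`, "suffixes"),
                    payload_species,
                    identical(mode, "permuted"))
  m <- data.table::data.table(
    read_id = names(seqs)[res$read],
    offset = res$offset,
    strand = c("forward", "reverse")[res$strand + 1L],
    permuted = res$permuted,
    species = levels[res$species])
  reads_info <- data.table::data.table(
    read_id = names(seqs), length = nchar(seqs),
    windows_scanned = res$windows_scanned)
  structure(m, reads = reads_info, mode = mode)
}

#' Search reads against a single shard (map step)
#'
#' One unit of the map step: the shard answers every window whose first
#' `prefix_len` bases equal its prefix and, in permuted mode, every
#' one-base substitution variant (of any window) whose mutated prefix
#' equals its prefix. Variants whose substitution changes the prefix are
#' thereby answered by the shard owning the new prefix, so the union over
#' all shards equals a global 1-edit search.
#'
#' @param reads FASTA/FASTQ path or named character vector of reads.
#' @param shard a shard of a `smart_index` (an element of `index$shards`)
#'   or a `smart_shard` from [load_shard()].
#' @param config a `smart_search_config`; its `params` must match the
#'   shard's index.
#' @return A match table (`data.table`) with columns `read_id`, `offset`
#'   (0-based on the scanned strand), `strand`, `permuted`, `species`, and
#'   attribute `reads` (per-read lengths and window counts).
#' @export
search_shard <- function(reads, shard, config) {
  stopifnot(inherits(config, "smart_search_config"))
  if (!is.null(shard$params) &&
      !identical(unclass(shard$params)[c("k", "prefix_len")],
                 unclass(config$params)[c("k", "prefix_len")])) {
    stop("search config params do not match the shard's index params")
  }
  seqs <- .as_read_sequences(reads)
  m <- .search_group(seqs, list(shard), encode_prefix(shard$prefix),
                     config$params, config$mode)
  .canonical_matches(m)
}

## canonical row order (C-locale radix sort)
.canonical_matches <- function(m) {
  read_id <- offset <- strand <- species <- NULL
  data.table::setorder(m, read_id, strand, offset, species)
  m
}

#' Merge per-shard match lists into per-read match sets (reduce step)
#'
#' Concatenates per-shard match tables, deduplicates on
#' (read, offset, strand, species) — a species supported by both an exact
#' window and a permuted variant is kept once with `permuted = FALSE` — and
#' sorts canonically, so the result is independent of shard processing
#' order.
#'
#' @param partials list of match tables from [search_shard()] /
#'   [search_reads()] map steps over the same reads.
#' @return A single canonical match table.
#' @export
reduce_matches <- function(partials) {
  stopifnot(is.list(partials), length(partials) > 0)
  reads_infos <- lapply(partials, attr, "reads")
  ri <- data.table::rbindlist(reads_infos)
  read_id <- length_ <- NULL
  chk <- unique(ri)
  if (anyDuplicated(chk$read_id)) {
    bad <- unique(chk$read_id[duplicated(chk$read_id)])
    stop("conflicting read id(s) across map partials: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  m <- data.table::rbindlist(partials)
  if (nrow(m) > 0) {
    permuted <- offset <- strand <- species <- NULL
    m <- m[, list(permuted = all(permuted)),
           by = c("read_id", "offset", "strand", "species")]
    data.table::setcolorder(m, c("read_id", "offset", "strand", "permuted",
                                 "species"))
  } else {
    m <- .empty_matches()
  }
  m <- .canonical_matches(m)
  mode <- unique(unlist(lapply(partials, attr, "mode")))
  structure(m, reads = chk, mode = if (length(mode) == 1) mode else NULL)
}

#' Map-reduce search of reads against a sharded index
#'
#' Splits the occupied shards into `workers` groups, scans the reads
#' against each group (concurrently when `workers > 1`), and reduces the
#' per-group match lists with [reduce_matches()]. Results are identical for
#' any `workers` and any shard order.
#'
#' @param index a `smart_index`.
#' @param reads FASTA/FASTQ path or named character vector of reads.
#' @param config a `smart_search_config`; defaults to exact mode with the
#'   index's params.
#' @param shard_order optional permutation of the occupied shard positions
#'   (mainly for testing order invariance).
#' @return A canonical match table (see [search_shard()] for columns).
#' @export
search_reads <- function(index, reads,
                         config = search_config(params = index$params),
                         shard_order = NULL) {
  stopifnot(inherits(index, "smart_index"),
            inherits(config, "smart_search_config"))
  if (!identical(unclass(config$params)[c("k", "prefix_len")],
                 unclass(index$params)[c("k", "prefix_len")])) {
    stop("search config params do not match the index params")
  }
  seqs <- .as_read_sequences(reads)
  occupied <- which(vapply(index$shards, function(s) length(s$suffixes) > 0,
                           logical(1)))
  if (!is.null(shard_order)) {
    if (!setequal(shard_order, occupied)) {
      stop("shard_order must be a permutation of the occupied shard positions")
    }
    occupied <- shard_order
  }
  if (length(occupied) == 0) {
    empty <- structure(.empty_matches(),
                       reads = data.table::data.table(
                         read_id = names(seqs), length = nchar(seqs),
                         windows_scanned = .count_windows(seqs, index$params)),
                       mode = config$mode)
    return(empty)
  }
  groups <- split(occupied,
                  rep_len(seq_len(min(config$workers, length(occupied))),
                          length(occupied)))
  run_one <- function(pos) {
    .search_group(seqs, index$shards[pos], pos - 1L, index$params,
                  config$mode)
  }
  partials <- if (config$workers > 1 && length(groups) > 1 &&
                  .Platform$OS.type == "unix") {
    parallel::mclapply(groups, run_one,
                       mc.cores = min(config$workers, length(groups)))
  } else {
    lapply(groups, run_one)
  }
  reduce_matches(partials)
}

## valid windows per read over both strands (used when no shard is occupied)
.count_windows <- function(seqs, params) {
  vapply(seqs, function(s) {
    nrow(sliding_windows(s, params)) +
      nrow(sliding_windows(reverse_complement(gsub("[^ACGTN]", "N", s)),
                           params))
  }, integer(1))
}

#' Write / read the intermediate match TSV
#'
#' One row per (read, offset, strand, permuted) event with the species list
#' comma-joined; per-read metadata (length, windows scanned) is carried in
#' `#read` header lines so unmatched reads survive the round trip.
#'
#' @param matches a match table from [search_reads()].
#' @param path output TSV path.
#' @return `path` invisibly (`write_matches`); a match table
#'   (`read_matches`).
#' @export
write_matches <- function(matches, path) {
  reads_info <- attr(matches, "reads")
  if (is.null(reads_info)) stop("matches lack the per-read attribute")
  mode <- attr(matches, "mode")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# smart-matches v1 mode=",
                    if (is.null(mode)) "unknown" else mode), con)
  writeLines(paste0("#read\t", reads_info$read_id, "\t", reads_info$length,
                    "\t", reads_info$windows_scanned), con)
  writeLines("read_id\toffset\tstrand\tpermuted\tspecies_list", con)
  if (nrow(matches) > 0) {
    species <- NULL
    g <- matches[, list(species_list = paste(sort(species), collapse = ",")),
                 by = c("read_id", "offset", "strand", "permuted")]
    writeLines(paste(g$read_id, g$offset, g$strand,
                     ifelse(g$permuted, "1", "0"), g$species_list,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_matches
#' @export
read_matches <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^#", lines)
  read_lines <- lines[startsWith(lines, "#read\t")]
  parts <- strsplit(read_lines, "\t", fixed = TRUE)
  reads_info <- data.table::data.table(
    read_id = vapply(parts, `[[`, character(1), 2L),
    length = as.integer(vapply(parts, `[[`, character(1), 3L)),
    windows_scanned = as.integer(vapply(parts, `[[`, character(1), 4L)))
  mode <- sub("^# smart-matches v1 mode=", "", lines[1])
  body <- lines[!hdr]
  body <- body[-1]  # column header
  if (length(body) == 0) {
    m <- .empty_matches()
  } else {
    bp <- strsplit(body, "\t", fixed = TRUE)
    sp <- lapply(bp, function(x) strsplit(x[[5]], ",", fixed = TRUE)[[1]])
    n <- lengths(sp)
    m <- data.table::data.table(
      read_id = rep(vapply(bp, `[[`, character(1), 1L), n),
      offset = rep(as.integer(vapply(bp, `[[`, character(1), 2L)), n),
      strand = rep(vapply(bp, `[[`, character(1), 3L), n),
      permuted = rep(vapply(bp, `[[`, character(1), 4L) == "1", n),
      species = unlist(sp, use.names = FALSE))
  }
  structure(.canonical_matches(m), reads = reads_info,
            mode = if (mode %in% c("exact", "permuted")) mode else NULL)
}
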