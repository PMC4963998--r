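#' Index parameters
#'
#' Parameters of the sharded k-mer database: the window length `k`, the
#' shard-key length `prefix_len` (the first `prefix_len` bases of a k-mer
#' select its shard, so there are `4^prefix_len` shards; 256 at the
#' defaults), and the class label that triggers the host override.
#'
#' @param k k-mer / window length in bases. Default 30.
#' @param prefix_len shard-key length in bases. Default 4.
#' @param mammalian_class class label treated as host. Default `"Mammalia"`.
#' @return A `smart_params` list with `k`, `prefix_len`, `mammalian_class`,
#'   and the derived `shard_count`.
#' @export
index_params <- function(k = 30L, prefix_len = 4L,
                         mammalian_class = "Mammalia") {
  k <- as.integer(k)
  prefix_len <- as.integer(prefix_len)
  if (is.na(k) || k < 2 || k > 32) {
    stop("k must be an integer in [2, 32] (2-bit encoding in a 64-bit word)")
  }
  if (is.na(prefix_len) || prefix_len <= 0 || prefix_len >= k) {
    stop("prefix_len must satisfy 0 < prefix_len < k")
  }
  if (prefix_len > 10) stop("prefix_len > 10 is not supported")
  if (!is.character(mammalian_class) || length(mammalian_class) != 1 ||
      !nzchar(mammalian_class)) {
    stop("mammalian_class must be a single non-empty label")
  }
  structure(list(k = k, prefix_len = prefix_len,
                 mammalian_class = mammalian_class,
                 shard_count = 4L^prefix_len),
            class = "smart_params")
}

.BASES <- c("A", "C", "G", "T")

#' Encode a shard prefix as its shard index
#'
#' Maps a base string of length `prefix_len` bijectively onto
#' `0 .. 4^prefix_len - 1` with A=0, C=1, G=2, T=3, first base most
#' significant. The shard at that position of the index owns every k-mer
#' beginning with the prefix.
#'
#' @param prefix base string(s) over A/C/G/T.
#' @return integer shard index (0-based), vectorized over `prefix`.
#' @examples
#' encode_prefix("AAAA")  # 0
#' encode_prefix("ACGT")  # 27
#' encode_prefix("TTTT")  # 255
#' @export
encode_prefix <- function(prefix) {
  if (length(prefix) == 0) return(integer(0))
  n <- nchar(prefix)
  if (length(unique(n)) != 1) stop("prefixes must have equal length")
  chars <- strsplit(prefix, "", fixed = TRUE)
  codes <- vapply(chars, function(cc) {
    d <- match(cc, .BASES) - 1L
    if (anyNA(d)) stop("prefix contains a non-ACGT character")
    sum(d * 4L^(rev(seq_along(d)) - 1L))
  }, numeric(1))
  as.integer(codes)
}

#' Decode a shard index back to its prefix string
#'
#' Inverse of [encode_prefix()].
#'
#' @param code integer shard index (0-based), vectorized.
#' @param prefix_len prefix length in bases.
#' @return character vector of prefixes.
#' @export
decode_prefix <- function(code, prefix_len = 4L) {
  prefix_len <- as.integer(prefix_len)
  code <- as.integer(code)
  if (any(is.na(code)) || any(code < 0) || any(code >= 4^prefix_len)) {
    stop("shard index out of range for prefix_len ", prefix_len)
  }
  vapply(code, function(x) {
    digits <- integer(prefix_len)
    for (i in seq_len(prefix_len)) {
      digits[prefix_len - i + 1L] <- x %% 4L
      x <- x %/% 4L
    }
    paste(.BASES[digits + 1L], collapse = "")
  }, character(1))
}

## all 4^prefix_len prefixes in shard order
.all_prefixes <- function(prefix_len) {
  decode_prefix(seq_len(4L^prefix_len) - 1L, prefix_len)
}

#' Tile a reference sequence into non-overlapping k-mers
#'
#' Cuts the forward strand at every `k` bases: tiles start at offsets
#' 0, k, 2k, ... (0-based) and a trailing remainder shorter than `k` is
#' discarded. The sequence is uppercased first; any tile still containing a
#' non-ACGT character (N, IUPAC ambiguity codes) is skipped. This step-k
#' tiling is what the database stores; reads are searched with a step-1
#' sliding window instead (see [sliding_windows()]).
#'
#' @param sequence a single reference sequence (character).
#' @param params a `smart_params` object.
#' @return data.frame with columns `offset` (0-based tile start) and `kmer`.
#' @examples
#' p <- index_params(k = 30)
#' seq95 <- paste(rep("ACGTA", 19), collapse = "")
#' nrow(tile_reference(seq95, p))  # floor(95/30) = 3
#' @export
tile_reference <- function(sequence, params = index_params()) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  k <- params$k
  L <- nchar(sequence)
  if (L < k) {
    return(data.frame(offset = integer(0), kmer = character(0),
                      stringsAsFactors = FALSE))
  }
  starts <- seq.int(1L, L - k + 1L, by = k)
  kmers <- substring(sequence, starts, starts + k - 1L)
  ok <- !grepl("[^ACGT]", kmers)
  data.frame(offset = starts[ok] - 1L, kmer = kmers[ok],
             stringsAsFactors = FALSE)
}

#' Build the sharded k-mer index from reference sequences
#'
#' Tiles every reference into non-overlapping k-mers, links each k-mer to
#' the species of its record, and routes each (k-mer, species) pair to the
#' shard owning the k-mer's prefix. Within a shard, the suffixes (the
#' remaining `k - prefix_len` bases) are sorted and each maps to the
#' deduplicated, sorted set of species whose references contain the full
#' k-mer. Sorting makes the result canonical: the index is byte-identical
#' under any permutation of the input records.
#'
#' @param references path to a (multi-)FASTA file, or a named character
#'   vector of sequences (names are record ids).
#' @param taxonomy a `smart_taxonomy` table covering every reference record.
#' @param params a `smart_params` object.
#' @return A `smart_index` object.
#' @export
build_index <- function(references, taxonomy, params = index_params()) {
  stopifnot(inherits(taxonomy, "smart_taxonomy"))
  seqs <- .as_named_sequences(references)
  if (length(seqs) == 0) stop("no reference sequences to index")
  missing <- setdiff(names(seqs), taxonomy$record_id)
  if (length(missing) > 0) {
    stop("reference record(s) absent from taxonomy: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }

  k <- params$k
  p <- params$prefix_len
  tiles <- lapply(names(seqs), function(id) {
    tl <- tile_reference(seqs[[id]], params)
    if (nrow(tl) == 0) return(NULL)
    data.table::data.table(
      kmer = tl$kmer,
      species = taxonomy$species_id[match(id, taxonomy$record_id)])
  })
  dt <- data.table::rbindlist(tiles)
  n_raw <- nrow(dt)
  if (n_raw == 0) stop("references yielded no ACGT-only tiles of length ", k)
  dt <- unique(dt)
  data.table::setorder(dt, kmer, species)  # radix: canonical byte order
  dt[, `:=`(prefix = substr(kmer, 1L, p), suffix = substr(kmer, p + 1L, k))]

  shards <- vector("list", params$shard_count)
  prefixes <- .all_prefixes(p)
  for (i in seq_along(shards)) {
    shards[[i]] <- list(prefix = prefixes[i], suffixes = character(0),
                        species = list())
  }
  suffix <- species <- NULL  # data.table NSE
  for (grp in split(dt, by = "prefix", sorted = TRUE)) {
    code <- encode_prefix(grp$prefix[1])
    agg <- grp[, list(species = list(species)), by = suffix]
    shards[[code + 1L]]$suffixes <- agg$suffix
    shards[[code + 1L]]$species <- agg$species
  }

  structure(list(params = params, shards = shards, taxonomy = taxonomy,
                 n_kmers_raw = n_raw, n_kmers_distinct = nrow(dt),
                 n_distinct_kmer_strings = length(unique(dt$kmer))),
            class = "smart_index")
}

## accept a FASTA path or a named character vector
.as_named_sequences <- function(x) {
  if (length(x) == 0) {
    return(stats::setNames(character(0), character(0)))
  }
  if (is.character(x) && length(x) == 1 && is.null(names(x)) &&
      file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x)
    out <- toupper(as.character(ss))
    names(out) <- sub("\\s.*$", "", names(ss))
  } else {
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      stop("sequences must be named (record ids) or given as a FASTA path")
    }
    out <- toupper(as.character(x))
    names(out) <- names(x)
  }
  if (anyDuplicated(names(out))) {
    stop("duplicate record id(s): ",
         paste(utils::head(unique(names(out)[duplicated(names(out))]), 5),
               collapse = ", "))
  }
  out
}

#' Exact-match lookup of one k-mer
#'
#' Routes the k-mer to the shard owning its prefix and looks up the
#' remaining suffix in that shard's table. Pure: returns the stored species
#' set or an empty character vector.
#'
#' @param index a `smart_index`, or a single `smart_shard` from
#'   [load_shard()] (which can only answer k-mers with its own prefix).
#' @param kmer a k-mer of length `params$k` over A/C/G/T.
#' @return character vector of species ids (sorted; empty if absent).
#' @export
lookup <- function(index, kmer) {
  UseMethod("lookup")
}

#' @export
lookup.smart_index <- function(index, kmer) {
  .check_kmer(kmer, index$params$k)
  code <- encode_prefix(substr(kmer, 1L, index$params$prefix_len))
  .shard_lookup(index$shards[[code + 1L]], kmer, index$params)
}

#' @export
lookup.smart_shard <- function(index, kmer) {
  .check_kmer(kmer, index$params$k)
  prefix <- substr(kmer, 1L, index$params$prefix_len)
  if (prefix != index$prefix) {
    stop("k-mer prefix ", prefix, " is not owned by shard ", index$prefix)
  }
  .shard_lookup(index, kmer, index$params)
}

.check_kmer <- function(kmer, k) {
  if (!is.character(kmer) || length(kmer) != 1) stop("kmer must be a single string")
  if (nchar(kmer) != k) stop("kmer must have length ", k)
  if (grepl("[^ACGT]", kmer)) stop("kmer contains a non-ACGT character")
}

.shard_lookup <- function(shard, kmer, params) {
  suffix <- substr(kmer, params$prefix_len + 1L, params$k)
  i <- match(suffix, shard$suffixes)
  if (is.na(i)) character(0) else shard$species[[i]]
}

#' Save a sharded index to a directory
#'
#' Writes one plain-text file per shard (`shard_<prefix>`, sorted
#' `suffix<TAB>species,species,...` lines), the taxonomy as
#' `taxonomy.tsv`, and a JSON `manifest` recording the parameters, per-shard
#' entry counts and MD5 checksums. Each shard is independent, so a single
#' shard can later be loaded without the other `4^prefix_len - 1`.
#'
#' @param index a `smart_index`.
#' @param directory output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
save_index <- function(index, directory) {
  stopifnot(inherits(index, "smart_index"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  shard_meta <- list()
  for (shard in index$shards) {
    f <- file.path(directory, paste0("shard_", shard$prefix))
    lines <- if (length(shard$suffixes) > 0) {
      paste0(shard$suffixes, "\t",
             vapply(shard$species, paste, character(1), collapse = ","))
    } else character(0)
    writeLines(lines, f)
    shard_meta[[shard$prefix]] <- list(
      n_entries = length(shard$suffixes),
      md5 = unname(tools::md5sum(f)))
  }
  tax_path <- file.path(directory, "taxonomy.tsv")
  write_taxonomy(index$taxonomy, tax_path)
  manifest <- list(
    format = "smart-index-v1",
    k = index$params$k,
    prefix_len = index$params$prefix_len,
    mammalian_class = index$params$mammalian_class,
    n_kmers_raw = index$n_kmers_raw,
    n_kmers_distinct = index$n_kmers_distinct,
    n_distinct_kmer_strings = index$n_distinct_kmer_strings,
    taxonomy_md5 = unname(tools::md5sum(tax_path)),
    shards = shard_meta)
  jsonlite::write_json(manifest, file.path(directory, "manifest"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

.read_manifest <- function(directory) {
  mf <- file.path(directory, "manifest")
  if (!file.exists(mf)) stop("no manifest in ", directory)
  jsonlite::read_json(mf, simplifyVector = FALSE)
}

.load_shard_file <- function(directory, prefix, meta) {
  f <- file.path(directory, paste0("shard_", prefix))
  if (!file.exists(f)) stop("missing shard file for prefix ", prefix)
  md5 <- unname(tools::md5sum(f))
  if (!identical(md5, meta$md5)) {
    stop("checksum mismatch for shard ", prefix, " (corrupt shard file)")
  }
  lines <- readLines(f, warn = FALSE)
  if (length(lines) != meta$n_entries) {
    stop("shard ", prefix, ": expected ", meta$n_entries, " entries, found ",
         length(lines))
  }
  if (length(lines) == 0) {
    return(list(prefix = prefix, suffixes = character(0), species = list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  list(prefix = prefix,
       suffixes = vapply(parts, `[[`, character(1), 1L),
       species = lapply(parts, function(x) {
         strsplit(x[[2]], ",", fixed = TRUE)[[1]]
       }))
}

#' Load a saved index
#'
#' Verifies the manifest checksums and reconstructs the full
#' `smart_index`; the round trip through [save_index()] is lossless.
#'
#' @param directory directory written by [save_index()].
#' @param params optional `smart_params` the caller expects; a mismatch
#'   with the manifest is an error.
#' @return A `smart_index`.
#' @export
load_index <- function(directory, params = NULL) {
  manifest <- .read_manifest(directory)
  mp <- index_params(k = manifest$k, prefix_len = manifest$prefix_len,
                     mammalian_class = manifest$mammalian_class)
  if (!is.null(params) && !identical(unclass(params), unclass(mp))) {
    stop("index parameters in manifest do not match the requested params")
  }
  tax_path <- file.path(directory, "taxonomy.tsv")
  if (!file.exists(tax_path)) stop("missing taxonomy.tsv in ", directory)
  if (!identical(unname(tools::md5sum(tax_path)), manifest$taxonomy_md5)) {
    stop("taxonomy.tsv checksum mismatch")
  }
  taxonomy <- load_taxonomy(tax_path, mammalian_class = mp$mammalian_class)
  prefixes <- .all_prefixes(mp$prefix_len)
  shards <- lapply(prefixes, function(px) {
    meta <- manifest$shards[[px]]
    if (is.null(meta)) stop("manifest lacks shard entry for prefix ", px)
    .load_shard_file(directory, px, meta)
  })
  n_distinct <- sum(vapply(shards, function(s) {
    sum(lengths(s$species))
  }, numeric(1)))
  structure(list(params = mp, shards = shards, taxonomy = taxonomy,
                 n_kmers_raw = manifest$n_kmers_raw,
                 n_kmers_distinct = n_distinct,
                 n_distinct_kmer_strings = manifest$n_distinct_kmer_strings),
            class = "smart_index")
}

#' Load a single shard from a saved index
#'
#' Loads one shard file (plus the taxonomy and parameters from the
#' manifest) without touching the other shards, supporting piecewise /
#' memory-bounded use of the database. The returned object answers
#' [lookup()] for k-mers with its prefix and can be searched with
#' [search_shard()].
#'
#' @param directory directory written by [save_index()].
#' @param prefix the shard's prefix string (e.g. `"ACGT"`).
#' @return A `smart_shard` object.
#' @export
load_shard <- function(directory, prefix) {
  manifest <- .read_manifest(directory)
  mp <- index_params(k = manifest$k, prefix_len = manifest$prefix_len,
                     mammalian_class = manifest$mammalian_class)
  if (nchar(prefix) != mp$prefix_len) {
    stop("prefix must have length ", mp$prefix_len)
  }
  encode_prefix(prefix)  # validates alphabet
  meta <- manifest$shards[[prefix]]
  if (is.null(meta)) stop("manifest lacks shard entry for prefix ", prefix)
  shard <- .load_shard_file(directory, prefix, meta)
  shard$params <- mp
  class(shard) <- "smart_shard"
  shard
}

#' @export
print.smart_index <- function(x, ...) {
  n_occupied <- sum(vapply(x$shards, function(s) length(s$suffixes) > 0,
                           logical(1)))
  cat("Sharded k-mer index\n")
  cat("  k =", x$params$k, ", prefix_len =", x$params$prefix_len,
      sprintf("(%d shards, %d occupied)\n", x$params$shard_count, n_occupied))
  cat("  distinct (k-mer, species) pairs:", x$n_kmers_distinct, "\n")
  cat("  distinct k-mer strings:", x$n_distinct_kmer_strings, "\n")
  cat("  species:", length(unique(x$taxonomy$species_id)),
      "| mammalian class:", x$params$mammalian_class, "\n")
  invisible(x)
}
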