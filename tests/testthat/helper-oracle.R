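# Independent brute-force oracle: a naive k-mer dictionary built by string
# tiling, scanned per window with plain string operations. Used to verify
# the sharded map-reduce search and the classification pipeline.

oracle_revcomp <- function(s) {
  chartr_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  paste(rev(unname(chartr_map[chars])), collapse = "")
}

# kmer -> sorted species set, from non-overlapping step-k tiles
oracle_dict <- function(sequences, taxonomy, k = 30) {
  e <- new.env(hash = TRUE, parent = emptyenv())
  for (id in names(sequences)) {
    sp <- taxonomy$species_id[match(id, taxonomy$record_id)]
    s <- toupper(sequences[[id]])
    L <- nchar(s)
    if (L < k) next
    starts <- seq.int(1L, L - k + 1L, by = k)
    kms <- substring(s, starts, starts + k - 1L)
    kms <- kms[!grepl("[^ACGT]", kms)]
    for (km in kms) e[[km]] <- sort(unique(c(e[[km]], sp)))
  }
  e
}

# all 3*k Hamming-distance-1 substitution variants of a k-mer
oracle_variants <- function(km) {
  k <- nchar(km)
  chars <- strsplit(km, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (i in seq_len(k)) {
    for (b in setdiff(c("A", "C", "G", "T"), chars[i])) {
      out <- c(out, paste0(substr(km, 1, i - 1), b, substr(km, i + 1, k)))
    }
  }
  out
}

# neighborhood-expanded dictionary: query -> union of species over stored
# k-mers at Hamming distance exactly 1 (equivalent to scanning all 3k
# variants of the query against the exact dictionary)
oracle_dict1 <- function(dict) {
  e1 <- new.env(hash = TRUE, parent = emptyenv())
  for (km in ls(dict)) {
    sp <- dict[[km]]
    for (v in oracle_variants(km)) e1[[v]] <- c(e1[[v]], sp)
  }
  for (v in ls(e1)) e1[[v]] <- sort(unique(e1[[v]]))
  e1
}

# single-pass scan of every window of every read on both strands.
# permuted = "none"  : exact lookups only
# permuted = "dict1" : 1-edit matches via the expanded dictionary
# permuted = "scan"  : 1-edit matches by looking up all 3k variants of each
#                      window (literal brute force; slow, tiny inputs only)
oracle_scan <- function(reads, dict, k = 30, permuted = "none",
                        dict1 = NULL) {
  stopifnot(permuted %in% c("none", "dict1", "scan"))
  if (permuted == "dict1" && is.null(dict1)) dict1 <- oracle_dict1(dict)
  rows <- vector("list", 2L * length(reads))
  n <- 0L
  win_count <- integer(length(reads))
  for (r in seq_along(reads)) {
    id <- names(reads)[r]
    for (strand in c("forward", "reverse")) {
      s <- toupper(reads[[r]])
      if (strand == "reverse") s <- oracle_revcomp(s)
      L <- nchar(s)
      if (L < k) next
      starts <- seq_len(L - k + 1L)
      wins <- substring(s, starts, starts + k - 1L)
      ok <- !grepl("[^ACGT]", wins)
      win_count[r] <- win_count[r] + sum(ok)
      offs <- starts[ok] - 1L
      wins <- wins[ok]
      exact <- mget(wins, envir = dict, ifnotfound = list(NULL))
      perm <- switch(permuted,
        none = vector("list", length(wins)),
        dict1 = mget(wins, envir = dict1, ifnotfound = list(NULL)),
        scan = lapply(wins, function(w) {
          hits <- mget(oracle_variants(w), envir = dict,
                       ifnotfound = list(NULL))
          sort(unique(unlist(hits, use.names = FALSE)))
        }))
      keep <- which(lengths(exact) > 0 | lengths(perm) > 0)
      if (length(keep) == 0) next
      parts <- lapply(keep, function(j) {
        ex <- exact[[j]]
        pm <- setdiff(perm[[j]], ex)
        data.frame(
          read_id = id,
          offset = offs[j],
          strand = strand,
          permuted = rep(c(FALSE, TRUE), c(length(ex), length(pm))),
          species = c(ex, pm),
          stringsAsFactors = FALSE)
      })
      n <- n + 1L
      rows[[n]] <- do.call(rbind, parts)
    }
  }
  m <- if (n > 0) {
    data.table::rbindlist(rows[seq_len(n)])
  } else {
    data.table::data.table(read_id = character(0), offset = integer(0),
                           strand = character(0), permuted = logical(0),
                           species = character(0))
  }
  data.table::setorder(m, read_id, strand, offset, species)
  attr(m, "windows_scanned") <-
    stats::setNames(win_count, names(reads))
  m
}

# independent per-read category assignment from an oracle match table
oracle_categories <- function(matches, taxonomy, read_ids,
                              apply_override = TRUE) {
  lin <- unique(as.data.frame(taxonomy)[c("species_id", "is_mammalian")])
  mam <- lin$species_id[lin$is_mammalian]
  split_sp <- split(matches$species, matches$read_id)
  out <- stats::setNames(rep("unmatched", length(read_ids)), read_ids)
  for (id in names(split_sp)) {
    sp <- split_sp[[id]]
    votes <- table(sp)
    winners <- names(votes)[votes == max(votes)]
    cat_tally <- if (length(winners) > 1) {
      "ambiguous"
    } else if (winners %in% mam) {
      "mammalian"
    } else {
      "non_mammalian"
    }
    out[[id]] <- if (apply_override && any(sp %in% mam)) "mammalian" else
      cat_tally
  }
  out
}
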