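#' Tally votes for one read's match set
#'
#' One vote per deduplicated (window, strand, species) match event at the
#' species level; genus and class tallies are derived by summing species
#' votes over the lineage, never tallied independently.
#'
#' @param match_set match table rows for a single read.
#' @param taxonomy a `smart_taxonomy` covering every matched species.
#' @return list with named integer vectors `species`, `genus`, `class`
#'   (empty for an empty match set).
#' @export
tally_votes <- function(match_set, taxonomy) {
  stopifnot(inherits(taxonomy, "smart_taxonomy"))
  if (nrow(match_set) == 0) {
    z <- integer(0)
    return(list(species = z, genus = z, class = z))
  }
  if (length(unique(match_set$read_id)) > 1) {
    stop("tally_votes expects the match set of a single read")
  }
  lin <- .species_lineage(taxonomy)
  unknown <- setdiff(unique(match_set$species), lin$species_id)
  if (length(unknown) > 0) {
    stop("matched species without lineage: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  sp <- table(match_set$species)
  sp_names <- names(sp)
  i <- match(sp_names, lin$species_id)
  agg <- function(labels) {
    v <- tapply(as.integer(sp), labels, sum)
    stats::setNames(as.integer(v), names(v))
  }
  list(species = stats::setNames(as.integer(sp), sp_names),
       genus = agg(lin$genus_id[i]),
       class = agg(lin$class_id[i]))
}

.verdict_of <- function(votes) {
  if (length(votes) == 0) return("UNMATCHED")
  top <- max(votes)
  winners <- names(votes)[votes == top]
  if (length(winners) > 1) "AMBIGUOUS" else winners
}

#' Classify a single read from its vote tally
#'
#' Per level the verdict is `UNMATCHED` with no votes, the unique
#' highest-voted taxon, or `AMBIGUOUS` on a tie (evaluated independently
#' per level, so a species-level tie can still resolve at genus level).
#' The host override is recorded separately: if any matched species is
#' mammalian the read's final category is `mammalian` regardless of the
#' tallies.
#'
#' @param match_set match table rows for one read.
#' @param taxonomy a `smart_taxonomy`.
#' @param tally optionally a precomputed [tally_votes()] result for
#'   `match_set`.
#' @param apply_override apply the mammalian-override rule when assigning
#'   the final category (default TRUE).
#' @return list with `read_id`, per-level verdicts, `category`,
#'   `mammalian_override`, `n_votes_species`, and the `tally`.
#' @export
classify_read <- function(match_set, taxonomy,
                          tally = tally_votes(match_set, taxonomy),
                          apply_override = TRUE) {
  if (sum(tally$species) != nrow(match_set)) {
    stop("tally is inconsistent with the match set")
  }
  read_id <- if (nrow(match_set) > 0) match_set$read_id[1] else NA_character_
  sv <- .verdict_of(tally$species)
  gv <- .verdict_of(tally$genus)
  cv <- .verdict_of(tally$class)
  lin <- .species_lineage(taxonomy)
  mam <- lin$species_id[lin$is_mammalian]
  override <- any(names(tally$species) %in% mam)
  category <- if (apply_override && override) {
    "mammalian"
  } else if (sv == "UNMATCHED") {
    "unmatched"
  } else if (sv == "AMBIGUOUS") {
    "ambiguous"
  } else if (sv %in% mam) {
    "mammalian"
  } else {
    "non_mammalian"
  }
  list(read_id = read_id, species_verdict = sv, genus_verdict = gv,
       class_verdict = cv, category = category,
       mammalian_override = override,
       n_votes_species = sum(tally$species), tally = tally)
}

#' Classify every read of a match table
#'
#' Vectorized classification: vote tallies per level, tie-aware verdicts,
#' the mammalian override, and the final sample category per read (with
#' precedence mammalian > unmatched > ambiguous > non_mammalian). Reads
#' that produced no match anywhere are included as `UNMATCHED` via the
#' match table's per-read attribute.
#'
#' @param matches a match table from [search_reads()] / [reduce_matches()].
#' @param taxonomy a `smart_taxonomy`.
#' @param apply_override apply the mammalian-override rule (default TRUE).
#'   With `FALSE`, reads keep their tally-derived category (a unique
#'   mammalian species verdict still counts as mammalian).
#' @return A `data.table` with one row per read: `read_id`,
#'   `species_verdict`, `genus_verdict`, `class_verdict`, `category`,
#'   `n_votes_species`, `mammalian_override`.
#' @export
classify_reads <- function(matches, taxonomy, apply_override = TRUE) {
  stopifnot(inherits(taxonomy, "smart_taxonomy"))
  reads_info <- attr(matches, "reads")
  all_ids <- if (!is.null(reads_info)) reads_info$read_id else
    unique(matches$read_id)

  lin <- .species_lineage(taxonomy)
  if (nrow(matches) > 0) {
    unknown <- setdiff(unique(matches$species), lin$species_id)
    if (length(unknown) > 0) {
      stop("matched species without lineage: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
  }

  m <- data.table::as.data.table(matches)
  i <- match(m$species, lin$species_id)
  m$genus <- lin$genus_id[i]
  m$class <- lin$class_id[i]
  m$is_mammalian <- lin$is_mammalian[i]

  level_verdict <- function(taxon_col) {
    N <- NULL
    votes <- m[, list(N = .N), by = c("read_id", taxon_col)]
    data.table::setnames(votes, taxon_col, "taxon")
    taxon <- NULL
    votes[, {
      top <- max(N)
      w <- taxon[N == top]
      list(verdict = if (length(w) > 1) "AMBIGUOUS" else w)
    }, by = "read_id"]
  }

  if (nrow(m) > 0) {
    sv <- level_verdict("species")
    gv <- level_verdict("genus")
    cv <- level_verdict("class")
    is_mammalian <- NULL
    ov <- m[, list(mammalian_override = any(is_mammalian),
                   n_votes_species = .N), by = "read_id"]
  } else {
    sv <- gv <- cv <- data.table::data.table(read_id = character(0),
                                             verdict = character(0))
    ov <- data.table::data.table(read_id = character(0),
                                 mammalian_override = logical(0),
                                 n_votes_species = integer(0))
  }

  out <- data.table::data.table(read_id = all_ids)
  out$species_verdict <- sv$verdict[match(out$read_id, sv$read_id)]
  out$genus_verdict <- gv$verdict[match(out$read_id, gv$read_id)]
  out$class_verdict <- cv$verdict[match(out$read_id, cv$read_id)]
  for (col in c("species_verdict", "genus_verdict", "class_verdict")) {
    out[[col]][is.na(out[[col]])] <- "UNMATCHED"
  }
  j <- match(out$read_id, ov$read_id)
  out$n_votes_species <- ifelse(is.na(j), 0L, ov$n_votes_species[j])
  out$mammalian_override <- !is.na(j) & ov$mammalian_override[j]

  mam_sp <- lin$species_id[lin$is_mammalian]
  out$category <- ifelse(
    apply_override & out$mammalian_override, "mammalian",
    ifelse(out$species_verdict == "UNMATCHED", "unmatched",
    ifelse(out$species_verdict == "AMBIGUOUS", "ambiguous",
    ifelse(out$species_verdict %in% mam_sp, "mammalian", "non_mammalian"))))
  data.table::setcolorder(out, c("read_id", "species_verdict",
                                 "genus_verdict", "class_verdict", "category",
                                 "n_votes_species", "mammalian_override"))
  out
}

#' Aggregate per-read classifications into a sample report
#'
#' Counts and fractions of the four sample categories (mammalian,
#' non-mammalian, ambiguous, unmatched — a partition of the reads, using
#' the species-level verdict convention) plus per-genus read counts over
#' reads with a unique genus verdict.
#'
#' @param classifications output of [classify_reads()].
#' @return A `smart_report` list with `total_reads`, `counts`, `fractions`,
#'   and `genus_counts` (named numeric, sorted decreasing).
#' @export
summarize_sample <- function(classifications) {
  cats <- c("mammalian", "non_mammalian", "ambiguous", "unmatched")
  counts <- stats::setNames(integer(length(cats)), cats)
  total <- nrow(classifications)
  if (total > 0) {
    tab <- table(factor(classifications$category, levels = cats))
    counts[] <- as.integer(tab)
  }
  fractions <- if (total > 0) counts / total else
    stats::setNames(numeric(length(cats)), cats)
  gv <- classifications$genus_verdict
  gv <- gv[!gv %in% c("AMBIGUOUS", "UNMATCHED")]
  genus_counts <- if (length(gv) > 0) {
    sort(table(gv), decreasing = TRUE)
  } else {
    table(character(0))
  }
  structure(list(total_reads = total, counts = counts,
                 fractions = fractions,
                 genus_counts = stats::setNames(as.numeric(genus_counts),
                                                names(genus_counts)),
                 normalized = NULL),
            class = "smart_report")
}

#' Normalize per-genus read counts by host genome coverage
#'
#' Divides each genus count by the host mean depth of coverage,
#' `depth = host_read_count * read_length / host_genome_length`, to make
#' per-genus loads comparable across samples of differing sequencing depth.
#' With zero host reads the depth is 0 and normalization is refused: the
#' counts are returned unchanged with attribute `normalized = FALSE` and a
#' warning.
#'
#' @param genus_counts named numeric vector of per-genus read counts.
#' @param host_read_count number of host (e.g. human) reads in the sample.
#' @param host_genome_length host genome length in bases.
#' @param read_length read length in bases (for variable-length reads pass
#'   total host bases / host_read_count).
#' @return named numeric vector with attributes `depth` and `normalized`.
#' @examples
#' normalize_by_host_coverage(c(Ga = 100), 1000, 50000, 100)  # depth 2x
#' @export
normalize_by_host_coverage <- function(genus_counts, host_read_count,
                                       host_genome_length, read_length) {
  if (host_genome_length <= 0) stop("host_genome_length must be positive")
  if (read_length <= 0) stop("read_length must be positive")
  if (host_read_count < 0) stop("host_read_count must be non-negative")
  depth <- host_read_count * read_length / host_genome_length
  if (depth == 0) {
    warning("host depth of coverage is 0; returning unnormalized counts")
    return(structure(genus_counts, depth = 0, normalized = FALSE))
  }
  structure(genus_counts / depth, depth = depth, normalized = TRUE)
}

#' @export
print.smart_report <- function(x, ...) {
  cat("Sample report:", x$total_reads, "reads\n")
  for (cat_name in names(x$counts)) {
    cat(sprintf("  %-14s %8d  (%.2f%%)\n", cat_name, x$counts[[cat_name]],
                100 * x$fractions[[cat_name]]))
  }
  if (length(x$genus_counts) > 0) {
    cat("Top genera:\n")
    top <- utils::head(x$genus_counts, 5)
    for (g in names(top)) cat(sprintf("  %-20s %g\n", g, top[[g]]))
  }
  invisible(x)
}

#' Write / read the per-read classification TSV
#'
#' @param classifications output of [classify_reads()].
#' @param path TSV path.
#' @return `path` invisibly (`write_classifications`); a `data.table`
#'   (`read_classifications`).
#' @export
write_classifications <- function(classifications, path) {
  data.table::fwrite(classifications, path, sep = "\t")
  invisible(path)
}

#' @rdname write_classifications
#' @export
read_classifications <- function(path) {
  data.table::fread(path, sep = "\t", colClasses = list(
    character = c("read_id", "species_verdict", "genus_verdict",
                  "class_verdict", "category")))
}

#' Write a sample report as JSON and TSV
#'
#' @param report a `smart_report` from [summarize_sample()].
#' @param directory output directory (created if needed); writes
#'   `report.json`, `categories.tsv` and `genus_counts.tsv`.
#' @return `directory` invisibly.
#' @export
write_report <- function(report, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  obj <- list(total_reads = report$total_reads,
              counts = as.list(report$counts),
              fractions = as.list(report$fractions),
              genus_counts = as.list(report$genus_counts))
  if (!is.null(report$normalized)) {
    obj$normalized_genus_counts <- as.list(report$normalized)
    obj$host_depth <- attr(report$normalized, "depth")
  }
  jsonlite::write_json(obj, file.path(directory, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cat_dt <- data.table::data.table(category = names(report$counts),
                                   n_reads = as.integer(report$counts),
                                   fraction = as.numeric(report$fractions))
  data.table::fwrite(cat_dt, file.path(directory, "categories.tsv"),
                     sep = "\t")
  gdt <- data.table::data.table(genus = names(report$genus_counts),
                                n_reads = as.numeric(report$genus_counts))
  if (!is.null(report$normalized)) {
    gdt$normalized <- as.numeric(
      report$normalized[match(gdt$genus, names(report$normalized))])
  }
  data.table::fwrite(gdt, file.path(directory, "genus_counts.tsv"),
                     sep = "\t")
  invisible(directory)
}
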