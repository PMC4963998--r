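#' Construct a three-level taxonomy table
#'
#' Builds the species/genus/class lineage table that links every reference
#' record to a single lineage. Classification aggregates votes at these
#' three levels, and the host-override rule fires on the class level, so
#' the table enforces that each species maps to exactly one
#' (genus, class) pair.
#'
#' @param entries data.frame with columns `record_id`, `species_id`,
#'   `genus_id`, `class_id` (one row per reference record). Exact duplicate
#'   rows are collapsed; duplicated `record_id`s with conflicting lineages
#'   are an error.
#' @param mammalian_class class label that marks a lineage as host
#'   (mammalian). Default `"Mammalia"`.
#' @return A `smart_taxonomy` data.frame with an added logical
#'   `is_mammalian` column and attribute `mammalian_class`.
#' @export
taxonomy_table <- function(entries, mammalian_class = "Mammalia") {
  required <- c("record_id", "species_id", "genus_id", "class_id")
  if (!is.data.frame(entries) || !all(required %in% names(entries))) {
    stop("taxonomy entries must be a data.frame with columns ",
         paste(required, collapse = ", "))
  }
  entries <- as.data.frame(entries)[required]
  for (col in required) {
    entries[[col]] <- as.character(entries[[col]])
    bad <- is.na(entries[[col]]) | !nzchar(entries[[col]])
    if (any(bad)) {
      stop("taxonomy column '", col, "' has empty labels (e.g. row ",
           which(bad)[1], ")")
    }
  }
  entries <- unique(entries)

  dup <- unique(entries$record_id[duplicated(entries$record_id)])
  if (length(dup) > 0) {
    stop("conflicting lineages for record id(s): ",
         paste(utils::head(dup, 5), collapse = ", "))
  }

  ## species -> single (genus, class)
  lineage <- unique(entries[c("species_id", "genus_id", "class_id")])
  dup_sp <- unique(lineage$species_id[duplicated(lineage$species_id)])
  if (length(dup_sp) > 0) {
    stop("species with more than one lineage: ",
         paste(utils::head(dup_sp, 5), collapse = ", "))
  }

  entries <- entries[order(entries$record_id, method = "radix"), ]
  rownames(entries) <- NULL
  entries$is_mammalian <- entries$class_id == mammalian_class
  attr(entries, "mammalian_class") <- mammalian_class
  class(entries) <- c("smart_taxonomy", "data.frame")
  entries
}

#' Read a taxonomy table from a TSV file
#'
#' One row per reference record with tab-separated columns
#' `record_id  species  genus  class`; lines starting with `#` and blank
#' lines are ignored.
#'
#' @param path path to the TSV file.
#' @inheritParams taxonomy_table
#' @return A `smart_taxonomy` table (see [taxonomy_table()]).
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("refA\tE. coli\tEscherichia\tGammaproteobacteria",
#'              "refB\tH. sapiens\tHomo\tMammalia"), tsv)
#' tax <- load_taxonomy(tsv)
#' lineage_of(tax, "refB")$is_mammalian
#' @export
load_taxonomy <- function(path, mammalian_class = "Mammalia") {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col != 4)) {
    bad <- idx[which(n_col != 4)[1]]
    stop("malformed taxonomy row at line ", bad, ": expected 4 tab-separated ",
         "columns, got ", n_col[which(n_col != 4)[1]])
  }
  if (length(fields) == 0) {
    entries <- data.frame(record_id = character(), species_id = character(),
                          genus_id = character(), class_id = character(),
                          stringsAsFactors = FALSE)
  } else {
    m <- do.call(rbind, fields)
    entries <- data.frame(record_id = m[, 1], species_id = m[, 2],
                          genus_id = m[, 3], class_id = m[, 4],
                          stringsAsFactors = FALSE)
  }
  taxonomy_table(entries, mammalian_class = mammalian_class)
}

#' Write a taxonomy table to TSV
#'
#' Inverse of [load_taxonomy()]; rows are written sorted by record id so the
#' output is canonical.
#'
#' @param taxonomy a `smart_taxonomy` table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  stopifnot(inherits(taxonomy, "smart_taxonomy"))
  o <- order(taxonomy$record_id, method = "radix")
  lines <- paste(taxonomy$record_id[o], taxonomy$species_id[o],
                 taxonomy$genus_id[o], taxonomy$class_id[o], sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Look up the lineage of a reference record
#'
#' @param taxonomy a `smart_taxonomy` table.
#' @param record_id reference record identifier.
#' @return list with `species_id`, `genus_id`, `class_id`, `is_mammalian`.
#' @export
lineage_of <- function(taxonomy, record_id) {
  stopifnot(inherits(taxonomy, "smart_taxonomy"), length(record_id) == 1)
  i <- match(record_id, taxonomy$record_id)
  if (is.na(i)) stop("record id not in taxonomy: ", record_id)
  list(species_id = taxonomy$species_id[i],
       genus_id = taxonomy$genus_id[i],
       class_id = taxonomy$class_id[i],
       is_mammalian = taxonomy$is_mammalian[i])
}

## species-level lineage (one row per species), used by vote aggregation
.species_lineage <- function(taxonomy) {
  unique(as.data.frame(taxonomy)[c("species_id", "genus_id", "class_id",
                                   "is_mammalian")])
}

#' @export
print.smart_taxonomy <- function(x, ...) {
  cat("Taxonomy table:", nrow(x), "record(s),",
      length(unique(x$species_id)), "species,",
      length(unique(x$genus_id)), "genera,",
      length(unique(x$class_id)), "classes",
      sprintf("(mammalian class: %s)\n", attr(x, "mammalian_class")))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 10), ...)
  invisible(x)
}
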