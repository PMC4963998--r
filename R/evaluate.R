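## Wilson score interval for a binomial proportion
.wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # boundary counts have exact endpoints; avoids drift at p = 0 or 1
  lo <- if (x == 0) 0 else max(0, centre - half)
  hi <- if (x == n) 1 else min(1, centre + half)
  c(lo, hi)
}

#' Sensitivity and precision against truth labels
#'
#' Per taxonomy level: sensitivity is the number of correct classifications
#' divided by the total number of reads, and precision the number of
#' correct classifications divided by the number of reads attempted. A read
#' is correct at a level iff its unique verdict equals the truth lineage's
#' taxon at that level. By default "attempted" means a unique taxon verdict
#' (`AMBIGUOUS` and `UNMATCHED` reads count toward the totals but not the
#' precision denominator); set `ambiguous_as_attempted = TRUE` to count
#' ambiguous reads as attempted-and-incorrect instead.
#'
#' @param classifications output of [classify_reads()].
#' @param truth truth table (see [simulate_reads()] / [read_truth()]) with
#'   `read_id`, `species_id`, `genus_id`, `class_id`.
#' @param ambiguous_as_attempted alternative precision denominator (see
#'   above).
#' @param conf confidence level for the Wilson score intervals.
#' @return A data.frame with one row per level (`species`, `genus`,
#'   `class`): `n_total`, `n_attempted`, `n_correct`, `sensitivity` with
#'   `sens_lo`/`sens_hi`, `precision` with `prec_lo`/`prec_hi` (`NA`
#'   precision when nothing was attempted).
#' @export
evaluate_classifications <- function(classifications, truth,
                                     ambiguous_as_attempted = FALSE,
                                     conf = 0.95) {
  need <- c("read_id", "species_id", "genus_id", "class_id")
  if (!all(need %in% names(truth))) {
    stop("truth must have columns ", paste(need, collapse = ", "))
  }
  orphans_c <- setdiff(classifications$read_id, truth$read_id)
  orphans_t <- setdiff(truth$read_id, classifications$read_id)
  if (length(orphans_c) > 0 || length(orphans_t) > 0) {
    stop("read ids do not match between classifications and truth; e.g. ",
         paste(utils::head(c(orphans_c, orphans_t), 5), collapse = ", "))
  }

  i <- match(classifications$read_id, truth$read_id)
  levels <- c(species = "species_verdict", genus = "genus_verdict",
              class = "class_verdict")
  truth_cols <- c(species = "species_id", genus = "genus_id",
                  class = "class_id")
  rows <- lapply(names(levels), function(lv) {
    verdict <- classifications[[levels[[lv]]]]
    truth_taxon <- truth[[truth_cols[[lv]]]][i]
    unique_verdict <- !verdict %in% c("AMBIGUOUS", "UNMATCHED")
    attempted <- if (ambiguous_as_attempted) {
      unique_verdict | verdict == "AMBIGUOUS"
    } else {
      unique_verdict
    }
    correct <- unique_verdict & verdict == truth_taxon
    n_total <- length(verdict)
    n_attempted <- sum(attempted)
    n_correct <- sum(correct)
    sens_ci <- .wilson_ci(n_correct, n_total, conf)
    prec_ci <- .wilson_ci(n_correct, n_attempted, conf)
    data.frame(level = lv, n_total = n_total, n_attempted = n_attempted,
               n_correct = n_correct,
               sensitivity = if (n_total > 0) n_correct / n_total else NA_real_,
               sens_lo = sens_ci[1], sens_hi = sens_ci[2],
               precision = if (n_attempted > 0) n_correct / n_attempted else
                 NA_real_,
               prec_lo = prec_ci[1], prec_hi = prec_ci[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
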