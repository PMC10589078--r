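#' Default genus exclusion list
#'
#' Genera treated as reference-database mismatches and excluded from
#' profiles: tropical taxa not present in the study region.
#'
#' @return Character vector of genus names.
#' @export
default_excluded_genera <- function() c("Clusia", "Hirtella", "Parinari")

#' Sample quality control on matched-read fraction
#'
#' A sample passes QC when at least `threshold` (default 5%, inclusive) of
#' its merged reads across both markers combined matched the reference
#' database. "Matched" counts genus-assigned plus matched-but-unassigned
#' reads, i.e. query matches, not genus assignments.
#'
#' @param counts A [locus_counts()] object.
#' @param threshold Minimum combined matched fraction (default 0.05).
#' @return `TRUE` or `FALSE`.
#' @examples
#' x <- locus_counts("s1", list(ITS1 = c(Acer = 60), ITS2 = c(Acer = 40)),
#'                   processed = c(ITS1 = 1000, ITS2 = 1000),
#'                   matched = c(ITS1 = 60, ITS2 = 40))
#' sample_qc(x)  # exactly 5%: passes (inclusive)
#' @export
sample_qc <- function(counts, threshold = 0.05) {
  stopifnot(inherits(counts, "locus_counts"))
  tot <- sum(counts$processed)
  if (tot == 0) stop("no reads processed in sample ", counts$sample_id)
  sum(counts$matched) / tot >= threshold
}

#' Dual-locus genus profile of one sample
#'
#' Aggregates the two markers with the maximum rule: for each genus the
#' larger of its ITS1 and ITS2 read counts is taken (a locus where the genus
#' is absent counts 0), the maxima are summed to the sample total, and each
#' genus's proportion is its maximum count over that total. Excluded genera
#' are dropped from both loci before any computation, so proportions are
#' shares of plausible pollen. Genera at or above `min_prop` (default 1%)
#' form the retained set; retained proportions are reported un-renormalized
#' unless `renormalize = TRUE`.
#'
#' @param counts A [locus_counts()] object.
#' @param exclude Genera to drop before computation (default
#'   [default_excluded_genera()]).
#' @param min_prop Minimum proportion for the retained set (default 0.01,
#'   inclusive).
#' @param renormalize Rescale retained proportions to sum to 1 (default
#'   `FALSE`).
#' @param qc_threshold Passed to [sample_qc()] to set the profile's
#'   `qc_pass` flag.
#' @return An object of class `"genus_profile"`: `sample_id`, `proportions`
#'   (all detected genera, pre-threshold, summing to 1), `retained` (genus
#'   names), `retained_proportions`, `qc_pass`, `excluded`, `min_prop`,
#'   `renormalized`.
#' @examples
#' x <- locus_counts("s1", list(ITS1 = c(A = 60, B = 20),
#'                              ITS2 = c(A = 10, B = 40)))
#' p <- dual_locus_profile(x, exclude = character(0))
#' p$proportions  # A 0.6, B 0.4
#' @export
dual_locus_profile <- function(counts, exclude = default_excluded_genera(),
                               min_prop = 0.01, renormalize = FALSE,
                               qc_threshold = 0.05) {
  stopifnot(inherits(counts, "locus_counts"))
  tabs <- lapply(counts$counts, function(x) x[!names(x) %in% exclude])
  genera <- sort(unique(unlist(lapply(tabs, names))))
  m <- vapply(genera, function(g) {
    max(vapply(tabs, function(x) {
      if (g %in% names(x)) as.numeric(x[[g]]) else 0
    }, numeric(1)))
  }, numeric(1))
  total <- sum(m)
  if (total == 0) stop("no classified reads in sample ", counts$sample_id)
  p <- m / total
  retained <- names(p)[p >= min_prop]
  rp <- p[retained]
  if (isTRUE(renormalize) && length(rp)) rp <- rp / sum(rp)
  structure(list(sample_id = counts$sample_id, proportions = p,
                 retained = retained, retained_proportions = rp,
                 qc_pass = sample_qc(counts, qc_threshold),
                 excluded = exclude, min_prop = min_prop,
                 renormalized = isTRUE(renormalize)),
            class = "genus_profile")
}

#' @export
print.genus_profile <- function(x, digits = 3, ...) {
  cat("<genus_profile> sample ", x$sample_id,
      if (!x$qc_pass) " [QC FAIL]", "\n", sep = "")
  shown <- sort(x$proportions, decreasing = TRUE)
  flag <- ifelse(names(shown) %in% x$retained, "", " (below threshold)")
  for (i in seq_along(shown)) {
    cat("  ", format(names(shown)[i], width = 14), " ",
        format(round(shown[i], digits), nsmall = digits), flag[i], "\n",
        sep = "")
  }
  invisible(x)
}

#' Genus richness of a profile
#'
#' Number of genera in the retained set (at or above the profile's minimum
#' proportion threshold).
#'
#' @param profile A [dual_locus_profile()] result.
#' @return Integer count.
#' @export
genus_richness <- function(profile) {
  stopifnot(inherits(profile, "genus_profile"))
  length(profile$retained)
}

#' Host-plant pollen proportion of a profile
#'
#' Sum of retained-genus proportions whose family belongs to the host
#' families (default Rosaceae and Fabaceae, the bee's preferred forage
#' families). Uses the profile's retained proportions, i.e. un-renormalized
#' unless the profile was built with `renormalize = TRUE`. A retained genus
#' with unknown family contributes 0 and is reported via a message.
#'
#' @param profile A [dual_locus_profile()] result.
#' @param lineages Named list of [lineage()] objects keyed by genus name.
#' @param host_families Character vector of family names.
#' @return A proportion in `[0, 1]`.
#' @export
host_plant_proportion <- function(profile, lineages,
                                  host_families = c("Rosaceae", "Fabaceae")) {
  stopifnot(inherits(profile, "genus_profile"))
  total <- 0
  for (g in profile$retained) {
    fam <- if (g %in% names(lineages)) {
      taxon_at_rank(lineages[[g]], "family")
    } else NA_character_
    if (is.na(fam)) {
      message("genus ", g, " has no known family; contributes 0 to the ",
              "host-plant proportion")
      next
    }
    if (fam %in% host_families) total <- total + profile$retained_proportions[[g]]
  }
  total
}
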