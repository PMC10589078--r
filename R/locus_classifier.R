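#' Semi-global pairwise alignment with free end gaps
#'
#' Dynamic-programming optimal alignment in which gaps at either terminus of
#' either sequence cost zero, the alignment mode amplicon classifiers use to
#' compare a read against a (possibly longer or shorter) reference barcode.
#' Identity is the fraction of matching columns among alignment columns
#' (terminal-gap columns excluded, internal gap columns counted as
#' non-matches); query coverage is the fraction of query bases inside the
#' aligned region. Among equal-score alignments, the one maximising matched
#' columns (then minimising columns, then maximising aligned query bases) is
#' reported, which makes identity and coverage deterministic.
#'
#' Score only orders ties between accepted hits downstream; acceptance is
#' decided by the identity and coverage thresholds, so any sensible scoring
#' scheme yields the same accepted sets. `N` never matches any base.
#'
#' @param query,target Non-empty DNA strings (uppercase `A`/`C`/`G`/`T`/`N`).
#' @param match Match score (default +2).
#' @param mismatch Mismatch score (default -4).
#' @param gap Internal gap score per column (default -4); terminal gaps are
#'   always free.
#' @param query_global Force the query to align end to end (usearch_global /
#'   blastn semantics: only the target's overhangs are free). Default
#'   `FALSE`, i.e. free end gaps on both sequences. The query-global mode is
#'   what the reference-cleaning relaxed search uses, because ranking
#'   references by identity is only meaningful over alignments spanning the
#'   whole query.
#' @return A list with elements `score`, `matches`, `columns`, `identity`,
#'   `coverage`, and the 0-based half-open aligned spans `qstart`, `qend`,
#'   `tstart`, `tend`.
#' @examples
#' semiglobal_align("ACGTACGT", "TTACGTACGTTT")$identity  # 1 (read inside ref)
#' @export
semiglobal_align <- function(query, target, match = 2L, mismatch = -4L,
                             gap = -4L, query_global = FALSE) {
  if (!nzchar(query) || !nzchar(target)) stop("sequences must be non-empty")
  semiglobal_align_cpp(query, target, as.integer(match), as.integer(mismatch),
                       as.integer(gap), isTRUE(query_global))
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Search a read against a per-locus reference database
#'
#' Aligns the query against every reference (exhaustive search) and returns
#' the accepted hits: identity >= `min_identity` and query coverage >=
#' `min_coverage` (defaults 95% and 80%). Hits are sorted by identity
#' descending, then score descending, then reference id ascending, and
#' truncated to `max_accepts`. With `both_strands = TRUE` (the default) the
#' reverse complement of the query is also tried against each reference and
#' the better orientation kept, since merged amplicon orientation is not
#' guaranteed.
#'
#' @param query A DNA string (one merged read).
#' @param db Named character vector of reference sequences (names are
#'   reference ids).
#' @param min_identity,min_coverage Acceptance thresholds in `[0, 1]`.
#' @param max_accepts Maximum number of hits returned (default 100).
#' @param both_strands Also try the reverse complement (default `TRUE`).
#' @param match,mismatch,gap Scoring scheme passed to [semiglobal_align()].
#' @return A data frame with columns `ref_id`, `identity`, `coverage`,
#'   `score`, `strand`, `qstart`, `qend`, `tstart`, `tend`; zero rows if no
#'   hit is accepted.
#' @export
search_reference <- function(query, db, min_identity = 0.95,
                             min_coverage = 0.80, max_accepts = 100L,
                             both_strands = TRUE, match = 2L, mismatch = -4L,
                             gap = -4L) {
  if (length(db) == 0L) stop("reference database is empty")
  if (is.null(names(db)) || any(!nzchar(names(db)))) {
    stop("reference database must be a named character vector")
  }
  stopifnot(min_identity >= 0, min_identity <= 1,
            min_coverage >= 0, min_coverage <= 1)
  fwd <- semiglobal_align_many_cpp(query, unname(db), as.integer(match),
                                   as.integer(mismatch), as.integer(gap))
  strand <- rep("+", nrow(fwd))
  best <- fwd
  if (isTRUE(both_strands)) {
    rev <- semiglobal_align_many_cpp(revcomp(query), unname(db),
                                     as.integer(match), as.integer(mismatch),
                                     as.integer(gap))
    # keep the better orientation per reference: the alignment optimum
    # (score), then identity; ties stay on the forward strand
    take_rev <- rev[, "score"] > fwd[, "score"] |
      (rev[, "score"] == fwd[, "score"] & rev[, "identity"] > fwd[, "identity"])
    best[take_rev, ] <- rev[take_rev, ]
    strand[take_rev] <- "-"
  }
  hits <- data.frame(ref_id = names(db), identity = best[, "identity"],
                     coverage = best[, "coverage"], score = best[, "score"],
                     strand = strand, qstart = best[, "qstart"],
                     qend = best[, "qend"], tstart = best[, "tstart"],
                     tend = best[, "tend"], stringsAsFactors = FALSE)
  hits <- hits[hits$identity >= min_identity & hits$coverage >= min_coverage, ,
               drop = FALSE]
  hits <- hits[order(-hits$identity, -hits$score, hits$ref_id), , drop = FALSE]
  rownames(hits) <- NULL
  utils::head(hits, as.integer(max_accepts))
}

#' Assign a read to a genus from its accepted hits
#'
#' Takes all hits tied with the top hit on (identity, score). If the tied
#' references' lineages share a genus the read is assigned to it; otherwise
#' their lowest common ancestor decides: a known LCA genus assigns the read,
#' an LCA above genus leaves it matched-but-unassigned. No accepted hits at
#' all means unmatched.
#'
#' @param hits Data frame of hits as produced by [search_reference()]
#'   (already sorted).
#' @param lineages Named list of [lineage()] objects keyed by reference id.
#' @return A list with `outcome` (one of `"genus"`, `"matched_unassigned"`,
#'   `"unmatched"`), `genus` (`NA` unless outcome is `"genus"`), and
#'   `top_hits` (the tied hit rows).
#' @export
assign_read <- function(hits, lineages) {
  if (nrow(hits) == 0L) {
    return(list(outcome = "unmatched", genus = NA_character_,
                top_hits = hits))
  }
  tied <- hits[hits$identity == hits$identity[1] & hits$score == hits$score[1],
               , drop = FALSE]
  missing <- setdiff(tied$ref_id, names(lineages))
  if (length(missing)) {
    stop("hit references absent from lineage table: ",
         paste(missing, collapse = ", "))
  }
  lca <- lowest_common_ancestor(lineages[tied$ref_id])
  g <- taxon_at_rank(lca, "genus")
  if (!is.na(g)) {
    list(outcome = "genus", genus = g, top_hits = tied)
  } else {
    list(outcome = "matched_unassigned", genus = NA_character_,
         top_hits = tied)
  }
}

#' Per-sample, per-locus genus read counts
#'
#' Container produced by [classify_sample()] (or built directly from count
#' tables): for each locus, genus-level read counts plus the totals needed
#' for sample QC — reads processed and reads matched (genus-assigned plus
#' matched-but-unassigned).
#'
#' @param sample_id Sample identifier.
#' @param counts Named list, one element per locus (e.g. `"ITS1"`, `"ITS2"`),
#'   each a named non-negative integer vector of genus read counts.
#' @param processed Named numeric: total reads processed per locus. Defaults
#'   to the per-locus count sums.
#' @param matched Named numeric: total matched reads per locus. Defaults to
#'   the per-locus count sums.
#' @return An object of class `"locus_counts"`.
#' @examples
#' locus_counts("s1", list(ITS1 = c(Acer = 60, Malus = 20),
#'                         ITS2 = c(Acer = 10, Malus = 40)))
#' @export
locus_counts <- function(sample_id, counts, processed = NULL, matched = NULL) {
  stopifnot(is.list(counts), length(counts) >= 1L, !is.null(names(counts)))
  sums <- vapply(counts, function(x) sum(as.numeric(x)), numeric(1))
  if (is.null(matched)) matched <- sums
  if (is.null(processed)) processed <- matched
  matched <- matched[names(counts)]
  processed <- processed[names(counts)]
  if (any(matched > processed)) stop("matched reads exceed processed reads")
  if (any(sums > matched + 1e-9)) stop("genus counts exceed matched reads")
  structure(list(sample_id = sample_id, counts = counts,
                 processed = processed, matched = matched),
            class = "locus_counts")
}

#' @export
print.locus_counts <- function(x, ...) {
  cat("<locus_counts> sample", x$sample_id, "\n")
  for (loc in names(x$counts)) {
    cat("  ", loc, ": ", length(x$counts[[loc]]), " genera, ",
        x$matched[[loc]], "/", x$processed[[loc]], " reads matched\n",
        sep = "")
  }
  invisible(x)
}

#' Classify all reads of one sample
#'
#' Runs [search_reference()] and [assign_read()] over every merged read of a
#' sample and tabulates genus-level counts per locus. Identical read
#' sequences are classified once and their counts aggregated, which changes
#' nothing in the result (classification depends only on the sequence).
#'
#' @param reads Data frame with columns `id`, `locus`, `sequence` (a column
#'   `sample_id` is carried through if present).
#' @param dbs Named list of per-locus reference databases, each a named
#'   character vector of sequences.
#' @param lineages Named list of [lineage()] objects keyed by reference id.
#' @param sample_id Sample identifier (defaults to the reads' `sample_id`
#'   column, else `"sample"`).
#' @param ... Passed to [search_reference()] (thresholds, scoring, strands).
#' @return A [locus_counts()] object. The per-locus `matched` totals count
#'   genus-assigned plus matched-but-unassigned reads; `processed` counts all
#'   reads seen.
#' @export
classify_sample <- function(reads, dbs, lineages, sample_id = NULL, ...) {
  stopifnot(is.data.frame(reads),
            all(c("id", "locus", "sequence") %in% names(reads)))
  if (is.null(sample_id)) {
    sample_id <- if ("sample_id" %in% names(reads) && nrow(reads) > 0L) {
      reads$sample_id[1]
    } else "sample"
  }
  loci <- if (nrow(reads) > 0L) sort(unique(reads$locus)) else names(dbs)
  bad <- setdiff(unique(reads$locus), names(dbs))
  if (length(bad)) {
    stop("no reference database for locus: ", paste(bad, collapse = ", "))
  }
  counts <- list(); processed <- c(); matched <- c()
  for (loc in loci) {
    sub <- reads[reads$locus == loc, , drop = FALSE]
    tab <- table(sub$sequence)
    gcount <- numeric(0)
    n_matched <- 0
    for (k in seq_along(tab)) {
      seqk <- names(tab)[k]
      mult <- as.numeric(tab[[k]])
      hits <- search_reference(seqk, dbs[[loc]], ...)
      a <- assign_read(hits, lineages)
      if (a$outcome == "genus") {
        gcount[a$genus] <- (if (a$genus %in% names(gcount))
          gcount[[a$genus]] else 0) + mult
        n_matched <- n_matched + mult
      } else if (a$outcome == "matched_unassigned") {
        n_matched <- n_matched + mult
      }
    }
    counts[[loc]] <- if (length(gcount)) {
      gcount[order(names(gcount))]
    } else setNames(numeric(0), character(0))
    processed[loc] <- nrow(sub)
    matched[loc] <- n_matched
  }
  locus_counts(sample_id, counts, processed = processed, matched = matched)
}
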