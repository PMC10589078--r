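#' Contrast database for reference-barcode decontamination
#'
#' A set of sequences with lineages used as evidence when flagging reference
#' barcodes: a `plant` contrast database (what correctly labeled plant
#' barcodes should match) or a `non_plant` one (fungal and other off-target
#' sequences that mislabeled barcodes actually come from).
#'
#' @param kind `"plant"` or `"non_plant"`.
#' @param sequences Named character vector of uppercase DNA sequences.
#' @param lineages Named list of [lineage()] objects covering every sequence
#'   id.
#' @return An object of class `"contrast_db"`.
#' @export
contrast_db <- function(kind = c("plant", "non_plant"), sequences, lineages) {
  kind <- match.arg(kind)
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  missing <- setdiff(names(sequences), names(lineages))
  if (length(missing)) {
    stop("contrast records without lineage: ", paste(missing, collapse = ", "))
  }
  structure(list(kind = kind, sequences = sequences,
                 lineages = lineages[names(sequences)]),
            class = "contrast_db")
}

#' @export
print.contrast_db <- function(x, ...) {
  cat("<contrast_db> kind=", x$kind, ", ", length(x$sequences),
      " records\n", sep = "")
  invisible(x)
}

check_dna <- function(seq, what = "sequence") {
  if (grepl("[^ACGTN]", seq)) {
    stop(what, " contains characters outside the A/C/G/T/N alphabet")
  }
  invisible(seq)
}

#' Exact full-coverage matches of a barcode in a contrast database
#'
#' The blastn-style "100% identity, 100% query coverage" criterion: a
#' contrast record matches iff it contains the barcode sequence as an exact
#' contiguous substring (the reference may be longer than the barcode;
#' equal-length exact equality is the special case). `N` never matches any
#' base, so a barcode containing `N` has no exact matches.
#'
#' @param sequence Barcode DNA string (uppercase `A`/`C`/`G`/`T`/`N`).
#' @param db A [contrast_db()].
#' @return Character vector of matching contrast record ids (possibly
#'   empty), in the database's record order.
#' @export
exact_full_matches <- function(sequence, db) {
  stopifnot(inherits(db, "contrast_db"))
  check_dna(sequence, "barcode")
  if (grepl("N", sequence, fixed = TRUE)) return(character(0))
  # targets may contain N; fixed-string search cannot pair N with a real base
  hit <- vapply(db$sequences, function(t) grepl(sequence, t, fixed = TRUE),
                logical(1))
  names(db$sequences)[hit]
}

#' Flag one reference barcode as correctly labeled or mislabeled
#'
#' Applies the decontamination cascade, in order:
#' 1. any exact full-coverage match in the non-plant contrast database flags
#'    the barcode mislabeled (`nonplant_exact_hit`);
#' 2. otherwise, exact matches in the plant contrast database are compared by
#'    genus: a same-genus match flags correctly labeled
#'    (`plant_genus_match`; same-genus concordance wins even when
#'    different-genus matches coexist, with a warning), matches only to other
#'    genera flag mislabeled (`plant_genus_mismatch`);
#' 3. with no exact plant match, the top relaxed hit (highest-identity
#'    semi-global alignment over the plant database, ties broken by longer
#'    aligned span then smallest record id; multi-genus ties are resolved by
#'    their lowest common ancestor) decides: same genus flags correctly
#'    labeled (`no_plant_hit_tophit_same_genus`), anything else — including
#'    no hit reaching `relaxed_min_identity` — flags mislabeled
#'    (`no_plant_hit_tophit_other`);
#' 4. finally, any exact match whose lineage class is known and is not
#'    Magnoliopsida overrides the outcome of (2)-(3) to mislabeled
#'    (`non_magnoliopsida_hit`).
#'
#' @param id Barcode id (used in the decision row).
#' @param sequence Barcode DNA string.
#' @param labeled_lineage The barcode's labeled [lineage()]; its genus must
#'   be known.
#' @param nonplant,plant Non-empty [contrast_db()] objects of the matching
#'   kinds.
#' @param relaxed_min_identity Minimum identity for the relaxed top hit of
#'   rule (3) (default 0: the best hit counts regardless).
#' @return One-row data frame: `id`, `status` (`"mislabeled"` or
#'   `"correctly_labeled"`), `rule`, `evidence` (comma-joined contrast ids).
#' @export
flag_barcode <- function(id, sequence, labeled_lineage, nonplant, plant,
                         relaxed_min_identity = 0) {
  stopifnot(inherits(nonplant, "contrast_db"), nonplant$kind == "non_plant",
            inherits(plant, "contrast_db"), plant$kind == "plant",
            length(nonplant$sequences) > 0L, length(plant$sequences) > 0L)
  genus <- taxon_at_rank(labeled_lineage, "genus")
  if (is.na(genus)) stop("barcode ", id, " has no known labeled genus")

  decide <- function(status, rule, evidence) {
    data.frame(id = id, status = status, rule = rule,
               evidence = paste(evidence, collapse = ","),
               stringsAsFactors = FALSE)
  }

  np_hits <- exact_full_matches(sequence, nonplant)
  if (length(np_hits)) {
    return(decide("mislabeled", "nonplant_exact_hit", np_hits))
  }

  p_hits <- exact_full_matches(sequence, plant)
  if (length(p_hits)) {
    hit_class <- vapply(plant$lineages[p_hits], taxon_at_rank, character(1),
                        rank = "class")
    alien <- p_hits[!is.na(hit_class) & hit_class != "Magnoliopsida"]
    hit_genus <- vapply(plant$lineages[p_hits], taxon_at_rank, character(1),
                        rank = "genus")
    same <- p_hits[!is.na(hit_genus) & hit_genus == genus]
    if (length(alien)) {
      return(decide("mislabeled", "non_magnoliopsida_hit", alien))
    }
    if (length(same)) {
      if (length(same) < length(p_hits)) {
        warning("barcode ", id, " has exact plant matches in several genera; ",
                "same-genus concordance retained (evidence: ",
                paste(p_hits, collapse = ","), ")")
      }
      return(decide("correctly_labeled", "plant_genus_match", same))
    }
    return(decide("mislabeled", "plant_genus_mismatch", p_hits))
  }

  # rule (3): relaxed top hit over the plant database, with the barcode
  # aligned end to end (identity ranking is only meaningful over
  # query-spanning alignments)
  aln <- semiglobal_align_many_cpp(sequence, unname(plant$sequences),
                                   2L, -4L, -4L, query_global = TRUE)
  hits <- data.frame(ref_id = names(plant$sequences),
                     identity = aln[, "identity"],
                     span = aln[, "tend"] - aln[, "tstart"],
                     stringsAsFactors = FALSE)
  hits <- hits[hits$identity >= relaxed_min_identity, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(decide("mislabeled", "no_plant_hit_tophit_other", character(0)))
  }
  hits <- hits[order(-hits$identity, -hits$span, hits$ref_id), , drop = FALSE]
  top <- hits[hits$identity == hits$identity[1], , drop = FALSE]
  top <- top[top$span == max(top$span), , drop = FALSE]
  if (nrow(top) > 1L) {
    # tie spanning several records: test genus equality against the LCA
    lca <- lowest_common_ancestor(plant$lineages[top$ref_id])
    top_genus <- taxon_at_rank(lca, "genus")
  } else {
    top_genus <- taxon_at_rank(plant$lineages[[top$ref_id[1]]], "genus")
  }
  if (!is.na(top_genus) && top_genus == genus) {
    decide("correctly_labeled", "no_plant_hit_tophit_same_genus", top$ref_id)
  } else {
    decide("mislabeled", "no_plant_hit_tophit_other", top$ref_id)
  }
}

#' Clean a reference barcode database
#'
#' Flags every barcode with [flag_barcode()] and removes the ones flagged
#' mislabeled. Decisions are independent across barcodes, so the result does
#' not depend on record order.
#'
#' @param barcodes Data frame with columns `id`, `locus`, `sequence`.
#' @param lineages Named list of labeled [lineage()]s covering every barcode
#'   id.
#' @param nonplant,plant [contrast_db()] objects.
#' @param relaxed_min_identity Passed to [flag_barcode()].
#' @return A list with `retained` (the subset of `barcodes` flagged
#'   correctly labeled), `decisions` (one row per barcode: `id`, `locus`,
#'   `status`, `rule`, `evidence`), and `report` (per-locus rule counts and
#'   fraction removed).
#' @export
clean_database <- function(barcodes, lineages, nonplant, plant,
                           relaxed_min_identity = 0) {
  stopifnot(is.data.frame(barcodes),
            all(c("id", "locus", "sequence") %in% names(barcodes)))
  if (nrow(barcodes) == 0L) {
    return(list(retained = barcodes,
                decisions = data.frame(id = character(0), locus = character(0),
                                       status = character(0), rule = character(0),
                                       evidence = character(0)),
                report = data.frame(locus = character(0), n = integer(0),
                                    n_removed = integer(0),
                                    fraction_removed = numeric(0))))
  }
  missing <- setdiff(barcodes$id, names(lineages))
  if (length(missing)) {
    stop("barcodes without lineage: ", paste(missing, collapse = ", "))
  }
  decs <- do.call(rbind, lapply(seq_len(nrow(barcodes)), function(i) {
    d <- flag_barcode(barcodes$id[i], barcodes$sequence[i],
                      lineages[[barcodes$id[i]]], nonplant, plant,
                      relaxed_min_identity = relaxed_min_identity)
    cbind(d[1], locus = barcodes$locus[i], d[-1])
  }))
  rownames(decs) <- NULL
  retained <- barcodes[decs$status == "correctly_labeled", , drop = FALSE]
  rownames(retained) <- NULL
  rules <- c("nonplant_exact_hit", "plant_genus_mismatch", "plant_genus_match",
             "no_plant_hit_tophit_same_genus", "no_plant_hit_tophit_other",
             "non_magnoliopsida_hit")
  report <- do.call(rbind, lapply(sort(unique(decs$locus)), function(loc) {
    sub <- decs[decs$locus == loc, , drop = FALSE]
    counts <- vapply(rules, function(r) sum(sub$rule == r), integer(1))
    cbind(data.frame(locus = loc, n = nrow(sub),
                     n_removed = sum(sub$status == "mislabeled"),
                     fraction_removed = sum(sub$status == "mislabeled") / nrow(sub)),
          as.data.frame(as.list(counts)))
  }))
  rownames(report) <- NULL
  list(retained = retained, decisions = decs, report = report)
}
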