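#' @useDynLib pollenniche, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rbinom rmultinom rnorm sd setNames
#' @importFrom utils read.delim write.table
NULL

#' The fixed taxonomic rank order
#'
#' All lineages in the package use this seven-rank convention, from kingdom
#' down to species. The unit of read assignment is genus.
#'
#' @return Character vector of the seven rank names, broadest first.
#' @export
lineage_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus", "species")
}

#' Construct a taxonomic lineage
#'
#' A lineage is a named character vector over the seven fixed ranks
#' (see [lineage_ranks()]). Unknown taxa are stored as `NA`; once a rank is
#' unknown every deeper rank is forced to unknown, so a lineage is always a
#' known prefix followed by an unknown suffix.
#'
#' @param ... Rank-name = taxon-name pairs, e.g. `genus = "Acer"`. Unnamed
#'   ranks default to unknown. A single named character vector may also be
#'   supplied as the only argument.
#' @return A named character vector of length 7 with class `"lineage"`.
#' @examples
#' lineage(kingdom = "Viridiplantae", phylum = "Streptophyta",
#'         class = "Magnoliopsida", order = "Sapindales",
#'         family = "Sapindaceae", genus = "Acer", species = "Acer rubrum")
#' @export
lineage <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]]))) {
    args <- as.list(args[[1]])
  }
  ranks <- lineage_ranks()
  bad <- setdiff(names(args), ranks)
  if (length(bad)) {
    stop("unrecognized rank name(s): ", paste(bad, collapse = ", "))
  }
  out <- setNames(rep(NA_character_, length(ranks)), ranks)
  for (r in names(args)) {
    v <- args[[r]]
    if (is.null(v) || is.na(v)) next
    v <- trimws(as.character(v))
    out[r] <- if (nzchar(v)) v else NA_character_
  }
  # unknown at any rank propagates to all deeper ranks
  first_na <- which(is.na(out))
  if (length(first_na)) out[seq(min(first_na), length(out))] <- NA_character_
  structure(out, class = "lineage")
}

#' @export
print.lineage <- function(x, ...) {
  shown <- ifelse(is.na(x), "?", unclass(x))
  cat("<lineage> ", paste(shown, collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' Taxon name at a given rank
#'
#' @param x A [lineage()].
#' @param rank One of the seven fixed rank names.
#' @return The stored taxon name at `rank`, or `NA` if unknown.
#' @examples
#' taxon_at_rank(lineage(kingdom = "Viridiplantae", phylum = "Streptophyta",
#'                       class = "Magnoliopsida", order = "Sapindales",
#'                       family = "Sapindaceae", genus = "Acer"), "genus")
#' @export
taxon_at_rank <- function(x, rank) {
  stopifnot(inherits(x, "lineage"))
  if (length(rank) != 1L || !rank %in% lineage_ranks()) {
    stop("unrecognized rank: ", paste(rank, collapse = ", "))
  }
  unname(unclass(x)[rank])
}

#' Lowest common ancestor of a set of lineages
#'
#' Returns the lineage equal to the inputs on every leading rank where all
#' agree (unknowns disagree with everything, including each other), and
#' unknown from the first disagreement down. The LCA of a single lineage is
#' itself; the operation is associative, commutative and idempotent.
#'
#' @param lineages A non-empty list of [lineage()] objects (a single lineage
#'   is also accepted).
#' @return A [lineage()].
#' @examples
#' malus  <- lineage(kingdom = "Viridiplantae", phylum = "Streptophyta",
#'                   class = "Magnoliopsida", order = "Rosales",
#'                   family = "Rosaceae", genus = "Malus")
#' prunus <- lineage(kingdom = "Viridiplantae", phylum = "Streptophyta",
#'                   class = "Magnoliopsida", order = "Rosales",
#'                   family = "Rosaceae", genus = "Prunus")
#' lowest_common_ancestor(list(malus, prunus))  # known through family
#' @export
lowest_common_ancestor <- function(lineages) {
  if (inherits(lineages, "lineage")) lineages <- list(lineages)
  if (length(lineages) == 0L) stop("cannot take the LCA of an empty collection")
  stopifnot(all(vapply(lineages, inherits, logical(1), "lineage")))
  m <- do.call(rbind, lapply(lineages, unclass))
  ranks <- lineage_ranks()
  out <- setNames(rep(NA_character_, length(ranks)), ranks)
  for (i in seq_along(ranks)) {
    col <- m[, i]
    if (anyNA(col) || length(unique(col)) != 1L) break
    out[i] <- col[1]
  }
  do.call(lineage, as.list(out))
}

#' Read a lineage table
#'
#' Parses the package's 8-column lineage TSV: a header row, then one row per
#' sequence with columns `id` plus the seven ranks of [lineage_ranks()].
#' Empty cells are unknown. Whitespace is trimmed; names are otherwise taken
#' verbatim (comparison throughout the package is exact and case-sensitive).
#'
#' @param path Path to the TSV file.
#' @return A named list of [lineage()] objects keyed by sequence id.
#' @export
read_lineage_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   na.strings = c("", "NA"), check.names = FALSE,
                   fileEncoding = "UTF-8")
  if (ncol(df) != 8L) {
    stop("lineage TSV must have 8 columns (id + 7 ranks), found ", ncol(df))
  }
  ids <- trimws(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate lineage ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    vals <- as.character(df[i, 2:8])
    do.call(lineage, as.list(setNames(vals, lineage_ranks())))
  })
  names(out) <- ids
  out
}

#' Write a lineage table
#'
#' Inverse of [read_lineage_tsv()]: writes the 8-column TSV with a header
#' row, unknown ranks as empty cells.
#'
#' @param lineages Named list of [lineage()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lineage_tsv <- function(lineages, path) {
  m <- do.call(rbind, lapply(lineages, unclass))
  m[is.na(m)] <- ""
  df <- data.frame(id = names(lineages), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("id", lineage_ranks())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
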