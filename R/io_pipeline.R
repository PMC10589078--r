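#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper over Biostrings that enforces the package's contracts:
#' unique ids within a file (the id is the header word before the first
#' whitespace), sequences uppercased; FASTQ qualities are read but unused.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension; default), `"fasta"` or `"fastq"`.
#' @return Named character vector of uppercase sequences.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) {
      "fastq"
    } else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  ids <- sub("\\s.*$", "", names(x))
  dups <- unique(ids[duplicated(ids)])
  if (length(dups)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(dups, collapse = ", "))
  }
  setNames(toupper(as.character(x)), ids)
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a sample/locus/reads-file manifest
#'
#' @param manifest A data frame with columns `sample_id`, `locus`, `path`,
#'   or the path of a TSV holding one.
#' @param check_paths Verify that every reads file exists (default `TRUE`).
#' @return The validated manifest data frame.
#' @export
read_manifest <- function(manifest, check_paths = TRUE) {
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- read.delim(manifest, sep = "\t", colClasses = "character",
                           fileEncoding = "UTF-8")
  }
  stopifnot(is.data.frame(manifest))
  need <- c("sample_id", "locus", "path")
  if (!all(need %in% names(manifest))) {
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(manifest) == 0L) stop("no samples in manifest")
  key <- paste(manifest$sample_id, manifest$locus)
  if (anyDuplicated(key)) {
    stop("duplicate (sample_id, locus) pairs in manifest: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  if (check_paths) {
    miss <- manifest$path[!file.exists(manifest$path)]
    if (length(miss)) {
      stop("reads files not found: ", paste(miss, collapse = ", "))
    }
  }
  manifest
}

# one lineage per genus, truncated at genus (species dropped), for
# host-family lookups
genus_lineages <- function(lineages) {
  out <- list()
  for (lin in lineages) {
    g <- taxon_at_rank(lin, "genus")
    if (is.na(g) || g %in% names(out)) next
    vals <- as.list(unclass(lin))
    vals$species <- NA_character_
    out[[g]] <- do.call(lineage, vals)
  }
  out
}

#' Printed experimental diet table
#'
#' The published diet formulation table bundled with the package: protein
#' and lipid concentrations (µg per mg) and printed P:L ratios of the
#' altered multifloral, monofloral, and naturally different multifloral
#' diets. Control rows without printed concentrations are omitted.
#'
#' @return Data frame with columns `diet_set`, `diet`, `printed_ratio`,
#'   `protein_ug_mg`, `lipid_ug_mg`, `n`.
#' @examples
#' d <- diet_table()
#' round(pl_ratio(d$protein_ug_mg, d$lipid_ug_mg), 1)
#' @export
diet_table <- function() {
  path <- system.file("extdata", "diet_table.tsv", package = "pollenniche")
  read.delim(path, sep = "\t", fileEncoding = "UTF-8",
             stringsAsFactors = FALSE)
}

#' Run the full metabarcoding analysis pipeline
#'
#' Sequences the stages end to end: optional reference-database cleaning
#' ([clean_database()]), per-sample read classification
#' ([classify_sample()]), and dual-locus genus profiling
#' ([dual_locus_profile()]) with QC, richness and host-plant proportion.
#' All stage outputs are written as TSVs with stable names under `out_dir`,
#' together with a machine-readable JSON run summary echoing every
#' threshold used and per-stage counts.
#'
#' @param manifest Manifest data frame or TSV path (see [read_manifest()]).
#' @param ref_fasta Named list of per-locus reference FASTA paths, e.g.
#'   `list(ITS1 = ..., ITS2 = ...)`.
#' @param ref_lineages Path to the 8-column lineage TSV covering the
#'   reference ids.
#' @param out_dir Output directory (created if needed).
#' @param nonplant_fasta,nonplant_lineages,plant_fasta,plant_lineages
#'   Contrast-database files; cleaning runs only when all four are given.
#' @param min_identity,min_coverage,max_accepts,both_strands Passed to
#'   [search_reference()].
#' @param qc_threshold,min_prop,exclude,renormalize Passed to
#'   [dual_locus_profile()].
#' @param host_families Passed to [host_plant_proportion()].
#' @return Invisibly, a list with the per-sample profiles, the count and
#'   summary data frames, and the cleaning report (or `NULL`).
#' @export
run_pipeline <- function(manifest, ref_fasta, ref_lineages, out_dir,
                         nonplant_fasta = NULL, nonplant_lineages = NULL,
                         plant_fasta = NULL, plant_lineages = NULL,
                         min_identity = 0.95, min_coverage = 0.80,
                         max_accepts = 100L, both_strands = TRUE,
                         qc_threshold = 0.05, min_prop = 0.01,
                         exclude = default_excluded_genera(),
                         renormalize = FALSE,
                         host_families = c("Rosaceae", "Fabaceae")) {
  manifest <- read_manifest(manifest)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lineages <- read_lineage_tsv(ref_lineages)
  dbs <- lapply(ref_fasta, read_sequences)

  clean_report <- NULL
  if (!is.null(plant_fasta) && !is.null(nonplant_fasta)) {
    plant <- contrast_db("plant", read_sequences(plant_fasta),
                         read_lineage_tsv(plant_lineages))
    nonplant <- contrast_db("non_plant", read_sequences(nonplant_fasta),
                            read_lineage_tsv(nonplant_lineages))
    barcodes <- do.call(rbind, lapply(names(dbs), function(loc) {
      data.frame(id = names(dbs[[loc]]), locus = loc,
                 sequence = unname(dbs[[loc]]), stringsAsFactors = FALSE)
    }))
    cleaned <- clean_database(barcodes, lineages, nonplant, plant)
    clean_report <- cleaned$report
    write.table(cleaned$decisions, file.path(out_dir, "clean_decisions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (loc in names(dbs)) {
      keep <- cleaned$retained$id[cleaned$retained$locus == loc]
      dbs[[loc]] <- dbs[[loc]][names(dbs[[loc]]) %in% keep]
      write_sequences(dbs[[loc]],
                      file.path(out_dir, paste0("retained_", loc, ".fasta")))
    }
  }

  counts_rows <- NULL; summary_rows <- NULL; profiles <- list()
  glin <- genus_lineages(lineages)
  for (s in unique(manifest$sample_id)) {
    rows <- manifest[manifest$sample_id == s, , drop = FALSE]
    reads <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
      seqs <- read_sequences(rows$path[i])
      data.frame(id = names(seqs), sample_id = s, locus = rows$locus[i],
                 sequence = unname(seqs), stringsAsFactors = FALSE)
    }))
    lc <- classify_sample(reads, dbs, lineages, sample_id = s,
                          min_identity = min_identity,
                          min_coverage = min_coverage,
                          max_accepts = max_accepts,
                          both_strands = both_strands)
    for (loc in names(lc$counts)) {
      cc <- lc$counts[[loc]]
      if (length(cc)) {
        counts_rows <- rbind(counts_rows, data.frame(
          sample_id = s, locus = loc, genus = names(cc),
          count = as.numeric(cc), stringsAsFactors = FALSE))
      }
    }
    prof <- dual_locus_profile(lc, exclude = exclude, min_prop = min_prop,
                               renormalize = renormalize,
                               qc_threshold = qc_threshold)
    profiles[[s]] <- prof
    summary_rows <- rbind(summary_rows, data.frame(
      sample_id = s, qc_pass = prof$qc_pass, richness = genus_richness(prof),
      host_proportion = host_plant_proportion(prof, glin, host_families),
      stringsAsFactors = FALSE))
  }
  if (!any(summary_rows$qc_pass)) stop("all samples failed the QC threshold")

  prof_rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(sample_id = p$sample_id, genus = names(p$proportions),
               proportion = signif(unname(p$proportions), 6),
               retained = names(p$proportions) %in% p$retained,
               stringsAsFactors = FALSE)
  }))
  write.table(counts_rows, file.path(out_dir, "genus_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(prof_rows, file.path(out_dir, "profiles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(summary_rows, file.path(out_dir, "sample_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    thresholds = list(min_identity = min_identity,
                      min_coverage = min_coverage,
                      max_accepts = max_accepts, both_strands = both_strands,
                      qc_threshold = qc_threshold, min_prop = min_prop,
                      renormalize = renormalize, exclude = exclude,
                      host_families = host_families),
    n_samples = length(profiles),
    n_reference = vapply(dbs, length, integer(1)),
    cleaning = clean_report)
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(profiles = profiles, counts = counts_rows,
                 summary = summary_rows, clean_report = clean_report))
}
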