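#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators with validated
#' defaults chosen to emulate the structure of a dual-locus pollen
#' metabarcoding study at desk scale: a handful of co-flowering genera with
#' a skewed mixture, a few reference species per genus, per-locus 2-fold
#' amplification bias (so the two markers disagree and the dual-locus
#' maximum rule has something to reconcile), ~1% substitution sequencing
#' error, and provision nutrition moments on the µg/mg scale typical of
#' spring bee provisions.
#'
#' One global `seed` is expanded into independent per-generator substreams
#' (reference db, reads, nutrition, rearing), so adding one generator call
#' never perturbs another stream's output.
#'
#' @param seed Integer seed (mandatory).
#' @param n_genera Number of plant genera (default 5; up to 8 draw names and
#'   families from a built-in synthetic pool, beyond that `GenusNN`).
#' @param species_per_genus Reference species per genus (default 3).
#' @param barcode_length Length of simulated barcodes and reads (default
#'   150).
#' @param intergenus_divergence Per-base substitution fraction applied when
#'   evolving genus founders from the shared ancestor (default 0.2).
#' @param intragenus_divergence Per-base substitution fraction from founder
#'   to species (default 0.02).
#' @param mislabel_rate Fraction of reference barcodes planted as mislabels
#'   (default 0.1).
#' @param nonplant_contaminant_count Non-plant (fungal) contrast sequences
#'   (default 20).
#' @param composition Named numeric of true genus proportions summing to 1;
#'   default 5 genera at 0.40/0.25/0.20/0.10/0.05.
#' @param reads_per_locus Merged reads simulated per sample per locus
#'   (default 2000).
#' @param bias Named list with elements `ITS1` and `ITS2`, each a named
#'   multiplicative amplification factor per genus; the default alternates
#'   2-fold preference between the loci.
#' @param error_rate Per-base substitution sequencing error (default 0.01).
#' @param nutrition Named numeric with `protein_mean`, `protein_sd`,
#'   `lipid_mean`, `lipid_sd` (µg/mg; defaults 151.42/47.78 and
#'   53.94/20.66).
#' @param weeks Number of collection weeks for nutrition labels (default 6).
#' @param sites Site labels assigned round-robin (default `"A"`–`"D"`).
#' @param survival Named list of per-diet stage probabilities, each a
#'   numeric vector `c(cocoon, pupation, adult)` of probabilities
#'   conditional on reaching the prior stage.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(seed,
                       n_genera = 5L,
                       species_per_genus = 3L,
                       barcode_length = 150L,
                       intergenus_divergence = 0.2,
                       intragenus_divergence = 0.02,
                       mislabel_rate = 0.1,
                       nonplant_contaminant_count = 20L,
                       composition = NULL,
                       reads_per_locus = 2000L,
                       bias = NULL,
                       error_rate = 0.01,
                       nutrition = c(protein_mean = 151.42, protein_sd = 47.78,
                                     lipid_mean = 53.94, lipid_sd = 20.66),
                       weeks = 6L,
                       sites = c("A", "B", "C", "D"),
                       survival = list(
                         control = c(0.80, 0.85, 0.90),
                         high_protein = c(0.70, 0.80, 0.85),
                         high_lipid = c(0.30, 0.60, 0.80),
                         monofloral_good = c(0.75, 0.80, 0.85),
                         monofloral_poor = c(0.00, 0.00, 0.00))) {
  if (missing(seed) || !is.finite(seed)) stop("an integer seed is mandatory")
  seed <- as.integer(seed)
  genera <- synthetic_genus_table(n_genera)
  if (is.null(composition)) {
    props <- c(0.40, 0.25, 0.20, 0.10, 0.05)
    if (n_genera != 5L) {
      props <- rev(seq_len(n_genera)) / sum(seq_len(n_genera))
    }
    composition <- setNames(props, genera$genus[seq_len(n_genera)])
  }
  if (abs(sum(composition) - 1) > 1e-9) stop("composition must sum to 1")
  if (any(composition < 0)) stop("composition proportions must be >= 0")
  if (is.null(bias)) {
    g <- genera$genus
    odd <- seq_along(g) %% 2L == 1L
    bias <- list(ITS1 = setNames(ifelse(odd, 2, 1), g),
                 ITS2 = setNames(ifelse(odd, 1, 2), g))
  }
  rates <- c(intergenus_divergence, intragenus_divergence, mislabel_rate,
             error_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (any(nutrition[c("protein_sd", "lipid_sd")] < 0)) {
    stop("nutrition SDs must be >= 0")
  }
  for (d in names(survival)) {
    p <- survival[[d]]
    if (length(p) != 3L || any(p < 0 | p > 1)) {
      stop("survival probabilities for diet '", d,
           "' must be three values in [0, 1]")
    }
  }
  structure(list(seed = seed, n_genera = as.integer(n_genera),
                 species_per_genus = as.integer(species_per_genus),
                 barcode_length = as.integer(barcode_length),
                 intergenus_divergence = intergenus_divergence,
                 intragenus_divergence = intragenus_divergence,
                 mislabel_rate = mislabel_rate,
                 nonplant_contaminant_count = as.integer(nonplant_contaminant_count),
                 composition = composition,
                 reads_per_locus = as.integer(reads_per_locus),
                 bias = bias, error_rate = error_rate, nutrition = nutrition,
                 weeks = as.integer(weeks), sites = sites,
                 survival = survival, genera = genera),
            class = "sim_config")
}

# synthetic stand-ins for regional plant genera (names only; sequences are
# simulated, no real barcode data is embedded)
synthetic_genus_table <- function(n_genera) {
  pool <- data.frame(
    genus = c("Malus", "Cercis", "Acer", "Lonicera", "Quercus", "Prunus",
              "Salix", "Trifolium"),
    family = c("Rosaceae", "Fabaceae", "Sapindaceae", "Caprifoliaceae",
               "Fagaceae", "Rosaceae", "Salicaceae", "Fabaceae"),
    order = c("Rosales", "Fabales", "Sapindales", "Dipsacales", "Fagales",
              "Rosales", "Malpighiales", "Fabales"),
    stringsAsFactors = FALSE)
  if (n_genera <= nrow(pool)) return(pool[seq_len(n_genera), , drop = FALSE])
  extra <- data.frame(
    genus = sprintf("Genus%02d", seq_len(n_genera - nrow(pool))),
    family = sprintf("Family%02d", seq_len(n_genera - nrow(pool))),
    order = sprintf("Order%02d", seq_len(n_genera - nrow(pool))),
    stringsAsFactors = FALSE)
  rbind(pool, extra)
}

# expand the global seed into an independent substream seed (< 2^31)
stream_seed <- function(seed, stream) {
  offset <- c(refdb = 101L, reads = 211L, nutrition = 307L, rearing = 401L)
  if (!stream %in% names(offset)) stop("unknown stream: ", stream)
  (as.numeric(seed) * 48271 + offset[[stream]]) %% 2147483647
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1))
}

mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(bases)) < rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  }
  paste(bases, collapse = "")
}

plant_lineage <- function(genus_row, species = NA_character_) {
  lineage(kingdom = "Viridiplantae", phylum = "Streptophyta",
          class = "Magnoliopsida", order = genus_row$order,
          family = genus_row$family, genus = genus_row$genus,
          species = species)
}

#' Generate a synthetic reference database with planted mislabels
#'
#' Simulates, per locus (ITS1 and ITS2): one founder barcode per genus
#' evolved from a shared ancestor at the inter-genus divergence, species
#' barcodes evolved from each founder at the intra-genus divergence, a plant
#' contrast database holding an exact (correctly labeled) copy of every true
#' sequence, a non-plant contrast database of random fungal-labeled
#' contaminants, and a barcode set to clean in which a fraction
#' `mislabel_rate` of records keep their label but carry an exact copy of
#' either another genus's plant sequence or a non-plant contaminant. The
#' truth table records every planted mislabel.
#'
#' @param config A [sim_config()].
#' @return A list: `barcodes` (data frame `id`, `locus`, `sequence` — the
#'   set to clean), `barcode_lineages`, `plant` and `nonplant`
#'   ([contrast_db()]s), `reference` (data frame of true sequences `id`,
#'   `locus`, `genus`, `sequence` — the cleaned classification database),
#'   `reference_lineages`, and `truth` (data frame `id`, `locus`,
#'   `true_status`, `planted_as`).
#' @export
generate_reference_db <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, "refdb"))
  genera <- config$genera
  loci <- c("ITS1", "ITS2")
  ref <- NULL
  lineages <- list()
  for (loc in loci) {
    founders <- NULL
    for (attempt in 1:10) {
      ancestor <- random_dna(1, config$barcode_length)
      founders <- vapply(seq_len(nrow(genera)), function(i) {
        mutate_dna(ancestor, config$intergenus_divergence)
      }, character(1))
      if (!anyDuplicated(founders)) break
      warning("identical genus founders drawn; regenerating")
      if (attempt == 10) stop("could not draw distinct genus founders; ",
                              "increase divergence or barcode length")
    }
    for (i in seq_len(nrow(genera))) {
      for (k in seq_len(config$species_per_genus)) {
        id <- sprintf("%s_sp%d_%s", genera$genus[i], k, loc)
        seq <- mutate_dna(founders[i], config$intragenus_divergence)
        ref <- rbind(ref, data.frame(id = id, locus = loc,
                                     genus = genera$genus[i], sequence = seq,
                                     stringsAsFactors = FALSE))
        lineages[[id]] <- plant_lineage(genera[i, ],
                                        paste(genera$genus[i],
                                              sprintf("sp%d", k)))
      }
    }
  }
  # plant contrast database: an exact correctly labeled copy of every true
  # sequence (what a curated public database would hold)
  plant_seqs <- setNames(ref$sequence, paste0("plantdb_", ref$id))
  plant_lins <- setNames(lineages[ref$id], names(plant_seqs))
  plant <- contrast_db("plant", plant_seqs, plant_lins)
  # non-plant contaminants, fungal-labeled
  np_seqs <- setNames(random_dna(config$nonplant_contaminant_count,
                                 config$barcode_length + 30L),
                      sprintf("nonplant_%03d",
                              seq_len(config$nonplant_contaminant_count)))
  np_lins <- lapply(seq_along(np_seqs), function(i) {
    lineage(kingdom = "Fungi", phylum = "Ascomycota",
            class = "Sordariomycetes")
  })
  names(np_lins) <- names(np_seqs)
  nonplant <- contrast_db("non_plant", np_seqs, np_lins)

  # barcode set to clean: true records with a planted fraction of mislabels
  barcodes <- data.frame(id = paste0("bc_", ref$id), locus = ref$locus,
                         sequence = ref$sequence, stringsAsFactors = FALSE)
  bc_lineages <- setNames(lineages[ref$id], barcodes$id)
  truth <- data.frame(id = barcodes$id, locus = barcodes$locus,
                      true_status = "correctly_labeled",
                      planted_as = NA_character_, stringsAsFactors = FALSE)
  n_mis <- round(config$mislabel_rate * nrow(barcodes))
  if (n_mis > 0) {
    planted <- sample(nrow(barcodes), n_mis)
    for (j in seq_along(planted)) {
      i <- planted[j]
      if (j %% 2L == 1L) {
        # exact copy of another genus's plant sequence, same locus
        pool <- which(ref$locus == barcodes$locus[i] &
                        ref$genus != ref$genus[i])
        src <- sample(pool, 1L)
        barcodes$sequence[i] <- ref$sequence[src]
        truth$planted_as[i] <- "cross_genus_copy"
      } else {
        src <- sample(length(np_seqs), 1L)
        barcodes$sequence[i] <- unname(np_seqs[src])
        truth$planted_as[i] <- "nonplant_copy"
      }
      truth$true_status[i] <- "mislabeled"
    }
  }
  list(barcodes = barcodes, barcode_lineages = bc_lineages, plant = plant,
       nonplant = nonplant, reference = ref, reference_lineages = lineages,
       truth = truth)
}

#' Simulate merged amplicon reads for one sample
#'
#' For each locus, read counts per genus are drawn multinomially from the
#' true composition reweighted by that locus's amplification bias; each read
#' copies a uniformly chosen conspecific reference sequence and substitutes
#' each base independently with the configured error rate. The per-read true
#' genus is recorded.
#'
#' @param config A [sim_config()].
#' @param refdb Result of [generate_reference_db()] (reads are drawn from
#'   its true `reference` sequences).
#' @param sample_id Sample identifier used in read ids.
#' @return A list: `reads` (data frame `id`, `sample_id`, `locus`,
#'   `sequence`) and `truth` (data frame `id`, `locus`, `true_genus`).
#' @export
generate_sample_reads <- function(config, refdb, sample_id = "S1") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, "reads"))
  comp <- config$composition
  missing <- setdiff(names(comp), unique(refdb$reference$genus))
  if (length(missing)) {
    stop("composition genera absent from reference db: ",
         paste(missing, collapse = ", "))
  }
  reads <- NULL; truth <- NULL
  for (loc in c("ITS1", "ITS2")) {
    if (config$reads_per_locus == 0L) next
    w <- comp * config$bias[[loc]][names(comp)]
    w <- w / sum(w)
    counts <- as.vector(rmultinom(1, config$reads_per_locus, w))
    names(counts) <- names(comp)
    idx <- 0L
    for (g in names(counts)) {
      if (counts[[g]] == 0) next
      pool <- refdb$reference[refdb$reference$locus == loc &
                                refdb$reference$genus == g, , drop = FALSE]
      for (r in seq_len(counts[[g]])) {
        idx <- idx + 1L
        src <- pool[sample(nrow(pool), 1L), ]
        reads <- rbind(reads, data.frame(
          id = sprintf("%s_%s_r%05d", sample_id, loc, idx),
          sample_id = sample_id, locus = loc,
          sequence = mutate_dna(src$sequence, config$error_rate),
          stringsAsFactors = FALSE))
        truth <- rbind(truth, data.frame(
          id = sprintf("%s_%s_r%05d", sample_id, loc, idx), locus = loc,
          true_genus = g, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(reads)) {
    reads <- data.frame(id = character(0), sample_id = character(0),
                        locus = character(0), sequence = character(0))
    truth <- data.frame(id = character(0), locus = character(0),
                        true_genus = character(0))
  }
  list(reads = reads, truth = truth)
}

#' Simulate provision nutrition samples
#'
#' Protein and lipid concentrations are drawn from zero-truncated normal
#' distributions with the configured moments (interpreted pre-truncation;
#' the truncation bias is negligible at these coefficients of variation).
#' Site and week labels are assigned round-robin.
#'
#' @param config A [sim_config()].
#' @param n Number of provisions (>= 1).
#' @return Data frame: `sample_id`, `protein_ug_mg`, `lipid_ug_mg`, `site`,
#'   `week`.
#' @export
generate_provision_nutrition <- function(config, n) {
  stopifnot(inherits(config, "sim_config"), n >= 1)
  if (any(config$nutrition[c("protein_sd", "lipid_sd")] < 0)) {
    stop("nutrition SDs must be >= 0")
  }
  set.seed(stream_seed(config$seed, "nutrition"))
  draw_trunc <- function(n, mean, sd) {
    x <- rnorm(n, mean, sd)
    while (any(x <= 0)) x[x <= 0] <- rnorm(sum(x <= 0), mean, sd)
    x
  }
  data.frame(
    sample_id = sprintf("prov%03d", seq_len(n)),
    protein_ug_mg = draw_trunc(n, config$nutrition[["protein_mean"]],
                               config$nutrition[["protein_sd"]]),
    lipid_ug_mg = draw_trunc(n, config$nutrition[["lipid_mean"]],
                             config$nutrition[["lipid_sd"]]),
    site = rep_len(config$sites, n),
    week = rep_len(seq_len(config$weeks), n),
    stringsAsFactors = FALSE)
}

#' Simulate rearing outcomes
#'
#' Per diet group, stage outcomes are Bernoulli draws conditional on
#' reaching the prior stage (cocoon completion, then pupation, then adult
#' survival), so the nesting invariant holds by construction. Development
#' timings are drawn uniformly from plausible day ranges for individuals
#' that reached the stage, `NA` otherwise.
#'
#' @param config A [sim_config()] (diet groups and probabilities come from
#'   its `survival` field).
#' @param n_per_diet Individuals per diet group.
#' @return Data frame in the format [survival_summary()] consumes.
#' @export
generate_rearing_outcomes <- function(config, n_per_diet) {
  stopifnot(inherits(config, "sim_config"), n_per_diet >= 1)
  set.seed(stream_seed(config$seed, "rearing"))
  out <- NULL
  for (d in names(config$survival)) {
    p <- config$survival[[d]]
    cocoon <- rbinom(n_per_diet, 1, p[1]) == 1L
    pupated <- cocoon & (rbinom(n_per_diet, 1, p[2]) == 1L)
    adult <- pupated & (rbinom(n_per_diet, 1, p[3]) == 1L)
    out <- rbind(out, data.frame(
      individual_id = sprintf("%s_%03d", d, seq_len(n_per_diet)),
      diet = d, cocoon_completed = cocoon, pupated = pupated,
      adult_survived = adult,
      days_to_cocoon = ifelse(cocoon, sample(14:24, n_per_diet, TRUE),
                              NA_real_),
      days_to_pupation = ifelse(pupated, sample(10:20, n_per_diet, TRUE),
                                NA_real_),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
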