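make_plant_db <- function(seqs, genera, classes = NULL) {
  if (is.null(classes)) classes <- rep("Magnoliopsida", length(seqs))
  lins <- lapply(seq_along(seqs), function(i) {
    test_lineage(genera[i], class = classes[i])
  })
  names(lins) <- names(seqs)
  contrast_db("plant", seqs, lins)
}

make_nonplant_db <- function(seqs) {
  lins <- lapply(seq_along(seqs), function(i) {
    lineage(kingdom = "Fungi", phylum = "Ascomycota",
            class = "Sordariomycetes")
  })
  names(lins) <- names(seqs)
  contrast_db("non_plant", seqs, lins)
}

test_that("exact_full_matches implements 100% identity / 100% coverage", {
  db <- make_nonplant_db(c(f1 = "ACGTACGT", f2 = "ACGTACGA",
                           f3 = "AACGTACGTT"))
  expect_identical(exact_full_matches("ACGTACGT", db), c("f1", "f3"))
  expect_identical(exact_full_matches("CGTAC", db),
                   c("f1", "f2", "f3"))  # substring containment
  db2 <- make_nonplant_db(c(f1 = "ACGTACGA"))
  expect_identical(exact_full_matches("ACGTACGT", db2), character(0))
  expect_error(exact_full_matches("ACGU", db), "alphabet")
})

test_that("exact matching agrees with a naive substring-scan oracle", {
  set.seed(7)
  for (rep in 1:40) {
    target <- random_seq(sample(10:30, 1))
    bar <- if (rep %% 2 == 0) {
      off <- sample(nchar(target) - 4, 1)
      substring(target, off, off + sample(3:5, 1))
    } else random_seq(sample(4:12, 1))
    db <- make_nonplant_db(c(t1 = target))
    expect_identical(length(exact_full_matches(bar, db)) > 0,
                     oracle_substring_hit(bar, target), info = bar)
  }
})

test_that("an N in the barcode precludes any exact hit", {
  db <- make_nonplant_db(c(f1 = "ACGNACGT"))
  expect_identical(exact_full_matches("ACGNACGT", db), character(0))
})

test_that("the flagging cascade applies its rules in order", {
  plant <- make_plant_db(c(p_mal = "ACGTACGTACGTACGTACGT",
                           p_pru = "TTTTGGGGCCCCAAAATTTT"),
                         genera = c("Malus", "Prunus"))
  nonplant <- make_nonplant_db(c(f1 = "GGCCGGCCGGCCGGCCGGCC"))
  mal <- test_lineage("Malus")

  # (1) non-plant exact hit wins over everything
  d <- flag_barcode("b1", "GGCCGGCCGGCCGGCCGGCC", mal, nonplant, plant)
  expect_identical(d$status, "mislabeled")
  expect_identical(d$rule, "nonplant_exact_hit")
  expect_identical(d$evidence, "f1")

  # (2) same-genus plant exact hit -> correctly labeled
  d <- flag_barcode("b2", "ACGTACGTACGTACGTACGT", mal, nonplant, plant)
  expect_identical(d$status, "correctly_labeled")
  expect_identical(d$rule, "plant_genus_match")

  # (2) cross-genus plant exact hit -> mislabeled
  d <- flag_barcode("b3", "TTTTGGGGCCCCAAAATTTT", mal, nonplant, plant)
  expect_identical(d$status, "mislabeled")
  expect_identical(d$rule, "plant_genus_mismatch")

  # barcode with unknown genus violates the record invariant
  expect_error(
    flag_barcode("b4", "ACGT", lineage(kingdom = "Viridiplantae"),
                 nonplant, plant),
    "genus")
})

test_that("relaxed top hit decides when no exact plant match exists", {
  set.seed(11)
  base <- random_seq(100)
  plant <- make_plant_db(c(p_mal = base, p_pru = random_seq(100)),
                         genera = c("Malus", "Prunus"))
  nonplant <- make_nonplant_db(c(f1 = random_seq(60)))
  # mutate 3 of 100 bases: no exact hit, top relaxed hit is its own genus
  chars <- strsplit(base, "")[[1]]
  pos <- sample(100, 3)
  for (i in pos) chars[i] <- setdiff(c("A", "C", "G", "T"), chars[i])[1]
  mutated <- paste(chars, collapse = "")
  d <- flag_barcode("b1", mutated, test_lineage("Malus"), nonplant, plant)
  expect_identical(d$status, "correctly_labeled")
  expect_identical(d$rule, "no_plant_hit_tophit_same_genus")
  # oracle: exhaustive query-spanning alignment over the plant db confirms
  # the top hit
  ids <- vapply(c(p_mal = base, p_pru = plant$sequences[["p_pru"]]),
                function(s) {
                  oracle_semiglobal(mutated, s, query_global = TRUE)$identity
                }, numeric(1))
  expect_identical(names(which.max(ids)), "p_mal")
  expect_equal(max(ids), 0.97)
  # same barcode labeled as the other genus -> mislabeled
  d2 <- flag_barcode("b2", mutated, test_lineage("Prunus"), nonplant, plant)
  expect_identical(d2$status, "mislabeled")
  expect_identical(d2$rule, "no_plant_hit_tophit_other")
})

test_that("a non-Magnoliopsida exact match overrides a genus match", {
  plant <- make_plant_db(c(p1 = "ACGTACGTACGTACGTACGT",
                           p2 = "ACGTACGTACGTACGTACGT"),
                         genera = c("Malus", "Malus"),
                         classes = c("Magnoliopsida", "Pinopsida"))
  nonplant <- make_nonplant_db(c(f1 = "GGGGGGGGGGGGGGGGGGGG"))
  d <- flag_barcode("b1", "ACGTACGTACGTACGTACGT", test_lineage("Malus"),
                    nonplant, plant)
  expect_identical(d$status, "mislabeled")
  expect_identical(d$rule, "non_magnoliopsida_hit")
  expect_identical(d$evidence, "p2")
})

test_that("same-genus concordance wins over a coexisting cross-genus match", {
  plant <- make_plant_db(c(p_mal = "ACGTACGTACGTACGTACGT",
                           p_pru = "ACGTACGTACGTACGTACGT"),
                         genera = c("Malus", "Prunus"))
  nonplant <- make_nonplant_db(c(f1 = "GGGGGGGGGGGGGGGGGGGG"))
  expect_warning(
    d <- flag_barcode("b1", "ACGTACGTACGTACGTACGT", test_lineage("Malus"),
                      nonplant, plant),
    "several genera")
  expect_identical(d$status, "correctly_labeled")
  expect_identical(d$rule, "plant_genus_match")
})

test_that("clean_database removes exactly the planted mislabels", {
  cfg <- sim_config(seed = 5, n_genera = 5, species_per_genus = 5,
                    mislabel_rate = 0.2)  # 50 barcodes, 10 planted
  db <- generate_reference_db(cfg)
  res <- clean_database(db$barcodes, db$barcode_lineages, db$nonplant,
                        db$plant)
  planted <- db$truth$id[db$truth$true_status == "mislabeled"]
  removed <- res$decisions$id[res$decisions$status == "mislabeled"]
  expect_setequal(removed, planted)
  expect_identical(sort(res$retained$id),
                   sort(setdiff(db$barcodes$id, planted)))
  expect_equal(sum(res$report$n_removed), length(planted))
  expect_equal(res$report$fraction_removed,
               res$report$n_removed / res$report$n)
})

test_that("an all-concordant database loses nothing", {
  cfg <- sim_config(seed = 6, n_genera = 4, species_per_genus = 3,
                    mislabel_rate = 0)
  db <- generate_reference_db(cfg)
  res <- clean_database(db$barcodes, db$barcode_lineages, db$nonplant,
                        db$plant)
  expect_equal(nrow(res$retained), nrow(db$barcodes))
  expect_true(all(res$decisions$status == "correctly_labeled"))
})

test_that("cleaning decisions do not depend on record order", {
  cfg <- sim_config(seed = 8, n_genera = 4, species_per_genus = 3,
                    mislabel_rate = 0.25)
  db <- generate_reference_db(cfg)
  res1 <- clean_database(db$barcodes, db$barcode_lineages, db$nonplant,
                         db$plant)
  perm <- db$barcodes[rev(seq_len(nrow(db$barcodes))), , drop = FALSE]
  res2 <- clean_database(perm, db$barcode_lineages, db$nonplant, db$plant)
  d1 <- res1$decisions[order(res1$decisions$id), ]
  d2 <- res2$decisions[order(res2$decisions$id), ]
  rownames(d1) <- rownames(d2) <- NULL
  expect_identical(d1, d2)
})

test_that("an empty barcode collection yields an empty report", {
  cfg <- sim_config(seed = 9, n_genera = 3, species_per_genus = 2)
  db <- generate_reference_db(cfg)
  res <- clean_database(db$barcodes[0, ], db$barcode_lineages, db$nonplant,
                        db$plant)
  expect_equal(nrow(res$retained), 0L)
  expect_equal(nrow(res$decisions), 0L)
})
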