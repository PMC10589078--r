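test_that("semiglobal self-alignment and single-mismatch identity", {
  q <- "ACGTACGTACGTACGTACGT"
  a <- semiglobal_align(q, q)
  expect_equal(a$identity, 1.0)
  expect_equal(a$coverage, 1.0)
  t1 <- paste0(substring(q, 1, 9), "T", substring(q, 11, 20))  # 1 of 20 off
  expect_equal(semiglobal_align(q, t1)$identity, 0.95)
  expect_error(semiglobal_align("", q), "non-empty")
})

test_that("terminal gaps are free: a read inside a longer reference", {
  a <- semiglobal_align("ACGTACGT", "GGGGACGTACGTGGGG")
  expect_equal(a$identity, 1.0)
  expect_equal(a$coverage, 1.0)
  expect_equal(a$score, 16)  # 8 matches, no penalty for the reference tails
  expect_equal(c(a$tstart, a$tend), c(4, 12))
})

test_that("aligner agrees with the brute-force DP oracle on random pairs", {
  set.seed(13)
  for (rep in 1:60) {
    q <- random_seq(sample(3:40, 1))
    t <- random_seq(sample(3:40, 1))
    got <- semiglobal_align(q, t)
    exp <- oracle_semiglobal(q, t)
    expect_equal(got$score, exp$score, info = paste(q, t))
    expect_equal(got$identity, exp$identity, info = paste(q, t))
    expect_equal(got$coverage, exp$coverage, info = paste(q, t))
  }
})

test_that("query-global mode matches its oracle and spans the query", {
  set.seed(14)
  for (rep in 1:30) {
    q <- random_seq(sample(3:30, 1))
    t <- random_seq(sample(3:40, 1))
    got <- semiglobal_align(q, t, query_global = TRUE)
    exp <- oracle_semiglobal(q, t, query_global = TRUE)
    expect_equal(got$score, exp$score, info = paste(q, t))
    expect_equal(got$identity, exp$identity, info = paste(q, t))
    expect_equal(got$coverage, 1.0)  # the query always aligns end to end
  }
})

test_that("search_reference applies thresholds and truncation", {
  set.seed(17)
  ref <- random_seq(60)
  db <- c(r1 = ref, r2 = random_seq(60))
  hits <- search_reference(ref, db)
  expect_equal(nrow(hits), 1L)
  expect_identical(hits$ref_id, "r1")
  expect_equal(hits$identity, 1.0)

  # ~90% identity to every reference -> rejected at the 95% threshold
  chars <- strsplit(ref, "")[[1]]
  pos <- sample(60, 6)
  for (i in pos) chars[i] <- setdiff(c("A", "C", "G", "T"), chars[i])[1]
  query <- paste(chars, collapse = "")
  expect_equal(nrow(search_reference(query, c(r1 = ref))), 0L)

  # 120 perfect references truncate to max_accepts = 100
  db120 <- setNames(rep(ref, 120), sprintf("r%03d", 1:120))
  hits <- search_reference(ref, db120)
  expect_equal(nrow(hits), 100L)
  expect_identical(hits$ref_id, sprintf("r%03d", 1:100))  # id ascending
})

test_that("reverse-complement reads are found when both strands are on", {
  set.seed(19)
  ref <- random_seq(50)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", ref), "")[[1]]),
              collapse = "")
  hits <- search_reference(rc, c(r1 = ref), both_strands = TRUE)
  expect_equal(nrow(hits), 1L)
  expect_identical(hits$strand, "-")
  expect_equal(hits$identity, 1.0)
  expect_equal(nrow(search_reference(rc, c(r1 = ref), both_strands = FALSE)),
               0L)
})

test_that("assign_read follows top-hit ties through the LCA", {
  lins <- list(mal1 = test_lineage("Malus", species = "Malus domestica"),
               pru1 = test_lineage("Prunus", species = "Prunus avium"),
               acer1 = test_lineage("Acer", family = "Sapindaceae",
                                    order = "Sapindales",
                                    species = "Acer rubrum"),
               acer2 = test_lineage("Acer", family = "Sapindaceae",
                                    order = "Sapindales",
                                    species = "Acer saccharum"))
  hit <- function(ids, identity = 1, score = 10) {
    data.frame(ref_id = ids, identity = identity, coverage = 1,
               score = score, stringsAsFactors = FALSE)
  }
  a <- assign_read(hit("mal1"), lins)
  expect_identical(a$outcome, "genus")
  expect_identical(a$genus, "Malus")

  # tie across Rosaceae genera: matched but unassigned
  a <- assign_read(hit(c("mal1", "pru1")), lins)
  expect_identical(a$outcome, "matched_unassigned")

  # tie within one genus resolves at genus; oracle = taxonomy module
  a <- assign_read(hit(c("acer1", "acer2")), lins)
  expect_identical(a$outcome, "genus")
  expect_identical(a$genus, "Acer")
  lca <- lowest_common_ancestor(lins[c("acer1", "acer2")])
  expect_identical(a$genus, taxon_at_rank(lca, "genus"))

  # only the tied top group decides: a lower-identity Prunus hit is ignored
  h <- rbind(hit("mal1"), hit("pru1", identity = 0.97, score = 5))
  a <- assign_read(h, lins)
  expect_identical(a$genus, "Malus")

  expect_identical(assign_read(hit("mal1")[0, ], lins)$outcome, "unmatched")
  expect_error(assign_read(hit("ghost"), lins), "absent")
})

test_that("classify_sample counts reads and preserves totals", {
  set.seed(23)
  ref <- random_seq(60)
  dbs <- list(ITS1 = c(acer1 = ref))
  lins <- list(acer1 = test_lineage("Acer", family = "Sapindaceae"))
  reads <- data.frame(id = sprintf("r%02d", 1:10), locus = "ITS1",
                      sequence = ref, stringsAsFactors = FALSE)
  lc <- classify_sample(reads, dbs, lins, sample_id = "s1")
  expect_equal(unname(lc$counts$ITS1["Acer"]), 10)
  expect_equal(unname(lc$matched["ITS1"]), 10)
  expect_equal(unname(lc$processed["ITS1"]), 10)

  empty <- classify_sample(reads[0, ], dbs, lins, sample_id = "s0")
  expect_equal(sum(empty$processed), 0)

  expect_error(classify_sample(
    data.frame(id = "r", locus = "ITS9", sequence = ref), dbs, lins),
    "ITS9")
})

test_that("classification is invariant to read and reference order and
          conserves reads across outcome classes", {
  cfg <- sim_config(seed = 29, n_genera = 3, species_per_genus = 2,
                    barcode_length = 80, reads_per_locus = 60,
                    composition = c(Malus = 0.5, Cercis = 0.3, Acer = 0.2))
  db <- generate_reference_db(cfg)
  sim <- generate_sample_reads(cfg, db, "s1")
  dbs <- split(setNames(db$reference$sequence, db$reference$id),
               db$reference$locus)
  lc1 <- classify_sample(sim$reads, dbs, db$reference_lineages)
  perm_reads <- sim$reads[rev(seq_len(nrow(sim$reads))), ]
  dbs_perm <- lapply(dbs, function(x) x[rev(seq_along(x))])
  lc2 <- classify_sample(perm_reads, dbs_perm, db$reference_lineages)
  expect_equal(lc1$counts, lc2$counts)
  expect_equal(lc1$matched, lc2$matched)
  for (loc in names(lc1$counts)) {
    # genus counts + matched_unassigned + unmatched = reads processed
    unassigned <- lc1$matched[[loc]] - sum(lc1$counts[[loc]])
    unmatched <- lc1$processed[[loc]] - lc1$matched[[loc]]
    expect_gte(unassigned, 0)
    expect_gte(unmatched, 0)
    expect_equal(sum(lc1$counts[[loc]]) + unassigned + unmatched,
                 lc1$processed[[loc]])
  }
})

test_that("error-free reads over divergent genera are fully recovered", {
  cfg <- sim_config(seed = 31, n_genera = 4, species_per_genus = 2,
                    barcode_length = 100, reads_per_locus = 50,
                    error_rate = 0, intergenus_divergence = 0.25,
                    composition = c(Malus = 0.4, Cercis = 0.3, Acer = 0.2,
                                    Lonicera = 0.1))
  db <- generate_reference_db(cfg)
  sim <- generate_sample_reads(cfg, db, "s1")
  dbs <- split(setNames(db$reference$sequence, db$reference$id),
               db$reference$locus)
  lc <- classify_sample(sim$reads, dbs, db$reference_lineages)
  for (loc in names(lc$counts)) {
    truth <- table(sim$truth$true_genus[sim$truth$locus == loc])
    expect_equal(lc$counts[[loc]][sort(names(truth))],
                 setNames(as.numeric(truth[sort(names(truth))]),
                          sort(names(truth))))
    expect_equal(unname(lc$matched[loc]), sum(truth))
  }
})
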