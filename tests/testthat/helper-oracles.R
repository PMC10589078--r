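# Independent oracles, written against the documented conventions and kept
# free of any package internals.

# Brute-force free-end-gap DP in plain R. Cell value: c(score, matches,
# columns, query-consuming columns, target-consuming columns), optimised
# lexicographically (score desc, matches desc, columns asc, qcols desc,
# tcols desc) so identity and coverage are uniquely determined.
oracle_semiglobal <- function(q, t, match = 2, mismatch = -4, gap = -4,
                              query_global = FALSE) {
  qs <- strsplit(q, "")[[1]]
  ts <- strsplit(t, "")[[1]]
  n <- length(qs); m <- length(ts)
  lex_better <- function(a, b) {
    if (a[1] != b[1]) return(a[1] > b[1])
    if (a[2] != b[2]) return(a[2] > b[2])
    if (a[3] != b[3]) return(a[3] < b[3])
    if (a[4] != b[4]) return(a[4] > b[4])
    a[5] > b[5]
  }
  H <- array(0, dim = c(n + 1, m + 1, 5))
  if (query_global) {
    for (i in 1:n) H[i + 1, 1, ] <- H[i, 1, ] + c(gap, 0, 1, 1, 0)
  }
  for (i in 1:n) {
    for (j in 1:m) {
      hit <- qs[i] == ts[j] && qs[i] != "N"
      diag <- H[i, j, ] + c(if (hit) match else mismatch, hit, 1, 1, 1)
      up <- H[i, j + 1, ] + c(gap, 0, 1, 1, 0)
      left <- H[i + 1, j, ] + c(gap, 0, 1, 0, 1)
      best <- diag
      if (lex_better(up, best)) best <- up
      if (lex_better(left, best)) best <- left
      H[i + 1, j + 1, ] <- best
    }
  }
  best <- H[n + 1, 1, ]
  for (j in 1:(m + 1)) if (lex_better(H[n + 1, j, ], best)) best <- H[n + 1, j, ]
  if (!query_global) {
    for (i in 1:(n + 1)) if (lex_better(H[i, m + 1, ], best)) best <- H[i, m + 1, ]
  }
  list(score = best[1], matches = best[2], columns = best[3],
       identity = if (best[3] > 0) best[2] / best[3] else 0,
       coverage = best[4] / n)
}

# naive substring scan over all offsets (exact-match oracle); an N anywhere
# in the barcode matches nothing
oracle_substring_hit <- function(barcode, target) {
  if (grepl("N", barcode, fixed = TRUE)) return(FALSE)
  nb <- nchar(barcode); nt <- nchar(target)
  if (nb > nt) return(FALSE)
  for (off in 0:(nt - nb)) {
    if (substring(target, off + 1, off + nb) == barcode) return(TRUE)
  }
  FALSE
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# small plant lineage factory for tests
test_lineage <- function(genus, family = "Rosaceae", order = "Rosales",
                         class = "Magnoliopsida", species = NA) {
  lineage(kingdom = "Viridiplantae", phylum = "Streptophyta", class = class,
          order = order, family = family, genus = genus, species = species)
}
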