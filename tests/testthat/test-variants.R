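test_that("mutation codes parse, validate and reject degenerate cases", {
  m <- parse_mutation("A2G", "MAV")
  expect_equal(m$wt, "A")
  expect_equal(m$pos, 2L)
  expect_equal(m$mut, "G")
  expect_error(parse_mutation("M1M", "MAV"), "identical")
  expect_error(parse_mutation("G2A", "MAV"), "not 'G'")
  expect_error(parse_mutation("A0G", "MAV"))
  expect_error(parse_mutation("A9G", "MAV"), "out of range")
  expect_error(parse_mutation("B2G", "MAV"), "amino-acid")
  expect_error(parse_mutation("AG"), "malformed")
})

test_that("applying a mutation changes exactly one position and inverts", {
  expect_equal(apply_mutation("MAV", "A2G"), "MGV")
  set.seed(11)
  for (i in 1:20) {
    s <- random_sequence(sample(10:60, 1))
    pos <- sample(nchar(s), 1)
    wt <- substr(s, pos, pos)
    mut <- sample(setdiff(ddgfuse:::AA_ALPHABET, wt), 1)
    code <- paste0(wt, pos, mut)
    s2 <- apply_mutation(s, code)
    expect_equal(nchar(s2), nchar(s))
    diff <- which(utf8ToInt(s) != utf8ToInt(s2))
    expect_equal(diff, pos)
    expect_equal(apply_mutation(s2, paste0(mut, pos, wt)), s)
  }
})

test_that("reversal negates ddG, swaps letters and is an involution", {
  v <- variant_table(c("P1", "P2"), c("A10G", "L5V"), ddg = c(1.2, -0.4),
                     fold = c(1L, 2L))
  r <- reverse_variants(v)
  expect_equal(r$mutation, c("G10A", "V5L"))
  expect_equal(r$ddg, c(-1.2, 0.4))
  expect_equal(r$direction, c("reverse", "reverse"))
  expect_equal(r$fold, v$fold)
  expect_identical(reverse_variants(r), v)
  z <- variant_table("P1", "A1C", ddg = 0)
  expect_equal(reverse_variants(z)$ddg, 0)
})

test_that("duplicate records average per key and the operation is idempotent", {
  v <- variant_table(c("P1", "P1", "P1"), c("A10G", "A10G", "L5V"),
                     ddg = c(1.0, 2.0, 0.5))
  d <- deduplicate_average(v)
  expect_equal(nrow(d), 2L)
  expect_equal(d$ddg[d$mutation == "A10G"], 1.5)
  expect_equal(d$ddg[d$mutation == "L5V"], 0.5)
  expect_identical(deduplicate_average(d), d)
  cancel <- variant_table(c("P1", "P1"), c("A10G", "A10G"), ddg = c(1, -1))
  expect_equal(deduplicate_average(cancel)$ddg, 0)
  empty <- variant_table(character(0), character(0))
  expect_equal(nrow(deduplicate_average(empty)), 0L)
})

test_that("variant CSV round-trips exactly in key fields and to >= 6 digits in ddG", {
  set.seed(3)
  v <- variant_table(
    sprintf("P%d", 1:8),
    c("A10G", "L5V", "K7E", "M1W", "C3S", "D4N", "F6Y", "H2R"),
    ddg = c(stats::rnorm(6), NA, 1.23456789),
    direction = rep(c("direct", "reverse"), 4),
    fold = c(1:4, 1:4)
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_variants(v, f)
  v2 <- read_variants(f)
  expect_identical(v2$protein_id, v$protein_id)
  expect_identical(v2$mutation, v$mutation)
  expect_identical(v2$direction, v$direction)
  expect_identical(v2$fold, v$fold)
  expect_equal(v2$ddg, v$ddg, tolerance = 1e-9)
  expect_equal(read_variants(f, flip_sign = TRUE)$ddg, -v$ddg,
               tolerance = 1e-9)
})

test_that("FASTA sequences round-trip and invalid letters are rejected", {
  seqs <- c(P1 = "MAVKLE", P2 = random_sequence(130))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">bad", "MAXB"), f2)
  expect_error(read_fasta(f2), "non-standard")
})

test_that("identical sequences share a fold; dissimilar ones spread one per fold", {
  same <- stats::setNames(rep(strrep("MAVKLEDR", 6), 10),
                          paste0("S", 1:10))
  expect_warning(f <- homology_fold_split(same, k = 5), "empty")
  expect_equal(length(unique(f)), 1L)

  # five sequences over disjoint letter pairs: every pairwise identity is 0
  dis <- stats::setNames(
    vapply(list(c("A", "G"), c("C", "H"), c("D", "I"), c("E", "K"),
                c("F", "L")),
           function(p) strrep(paste(p, collapse = ""), 15), ""),
    paste0("D", 1:5))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(sequence_identity(dis[[i]], dis[[j]]), 0)
  }
  f2 <- homology_fold_split(dis, k = 5)
  expect_equal(sort(unname(f2)), 1:5)
})

test_that("fold assignment is a partition respecting cluster purity", {
  seqs <- sim_sequence_clusters(n_clusters = 7, copies_per_cluster = 3,
                                length = 60, seed = 5)
  f <- homology_fold_split(seqs, k = 4, identity_threshold = 0.25)
  expect_setequal(names(f), names(seqs))
  expect_true(all(f %in% 1:4))
  # brute force: any pair at/above threshold must share a fold
  n <- length(seqs)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (sequence_identity(seqs[[i]], seqs[[j]]) >= 0.25) {
      expect_equal(f[[i]], f[[j]])
    }
  }
})
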