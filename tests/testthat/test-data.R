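test_that("FASTA records round-trip through write/read", {
  prot <- data.frame(id = c("sp|Q1|TEST", "p2"),
                     sequence = c(random_sequence(30, seed = 500),
                                  random_sequence(25)))
  path <- tempfile(fileext = ".fasta")
  write_fasta(prot, path)
  back <- read_fasta(path)
  expect_equal(back$id, c("sp|Q1|TEST", "p2"))
  expect_equal(back$sequence, prot$sequence)
})

test_that("read_fasta takes the first header token and cleans sequences", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">prot1 some description", "mektw", ">prot2", "ARNDX"), path)
  expect_warning(rec <- read_fasta(path), "X")
  expect_equal(rec$id, c("prot1", "prot2"))
  expect_equal(rec$sequence, c("MEKTW", "ARND"))
})

test_that("read_fasta rejects duplicates, empties and header-only records", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "MEK", ">a", "TWC"), path)
  expect_error(read_fasta(path), "duplicate")
  empty <- tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "empty")
  hdr <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "MEK", ">b"), hdr)
  expect_error(suppressWarnings(read_fasta(hdr)), "unencodable|empty")
})

test_that("pair lists round-trip and comments are skipped", {
  pairs <- data.frame(id_a = c("p1", "p2"), id_b = c("p2", "p3"),
                      label = c(1L, 0L))
  path <- tempfile(fileext = ".tsv")
  write_pairs(pairs, path)
  expect_equal(read_pairs(path), pairs)
  withcomment <- tempfile(fileext = ".tsv")
  writeLines(c("# interactome subset", "p1\tp2\t1", "", "p3\tp4\t0"),
             withcomment)
  got <- read_pairs(withcomment)
  expect_equal(nrow(got), 2L)
  expect_equal(got$label, c(1L, 0L))
})

test_that("read_pairs reports malformed lines by number", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("p1\tp2\t1", "p3\tp4\tmaybe"), path)
  expect_error(read_pairs(path), "line 2.*maybe")
  short <- tempfile(fileext = ".tsv")
  writeLines(c("# hdr", "p1\tp2"), short)
  expect_error(read_pairs(short), "line 2")
})

test_that("negative sampling avoids positives, self-pairs and usage skew", {
  positives <- data.frame(id_a = "p1", id_b = "p2", label = 1L)
  ids <- paste0("p", 1:4)
  neg <- sample_negative_pairs(positives, ids, n = 2, seed = 1)
  expect_equal(nrow(neg), 2L)
  expect_true(all(neg$label == 0L))
  expect_true(all(neg$id_a != neg$id_b))
  keys <- function(df) paste(pmin(df$id_a, df$id_b), pmax(df$id_a, df$id_b))
  expect_false(any(keys(neg) %in% keys(positives)))
  expect_false(anyDuplicated(keys(neg)) > 0)
  usage <- table(factor(c(neg$id_a, neg$id_b), levels = ids))
  expect_lte(max(usage) - min(usage), 1)
  # the drawn pairs are among the enumerated valid outcomes
  valid <- c("p1 p3", "p1 p4", "p2 p3", "p2 p4", "p3 p4")
  expect_true(all(keys(neg) %in% valid))
})

test_that("negative sampling balances the dataset and detects exhaustion", {
  set.seed(501)
  ids <- paste0("q", 1:12)
  positives <- data.frame(id_a = ids[1:6], id_b = ids[7:12],
                          label = 1L)
  neg <- sample_negative_pairs(positives, ids, n = nrow(positives), seed = 2)
  expect_equal(nrow(neg), nrow(positives))
  # only one unordered pair exists for two proteins and it is positive
  expect_error(
    sample_negative_pairs(data.frame(id_a = "a", id_b = "b", label = 1L),
                          c("a", "b"), n = 1, seed = 3),
    "could not sample")
})

test_that("negative samples never intersect positives across many seeds", {
  ids <- paste0("r", 1:8)
  positives <- data.frame(id_a = ids[c(1, 2, 3)], id_b = ids[c(5, 6, 7)],
                          label = 1L)
  keys <- function(df) paste(pmin(df$id_a, df$id_b), pmax(df$id_a, df$id_b))
  for (seed in 1:100) {
    neg <- sample_negative_pairs(positives, ids, n = 3, seed = seed)
    expect_false(any(keys(neg) %in% keys(positives)))
    expect_true(all(neg$id_a != neg$id_b))
  }
})

test_that("generate_synthetic is deterministic and obeys the motif rule", {
  ds1 <- generate_synthetic(n_proteins = 20, n_positive = 8, n_negative = 8,
                            seed = 7)
  ds2 <- generate_synthetic(n_proteins = 20, n_positive = 8, n_negative = 8,
                            seed = 7)
  expect_identical(ds1, ds2)
  motif_of <- stats::setNames(ds1$proteins$motif, ds1$proteins$id)
  pos <- ds1$pairs[ds1$pairs$label == 1L, ]
  expect_true(all(motif_of[pos$id_a] == "a" & motif_of[pos$id_b] == "b"))
  neg <- ds1$pairs[ds1$pairs$label == 0L, ]
  expect_true(all(motif_of[neg$id_a] == motif_of[neg$id_b]))
  # inserted motifs are literally present
  expect_true(all(grepl(SparsePPI:::SYNTH_MOTIF_A, ds1$proteins$sequence[
    ds1$proteins$motif == "a"], fixed = TRUE)))
  expect_true(all(grepl(SparsePPI:::SYNTH_MOTIF_B, ds1$proteins$sequence[
    ds1$proteins$motif == "b"], fixed = TRUE)))
  expect_error(generate_synthetic(n_proteins = 4, n_positive = 100,
                                  n_negative = 2, seed = 1), "infeasible")
})
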