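test_that("self-alignment scores the diagonal sum at 100% identity", {
  p <- scoring_params()
  for (s in c("MKWVTFISLLLLFSSAYS", "ARNDCQEGHIKLMFPSTWYV")) {
    al <- smith_waterman(s, s, p)
    res <- strsplit(s, "")[[1]]
    expect_equal(al$raw_score, sum(diag(p$matrix[res, res])))
    expect_equal(al$pct_identity, 100)
    expect_equal(al$q_start, 0)
    expect_equal(al$q_end, nchar(s))
  }
})

test_that("no positive-scoring pair gives score 0 and an empty alignment", {
  p <- scoring_params()
  al <- smith_waterman("AAAA", "TTTT", p)   # BLOSUM62 A/T scores 0
  expect_equal(al$raw_score, 0)
  expect_equal(al$align_len, 0)
  expect_error(smith_waterman("", "AA", p), "non-empty")
})

test_that("scores match the exhaustive gap-enumeration oracle on small pairs", {
  p <- scoring_params()
  set.seed(14)
  for (i in 1:60) {
    a <- rand_prot(sample.int(30, 1))
    b <- rand_prot(sample.int(30, 1))
    expect_identical(sw_score(a, b, p),
                     as.integer(oracle_sw_score(a, b, p$matrix)))
  }
})

test_that("raw score is symmetric and dominated by supersequences", {
  p <- scoring_params()
  set.seed(15)
  for (i in 1:25) {
    a <- rand_prot(sample(10:40, 1))
    b <- rand_prot(sample(10:40, 1))
    expect_identical(sw_score(a, b, p), sw_score(b, a, p))
    # b embedded in a longer subject can only score >= b alone
    b2 <- paste0(rand_prot(10), b, rand_prot(10))
    expect_gte(sw_score(a, b2, p), sw_score(a, b, p))
  }
})

test_that("scores agree with Biostrings local alignment as a cross-check", {
  p <- scoring_params()
  set.seed(16)
  for (i in 1:10) {
    a <- rand_prot(60); b <- rand_prot(80)
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = p$matrix, gapOpening = 11, gapExtension = 1,
      type = "local", scoreOnly = TRUE)
    expect_equal(sw_score(a, b, p), as.integer(ref))
  }
})

test_that("bit score and E-value follow the Karlin-Altschul identities", {
  p <- scoring_params()
  expect_equal(bit_score(0, p), -log(0.041) / log(2), tolerance = 1e-12)
  expect_equal(bit_score(0, p), 4.608, tolerance = 1e-3)
  # algebraic zero: lambda * S = ln K
  pz <- scoring_params(lambda = log(2), K = 4)
  expect_equal(bit_score(2, pz), 0, tolerance = 1e-12)
  # strictly increasing in S
  s <- 0:1000
  expect_true(all(diff(bit_score(s, p)) > 0))
  # E = K m n at S = 0; doubling n doubles E
  expect_equal(e_value(0, 100, 1000, p), 0.041 * 100 * 1000)
  expect_equal(e_value(57, 100, 2000, p), 2 * e_value(57, 100, 1000, p))
  expect_error(e_value(10, 0, 10, p), "positive")
})

test_that("search finds an identical subject as a convincing top hit", {
  p <- scoring_params()
  set.seed(17)
  subj <- rand_prot(500)
  db <- protein_db(c("target", "junk"), c(subj, rand_prot(400)))
  hits <- search_homology(data.frame(orf_id = "q1", aa_seq = subj), db, p)
  expect_equal(hits$subject_id[1], "target")
  expect_equal(hits$tier[1], "convincing")
  expect_equal(hits$pct_identity[1], 100)
  expect_lt(hits$evalue[1], 1e-100)
})

test_that("tier assignment is consistent with the E-value thresholds", {
  p <- scoring_params()
  set.seed(18)
  sp <- seed_protein()
  res <- strsplit(sp, "")[[1]]
  db <- protein_db(sprintf("S%d", 1:4),
                   vapply(1:4, function(i) paste(sample(res), collapse = ""),
                          character(1)))
  queries <- data.frame(orf_id = sprintf("q%d", 1:10),
                        aa_seq = vapply(1:10, function(i) rand_prot(350),
                                        character(1)))
  hits <- search_homology(queries, db, p)
  if (nrow(hits)) {
    expect_true(all(hits$evalue < p$report_evalue_max))
    expect_true(all((hits$evalue <= p$convincing_evalue_max) ==
                    (hits$tier == "convincing")))
    expect_true(all(hits$raw_score > 0))
    # best hit per (query, subject) only
    expect_false(anyDuplicated(paste(hits$query_id, hits$subject_id)) > 0)
  }
})

test_that("random queries against shuffled subjects are never convincing", {
  p <- scoring_params()
  conv <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    db <- protein_db(sprintf("S%d", 1:3),
                     vapply(1:3, function(i) rand_prot(300), character(1)))
    q <- data.frame(orf_id = "q", aa_seq = rand_prot(350))
    hits <- search_homology(q, db, p)
    conv <- conv + sum(hits$tier == "convincing")
  }
  expect_lte(conv, 1L)   # zero convincing in >= 9/10 seeds
})

test_that("a diverged env-like ORF is convincing while a decoy is not", {
  p <- scoring_params()
  sp <- substr(seed_protein(), 1, 534)
  mut <- mutate_protein(sp, 0.2, seed = 77)
  d <- withr::local_tempdir()
  db_fa <- file.path(d, "db.fa")
  write_fixture_db(db_fa, 77)
  db <- read_protein_db(db_fa)
  set.seed(78)
  queries <- data.frame(orf_id = c("env_like", "decoy"),
                        aa_seq = c(mut, rand_prot(534)))
  hits <- search_homology(queries, db, p)
  env_hits <- hits[hits$query_id == "env_like", ]
  expect_equal(env_hits$subject_id[1], "SYN_ENV_SEED")
  expect_equal(env_hits$tier[1], "convincing")
  decoy <- hits[hits$query_id == "decoy", ]
  expect_false(any(decoy$tier == "convincing"))
})

test_that("outfmt-6-style output uses 1-based inclusive coordinates", {
  p <- scoring_params()
  hits <- search_homology(data.frame(orf_id = "q", aa_seq = "MKWVTFISLL"),
                          protein_db("s", "MKWVTFISLL"), p)
  d <- withr::local_tempdir()
  f <- file.path(d, "hits.tsv")
  write_hits_tsv(hits, f)
  out <- read.delim(f)
  expect_equal(out$qstart, 1L)
  expect_equal(out$qend, 10L)
  expect_equal(out$sstart, 1L)
  expect_equal(out$send, 10L)
  expect_equal(out$tier, "convincing")
})
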