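test_that("generators are pure functions of their seed", {
  a <- sim_expression(n_genes = 100, seed = 51)
  b <- sim_expression(n_genes = 100, seed = 51)
  expect_identical(a$table$intensity, b$table$intensity)
  expect_identical(a$truth$up_genes, b$truth$up_genes)
  g1 <- sim_genome("gX", seed = 52, chrom_len = 2.1e6)
  g2 <- sim_genome("gX", seed = 52, chrom_len = 2.1e6)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(mutate_protein("ARNDCQEGHIKL", 0.5, 53),
                   mutate_protein("ARNDCQEGHIKL", 0.5, 53))
  expect_identical(reverse_translate("MKW", 54), reverse_translate("MKW", 54))
})

test_that("mutate_protein hits its divergence within binomial bounds", {
  sp <- seed_protein()
  expect_identical(mutate_protein(sp, 0, 1), sp)
  long <- paste(rep(sp, 2), collapse = "")   # 1080 residues
  long <- substr(long, 1, 1000)
  mut <- mutate_protein(long, 0.5, 2)
  ham <- sum(strsplit(long, "")[[1]] != strsplit(mut, "")[[1]])
  expect_gte(ham, 440)
  expect_lte(ham, 560)
  expect_error(mutate_protein(sp, 0.95, 1), "0.9")
})

test_that("reverse_translate emits synonymous stop-free codons", {
  aa <- "MKWARNDCQEGHILFPSTYV"
  nt <- reverse_translate(aa, 55)
  expect_equal(nchar(nt), 3 * nchar(aa))
  expect_equal(translate_nt(nt), aa)
  expect_false(grepl("\\*", translate_nt(nt)))
})

test_that("a planted ORF is recovered at exact coordinates (both strands)", {
  for (strand in c("+", "-")) {
    gen <- sim_genome("gA", seed = 56, chrom_len = 2.2e6,
                      plants = list(plant_spec("gA", offset_nt = 5000L,
                                               strand = strand,
                                               divergence = 0)))
    pl <- gen$truth$planted_orfs[[1]]
    w <- make_window(gen$loci, flank = 1e6, chrom_length = 2.2e6)
    rec <- extract_sequence(gen$genome, w)
    orfs <- find_orfs(rec, orf_config(1000), abs_offset = w$start)
    hit <- orfs[orfs$abs_start == pl$abs_start &
                orfs$abs_end == pl$abs_end & orfs$strand == strand, ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$aa_seq, pl$protein)
    expect_equal(hit$aa_seq, substr(seed_protein(), 1, 534))
  }
})

test_that("a diverged plant differs from the seed at about the target rate", {
  gen <- sim_genome("gA", seed = 57, chrom_len = 2.2e6,
                    plants = list(plant_spec("gA", offset_nt = 5000L,
                                             divergence = 0.2)))
  pl <- gen$truth$planted_orfs[[1]]
  src <- substr(seed_protein(), 1, 534)
  ham <- sum(strsplit(src, "")[[1]] != strsplit(pl$protein, "")[[1]])
  # binomial(534, 0.2): 95% band approx 107 +/- 2 * 9.2
  expect_gte(ham, 80)
  expect_lte(ham, 135)
})

test_that("a plant that does not fit its window is a layout error", {
  expect_error(
    sim_genome("gA", seed = 58, chrom_len = 2.2e6,
               plants = list(plant_spec("gA", offset_nt = as.integer(2.3e6),
                                        divergence = 0))),
    "fit")
  expect_error(
    sim_genome("gA", seed = 58,
               plants = list(plant_spec("nope", offset_nt = 0L))),
    "unknown gene")
})

test_that("noiseless expression recovery is exact, null matrices are empty", {
  se <- sim_expression(n_genes = 200, seed = 59, noise_sigma = 0)
  calls <- call_upregulated(se$table, "treat_low")
  expect_setequal(calls$gene_id[calls$concordant], se$truth$up_genes)
  null <- sim_expression(n_genes = 200, seed = 60, true_fold = 1)
  nc <- call_upregulated(null$table, "treat_low")
  expect_equal(sum(nc$concordant), 0L)
})

test_that("sim_dataset writes a coherent file bundle with truth", {
  d <- withr::local_tempdir()
  ps <- sim_dataset(d, seed = 61)
  for (f in c("matrix", "samples", "genome", "annotation", "protein_db",
              "ct", "truth"))
    expect_true(file.exists(ps[[f]]))
  truth <- jsonlite::read_json(ps$truth, simplifyVector = TRUE)
  expect_length(truth$up_genes, 5)
  expect_equal(truth$planted_orfs$kind, c("env", "decoy"))
  loci <- read_gene_loci(ps$annotation)
  expect_true(all(truth$up_genes %in% loci$gene_id))
  # the env plant lies inside the window of its gene and nowhere else
  env <- truth$planted_orfs[1, ]
  genome <- Biostrings::readDNAStringSet(ps$genome)
  w <- make_windows(loci, genome)
  inside <- w$chrom == env$chrom & w$start <= env$abs_start &
    w$end >= env$abs_end
  expect_equal(sum(inside), 1L)
  expect_equal(w$source_gene[inside], truth$env_gene)
})
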