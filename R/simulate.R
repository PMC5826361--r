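#' The bundled synthetic seed protein
#'
#' A fixed 540-residue envelope-like amino-acid sequence shipped with the
#' package (`inst/extdata/synthetic_env_seed.fa`). It is a synthetic
#' sequence, not a real viral protein: real env proteins are user-supplied
#' inputs for real runs. The generators derive planted ORFs and the fixture
#' database from it.
#'
#' @return a single amino-acid string of length 540.
#' @export
seed_protein <- function() {
  path <- system.file("extdata", "synthetic_env_seed.fa", package = "ervscan")
  as.character(Biostrings::readAAStringSet(path)[[1L]])
}

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Mutate a protein to a target per-residue divergence
#'
#' Each residue is independently substituted with probability `divergence`
#' by a uniformly chosen *different* residue from the 20-letter alphabet.
#' Deterministic given the seed.
#'
#' @param aa amino-acid string.
#' @param divergence substitution probability in `[0, 0.9)`.
#' @param seed integer seed.
#' @return the mutated amino-acid string.
#' @export
mutate_protein <- function(aa, divergence, seed) {
  if (divergence < 0 || divergence >= 0.9)
    stop("divergence must lie in [0, 0.9)")
  res <- strsplit(aa, "", fixed = TRUE)[[1L]]
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  hit <- runif(length(res)) < divergence
  if (any(hit)) {
    res[hit] <- vapply(res[hit], function(r) {
      sample(setdiff(.AA20, r), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  paste(res, collapse = "")
}

# codons per amino acid under the standard code (no stop codons map to an aa)
.CODONS_BY_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

#' Reverse-translate a protein with uniform synonymous codon choice
#'
#' @param aa amino-acid string over the 20-letter alphabet.
#' @param seed integer seed.
#' @return a nucleotide string of length `3 * nchar(aa)` containing no
#'   in-frame stop codon.
#' @export
reverse_translate <- function(aa, seed) {
  res <- strsplit(aa, "", fixed = TRUE)[[1L]]
  if (!all(res %in% .AA20)) stop("sequence contains non-standard residues")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  paste(vapply(res, function(r) {
    cods <- .CODONS_BY_AA[[r]]
    cods[sample.int(length(cods), 1L)]
  }, character(1), USE.NAMES = FALSE), collapse = "")
}

#' Specification of one planted ORF
#'
#' Describes an ORF to plant inside the window of a gene: the mutated seed
#' protein is reverse-translated and bracketed by in-frame stop codons, so
#' the planted coding region is a maximal stop-free run recoverable at exact
#' coordinates.
#'
#' @param window_gene gene whose window receives the plant.
#' @param offset_nt 0-based offset of the insertion from the window start.
#' @param strand `"+"` or `"-"`.
#' @param divergence per-residue substitution probability, `[0, 0.9)`.
#' @param orf_len_nt coding length in nt (multiple of 3, >= 1000 by
#'   convention of the screen). Default 1602.
#' @param protein source protein (default: the bundled seed protein,
#'   truncated to `orf_len_nt / 3` residues).
#' @param kind free-text label stored in the truth (`"env"` or `"decoy"`).
#' @return a list of class `"plant_spec"`.
#' @export
plant_spec <- function(window_gene, offset_nt, strand = "+", divergence = 0,
                       orf_len_nt = 1602L, protein = NULL, kind = "env") {
  if (orf_len_nt %% 3 != 0) stop("orf_len_nt must be a multiple of 3")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(window_gene = window_gene, offset_nt = as.integer(offset_nt),
                 strand = strand, divergence = divergence,
                 orf_len_nt = as.integer(orf_len_nt), protein = protein,
                 kind = kind),
            class = "plant_spec")
}

#' Simulate a genome with annotated genes and planted ORFs
#'
#' Generates i.i.d. background nucleotides at the requested GC content,
#' places non-overlapping gene features at fixed fractional positions
#' (`genes_per_chrom` per chromosome, spaced so that 2 Mbp windows of
#' neighboring genes do not overlap at the default geometry), and realizes
#' each [plant_spec()] by inserting `stop + reverse-translated protein +
#' stop` at the requested offset inside the gene's window. Pure function of
#' `seed`.
#'
#' @param gene_ids character vector of gene ids to annotate.
#' @param seed integer seed.
#' @param chrom_len chromosome length in bp. Default 4.4e6.
#' @param genes_per_chrom genes per chromosome. Default 2.
#' @param gc GC content of the background. Default 0.41 (human-like).
#' @param gene_len annotated gene length. Default 2e4.
#' @param plants list of [plant_spec()]s.
#' @param flank flank used to locate plant windows. Default 1e6.
#' @return list with `genome` (named `DNAStringSet`), `loci` (data.frame as
#'   [read_gene_loci()]), and `truth` (list with `planted_orfs`).
#' @export
sim_genome <- function(gene_ids, seed, chrom_len = 4.4e6,
                       genes_per_chrom = 2L, gc = 0.41, gene_len = 2e4,
                       plants = list(), flank = 1e6) {
  n_chrom <- ceiling(length(gene_ids) / genes_per_chrom)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chroms <- lapply(seq_len(n_chrom), function(i) {
    paste(sample(names(p), chrom_len, replace = TRUE, prob = p), collapse = "")
  })
  names(chroms) <- sprintf("chr%d", seq_len(n_chrom))

  loci <- data.frame(gene_id = gene_ids, chrom = NA_character_,
                     start = NA_real_, end = NA_real_, strand = "+",
                     stringsAsFactors = FALSE)
  for (i in seq_along(gene_ids)) {
    ci <- (i - 1L) %/% genes_per_chrom + 1L
    k <- (i - 1L) %% genes_per_chrom + 1L
    center <- chrom_len * (2 * k - 1) / (2 * genes_per_chrom)
    loci$chrom[i] <- sprintf("chr%d", ci)
    loci$start[i] <- floor(center - gene_len / 2)
    loci$end[i] <- loci$start[i] + gene_len
    loci$strand[i] <- if (i %% 2 == 0) "-" else "+"
  }

  planted <- list()
  for (j in seq_along(plants)) {
    pl <- plants[[j]]
    row <- loci[loci$gene_id == pl$window_gene, , drop = FALSE]
    if (nrow(row) != 1L) stop("plant names unknown gene: ", pl$window_gene)
    win <- make_window(row, flank = flank, chrom_length = chrom_len)
    src <- pl$protein
    if (is.null(src)) src <- substr(seed_protein(), 1L, pl$orf_len_nt / 3L)
    if (nchar(src) != pl$orf_len_nt / 3L)
      stop("plant protein length does not match orf_len_nt")
    mut <- mutate_protein(src, pl$divergence, child_seed(seed, 100 + j))
    coding <- reverse_translate(mut, child_seed(seed, 200 + j))
    region <- paste0("TAA", coding, "TAG")
    if (pl$strand == "-") region <- reverse_complement(region)
    pos <- win$start + pl$offset_nt              # 0-based insertion start
    if (pos < 0 || pos + nchar(region) > win$end)
      stop("planted ORF does not fit inside the window of ", pl$window_gene)
    s <- chroms[[win$chrom]]
    chroms[[win$chrom]] <- paste0(substr(s, 1L, pos),
                                  region,
                                  substr(s, pos + nchar(region) + 1L,
                                         chrom_len))
    planted[[j]] <- list(window_gene = pl$window_gene, chrom = win$chrom,
                         abs_start = pos + 3, abs_end = pos + 3 + pl$orf_len_nt,
                         strand = pl$strand, divergence = pl$divergence,
                         orf_len_nt = pl$orf_len_nt, protein = mut,
                         kind = pl$kind)
  }
  genome <- Biostrings::DNAStringSet(unlist(chroms))
  list(genome = genome, loci = loci,
       truth = list(planted_orfs = planted, seed = seed, gc = gc,
                    rng = "base R Mersenne-Twister, per-component child seeds"))
}

#' Simulate an expression matrix with planted up-regulated genes
#'
#' Two replicates of three conditions (control / low dose / high dose).
#' Baseline intensities are log-normal with median about 500; per replicate
#' the control value is `baseline * exp(N(0, sigma^2))` and the treated
#' value is `control * fold * exp(N(0, sigma^2))`, with `fold = true_fold`
#' for the planted genes and 1 otherwise (both treated conditions).
#'
#' @param n_genes total genes. Default 1000.
#' @param seed integer seed.
#' @param n_up number of planted up-regulated genes (ignored when
#'   `up_gene_ids` is given). Default 5.
#' @param up_gene_ids optional explicit planted gene ids.
#' @param true_fold planted fold change. Default 5.
#' @param noise_sigma sd of the multiplicative log-normal noise. Default 0.1.
#' @param baseline_sdlog spread of the baseline distribution. Default 0.5.
#' @return list with `table` (an [expression_table()]) and `truth`
#'   (`up_genes`, `true_fold`).
#' @export
sim_expression <- function(n_genes = 1000L, seed, n_up = 5L,
                           up_gene_ids = NULL, true_fold = 5,
                           noise_sigma = 0.1, baseline_sdlog = 0.5) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  if (is.null(up_gene_ids)) up_gene_ids <- sort(sample(genes, n_up))
  stopifnot(all(up_gene_ids %in% genes))
  fold <- ifelse(genes %in% up_gene_ids, true_fold, 1)
  base <- rlnorm(n_genes, meanlog = log(500), sdlog = baseline_sdlog)
  samples <- data.frame(
    sample_id = c("ctrl_r1", "ctrl_r2", "low_r1", "low_r2",
                  "high_r1", "high_r2"),
    condition = c("control", "control", "treat_low", "treat_low",
                  "treat_high", "treat_high"),
    replicate = c(1L, 2L, 1L, 2L, 1L, 2L), stringsAsFactors = FALSE)
  noise <- function() exp(rnorm(n_genes, 0, noise_sigma))
  ctrl <- list(base * noise(), base * noise())
  mat <- cbind(ctrl[[1]], ctrl[[2]],
               ctrl[[1]] * fold * noise(), ctrl[[2]] * fold * noise(),
               ctrl[[1]] * fold * noise(), ctrl[[2]] * fold * noise())
  rownames(mat) <- genes
  list(table = expression_table(mat, samples),
       truth = list(up_genes = up_gene_ids, true_fold = true_fold,
                    noise_sigma = noise_sigma))
}

#' Simulate a Ct table with known fold changes
#'
#' For each group, `dCt = baseline_dct - log2(true_fold) + N(0, sigma^2)`;
#' the reference gene Ct is fixed at `ref_ct` so that with `sigma = 0` the
#' recovered relative expressions reproduce the group folds exactly.
#'
#' @param groups named list: each element `list(n = <samples>, fold =
#'   <true fold>)`. Default a 3x3 design with folds 1, 2, 4 (control, low
#'   dose, high dose).
#' @param sigma Ct noise sd in cycles. Default 0.1.
#' @param seed integer seed.
#' @param target,reference gene labels written into the table.
#' @param baseline_dct dCt of a fold-1 sample. Default 6.
#' @param ref_ct reference-gene Ct. Default 18.
#' @return list with `table` (Ct data.frame) and `truth` (`true_folds` per
#'   sample).
#' @export
sim_ct <- function(groups = list(control = list(n = 3, fold = 1),
                                 treat_low = list(n = 3, fold = 2),
                                 treat_high = list(n = 3, fold = 4)),
                   sigma = 0.1, seed, target = "TARGET", reference = "ACTB",
                   baseline_dct = 6, ref_ct = 18) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  rows <- list(); folds <- numeric(0)
  for (g in names(groups)) {
    n <- groups[[g]]$n; f <- groups[[g]]$fold
    if (f <= 0) stop("true folds must be positive")
    for (i in seq_len(n)) {
      sid <- sprintf("%s_s%d", g, i)
      dct <- baseline_dct - log2(f) + rnorm(1, 0, sigma)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, group = g, target_gene = target,
        reference_gene = reference, ct_target = ref_ct + dct,
        ct_reference = ref_ct, stringsAsFactors = FALSE)
      folds[sid] <- f
    }
  }
  list(table = do.call(rbind, rows), truth = list(true_folds = folds))
}

#' Generate a complete synthetic dataset on disk
#'
#' Emits every input the pipeline needs, with ground truth: an expression
#' matrix with 5 planted up-regulated genes (fold 5, noise sigma 0.1, 2
#' replicates x 3 conditions), a genome annotating the 5 planted genes plus
#' one unrelated gene (windows of neighboring genes disjoint at the 2 Mbp
#' geometry), one env-like ORF (1,602 nt, minus strand, divergence 0.2 from
#' the seed protein) planted in the window of the first planted gene and one
#' random-protein decoy ORF in the window of the second, a fixture protein
#' database (seed protein plus three shuffles), and a Ct table (folds 1, 2,
#' 4). Everything is a pure function of `seed`.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer top-level seed.
#' @param divergence env-plant divergence. Default 0.2.
#' @return invisibly, a list with the file paths and the merged `truth`
#'   (also serialized to `truth.json`).
#' @export
sim_dataset <- function(out_dir, seed, divergence = 0.2) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  expr <- sim_expression(seed = child_seed(seed, 1))
  up <- expr$truth$up_genes
  extra <- setdiff(expr$table$genes, up)[1L]
  env_gene <- up[1L]; decoy_gene <- up[2L]

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(child_seed(seed, 4))
  decoy_prot <- paste(sample(.AA20, 534, replace = TRUE), collapse = "")
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  plants <- list(
    plant_spec(env_gene, offset_nt = 300000L, strand = "-",
               divergence = divergence, orf_len_nt = 1602L, kind = "env"),
    plant_spec(decoy_gene, offset_nt = 1500000L, strand = "+",
               divergence = 0, orf_len_nt = 1602L, protein = decoy_prot,
               kind = "decoy"))
  gen <- sim_genome(c(up, extra), seed = child_seed(seed, 2), plants = plants)
  ct <- sim_ct(seed = child_seed(seed, 3))

  paths <- list(
    matrix = file.path(out_dir, "matrix.tsv"),
    samples = file.path(out_dir, "samples.tsv"),
    genome = file.path(out_dir, "genome.fa"),
    annotation = file.path(out_dir, "genes.gff3"),
    protein_db = file.path(out_dir, "retro_db.fa"),
    ct = file.path(out_dir, "ct.tsv"),
    truth = file.path(out_dir, "truth.json"))

  mat <- expr$table$intensity
  write_tsv(data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                       stringsAsFactors = FALSE), paths$matrix)
  write_tsv(expr$table$samples, paths$samples)
  Biostrings::writeXStringSet(gen$genome, paths$genome)
  .write_gff3(gen$loci, paths$annotation)
  write_fixture_db(paths$protein_db, seed)
  write_tsv(ct$table, paths$ct)

  truth <- list(seed = seed,
                rng = "base R Mersenne-Twister, per-component child seeds",
                up_genes = expr$truth$up_genes,
                true_fold = expr$truth$true_fold,
                env_gene = env_gene, decoy_gene = decoy_gene,
                planted_orfs = gen$truth$planted_orfs,
                ct_true_folds = as.list(ct$truth$true_folds))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, list(truth_data = truth)))
}

# internal: minimal valid GFF3 for gene features (1-based closed coordinates)
.write_gff3 <- function(loci, path) {
  con <- file(path, "w")
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(loci))) {
    writeLines(sprintf("%s\tervscan_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_name=%s",
                       loci$chrom[i], loci$start[i] + 1, loci$end[i],
                       loci$strand[i], loci$gene_id[i], loci$gene_id[i]), con)
  }
  close(con)
  invisible(path)
}

#' Write the fixture protein database
#'
#' The bundled synthetic seed protein plus three residue shuffles of it
#' (decoy subjects with identical composition), total length 2,160 residues.
#'
#' @param path output FASTA path.
#' @param seed integer seed for the shuffles.
#' @return the path, invisibly.
#' @export
write_fixture_db <- function(path, seed) {
  sp <- seed_protein()
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(child_seed(seed, 5))
  res <- strsplit(sp, "")[[1L]]
  shuf <- vapply(1:3, function(i) paste(sample(res), collapse = ""),
                 character(1))
  aa <- Biostrings::AAStringSet(c(SYN_ENV_SEED = sp,
                                  setNames(shuf, sprintf("SHUFFLE_%d", 1:3))))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
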