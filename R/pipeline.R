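#' Pipeline configuration
#'
#' Collects input paths and stage parameters for [run_pipeline()]. All
#' referenced files must exist; the configuration is serialized verbatim
#' into the output directory.
#'
#' @param matrix,samples expression matrix and sample-sheet TSVs.
#' @param genome genome FASTA.
#' @param annotation gene annotation (GFF3 or BED).
#' @param protein_db subject protein FASTA.
#' @param out_dir output directory.
#' @param ct optional Ct TSV; when given, the 2^-ddCt stage runs.
#' @param fold_threshold,intensity_threshold,pseudo_count,intensity_on see
#'   [filter_config()].
#' @param flank,window_mode see [make_window()].
#' @param min_len_nt,orf_mode,include_partial_at_ends,min_len_op see
#'   [orf_config()].
#' @param gap_open,gap_extend,lambda,K,report_evalue_max,convincing_evalue_max
#'   see [scoring_params()].
#' @param attribute GFF3 gene-id attribute. Default `"gene_name"`.
#' @param seed integer recorded in the report (the analysis stages are
#'   deterministic; the seed governs any generator that produced the
#'   inputs).
#' @return an object of class `"erv_config"`.
#' @export
erv_config <- function(matrix, samples, genome, annotation, protein_db,
                       out_dir, ct = NULL,
                       fold_threshold = 3, intensity_threshold = 100,
                       pseudo_count = 0, intensity_on = "treated",
                       flank = 1e6, window_mode = "flank",
                       min_len_nt = 1000L, orf_mode = "between_stops",
                       include_partial_at_ends = TRUE, min_len_op = "ge",
                       gap_open = 11L, gap_extend = 1L, lambda = 0.267,
                       K = 0.041, report_evalue_max = 10,
                       convincing_evalue_max = 0.01,
                       attribute = "gene_name", seed = 1L) {
  cfg <- list(matrix = matrix, samples = samples, genome = genome,
              annotation = annotation, protein_db = protein_db, ct = ct,
              out_dir = out_dir, fold_threshold = fold_threshold,
              intensity_threshold = intensity_threshold,
              pseudo_count = pseudo_count, intensity_on = intensity_on,
              flank = flank, window_mode = window_mode,
              min_len_nt = min_len_nt, orf_mode = orf_mode,
              include_partial_at_ends = include_partial_at_ends,
              min_len_op = min_len_op, gap_open = gap_open,
              gap_extend = gap_extend, lambda = lambda, K = K,
              report_evalue_max = report_evalue_max,
              convincing_evalue_max = convincing_evalue_max,
              attribute = attribute, seed = seed)
  for (f in c("matrix", "samples", "genome", "annotation", "protein_db")) {
    if (!file.exists(cfg[[f]])) stop("input file missing: ", cfg[[f]])
  }
  if (!is.null(ct) && !file.exists(ct)) stop("input file missing: ", ct)
  structure(cfg, class = "erv_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of [erv_config()].
#' @return an `"erv_config"`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  do.call(erv_config, yaml::read_yaml(path))
}

#' Run the whole screening pipeline
#'
#' Executes, in order: up-regulation calling (per treated condition, union
#' of concordant genes), window construction around each candidate gene,
#' ORF scanning of every window, protein-level homology search of all
#' translated ORFs against the subject database, and (when a Ct table is
#' configured) 2^-ddCt quantification. Stage outputs (`calls.tsv`,
#' `windows.bed`, `orfs.tsv`, `proteins.fa`, `hits.tsv`, `fold.tsv`,
#' `report.json`, `manifest.json`, `config.json`, `run.log`) are written
#' under `out_dir`. The analysis is deterministic: re-running an identical
#' configuration reproduces `report.json` byte for byte.
#'
#' @param config an [erv_config()].
#' @param quiet suppress console logging. Default `FALSE`.
#' @return the report, an object of class `"erv_report"` (also written as
#'   `report.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "erv_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  cat("", file = logf)
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      say("stage %s FAILED: %s", name, conditionMessage(e))
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    say("stage %s done (%.1f s)", name, proc.time()[["elapsed"]] - t0)
    out
  }
  cfg_plain <- unclass(config)
  jsonlite::write_json(cfg_plain[!vapply(cfg_plain, is.null, logical(1))],
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  fc <- filter_config(config$fold_threshold, config$intensity_threshold,
                      config$pseudo_count, config$intensity_on)
  oc <- orf_config(config$min_len_nt, config$orf_mode,
                   config$include_partial_at_ends, config$min_len_op)
  sp <- scoring_params(gap_open = config$gap_open,
                       gap_extend = config$gap_extend,
                       lambda = config$lambda, K = config$K,
                       report_evalue_max = config$report_evalue_max,
                       convincing_evalue_max = config$convincing_evalue_max)

  # 1 -- expression filter
  candidates <- stage("filter", {
    tab <- read_expression(config$matrix, config$samples)
    conds <- setdiff(unique(tab$samples$condition), "control")
    calls <- lapply(sort(conds), function(cd) call_upregulated(tab, cd, fc))
    all_calls <- do.call(rbind, calls)
    write_tsv(all_calls, file.path(config$out_dir, "calls.tsv"))
    do.call(combine_conditions, calls)
  })

  # 2 -- windows around candidate genes
  win <- stage("windows", {
    loci <- read_gene_loci(config$annotation, attribute = config$attribute)
    genome <- .as_genome(config$genome)
    found <- intersect(names(candidates), loci$gene_id)
    unmapped <- setdiff(names(candidates), loci$gene_id)
    windows <- if (length(found)) {
      make_windows(loci[match(found, loci$gene_id), , drop = FALSE], genome,
                   flank = config$flank, mode = config$window_mode)
    } else {
      data.frame(window_id = character(), chrom = character(),
                 start = numeric(), end = numeric(),
                 source_gene = character(), flank = numeric())
    }
    write_windows_bed(windows, file.path(config$out_dir, "windows.bed"))
    list(windows = windows, genome = genome, unmapped = unmapped)
  })

  # 3 -- ORF scan of every window
  orfs <- stage("orfs", {
    res <- lapply(seq_len(nrow(win$windows)), function(i) {
      w <- win$windows[i, ]
      rec <- extract_sequence(win$genome, w)
      o <- find_orfs(rec, oc, window_id = w$window_id,
                     abs_offset = w$start)
      if (nrow(o)) o$chrom <- w$chrom
      o
    })
    res <- res[vapply(res, nrow, integer(1)) > 0L]
    o <- if (length(res)) do.call(rbind, res) else find_orfs("ACGT", orf_config(3))[0, ]
    write_orfs(o, file.path(config$out_dir, "orfs.tsv"),
               file.path(config$out_dir, "proteins.fa"))
    o
  })

  # 4 -- homology search
  hits <- stage("search", {
    db <- read_protein_db(config$protein_db)
    h <- if (nrow(orfs)) search_homology(orfs, db, sp) else
      search_homology(data.frame(orf_id = "empty", aa_seq = "A"),
                      db, sp)[0, ]
    write_hits_tsv(h, file.path(config$out_dir, "hits.tsv"))
    h
  })

  # 5 -- optional qPCR quantification
  fold <- NULL
  if (!is.null(config$ct)) {
    fold <- stage("ddct", {
      f <- relative_expression(read_ct_table(config$ct))
      write_tsv(f, file.path(config$out_dir, "fold.tsv"))
      f
    })
  }

  report <- .build_report(config, candidates, win, orfs, hits, fold)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c("config.json", "calls.tsv", "windows.bed", "orfs.tsv",
             "proteins.fa", "hits.tsv", "report.json",
             if (!is.null(fold)) "fold.tsv")
  manifest <- lapply(files, function(f)
    list(file = f, md5 = unname(tools::md5sum(file.path(config$out_dir, f)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("pipeline complete: %d candidate gene(s), %d ORF(s), %d hit(s)",
      length(candidates), nrow(orfs), nrow(hits))
  structure(report, class = "erv_report")
}

# internal: consolidated per-gene report
.build_report <- function(config, candidates, win, orfs, hits, fold) {
  genes <- list()
  for (g in names(candidates)) {
    w <- win$windows[win$windows$source_gene == g, , drop = FALSE]
    entry <- list(gene_id = g, conditions = as.list(candidates[[g]]))
    if (nrow(w) == 1L) {
      o <- orfs[orfs$window_id == w$window_id, , drop = FALSE]
      h <- hits[hits$query_id %in% o$orf_id, , drop = FALSE]
      conv <- h[h$tier == "convincing", , drop = FALSE]
      entry$window <- list(window_id = w$window_id, chrom = w$chrom,
                           start = w$start, end = w$end)
      entry$orf_count <- nrow(o)
      entry$n_hits <- nrow(h)
      entry$n_convincing <- nrow(conv)
      if (nrow(conv)) {
        b <- conv[which.min(conv$evalue), ]
        qo <- o[o$orf_id == b$query_id, ]
        entry$best_convincing_hit <- list(
          orf_id = b$query_id, subject_id = b$subject_id,
          evalue = b$evalue, bit_score = b$bit_score,
          pct_identity = b$pct_identity,
          orf_abs_start = qo$abs_start, orf_abs_end = qo$abs_end,
          orf_strand = qo$strand)
      }
    } else {
      entry$window <- NULL
      entry$unmapped <- TRUE
    }
    genes[[g]] <- entry
  }
  list(
    parameters = list(
      fold_threshold = config$fold_threshold,
      intensity_threshold = config$intensity_threshold,
      intensity_rule = sprintf("strictly > %g on the %s sample; fold >= %g",
                               config$intensity_threshold,
                               config$intensity_on, config$fold_threshold),
      flank = config$flank, min_len_nt = config$min_len_nt,
      orf_mode = config$orf_mode, lambda = config$lambda, K = config$K,
      evalue_note = "no effective-length edge correction (raw m, n)",
      report_evalue_max = config$report_evalue_max,
      convincing_evalue_max = config$convincing_evalue_max,
      seed = config$seed),
    n_candidates = length(candidates),
    unmapped_genes = as.list(win$unmapped),
    total_orfs = nrow(orfs),
    total_hits = nrow(hits),
    total_convincing = sum(hits$tier == "convincing"),
    genes = genes,
    ddct = if (!is.null(fold)) list(
      samples = fold,
      groups = fold_summary(fold)) else NULL)
}

#' @export
print.erv_report <- function(x, ...) {
  cat(sprintf("ERV scan report: %d candidate gene(s), %d ORF(s) >= threshold, %d hit(s) (%d convincing)\n",
              x$n_candidates, x$total_orfs, x$total_hits, x$total_convincing))
  for (g in x$genes) {
    cat(sprintf("  %s [%s]: ", g$gene_id,
                paste(unlist(g$conditions), collapse = ",")))
    if (isTRUE(g$unmapped)) { cat("no locus in annotation\n"); next }
    cat(sprintf("%d ORFs, %d hits, %d convincing", g$orf_count, g$n_hits,
                g$n_convincing))
    if (!is.null(g$best_convincing_hit))
      cat(sprintf(" | best: %s vs %s, E = %.3g",
                  g$best_convincing_hit$orf_id,
                  g$best_convincing_hit$subject_id,
                  g$best_convincing_hit$evalue))
    cat("\n")
  }
  invisible(x)
}
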