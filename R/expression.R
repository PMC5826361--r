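#' Filter configuration for up-regulation calling
#'
#' Holds the thresholds used to call a gene up-regulated after
#' hypoxia-mimetic treatment: the fold-change cutoff (treated/control, default
#' 3), the minimum signal intensity on the linear RMA scale (default 100), and
#' an optional pseudo-count added to both numerator and denominator of the
#' fold change. The fold comparison is non-strict (`>=`), the intensity
#' comparison strict (`>`); `intensity_on` selects which sample(s) the
#' intensity rule applies to (default the treated sample).
#'
#' @param fold_threshold fold-change cutoff, must be > 1. Default 3.
#' @param intensity_threshold minimum linear intensity, >= 0. Default 100.
#' @param pseudo_count non-negative value added to numerator and denominator
#'   of every fold change. Default 0 (RMA linear values are positive in
#'   practice).
#' @param intensity_on one of `"treated"`, `"control"`, `"both"`: which
#'   sample's intensity must exceed `intensity_threshold`.
#' @return an object of class `"filter_config"`.
#' @export
filter_config <- function(fold_threshold = 3, intensity_threshold = 100,
                          pseudo_count = 0,
                          intensity_on = c("treated", "control", "both")) {
  .check_number(fold_threshold, "fold_threshold")
  .check_number(intensity_threshold, "intensity_threshold")
  .check_number(pseudo_count, "pseudo_count")
  if (fold_threshold <= 1) stop("fold_threshold must be > 1")
  if (intensity_threshold < 0) stop("intensity_threshold must be >= 0")
  if (pseudo_count < 0) stop("pseudo_count must be >= 0")
  structure(list(fold_threshold = fold_threshold,
                 intensity_threshold = intensity_threshold,
                 pseudo_count = pseudo_count,
                 intensity_on = match.arg(intensity_on)),
            class = "filter_config")
}

.CONDITIONS <- c("control", "treat_low", "treat_high")

#' Construct an expression table
#'
#' Bundles a gene x sample matrix of linear (RMA-normalized) intensities with
#' its sample metadata. Conditions map to the treatment arms of the
#' cobalt-chloride hypoxia model: `control` (0 uM), `treat_low` (100 uM),
#' `treat_high` (200 uM).
#'
#' @param intensity numeric matrix, rows = genes (rownames = gene ids),
#'   columns = samples in the order of `samples$sample_id`. No negative
#'   values.
#' @param samples data.frame with columns `sample_id`, `condition`
#'   (`control`/`treat_low`/`treat_high`) and `replicate` (positive integer).
#'   Each (condition, replicate) pair must be unique.
#' @return an object of class `"expression_table"` with elements `genes`,
#'   `samples`, `intensity`.
#' @export
expression_table <- function(intensity, samples) {
  intensity <- as.matrix(intensity)
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and non-negative")
  if (is.null(rownames(intensity))) stop("intensity matrix needs gene ids as rownames")
  if (anyDuplicated(rownames(intensity))) stop("gene identifiers must be unique")
  need <- c("sample_id", "condition", "replicate")
  if (!all(need %in% names(samples)))
    stop("samples must have columns sample_id, condition, replicate")
  samples$condition <- as.character(samples$condition)
  samples$replicate <- as.integer(samples$replicate)
  if (!all(samples$condition %in% .CONDITIONS))
    stop("condition must be one of: ", paste(.CONDITIONS, collapse = ", "))
  if (any(samples$replicate < 1)) stop("replicate must be a positive integer")
  key <- paste(samples$condition, samples$replicate)
  if (anyDuplicated(key)) stop("each (condition, replicate) pair must be unique")
  if (ncol(intensity) != nrow(samples))
    stop("intensity columns must match the samples table")
  colnames(intensity) <- samples$sample_id
  structure(list(genes = rownames(intensity), samples = samples,
                 intensity = intensity),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d genes x %d samples (%s)\n",
              length(x$genes), nrow(x$samples),
              paste(sort(unique(x$samples$condition)), collapse = ", ")))
  invisible(x)
}

#' Read an expression matrix and its sample sheet from TSV
#'
#' The matrix TSV has a first column of gene ids and one column per sample;
#' the samples TSV has columns `sample_id`, `condition`, `replicate`.
#'
#' @param matrix_path path to the intensity TSV.
#' @param samples_path path to the sample-sheet TSV.
#' @return an [expression_table()].
#' @export
read_expression <- function(matrix_path, samples_path) {
  m <- read_tsv(matrix_path)
  samples <- read_tsv(samples_path)
  genes <- as.character(m[[1L]])
  mat <- as.matrix(m[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  ord <- match(samples$sample_id, colnames(mat))
  if (anyNA(ord)) stop("samples sheet names samples missing from the matrix: ",
                       paste(samples$sample_id[is.na(ord)], collapse = ", "))
  expression_table(mat[, ord, drop = FALSE], samples)
}

# internal: column index of the sample for (condition, replicate); error names
# the missing key
.sample_col <- function(table, condition, replicate) {
  i <- which(table$samples$condition == condition &
             table$samples$replicate == replicate)
  if (length(i) != 1L)
    stop(sprintf("no sample for (condition=%s, replicate=%d)",
                 condition, replicate), call. = FALSE)
  i
}

#' Treated/control fold change for one gene in one replicate
#'
#' Computes `(treated + pseudo_count) / (control + pseudo_count)`. When both
#' values (plus pseudo-count) are zero the fold is defined as 1; when only the
#' denominator is zero the fold is `+Inf`.
#'
#' @param table an [expression_table()].
#' @param gene gene identifier present in the table.
#' @param condition `"treat_low"` or `"treat_high"`.
#' @param replicate replicate number; both the treated and the matching
#'   control sample must exist.
#' @param config a [filter_config()].
#' @return a single numeric fold change.
#' @export
fold_change <- function(table, gene, condition, replicate,
                        config = filter_config()) {
  stopifnot(inherits(table, "expression_table"))
  if (!gene %in% table$genes) stop(sprintf("gene '%s' not in table", gene))
  tr <- table$intensity[gene, .sample_col(table, condition, replicate)]
  ct <- table$intensity[gene, .sample_col(table, "control", replicate)]
  .ratio(tr, ct, config$pseudo_count)
}

.ratio <- function(treated, control, pseudo) {
  num <- treated + pseudo
  den <- control + pseudo
  out <- num / den
  out[den == 0 & num > 0] <- Inf
  out[den == 0 & num == 0] <- 1
  out
}

#' Call up-regulated genes in one treatment condition
#'
#' A replicate "passes" for a gene when the treated/control fold change is at
#' least `fold_threshold` and the intensity rule holds (by default: treated
#' intensity strictly above `intensity_threshold`). A gene is `concordant`
#' when every replicate of the condition passes -- the "found in both
#' replications" rule of the two-replicate design.
#'
#' @param table an [expression_table()].
#' @param condition `"treat_low"` or `"treat_high"` (calling against
#'   `"control"` itself is an error).
#' @param config a [filter_config()].
#' @param all_genes if `TRUE` return one row per gene; default `FALSE`
#'   returns only genes passing in at least one replicate.
#' @return a data.frame with columns `gene_id`, `condition`,
#'   `fold_rep<i>` and `treated_intensity_rep<i>` for each replicate,
#'   `n_passed`, and logical `concordant`, sorted by `gene_id`.
#' @export
call_upregulated <- function(table, condition, config = filter_config(),
                             all_genes = FALSE) {
  stopifnot(inherits(table, "expression_table"))
  if (identical(condition, "control"))
    stop("cannot call up-regulation for the control condition")
  if (!condition %in% .CONDITIONS) stop("unknown condition: ", condition)
  reps <- sort(intersect(
    table$samples$replicate[table$samples$condition == condition],
    table$samples$replicate[table$samples$condition == "control"]))
  if (length(reps) == 0L)
    stop("no replicate has both control and ", condition, " samples")

  folds <- ints <- matrix(NA_real_, length(table$genes), length(reps))
  pass <- matrix(FALSE, length(table$genes), length(reps))
  for (k in seq_along(reps)) {
    tr <- table$intensity[, .sample_col(table, condition, reps[k])]
    ct <- table$intensity[, .sample_col(table, "control", reps[k])]
    folds[, k] <- .ratio(tr, ct, config$pseudo_count)
    ints[, k] <- tr
    int_ok <- switch(config$intensity_on,
      treated = tr > config$intensity_threshold,
      control = ct > config$intensity_threshold,
      both    = tr > config$intensity_threshold & ct > config$intensity_threshold)
    pass[, k] <- folds[, k] >= config$fold_threshold & int_ok
  }
  n_passed <- rowSums(pass)
  out <- data.frame(gene_id = table$genes, condition = condition,
                    stringsAsFactors = FALSE)
  for (k in seq_along(reps)) {
    out[[sprintf("fold_rep%d", reps[k])]] <- folds[, k]
    out[[sprintf("treated_intensity_rep%d", reps[k])]] <- ints[, k]
  }
  out$n_passed <- as.integer(n_passed)
  out$concordant <- n_passed == length(reps)
  if (!all_genes) out <- out[out$n_passed > 0L, , drop = FALSE]
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine per-condition up-regulation calls
#'
#' Collects, for every gene concordant in at least one condition, the set of
#' conditions in which it is concordant. The pipeline's default candidate set
#' is the union of conditions.
#'
#' @param ... one or more call data.frames from [call_upregulated()].
#' @return a named list mapping gene id to a sorted character vector of
#'   conditions, alphabetical by gene id.
#' @export
combine_conditions <- function(...) {
  calls <- list(...)
  out <- list()
  for (cl in calls) {
    if (is.null(cl) || nrow(cl) == 0L) next
    hit <- cl[cl$concordant, , drop = FALSE]
    for (i in seq_len(nrow(hit))) {
      g <- hit$gene_id[i]
      out[[g]] <- sort(unique(c(out[[g]], hit$condition[i])))
    }
  }
  if (length(out) == 0L) return(setNames(list(), character(0)))
  out[order(names(out))]
}
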