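#' Difference of Ct values
#'
#' `delta Ct = Ct(target) - Ct(reference)`, the within-sample normalization
#' against the housekeeping gene.
#'
#' @param ct_target,ct_reference finite numeric cycle-threshold values.
#' @return `ct_target - ct_reference`.
#' @export
delta_ct <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("Ct values must be finite")
  ct_target - ct_reference
}

#' Read a Ct table from TSV
#'
#' Expected columns: `sample_id`, `group`, `target_gene`, `reference_gene`,
#' `ct_target`, `ct_reference`; one row per technical replicate is allowed.
#'
#' @param path TSV path.
#' @return a data.frame.
#' @export
read_ct_table <- function(path) {
  ct <- read_tsv(path)
  need <- c("sample_id", "group", "target_gene", "reference_gene",
            "ct_target", "ct_reference")
  if (!all(need %in% names(ct)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  ct
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates of one biological sample are averaged on the Ct
#' scale; per sample, `dCt = mean Ct(target) - mean Ct(reference)`. The
#' calibrator is the median sample: `ddCt_i = dCt_i - median(dCt)` and
#' `rel_expr_i = 2^(-ddCt_i)`, so the median relative expression over all
#' samples is 1 (exactly, for an odd number of samples; median of the log2
#' values is 0 for even counts, midpoint convention).
#'
#' @param table data.frame as from [read_ct_table()]. A single target gene
#'   and a single reference gene are required.
#' @return data.frame with one row per sample: `sample_id`, `group`,
#'   `delta_ct`, `rel_expr`, in first-appearance order of samples.
#' @export
relative_expression <- function(table) {
  if (nrow(table) == 0L) stop("empty Ct table")
  if (length(unique(table$target_gene)) != 1L)
    stop("mixed target genes; run one analysis per target")
  if (length(unique(table$reference_gene)) != 1L)
    stop("reference gene must be identical within one analysis")
  if (any(!is.finite(table$ct_target)) || any(!is.finite(table$ct_reference)))
    stop("Ct values must be finite")
  if (any(table$ct_target <= 0 | table$ct_target > 45) ||
      any(table$ct_reference <= 0 | table$ct_reference > 45))
    stop("Ct values must lie in (0, 45]")
  sid <- unique(table$sample_id)
  dct <- vapply(sid, function(s) {
    rows <- table$sample_id == s
    mean(table$ct_target[rows]) - mean(table$ct_reference[rows])
  }, numeric(1))
  grp <- table$group[match(sid, table$sample_id)]
  ddct <- dct - median(dct)
  data.frame(sample_id = sid, group = grp, delta_ct = unname(dct),
             rel_expr = 2^(-ddct), stringsAsFactors = FALSE, row.names = NULL)
}

#' Group means and standard deviations of relative expression
#'
#' @param fold data.frame from [relative_expression()].
#' @return data.frame with `group`, `n`, `mean_rel_expr`, `sd_rel_expr`.
#' @export
fold_summary <- function(fold) {
  sp <- split(fold$rel_expr, fold$group)
  data.frame(group = names(sp),
             n = vapply(sp, length, integer(1)),
             mean_rel_expr = vapply(sp, mean, numeric(1)),
             sd_rel_expr = vapply(sp, stats::sd, numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}
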