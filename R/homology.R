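#' Scoring parameters for the homology search
#'
#' Substitution matrix, affine gap penalties and Karlin-Altschul statistical
#' parameters. Defaults are the standard gapped BLOSUM62 / gap 11,1 values
#' (`lambda = 0.267`, `K = 0.041`). A gap of length g costs
#' `gap_open + g * gap_extend`. Hits with E-value below `report_evalue_max`
#' (default 10, the conventional reporting threshold) are kept; hits at or
#' below `convincing_evalue_max` (default 0.01) are classed `convincing`,
#' the rest `weak`.
#'
#' @param matrix substitution matrix name (a Biostrings data matrix, default
#'   `"BLOSUM62"`) or an integer matrix with residue dimnames.
#' @param gap_open,gap_extend positive integers, default 11 and 1.
#' @param lambda,K Karlin-Altschul parameters, > 0.
#' @param report_evalue_max,convincing_evalue_max E-value thresholds;
#'   `convincing_evalue_max < report_evalue_max`.
#' @return an object of class `"scoring_params"` with the resolved matrix
#'   attached.
#' @export
scoring_params <- function(matrix = "BLOSUM62", gap_open = 11L,
                           gap_extend = 1L, lambda = 0.267, K = 0.041,
                           report_evalue_max = 10, convincing_evalue_max = 0.01) {
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    mat <- get(matrix, envir = e)
  } else mat <- matrix
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (is.null(rownames(mat))) stop("substitution matrix needs residue dimnames")
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be positive")
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  if (!(convincing_evalue_max < report_evalue_max))
    stop("convincing_evalue_max must be below report_evalue_max")
  structure(list(matrix = mat, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), lambda = lambda, K = K,
                 report_evalue_max = report_evalue_max,
                 convincing_evalue_max = convincing_evalue_max,
                 min_sub = min(mat)),
            class = "scoring_params")
}

# internal: residues to 0-based matrix indices; unknown letters -> -1 and
# score min(matrix) against everything
.aa_encode <- function(x, mat) {
  idx <- match(strsplit(toupper(x), "", fixed = TRUE)[[1L]], rownames(mat))
  idx[is.na(idx)] <- 0L
  as.integer(idx - 1L)
}

#' Optimal local alignment of two protein sequences
#'
#' Exact Smith-Waterman alignment under affine gap penalties, with one
#' optimal traceback (tie-break: diagonal, then gap in query, then gap in
#' subject). The score is 0, with empty spans, when no residue pair scores
#' positively.
#'
#' @param a,b non-empty amino-acid strings (query, subject).
#' @param params a [scoring_params()].
#' @return list with `raw_score`, `q_start`, `q_end`, `s_start`, `s_end`
#'   (0-based half-open spans), `align_len` and `pct_identity`.
#' @export
smith_waterman <- function(a, b, params = scoring_params()) {
  stopifnot(is.character(a), is.character(b))
  if (nchar(a) == 0L || nchar(b) == 0L) stop("sequences must be non-empty")
  r <- sw_align_c(.aa_encode(a, params$matrix), .aa_encode(b, params$matrix),
                  params$matrix, params$gap_open, params$gap_extend,
                  params$min_sub)
  list(raw_score = r$score,
       q_start = r$q_start, q_end = r$q_end,
       s_start = r$s_start, s_end = r$s_end,
       align_len = r$align_len,
       pct_identity = if (r$align_len > 0) 100 * r$matches / r$align_len else 0)
}

#' Smith-Waterman raw score only
#'
#' Linear-memory variant of [smith_waterman()] used when spans are not
#' needed (e.g. the all-pairs pass of [search_homology()]).
#'
#' @inheritParams smith_waterman
#' @return integer raw score.
#' @export
sw_score <- function(a, b, params = scoring_params()) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("sequences must be non-empty")
  sw_score_c(.aa_encode(a, params$matrix), .aa_encode(b, params$matrix),
             params$matrix, params$gap_open, params$gap_extend, params$min_sub)
}

#' Bit score from a raw alignment score
#'
#' `S' = (lambda * S - ln K) / ln 2`.
#'
#' @param raw_score raw alignment score(s), >= 0.
#' @param params a [scoring_params()].
#' @return numeric bit score(s).
#' @export
bit_score <- function(raw_score, params = scoring_params()) {
  (params$lambda * raw_score - log(params$K)) / log(2)
}

#' Karlin-Altschul E-value
#'
#' Expected number of chance local alignments scoring at least `raw_score`
#' for a query of length `m` against a database of total length `n`:
#' `E = K * m * n * exp(-lambda * S)`. No effective-length edge correction
#' is applied (raw `m` and `n` are used).
#'
#' @param raw_score raw alignment score(s).
#' @param m query length, > 0.
#' @param n database total length, > 0.
#' @param params a [scoring_params()].
#' @return numeric E-value(s).
#' @export
e_value <- function(raw_score, m, n, params = scoring_params()) {
  if (any(m <= 0) || any(n <= 0)) stop("m and n must be positive")
  params$K * m * n * exp(-params$lambda * raw_score)
}

#' Read a protein database from FASTA
#'
#' @param path FASTA of subject proteins (e.g. a user-supplied set of
#'   retro-transcribing virus proteins).
#' @return an object of class `"protein_db"`: data.frame with `subject_id`,
#'   `description`, `aa_seq`, plus attribute `total_length`.
#' @export
read_protein_db <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  protein_db(subject_id = sub("\\s.*$", "", names(aa)),
             aa_seq = as.character(aa),
             description = sub("^\\S+\\s*", "", names(aa)))
}

#' Construct a protein database from vectors
#'
#' @param subject_id,aa_seq,description parallel character vectors;
#'   `description` defaults to empty strings.
#' @return see [read_protein_db()].
#' @export
protein_db <- function(subject_id, aa_seq, description = "") {
  if (length(subject_id) == 0L) stop("protein database must be non-empty")
  df <- data.frame(subject_id = as.character(subject_id),
                   description = rep_len(as.character(description),
                                         length(subject_id)),
                   aa_seq = toupper(as.character(aa_seq)),
                   stringsAsFactors = FALSE)
  if (any(nchar(df$aa_seq) == 0L)) stop("empty subject sequence")
  structure(df, total_length = sum(nchar(df$aa_seq)), class = c("protein_db",
                                                                "data.frame"))
}

#' Search translated ORFs against a protein database
#'
#' Scores every (query, subject) pair with exact Smith-Waterman alignment,
#' converts raw scores to Karlin-Altschul E-values against the whole database
#' length, keeps per query the best hit per subject with
#' `evalue < report_evalue_max`, and classifies each kept hit as
#' `convincing` (`evalue <= convincing_evalue_max`) or `weak`.
#'
#' @param orfs data.frame from [find_orfs()], or any data.frame with
#'   `orf_id` and `aa_seq` columns (an `AAStringSet` is also accepted).
#' @param db a [protein_db()].
#' @param params a [scoring_params()].
#' @return data.frame of hits sorted by (`query_id`, `evalue`, `subject_id`):
#'   `query_id`, `subject_id`, `raw_score`, `bit_score`, `evalue`,
#'   `pct_identity`, `align_len`, `q_start`, `q_end`, `s_start`, `s_end`
#'   (0-based half-open), `tier`.
#' @export
search_homology <- function(orfs, db, params = scoring_params()) {
  if (methods::is(orfs, "AAStringSet"))
    orfs <- data.frame(orf_id = names(orfs), aa_seq = as.character(orfs),
                       stringsAsFactors = FALSE)
  stopifnot(inherits(db, "protein_db"))
  if (nrow(orfs) == 0L) stop("no query ORFs")
  n_db <- attr(db, "total_length")
  hits <- vector("list", nrow(orfs) * nrow(db))
  h <- 0L
  for (q in seq_len(nrow(orfs))) {
    qa <- orfs$aa_seq[q]
    m <- nchar(qa)
    for (s in seq_len(nrow(db))) {
      sc <- sw_score(qa, db$aa_seq[s], params)
      if (sc <= 0L) next
      ev <- e_value(sc, m, n_db, params)
      if (!(ev < params$report_evalue_max)) next
      al <- smith_waterman(qa, db$aa_seq[s], params)
      h <- h + 1L
      hits[[h]] <- data.frame(
        query_id = orfs$orf_id[q], subject_id = db$subject_id[s],
        raw_score = sc, bit_score = bit_score(sc, params), evalue = ev,
        pct_identity = al$pct_identity, align_len = al$align_len,
        q_start = al$q_start, q_end = al$q_end,
        s_start = al$s_start, s_end = al$s_end,
        tier = if (ev <= params$convincing_evalue_max) "convincing" else "weak",
        stringsAsFactors = FALSE)
    }
  }
  if (h == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      raw_score = integer(), bit_score = numeric(),
                      evalue = numeric(), pct_identity = numeric(),
                      align_len = integer(), q_start = integer(),
                      q_end = integer(), s_start = integer(),
                      s_end = integer(), tier = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits[seq_len(h)])
  out <- out[order(out$query_id, out$evalue, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write hits in a BLAST outfmt-6-style TSV
#'
#' Columns qseqid, sseqid, pident, length, qstart, qend, sstart, send,
#' evalue, bitscore, tier; coordinates 1-based inclusive as in outfmt 6.
#'
#' @param hits data.frame from [search_homology()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- data.frame(qseqid = hits$query_id, sseqid = hits$subject_id,
                    pident = round(hits$pct_identity, 3),
                    length = hits$align_len,
                    qstart = hits$q_start + 1L, qend = hits$q_end,
                    sstart = hits$s_start + 1L, send = hits$s_end,
                    evalue = signif(hits$evalue, 6),
                    bitscore = round(hits$bit_score, 1),
                    tier = hits$tier, stringsAsFactors = FALSE)
  write_tsv(out, path)
}
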