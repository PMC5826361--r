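#' ORF scanner configuration
#'
#' @param min_len_nt minimum ORF length in nucleotides (>= 3). Default 1000,
#'   the 1 kb screening threshold.
#' @param mode `"between_stops"` (default): maximal stop-free codon runs;
#'   `"start_to_stop"`: from the first ATG inside such a run to its closing
#'   stop.
#' @param include_partial_at_ends include runs truncated by the sequence
#'   ends. Default `TRUE`.
#' @param min_len_op `"ge"` (default, length >= min) or `"gt"` (strictly >).
#' @return an object of class `"orf_config"`.
#' @export
orf_config <- function(min_len_nt = 1000L,
                       mode = c("between_stops", "start_to_stop"),
                       include_partial_at_ends = TRUE,
                       min_len_op = c("ge", "gt")) {
  if (min_len_nt < 3) stop("min_len_nt must be >= 3")
  structure(list(min_len_nt = as.integer(min_len_nt), mode = match.arg(mode),
                 include_partial_at_ends = isTRUE(include_partial_at_ends),
                 min_len_op = match.arg(min_len_op)),
            class = "orf_config")
}

#' Reverse complement of a nucleotide string
#'
#' @param seq character string over A/C/G/T/N (uppercase).
#' @return the reverse complement, same alphabet.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (grepl("[^ACGTN]", seq)) stop("sequence contains characters outside ACGTN")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate a nucleotide string under the standard genetic code
#'
#' Codons containing N translate to `X`; stop codons appear as `*` in the
#' raw output (ORF records produced by [find_orfs()] never contain one).
#'
#' @param nt nucleotide string, length divisible by 3.
#' @return amino-acid string of length `nchar(nt)/3`.
#' @export
translate_nt <- function(nt) {
  stopifnot(is.character(nt), length(nt) == 1L)
  if (nchar(nt) %% 3 != 0) stop("length not divisible by 3")
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                     if.fuzzy.codon = "X"))
}

# Stop codons of the standard code as base-4 codon codes (A=0,C=1,G=2,T=3):
# TAA = 48, TAG = 50, TGA = 56. N gives NA; NA codons never terminate an ORF.
.STOP_CODES <- c(48L, 50L, 56L)
.ATG_CODE <- 14L

.BASE_CODE <- local({
  v <- rep(NA_integer_, 256L)
  v[utf8ToInt("A")] <- 0L; v[utf8ToInt("C")] <- 1L
  v[utf8ToInt("G")] <- 2L; v[utf8ToInt("T")] <- 3L
  v
})

# internal: per-frame stop-free runs on one strand-oriented sequence.
# Returns data.frame(frame, rel_start, rel_end) in that sequence's
# coordinates, coding region only (flanking stops excluded).
.scan_frames <- function(seq, config) {
  L <- nchar(seq)
  if (L < 3L) return(data.frame(frame = integer(), rel_start = integer(),
                                rel_end = integer()))
  code <- .BASE_CODE[utf8ToInt(seq)]
  # codon code starting at 0-based position p (p = 0 .. L-3)
  cid <- 16L * code[1:(L - 2L)] + 4L * code[2:(L - 1L)] + code[3:L]
  is_stop <- !is.na(cid) & cid %in% .STOP_CODES
  res <- vector("list", 3L)
  keep_len <- if (config$min_len_op == "ge") {
    function(nt) nt >= config$min_len_nt
  } else function(nt) nt > config$min_len_nt
  for (f in 0:2) {
    if (f + 3L > L) next
    pos <- seq.int(f + 1L, L - 2L, by = 3L)        # 1-based codon starts
    stop_idx <- which(is_stop[pos])                # codon indices in frame
    nc <- length(pos)
    b <- c(0L, stop_idx, nc + 1L)
    lo <- b[-length(b)] + 1L                       # codon index range per run
    hi <- b[-1L] - 1L
    valid <- hi >= lo
    left_open <- b[-length(b)] == 0L               # truncated at sequence start
    right_open <- b[-1L] == nc + 1L                # truncated at sequence end
    if (config$mode == "between_stops") {
      if (!config$include_partial_at_ends)
        valid <- valid & !left_open & !right_open
    } else {
      # ATG anchors the start, so only a missing closing stop is "partial"
      if (!config$include_partial_at_ends) valid <- valid & !right_open
      atg_idx <- which(!is.na(cid[pos]) & cid[pos] == .ATG_CODE)
      k <- findInterval(lo - 0.5, atg_idx) + 1L    # first ATG at or after lo
      has <- k <= length(atg_idx)
      first_atg <- rep(NA_integer_, length(lo))
      first_atg[has] <- atg_idx[k[has]]
      valid <- valid & has & !is.na(first_atg) & first_atg <= hi
      lo[valid] <- first_atg[valid]
    }
    nt_len <- 3L * (hi - lo + 1L)
    valid <- valid & keep_len(nt_len)
    lo <- lo[valid]; nt_len <- nt_len[valid]
    res[[f + 1L]] <- if (length(lo))
      data.frame(frame = f, rel_start = pos[lo] - 1L,
                 rel_end = pos[lo] - 1L + nt_len) else NULL
  }
  out <- do.call(rbind, res)
  if (is.null(out)) data.frame(frame = integer(), rel_start = integer(),
                               rel_end = integer()) else out
}

#' Enumerate ORFs on both strands of a window sequence
#'
#' Scans all six reading frames for maximal runs of codons free of the stop
#' codons TAA/TAG/TGA (codons containing N never terminate a run) and reports
#' runs meeting the length threshold, with their translation. Minus-strand
#' ORFs are reported in forward window coordinates with `strand = "-"`;
#' `frame` is the frame on the scanned strand.
#'
#' @param seq a sequence record from [extract_sequence()], or a plain
#'   character string.
#' @param config an [orf_config()].
#' @param window_id window identifier (defaults to the record id).
#' @param abs_offset genome coordinate of window position 0; used to report
#'   absolute coordinates.
#' @return data.frame with columns `orf_id`, `window_id`, `rel_start`,
#'   `rel_end`, `abs_start`, `abs_end`, `strand`, `frame`, `nt_len`,
#'   `nt_seq`, `aa_seq`, sorted by (`rel_start`, `strand`, `frame`).
#' @export
find_orfs <- function(seq, config = orf_config(), window_id = NULL,
                      abs_offset = 0) {
  if (is.list(seq)) {
    if (is.null(window_id)) window_id <- seq$id
    seq <- seq$seq
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("empty sequence")
  if (grepl("[^ACGTN]", seq)) stop("sequence contains characters outside ACGTN")
  if (is.null(window_id)) window_id <- "window"
  L <- nchar(seq)

  fwd <- .scan_frames(seq, config)
  fwd$strand <- rep("+", nrow(fwd))
  rc <- reverse_complement(seq)
  rev <- .scan_frames(rc, config)
  rev$strand <- rep("-", nrow(rev))
  if (nrow(rev)) {
    # mirror reverse-scan coordinates onto the forward window axis
    rs <- L - rev$rel_end
    rev$rel_end <- L - rev$rel_start
    rev$rel_start <- rs
  }
  orfs <- rbind(fwd, rev)
  if (nrow(orfs) == 0L) {
    return(data.frame(orf_id = character(), window_id = character(),
                      rel_start = integer(), rel_end = integer(),
                      abs_start = numeric(), abs_end = numeric(),
                      strand = character(), frame = integer(),
                      nt_len = integer(), nt_seq = character(),
                      aa_seq = character(), stringsAsFactors = FALSE))
  }
  orfs <- orfs[order(orfs$rel_start, orfs$strand, orfs$frame), , drop = FALSE]
  nt <- character(nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    s <- substr(seq, orfs$rel_start[i] + 1L, orfs$rel_end[i])
    nt[i] <- if (orfs$strand[i] == "+") s else reverse_complement(s)
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                           if.fuzzy.codon = "X"))
  data.frame(orf_id = sprintf("%s|orf%03d", window_id, seq_len(nrow(orfs))),
             window_id = window_id,
             rel_start = orfs$rel_start, rel_end = orfs$rel_end,
             abs_start = abs_offset + orfs$rel_start,
             abs_end = abs_offset + orfs$rel_end,
             strand = orfs$strand, frame = orfs$frame,
             nt_len = orfs$rel_end - orfs$rel_start,
             nt_seq = nt, aa_seq = aa,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write ORF records as a TSV table and a protein FASTA
#'
#' @param orfs data.frame from [find_orfs()] (optionally with a `chrom`
#'   column).
#' @param tsv_path,fasta_path output paths (`NULL` to skip one of them).
#' @return invisibly, the paths written.
#' @export
write_orfs <- function(orfs, tsv_path = NULL, fasta_path = NULL) {
  if (!is.null(tsv_path)) {
    cols <- intersect(c("orf_id", "window_id", "chrom", "abs_start", "abs_end",
                        "strand", "frame", "nt_len"), names(orfs))
    write_tsv(orfs[, cols, drop = FALSE], tsv_path)
  }
  if (!is.null(fasta_path)) {
    aa <- Biostrings::AAStringSet(setNames(orfs$aa_seq, orfs$orf_id))
    Biostrings::writeXStringSet(aa, fasta_path)
  }
  invisible(c(tsv_path, fasta_path))
}
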