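#' Read gene loci from a GFF3 or BED annotation
#'
#' Imports gene features and returns one locus per gene id in 0-based
#' half-open coordinates. GFF3 input (1-based closed) is converted; BED is
#' passed through unchanged. When a gene id has several features the longest
#' wins; ties resolve to the first in file order.
#'
#' @param path annotation file (`.gff3`/`.gff` or `.bed`).
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @param attribute GFF3 attribute holding the gene id (default
#'   `"gene_name"`, falling back to `Name`, `gene_id`, `ID`).
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @export
read_gene_loci <- function(path, format = c("auto", "gff3", "bed"),
                           attribute = "gene_name") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  if (format == "gff3") {
    typ <- as.character(gr$type)
    if (any(typ == "gene")) gr <- gr[typ == "gene"]
    mc <- S4Vectors::mcols(gr)
    ids <- NULL
    for (key in unique(c(attribute, "Name", "gene_id", "ID"))) {
      if (key %in% names(mc) && !all(is.na(mc[[key]]))) {
        ids <- as.character(mc[[key]]); break
      }
    }
    if (is.null(ids)) stop("no usable gene-id attribute in ", path)
  } else {
    ids <- as.character(gr$name)
  }
  df <- data.frame(gene_id = ids,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,   # to 0-based
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  # longest feature per gene id, first in file order on ties
  len <- df$end - df$start
  keep <- order(df$gene_id, -len, seq_len(nrow(df)))
  df <- df[keep, , drop = FALSE]
  df <- df[!duplicated(df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build the genomic window around a gene locus
#'
#' Default mode flanks the gene body by `flank` on each side (the 2 Mbp
#' neighborhood is `flank = 1e6`), clamped to the chromosome; `"centered"`
#' instead places a window of `2 * flank` centered on the gene midpoint.
#'
#' @param locus one-row data.frame (or list) with `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open).
#' @param flank flank size in bp, >= 0. Default 1e6.
#' @param chrom_length chromosome length; must cover the locus.
#' @param mode `"flank"` (default) or `"centered"`.
#' @return one-row data.frame: `window_id`, `chrom`, `start`, `end`,
#'   `source_gene`, `flank`.
#' @export
make_window <- function(locus, flank = 1e6, chrom_length,
                        mode = c("flank", "centered")) {
  mode <- match.arg(mode)
  .check_number(flank, "flank"); .check_number(chrom_length, "chrom_length")
  s <- as.numeric(locus$start); e <- as.numeric(locus$end)
  if (flank < 0) stop("flank must be >= 0")
  if (!(s >= 0 && s < e)) stop("invalid locus interval")
  if (e > chrom_length)
    stop(sprintf("locus [%d,%d) outside chromosome of length %d",
                 s, e, chrom_length))
  if (mode == "flank") {
    ws <- max(0, s - flank); we <- min(chrom_length, e + flank)
  } else {
    mid <- floor((s + e) / 2)
    ws <- max(0, mid - flank); we <- min(chrom_length, mid + flank)
    ws <- min(ws, s); we <- max(we, e)   # window always contains the gene
  }
  data.frame(window_id = sprintf("%s:%d-%d(%s)", locus$chrom, ws, we,
                                 locus$gene_id),
             chrom = as.character(locus$chrom), start = ws, end = we,
             source_gene = as.character(locus$gene_id), flank = flank,
             stringsAsFactors = FALSE)
}

#' Windows for a set of candidate genes
#'
#' @param loci data.frame from [read_gene_loci()] (or equivalent).
#' @param genome a named `DNAStringSet` or a FASTA path; supplies chromosome
#'   lengths.
#' @inheritParams make_window
#' @return data.frame of windows, one row per locus, in input order.
#' @export
make_windows <- function(loci, genome, flank = 1e6,
                         mode = c("flank", "centered")) {
  mode <- match.arg(mode)
  genome <- .as_genome(genome)
  out <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    chrom <- loci$chrom[i]
    if (!chrom %in% names(genome))
      stop("chromosome not in genome: ", chrom)
    out[[i]] <- make_window(loci[i, ], flank = flank,
                            chrom_length = length(genome[[chrom]]),
                            mode = mode)
  }
  do.call(rbind, out)
}

# internal: accept a DNAStringSet or a FASTA path; names truncated at first
# whitespace as in common FASTA usage
.as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L)
    genome <- Biostrings::readDNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a DNAStringSet or FASTA path")
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Extract the sequence of a genomic window
#'
#' Returns the uppercase window subsequence (soft-masked lowercase input is
#' uppercased); the record id encodes `chrom:start-end(gene)`.
#'
#' @param genome a named `DNAStringSet` or FASTA path.
#' @param window one-row data.frame from [make_window()].
#' @return list with elements `id` and `seq` (plain uppercase character
#'   string over A/C/G/T/N).
#' @export
extract_sequence <- function(genome, window) {
  genome <- .as_genome(genome)
  chrom <- window$chrom
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  s <- as.numeric(window$start); e <- as.numeric(window$end)
  L <- length(genome[[chrom]])
  if (!(s >= 0 && s < e && e <= L))
    stop(sprintf("window [%s,%s) out of bounds for %s (length %d)",
                 format(s, scientific = FALSE), format(e, scientific = FALSE),
                 chrom, L))
  seq <- toupper(as.character(Biostrings::subseq(genome[[chrom]], s + 1, e)))
  if (grepl("[^ACGTN]", seq)) stop("window sequence contains non-ACGTN characters")
  list(id = window$window_id, seq = seq)
}

#' Write windows as a 6-column BED file
#'
#' @param windows data.frame from [make_windows()].
#' @param path output path.
#' @param strand optional strand vector (defaults to `+`).
#' @return the path, invisibly.
#' @export
write_windows_bed <- function(windows, path, strand = NULL) {
  if (is.null(strand)) strand <- rep("+", nrow(windows))
  bed <- data.frame(windows$chrom,
                    format(windows$start, scientific = FALSE, trim = TRUE),
                    format(windows$end, scientific = FALSE, trim = TRUE),
                    windows$window_id, rep(0L, nrow(windows)), strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
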