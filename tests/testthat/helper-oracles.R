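# Independent oracles used by the property tests. These deliberately share no
# code with the package: the alignment oracle enumerates gap lengths
# exhaustively instead of using the Gotoh recurrences; the ORF oracle
# tokenizes codon strings with rle(); the translation oracle carries its own
# hard-coded codon table.

# exhaustive affine-gap local alignment score: gap of length g costs
# open + g * ext; for each cell every gap length is enumerated
oracle_sw_score <- function(a, b, mat, gap_open = 11, gap_ext = 1) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  ia <- match(A, rownames(mat))
  ib <- match(B, rownames(mat))
  lowest <- min(mat)
  m <- length(A); n <- length(B)
  H <- matrix(0, m + 1, n + 1)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- if (is.na(ia[i]) || is.na(ib[j])) lowest else mat[ia[i], ib[j]]
      best <- max(0, H[i, j] + s)
      for (g in seq_len(j)) {
        cand <- H[i + 1, j + 1 - g] - gap_open - g * gap_ext
        if (cand > best) best <- cand
      }
      for (g in seq_len(i)) {
        cand <- H[i + 1 - g, j + 1] - gap_open - g * gap_ext
        if (cand > best) best <- cand
      }
      H[i + 1, j + 1] <- best
    }
  }
  max(H)
}

oracle_rc <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# hard-coded standard genetic code; codons containing N -> X
ORACLE_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(nt) {
  chars <- strsplit(nt, "", fixed = TRUE)[[1]]
  starts <- seq(1, length(chars), by = 3)
  aa <- vapply(starts, function(p) {
    cod <- paste(chars[p:(p + 2)], collapse = "")
    if (grepl("N", cod, fixed = TRUE)) "X"
    else unname(ORACLE_CODE[cod])
  }, character(1))
  paste(aa, collapse = "")
}

# rle-based stop-codon tokenizer over all six frames
oracle_find_orfs <- function(seq, min_len, mode = "between_stops",
                             include_partial = TRUE, op = "ge") {
  scan1 <- function(s, strand) {
    L <- nchar(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    out <- list()
    for (f in 0:2) {
      if (f + 3 > L) next
      starts <- seq(f + 1, L - 2, by = 3)
      codons <- vapply(starts, function(p)
        paste(chars[p:(p + 2)], collapse = ""), character(1))
      r <- rle(codons %in% c("TAA", "TAG", "TGA"))
      hi_all <- cumsum(r$lengths)
      lo_all <- hi_all - r$lengths + 1L
      for (k in seq_along(r$values)) {
        if (r$values[k]) next
        lo <- lo_all[k]; hi <- hi_all[k]
        left_open <- lo == 1L
        right_open <- hi == length(codons)
        if (mode == "between_stops") {
          if (!include_partial && (left_open || right_open)) next
        } else {
          if (!include_partial && right_open) next
          atg <- which(codons[lo:hi] == "ATG")
          if (length(atg) == 0L) next
          lo <- lo + atg[1L] - 1L
        }
        len <- 3L * (hi - lo + 1L)
        keep <- if (op == "ge") len >= min_len else len > min_len
        if (!keep) next
        a <- starts[lo] - 1L
        out[[length(out) + 1L]] <-
          data.frame(rel_start = a, rel_end = a + len, strand = strand,
                     frame = f)
      }
    }
    out
  }
  L <- nchar(seq)
  fwd <- scan1(seq, "+")
  rev <- scan1(oracle_rc(seq), "-")
  rev <- lapply(rev, function(d) {
    new_start <- L - d$rel_end
    d$rel_end <- L - d$rel_start
    d$rel_start <- new_start
    d
  })
  all <- c(fwd, rev)
  if (length(all) == 0L)
    return(data.frame(rel_start = integer(), rel_end = integer(),
                      strand = character(), frame = integer()))
  d <- do.call(rbind, all)
  d <- d[order(d$rel_start, d$strand, d$frame), , drop = FALSE]
  rownames(d) <- NULL
  d
}

rand_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

rand_prot <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# small expression table built by hand: 2 replicates x 3 conditions
tiny_expression <- function(mat) {
  samples <- data.frame(
    sample_id = c("c1", "c2", "l1", "l2", "h1", "h2"),
    condition = c("control", "control", "treat_low", "treat_low",
                  "treat_high", "treat_high"),
    replicate = c(1L, 2L, 1L, 2L, 1L, 2L))
  expression_table(mat, samples)
}
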