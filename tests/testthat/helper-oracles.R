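# Independent oracles and small fixture builders used across the suite.

# Brute-force affine-gap Smith-Waterman score: full-matrix dynamic
# programming in plain R, kept independent of the package's compiled kernel.
sw_oracle_score <- function(a, b, scheme = scoring_scheme()) {
  S <- scheme$matrix
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  oc <- scheme$gap_open + scheme$gap_extend; ge <- scheme$gap_extend
  M <- matrix(-Inf, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in seq_len(n) + 1) for (j in seq_len(m) + 1) {
    Ix[i, j] <- max(M[i - 1, j] - oc, Ix[i - 1, j] - ge)
    Iy[i, j] <- max(M[i, j - 1] - oc, Iy[i, j - 1] - ge)
    M[i, j] <- max(0, max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) +
                     S[A[i - 1], B[j - 1]])
    if (M[i, j] > best) best <- M[i, j]
  }
  best
}

# Naive sliding-window motif scan: substring comparison at every offset.
motif_oracle <- function(seq, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  res <- strsplit(seq, "")[[1]]
  k <- length(pat)
  hits <- integer(0)
  if (length(res) < k) return(hits)
  for (start in seq_len(length(res) - k + 1)) {
    win <- res[start:(start + k - 1)]
    if (all(pat == "x" | pat == win)) hits <- c(hits, start)
  }
  hits
}

AA <- c("A","R","N","D","C","Q","E","G","H","I",
        "L","K","M","F","P","S","T","W","Y","V")

rand_protein <- function(len) paste(sample(AA, len, replace = TRUE), collapse = "")

# A tiny genome built directly from a protein/label table, one gene per
# 3*len bp with 100 bp spacers on a single contig.
toy_genome <- function(id, proteins, labels = NULL, strands = NULL,
                       spacer = 100L) {
  n <- length(proteins)
  if (is.null(labels)) labels <- replicate(n, character(0), simplify = FALSE)
  if (is.null(strands)) strands <- rep("+", n)
  pos <- spacer + 1L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cds <- 3L * nchar(proteins[i])
    rows[[i]] <- data.frame(gene_id = sprintf("%s_g%02d", id, i),
                            contig_id = paste0(id, "_c1"),
                            start = pos, end = pos + cds - 1L, strand = strands[i],
                            protein = proteins[i], stringsAsFactors = FALSE)
    pos <- pos + cds + spacer
  }
  genes <- do.call(rbind, rows)
  genes$families <- labels
  contig <- setNames(paste(sample(c("A","C","G","T"), pos - 1L, replace = TRUE),
                           collapse = ""), paste0(id, "_c1"))
  genome_record(id, contig, genes)
}
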