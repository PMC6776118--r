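#' Scoring scheme for local protein alignment
#'
#' Bundles the substitution matrix, affine gap costs, Karlin-Altschul
#' parameters and the E-value cutoff used by the alignment and orthology
#' functions. Defaults are the de facto BLASTP defaults: BLOSUM62,
#' gap open 11 / extend 1 (a gap of length L costs `11 + L`), gapped
#' Karlin-Altschul constants lambda = 0.267 and K = 0.041, and an E-value
#' threshold of 1e-5. The ambiguity residue `X` scores 0 against everything.
#'
#' @param matrix_name substitution matrix name (one shipped with Biostrings).
#' @param gap_open,gap_extend positive gap costs.
#' @param lambda,K Karlin-Altschul parameters (> 0).
#' @param e_value_threshold hits with E-value >= this are discarded by
#'   [top_hit()].
#' @return object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix_name = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041, e_value_threshold = 1e-5) {
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, K > 0)
  e <- new.env()
  utils::data(list = matrix_name, package = "Biostrings", envir = e)
  S <- get(matrix_name, envir = e)
  storage.mode(S) <- "integer"
  if ("X" %in% rownames(S)) { S["X", ] <- 0L; S[, "X"] <- 0L }
  structure(list(matrix_name = matrix_name, matrix = S,
                 alphabet = rownames(S),
                 gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K, e_value_threshold = e_value_threshold),
            class = "scoring_scheme")
}

# Encode amino-acid strings as 0-based indices into the scheme matrix.
encode_proteins <- function(seqs, scheme) {
  lut <- setNames(seq_along(scheme$alphabet) - 1L, scheme$alphabet)
  lapply(strsplit(toupper(seqs), ""), function(ch) {
    codes <- lut[ch]
    if (anyNA(codes)) stop("unknown residue(s): ",
                           paste(unique(ch[is.na(codes)]), collapse = ", "))
    unname(codes)
  })
}

bit_score <- function(raw, scheme) (scheme$lambda * raw - log(scheme$K)) / log(2)
e_value <- function(raw, m, n, scheme) m * n * 2^(-bit_score(raw, scheme))

#' Optimal local alignment of two protein sequences
#'
#' Exact Smith-Waterman with affine gaps under the given [scoring_scheme()],
#' with bit score and E-value from the Karlin-Altschul formula
#' `bit = (lambda * raw - ln K) / ln 2`, `E = m * n * 2^-bit` where `m`, `n`
#' are the sequence lengths.
#'
#' @param a,b non-empty amino-acid strings (20-letter alphabet plus `X`).
#' @param scheme a [scoring_scheme()].
#' @param query_id,subject_id optional ids carried into the result.
#' @return list of class `alignment_hit`: `query_id`, `subject_id`,
#'   `raw_score`, `bit_score`, `e_value`, `percent_identity` (over aligned
#'   columns, gaps included), `aligned_length`, `query_cover`,
#'   `subject_cover`.
#' @export
align_pair <- function(a, b, scheme = scoring_scheme(),
                       query_id = NA_character_, subject_id = NA_character_) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  enc <- encode_proteins(c(a, b), scheme)
  r <- .sw_align_cpp(enc[[1]], enc[[2]], scheme$matrix,
                     scheme$gap_open, scheme$gap_extend)
  m <- nchar(a); n <- nchar(b)
  structure(list(
    query_id = query_id, subject_id = subject_id,
    raw_score = r$score,
    bit_score = bit_score(r$score, scheme),
    e_value = e_value(r$score, m, n, scheme),
    percent_identity = if (r$aligned_length > 0) 100 * r$identical / r$aligned_length else 0,
    aligned_length = r$aligned_length,
    query_cover = if (r$aend > 0) (r$aend - r$astart + 1) / m else 0,
    subject_cover = if (r$bend > 0) (r$bend - r$bstart + 1) / n else 0,
    query_span = c(r$astart, r$aend), subject_span = c(r$bstart, r$bend)),
    class = "alignment_hit")
}

# Optimal local-alignment raw-score matrix for two encoded proteomes.
proteome_score_matrix <- function(enc_a, enc_b, scheme) {
  .sw_score_matrix_cpp(enc_a, enc_b, scheme$matrix, scheme$gap_open, scheme$gap_extend)
}

# Index of the top-scoring subject for each query row of a score matrix.
# Ties broken by higher score then lexicographically smaller subject id.
top_index <- function(score_row, subject_ids) {
  best <- max(score_row)
  cand <- which(score_row == best)
  cand[order(subject_ids[cand])][1]
}

#' Top-scoring database hit for a query protein
#'
#' Aligns the query against every protein of `db` and returns the
#' highest-bit-score hit whose E-value is below the scheme threshold, or
#' `NULL` if no hit qualifies. Ties are broken by the lexicographically
#' smaller subject id.
#'
#' @param query amino-acid string, or a single row of a genome's gene table.
#' @param db a [genome_record()] with at least one protein.
#' @param scheme a [scoring_scheme()].
#' @param query_id id carried into the result.
#' @return an `alignment_hit` or `NULL`.
#' @export
top_hit <- function(query, db, scheme = scoring_scheme(), query_id = NA_character_) {
  if (is.data.frame(query)) { query_id <- query$gene_id[1]; query <- query$protein[1] }
  if (nrow(db$genes) == 0L) return(NULL)
  enc_q <- encode_proteins(query, scheme)
  enc_db <- encode_proteins(db$genes$protein, scheme)
  scores <- proteome_score_matrix(enc_q, enc_db, scheme)
  j <- top_index(scores[1, ], db$genes$gene_id)
  hit <- align_pair(query, db$genes$protein[j], scheme,
                    query_id = query_id, subject_id = db$genes$gene_id[j])
  if (hit$e_value < scheme$e_value_threshold) hit else NULL
}

#' Reciprocal best-hit orthologs between two genomes
#'
#' A pair `(a, b)` is an ortholog pair iff `b` is the top qualifying hit of
#' `a` in genome B and `a` is the top qualifying hit of `b` in genome A
#' (bidirectional top-scoring hits, E-value below the scheme threshold).
#'
#' @param ga,gb [genome_record()]s with at least one protein each.
#' @param scheme a [scoring_scheme()].
#' @return data frame with columns `gene_a`, `gene_b`, `percent_identity`.
#' @export
reciprocal_orthologs <- function(ga, gb, scheme = scoring_scheme()) {
  stopifnot(nrow(ga$genes) > 0, nrow(gb$genes) > 0)
  t0 <- proc.time()[3]
  enc_a <- encode_proteins(ga$genes$protein, scheme)
  enc_b <- encode_proteins(gb$genes$protein, scheme)
  scores <- proteome_score_matrix(enc_a, enc_b, scheme)
  la <- nchar(ga$genes$protein); lb <- nchar(gb$genes$protein)
  ids_a <- ga$genes$gene_id; ids_b <- gb$genes$gene_id
  na <- length(ids_a); nb <- length(ids_b)
  best_ab <- vapply(seq_len(na), function(i) top_index(scores[i, ], ids_b), 1L)
  best_ba <- vapply(seq_len(nb), function(j) top_index(scores[, j], ids_a), 1L)
  keep <- which(best_ba[best_ab] == seq_len(na))
  if (length(keep)) {
    j <- best_ab[keep]
    ev <- e_value(scores[cbind(keep, j)], la[keep], lb[j], scheme)
    ok <- ev < scheme$e_value_threshold
    keep <- keep[ok]; j <- j[ok]
    # identity over aligned columns needs a traceback: only for accepted pairs
    pid <- vapply(seq_along(keep), function(k) {
      r <- .sw_align_cpp(enc_a[[keep[k]]], enc_b[[j[k]]], scheme$matrix,
                         scheme$gap_open, scheme$gap_extend)
      if (r$aligned_length > 0) 100 * r$identical / r$aligned_length else 0
    }, 1)
  } else {
    j <- integer(0); pid <- numeric(0)
  }
  log_stage("reciprocal_orthologs", genomes = c(ga$genome_id, gb$genome_id),
            n_pairs = length(keep), elapsed = proc.time()[3] - t0)
  data.frame(gene_a = ids_a[keep], gene_b = ids_b[j],
             percent_identity = pid, stringsAsFactors = FALSE)
}

#' Average amino acid identity of two genomes
#'
#' AAI is the unweighted arithmetic mean of the percent identities of the
#' reciprocal best-hit ortholog pairs. With fewer than `min_orthologs` pairs
#' the estimate is flagged unreliable; with zero pairs it is `NA`.
#'
#' @param pairs data frame from [reciprocal_orthologs()], or two
#'   [genome_record()]s via `aai_between()`.
#' @param genome_a,genome_b genome ids carried into the result.
#' @param min_orthologs minimum pair count for a reliable AAI (default 20).
#' @param bands [rank_bands()] used to label the taxonomic rank.
#' @return list of class `aai_result`: `genome_a`, `genome_b`,
#'   `n_orthologs`, `aai`, `reliable`, `rank`.
#' @export
compute_aai <- function(pairs, genome_a = NA_character_, genome_b = NA_character_,
                        min_orthologs = 20, bands = rank_bands()) {
  n <- nrow(pairs)
  aai <- if (n > 0) mean(pairs$percent_identity) else NA_real_
  structure(list(genome_a = genome_a, genome_b = genome_b,
                 n_orthologs = n, aai = aai,
                 reliable = n >= min_orthologs,
                 rank = if (is.na(aai)) NA_character_ else assign_rank(aai, bands)),
            class = "aai_result")
}

#' @rdname compute_aai
#' @param ga,gb [genome_record()]s.
#' @param scheme a [scoring_scheme()].
#' @export
aai_between <- function(ga, gb, scheme = scoring_scheme(), min_orthologs = 20,
                        bands = rank_bands()) {
  compute_aai(reciprocal_orthologs(ga, gb, scheme),
              ga$genome_id, gb$genome_id, min_orthologs, bands)
}

#' @export
print.aai_result <- function(x, ...) {
  cat(sprintf("<aai_result> %s vs %s: AAI %s over %d ortholog pair(s)%s%s\n",
              x$genome_a, x$genome_b,
              if (is.na(x$aai)) "NA" else sprintf("%.2f", x$aai),
              x$n_orthologs,
              if (!is.na(x$rank)) paste0(" [", x$rank, "]") else "",
              if (!x$reliable) " (unreliable: few orthologs)" else ""))
  invisible(x)
}

#' AAI bands for taxonomic rank delineation
#'
#' Default bands follow published standards for taxa descriptions of
#' uncultivated microorganisms: 45-65% AAI for same family, 65-95% for same
#' genus, 95-100% for same species. Bands are half-open at the upper bound
#' (so AAI 65 is genus, 95 is species); the species band is closed at 100.
#'
#' @param species,genus,family numeric `(lower, upper)` bounds.
#' @return list of class `rank_bands`.
#' @export
rank_bands <- function(species = c(95, 100), genus = c(65, 95), family = c(45, 65)) {
  stopifnot(family[1] < family[2], genus[1] < genus[2], species[1] < species[2],
            family[2] <= genus[1], genus[2] <= species[1])
  structure(list(species = species, genus = genus, family = family),
            class = "rank_bands")
}

#' Assign a taxonomic rank from an AAI value
#'
#' @param aai AAI percentage in `[0, 100]`.
#' @param bands a [rank_bands()].
#' @return one of `"same_species"`, `"same_genus"`, `"same_family"`,
#'   `"above_family"`.
#' @export
assign_rank <- function(aai, bands = rank_bands()) {
  if (is.na(aai) || aai < 0 || aai > 100) stop("aai must lie in [0, 100]")
  if (aai >= bands$species[1]) "same_species"
  else if (aai >= bands$genus[1]) "same_genus"
  else if (aai >= bands$family[1]) "same_family"
  else "above_family"
}

#' Pairwise AAI matrix for a genome collection
#'
#' @param genomes named list of [genome_record()].
#' @param scheme a [scoring_scheme()].
#' @param min_orthologs see [compute_aai()].
#' @return symmetric numeric matrix of AAI values; the diagonal is 100.
#' @export
aai_matrix <- function(genomes, scheme = scoring_scheme(), min_orthologs = 20) {
  ids <- vapply(genomes, `[[`, "", "genome_id")
  n <- length(genomes)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- aai_between(genomes[[i]], genomes[[j]], scheme, min_orthologs)
    m[i, j] <- m[j, i] <- r$aai
  }
  m
}

#' Genus-level grouping by single linkage on an AAI matrix
#'
#' Genomes are grouped into the connected components of the graph joining
#' every pair with AAI at or above `threshold` (single linkage).
#'
#' @param aai_mat square symmetric AAI matrix with genome ids as dimnames.
#' @param threshold linkage threshold in AAI points (default 65, the genus
#'   bound).
#' @return named integer vector: group index per genome.
#' @export
cluster_genus_groups <- function(aai_mat, threshold = 65) {
  stopifnot(is.matrix(aai_mat), nrow(aai_mat) == ncol(aai_mat))
  if (!isTRUE(all.equal(aai_mat, t(aai_mat), check.attributes = FALSE)))
    stop("AAI matrix must be symmetric")
  adj <- !is.na(aai_mat) & aai_mat >= threshold
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  setNames(as.integer(comp), rownames(aai_mat))
}

#' Assign a contig to a reference genome by ORF identity and footprint
#'
#' A contig is assigned to the reference when the union of the nucleotide
#' footprints (amino-acid aligned length x 3, placed at the gene's
#' coordinates) of its ORFs' top hits with identity above `min_identity`
#' covers more than `min_cover` of the contig length.
#'
#' @param genome [genome_record()] holding the contig.
#' @param contig_id contig to test.
#' @param ref reference [genome_record()].
#' @param scheme a [scoring_scheme()].
#' @param min_identity strict identity threshold in percent (default 98).
#' @param min_cover strict covered-fraction threshold (default 0.8).
#' @return list: `assigned` (logical), `covered_fraction`, `n_hits`.
#' @export
map_contig_to_reference <- function(genome, contig_id, ref,
                                    scheme = scoring_scheme(),
                                    min_identity = 98, min_cover = 0.8) {
  genes <- genome$genes[genome$genes$contig_id == contig_id, , drop = FALSE]
  if (nrow(genes) == 0L) stop("contig has no genes: ", contig_id)
  clen <- nchar(genome$contigs[[contig_id]])
  spans <- list()
  nhits <- 0L
  for (i in seq_len(nrow(genes))) {
    hit <- top_hit(genes$protein[i], ref, scheme, query_id = genes$gene_id[i])
    if (is.null(hit) || hit$percent_identity <= min_identity) next
    nhits <- nhits + 1L
    fp_start <- genes$start[i] + (hit$query_span[1] - 1L) * 3L
    fp_end <- min(genes$end[i], fp_start + hit$aligned_length * 3L - 1L)
    spans[[nhits]] <- c(fp_start, fp_end)
  }
  covered <- if (nhits) {
    ir <- IRanges::reduce(IRanges::IRanges(
      start = vapply(spans, `[`, 1, 1), end = vapply(spans, `[`, 1, 2)))
    sum(IRanges::width(ir)) / clen
  } else 0
  list(assigned = covered > min_cover, covered_fraction = covered, n_hits = nhits)
}

#' Trim gap-rich columns from a multiple alignment
#'
#' Removes every column whose gap fraction is strictly greater than
#' `max_gap_fraction` (default 0.95); a column with exactly 95% gaps is
#' retained. Row order is preserved.
#'
#' @param msa character vector of equal-length gapped sequences (gap = `-`).
#' @param max_gap_fraction columns with gap fraction strictly above this are
#'   dropped.
#' @return character vector of trimmed rows.
#' @export
trim_alignment_columns <- function(msa, max_gap_fraction = 0.95) {
  stopifnot(length(msa) > 0)
  lens <- nchar(msa)
  if (length(unique(lens)) != 1L) stop("ragged alignment")
  chars <- do.call(rbind, strsplit(msa, ""))
  gap_frac <- colMeans(chars == "-")
  kept <- chars[, gap_frac <= max_gap_fraction, drop = FALSE]
  vapply(seq_len(nrow(kept)), function(i) paste(kept[i, ], collapse = ""), "")
}
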