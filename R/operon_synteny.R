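#' Operon architecture model
#'
#' @param model_id short id (e.g. `"faeDCAB"`).
#' @param core_order ordered character vector of core gene-family symbols.
#' @param accessory symbols tolerated as insertions (e.g. the dctPQM
#'   transporter genes).
#' @param max_intervening_genes maximum number of non-member genes between
#'   consecutive cluster members (default 3).
#' @param max_gap_bp maximum intergenic distance between consecutive members
#'   (default 5000).
#' @param require_co_strand break clusters at strand switches (default TRUE).
#' @return list of class `operon_model`.
#' @export
operon_model <- function(model_id, core_order, accessory = character(0),
                         max_intervening_genes = 3, max_gap_bp = 5000,
                         require_co_strand = TRUE) {
  core_order <- as.character(core_order)
  if (!length(core_order) || anyDuplicated(core_order))
    stop("core_order must be non-empty with unique symbols")
  structure(list(model_id = model_id, core_order = core_order,
                 accessory = as.character(accessory),
                 max_intervening_genes = as.integer(max_intervening_genes),
                 max_gap_bp = as.integer(max_gap_bp),
                 require_co_strand = isTRUE(require_co_strand)),
            class = "operon_model")
}

#' Path to the packaged operon model file
#' @return file path under the installed package.
#' @export
default_operon_file <- function()
  system.file("extdata", "operon_models.yaml", package = "magchar", mustWork = TRUE)

#' Read operon models from a YAML file
#' @param path YAML file; defaults to the packaged faeDCAB/bssDCAB/assDCAB
#'   models.
#' @return named list of [operon_model()].
#' @export
read_operon_models <- function(path = default_operon_file()) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(id) {
    x <- raw[[id]]
    operon_model(id, unlist(x$core_order), unlist(x$accessory) %||% character(0),
                 x$max_intervening_genes %||% 3, x$max_gap_bp %||% 5000,
                 x$require_co_strand %||% TRUE)
  })
  setNames(out, names(raw))
}

#' Find co-located gene clusters carrying target symbols
#'
#' Scans each contig in coordinate order and returns maximal runs of genes
#' carrying any target symbol such that consecutive members are separated by
#' at most `max_intervening_genes` other genes and at most `max_gap_bp`
#' between the end of one member and the start of the next; clusters never
#' span contigs, and a strand switch breaks a cluster when
#' `require_co_strand`.
#'
#' @param genome a [genome_record()].
#' @param symbols target gene-family symbols.
#' @param max_intervening_genes,max_gap_bp,require_co_strand see
#'   [operon_model()].
#' @return list of clusters; each is a data frame of member genes (gene_id,
#'   contig_id, start, end, strand, families) sorted by start.
#' @export
find_clusters <- function(genome, symbols, max_intervening_genes = 3,
                          max_gap_bp = 5000, require_co_strand = TRUE) {
  g <- genome$genes
  carries <- vapply(g$families, function(f) any(symbols %in% f), TRUE)
  clusters <- list()
  for (ctg in unique(g$contig_id)) {
    on_ctg <- g[g$contig_id == ctg, , drop = FALSE]
    on_ctg <- on_ctg[order(on_ctg$start), , drop = FALSE]
    hit_rows <- which(vapply(on_ctg$families, function(f) any(symbols %in% f), TRUE))
    if (!length(hit_rows)) next
    current <- hit_rows[1]
    for (r in hit_rows[-1]) {
      prev <- current[length(current)]
      gap_bp <- on_ctg$start[r] - on_ctg$end[prev] - 1L
      intervening <- r - prev - 1L
      strand_break <- require_co_strand && on_ctg$strand[r] != on_ctg$strand[prev]
      if (intervening <= max_intervening_genes && gap_bp <= max_gap_bp &&
          !strand_break) {
        current <- c(current, r)
      } else {
        clusters[[length(clusters) + 1L]] <- on_ctg[current, , drop = FALSE]
        current <- r
      }
    }
    clusters[[length(clusters) + 1L]] <- on_ctg[current, , drop = FALSE]
  }
  clusters
}

# First model-vocabulary symbol a gene carries, else its first own symbol,
# else "?" (unknown).
cluster_symbols <- function(cluster, vocab) {
  vapply(cluster$families, function(f) {
    hit <- intersect(vocab, f)
    if (length(hit)) hit[1]
    else if (length(f)) f[1]
    else "?"
  }, "")
}

#' Match a gene cluster against an operon model
#'
#' The cluster is canonicalized to the operon's leading strand (clusters on
#' the reverse strand have gene order and strands flipped) before the
#' architecture string is emitted. `core_complete` is TRUE iff every core
#' symbol is present; `insertions` lists accessory symbols interleaved with
#' the core; symbols outside the model vocabulary are flagged `unknown`, not
#' an error.
#'
#' @param cluster one element of [find_clusters()].
#' @param model an [operon_model()].
#' @return list of class `operon_hit`: `contig_id`, `members`,
#'   `architecture_string`, `core_complete`, `insertions`, `unknown`,
#'   `split_across_contigs` (filled by [detect_operons()]).
#' @export
match_operon <- function(cluster, model) {
  stopifnot(nrow(cluster) > 0)
  members <- cluster[order(cluster$start), , drop = FALSE]
  # canonical orientation: majority strand of the cluster defines the lead
  if (mean(members$strand == "-") > 0.5) {
    members <- members[rev(seq_len(nrow(members))), , drop = FALSE]
    members$strand <- ifelse(members$strand == "-", "+", "-")
  }
  vocab <- c(model$core_order, model$accessory)
  syms <- cluster_symbols(members, vocab)
  structure(list(
    contig_id = members$contig_id[1],
    members = members,
    architecture_string = paste(syms, collapse = "-"),
    core_complete = all(model$core_order %in% syms),
    insertions = intersect(unique(syms), model$accessory),
    unknown = setdiff(unique(syms), vocab),
    split_across_contigs = FALSE),
    class = "operon_hit")
}

#' @export
print.operon_hit <- function(x, ...) {
  cat(sprintf("<operon_hit> %s: %s%s%s%s\n", x$contig_id, x$architecture_string,
              if (x$core_complete) " [core complete]" else " [core incomplete]",
              if (length(x$insertions)) paste0(" insertions: ",
                                               paste(x$insertions, collapse = ",")) else "",
              if (x$split_across_contigs) " (split across contigs)" else ""))
  invisible(x)
}

#' Detect operons matching a model in one genome
#'
#' Runs [find_clusters()] with the model's symbols and constraints, matches
#' each cluster with [match_operon()], and sets `split_across_contigs` on
#' every hit when the model's symbols span more than one contig of the
#' genome (fragmentary assembly).
#'
#' @param genome a [genome_record()].
#' @param model an [operon_model()].
#' @return list of `operon_hit`.
#' @export
detect_operons <- function(genome, model) {
  vocab <- c(model$core_order, model$accessory)
  clusters <- find_clusters(genome, vocab, model$max_intervening_genes,
                            model$max_gap_bp, model$require_co_strand)
  hits <- lapply(clusters, match_operon, model = model)
  ctgs <- unique(vapply(hits, `[[`, "", "contig_id"))
  if (length(ctgs) > 1)
    hits <- lapply(hits, function(h) { h$split_across_contigs <- TRUE; h })
  hits
}

#' Does a genome carry a complete operon for a model?
#'
#' TRUE iff some single cluster contains every core symbol of the model.
#'
#' @param genome a [genome_record()].
#' @param model an [operon_model()].
#' @return logical.
#' @export
has_complete_operon <- function(genome, model) {
  any(vapply(detect_operons(genome, model), `[[`, TRUE, "core_complete"))
}

#' Scan a protein for a motif pattern
#'
#' `pattern` is a string over the amino-acid letters plus `x` (any residue),
#' e.g. the ferredoxin motif `"CxxCxxCxxxC"`. All (possibly overlapping)
#' 1-based match start positions are returned.
#'
#' @param protein_seq amino-acid string.
#' @param pattern motif pattern.
#' @return integer vector of match positions (possibly empty).
#' @export
scan_motif <- function(protein_seq, pattern = FERREDOXIN_MOTIF) {
  if (!nzchar(pattern) || grepl("[^ACDEFGHIKLMNPQRSTVWYXx]", pattern))
    stop("pattern must use amino-acid letters plus 'x'")
  rex <- paste0("(?=", gsub("x", ".", pattern, fixed = TRUE), ")")
  m <- gregexpr(rex, protein_seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# Longest common subsequence length of two character vectors.
lcs_length <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (!na || !nb) return(0L)
  d <- matrix(0L, na + 1, nb + 1)
  for (i in seq_len(na)) for (j in seq_len(nb))
    d[i + 1, j + 1] <- if (a[i] == b[j]) d[i, j] + 1L
                       else max(d[i, j + 1], d[i + 1, j])
  d[na + 1, nb + 1]
}

#' Synteny similarity of two operon hits
#'
#' `similarity = Jaccard(shared symbols) * (LCS of the shared-symbol orders /
#' number of shared symbols)`; symmetric, in `[0, 1]`, 0 when no symbols are
#' shared and 1 for identical architectures (reverse-strand clusters are
#' already canonicalized by [match_operon()]).
#'
#' @param a,b `operon_hit` objects.
#' @return numeric similarity.
#' @export
compare_synteny <- function(a, b) {
  sa <- strsplit(a$architecture_string, "-", fixed = TRUE)[[1]]
  sb <- strsplit(b$architecture_string, "-", fixed = TRUE)[[1]]
  if (!length(sa) || !length(sb)) stop("empty operon hit")
  shared <- intersect(unique(sa), unique(sb))
  if (!length(shared)) return(0)
  jac <- length(shared) / length(union(unique(sa), unique(sb)))
  oa <- sa[sa %in% shared]; oa <- oa[!duplicated(oa)]
  ob <- sb[sb %in% shared]; ob <- ob[!duplicated(ob)]
  jac * lcs_length(oa, ob) / length(shared)
}
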