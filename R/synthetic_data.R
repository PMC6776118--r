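# Amino-acid background frequencies (Robinson-Robinson-like, renormalized);
# used for i.i.d. protein synthesis.
AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
AA_BACKGROUND <- c(0.078,0.051,0.045,0.054,0.019,0.043,0.063,0.074,0.022,0.051,
                   0.091,0.057,0.022,0.039,0.052,0.071,0.058,0.013,0.032,0.064)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

FAE_CORE <- c("faeD", "faeC", "faeA", "faeB")
FAE_OPERON_WITH_DCT <- c("faeD", "dctP", "dctQ", "dctM", "faeC", "faeA", "faeB")
FERREDOXIN_MOTIF <- "CxxCxxCxxxC"

# Evaluate expr under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE,
                                             prob = AA_BACKGROUND), collapse = "")

# Overwrite a protein with the ferredoxin motif at a 1-based position;
# 'x' positions are filled with random non-C residues.
inject_motif <- function(protein, pos, pattern = FERREDOXIN_MOTIF) {
  pat <- strsplit(pattern, "")[[1]]
  res <- strsplit(protein, "")[[1]]
  fill <- sample(setdiff(AA20, "C"), length(pat), replace = TRUE)
  res[pos + seq_along(pat) - 1] <- ifelse(pat == "x", fill, pat)
  paste(res, collapse = "")
}

#' Simulation parameters for synthetic genome collections
#'
#' Defaults describe a desk-scale stand-in for a small related-genome
#' collection: 200 proteins of 80-150 aa on 10 contigs with 100 bp
#' intergenic spacers, a planted faeDCAB operon carrying the dctPQM
#' transporter insertion, and the packaged 107-id marker set.
#'
#' @param n_genomes number of descendant genomes to derive per collection.
#' @param n_proteins proteins per genome (must exceed the planted feature
#'   count).
#' @param protein_length_range `(min, max)` amino acids.
#' @param divergence per-site substitution probability in `[0, 1)` applied to
#'   each descendant against the ancestor.
#' @param marker_dropout fraction of the marker set omitted.
#' @param marker_duplication fraction of the marker set present twice.
#' @param fragmentation target number of contigs.
#' @param plant_fae_operon plant a co-strand faeDCAB operon.
#' @param dct_insertion insert dctP/dctQ/dctM between faeD and faeC.
#' @param pathway_complements named list: pathway gene-symbol vectors to
#'   stamp onto otherwise unlabeled genes.
#' @param seed integer; fixed seed gives byte-identical output.
#' @return validated list of class `simulation_params`.
#' @export
simulation_params <- function(n_genomes = 2, n_proteins = 200,
                              protein_length_range = c(80, 150),
                              divergence = 0.1, marker_dropout = 0,
                              marker_duplication = 0, fragmentation = 10,
                              plant_fae_operon = TRUE, dct_insertion = TRUE,
                              pathway_complements = list(), seed = 1) {
  stopifnot(n_genomes >= 1, n_proteins >= 1,
            length(protein_length_range) == 2,
            protein_length_range[1] >= 15,
            protein_length_range[1] <= protein_length_range[2],
            divergence >= 0, divergence < 1,
            marker_dropout >= 0, marker_dropout <= 1,
            marker_duplication >= 0, marker_duplication <= 1,
            fragmentation >= 1)
  structure(list(n_genomes = n_genomes, n_proteins = n_proteins,
                 protein_length_range = protein_length_range,
                 divergence = divergence, marker_dropout = marker_dropout,
                 marker_duplication = marker_duplication,
                 fragmentation = as.integer(fragmentation),
                 plant_fae_operon = plant_fae_operon,
                 dct_insertion = dct_insertion,
                 pathway_complements = pathway_complements,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Path to the packaged synthetic 107-id marker set
#' @return file path under the installed package.
#' @export
default_marker_file <- function()
  system.file("extdata", "markers107.txt", package = "magchar", mustWork = TRUE)

# Lay out proteins on contigs: fixed 100 bp intergenic spacers, CDS length
# 3 x protein length, all genes on '+' unless a strand is supplied.
layout_genome <- function(genome_id, proteins, labels, n_contigs,
                          spacer = 100L, source = "synthetic") {
  n <- length(proteins)
  n_contigs <- min(n_contigs, n)
  chunk <- sort(rep(seq_len(n_contigs), length.out = n))
  if (!is.null(attr(proteins, "keep_first"))) {
    k1 <- attr(proteins, "keep_first")  # planted run must share contig 1
    chunk[seq_len(k1)] <- 1L
  }
  contigs <- character(n_contigs)
  names(contigs) <- sprintf("%s_ctg%03d", genome_id, seq_len(n_contigs))
  rows <- vector("list", n)
  for (k in seq_len(n_contigs)) {
    idx <- which(chunk == k)
    pos <- spacer + 1L
    seq_parts <- character(0)
    for (i in idx) {
      cds_len <- 3L * nchar(proteins[i])
      rows[[i]] <- data.frame(
        gene_id = sprintf("%s_g%04d", genome_id, i),
        contig_id = names(contigs)[k],
        start = pos, end = pos + cds_len - 1L, strand = "+",
        protein = proteins[i], stringsAsFactors = FALSE)
      pos <- pos + cds_len + spacer
      seq_parts <- c(seq_parts, cds_len)
    }
    contigs[k] <- paste(sample(c("A", "C", "G", "T"), pos - 1L, replace = TRUE),
                        collapse = "")
  }
  genes <- do.call(rbind, rows)
  genes$families <- labels
  genes$verified <- TRUE
  genome_record(genome_id, contigs, genes, source = source)
}

#' Generate an ancestor genome
#'
#' Proteins are drawn i.i.d. from a fixed amino-acid background frequency and
#' laid on contigs with 100 bp intergenic spacers. The first genes carry the
#' marker-set ids (after dropout/duplication), a planted faeDCAB(+dctPQM)
#' operon sits consecutively and co-strand on one contig, faeD carries two
#' disjoint ferredoxin `CxxCxxCxxxC` motifs, and any requested pathway
#' complements are stamped onto further genes.
#'
#' @param params a [simulation_params()].
#' @param markers a [marker_set()]; defaults to the packaged 107-id set.
#' @param genome_id id of the generated genome.
#' @return a [genome_record()].
#' @export
generate_ancestor <- function(params, markers = read_marker_set(default_marker_file()),
                              genome_id = "ancestor") {
  stopifnot(inherits(params, "simulation_params"))
  with_seed(params$seed, {
    operon <- if (params$plant_fae_operon) {
      if (params$dct_insertion) FAE_OPERON_WITH_DCT else FAE_CORE
    } else character(0)
    n_drop <- round(params$marker_dropout * markers$size)
    n_dup <- round(params$marker_duplication * markers$size)
    kept <- markers$marker_ids
    if (n_drop > 0) kept <- kept[-sample(markers$size, n_drop)]
    dup <- if (n_dup > 0) sample(kept, min(n_dup, length(kept))) else character(0)
    extra <- unique(unlist(params$pathway_complements))
    planted <- length(operon) + length(kept) + length(dup) + length(extra)
    if (params$n_proteins < planted)
      stop("n_proteins (", params$n_proteins, ") smaller than planted feature count (",
           planted, ")")
    labels <- c(as.list(operon),
                as.list(kept), as.list(dup), as.list(extra),
                replicate(params$n_proteins - planted, character(0), simplify = FALSE))
    cand <- seq(params$protein_length_range[1], params$protein_length_range[2])
    lens <- cand[sample.int(length(cand), params$n_proteins, replace = TRUE)]
    proteins <- vapply(lens, random_protein, "")
    if (params$plant_fae_operon) {
      # faeD gets two disjoint ferredoxin motifs (activating-enzyme signature)
      i_faeD <- which(vapply(labels, function(l) "faeD" %in% l, TRUE))[1]
      L <- nchar(proteins[i_faeD])
      proteins[i_faeD] <- inject_motif(proteins[i_faeD], 3)
      pos2 <- min(30L, L - 10L)
      if (pos2 >= 14L) proteins[i_faeD] <- inject_motif(proteins[i_faeD], pos2)
    }
    if (length(operon)) attr(proteins, "keep_first") <- length(operon)
    layout_genome(genome_id, proteins, labels, params$fragmentation)
  })
}

#' Mutate a descendant genome at a fixed per-site divergence
#'
#' Each amino-acid site is independently replaced with probability `p` by a
#' residue drawn uniformly from the 19 other residues, so expected identity
#' against the ancestor is exactly `100 * (1 - p)`. Gene complement,
#' coordinates and labels are preserved.
#'
#' @param ancestor a [genome_record()].
#' @param p per-site substitution probability in `[0, 1)`.
#' @param seed integer seed.
#' @param genome_id id for the descendant.
#' @return a [genome_record()].
#' @export
mutate_descendant <- function(ancestor, p, seed,
                              genome_id = paste0(ancestor$genome_id, "_desc")) {
  if (p < 0 || p >= 1) stop("divergence p must lie in [0, 1)")
  with_seed(seed, {
    g <- ancestor
    g$genome_id <- genome_id
    names(g$contigs) <- sub(ancestor$genome_id, genome_id, names(g$contigs), fixed = TRUE)
    g$genes$contig_id <- sub(ancestor$genome_id, genome_id, g$genes$contig_id, fixed = TRUE)
    g$genes$gene_id <- sub(ancestor$genome_id, genome_id, g$genes$gene_id, fixed = TRUE)
    g$genes$protein <- vapply(g$genes$protein, function(prot) {
      res <- strsplit(prot, "")[[1]]
      hit <- runif(length(res)) < p
      if (any(hit)) {
        res[hit] <- vapply(res[hit], function(r)
          sample(setdiff(AA20, r), 1), "")
      }
      paste(res, collapse = "")
    }, "", USE.NAMES = FALSE)
    genome_record(g$genome_id, g$contigs, g$genes, lineage = ancestor$lineage,
                  source = sprintf("descendant of %s at p=%g", ancestor$genome_id, p))
  })
}

#' Generate a related-genome collection
#'
#' One ancestor plus `n_genomes` descendants at the parameterized divergence.
#'
#' @param params a [simulation_params()].
#' @param markers a [marker_set()].
#' @return named list of [genome_record()] (ancestor first).
#' @export
generate_collection <- function(params, markers = read_marker_set(default_marker_file())) {
  anc <- generate_ancestor(params, markers)
  descs <- lapply(seq_len(params$n_genomes), function(i)
    mutate_descendant(anc, params$divergence, seed = params$seed + i,
                      genome_id = sprintf("genome%02d", i)))
  out <- c(list(anc), descs)
  setNames(out, vapply(out, `[[`, "", "genome_id"))
}
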