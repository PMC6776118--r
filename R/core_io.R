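#' Construct a genome record
#'
#' A `genome_record` bundles a draft genome's contigs, gene calls with their
#' protein translations and gene-family labels, an optional lineage label and
#' an optional quality estimate. It is the unit every other stage of the
#' package consumes.
#'
#' @param genome_id single non-empty string, unique within a collection.
#' @param contigs named character vector of DNA sequences over `{A,C,G,T,N}`;
#'   names are contig ids.
#' @param genes data frame with columns `gene_id`, `contig_id`, `start`,
#'   `end` (1-based inclusive), `strand` (`"+"`/`"-"`), `protein` (amino acid
#'   string over the 20-letter alphabet plus `X`), and optionally a list
#'   column `families` (character vectors of gene-family symbols such as
#'   `"faeA"`, `"dctP"`, marker ids) and a logical `verified` column.
#' @param lineage optional lineage label (e.g. `"JS1-4"`).
#' @param quality optional [quality_estimate()].
#' @param source free-text provenance.
#' @return object of class `genome_record`.
#' @export
genome_record <- function(genome_id, contigs, genes, lineage = NULL,
                          quality = NULL, source = "") {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  contig_ids <- names(contigs)
  contigs <- setNames(toupper(as.character(contigs)), contig_ids)
  if (length(contigs) &&
      (is.null(names(contigs)) || anyNA(names(contigs)) || !all(nzchar(names(contigs)))))
    stop("contigs must be a named character vector")
  if (anyDuplicated(names(contigs)))
    stop("duplicate contig ids in genome '", genome_id, "'")
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    stop("contig(s) with non-ACGTN characters: ",
         paste(names(contigs)[bad], collapse = ", "))
  if (any(nchar(contigs) == 0L)) stop("zero-length contig")

  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (nrow(genes)) {
    need <- c("gene_id", "contig_id", "start", "end", "strand", "protein")
    miss <- setdiff(need, names(genes))
    if (length(miss)) stop("gene table missing column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(genes$gene_id))
      stop("duplicate gene ids in genome '", genome_id, "'")
    unknown <- setdiff(genes$contig_id, names(contigs))
    if (length(unknown))
      stop("gene(s) reference unknown contig(s): ", paste(unique(unknown), collapse = ", "))
    genes$start <- as.integer(genes$start); genes$end <- as.integer(genes$end)
    clen <- nchar(contigs)[genes$contig_id]
    if (any(genes$start < 1L | genes$start > genes$end | genes$end > clen))
      stop("gene coordinates outside contig bounds in genome '", genome_id, "'")
    if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    genes$protein <- toupper(genes$protein)
    if (any(!nzchar(genes$protein)) || any(grepl("[^ACDEFGHIKLMNPQRSTVWYX]", genes$protein)))
      stop("protein sequences must be non-empty over the 20 amino acids plus X")
    if (is.null(genes$families)) genes$families <- replicate(nrow(genes), character(0), simplify = FALSE)
    genes$families <- lapply(genes$families, as.character)
    if (is.null(genes$verified)) genes$verified <- TRUE
  } else {
    genes <- data.frame(gene_id = character(0), contig_id = character(0),
                        start = integer(0), end = integer(0), strand = character(0),
                        protein = character(0), stringsAsFactors = FALSE)
    genes$families <- list()
    genes$verified <- logical(0)
  }

  structure(list(genome_id = genome_id, contigs = contigs, genes = genes,
                 lineage = lineage, quality = quality, source = source),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d contig(s), %d gene(s)%s%s\n",
              x$genome_id, length(x$contigs), nrow(x$genes),
              if (!is.null(x$lineage)) paste0(", lineage ", x$lineage) else "",
              if (!is.null(x$quality)) paste0(", tier ", x$quality$tier) else ""))
  invisible(x)
}

# All family symbols carried by a genome (one flat character vector)
genome_symbols <- function(genome) unique(unlist(genome$genes$families))

#' Read a genome from FASTA + GFF3 + protein FASTA
#'
#' Contigs come from a nucleotide FASTA; gene calls from a GFF3 subset
#' containing CDS features (1-based inclusive coordinates, strand column,
#' `ID` attribute); protein translations from a companion protein FASTA whose
#' headers are gene ids. Gene-family labels are read from a `gene_family`
#' attribute with `|`-separated symbols; an optional `verified` attribute
#' (`true`/`false`) marks database-confirmed annotations.
#'
#' @param fasta_path nucleotide FASTA of contigs.
#' @param gff_path GFF3 file of CDS features.
#' @param protein_fasta_path protein FASTA keyed by gene id.
#' @param genome_id id for the record; defaults to the FASTA basename.
#' @return a [genome_record()].
#' @export
read_genome <- function(fasta_path, gff_path, protein_fasta_path,
                        genome_id = sub("\\.(fa|fna|fasta)$", "", basename(fasta_path))) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  contigs <- setNames(as.character(dna), sub("\\s.*$", "", names(dna)))
  gr <- rtracklayer::import(gff_path)
  gr <- gr[gr$type == "CDS"]
  aa <- Biostrings::readAAStringSet(protein_fasta_path)
  names(aa) <- sub("\\s.*$", "", names(aa))
  ids <- as.character(gr$ID)
  missing_prot <- setdiff(ids, names(aa))
  if (length(missing_prot))
    stop("no protein sequence for gene(s): ", paste(head(missing_prot, 5), collapse = ", "))
  fam <- if (!is.null(gr$gene_family)) {
    lapply(as.character(gr$gene_family), function(s)
      if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, "|", fixed = TRUE)[[1]])
  } else replicate(length(gr), character(0), simplify = FALSE)
  ver <- if (!is.null(gr$verified)) !(tolower(as.character(gr$verified)) %in% "false")
         else rep(TRUE, length(gr))
  genes <- data.frame(
    gene_id = ids,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    protein = as.character(aa[ids]),
    stringsAsFactors = FALSE)
  genes$families <- fam
  genes$verified <- ver
  genome_record(genome_id, contigs, genes)
}

#' Write a genome to FASTA + GFF3 + protein FASTA
#'
#' Inverse of [read_genome()]: writes `<id>.fna`, `<id>.gff3` and `<id>.faa`
#' under `dir`. Round-trips all fields `read_genome` consumes.
#'
#' @param genome a [genome_record()].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, genome$genome_id)
  paths <- paste0(base, c(".fna", ".gff3", ".faa"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$contigs), paths[1])
  g <- genome$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$contig_id,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand)
  gr$source <- "magchar"
  gr$type <- "CDS"
  gr$ID <- g$gene_id
  gr$gene_family <- vapply(g$families, paste, "", collapse = "|")
  gr$verified <- ifelse(g$verified, "true", "false")
  gr$phase <- 0L
  rtracklayer::export(gr, paths[2], format = "gff3")
  aa <- Biostrings::AAStringSet(setNames(g$protein, g$gene_id))
  Biostrings::writeXStringSet(aa, paths[3])
  invisible(setNames(paths, c("fasta", "gff3", "protein")))
}

#' Read a domain-hit table (tabular HMM-search output)
#'
#' Accepts a whitespace- or tab-delimited table with header columns
#' `protein_id`, `model_id`, `e_value` and either `model_coverage` directly
#' or `ali_from`, `ali_to`, `model_length` from which coverage is computed as
#' `(ali_to - ali_from + 1) / model_length`.
#'
#' @param tsv_path path to the table.
#' @return data frame with one row per hit: `protein_id`, `model_id`,
#'   `e_value`, `model_coverage`, `ali_from`, `ali_to`.
#' @export
read_domain_hits <- function(tsv_path) {
  df <- read.table(tsv_path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("protein_id", "model_id", "e_value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("domain-hit table missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$e_value < 0)) stop("negative E-value in domain-hit table")
  if (is.null(df$model_coverage)) {
    if (!all(c("ali_from", "ali_to", "model_length") %in% names(df)))
      stop("need model_coverage or ali_from/ali_to/model_length")
    df$model_coverage <- (df$ali_to - df$ali_from + 1) / df$model_length
  }
  if (is.null(df$ali_from)) df$ali_from <- NA_integer_
  if (is.null(df$ali_to)) df$ali_to <- NA_integer_
  if (any(df$model_coverage < 0 | df$model_coverage > 1))
    stop("model_coverage outside [0,1]")
  df[c("protein_id", "model_id", "e_value", "model_coverage", "ali_from", "ali_to")]
}

#' Write / read a genome-by-feature matrix as TSV
#'
#' The TSV has a header row of feature ids, a first column `genome_id`, and
#' numeric (count or 0/1) cells.
#'
#' @param m matrix with rownames = genome ids, colnames = feature ids.
#' @param path output path.
#' @return `write_matrix`: invisibly, `path`. `read_matrix`: the matrix.
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)) || nrow(m) == 0,
            !is.null(colnames(m)) || ncol(m) == 0)
  ids <- rownames(m) %||% character(0)
  df <- data.frame(genome_id = ids, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$genome_id
  storage.mode(m) <- "numeric"
  m
}

#' Read a genome collection from a directory
#'
#' Expects per-genome triples `<id>.fna`, `<id>.gff3`, `<id>.faa` as written
#' by [write_genome()].
#'
#' @param dir directory of genome files.
#' @return named list of [genome_record()].
#' @export
read_genome_dir <- function(dir) {
  fnas <- sort(list.files(dir, pattern = "\\.fna$", full.names = TRUE))
  if (!length(fnas)) stop("no .fna genomes under ", dir)
  recs <- lapply(fnas, function(f) {
    base <- sub("\\.fna$", "", f)
    read_genome(f, paste0(base, ".gff3"), paste0(base, ".faa"))
  })
  setNames(recs, vapply(recs, `[[`, "", "genome_id"))
}
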