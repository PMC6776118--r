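#' Assembly statistics of a genome
#'
#' N50 is the length of the shortest contig in the smallest set of longest
#' contigs whose summed length reaches at least half the assembly size. GC
#' percent is `100 * (G + C) / (A + C + G + T)`; ambiguous `N` bases are
#' excluded from the denominator.
#'
#' @param genome a [genome_record()] with at least one contig.
#' @return list of class `assembly_stats`: `size_bp`, `gc_percent`,
#'   `n_scaffolds`, `n50_bp`.
#' @export
compute_assembly_stats <- function(genome) {
  if (length(genome$contigs) == 0L) stop("empty genome")
  lens <- nchar(genome$contigs)
  total <- sum(lens)
  sorted <- sort(lens, decreasing = TRUE)
  n50 <- sorted[which(cumsum(sorted) >= total / 2)[1]]
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(genome$contigs), baseOnly = TRUE))
  acgt <- sum(counts[c("A", "C", "G", "T")])
  structure(list(size_bp = total,
                 gc_percent = 100 * sum(counts[c("G", "C")]) / acgt,
                 n_scaffolds = length(lens),
                 n50_bp = unname(n50)),
            class = "assembly_stats")
}

#' Marker set for completeness/contamination estimation
#'
#' A flat set of single-copy marker gene-family symbols (e.g. a 107-marker
#' bacterial set). The package ships a synthetic 107-id set under
#' `inst/extdata/markers107.txt` usable with the simulator.
#'
#' @param marker_ids character vector of unique marker symbols.
#' @param set_id label for the set.
#' @return list of class `marker_set`: `set_id`, `marker_ids`, `size`.
#' @export
marker_set <- function(marker_ids, set_id = "markers") {
  marker_ids <- unique(as.character(marker_ids))
  if (!length(marker_ids)) stop("empty marker set")
  structure(list(set_id = set_id, marker_ids = marker_ids,
                 size = length(marker_ids)),
            class = "marker_set")
}

#' Read a marker set from a text file (one marker id per line)
#' @param path text file of marker ids.
#' @param set_id label for the set.
#' @return a [marker_set()].
#' @export
read_marker_set <- function(path, set_id = basename(path)) {
  ids <- readLines(path)
  ids <- trimws(ids[nzchar(trimws(ids)) & !startsWith(trimws(ids), "#")])
  marker_set(ids, set_id)
}

#' Quality estimate container
#'
#' @param completeness_percent completeness in `[0, 100]`.
#' @param contamination_percent contamination (>= 0; may exceed 100).
#' @param tier optional tier label; computed with [assign_tier()] if missing.
#' @return list of class `quality_estimate`.
#' @export
quality_estimate <- function(completeness_percent, contamination_percent,
                             tier = NULL) {
  stopifnot(completeness_percent >= 0, completeness_percent <= 100,
            contamination_percent >= 0)
  q <- structure(list(completeness_percent = completeness_percent,
                      contamination_percent = contamination_percent,
                      tier = tier),
                 class = "quality_estimate")
  if (is.null(tier)) q$tier <- assign_tier(q)
  q
}

#' Estimate genome completeness and contamination from a marker set
#'
#' Completeness is the percentage of distinct markers represented at least
#' once; contamination is the percentage of surplus marker copies:
#' `100 * sum(max(0, copies - 1)) / set size`.
#'
#' @param genome a [genome_record()] whose gene `families` carry marker ids.
#' @param markers a [marker_set()].
#' @return a [quality_estimate()] with the tier filled in.
#' @export
estimate_quality <- function(genome, markers) {
  stopifnot(inherits(markers, "marker_set"), markers$size > 0)
  fams <- unlist(genome$genes$families)
  copies <- table(fams[fams %in% markers$marker_ids])
  completeness <- 100 * length(copies) / markers$size
  contamination <- 100 * sum(pmax(0, as.integer(copies) - 1L)) / markers$size
  quality_estimate(completeness, contamination)
}

#' MIMAG-style quality tier from completeness and contamination
#'
#' High: completeness > 90 and contamination < 5. Medium: completeness >= 50
#' and contamination < 10 (and not High). Otherwise Low. The published MIMAG
#' High tier additionally requires rRNA/tRNA presence; these enter as
#' optional booleans defaulting to satisfied, so tiering from completeness
#' and contamination alone is the default behaviour.
#'
#' @param q a [quality_estimate()], or a completeness percentage when
#'   `contamination` is given.
#' @param contamination contamination percentage (when `q` is numeric).
#' @param rrna_present,trna_present optional extra MIMAG requirements for the
#'   High tier.
#' @return `"High"`, `"Medium"` or `"Low"`.
#' @export
assign_tier <- function(q, contamination = NULL, rrna_present = TRUE,
                        trna_present = TRUE) {
  if (inherits(q, "quality_estimate")) {
    comp <- q$completeness_percent; cont <- q$contamination_percent
  } else {
    comp <- q; cont <- contamination
  }
  stopifnot(is.numeric(comp), is.numeric(cont))
  if (comp > 90 && cont < 5 && rrna_present && trna_present) "High"
  else if (comp >= 50 && cont < 10) "Medium"
  else "Low"
}

#' @export
print.quality_estimate <- function(x, ...) {
  cat(sprintf("<quality_estimate> completeness %.2f%%, contamination %.2f%%, tier %s\n",
              x$completeness_percent, x$contamination_percent, x$tier))
  invisible(x)
}

#' Quality summary table for a genome collection
#'
#' Quality metadata already attached to a genome (e.g. by an external
#' estimator or the packaged fixture) takes precedence; otherwise the marker
#' set is required and [estimate_quality()] is used.
#'
#' @param genomes named list of [genome_record()].
#' @param markers a [marker_set()] used for genomes without attached quality.
#' @return data frame with one row per genome: assembly stats, completeness,
#'   contamination and tier.
#' @export
quality_table <- function(genomes, markers = NULL) {
  rows <- lapply(genomes, function(g) {
    st <- compute_assembly_stats(g)
    q <- g$quality
    if (is.null(q) && !is.null(markers)) q <- estimate_quality(g, markers)
    if (is.null(q)) stop("no marker set given and no quality attached: ", g$genome_id)
    data.frame(genome_id = g$genome_id, size_bp = st$size_bp,
               gc = round(st$gc_percent, 2), n_scaffolds = st$n_scaffolds,
               n50 = st$n50_bp,
               completeness = q$completeness_percent,
               contamination = q$contamination_percent,
               tier = q$tier, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
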