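#' Pathway definition
#'
#' An ordered list of steps; each step is a non-empty set of alternative
#' gene-family symbols (any one suffices). `prior_status` selects which
#' presence standard applies: pathways already described in the lineage
#' context (`"previously_described"`) are called present when at least 75%
#' of the steps are detected; pathways not found there before (`"novel"`)
#' require every step.
#'
#' @param pathway_id short id.
#' @param steps list of character vectors of alternative symbols.
#' @param prior_status `"previously_described"` or `"novel"`.
#' @param name human-readable name.
#' @return list of class `pathway_definition`.
#' @export
pathway_definition <- function(pathway_id, steps,
                               prior_status = c("previously_described", "novel"),
                               name = pathway_id) {
  prior_status <- match.arg(prior_status)
  steps <- lapply(steps, as.character)
  if (!length(steps) || any(!lengths(steps)))
    stop("pathway must have >= 1 step and no empty step")
  structure(list(pathway_id = pathway_id, name = name, steps = steps,
                 prior_status = prior_status),
            class = "pathway_definition")
}

#' Path to the packaged pathway definition file
#' @return file path under the installed package.
#' @export
default_pathway_file <- function()
  system.file("extdata", "pathways.yaml", package = "magchar", mustWork = TRUE)

#' Read pathway definitions from a YAML file
#'
#' Each entry: `pathway_id: {name, prior_status, steps: [[sym, ...], ...]}`.
#'
#' @param path YAML file; defaults to the packaged definitions.
#' @return named list of [pathway_definition()].
#' @export
read_pathway_definitions <- function(path = default_pathway_file()) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(id) {
    x <- raw[[id]]
    pathway_definition(id, lapply(x$steps, unlist),
                       prior_status = x$prior_status, name = x$name %||% id)
  })
  setNames(out, names(raw))
}

#' Genome-by-gene presence matrix
#'
#' @param genomes named list of [genome_record()].
#' @param catalog character vector of gene-family symbols (columns).
#' @return 0/1 integer matrix, genomes as rows.
#' @export
build_presence_matrix <- function(genomes, catalog) {
  if (!length(catalog)) stop("empty gene catalog")
  catalog <- unique(as.character(catalog))
  m <- t(vapply(genomes, function(g)
    as.integer(catalog %in% genome_symbols(g)), integer(length(catalog))))
  dimnames(m) <- list(vapply(genomes, `[[`, "", "genome_id"), catalog)
  m
}

#' Call pathway presence for one genome
#'
#' A step counts as detected if any of its alternative symbols is present.
#' `fraction_detected = detected steps / total steps`. Under the
#' previously-described standard the pathway is present iff the fraction is
#' at least 0.75 (inclusive boundary); under the novel standard iff every
#' step is detected.
#'
#' @param genome_row named 0/1 vector (a row of [build_presence_matrix()]),
#'   a character vector of present symbols, or a [genome_record()].
#' @param pd a [pathway_definition()].
#' @return list of class `presence_call`: `subject`, `id`, `status`
#'   (`"present"`/`"absent"`), `fraction_detected`, `supporting` (symbols).
#' @export
call_pathway <- function(genome_row, pd) {
  stopifnot(inherits(pd, "pathway_definition"))
  subject <- NA_character_
  if (inherits(genome_row, "genome_record")) {
    subject <- genome_row$genome_id
    present <- genome_symbols(genome_row)
  } else if (is.character(genome_row)) {
    present <- genome_row
  } else {
    present <- names(genome_row)[genome_row > 0]
    subject <- attr(genome_row, "genome_id") %||% NA_character_
  }
  det <- vapply(pd$steps, function(alts) any(alts %in% present), TRUE)
  frac <- mean(det)
  status <- if (pd$prior_status == "previously_described") {
    if (frac >= 0.75) "present" else "absent"
  } else {
    if (all(det)) "present" else "absent"
  }
  structure(list(subject = subject, id = pd$pathway_id, status = status,
                 fraction_detected = frac,
                 supporting = intersect(unlist(pd$steps), present)),
            class = "presence_call")
}

#' @export
print.presence_call <- function(x, ...) {
  cat(sprintf("<presence_call> %s / %s: %s (%.0f%% of steps)\n",
              x$subject, x$id, x$status, 100 * x$fraction_detected))
  invisible(x)
}

#' Pathway presence table over a genome collection
#'
#' @param genomes named list of [genome_record()].
#' @param definitions list of [pathway_definition()].
#' @return data frame: `genome_id`, `pathway_id`, `prior_status`, `status`,
#'   `fraction_detected`.
#' @export
call_pathways <- function(genomes, definitions = read_pathway_definitions()) {
  rows <- lapply(genomes, function(g)
    do.call(rbind, lapply(definitions, function(pd) {
      pc <- call_pathway(g, pd)
      data.frame(genome_id = g$genome_id, pathway_id = pd$pathway_id,
                 prior_status = pd$prior_status, status = pc$status,
                 fraction_detected = pc$fraction_detected,
                 stringsAsFactors = FALSE)
    })))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lineage-level gene status conditioned on genome quality
#'
#' Within one lineage: a gene is called present when it is detected in every
#' Medium-or-High-quality genome; it is called absent when it is detected in
#' no genome at all and the lineage contains at least one High-quality genome
#' (so low completeness cannot masquerade as absence); otherwise the status
#' is uncertain. A lineage with no Medium-or-High genome yields uncertain
#' with a warning.
#'
#' @param genomes list of [genome_record()] from one lineage, each with a
#'   quality tier attached.
#' @param symbol gene-family symbol to call.
#' @return a `presence_call` with status `"present"`, `"absent"` or
#'   `"uncertain"`.
#' @export
call_lineage_gene_status <- function(genomes, symbol) {
  tiers <- vapply(genomes, function(g) {
    if (is.null(g$quality)) stop("genome without quality tier: ", g$genome_id)
    g$quality$tier
  }, "")
  detected <- vapply(genomes, function(g) symbol %in% genome_symbols(g), TRUE)
  lineage <- unique(unlist(lapply(genomes, `[[`, "lineage")))
  subject <- if (length(lineage) == 1) lineage else paste(lineage, collapse = "+")
  mh <- tiers %in% c("Medium", "High")
  ids <- vapply(genomes, `[[`, "", "genome_id")
  status <- if (!any(mh)) {
    warning("lineage '", subject, "' has no Medium-or-High-quality genome; status uncertain")
    "uncertain"
  } else if (all(detected[mh])) {
    "present"
  } else if (!any(detected) && any(tiers == "High")) {
    "absent"
  } else {
    "uncertain"
  }
  structure(list(subject = subject, id = symbol, status = status,
                 fraction_detected = mean(detected),
                 supporting = ids[detected]),
            class = "presence_call")
}

#' Filter CAZyme domain hits
#'
#' Keeps hits with E-value at most `e_value_max` and coverage at least
#' `coverage_min` (defaults 1e-18 and 0.35, the dbCAN screening thresholds).
#' Coverage is measured over the HMM model (`model_coverage`); set
#' `coverage_field` to use a differently computed column.
#'
#' @param hits data frame from [read_domain_hits()].
#' @param e_value_max inclusive E-value ceiling.
#' @param coverage_min inclusive coverage floor.
#' @param coverage_field column holding the coverage fraction.
#' @return the qualifying rows of `hits`.
#' @export
filter_cazy_hits <- function(hits, e_value_max = 1e-18, coverage_min = 0.35,
                             coverage_field = "model_coverage") {
  stopifnot(coverage_field %in% names(hits))
  hits[hits$e_value <= e_value_max & hits[[coverage_field]] >= coverage_min, ,
       drop = FALSE]
}
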