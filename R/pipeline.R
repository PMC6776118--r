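#' Pipeline configuration
#'
#' All stage thresholds in one place; the configuration is echoed into the
#' run report so no defaults stay hidden.
#'
#' @param input_dir directory of genome triples for [read_genome_dir()]
#'   (optional when genomes are passed to [run_pipeline()] directly).
#' @param marker_file marker-id text file (one id per line).
#' @param pathway_file,operon_file,ledger_file,energy_table packaged-format
#'   YAML/TSV paths; defaults are the shipped definitions.
#' @param gap_open,gap_extend,lambda,K,e_value_threshold alignment scheme
#'   parameters (see [scoring_scheme()]).
#' @param min_orthologs minimum ortholog pairs for a reliable AAI.
#' @param genus_threshold single-linkage AAI threshold for genus grouping.
#' @param bands a [rank_bands()].
#' @param run_aai compute the pairwise AAI matrix (the expensive stage).
#' @param lineage_symbols gene symbols for the lineage-level status stage.
#' @param seed integer seed echoed into the report (the pipeline itself is
#'   deterministic; the seed feeds any simulation used to produce inputs).
#' @param out_dir directory for stage TSVs (optional).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL,
                            marker_file = default_marker_file(),
                            pathway_file = default_pathway_file(),
                            operon_file = default_operon_file(),
                            ledger_file = default_ledger_file(),
                            energy_table = system.file("extdata", "formation_energies.tsv",
                                                       package = "magchar"),
                            gap_open = 11, gap_extend = 1,
                            lambda = 0.267, K = 0.041, e_value_threshold = 1e-5,
                            min_orthologs = 20, genus_threshold = 65,
                            bands = rank_bands(), run_aai = TRUE,
                            lineage_symbols = c("faeA", "faeB", "faeC", "faeD",
                                                "assK", "mcmLS", "pccA",
                                                "pta", "ack", "ptb", "buk", "acdAB"),
                            seed = 1, out_dir = NULL) {
  stopifnot(min_orthologs >= 0, genus_threshold >= 0, genus_threshold <= 100,
            e_value_threshold > 0)
  structure(list(input_dir = input_dir, marker_file = marker_file,
                 pathway_file = pathway_file, operon_file = operon_file,
                 ledger_file = ledger_file, energy_table = energy_table,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K, e_value_threshold = e_value_threshold,
                 min_orthologs = min_orthologs, genus_threshold = genus_threshold,
                 bands = bands, run_aai = isTRUE(run_aai),
                 lineage_symbols = lineage_symbols,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected. `bands` may be given as
#' `bands: {species: [95,100], genus: [65,95], family: [45,65]}`.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), "bands")
  unknown <- setdiff(names(raw), c(known, "bands"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$bands))
    raw$bands <- rank_bands(unlist(raw$bands$species), unlist(raw$bands$genus),
                            unlist(raw$bands$family))
  do.call(pipeline_config, raw)
}

write_tsv <- function(df, path)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Run the full characterization pipeline
#'
#' Stages: quality tiering -> pairwise AAI, rank labels and genus-level
#' grouping -> pathway presence and lineage-level gene status -> operon
#' detection -> pathway energetics. Cross-stage consistency is asserted
#' (lineage calls use exactly the tiers of the quality stage; every genome
#' with a complete core operon must also satisfy the operon pathway rule)
#' and any stage failure aborts with the stage name.
#'
#' @param genomes named list of [genome_record()]; read from
#'   `config$input_dir` when omitted.
#' @param config a [pipeline_config()].
#' @return list of class `run_report`: `quality`, `aai` (matrix or NULL),
#'   `ranks`, `groups`, `pathways`, `lineage_status`, `operons`,
#'   `fae_positive`, `energetics`, `config`.
#' @export
run_pipeline <- function(genomes = NULL, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(genomes)) {
    if (is.null(config$input_dir)) stop("stage=load: no genomes and no input_dir")
    genomes <- read_genome_dir(config$input_dir)
  }
  if (!length(genomes)) stop("stage=load: empty genome collection")
  ids <- vapply(genomes, `[[`, "", "genome_id")
  if (anyDuplicated(ids)) stop("stage=load: duplicate genome ids")
  names(genomes) <- ids
  scheme <- scoring_scheme(gap_open = config$gap_open, gap_extend = config$gap_extend,
                           lambda = config$lambda, K = config$K,
                           e_value_threshold = config$e_value_threshold)
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e)
      stop("stage=", name, ": ", conditionMessage(e), call. = FALSE))
    log_stage(name, n_genomes = length(genomes), elapsed = proc.time()[3] - t0)
    out
  }

  markers <- if (!is.null(config$marker_file)) read_marker_set(config$marker_file)
  quality <- stage("quality", quality_table(genomes, markers))

  aai <- ranks <- groups <- NULL
  if (config$run_aai) {
    aai <- stage("aai", aai_matrix(genomes, scheme, config$min_orthologs))
    ranks <- stage("ranks", {
      ut <- which(upper.tri(aai), arr.ind = TRUE)
      data.frame(genome_a = rownames(aai)[ut[, 1]], genome_b = colnames(aai)[ut[, 2]],
                 aai = aai[ut],
                 rank = vapply(aai[ut], function(v)
                   if (is.na(v)) NA_character_ else assign_rank(v, config$bands), ""),
                 stringsAsFactors = FALSE)
    })
    groups <- stage("groups", cluster_genus_groups(aai, config$genus_threshold))
  }

  definitions <- read_pathway_definitions(config$pathway_file)
  pathways <- stage("pathways", call_pathways(genomes, definitions))

  lineage_status <- stage("lineage_status", {
    lineages <- unique(unlist(lapply(genomes, `[[`, "lineage")))
    lineages <- lineages[!is.na(lineages)]
    rows <- list()
    for (lin in lineages) {
      members <- Filter(function(g) identical(g$lineage, lin), genomes)
      for (sym in config$lineage_symbols) {
        pc <- withCallingHandlers(call_lineage_gene_status(members, sym),
                                  warning = function(w) invokeRestart("muffleWarning"))
        rows[[length(rows) + 1L]] <- data.frame(
          lineage = lin, gene = sym, status = pc$status,
          fraction_detected = pc$fraction_detected, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows) %||% data.frame()
  })

  models <- read_operon_models(config$operon_file)
  operons <- stage("operons", {
    rows <- list()
    for (g in genomes) for (m in models) {
      for (h in detect_operons(g, m)) {
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = g$genome_id, model_id = m$model_id,
          contig_id = h$contig_id, architecture = h$architecture_string,
          core_complete = h$core_complete,
          insertions = paste(h$insertions, collapse = ","),
          split_across_contigs = h$split_across_contigs,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows) %||% data.frame()
  })
  fae_model <- models[["faeDCAB"]]
  fae_positive <- if (!is.null(fae_model)) stage("fae_positive",
    names(genomes)[vapply(genomes, has_complete_operon, TRUE, model = fae_model)])
  else character(0)

  energetics <- stage("energetics",
    summarize_energetics(read_reaction_ledger(config$ledger_file),
                         if (!is.null(config$energy_table) && nzchar(config$energy_table))
                           read_energy_table(config$energy_table)))

  stage("consistency", {
    # lineage calls must rest on the tiers reported by the quality stage
    tier_by_id <- setNames(quality$tier, quality$genome_id)
    for (g in genomes) {
      q <- g$quality
      if (!is.null(q) && !identical(q$tier, tier_by_id[[g$genome_id]]))
        stop("tier mismatch for ", g$genome_id)
    }
    # a complete core operon implies the all-steps operon pathway call
    if (!is.null(fae_model) && "fae_operon" %in% pathways$pathway_id) {
      pw_pos <- pathways$genome_id[pathways$pathway_id == "fae_operon" &
                                     pathways$status == "present"]
      if (!all(fae_positive %in% pw_pos))
        stop("operon-complete genome not pathway-positive: ",
             paste(setdiff(fae_positive, pw_pos), collapse = ","))
    }
    TRUE
  })

  report <- structure(list(quality = quality, aai = aai, ranks = ranks,
                           groups = groups, pathways = pathways,
                           lineage_status = lineage_status, operons = operons,
                           fae_positive = fae_positive, energetics = energetics,
                           config = config,
                           version = as.character(utils::packageVersion("magchar"))),
                      class = "run_report")
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' Write a run report's stage tables to a directory
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(report$quality, file.path(dir, "quality.tsv"))
  if (!is.null(report$aai)) {
    write_matrix(report$aai, file.path(dir, "aai.tsv"))
    write_tsv(report$ranks, file.path(dir, "ranks.tsv"))
    write_tsv(data.frame(genome_id = names(report$groups),
                         group = unname(report$groups)),
              file.path(dir, "groups.tsv"))
  }
  write_tsv(report$pathways, file.path(dir, "pathways.tsv"))
  if (nrow(report$lineage_status))
    write_tsv(report$lineage_status, file.path(dir, "lineage_status.tsv"))
  if (nrow(report$operons))
    write_tsv(report$operons, file.path(dir, "operons.tsv"))
  write_tsv(report$energetics$per_step, file.path(dir, "energetics_steps.tsv"))
  write_tsv(data.frame(net_atp = report$energetics$net_atp,
                       balanced = report$energetics$balanced,
                       dg0_net_kj_mol = report$energetics$dg_net),
            file.path(dir, "energetics.tsv"))
  cfg <- report$config
  cfg$bands <- list(species = cfg$bands$species, genus = cfg$bands$genus,
                    family = cfg$bands$family)
  yaml::write_yaml(c(unclass(cfg), list(magchar_version = report$version)),
                   file.path(dir, "config_echo.yaml"))
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  genomes: %d (%s High / %s Medium / %s Low)\n",
              nrow(x$quality), sum(x$quality$tier == "High"),
              sum(x$quality$tier == "Medium"), sum(x$quality$tier == "Low")))
  if (!is.null(x$groups))
    cat(sprintf("  genus-level groups: %d\n", length(unique(x$groups))))
  if (nrow(x$pathways))
    cat(sprintf("  pathway calls: %d present / %d total\n",
                sum(x$pathways$status == "present"), nrow(x$pathways)))
  cat(sprintf("  complete faeDCAB operons: %d genome(s)%s\n",
              length(x$fae_positive),
              if (length(x$fae_positive))
                paste0(" [", paste(x$fae_positive, collapse = ", "), "]") else ""))
  cat(sprintf("  ledger: net ATP %+g per alkane, carbon-balanced: %s\n",
              x$energetics$net_atp, x$energetics$balanced))
  invisible(x)
}
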