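# Roster of the 17-genome study fixture. The seven FAE-containing genomes
# carry the completeness/contamination printed for them (this-study values);
# quality values of the ten FAE-free genomes are synthetic stand-ins chosen
# to respect their published tier descriptions. All sequences are synthetic.
fixture_roster <- function() {
  fae <- data.frame(
    genome_id = c("UBA4082", "UBA5772", "UBA6794", "UBA6251",
                  "Maxbin015", "Maxbin017", "Maxbin027"),
    lineage = c("JS1-5", "JS1-5", "JS1-4", "JS1-2", "JS1-4", "JS1-4", "JS1-6"),
    completeness = c(98.31, 94.54, 78.81, 64.41, 98.31, 98.31, 98.31),
    contamination = c(4.24, 4.49, 0, 0, 0, 0, 4.24),
    fae = TRUE, stringsAsFactors = FALSE)
  other <- data.frame(
    genome_id = c("Maxbin010", "UBA3950", "MAG-35_14", "MAG-34_13", "MAG-34_18",
                  "MAG-33_29", "MAG-CG17", "MAG-33_16", "MAG-33_13", "MAG-4572_76"),
    lineage = c("JS1-1", "OP9-3", "JS1-1", "JS1-7", "JS1-7",
                "JS1-7", "JS1-7", "JS1-7", "JS1-7", "JS1-1"),
    completeness = c(96.5, 92.4, 91.2, 75.0, 68.0, 71.5, 66.0, 59.0, 55.5, 62.0),
    contamination = c(2.1, 3.0, 1.5, 2.0, 1.0, 3.2, 0.5, 2.4, 1.1, 4.0),
    fae = FALSE, stringsAsFactors = FALSE)
  rbind(fae, other)
}

GLYCOLYSIS_GENES <- c("glk", "pgi", "pfk", "fba", "tpi", "gap",
                      "pgk", "gpm", "eno", "pyk")

# Gene complement stamped on each fixture genome besides the planted operon.
fixture_complement <- function(row) {
  base <- c(GLYCOLYSIS_GENES, "pta", "ack")
  if (row$lineage != "OP9-3") base <- c(base, "ptb", "buk")
  if (row$fae) base <- c(base, "assK", "mcmLS", "pccA")
  if (row$lineage %in% c("JS1-1", "JS1-4", "JS1-6", "JS1-7"))
    base <- c(base, "prpE", "mcmLS", "pccA")
  if (row$genome_id == "Maxbin010") base <- c(base, "pflD", "acdAB")
  unique(base)
}

#' The packaged 17-genome study fixture
#'
#' A synthetic transcription of the study collection: 17 named genomes of
#' which the seven FAE-containing ones carry a complete planted
#' faeD-dctPQM-faeCAB operon (plus faeE/faeF/faeG tail genes) and the printed
#' completeness/contamination values; the other ten carry no fae genes.
#' Presence/absence of pathway genes follows the published per-lineage
#' complements; protein sequences are synthesized (real MAG sequences are
#' not redistributed), so only label-based analyses — quality tiering,
#' pathway calls, operon detection — reproduce published results from it.
#'
#' @return list with `genomes` (named list of 17 [genome_record()]) and
#'   `presence` (genome x gene 0/1 matrix over the fixture's gene catalog).
#' @export
make_study_fixture <- function() {
  roster <- fixture_roster()
  genomes <- with_seed(1406L, {
    lapply(seq_len(nrow(roster)), function(i) {
      row <- roster[i, ]
      operon <- if (row$fae) c(FAE_OPERON_WITH_DCT, "faeE", "faeF", "faeG")
                else character(0)
      complement <- fixture_complement(row)
      labels <- c(as.list(operon), as.list(complement),
                  replicate(10, character(0), simplify = FALSE))
      lens <- 60L + sample.int(60L, length(labels), replace = TRUE)
      proteins <- vapply(lens, random_protein, "")
      if (row$fae) {
        proteins[1] <- inject_motif(proteins[1], 3)    # faeD is first
        proteins[1] <- inject_motif(proteins[1], 30)
      }
      if (length(operon)) attr(proteins, "keep_first") <- length(operon)
      g <- layout_genome(row$genome_id, proteins, labels, n_contigs = 3L,
                         source = "synthetic fixture (published presence/absence; sequences simulated)")
      g$lineage <- row$lineage
      g$quality <- quality_estimate(row$completeness, row$contamination)
      g
    })
  })
  genomes <- setNames(genomes, roster$genome_id)
  catalog <- sort(unique(unlist(lapply(genomes, genome_symbols))))
  list(genomes = genomes, presence = build_presence_matrix(genomes, catalog))
}
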