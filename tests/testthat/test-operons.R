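fae_model <- read_operon_models()[["faeDCAB"]]

operon_genome <- function(id, labels, strands = NULL, spacer = 100L) {
  set.seed(1)
  prots <- replicate(length(labels), rand_protein(50))
  toy_genome(id, prots, labels = lapply(labels, function(x)
    if (is.na(x)) character(0) else x), strands = strands, spacer = spacer)
}

test_that("clusters respect gene-count and bp gap thresholds and contig borders", {
  g <- operon_genome("op", c("faeD", "faeC", "faeA", "faeB"))
  cl <- find_clusters(g, c("faeD", "faeC", "faeA", "faeB"))
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]), 4L)

  # genes 6 kb apart split with max_gap_bp = 5000
  g2 <- operon_genome("far", c("faeA", "faeB"), spacer = 6000L)
  expect_length(find_clusters(g2, c("faeA", "faeB"), max_gap_bp = 5000), 2L)
  expect_length(find_clusters(g2, c("faeA", "faeB"), max_gap_bp = 7000), 1L)

  # too many intervening genes split a cluster
  g3 <- operon_genome("gap", c("faeA", NA, NA, NA, NA, "faeB"))
  expect_length(find_clusters(g3, c("faeA", "faeB"), max_intervening_genes = 3,
                              max_gap_bp = 1e6), 2L)
  expect_length(find_clusters(g3, c("faeA", "faeB"), max_intervening_genes = 4,
                              max_gap_bp = 1e6), 1L)

  # different contigs always separate clusters
  gs <- generate_ancestor(simulation_params(n_proteins = 120, seed = 3,
                                            plant_fae_operon = FALSE))
  genes <- gs$genes
  genes$families[[1]] <- "faeA"           # first gene of contig 1
  per_ctg <- split(seq_len(nrow(genes)), genes$contig_id)
  genes$families[[per_ctg[[2]][1]]] <- "faeB"
  g4 <- genome_record("split", gs$contigs, genes)
  expect_length(find_clusters(g4, c("faeA", "faeB")), 2L)
})

test_that("operon matching flags completeness, insertions and unknown symbols", {
  m <- fae_model
  core <- match_operon(find_clusters(
    operon_genome("c1", c("faeD", "faeC", "faeA", "faeB")),
    c(m$core_order, m$accessory))[[1]], m)
  expect_true(core$core_complete)
  expect_length(core$insertions, 0L)
  expect_equal(core$architecture_string, "faeD-faeC-faeA-faeB")

  ins <- match_operon(find_clusters(
    operon_genome("c2", c("faeD", "dctP", "dctQ", "dctM", "faeC", "faeA", "faeB")),
    c(m$core_order, m$accessory))[[1]], m)
  expect_true(ins$core_complete)
  expect_setequal(ins$insertions, c("dctP", "dctQ", "dctM"))
  expect_equal(ins$architecture_string, "faeD-dctP-dctQ-dctM-faeC-faeA-faeB")

  solo <- match_operon(find_clusters(
    operon_genome("c3", "faeA"), m$core_order)[[1]], m)
  expect_false(solo$core_complete)

  odd <- match_operon(find_clusters(
    operon_genome("c4", c("faeD", "weird", "faeC", "faeA", "faeB")),
    c(m$core_order, "weird"))[[1]], m)
  expect_equal(odd$unknown, "weird")
  expect_true(odd$core_complete)
})

test_that("reverse-strand clusters are canonicalized before architecture emission", {
  m <- fae_model
  g <- operon_genome("rev", c("faeB", "faeA", "faeC", "faeD"),
                     strands = rep("-", 4))
  hit <- match_operon(find_clusters(g, m$core_order)[[1]], m)
  expect_equal(hit$architecture_string, "faeD-faeC-faeA-faeB")
  fwd <- match_operon(find_clusters(
    operon_genome("fwd", c("faeD", "faeC", "faeA", "faeB")), m$core_order)[[1]], m)
  expect_equal(compare_synteny(hit, fwd), 1)
})

test_that("motif scanning equals the sliding-window oracle and finds planted motifs", {
  expect_equal(scan_motif("CAACAACAAAC", "CxxCxxCxxxC"), 1L)
  expect_equal(scan_motif("MKLVNNNN", "CxxCxxCxxxC"), integer(0))
  expect_error(scan_motif("MKLV", "Cz"), "amino-acid letters")
  set.seed(55)
  for (trial in seq_len(40)) {
    s <- paste(sample(c("C", "A", "G"), 200, replace = TRUE,
                      prob = c(0.4, 0.3, 0.3)), collapse = "")
    pat <- sample(c("CxxCxxCxxxC", "CxxC", "GAC", "CC"), 1)
    expect_identical(scan_motif(s, pat), motif_oracle(s, pat),
                     label = paste("trial", trial, pat))
  }
  long <- paste(rep("CA", 250), collapse = "")
  expect_identical(scan_motif(long, "CxC"), motif_oracle(long, "CxC"))
})

test_that("planted operons are recovered and faeD carries two ferredoxin clusters", {
  for (seed in c(2L, 13L, 29L)) {
    p <- simulation_params(n_proteins = 130, seed = seed, dct_insertion = TRUE)
    g <- generate_ancestor(p)
    hits <- detect_operons(g, fae_model)
    complete <- Filter(function(h) h$core_complete, hits)
    expect_length(complete, 1L)
    expect_setequal(complete[[1]]$insertions, c("dctP", "dctQ", "dctM"))
    faeD <- g$genes$protein[vapply(g$genes$families, function(f) "faeD" %in% f, TRUE)]
    expect_gte(length(scan_motif(faeD, "CxxCxxCxxxC")), 2L)
  }
})

test_that("synteny similarity is the Jaccard x order-conservation product", {
  m <- fae_model
  mk <- function(id, labels) match_operon(find_clusters(
    operon_genome(id, labels), c(m$core_order, m$accessory, "bssA", "bssB"))[[1]], m)
  a <- mk("sa", c("faeD", "faeC", "faeA", "faeB"))
  expect_equal(compare_synteny(a, a), 1)
  b <- mk("sb", c("bssA", "bssB"))
  expect_equal(compare_synteny(a, b), 0)
  # faeDCAB vs faeBACD: shared = 4/4, LCS of (D,C,A,B) vs (B,A,C,D) = 1
  r <- mk("sc", c("faeB", "faeA", "faeC", "faeD"))
  expect_equal(compare_synteny(a, r), 1 * 1 / 4)
  expect_equal(compare_synteny(r, a), compare_synteny(a, r))
  # partial overlap: shared {faeC, faeA, faeB} of 5 symbols, order conserved
  pp <- mk("sd", c("dctP", "faeC", "faeA", "faeB"))
  expect_equal(compare_synteny(a, pp), (3 / 5) * (3 / 3))
})

test_that("operons split across contigs are flagged", {
  p <- simulation_params(n_proteins = 120, seed = 3, plant_fae_operon = FALSE)
  base <- generate_ancestor(p)
  genes <- base$genes
  per_ctg <- split(seq_len(nrow(genes)), genes$contig_id)
  genes$families[[per_ctg[[1]][1]]] <- "faeD"
  genes$families[[per_ctg[[1]][2]]] <- "faeC"
  genes$families[[per_ctg[[2]][1]]] <- "faeA"
  genes$families[[per_ctg[[2]][2]]] <- "faeB"
  g <- genome_record("frag", base$contigs, genes)
  hits <- detect_operons(g, fae_model)
  expect_true(all(vapply(hits, `[[`, TRUE, "split_across_contigs")))
  expect_false(any(vapply(hits, `[[`, TRUE, "core_complete")))
})
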