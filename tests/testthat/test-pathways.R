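row_from <- function(symbols, catalog) {
  v <- setNames(as.integer(catalog %in% symbols), catalog)
  v
}

test_that("presence matrix reflects family labels", {
  g1 <- toy_genome("g1", c("MKLV", "MKLW"), labels = list("faeA", character(0)))
  g0 <- toy_genome("g0", "MKLV")
  m <- build_presence_matrix(list(g1 = g1, g0 = g0), c("faeA", "faeB"))
  expect_equal(m["g1", ], c(faeA = 1L, faeB = 0L))
  expect_equal(unname(m["g0", ]), c(0L, 0L))
  expect_error(build_presence_matrix(list(g1 = g1), character(0)), "empty gene catalog")
})

test_that("dual presence standards: 75% for described, all steps for novel", {
  steps10 <- lapply(sprintf("s%02d", 1:10), identity)
  desc <- pathway_definition("p", steps10, "previously_described")
  nov <- pathway_definition("p", steps10, "novel")
  syms8 <- sprintf("s%02d", 1:8)
  expect_equal(call_pathway(syms8, desc)$status, "present")   # 0.8 >= 0.75
  expect_equal(call_pathway(syms8, nov)$status, "absent")     # 8 of 10
  syms9 <- sprintf("s%02d", 1:9)
  expect_equal(call_pathway(syms9, nov)$status, "absent")     # 9 of 10
  expect_equal(call_pathway(sprintf("s%02d", 1:10), nov)$status, "present")
  # inclusive boundary: exactly 75% of steps
  steps4 <- lapply(c("a", "b", "c", "d"), identity)
  desc4 <- pathway_definition("q", steps4, "previously_described")
  expect_equal(call_pathway(c("a", "b", "c"), desc4)$status, "present")
  expect_equal(call_pathway(c("a", "b"), desc4)$status, "absent")
  # alternatives collapse within a step
  alt <- pathway_definition("r", list(c("pfk", "pfp"), "fba"), "novel")
  expect_equal(call_pathway(c("pfp", "fba"), alt)$status, "present")
})

test_that("novel-rule presence implies described-rule presence, and calls are monotone", {
  set.seed(17)
  catalog <- sprintf("s%02d", 1:12)
  for (trial in seq_len(60)) {
    n_steps <- sample(1:6, 1)
    steps <- replicate(n_steps, sample(catalog, sample(1:2, 1)), simplify = FALSE)
    pd_desc <- pathway_definition("p", steps, "previously_described")
    pd_nov <- pathway_definition("p", steps, "novel")
    present <- sample(catalog, sample(0:12, 1))
    c_nov <- call_pathway(present, pd_nov)
    c_desc <- call_pathway(present, pd_desc)
    if (c_nov$status == "present") expect_equal(c_desc$status, "present")
    # monotonicity: adding one more detected gene never flips present -> absent
    extra <- sample(catalog, 1)
    more <- union(present, extra)
    for (pd in list(pd_desc, pd_nov)) {
      before <- call_pathway(present, pd)
      after <- call_pathway(more, pd)
      expect_gte(after$fraction_detected, before$fraction_detected)
      if (before$status == "present") expect_equal(after$status, "present")
    }
  }
})

lineage_toy <- function(tiers, detected, lineage = "L1") {
  stopifnot(length(tiers) == length(detected))
  lapply(seq_along(tiers), function(i) {
    g <- toy_genome(sprintf("m%d", i), "MKLV",
                    labels = list(if (detected[i]) "geneX" else character(0)))
    g$lineage <- lineage
    g$quality <- quality_estimate(
      c(High = 95, Medium = 70, Low = 30)[[tiers[i]]],
      c(High = 1, Medium = 6, Low = 15)[[tiers[i]]])
    g
  })
}

test_that("lineage-level status follows the quality-conditioned rule exactly", {
  # spot checks from the rule statement
  expect_equal(call_lineage_gene_status(
    lineage_toy(c("High", "Medium", "Medium"), c(TRUE, TRUE, TRUE)), "geneX")$status,
    "present")
  expect_equal(call_lineage_gene_status(
    lineage_toy(c("High", "High", "Low"), c(FALSE, FALSE, FALSE)), "geneX")$status,
    "absent")
  expect_equal(call_lineage_gene_status(
    lineage_toy(c("Medium", "Medium", "Medium"), c(TRUE, FALSE, FALSE)), "geneX")$status,
    "uncertain")
  expect_warning(
    st <- call_lineage_gene_status(lineage_toy("Low", FALSE), "geneX")$status,
    "no Medium-or-High")
  expect_equal(st, "uncertain")

  # exhaustive enumeration over all 3-genome tier x detection configurations,
  # against an independent restatement of the precedence table
  oracle <- function(tiers, det) {
    mh <- tiers %in% c("Medium", "High")
    if (!any(mh)) return("uncertain")
    if (all(det[mh])) return("present")
    if (!any(det) && any(tiers == "High")) return("absent")
    "uncertain"
  }
  tiers_all <- expand.grid(rep(list(c("High", "Medium", "Low")), 3),
                           stringsAsFactors = FALSE)
  det_all <- expand.grid(rep(list(c(TRUE, FALSE)), 3))
  for (i in seq_len(nrow(tiers_all))) for (j in seq_len(nrow(det_all))) {
    tiers <- unlist(tiers_all[i, ]); det <- unlist(det_all[j, ])
    got <- suppressWarnings(
      call_lineage_gene_status(lineage_toy(tiers, det), "geneX")$status)
    expect_equal(got, oracle(tiers, det),
                 label = paste(paste(tiers, collapse = ","), "/",
                               paste(det, collapse = ",")))
  }
})

test_that("lineage status is order-invariant and unaffected by Low-quality genomes", {
  set.seed(3)
  for (trial in seq_len(30)) {
    n <- sample(2:5, 1)
    tiers <- sample(c("High", "Medium", "Low"), n, replace = TRUE)
    det <- sample(c(TRUE, FALSE), n, replace = TRUE)
    gs <- lineage_toy(tiers, det)
    s1 <- suppressWarnings(call_lineage_gene_status(gs, "geneX")$status)
    perm <- sample(n)
    s2 <- suppressWarnings(call_lineage_gene_status(gs[perm], "geneX")$status)
    expect_equal(s1, s2)
    # dropping an undetected Low genome never changes a present/absent call
    drop <- which(tiers == "Low" & !det)
    if (length(drop) && n > 1 && s1 != "uncertain") {
      s3 <- suppressWarnings(
        call_lineage_gene_status(gs[-drop[1]], "geneX")$status)
      expect_equal(s3, s1)
    }
  }
})

test_that("CAZyme filter keeps only hits passing both thresholds", {
  hits <- data.frame(
    protein_id = sprintf("p%d", 1:6), model_id = "GH13",
    e_value = c(1e-20, 1e-10, 1e-20, 1e-10, 1e-18, 1e-17),
    model_coverage = c(0.5, 0.9, 0.1, 0.2, 0.35, 0.36))
  kept <- filter_cazy_hits(hits)
  expect_equal(kept$protein_id, c("p1", "p5"))
  expect_equal(nrow(filter_cazy_hits(hits[c(2, 4), ])), 0L)
  expect_equal(filter_cazy_hits(data.frame(protein_id = "a", model_id = "m",
                                           e_value = 1e-20, model_coverage = 0.5))$protein_id,
               "a")
})
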