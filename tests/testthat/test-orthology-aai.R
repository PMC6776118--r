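scheme <- scoring_scheme()

test_that("align_pair matches identity and Karlin-Altschul expectations", {
  h <- align_pair("PEPTIDE", "PEPTIDE", scheme)
  expect_equal(h$percent_identity, 100)
  h2 <- align_pair("PEPTIDE", "PEPSIDE", scheme)
  expect_equal(h2$aligned_length, 7L)
  expect_equal(h2$percent_identity, 100 * 6 / 7)
  set.seed(7)
  self <- rand_protein(200)
  h3 <- align_pair(self, self, scheme)
  expect_lt(h3$e_value, 1e-5)
  expect_equal(h3$bit_score,
               (scheme$lambda * h3$raw_score - log(scheme$K)) / log(2))
  expect_error(align_pair("", "PEPTIDE", scheme), "empty sequence")
  expect_error(align_pair("PEPB1DE", "PEPTIDE", scheme), "unknown residue")
})

test_that("compiled Smith-Waterman agrees with the brute-force oracle", {
  set.seed(101)
  for (trial in seq_len(200)) {
    a <- rand_protein(sample(1:30, 1))
    b <- rand_protein(sample(1:30, 1))
    h <- align_pair(a, b, scheme)
    expect_identical(h$raw_score, as.integer(sw_oracle_score(a, b, scheme)),
                     label = sprintf("trial %d: %s vs %s", trial, a, b))
  }
})

test_that("top_hit picks the highest score, breaks ties lexicographically, and can decline", {
  set.seed(11)
  target <- rand_protein(120)
  decoys <- replicate(5, rand_protein(120))
  db <- toy_genome("db", c(decoys, target))
  hit <- top_hit(target, db, scheme)
  expect_equal(hit$subject_id, "db_g06")
  expect_equal(hit$percent_identity, 100)

  # two identical subjects: lexicographically smaller gene id wins
  db2 <- toy_genome("tie", c(target, target))
  hit2 <- top_hit(target, db2, scheme)
  expect_equal(hit2$subject_id, "tie_g01")

  # nothing below the E-value threshold
  short_db <- toy_genome("na", replicate(3, rand_protein(20)))
  expect_null(top_hit(rand_protein(20), short_db, scheme))
})

test_that("reciprocal orthologs are mutual top hits and transpose-symmetric", {
  set.seed(23)
  p <- simulation_params(n_proteins = 120, fragmentation = 3, seed = 31)
  anc <- generate_ancestor(p, genome_id = "A")
  desc <- mutate_descendant(anc, 0.15, seed = 32, genome_id = "B")
  ab <- reciprocal_orthologs(anc, desc, scheme)
  ba <- reciprocal_orthologs(desc, anc, scheme)
  expect_equal(nrow(ab), nrow(ba))
  key_ab <- paste(ab$gene_a, ab$gene_b)
  key_ba <- paste(ba$gene_b, ba$gene_a)
  expect_setequal(key_ab, key_ba)

  # identical proteomes: every protein pairs with its copy
  twin <- mutate_descendant(anc, 0, seed = 1, genome_id = "twin")
  self_pairs <- reciprocal_orthologs(anc, twin, scheme)
  expect_equal(nrow(self_pairs), nrow(anc$genes))
  expect_true(all(self_pairs$percent_identity == 100))
})

test_that("non-mutual best hits are excluded", {
  # b1 equals a2 exactly; a1 is a slightly perturbed a2. a1's best is b1,
  # but b1's best is a2, so (a1, b1) must not be paired.
  set.seed(5)
  base <- rand_protein(100)
  perturbed <- sub("^(.{10}).", "\\1W", base)  # one substitution at site 11
  if (perturbed == base) perturbed <- sub(".$", "W", base)
  ga <- toy_genome("ga", c(perturbed, base))   # a1 = perturbed, a2 = base
  gb <- toy_genome("gb", base)                 # b1 = base
  pairs <- reciprocal_orthologs(ga, gb, scheme)
  expect_equal(pairs$gene_a, "ga_g02")
  expect_equal(pairs$gene_b, "gb_g01")
})

test_that("AAI is the unweighted mean with a reliability flag", {
  pairs <- data.frame(gene_a = c("a", "b"), gene_b = c("x", "y"),
                      percent_identity = c(90, 70))
  r <- compute_aai(pairs, "A", "B", min_orthologs = 2)
  expect_equal(r$aai, 80)
  expect_true(r$reliable)
  r2 <- compute_aai(pairs, "A", "B", min_orthologs = 20)
  expect_false(r2$reliable)
  r0 <- compute_aai(pairs[0, ], "A", "B")
  expect_true(is.na(r0$aai))
  expect_equal(r0$n_orthologs, 0L)
})

test_that("AAI self-identity and divergence recovery", {
  p <- simulation_params(n_proteins = 120, fragmentation = 3, seed = 77)
  g <- generate_ancestor(p, genome_id = "self")
  self <- aai_between(g, mutate_descendant(g, 0, seed = 1, genome_id = "self2"),
                      scheme)
  expect_equal(self$aai, 100)
  d <- mutate_descendant(g, 0.1, seed = 2)
  r <- aai_between(g, d, scheme)
  expect_lt(abs(r$aai - 90), 2)
})

test_that("rank assignment is a monotone step function with the published bands", {
  expect_equal(assign_rank(75), "same_genus")
  expect_equal(assign_rank(62), "same_family")
  expect_equal(assign_rank(96), "same_species")
  expect_equal(assign_rank(44.9), "above_family")
  # boundaries: half-open bands, species closed at 100
  expect_equal(assign_rank(45), "same_family")
  expect_equal(assign_rank(65), "same_genus")
  expect_equal(assign_rank(95), "same_species")
  expect_equal(assign_rank(100), "same_species")
  expect_error(assign_rank(101), "\\[0, 100\\]")
  ranks <- vapply(seq(0, 100, by = 0.5), assign_rank, "")
  lev <- c("above_family", "same_family", "same_genus", "same_species")
  expect_true(all(diff(match(ranks, lev)) >= 0))
})

test_that("genus grouping is single linkage on the AAI threshold", {
  m1 <- matrix(99, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(unname(cluster_genus_groups(m1)), rep(1L, 3))
  m2 <- matrix(c(100, 70, 50, 70, 100, 70, 50, 70, 100), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(length(unique(cluster_genus_groups(m2))), 1L)  # chained via b
  m3 <- matrix(40, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(m3) <- 100
  expect_equal(length(unique(cluster_genus_groups(m3))), 3L)
  m_bad <- m3; m_bad[1, 2] <- 80
  expect_error(cluster_genus_groups(m_bad), "symmetric")
})

test_that("contig assignment needs >98% identity and >80% footprint", {
  set.seed(9)
  prots <- replicate(3, rand_protein(100))
  g <- toy_genome("q", prots, spacer = 10L)  # 3 x 300 bp CDS on a 930 bp contig
  ref <- toy_genome("ref", prots)
  res <- map_contig_to_reference(g, "q_c1", ref, scheme)
  expect_true(res$assigned)
  expect_gt(res$covered_fraction, 0.8)

  # ~97% identity: below the strict cutoff
  mut <- vapply(prots, function(pr) {
    ch <- strsplit(pr, "")[[1]]
    idx <- seq(1, 100, by = 33)
    ch[idx] <- vapply(ch[idx], function(r) setdiff(AA, r)[1], "")
    paste(ch, collapse = "")
  }, "")
  g97 <- toy_genome("q97", mut, spacer = 10L)
  expect_false(map_contig_to_reference(g97, "q97_c1", ref, scheme)$assigned)

  # perfect identity but sparse footprint (wide spacers)
  g_sparse <- toy_genome("qs", prots[1], spacer = 700L)
  expect_false(map_contig_to_reference(g_sparse, "qs_c1", ref, scheme)$assigned)
})

test_that("alignment-column trimming drops only columns with >95% gaps", {
  rows96 <- c(rep("-A", 24), "CA")          # 24/25 = 96% gaps in column 1
  expect_equal(trim_alignment_columns(rows96), substr(rows96, 2, 2))
  rows95 <- c(rep("-A", 19), "CA")          # 19/20 = 95%: retained
  expect_equal(trim_alignment_columns(rows95), rows95)
  expect_error(trim_alignment_columns(c("AB", "ABC")), "ragged")

  set.seed(33)
  msa <- replicate(40, paste(sample(c("-", "A", "C", "D"), 30, replace = TRUE,
                                    prob = c(0.85, 0.05, 0.05, 0.05)),
                             collapse = ""))
  trimmed <- trim_alignment_columns(msa)
  chars <- do.call(rbind, strsplit(msa, ""))
  keep <- colMeans(chars == "-") <= 0.95
  oracle <- apply(chars[, keep, drop = FALSE], 1, paste, collapse = "")
  expect_equal(trimmed, oracle)
})
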