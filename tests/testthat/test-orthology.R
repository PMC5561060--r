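write_hits <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

test_that("read_blast_hits parses outfmt-6 and reports bad lines", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  h <- SIM$hits$hits
  write_hits(h, tf)
  back <- read_blast_hits(tf)
  expect_equal(nrow(back), nrow(h))
  expect_equal(back$bitscore, h$bitscore)
  writeLines(c(paste(rep("x", 12), collapse = "\t")), tf)
  expect_error(read_blast_hits(tf), "line 1.*non-numeric")
  writeLines("a\tb\tc", tf)
  expect_error(read_blast_hits(tf), "expected 12 fields")
  writeLines(character(), tf)
  expect_equal(nrow(read_blast_hits(tf)), 0L)
})

test_that("sequence_matches filters, deduplicates and matches a threshold oracle", {
  empty <- sequence_matches(read_blast_hits(withr::local_tempfile(
    fileext = ".tsv", lines = character())))
  expect_equal(nrow(empty), 0L)
  two <- data.frame(qseqid = "m1", sseqid = "h1", pident = c(80, 85),
                    length = 100, mismatch = 10, gapopen = 0, qstart = 1,
                    qend = 100, sstart = 1, send = 100, evalue = 1e-20,
                    bitscore = c(50, 80))
  got <- sequence_matches(two)
  expect_equal(nrow(got), 1L)
  expect_equal(got$similarity_score, 80)
  # random table vs independent filter
  set.seed(14)
  n <- 120
  tab <- data.frame(qseqid = sample(sprintf("m%02d", 1:15), n, TRUE),
                    sseqid = sample(sprintf("h%02d", 1:15), n, TRUE),
                    pident = runif(n, 30, 100), length = 100, mismatch = 0,
                    gapopen = 0, qstart = 1, qend = 100, sstart = 1,
                    send = 100, evalue = 10^-runif(n, 0, 30),
                    bitscore = runif(n, 30, 300))
  got <- sequence_matches(tab, min_identity = 60, max_evalue = 1e-5)
  pass <- tab[tab$pident >= 60 & tab$evalue <= 1e-5, ]
  want <- vapply(split(pass$bitscore, paste(pass$qseqid, pass$sseqid)),
                 max, 0)
  expect_equal(stats::setNames(got$similarity_score,
                               paste(got$mouse_gene, got$human_gene)),
               want[paste(got$mouse_gene, got$human_gene)])
  expect_equal(nrow(got), length(want))
})

toy_anchors <- function() {
  data.frame(
    mouse_chrom = "chr1", mouse_start = c(1000, 20000, 40000),
    mouse_end = c(3000, 22000, 42000),
    mouse_gene = c("A", "B", "C"),
    human_chrom = "hchr1", human_start = c(5000, 24000, 44000),
    human_end = c(7000, 26000, 46000),
    human_gene = c("hA", "hB", "hC"),
    orientation = "same", stringsAsFactors = FALSE)
}

test_that("synteny_matches finds planted pairs between flanking anchors", {
  anchors <- toy_anchors()
  mouse_lnc <- data.frame(gene_id = "lnc1", chrom = "chr1",
                          start = 10000, end = 12000)
  human_lnc <- data.frame(gene_id = c("hlnc1", "far"), chrom = "hchr1",
                          start = c(14000, 100000), end = c(16000, 101000),
                          strand = "+")
  got <- synteny_matches(mouse_lnc, human_lnc, anchors)
  expect_equal(got$human_gene, "hlnc1")
  expect_equal(got$synteny_score, 1)

  # two human lncRNAs in the window dilute the score to 1/2
  human2 <- rbind(human_lnc,
                  data.frame(gene_id = "hlnc2", chrom = "hchr1",
                             start = 17000, end = 18000, strand = "+"))
  got2 <- synteny_matches(mouse_lnc, human2, anchors)
  expect_equal(sort(got2$human_gene), c("hlnc1", "hlnc2"))
  expect_equal(got2$synteny_score, c(0.5, 0.5))

  # inverted local order (swap the two flanking anchors on the human side):
  # the window is the reflected span and the pair is still found
  anchors_inv <- anchors
  anchors_inv[1:2, c("human_start", "human_end")] <-
    anchors[2:1, c("human_start", "human_end")]
  anchors_inv$orientation[1:2] <- "inverted"
  got3 <- synteny_matches(mouse_lnc, human_lnc, anchors_inv)
  expect_equal(got3$human_gene, "hlnc1")

  # no downstream anchor -> no candidates, warning report
  lone <- data.frame(gene_id = "lnc2", chrom = "chr1",
                     start = 50000, end = 51000)
  expect_warning(got4 <- synteny_matches(lone, human_lnc, anchors),
                 "flanking anchor")
  expect_equal(nrow(got4), 0L)
  expect_equal(attr(got4, "unplaced"), "lnc2")
})

test_that("resolve_orthologs is a deterministic greedy 1:1 matching", {
  cand <- data.frame(
    mouse_gene = c("m1", "m1"), human_gene = c("h1", "h2"),
    evidence = "sequence", similarity_score = c(80, 50),
    synteny_score = NA_real_)
  got <- resolve_orthologs(cand)
  expect_equal(got$human_gene, "h1")
  # score-tied 2x2 block resolves by lexicographic ids
  tied <- data.frame(
    mouse_gene = c("m1", "m1", "m2", "m2"),
    human_gene = c("h1", "h2", "h1", "h2"),
    evidence = "synteny", similarity_score = NA_real_, synteny_score = 0.5)
  got2 <- resolve_orthologs(tied)
  expect_equal(got2$mouse_gene, c("m1", "m2"))
  expect_equal(got2$human_gene, c("h1", "h2"))
  expect_equal(resolve_orthologs(tied), got2)   # deterministic
  # evidence union outranks either single source
  dual <- data.frame(
    mouse_gene = c("m1", "m1"), human_gene = c("h1", "h2"),
    evidence = c("synteny", "sequence"),
    similarity_score = c(NA, 500), synteny_score = c(1, NA))
  dual <- rbind(dual, data.frame(mouse_gene = "m1", human_gene = "h1",
                                 evidence = "sequence",
                                 similarity_score = 10,
                                 synteny_score = NA))
  got3 <- resolve_orthologs(dual)
  expect_equal(got3$human_gene, "h1")
  expect_equal(got3$evidence, "sequence,synteny")
})

test_that("resolution satisfies the matching properties on random instances", {
  set.seed(99)
  for (rep in 1:40) {
    nm <- sample(2:8, 1); nh <- sample(2:8, 1)
    n <- sample(3:12, 1)
    cand <- data.frame(
      mouse_gene = sample(sprintf("m%d", 1:nm), n, TRUE),
      human_gene = sample(sprintf("h%d", 1:nh), n, TRUE),
      evidence = sample(c("sequence", "synteny"), n, TRUE),
      similarity_score = ifelse(runif(n) < 0.5, NA, round(runif(n, 10, 99))),
      synteny_score = ifelse(runif(n) < 0.5, NA,
                             round(runif(n, 0.1, 1), 2)))
    res <- resolve_orthologs(cand)
    merged <- attr(res, "merged_candidates")
    expect_true(verify_matching(res, merged))
    expect_lte(nrow(res), min(length(unique(cand$mouse_gene)),
                              length(unique(cand$human_gene))))
    # evidence bookkeeping conserves counts over the merged candidates
    ev <- merged$evidence
    expect_equal(sum(ev == "sequence") + sum(ev == "synteny") +
                   sum(ev == "sequence,synteny"), nrow(merged))
  }
})

test_that("ortholog expression clustering recovers planted archetypes", {
  set.seed(7)
  n_per <- 10
  pairs <- data.frame(mouse_gene = sprintf("m%02d", 1:(3 * n_per)),
                      human_gene = sprintf("h%02d", 1:(3 * n_per)))
  arch <- rep(1:3, each = n_per)
  mouse_med <- c(12, 12, 0.3)[arch]
  human_med <- c(20, 2, 0.3)[arch]
  mk <- function(med, n_s, prefix) {
    m <- matrix(2^(log2(med) + rnorm(length(med) * n_s, 0, 0.2)),
                length(med), n_s)
    dimnames(m) <- list(NULL, sprintf("%s%d", prefix, 1:n_s))
    m
  }
  me <- mk(mouse_med, 12, "ms")
  rownames(me) <- pairs$mouse_gene
  he <- mk(human_med, 6, "hs")
  rownames(he) <- pairs$human_gene
  mouse_em <- expression_matrix(me, unit = "fpkm")
  human_em <- expression_matrix(he, unit = "fpkm")
  got <- cluster_ortholog_expression(pairs, mouse_em, human_em, k = 3)
  expect_true(all(got$expression_group == arch))  # labels ordered by human level
  # k = 1 puts everything together; duplicated vectors share a label
  expect_true(all(cluster_ortholog_expression(pairs, mouse_em, human_em,
                                              k = 1)$expression_group == 1))
  # permutation invariance of the labelling
  perm <- sample(nrow(pairs))
  got_p <- cluster_ortholog_expression(pairs[perm, ], mouse_em, human_em,
                                       k = 3)
  expect_equal(got_p$expression_group[order(perm)], got$expression_group)
  # pairs with missing expression are excluded with a report
  pairs2 <- rbind(pairs, data.frame(mouse_gene = "absent",
                                    human_gene = "h01"))
  got2 <- cluster_ortholog_expression(pairs2, mouse_em, human_em, k = 3)
  expect_equal(nrow(got2), nrow(pairs))
  expect_equal(attr(got2, "excluded")$mouse_gene, "absent")
})
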