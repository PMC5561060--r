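test_that("GTF coordinates convert between 1-based input and internal 0-based", {
  tf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\texon\t101\t200\t.\t+\t.\t",
           'transcript_id "t1"; gene_id "g1";'),
    paste0("chr1\tsrc\texon\t301\t400\t.\t+\t.\t",
           'transcript_id "t1"; gene_id "g1";'),
    paste0("chr1\tsrc\tCDS\t120\t180\t.\t+\t.\t",
           'transcript_id "t1"; gene_id "g1";')), tf)
  ts <- parse_gtf(tf)
  expect_equal(ts$exons$start, c(100, 300))
  expect_equal(ts$exons$end, c(200, 400))
  expect_equal(ts$tx$mature_length, 200)
  expect_equal(ts$tx$n_exons, 2L)
})

test_that("malformed GTF rows abort with the offending line number", {
  tf <- withr::local_tempfile(fileext = ".gtf")
  good <- paste0("chr1\tsrc\texon\t101\t200\t.\t+\t.\t",
                 'transcript_id "t1"; gene_id "g1";')
  writeLines(c(good, "chr1\tsrc\texon\tbroken"), tf)
  expect_error(parse_gtf(tf), "line 2")
  writeLines(c(good,
               paste0("chr1\tsrc\texon\t500\t400\t.\t+\t.\t",
                      'transcript_id "t2"; gene_id "g2";')), tf)
  expect_error(parse_gtf(tf), "line 2.*end < start")
  writeLines(c(good,
               paste0("chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id \"g\";")),
             tf)
  expect_error(parse_gtf(tf), "line 2.*transcript_id")
})

test_that("write_gtf and parse_gtf are inverse on a random transcript set", {
  adv <- simulate_adversarial_transcripts(n = 500, seed = 11)
  tf <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(adv$ts, tf)
  back <- parse_gtf(tf)
  expect_equal(back$exons, adv$ts$exons)
  expect_equal(back$tx, adv$ts$tx)
  # biotypes survive too
  tf2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(SIM$ann$reference, tf2)
  back2 <- parse_gtf(tf2)
  expect_equal(back2$tx$biotype, SIM$ann$reference$tx$biotype)
  # empty set round-trips to a valid empty file
  tf3 <- withr::local_tempfile(fileext = ".gtf")
  empty <- subset_transcripts(adv$ts, character())
  expect_silent(write_gtf(empty, tf3))
  expect_equal(nrow(parse_gtf(tf3)$tx), 0L)
})

test_that("transcript_set enforces its invariants", {
  bad <- data.frame(transcript_id = "t", gene_id = "g", chrom = "chr1",
                    start = c(100, 150), end = c(200, 260), strand = "+")
  expect_error(transcript_set(bad), "overlapping exons")
  bad2 <- data.frame(transcript_id = "t", gene_id = "g",
                     chrom = c("chr1", "chr2"), start = c(1, 300),
                     end = c(100, 400), strand = "+")
  expect_error(transcript_set(bad2), "multiple chromosomes")
  bad3 <- data.frame(transcript_id = "t", gene_id = "g", chrom = "chr1",
                     start = 100, end = 100, strand = "+")
  expect_error(transcript_set(bad3), "end <= start")
})

test_that("exonic_overlap matches the per-base oracle and is symmetric", {
  adv <- simulate_adversarial_transcripts(n = 120, chrom_len = 30000,
                                          seed = 5)
  ids <- adv$ts$tx$transcript_id
  for (mode in c("same", "opposite", "ignore")) {
    got <- exonic_overlap(adv$ts, adv$ts, mode)
    got_t <- stats::setNames(got$overlap_bp, paste(got$tx_a, got$tx_b))
    set.seed(1)
    pairs <- cbind(sample(ids, 250, replace = TRUE),
                   sample(ids, 250, replace = TRUE))
    for (k in seq_len(nrow(pairs))) {
      ea <- adv$ts$exons[adv$ts$exons$transcript_id == pairs[k, 1], ]
      eb <- adv$ts$exons[adv$ts$exons$transcript_id == pairs[k, 2], ]
      want <- oracle_exonic_overlap(ea, eb, mode)
      have <- got_t[paste(pairs[k, 1], pairs[k, 2])]
      expect_equal(unname(ifelse(is.na(have), 0, have)), want)
    }
    # symmetry: transposing the pair table gives the same relation
    expect_setequal(paste(got$tx_a, got$tx_b, got$overlap_bp),
                    paste(got$tx_b, got$tx_a, got$overlap_bp))
  }
  # identical transcripts overlap by the mature length
  one <- subset_transcripts(adv$ts, ids[1])
  self <- exonic_overlap(one, one, "same")
  expect_equal(self$overlap_bp, one$tx$mature_length)
})

test_that("strand '.' is incomparable under strand-aware overlap", {
  ts <- transcript_set(data.frame(
    transcript_id = c("a", "b"), gene_id = c("a", "b"), chrom = "chr1",
    start = c(0, 0), end = c(500, 500), strand = c(".", "+")))
  expect_warning(got <- exonic_overlap(ts, ts, "same"), "incomparable")
  expect_false(any(got$tx_a == "a" | got$tx_b == "a"))
})

test_that("gene_distance matches brute force and is symmetric and monotone", {
  expect_equal(gene_distance(genomic_intervals("chr1", 100, 200),
                             genomic_intervals("chr1", 150, 300)), 0)
  expect_equal(gene_distance(genomic_intervals("chr1", 100, 200),
                             genomic_intervals("chr1", 500, 600)), 300)
  expect_true(is.na(gene_distance(genomic_intervals("chr1", 1, 10),
                                  genomic_intervals("chr2", 1, 10))))
  set.seed(9)
  for (k in 1:300) {
    a <- list(chrom = sample(c("c1", "c2"), 1),
              start = sample(0:5000, 1))
    a$end <- a$start + sample(1:500, 1)
    b <- list(chrom = sample(c("c1", "c2"), 1),
              start = sample(0:5000, 1))
    b$end <- b$start + sample(1:500, 1)
    want <- oracle_gene_distance(a, b)
    have <- gene_distance(as.data.frame(a), as.data.frame(b))
    expect_equal(have, want)
    expect_equal(have, gene_distance(as.data.frame(b), as.data.frame(a)))
    if (a$chrom == b$chrom && b$start >= a$end) {
      shifted <- as.data.frame(b)
      shifted$start <- shifted$start + 100
      shifted$end <- shifted$end + 100
      expect_gte(gene_distance(as.data.frame(a), shifted), have)
    }
  }
})

test_that("gene grouping is the transitive closure and partitions the input", {
  adv <- simulate_adversarial_transcripts(n = 80, chrom_len = 20000,
                                          seed = 3)
  ids <- adv$ts$tx$transcript_id
  for (mode in c("same_strand_exonic", "any_overlap")) {
    gs <- group_transcripts_into_genes(adv$ts, mode = mode)
    # partition: every transcript in exactly one gene
    expect_setequal(gs$members$transcript_id, ids)
    expect_equal(anyDuplicated(gs$members$transcript_id), 0L)
    # oracle components from pairwise relation
    n <- length(ids)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        ei <- adv$ts$exons[adv$ts$exons$transcript_id == ids[i], ]
        ej <- adv$ts$exons[adv$ts$exons$transcript_id == ids[j], ]
        adj[i, j] <- if (mode == "same_strand_exonic") {
          oracle_exonic_overlap(ei, ej, "same") > 0
        } else {
          ei$chrom[1] == ej$chrom[1] &&
            min(ei$start) < max(ej$end) && min(ej$start) < max(ei$end)
        }
      }
    }
    comp <- oracle_components(adj)
    have <- gs$members$gene_id[match(ids, gs$members$transcript_id)]
    expect_equal(partition_sets(ids, have), partition_sets(ids, comp))
  }
})

test_that("grouping handles chains and strand splits as specified", {
  # A and B overlap only via C -> one gene of three
  ts <- transcript_set(data.frame(
    transcript_id = c("A", "B", "C"), gene_id = c("A", "B", "C"),
    chrom = "chr1", start = c(0, 900, 450), end = c(500, 1400, 950),
    strand = "+"))
  gs <- group_transcripts_into_genes(ts)
  expect_equal(nrow(gs$genes), 1L)
  expect_equal(gs$genes$n_transcripts, 3L)
  # opposite strands under same_strand_exonic -> two genes
  ts2 <- transcript_set(data.frame(
    transcript_id = c("A", "B"), gene_id = c("A", "B"), chrom = "chr1",
    start = c(0, 100), end = c(500, 600), strand = c("+", "-")))
  expect_equal(nrow(group_transcripts_into_genes(ts2)$genes), 2L)
  expect_equal(nrow(group_transcripts_into_genes(ts2, "any_overlap")$genes),
               1L)
})

test_that("BED round-trips and rejects malformed rows", {
  tf <- withr::local_tempfile(fileext = ".bed")
  df <- data.frame(chrom = c("chr1", "chr2"), start = c(0, 100),
                   end = c(50, 400), name = c("a", "b"), score = c(0, 0),
                   strand = c("+", "-"))
  write_bed(df, tf)
  back <- read_bed(tf)
  expect_equal(back$start, df$start)
  expect_equal(back$end, df$end)
  expect_equal(back$strand, df$strand)
  writeLines("chr1\t10", tf)
  expect_error(read_bed(tf), "fewer than 3")
})
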