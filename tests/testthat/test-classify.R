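test_that("find_orfs handles canonical and degenerate cases", {
  expect_equal(find_orfs("ATGTAA"), 1L)
  expect_equal(find_orfs("atgaaatga"), 2L)        # lower case, ATG AAA TGA
  expect_equal(find_orfs("CCCCCCCCCCCC"), 0L)     # no ATG
  expect_equal(find_orfs("ATGAAAAAA"), 0L)        # ORF without a stop
  expect_equal(find_orfs("GATGTAAT"), 1L)         # frame 1
  expect_equal(find_orfs("NNATGNNNTAANN"), 2L)    # N never matches ATG/stop
  expect_error(find_orfs("ATGXTAA"), "illegal character")
})

test_that("find_orfs equals an exhaustive codon-walk oracle", {
  seqs <- simulate_orf_sequences(n = 60, coding_fraction = 0.5,
                                 length_nt = 800, seed = 21)
  for (i in seq_len(nrow(seqs))) {
    expect_equal(find_orfs(seqs$sequence[i]),
                 oracle_longest_orf(seqs$sequence[i]))
    if (seqs$is_coding[i]) {
      expect_gte(find_orfs(seqs$sequence[i]), seqs$planted_orf_aa[i])
    }
  }
  # fully random sequences too (no planted structure)
  set.seed(4)
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 600, replace = TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
               collapse = "")
    expect_equal(find_orfs(s), oracle_longest_orf(s))
  }
})

test_that("coding_filter follows its truth table and never drops silently", {
  set.seed(8)
  n <- 200
  assess <- data.frame(
    transcript_id = sprintf("t%03d", 1:n),
    longest_orf_aa = sample(c(NA, 10:250), n, replace = TRUE),
    external_coding_score = sample(c(NA, seq(-50, 50, by = 5)), n,
                                   replace = TRUE),
    homology_hit = sample(c(TRUE, FALSE), n, replace = TRUE))
  ids <- c(assess$transcript_id, "missing1", "missing2")
  got <- coding_filter(ids, assess, orf_max_aa = 100, score_cutoff = 0)
  expect_equal(nrow(got), length(ids))
  for (i in seq_len(n)) {
    a <- assess[i, ]
    want <- if (is.na(a$longest_orf_aa) && !a$homology_hit &&
                is.na(a$external_coding_score)) {
      "needs_assessment"
    } else if ((!is.na(a$longest_orf_aa) && a$longest_orf_aa >= 100) ||
                 a$homology_hit ||
                 (!is.na(a$external_coding_score) &&
                    a$external_coding_score >= 0)) {
      "drop"
    } else {
      "keep"
    }
    expect_equal(got$status[i], want)
  }
  expect_true(all(got$status[got$transcript_id %in%
                               c("missing1", "missing2")] ==
                    "needs_assessment"))
})

mk_ts <- function(...) {
  rows <- list(...)
  transcript_set(do.call(rbind, lapply(rows, as.data.frame)))
}
exon_row <- function(tid, chrom, start, end, strand, gid = tid) {
  data.frame(transcript_id = tid, gene_id = gid, chrom = chrom,
             start = start, end = end, strand = strand)
}

test_that("classify_lncrna applies the documented decision order", {
  coding <- as_gene_set(mk_ts(
    exon_row("ct1", "chr1", c(10000, 11000, 16000), c(10400, 11500, 16400),
             "+", "cg1")))
  small <- data.frame(chrom = "chr1", start = 40500, end = 40600,
                      strand = "+", name = "mir")
  ts <- mk_ts(
    exon_row("short1", "chr1", 30000, 30150, "+"),          # 150 nt
    exon_row("anti1", "chr1", c(10200, 11200), c(10450, 11400), "-"),
    exon_row("intr1", "chr1", 12000, 12500, "+"),           # inside cg1 intron
    exon_row("intr2", "chr1", 12000, 12500, "-"),           # opposite strand
    exon_row("host1", "chr1", c(40000, 41000), c(40400, 41400), "+"),
    exon_row("linc1", "chr1", c(60000, 61000), c(60400, 61500), "-"),
    exon_row("samestrand1", "chr1", c(10200, 11200), c(10450, 11400), "+"),
    exon_row("lowexp1", "chr1", c(70000, 71000), c(70400, 71500), "+"))
  fpkm <- c(short1 = 5, anti1 = 5, intr1 = 5, intr2 = 5, host1 = 5,
            linc1 = 5, samestrand1 = 5, lowexp1 = 0.01)
  got <- classify_lncrna(ts, coding, small_rnas = small, max_fpkm = fpkm)
  cat_of <- stats::setNames(got$category, got$transcript_id)
  expect_equal(cat_of[["short1"]], "excluded_short")
  expect_equal(cat_of[["lowexp1"]], "excluded_low_expression")
  expect_equal(cat_of[["anti1"]], "antisense")
  expect_equal(cat_of[["samestrand1"]], "excluded_coding")
  expect_equal(cat_of[["intr1"]], "excluded_intronic_same_strand")
  expect_equal(cat_of[["intr2"]], "lincRNA")  # opposite strand in an intron
  expect_equal(cat_of[["host1"]], "small_rna_host")
  expect_equal(cat_of[["linc1"]], "lincRNA")
  # conservation: exactly one category per transcript
  expect_equal(sort(got$transcript_id), sort(ts$tx$transcript_id))
})

test_that("classification agrees with the per-base oracle on adversarial geometry", {
  adv <- simulate_adversarial_transcripts(n = 400, seed = 77)
  got <- classify_lncrna(adv$ts, adv$coding, small_rnas = adv$small_rnas,
                         max_fpkm = adv$max_fpkm)
  want <- oracle_classify_all(adv$ts, adv$coding, adv$small_rnas,
                              adv$max_fpkm)
  expect_equal(got$category[match(want$transcript_id, got$transcript_id)],
               want$category)
})

test_that("classification is invariant under translation and chrom renaming, and shortening forces excluded_short", {
  adv <- simulate_adversarial_transcripts(n = 120, seed = 13)
  base <- classify_lncrna(adv$ts, adv$coding, small_rnas = adv$small_rnas,
                          max_fpkm = adv$max_fpkm)
  shift <- function(ts, by, rename) {
    e <- ts$exons
    e$start <- e$start + by
    e$end <- e$end + by
    e$chrom <- rename[e$chrom]
    bt <- ts$tx$biotype
    names(bt) <- ts$tx$transcript_id
    transcript_set(e, biotype = bt)
  }
  rn <- c(chrA = "scaffold_9", chrB = "scaffold_4")
  ts2 <- shift(adv$ts, 1e6, rn)
  coding2 <- as_gene_set(shift(adv$coding$ts, 1e6, rn))
  small2 <- adv$small_rnas
  small2$start <- small2$start + 1e6
  small2$end <- small2$end + 1e6
  small2$chrom <- rn[small2$chrom]
  moved <- classify_lncrna(ts2, coding2, small_rnas = small2,
                           max_fpkm = adv$max_fpkm)
  expect_equal(moved$category[match(base$transcript_id,
                                    moved$transcript_id)],
               base$category)

  # decision-order property: truncating any transcript below 200 nt always
  # yields excluded_short, whatever its overlaps were
  some <- adv$ts$tx$transcript_id[1:20]
  short_exons <- do.call(rbind, lapply(some, function(tid) {
    e <- adv$ts$exons[adv$ts$exons$transcript_id == tid, ][1, ]
    e$end <- e$start + 150
    e
  }))
  shorts <- classify_lncrna(transcript_set(short_exons), adv$coding,
                            small_rnas = adv$small_rnas,
                            max_fpkm = adv$max_fpkm)
  expect_true(all(shorts$category == "excluded_short"))
})

test_that("classify_gene lifts transcript calls with host > antisense > lincRNA precedence", {
  ts <- mk_ts(exon_row("t1", "chr1", 0, 500, "+", "g1"),
              exon_row("t2", "chr1", 200, 900, "+", "g1"),
              exon_row("t3", "chr1", 5000, 5600, "+", "g2"),
              exon_row("t4", "chr1", 9000, 9600, "+", "g3"))
  gs <- as_gene_set(ts)
  calls <- data.frame(
    transcript_id = c("t1", "t2", "t3", "t4"),
    category = c("lincRNA", "antisense", "excluded_short", "small_rna_host"))
  got <- classify_gene(gs, calls)
  expect_equal(got$category[got$gene_id == "g1"], "antisense")
  expect_equal(got$category[got$gene_id == "g2"], "excluded")
  expect_equal(got$category[got$gene_id == "g3"], "small_rna_host")

  # random mixtures equal a max-under-precedence oracle
  set.seed(2)
  cats <- c("lincRNA", "antisense", "small_rna_host", "excluded_short",
            "excluded_coding")
  prec <- c(small_rna_host = 3, antisense = 2, lincRNA = 1,
            excluded_short = 0, excluded_coding = 0)
  for (rep in 1:30) {
    k <- sample(1:4, 1)
    cal <- data.frame(transcript_id = c("t1", "t2", "t3", "t4"),
                      category = sample(cats, 4, replace = TRUE))
    got <- classify_gene(gs, cal)
    for (g in c("g1", "g2", "g3")) {
      members <- gs$members$transcript_id[gs$members$gene_id == g]
      best <- max(prec[cal$category[cal$transcript_id %in% members]])
      want <- if (best == 0) "excluded" else names(prec)[match(best, prec)]
      expect_equal(got$category[got$gene_id == g], want)
    }
  }
})

test_that("call_novelty matches brute-force all-pairs overlap", {
  adv <- simulate_adversarial_transcripts(n = 120, chrom_len = 40000,
                                          seed = 31)
  ref <- simulate_adversarial_transcripts(n = 60, chrom_len = 40000,
                                          seed = 32)
  genes <- group_transcripts_into_genes(adv$ts)
  nov <- call_novelty(genes, ref$ts)
  for (i in seq_len(nrow(nov))) {
    members <- genes$members$transcript_id[
      genes$members$gene_id == nov$gene_id[i]]
    any_ov <- FALSE
    for (m in members) {
      em <- adv$ts$exons[adv$ts$exons$transcript_id == m, ]
      for (r in ref$ts$tx$transcript_id) {
        er <- ref$ts$exons[ref$ts$exons$transcript_id == r, ]
        if (oracle_exonic_overlap(em, er, "ignore") > 0) any_ov <- TRUE
      }
    }
    expect_equal(nov$novel[i], !any_ov)
  }
  expect_equal(sum(attr(nov, "counts")), nrow(nov))
  # gene on a chromosome absent from the reference is novel, with a warning
  lone <- transcript_set(exon_row("x1", "chrZ", 100, 900, "+"))
  gs <- group_transcripts_into_genes(lone)
  expect_warning(n2 <- call_novelty(gs, ref$ts), "chrZ")
  expect_true(all(n2$novel))
})
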