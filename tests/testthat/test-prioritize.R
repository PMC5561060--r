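grec <- function(chrom, start, end, strand, exons = NULL) {
  list(chrom = chrom, start = start, end = end, strand = strand,
       exons = exons)
}

test_that("label_relationship reproduces the documented precedence on worked cases", {
  # microRNA inside the intron of a two-exon lncRNA
  lnc <- grec("chr6", 30000, 46000, "+",
              exons = data.frame(start = c(30000, 44000),
                                 end = c(31000, 46000)))
  mir <- grec("chr6", 35000, 35100, "+")
  expect_equal(label_relationship(lnc, mir)$relationship, "host_in_intron")
  # gene overlapping the lncRNA exon -> contains, not host
  gene_in_exon <- grec("chr6", 30200, 30600, "+")
  expect_equal(label_relationship(lnc, gene_in_exon)$relationship,
               "contains")
  # lncRNA within a larger gene
  big <- grec("chr6", 20000, 60000, "+")
  expect_equal(label_relationship(lnc, big)$relationship, "within")
  # head-to-head divergent promoters 200 bp apart
  lnc2 <- grec("chr2", 9000, 9800, "-",
               exons = data.frame(start = 9000, end = 9800))
  gene2 <- grec("chr2", 10000, 15000, "+",
                exons = data.frame(start = c(10000, 12000),
                                   end = c(10500, 12500)))
  expect_equal(label_relationship(lnc2, gene2)$relationship,
               "overlapping_divergent")
  # same pair beyond the window is merely proximal, distance preserved
  gene3 <- grec("chr2", 11500, 15000, "+")
  got <- label_relationship(lnc2, gene3)
  expect_equal(got$relationship, "proximal")
  expect_equal(got$distance_bp, 1700)
  # antisense: opposite strands with exonic overlap
  anti <- grec("chr2", 9600, 10600, "+",
               exons = data.frame(start = 9600, end = 10600))
  expect_equal(label_relationship(lnc2, anti)$relationship, "antisense")
  # disjoint genes 249 bp apart
  a <- grec("chr14", 57109201, 57112912, "+")
  b <- grec("chr14", 57113161, 57120000, "+")
  got2 <- label_relationship(a, b)
  expect_equal(got2$relationship, "proximal")
  expect_equal(got2$distance_bp, 249)
  # different chromosomes: no relationship
  expect_true(is.na(label_relationship(a, grec("chr1", 1, 10, "+"))$relationship))
})

test_that("label_relationship equals a brute-force precedence oracle on random pairs", {
  set.seed(23)
  rand_rec <- function() {
    start <- sample(0:20000, 1)
    k <- sample(1:3, 1)
    w <- sample(100:800, k, replace = TRUE)
    gaps <- if (k > 1) sample(100:2000, k - 1, replace = TRUE) else integer()
    es <- start + cumsum(c(0, head(w, -1) + gaps))
    grec("c1", es[1], es[k] + w[k], sample(c("+", "-"), 1),
         exons = data.frame(start = es, end = es + w))
  }
  for (i in 1:400) {
    lnc <- rand_rec(); gene <- rand_rec()
    got <- label_relationship(lnc, gene)$relationship
    want <- oracle_relationship(lnc, gene)
    expect_equal(got, want)
  }
})

lnc_gs_from_spans <- function(df) {
  as_gene_set(transcript_set(data.frame(
    transcript_id = paste0("t_", df$gene_id), gene_id = df$gene_id,
    chrom = df$chrom, start = df$start, end = df$end, strand = df$strand)))
}

test_that("candidates_near_genes respects the 4 Mb boundary and nests monotonically", {
  lncs <- lnc_gs_from_spans(data.frame(
    gene_id = c("near", "far", "border"), chrom = "chr1",
    start = c(5e6, 10e6, 1e6 + 3e6), end = c(5e6 + 1e4, 10e6 + 1e4, 4e6 + 1e4),
    strand = "+"))
  disease <- data.frame(gene_id = "dg", chrom = "chr1", start = 9e5,
                        end = 1e6, strand = "+", term = "MP:0001967")
  got <- candidates_near_genes(lncs, disease)
  expect_setequal(got$lncrna_gene, c("near", "border"))   # 4.0 and 3.0 Mb
  expect_false("far" %in% got$lncrna_gene)                # 9 Mb away
  expect_equal(got$term, rep("MP:0001967", 2))
  # nesting as the threshold grows
  sets <- lapply(c(1e6, 4e6, 1e7), function(d) {
    candidates_near_genes(lncs, disease, max_distance = d)$lncrna_gene
  })
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))
  # sorted by distance then ids; proximal records carry the distance
  expect_equal(got$lncrna_gene, c("border", "near"))
  expect_equal(got$distance_bp, c(3e6, 4e6))
  expect_warning(candidates_near_genes(lncs, disease[0, ]), "empty")
})

test_that("correlation_screen calls planted directions and conserves records", {
  m <- rbind(l1 = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12),
             c1 = c(2, 4, 6, 8, 10, 12, 14, 16, 18, 20, 22, 24),
             l2 = 12:1, c2 = 1:12)
  m <- 2^m[, 1:12] - 1   # log2(fpkm + 1) is then exactly linear
  colnames(m) <- sprintf("s%02d", 1:12)
  em <- expression_matrix(m, unit = "fpkm")
  rec <- data.frame(lncrna_gene = c("l1", "l2", "ghost"),
                    disease_gene = c("c1", "c2", "c1"))
  got <- correlation_screen(rec, em)
  expect_equal(got$correlation_call, c("positive", "negative",
                                       "no_expression"))
  expect_equal(got$correlation_R[1], 1)
  expect_equal(got$correlation_R[2], -1)
  tab <- table(got$correlation_call)
  expect_equal(sum(tab), nrow(rec))   # conservation of records
})

test_that("map_position interpolates inside anchor blocks, snapping outside", {
  anchors <- data.frame(
    mouse_chrom = "chr1", mouse_start = c(1000, 50000),
    mouse_end = c(3000, 54000), mouse_gene = c("A", "B"),
    human_chrom = "hchr1", human_start = c(9000, 70000),
    human_end = c(11000, 74000), human_gene = c("hA", "hB"),
    orientation = c("same", "inverted"), stringsAsFactors = FALSE)
  # block endpoints map to block endpoints
  got <- map_position(c(9000, 11000), c("hchr1", "hchr1"), anchors)
  expect_equal(got$pos, c(1000, 3000))
  # midpoint of a same-orientation block maps to the midpoint
  expect_equal(map_position(10000, "hchr1", anchors)$pos, 2000)
  # inverted block reflects: human start maps to mouse end
  got_inv <- map_position(c(70000, 74000, 71000), rep("hchr1", 3), anchors)
  expect_equal(got_inv$pos, c(54000, 50000, 53000))
  # outside every block: snapped to the nearest edge and flagged
  out <- map_position(12000, "hchr1", anchors)
  expect_true(out$snapped)
  expect_equal(out$pos, 3000)
})

test_that("liftover round-trips within 1 bp and preserves containment", {
  anchors <- SIM$ann$anchors
  set.seed(77)
  blocks <- anchors[sample.int(nrow(anchors), 300, replace = TRUE), ]
  frac1 <- runif(300); frac2 <- runif(300)
  lo <- pmin(frac1, frac2); hi <- pmax(frac1, frac2)
  h_start <- round(blocks$human_start +
                     lo * (blocks$human_end - blocks$human_start))
  h_end <- round(blocks$human_start +
                   hi * (blocks$human_end - blocks$human_start))
  m1 <- map_position(h_start, blocks$human_chrom, anchors, "human_to_mouse")
  m2 <- map_position(h_end, blocks$human_chrom, anchors, "human_to_mouse")
  b1 <- map_position(m1$pos, m1$chrom, anchors, "mouse_to_human")
  b2 <- map_position(m2$pos, m2$chrom, anchors, "mouse_to_human")
  expect_false(any(m1$snapped | m2$snapped))
  expect_lte(max(abs(b1$pos - h_start)), 1)
  expect_lte(max(abs(b2$pos - h_end)), 1)
  # containment: a sub-interval maps inside its parent (same block)
  mid_lo <- pmin(m1$pos, m2$pos); mid_hi <- pmax(m1$pos, m2$pos)
  inner <- map_position(round(h_start + 0.25 * (h_end - h_start)),
                        blocks$human_chrom, anchors, "human_to_mouse")
  ok <- h_end > h_start
  expect_true(all(inner$pos[ok] >= mid_lo[ok] - 1 &
                    inner$pos[ok] <= mid_hi[ok] + 1))
})

test_that("map_locus_and_intersect maps loci and reports splits", {
  anchors <- data.frame(
    mouse_chrom = c("chr1", "chr2"), mouse_start = c(1000, 1000),
    mouse_end = c(3000, 3000), mouse_gene = c("A", "B"),
    human_chrom = "hchr1", human_start = c(9000, 40000),
    human_end = c(11000, 42000), human_gene = c("hA", "hB"),
    orientation = "same", stringsAsFactors = FALSE)
  loci <- data.frame(locus_id = c("ok", "splitcase"), chrom = "hchr1",
                     start = c(9100, 9100), end = c(10900, 41000))
  lncs <- lnc_gs_from_spans(data.frame(gene_id = "lnc", chrom = "chr1",
                                       start = 1500, end = 1800,
                                       strand = "+"))
  expect_warning(got <- map_locus_and_intersect(loci, anchors, lncs),
                 "split")
  expect_equal(got$mapped$split, c(FALSE, TRUE))
  expect_equal(got$mapped$start[1], 1100)
  expect_equal(got$mapped$end[1], 2900)
  expect_equal(got$hits$gene_id, "lnc")
  expect_equal(got$hits$locus_id, "ok")
})
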