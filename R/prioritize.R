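RELATIONSHIP_LABELS <- c("host_in_intron", "within", "contains", "antisense",
                         "overlapping_divergent", "proximal")

# A lightweight gene record used by the relationship labeller: span fields
# plus an optional exon table (start/end, 0-based half-open).
as_gene_record <- function(x) {
  if (is.data.frame(x)) x <- as.list(x[1L, , drop = FALSE])
  assert_cols(x, c("chrom", "start", "end", "strand"), "gene record")
  x$exons <- x$exons %||% data.frame(start = x$start, end = x$end)
  x
}

five_prime <- function(g) if (g$strand == "+") g$start else g$end

exon_overlap_bp <- function(ea, eb) {
  if (nrow(ea) == 0L || nrow(eb) == 0L) return(0)
  total <- 0
  for (i in seq_len(nrow(ea))) {
    total <- total +
      sum(pmax(0, pmin(ea$end[i], eb$end) - pmax(ea$start[i], eb$start)))
  }
  total
}

#' Positional relationship between a lncRNA gene and a disease gene
#'
#' Labels the pair with the first matching relationship, in precedence
#' order:
#' \enumerate{
#'   \item `host_in_intron` -- the disease feature (e.g. a microRNA) lies
#'     entirely inside an intron of the lncRNA;
#'   \item `within` / `contains` -- span containment (lncRNA within the
#'     gene, or the gene within the lncRNA outside its introns);
#'   \item `antisense` -- opposite-strand exonic overlap;
#'   \item `overlapping_divergent` -- opposite strands, 5' ends within
#'     `divergent_window_bp`, transcription pointing apart (head-to-head);
#'   \item `proximal` -- disjoint on the same chromosome, with the span
#'     distance reported.
#' }
#'
#' @param lnc,gene Gene records: one-row data frames or lists with
#'   `chrom`, `start`, `end`, `strand` and an optional `exons` data frame
#'   (`start`, `end`).
#' @param divergent_window_bp Window for the divergent-promoter test
#'   (default 1000 bp).
#' @return List with `relationship` and `distance_bp` (0 unless
#'   `proximal`); `relationship = NA` for different chromosomes.
#' @export
label_relationship <- function(lnc, gene, divergent_window_bp = 1000) {
  lnc <- as_gene_record(lnc)
  gene <- as_gene_record(gene)
  if (lnc$chrom != gene$chrom) {
    return(list(relationship = NA_character_, distance_bp = NA_real_))
  }
  done <- function(rel, d = 0) list(relationship = rel, distance_bp = d)

  # (1) disease feature inside an intron of the lncRNA
  le <- lnc$exons[order(lnc$exons$start), , drop = FALSE]
  if (nrow(le) > 1L) {
    introns <- data.frame(start = le$end[-nrow(le)], end = le$start[-1L])
    inside <- gene$start >= introns$start & gene$end <= introns$end
    if (any(inside)) return(done("host_in_intron"))
  }

  # (2) span containment
  if (gene$start <= lnc$start && lnc$end <= gene$end) return(done("within"))
  if (lnc$start <= gene$start && gene$end <= lnc$end) return(done("contains"))

  # (3) opposite-strand exonic overlap
  strands_ok <- lnc$strand %in% c("+", "-") && gene$strand %in% c("+", "-")
  if (strands_ok && lnc$strand != gene$strand &&
      exon_overlap_bp(lnc$exons, gene$exons) > 0) {
    return(done("antisense"))
  }

  # (4) divergent head-to-head promoters
  if (strands_ok && lnc$strand != gene$strand) {
    plus <- if (lnc$strand == "+") lnc else gene
    minus <- if (lnc$strand == "-") lnc else gene
    apart <- plus$start >= minus$start && plus$end >= minus$end
    if (apart &&
        abs(five_prime(plus) - five_prime(minus)) <= divergent_window_bp) {
      return(done("overlapping_divergent"))
    }
  }

  # (5) proximal
  d <- gene_distance(data.frame(chrom = lnc$chrom, start = lnc$start,
                                end = lnc$end),
                     data.frame(chrom = gene$chrom, start = gene$start,
                                end = gene$end))
  done("proximal", d)
}

gene_record_from_set <- function(gs, gene_id) {
  g <- gs$genes[gs$genes$gene_id == gene_id, , drop = FALSE]
  member_tx <- gs$members$transcript_id[gs$members$gene_id == gene_id]
  ex <- gs$ts$exons[gs$ts$exons$transcript_id %in% member_tx, , drop = FALSE]
  list(chrom = g$chrom, start = g$start, end = g$end, strand = g$strand,
       exons = ex[, c("start", "end"), drop = FALSE])
}

#' Candidate lncRNAs near disease genes
#'
#' Enumerates every (lncRNA gene, disease gene) pair within
#' `max_distance` bp on the same chromosome (span-to-span distance, 0 for
#' any overlap) and labels each with [label_relationship()]. Records are
#' sorted by distance, then ids.
#'
#' @param lnc_genes `gene_set` of lncRNA genes.
#' @param disease_genes `gene_set` of disease genes, or a data frame with
#'   `gene_id`, `chrom`, `start`, `end`, `strand` (e.g. an MGI
#'   deafness-gene table; an optional `term` column is carried through).
#' @param max_distance Maximum span distance in bp (default 4 Mb,
#'   inclusive).
#' @param divergent_window_bp Passed to [label_relationship()].
#' @return Data frame of `CandidateRecord`s: `lncrna_gene`,
#'   `disease_gene`, `relationship`, `distance_bp` (plus `term` when
#'   available). Empty disease list yields an empty result with a warning.
#' @export
candidates_near_genes <- function(lnc_genes, disease_genes,
                                  max_distance = 4e6,
                                  divergent_window_bp = 1000) {
  stopifnot(inherits(lnc_genes, "gene_set"))
  dg <- if (inherits(disease_genes, "gene_set")) {
    disease_genes$genes
  } else {
    disease_genes
  }
  empty <- data.frame(lncrna_gene = character(), disease_gene = character(),
                      relationship = character(), distance_bp = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(dg) || nrow(dg) == 0L) {
    warn_earlinc("empty disease-gene list")
    return(empty)
  }
  assert_cols(dg, c("gene_id", "chrom", "start", "end", "strand"),
              "disease_genes")
  lg <- lnc_genes$genes
  out <- list()
  for (i in seq_len(nrow(lg))) {
    same <- dg[dg$chrom == lg$chrom[i], , drop = FALSE]
    if (nrow(same) == 0L) next
    d <- gene_distance(lg[i, c("chrom", "start", "end")],
                       same[, c("chrom", "start", "end")])
    hit <- which(d <= max_distance)
    if (length(hit) == 0L) next
    lnc_rec <- gene_record_from_set(lnc_genes, lg$gene_id[i])
    for (j in hit) {
      gene_rec <- list(chrom = same$chrom[j], start = same$start[j],
                       end = same$end[j], strand = same$strand[j])
      rel <- label_relationship(lnc_rec, gene_rec,
                                divergent_window_bp = divergent_window_bp)
      rec <- data.frame(lncrna_gene = lg$gene_id[i],
                        disease_gene = same$gene_id[j],
                        relationship = rel$relationship,
                        distance_bp = rel$distance_bp,
                        stringsAsFactors = FALSE)
      if ("term" %in% names(same)) rec$term <- same$term[j]
      out[[length(out) + 1L]] <- rec
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$distance_bp, res$lncrna_gene, res$disease_gene, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Expression-correlation screen over candidate records
#'
#' Fills each candidate record with the Pearson correlation between the
#' lncRNA and disease-gene expression profiles and a call: `positive`
#' (`R > r_cutoff`, `p < alpha`), `negative` (`R < -r_cutoff`,
#' `p < alpha`), otherwise `none`. Pairs with a gene absent from the
#' matrix are flagged `no_expression`, never dropped, so
#' `positive + negative + none + no_expression` equals the input count.
#'
#' @param records Data frame from [candidates_near_genes()].
#' @param em `expression_matrix` (`fpkm`) indexed by gene id.
#' @param r_cutoff Correlation magnitude threshold (default 0.3,
#'   exclusive).
#' @param alpha P-value threshold (default 0.05, exclusive).
#' @param log_transform Correlate `log2(fpkm + 1)` (default) rather than
#'   raw FPKM.
#' @return `records` with columns `correlation_R`, `correlation_p`,
#'   `correlation_call` appended.
#' @export
correlation_screen <- function(records, em, r_cutoff = 0.3, alpha = 0.05,
                               log_transform = TRUE) {
  assert_cols(records, c("lncrna_gene", "disease_gene"), "records")
  stopifnot(inherits(em, "expression_matrix"))
  vals <- if (log_transform) log2(em$values + 1) else em$values
  n <- nrow(records)
  records$correlation_R <- NA_real_
  records$correlation_p <- NA_real_
  records$correlation_call <- "no_expression"
  for (i in seq_len(n)) {
    a <- records$lncrna_gene[i]
    b <- records$disease_gene[i]
    if (!(a %in% rownames(vals)) || !(b %in% rownames(vals))) next
    res <- correlate(vals[a, ], vals[b, ])
    records$correlation_R[i] <- res$r
    records$correlation_p[i] <- res$p_value
    records$correlation_call[i] <-
      if (res$status != "ok") {
        "none"
      } else if (res$r > r_cutoff && res$p_value < alpha) {
        "positive"
      } else if (res$r < -r_cutoff && res$p_value < alpha) {
        "negative"
      } else {
        "none"
      }
  }
  records
}

#' Map positions between genomes by interpolation within anchor blocks
#'
#' Each anchor block ties a mouse interval to a human interval (1:1
#' orthologous coding genes). A position inside a source-side block maps
#' to the proportionally equivalent position of the paired block, with the
#' fraction reversed for `inverted` blocks. Positions outside every block
#' snap to the nearest block edge (flagged).
#'
#' @param pos Numeric vector of positions (0-based).
#' @param chrom Chromosome of each position (on the source genome).
#' @param anchors Anchor table (see [synteny_matches()]).
#' @param direction `"human_to_mouse"` or `"mouse_to_human"`.
#' @return Data frame with `chrom` (target genome), `pos` (mapped,
#'   rounded to integer), `snapped` (logical).
#' @export
map_position <- function(pos, chrom, anchors,
                         direction = c("human_to_mouse", "mouse_to_human")) {
  direction <- match.arg(direction)
  validate_anchors(anchors)
  if (direction == "human_to_mouse") {
    src <- anchors[, c("human_chrom", "human_start", "human_end")]
    dst <- anchors[, c("mouse_chrom", "mouse_start", "mouse_end")]
  } else {
    src <- anchors[, c("mouse_chrom", "mouse_start", "mouse_end")]
    dst <- anchors[, c("human_chrom", "human_start", "human_end")]
  }
  names(src) <- names(dst) <- c("chrom", "start", "end")
  out_chrom <- rep(NA_character_, length(pos))
  out_pos <- rep(NA_real_, length(pos))
  snapped <- rep(FALSE, length(pos))
  for (i in seq_along(pos)) {
    on_chrom <- which(src$chrom == chrom[i])
    if (length(on_chrom) == 0L) next
    inside <- on_chrom[pos[i] >= src$start[on_chrom] &
                         pos[i] <= src$end[on_chrom]]
    if (length(inside) > 0L) {
      blk <- inside[1L]
      x <- pos[i]
    } else {
      edge_dist <- pmin(abs(src$start[on_chrom] - pos[i]),
                        abs(src$end[on_chrom] - pos[i]))
      blk <- on_chrom[which.min(edge_dist)]
      x <- if (abs(src$start[blk] - pos[i]) <= abs(src$end[blk] - pos[i]))
        src$start[blk] else src$end[blk]
      snapped[i] <- TRUE
    }
    frac <- (x - src$start[blk]) / (src$end[blk] - src$start[blk])
    out_chrom[i] <- dst$chrom[blk]
    out_pos[i] <- if (anchors$orientation[blk] == "same") {
      dst$start[blk] + frac * (dst$end[blk] - dst$start[blk])
    } else {
      dst$end[blk] - frac * (dst$end[blk] - dst$start[blk])
    }
  }
  data.frame(chrom = out_chrom, pos = round(out_pos), snapped = snapped,
             stringsAsFactors = FALSE)
}

#' Map disease loci to the other genome and intersect with lncRNA genes
#'
#' Both endpoints of each locus are mapped with [map_position()]. When the
#' mapped endpoints land on one target chromosome, the locus becomes the
#' hull of the two mapped positions; endpoints on different chromosomes
#' are flagged `split` and yield no interval. Mapped loci are intersected
#' with lncRNA gene spans.
#'
#' @param loci Data frame of loci on the source genome: `locus_id`,
#'   `chrom`, `start`, `end` (BED semantics).
#' @param anchors Anchor table.
#' @param lnc_genes `gene_set` of lncRNA genes on the target genome (or
#'   `NULL` to skip intersection).
#' @param direction Passed to [map_position()]; default human -> mouse.
#' @return List with `mapped` (per-locus: target `chrom`, `start`, `end`,
#'   `snapped`, `split`) and `hits` (`locus_id`, `gene_id` for each
#'   overlapping lncRNA gene).
#' @export
map_locus_and_intersect <- function(loci, anchors, lnc_genes = NULL,
                                    direction = "human_to_mouse") {
  assert_cols(loci, c("locus_id", "chrom", "start", "end"), "loci")
  a <- map_position(loci$start, loci$chrom, anchors, direction)
  b <- map_position(loci$end, loci$chrom, anchors, direction)
  split_flag <- is.na(a$chrom) | is.na(b$chrom) | a$chrom != b$chrom
  mapped <- data.frame(
    locus_id = loci$locus_id,
    chrom = ifelse(split_flag, NA_character_, a$chrom),
    start = ifelse(split_flag, NA_real_, pmin(a$pos, b$pos)),
    end = ifelse(split_flag, NA_real_, pmax(a$pos, b$pos)),
    snapped = a$snapped | b$snapped,
    split = split_flag,
    stringsAsFactors = FALSE)
  if (any(split_flag)) {
    warn_earlinc("locus/loci split across target chromosomes: %s",
                 paste(loci$locus_id[split_flag], collapse = ", "))
  }
  hits <- data.frame(locus_id = character(), gene_id = character(),
                     stringsAsFactors = FALSE)
  if (!is.null(lnc_genes)) {
    stopifnot(inherits(lnc_genes, "gene_set"))
    lg <- lnc_genes$genes
    for (i in which(!mapped$split)) {
      ov <- lg$chrom == mapped$chrom[i] & lg$start < mapped$end[i] &
        lg$end > mapped$start[i]
      if (any(ov)) {
        hits <- rbind(hits, data.frame(locus_id = mapped$locus_id[i],
                                       gene_id = lg$gene_id[ov],
                                       stringsAsFactors = FALSE))
      }
    }
  }
  list(mapped = mapped, hits = hits)
}
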