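strand_pair_ok <- function(sa, sb, strand_mode) {
  switch(strand_mode,
         same = sa == sb & sa %in% c("+", "-") & sb %in% c("+", "-"),
         opposite = sa != sb & sa %in% c("+", "-") & sb %in% c("+", "-"),
         ignore = rep(TRUE, length(sa)),
         stop_earlinc("unknown strand_mode '%s'", strand_mode))
}

#' Strand-aware exonic overlap between two transcript sets
#'
#' For every transcript pair (one from `a`, one from `b`) with at least one
#' base of exonic overlap satisfying `strand_mode`, returns the total
#' overlap in bp, summed over exon pairs. The relation is symmetric:
#' swapping `a` and `b` transposes the result. Transcripts on strand `"."`
#' are incomparable under `"same"` and `"opposite"` (overlap 0, with a
#' warning when such transcripts are present).
#'
#' @param a,b `transcript_set` objects.
#' @param strand_mode `"same"`, `"opposite"`, or `"ignore"`.
#' @return Data frame with columns `tx_a`, `tx_b`, `overlap_bp`
#'   (only pairs with positive overlap; zero rows when none).
#' @examples
#' ts <- transcript_set(data.frame(
#'   transcript_id = c("t1", "t2"), gene_id = c("g1", "g2"), chrom = "chr1",
#'   start = c(100, 150), end = c(200, 250), strand = "+"))
#' exonic_overlap(subset_transcripts(ts, "t1"),
#'                subset_transcripts(ts, "t2"), "same")  # 50 bp
#' @export
exonic_overlap <- function(a, b, strand_mode = c("same", "opposite", "ignore")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(a, "transcript_set"), inherits(b, "transcript_set"))
  empty <- data.frame(tx_a = character(), tx_b = character(),
                      overlap_bp = numeric(), stringsAsFactors = FALSE)
  if (nrow(a$exons) == 0L || nrow(b$exons) == 0L) return(empty)
  if (strand_mode != "ignore" &&
      (any(a$tx$strand == ".") || any(b$tx$strand == "."))) {
    warn_earlinc("strand '.' transcripts present; treated as incomparable under strand_mode='%s'",
                 strand_mode)
  }
  ga <- gr_exons(a)
  gb <- gr_exons(b)
  # suppress the seqlevel-merge notice when the two sets share no chroms
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(ga, gb, ignore.strand = TRUE))
  if (length(hits) == 0L) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ok <- strand_pair_ok(ga$strand_token[qi], gb$strand_token[si], strand_mode)
  qi <- qi[ok]; si <- si[ok]
  if (length(qi) == 0L) return(empty)
  w <- pmin(GenomicRanges::end(ga)[qi], GenomicRanges::end(gb)[si]) -
    pmax(GenomicRanges::start(ga)[qi], GenomicRanges::start(gb)[si]) + 1L
  key <- paste(ga$tx[qi], gb$tx[si], sep = "\r")
  agg <- rowsum(as.numeric(w), key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- data.frame(tx_a = vapply(parts, `[[`, "", 1L),
                    tx_b = vapply(parts, `[[`, "", 2L),
                    overlap_bp = agg[, 1L], stringsAsFactors = FALSE)
  out <- out[order(out$tx_a, out$tx_b, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Minimal union-find used for transitive-closure gene grouping.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Group transcripts into genes by overlap
#'
#' Genes are the transitive closure of the chosen pairwise overlap
#' relation: `same_strand_exonic` links transcripts whose exons overlap on
#' the same strand (the default, matching the lincRNA/antisense
#' distinction), `any_overlap` links transcripts whose spans overlap on
#' either strand (used for conservative novelty calls). Every transcript
#' lands in exactly one gene. Gene ids are deterministic: components are
#' ordered by chromosome, start, then first transcript id.
#'
#' @param ts A `transcript_set`.
#' @param mode Overlap relation, see above.
#' @param gene_prefix Prefix for generated gene ids.
#' @return A `gene_set`: list with `genes` (gene_id, chrom, start, end,
#'   strand, n_transcripts), `members` (gene_id, transcript_id), and `ts`
#'   (the input transcripts).
#' @export
group_transcripts_into_genes <- function(ts,
                                         mode = c("same_strand_exonic",
                                                  "any_overlap"),
                                         gene_prefix = "EARG") {
  mode <- match.arg(mode)
  stopifnot(inherits(ts, "transcript_set"))
  ids <- ts$tx$transcript_id
  n <- length(ids)
  parent <- uf_new(n)
  if (n > 0L) {
    if (mode == "same_strand_exonic") {
      pairs <- exonic_overlap(ts, ts, "same")
      pairs <- pairs[pairs$tx_a != pairs$tx_b, , drop = FALSE]
      ia <- match(pairs$tx_a, ids)
      ib <- match(pairs$tx_b, ids)
    } else {
      g <- gr_spans(ts$tx)
      hits <- GenomicRanges::findOverlaps(g, ignore.strand = TRUE,
                                          drop.self = TRUE,
                                          drop.redundant = TRUE)
      ia <- S4Vectors::queryHits(hits)
      ib <- S4Vectors::subjectHits(hits)
    }
    for (k in seq_along(ia)) {
      ra <- uf_find(parent, ia[k])
      rb <- uf_find(parent, ib[k])
      if (ra != rb) parent[rb] <- ra
    }
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), 0L)
  comp <- split(seq_len(n), root)

  comp_chrom <- vapply(comp, function(i) ts$tx$chrom[i][1L], "")
  comp_start <- vapply(comp, function(i) min(ts$tx$start[i]), 0)
  comp_first <- vapply(comp, function(i) sort(ts$tx$transcript_id[i], method = "radix")[1L], "")
  ord <- order(comp_chrom, comp_start, comp_first, method = "radix")
  comp <- comp[ord]
  gene_ids <- sprintf("%s%05d", gene_prefix, seq_along(comp))

  genes <- data.frame(
    gene_id = gene_ids,
    chrom = comp_chrom[ord],
    start = comp_start[ord],
    end = vapply(comp, function(i) max(ts$tx$end[i]), 0),
    strand = vapply(comp, function(i) {
      s <- unique(ts$tx$strand[i])
      if (length(s) == 1L) s else "."
    }, ""),
    n_transcripts = lengths(comp),
    stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  members <- data.frame(
    gene_id = rep(gene_ids, lengths(comp)),
    transcript_id = ts$tx$transcript_id[unlist(comp, use.names = FALSE)],
    stringsAsFactors = FALSE)
  structure(list(genes = genes, members = members, ts = ts),
            class = "gene_set")
}

#' Group a transcript set into genes using its declared gene ids
#'
#' Used for reference annotations whose transcripts already carry curated
#' gene ids (no overlap-based inference).
#'
#' @param ts A `transcript_set`.
#' @return A `gene_set` with one gene per distinct `gene_id`.
#' @export
as_gene_set <- function(ts) {
  stopifnot(inherits(ts, "transcript_set"))
  sp <- split(seq_len(nrow(ts$tx)), ts$tx$gene_id)
  genes <- data.frame(
    gene_id = names(sp),
    chrom = vapply(sp, function(i) ts$tx$chrom[i][1L], ""),
    start = vapply(sp, function(i) min(ts$tx$start[i]), 0),
    end = vapply(sp, function(i) max(ts$tx$end[i]), 0),
    strand = vapply(sp, function(i) {
      s <- unique(ts$tx$strand[i])
      if (length(s) == 1L) s else "."
    }, ""),
    n_transcripts = lengths(sp),
    stringsAsFactors = FALSE)
  bad <- vapply(sp, function(i) length(unique(ts$tx$chrom[i])) > 1L, TRUE)
  if (any(bad)) {
    stop_earlinc("gene(s) with transcripts on multiple chromosomes: %s",
                 paste(names(sp)[bad], collapse = ", "))
  }
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id, method = "radix"), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  members <- data.frame(gene_id = ts$tx$gene_id,
                        transcript_id = ts$tx$transcript_id,
                        stringsAsFactors = FALSE)
  structure(list(genes = genes, members = members, ts = ts),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %d genes from %d transcripts\n",
              nrow(x$genes), nrow(x$members)))
  invisible(x)
}
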