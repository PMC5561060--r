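BLAST6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                 "bitscore")

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' @param path Path to a 12-column tab-separated BLAST hit table
#'   (`qseqid sseqid pident length mismatch gapopen qstart qend sstart
#'   send evalue bitscore`). Comment lines (`#`) are skipped; malformed
#'   rows abort with their line number.
#' @return Data frame with the standard column names.
#' @export
read_blast_hits <- function(path) {
  if (!file.exists(path)) stop_earlinc("hit table not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    out <- as.data.frame(matrix(nrow = 0L, ncol = 12L))
    names(out) <- BLAST6_COLS
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1L]
    stop_earlinc("hit table parse error at line %d of %s: expected 12 fields, found %d",
                 lineno[bad], path, nf[bad])
  }
  out <- data.frame(
    qseqid = vapply(fields, `[[`, "", 1L),
    sseqid = vapply(fields, `[[`, "", 2L),
    stringsAsFactors = FALSE)
  num_cols <- BLAST6_COLS[3:12]
  for (j in seq_along(num_cols)) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", j + 2L)))
    if (anyNA(v)) {
      stop_earlinc("hit table parse error at line %d of %s: non-numeric %s",
                   lineno[which(is.na(v))[1L]], path, num_cols[j])
    }
    out[[num_cols[j]]] <- v
  }
  if (any(!nzchar(out$qseqid)) || any(!nzchar(out$sseqid))) {
    stop_earlinc("hit table %s: empty sequence id", path)
  }
  out
}

#' Sequence-similarity ortholog candidates
#'
#' Filters a BLAST-style hit table on identity and e-value and collapses
#' multiple local alignments of the same (query, subject) pair to the best
#' bit score.
#'
#' @param hits Data frame as returned by [read_blast_hits()].
#' @param min_identity Minimum percent identity (default 60).
#' @param max_evalue Maximum e-value (default 1e-5).
#' @return Data frame of candidate pairs: `mouse_gene`, `human_gene`,
#'   `similarity_score` (bit score), `evidence` (`"sequence"`).
#' @export
sequence_matches <- function(hits, min_identity = 60, max_evalue = 1e-5) {
  assert_cols(hits, c("qseqid", "sseqid", "pident", "evalue", "bitscore"),
              "hits")
  keep <- hits$pident >= min_identity & hits$evalue <= max_evalue
  h <- hits[keep, , drop = FALSE]
  if (nrow(h) == 0L) {
    return(data.frame(mouse_gene = character(), human_gene = character(),
                      similarity_score = numeric(),
                      synteny_score = numeric(), evidence = character(),
                      stringsAsFactors = FALSE))
  }
  h <- h[order(h$qseqid, h$sseqid, -h$bitscore, method = "radix"), , drop = FALSE]
  h <- h[!duplicated(h[, c("qseqid", "sseqid")]), , drop = FALSE]
  data.frame(mouse_gene = h$qseqid, human_gene = h$sseqid,
             similarity_score = h$bitscore, synteny_score = NA_real_,
             evidence = "sequence", row.names = NULL,
             stringsAsFactors = FALSE)
}

validate_anchors <- function(anchors) {
  assert_cols(anchors, c("mouse_chrom", "mouse_start", "mouse_end",
                         "mouse_gene", "human_chrom", "human_start",
                         "human_end", "human_gene", "orientation"),
              "anchors")
  if (!all(anchors$orientation %in% c("same", "inverted"))) {
    stop_earlinc("anchor orientation must be 'same' or 'inverted'")
  }
  if (anyDuplicated(anchors$mouse_gene) || anyDuplicated(anchors$human_gene)) {
    stop_earlinc("anchor genes must be 1:1 (no repeats on either side)")
  }
  invisible(anchors)
}

#' Synteny-based ortholog candidates
#'
#' For each mouse lncRNA gene, locates the nearest anchored coding genes
#' upstream and downstream on its chromosome. A human lncRNA is a synteny
#' candidate iff it lies strictly between the human orthologs of those two
#' flanking anchors *and* the two human orthologs are adjacent anchors on
#' their chromosome (conserved adjacency; this is what an anchor shuffle
#' destroys). The synteny score of each candidate is `1 / (1 + k)` where
#' `k` is the number of other human lncRNAs in the same window.
#'
#' Mouse lncRNAs without both flanking anchors are reported in the
#' `unplaced` attribute, not matched.
#'
#' @param mouse_lnc `gene_set` (or plain data frame with `gene_id`,
#'   `chrom`, `start`, `end`) of mouse lncRNA genes.
#' @param human_lnc Data frame of human lncRNA genes (`gene_id`, `chrom`,
#'   `start`, `end`).
#' @param anchors Anchor table: `mouse_chrom`, `mouse_start`, `mouse_end`,
#'   `mouse_gene`, `human_chrom`, `human_start`, `human_end`,
#'   `human_gene`, `orientation`.
#' @param require_adjacent Require conserved anchor adjacency on the human
#'   side (default `TRUE`).
#' @param warn_unplaced Emit a warning when mouse genes lack a usable
#'   flanking anchor pair (they are always listed in the `unplaced`
#'   attribute).
#' @return Data frame of candidate pairs: `mouse_gene`, `human_gene`,
#'   `synteny_score`, `evidence` (`"synteny"`); attribute `unplaced` lists
#'   mouse genes lacking a flanking anchor pair.
#' @export
synteny_matches <- function(mouse_lnc, human_lnc, anchors,
                            require_adjacent = TRUE,
                            warn_unplaced = TRUE) {
  genes <- if (inherits(mouse_lnc, "gene_set")) mouse_lnc$genes else mouse_lnc
  assert_cols(genes, c("gene_id", "chrom", "start", "end"), "mouse_lnc")
  assert_cols(human_lnc, c("gene_id", "chrom", "start", "end"), "human_lnc")
  validate_anchors(anchors)

  # human anchor rank along each human chromosome, for the adjacency test
  anchors <- anchors[order(anchors$human_chrom, anchors$human_start, method = "radix"), ,
                     drop = FALSE]
  anchors$human_rank <- stats::ave(anchors$human_start, anchors$human_chrom,
                                   FUN = seq_along)

  out <- list()
  unplaced <- character()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    on_chrom <- anchors[anchors$mouse_chrom == g$chrom, , drop = FALSE]
    up <- on_chrom[on_chrom$mouse_end <= g$start, , drop = FALSE]
    down <- on_chrom[on_chrom$mouse_start >= g$end, , drop = FALSE]
    if (nrow(up) == 0L || nrow(down) == 0L) {
      unplaced <- c(unplaced, g$gene_id)
      next
    }
    up <- up[which.max(up$mouse_end), ]
    down <- down[which.min(down$mouse_start), ]
    if (up$human_chrom != down$human_chrom) {
      unplaced <- c(unplaced, g$gene_id)
      next
    }
    if (require_adjacent && abs(up$human_rank - down$human_rank) != 1) {
      unplaced <- c(unplaced, g$gene_id)
      next
    }
    lo <- min(up$human_end, down$human_end)
    hi <- max(up$human_start, down$human_start)
    if (hi <= lo) {  # anchors overlap on human side; no window
      unplaced <- c(unplaced, g$gene_id)
      next
    }
    cand <- human_lnc[human_lnc$chrom == up$human_chrom &
                        human_lnc$start >= lo & human_lnc$end <= hi, ,
                      drop = FALSE]
    if (nrow(cand) == 0L) next
    score <- 1 / nrow(cand)  # 1/(1 + number of intervening human lncRNAs)
    out[[length(out) + 1L]] <- data.frame(
      mouse_gene = g$gene_id, human_gene = cand$gene_id,
      similarity_score = NA_real_, synteny_score = score,
      evidence = "synteny", stringsAsFactors = FALSE)
  }
  if (warn_unplaced && length(unplaced) > 0L) {
    warn_earlinc("%d mouse lncRNA gene(s) without a usable flanking anchor pair",
                 length(unplaced))
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(mouse_gene = character(), human_gene = character(),
               similarity_score = numeric(), synteny_score = numeric(),
               evidence = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "unplaced") <- unplaced
  res
}

#' Merge ortholog candidates and resolve multiple matching to 1:1 pairs
#'
#' Candidates for the same (mouse, human) pair are merged with the union
#' of their evidence and the best of each score. Pairs are then ranked --
#' evidence `{sequence, synteny}` over `{sequence}` over `{synteny}`, then
#' higher similarity score, then higher synteny score, then lexicographic
#' ids -- and selected greedily so that each gene is used at most once.
#' The output is therefore a matching: no mouse or human gene repeats.
#'
#' @param candidates Data frame with columns `mouse_gene`, `human_gene`,
#'   `evidence` (`"sequence"` or `"synteny"` per row), and optional
#'   `similarity_score`, `synteny_score`. Typically
#'   `rbind(sequence_matches(...), synteny_matches(...))`.
#' @return Data frame of resolved pairs: `mouse_gene`, `human_gene`,
#'   `evidence` (comma-joined, e.g. `"sequence,synteny"`),
#'   `similarity_score`, `synteny_score`. Attribute `merged_candidates`
#'   holds the merged (pre-resolution) pair table.
#' @export
resolve_orthologs <- function(candidates) {
  assert_cols(candidates, c("mouse_gene", "human_gene", "evidence"),
              "candidates")
  if (!"similarity_score" %in% names(candidates)) {
    candidates$similarity_score <- NA_real_
  }
  if (!"synteny_score" %in% names(candidates)) {
    candidates$synteny_score <- NA_real_
  }
  empty <- data.frame(mouse_gene = character(), human_gene = character(),
                      evidence = character(), similarity_score = numeric(),
                      synteny_score = numeric(), stringsAsFactors = FALSE)
  if (nrow(candidates) == 0L) {
    attr(empty, "merged_candidates") <- empty
    return(empty)
  }
  key <- paste(candidates$mouse_gene, candidates$human_gene, sep = "\r")
  merged <- do.call(rbind, lapply(split(seq_len(nrow(candidates)), key),
                                  function(i) {
    ev <- sort(unique(unlist(strsplit(candidates$evidence[i], ","))), method = "radix")
    data.frame(
      mouse_gene = candidates$mouse_gene[i[1L]],
      human_gene = candidates$human_gene[i[1L]],
      evidence = paste(ev, collapse = ","),
      similarity_score = if (all(is.na(candidates$similarity_score[i])))
        NA_real_ else max(candidates$similarity_score[i], na.rm = TRUE),
      synteny_score = if (all(is.na(candidates$synteny_score[i])))
        NA_real_ else max(candidates$synteny_score[i], na.rm = TRUE),
      stringsAsFactors = FALSE)
  }))
  rownames(merged) <- NULL

  ev_rank <- ifelse(merged$evidence == "sequence,synteny", 3L,
                    ifelse(merged$evidence == "sequence", 2L, 1L))
  sim <- ifelse(is.na(merged$similarity_score), -Inf,
                merged$similarity_score)
  syn <- ifelse(is.na(merged$synteny_score), -Inf, merged$synteny_score)
  ord <- order(-ev_rank, -sim, -syn, merged$mouse_gene, merged$human_gene, method = "radix")

  used_m <- character(); used_h <- character()
  take <- logical(nrow(merged))
  for (i in ord) {
    if (merged$mouse_gene[i] %in% used_m || merged$human_gene[i] %in% used_h) {
      next
    }
    take[i] <- TRUE
    used_m <- c(used_m, merged$mouse_gene[i])
    used_h <- c(used_h, merged$human_gene[i])
  }
  res <- merged[take, , drop = FALSE]
  res <- res[order(res$mouse_gene, res$human_gene, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "merged_candidates") <- merged
  res
}

#' Cluster resolved ortholog pairs by cross-species expression pattern
#'
#' Builds one feature vector per pair by concatenating the mouse and human
#' `log2(fpkm + 1)` profiles, standardizing each sample column across
#' pairs (so relative expression level between pairs is preserved -- the
#' property that separates "high in both" from "low in both"). Pairs are
#' clustered by average-linkage hierarchical clustering on Euclidean
#' distance and the tree is cut at `k` groups. Group labels are reordered
#' by descending mean human expression, so group 1 is the
#' highest-in-human group.
#'
#' @param pairs Resolved pairs from [resolve_orthologs()].
#' @param mouse_em,human_em `expression_matrix` objects (`fpkm`) indexed
#'   by the pair gene ids.
#' @param k Number of groups (default 3).
#' @return Data frame `mouse_gene`, `human_gene`, `expression_group`
#'   (integer in `1..k`). Pairs missing expression in either matrix are
#'   excluded and listed in the `excluded` attribute.
#' @export
cluster_ortholog_expression <- function(pairs, mouse_em, human_em, k = 3) {
  assert_cols(pairs, c("mouse_gene", "human_gene"), "pairs")
  stopifnot(inherits(mouse_em, "expression_matrix"),
            inherits(human_em, "expression_matrix"))
  ok <- pairs$mouse_gene %in% rownames(mouse_em$values) &
    pairs$human_gene %in% rownames(human_em$values)
  excluded <- pairs[!ok, , drop = FALSE]
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0L) {
    out <- data.frame(mouse_gene = character(), human_gene = character(),
                      expression_group = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "excluded") <- excluded
    return(out)
  }
  if (k < 1L || k > nrow(pairs)) {
    stop_earlinc("k must be between 1 and the number of usable pairs (%d)",
                 nrow(pairs))
  }
  m <- log2(mouse_em$values[pairs$mouse_gene, , drop = FALSE] + 1)
  h <- log2(human_em$values[pairs$human_gene, , drop = FALSE] + 1)
  feat <- cbind(scale_columns(m), scale_columns(h))
  if (k == 1L) {
    grp <- rep(1L, nrow(pairs))
  } else {
    hc <- stats::hclust(stats::dist(feat), method = "average")
    grp <- stats::cutree(hc, k = k)
  }
  human_mean <- rowMeans(h)
  grp_mean <- tapply(human_mean, grp, mean)
  relabel <- match(grp, as.integer(names(sort(grp_mean,
                                              decreasing = TRUE))))
  out <- data.frame(mouse_gene = pairs$mouse_gene,
                    human_gene = pairs$human_gene,
                    expression_group = as.integer(relabel),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

# Column standardization that tolerates zero-variance columns (left centered).
scale_columns <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
}
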