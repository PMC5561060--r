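#' Build a transcript set from an exon table
#'
#' The central container of the annotation layer: a set of stranded,
#' multi-exon transcript models. Exons are stored 0-based half-open, sorted
#' within each transcript, and must be non-overlapping and share one
#' chromosome and strand per transcript. The per-transcript summary (span
#' hull, exon count, mature length) is derived on construction.
#'
#' @param exons Data frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, one row per exon. Rows may arrive
#'   in any order; sorting is internal.
#' @param biotype Optional character vector of transcript biotypes, named
#'   by `transcript_id` (or a `biotype` column in `exons`). One of
#'   `"protein_coding"`, `"small_rna"`, `"lncRNA_candidate"`,
#'   `"known_lncRNA"`; `NA` means unassigned.
#' @return An object of class `transcript_set`: a list with elements
#'   `exons` (the validated exon table) and `tx` (one row per transcript:
#'   `transcript_id`, `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `n_exons`, `mature_length`, `biotype`).
#' @examples
#' ts <- transcript_set(data.frame(
#'   transcript_id = "t1", gene_id = "g1", chrom = "chr1",
#'   start = c(100, 300), end = c(200, 400), strand = "+"))
#' ts$tx$mature_length  # 200
#' @export
transcript_set <- function(exons, biotype = NULL) {
  assert_cols(exons, c("transcript_id", "gene_id", "chrom", "start", "end",
                       "strand"), "exons")
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  if ("biotype" %in% names(exons) && is.null(biotype)) {
    bt <- exons$biotype
    names(bt) <- exons$transcript_id
    biotype <- bt[!duplicated(names(bt))]
  }
  exons <- exons[, c("transcript_id", "gene_id", "chrom", "start", "end",
                     "strand")]
  validate_intervals(exons, "exons")
  exons <- exons[order(exons$transcript_id, exons$start, method = "radix"), , drop = FALSE]
  rownames(exons) <- NULL

  sp <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (id in names(sp)) {
    i <- sp[[id]]
    if (length(unique(exons$chrom[i])) != 1L ||
        length(unique(exons$strand[i])) != 1L) {
      stop_earlinc("transcript %s: exons on multiple chromosomes or strands",
                   id)
    }
    if (length(unique(exons$gene_id[i])) != 1L) {
      stop_earlinc("transcript %s: inconsistent gene_id", id)
    }
    if (length(i) > 1L &&
        any(exons$start[i][-1L] < exons$end[i][-length(i)])) {
      stop_earlinc("transcript %s: overlapping exons", id)
    }
  }

  ids <- names(sp)
  first <- vapply(sp, `[[`, 0L, 1L)
  tx <- data.frame(
    transcript_id = ids,
    gene_id = exons$gene_id[first],
    chrom = exons$chrom[first],
    start = vapply(sp, function(i) min(exons$start[i]), 0),
    end = vapply(sp, function(i) max(exons$end[i]), 0),
    strand = exons$strand[first],
    n_exons = lengths(sp),
    mature_length = vapply(sp, function(i) sum(exons$end[i] - exons$start[i]),
                           0),
    stringsAsFactors = FALSE)
  tx$biotype <- rep(NA_character_, nrow(tx))
  if (!is.null(biotype)) {
    if (is.null(names(biotype))) {
      stop_earlinc("biotype must be named by transcript_id")
    }
    hit <- match(tx$transcript_id, names(biotype))
    tx$biotype <- as.character(biotype)[hit]
  }
  tx <- tx[order(tx$chrom, tx$start, tx$transcript_id, method = "radix"), , drop = FALSE]
  rownames(tx) <- NULL

  structure(list(exons = exons, tx = tx), class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("<transcript_set> %d transcripts, %d exons on %d chromosome(s)\n",
              nrow(x$tx), nrow(x$exons), length(unique(x$tx$chrom))))
  invisible(x)
}

#' Number of transcripts in a transcript set
#' @param ts A `transcript_set`.
#' @return Integer count.
#' @export
n_transcripts <- function(ts) nrow(ts$tx)

#' Subset a transcript set by transcript id
#'
#' @param ts A `transcript_set`.
#' @param ids Transcript ids to keep; unknown ids are an error.
#' @return A `transcript_set` restricted to `ids`.
#' @export
subset_transcripts <- function(ts, ids) {
  stopifnot(inherits(ts, "transcript_set"))
  missing <- setdiff(ids, ts$tx$transcript_id)
  if (length(missing) > 0L) {
    stop_earlinc("unknown transcript id(s): %s",
                 paste(utils::head(missing, 5L), collapse = ", "))
  }
  bt <- ts$tx$biotype
  names(bt) <- ts$tx$transcript_id
  transcript_set(ts$exons[ts$exons$transcript_id %in% ids, , drop = FALSE],
                 biotype = bt[names(bt) %in% ids])
}

#' Combine transcript sets
#'
#' @param ... `transcript_set` objects with disjoint transcript ids.
#' @return A single merged `transcript_set`.
#' @export
bind_transcript_sets <- function(...) {
  sets <- list(...)
  sets <- sets[!vapply(sets, is.null, TRUE)]
  stopifnot(all(vapply(sets, inherits, TRUE, "transcript_set")))
  exons <- do.call(rbind, lapply(sets, `[[`, "exons"))
  bt <- unlist(lapply(sets, function(s) {
    v <- s$tx$biotype
    names(v) <- s$tx$transcript_id
    v
  }))
  if (anyDuplicated(names(bt))) {
    stop_earlinc("duplicate transcript ids across sets")
  }
  transcript_set(exons, biotype = bt)
}

# Internal: exons (or transcript spans) as GRanges, 1-based for IRanges
# arithmetic. The original strand token is kept as metadata so that "."
# can be treated as incomparable rather than as "*" (match-everything).
gr_exons <- function(ts) {
  e <- ts$exons
  GenomicRanges::GRanges(
    seqnames = e$chrom,
    ranges = IRanges::IRanges(start = e$start + 1L, end = e$end),
    tx = e$transcript_id,
    strand_token = e$strand)
}

gr_spans <- function(df, id_col = "transcript_id") {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    id = df[[id_col]],
    strand_token = if ("strand" %in% names(df)) df$strand else ".")
}
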