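LNC_CATEGORIES <- c("lincRNA", "antisense", "small_rna_host",
                    "excluded_coding", "excluded_short",
                    "excluded_low_expression",
                    "excluded_intronic_same_strand")

#' Longest open reading frame of a nucleotide sequence
#'
#' Scans the given (sense) strand in all three frames for complete
#' ATG-to-stop open reading frames and returns the length of the longest in
#' codons, the stop codon not counted. ORFs lacking an in-frame stop do not
#' count. `N` is permitted and never matches ATG or a stop codon.
#'
#' @param sequence A single nucleotide string over `A`, `C`, `G`, `T`, `N`
#'   (case-insensitive).
#' @return Integer: longest ORF length in codons, 0 if none.
#' @examples
#' find_orfs("ATGTAA")      # 1
#' find_orfs("CCCCCCCCC")   # 0
#' @export
find_orfs <- function(sequence) {
  if (!is_string(sequence)) stop_earlinc("sequence must be a single string")
  seq <- toupper(sequence)
  if (grepl("[^ACGTN]", seq)) {
    stop_earlinc("illegal character in sequence (allowed: A, C, G, T, N)")
  }
  n <- nchar(seq)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    n_codons <- (n - frame) %/% 3L
    if (n_codons < 2L) next
    starts <- frame + 3L * (seq_len(n_codons) - 1L) + 1L
    codons <- substring(seq, starts, starts + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% stops)
    if (length(atg) == 0L || length(stp) == 0L) next
    # index of the first stop strictly after each ATG
    nxt <- stp[findInterval(atg, stp) + 1L]
    len <- nxt - atg
    len <- len[!is.na(len)]
    if (length(len) > 0L) best <- max(best, max(len))
  }
  as.integer(best)
}

#' Coding-potential filter
#'
#' Applies the pre-computed per-transcript coding assessment (longest ORF,
#' protein/domain homology flag, external codon-substitution-style score)
#' to decide which transcripts survive as lncRNA candidates. A transcript
#' is dropped as `excluded_coding` when its longest ORF reaches
#' `orf_max_aa` codons, when it has a homology hit, or when its external
#' score reaches `score_cutoff`. Transcripts with no usable assessment are
#' routed to a `needs_assessment` status, never silently kept.
#'
#' @param transcript_ids Character vector of transcripts to assess.
#' @param assessments Data frame with columns `transcript_id`,
#'   `longest_orf_aa` (integer, `NA` = unknown), `external_coding_score`
#'   (numeric, `NA` = absent), `homology_hit` (logical).
#' @param orf_max_aa ORF-length threshold in codons (default 100).
#' @param score_cutoff External-score threshold; scores at or above it are
#'   treated as coding evidence (default 0, i.e. positive
#'   codon-substitution scores are coding-like).
#' @return Data frame with columns `transcript_id`, `status`
#'   (`"keep"`, `"drop"`, `"needs_assessment"`), `reason`.
#' @export
coding_filter <- function(transcript_ids, assessments, orf_max_aa = 100,
                          score_cutoff = 0) {
  assert_cols(assessments, c("transcript_id", "longest_orf_aa",
                             "external_coding_score", "homology_hit"),
              "assessments")
  hit <- match(transcript_ids, assessments$transcript_id)
  orf <- assessments$longest_orf_aa[hit]
  score <- assessments$external_coding_score[hit]
  homol <- assessments$homology_hit[hit]
  homol[is.na(homol)] <- FALSE

  status <- rep("keep", length(transcript_ids))
  reason <- rep("", length(transcript_ids))

  drop_orf <- !is.na(orf) & orf >= orf_max_aa
  drop_hom <- homol
  drop_score <- !is.na(score) & score >= score_cutoff
  drop <- drop_orf | drop_hom | drop_score
  status[drop] <- "drop"
  reason[drop_score] <- sprintf("external_coding_score >= %g", score_cutoff)
  reason[drop_hom] <- "protein homology hit"
  reason[drop_orf] <- sprintf("ORF >= %d codons", orf_max_aa)

  # no row, or unknown ORF with no other evidence either way
  unassessed <- is.na(hit) | (is.na(orf) & !homol & is.na(score))
  status[unassessed] <- "needs_assessment"
  reason[unassessed] <- "no usable coding assessment"

  data.frame(transcript_id = transcript_ids, status = status,
             reason = reason, stringsAsFactors = FALSE)
}

#' Classify lncRNA candidate transcripts
#'
#' Assigns each candidate transcript exactly one category following a fixed
#' decision order:
#' \enumerate{
#'   \item mature length at or below `min_length_nt` -> `excluded_short`;
#'   \item maximum FPKM across samples below `min_expression_fpkm`
#'     -> `excluded_low_expression` (only when `max_fpkm` is supplied);
#'   \item exonic overlap with a protein-coding gene on the same strand
#'     -> `excluded_coding`;
#'   \item exonic overlap with a protein-coding gene on the opposite strand
#'     -> `antisense`;
#'   \item containment within a coding gene's span on the same strand with
#'     no exonic overlap (intron-contained) -> `excluded_intronic_same_strand`;
#'   \item a small RNA inside an exon or intron of the transcript
#'     -> `small_rna_host`;
#'   \item otherwise (intergenic) -> `lincRNA`.
#' }
#' Transcripts are assumed to have passed [coding_filter()] already.
#'
#' @param ts `transcript_set` of candidates.
#' @param coding_genes `gene_set` of protein-coding genes (reference
#'   annotation).
#' @param small_rnas Optional interval data frame (`chrom`, `start`, `end`,
#'   optional `name`) of annotated small RNAs.
#' @param max_fpkm Optional named numeric vector: maximum FPKM per
#'   transcript across the study samples. `NA`/missing names skip the
#'   expression filter for that transcript.
#' @param min_length_nt Minimum mature length in nt, exclusive (default
#'   200: a lncRNA must be longer than 200 nt).
#' @param min_expression_fpkm Expression floor on the per-transcript
#'   maximum FPKM (default 0.1).
#' @return Data frame with columns `transcript_id`, `category`, `evidence`.
#' @export
classify_lncrna <- function(ts, coding_genes, small_rnas = NULL,
                            max_fpkm = NULL, min_length_nt = 200,
                            min_expression_fpkm = 0.1) {
  stopifnot(inherits(ts, "transcript_set"), inherits(coding_genes, "gene_set"))
  tx <- ts$tx
  n <- nrow(tx)
  category <- rep(NA_character_, n)
  evidence <- rep("", n)

  set_cat <- function(idx, cat, ev) {
    new <- idx & is.na(category)
    category[new] <<- cat
    evidence[new] <<- if (length(ev) == 1L) ev else ev[new]
  }

  # (1) length
  set_cat(tx$mature_length <= min_length_nt, "excluded_short",
          sprintf("mature length %d nt <= %d", as.integer(tx$mature_length),
                  as.integer(min_length_nt)))

  # (2) expression
  if (!is.null(max_fpkm)) {
    mx <- max_fpkm[tx$transcript_id]
    low <- !is.na(mx) & mx < min_expression_fpkm
    set_cat(low, "excluded_low_expression",
            sprintf("max FPKM %.4g < %.4g", mx, min_expression_fpkm))
  }

  # exonic overlaps with coding genes, both strand senses
  first_partner <- function(pairs) {
    pairs$gene <- coding_genes$members$gene_id[
      match(pairs$tx_b, coding_genes$members$transcript_id)]
    pairs <- pairs[order(pairs$tx_a, -pairs$overlap_bp, pairs$gene, method = "radix"), ,
                   drop = FALSE]
    pairs[!duplicated(pairs$tx_a), , drop = FALSE]
  }
  ov_same <- first_partner(exonic_overlap(ts, coding_genes$ts, "same"))
  ov_opp <- first_partner(exonic_overlap(ts, coding_genes$ts, "opposite"))

  # (3) same-strand exonic overlap with coding -> excluded_coding
  hit_same <- match(tx$transcript_id, ov_same$tx_a)
  set_cat(!is.na(hit_same), "excluded_coding",
          sprintf("same-strand exonic overlap with coding gene %s",
                  ov_same$gene[hit_same]))

  # (4) antisense
  hit_opp <- match(tx$transcript_id, ov_opp$tx_a)
  set_cat(!is.na(hit_opp), "antisense",
          sprintf("opposite-strand exonic overlap with coding gene %s",
                  ov_opp$gene[hit_opp]))

  # (5) intron-contained on the same strand
  g_tx <- gr_spans(tx)
  g_genes <- gr_spans(coding_genes$genes, id_col = "gene_id")
  within_hits <- GenomicRanges::findOverlaps(g_tx, g_genes, type = "within",
                                             ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(within_hits)
  si <- S4Vectors::subjectHits(within_hits)
  ok <- strand_pair_ok(g_tx$strand_token[qi], g_genes$strand_token[si], "same")
  contained <- rep(FALSE, n)
  host_gene <- rep(NA_character_, n)
  contained[qi[ok]] <- TRUE
  host_gene[qi[ok]] <- g_genes$id[si[ok]]
  set_cat(contained, "excluded_intronic_same_strand",
          sprintf("contained in coding gene %s on the same strand", host_gene))

  # (6) small-RNA host
  if (!is.null(small_rnas) && nrow(small_rnas) > 0L) {
    validate_intervals(small_rnas, "small_rnas")
    g_small <- GenomicRanges::GRanges(
      seqnames = small_rnas$chrom,
      ranges = IRanges::IRanges(small_rnas$start + 1L, small_rnas$end))
    host_hits <- GenomicRanges::findOverlaps(g_small, g_tx, type = "within",
                                             ignore.strand = TRUE)
    hosts <- rep(FALSE, n)
    small_name <- rep(NA_character_, n)
    hi <- S4Vectors::subjectHits(host_hits)
    hosts[hi] <- TRUE
    nm <- if ("name" %in% names(small_rnas)) small_rnas$name else
      sprintf("small_rna_%d", seq_len(nrow(small_rnas)))
    small_name[hi] <- nm[S4Vectors::queryHits(host_hits)]
    set_cat(hosts, "small_rna_host",
            sprintf("hosts small RNA %s", small_name))
  }

  # (7) intergenic
  set_cat(rep(TRUE, n), "lincRNA", "no overlap with coding annotation")

  out <- data.frame(transcript_id = tx$transcript_id, category = category,
                    evidence = evidence, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Gene-level lncRNA category
#'
#' Lifts transcript categories to genes with the precedence
#' `small_rna_host > antisense > lincRNA`; a gene whose transcripts are all
#' excluded is `excluded`.
#'
#' @param genes A `gene_set` of candidate lncRNA genes.
#' @param transcript_calls Output of [classify_lncrna()] covering every
#'   member transcript.
#' @return Data frame with columns `gene_id`, `category`.
#' @export
classify_gene <- function(genes, transcript_calls) {
  stopifnot(inherits(genes, "gene_set"))
  assert_cols(transcript_calls, c("transcript_id", "category"),
              "transcript_calls")
  cat_by_tx <- transcript_calls$category[
    match(genes$members$transcript_id, transcript_calls$transcript_id)]
  if (anyNA(cat_by_tx)) {
    stop_earlinc("unclassified member transcript(s): %s",
                 paste(utils::head(genes$members$transcript_id[is.na(cat_by_tx)],
                                   5L), collapse = ", "))
  }
  precedence <- c(small_rna_host = 3L, antisense = 2L, lincRNA = 1L)
  rank <- precedence[cat_by_tx]
  rank[is.na(rank)] <- 0L  # excluded_* categories
  best <- tapply(rank, genes$members$gene_id, max)
  category <- names(precedence)[match(best, precedence)]
  category[best == 0L] <- "excluded"
  out <- data.frame(gene_id = names(best), category = as.character(category),
                    stringsAsFactors = FALSE)
  out <- out[match(genes$genes$gene_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag novel lncRNA genes against a reference annotation
#'
#' A gene is novel iff none of its transcripts has any exonic overlap with
#' a reference lncRNA transcript. The default compares exons on either
#' strand (a conservative reading of "does not overlap the reference");
#' strand-restricted comparison is available via `strand_mode = "same"`.
#'
#' @param lnc_genes `gene_set` of candidate lncRNA genes.
#' @param reference `gene_set` (or `transcript_set`) of known lncRNAs.
#' @param strand_mode `"ignore"` (default) or `"same"`.
#' @return Data frame with columns `gene_id`, `novel` (logical), with
#'   attribute `counts` = c(novel, known). Chromosomes present in the
#'   candidates but absent from the reference trigger a warning report.
#' @export
call_novelty <- function(lnc_genes, reference,
                         strand_mode = c("ignore", "same")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(lnc_genes, "gene_set"))
  ref_ts <- if (inherits(reference, "gene_set")) reference$ts else reference
  stopifnot(inherits(ref_ts, "transcript_set"))
  unmatched <- setdiff(unique(lnc_genes$genes$chrom), unique(ref_ts$tx$chrom))
  if (length(unmatched) > 0L) {
    warn_earlinc("chromosome(s) absent from reference: %s",
                 paste(unmatched, collapse = ", "))
  }
  pairs <- exonic_overlap(lnc_genes$ts, ref_ts, strand_mode)
  overlapping_tx <- unique(pairs$tx_a)
  gene_hit <- lnc_genes$members$gene_id[
    lnc_genes$members$transcript_id %in% overlapping_tx]
  novel <- !(lnc_genes$genes$gene_id %in% gene_hit)
  out <- data.frame(gene_id = lnc_genes$genes$gene_id, novel = novel,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(novel = sum(novel), known = sum(!novel))
  out
}
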