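#' Configuration for the synthetic inner-ear study generator
#'
#' Defaults encode the emulated study conditions: a 2 tissues x 2 stages x
#' 3 replicates design (twelve samples), lincRNA/antisense transcripts
#' with 2-3 exons versus 4-5 for protein-coding and small-RNA-host
#' transcripts, lncRNA expression a median of ~0.3 FPKM against ~5.9 FPKM
#' for coding genes, a 66-sample multi-tissue specificity panel with 46%
#' of lncRNAs silent everywhere, negative-binomial counts at dispersion
#' 0.1, and a mirrored human genome carrying syntenic/sequence orthologs
#' between 1:1 coding-gene anchors.
#'
#' @param seed Integer seed; every generator consumes seeds derived from
#'   it, so equal seeds give byte-identical outputs.
#' @param ... Named overrides of any default listed below.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # genome geometry
    n_chroms = 2L,
    n_coding = 60L,
    coding_exons = c(4L, 5L),
    coding_exon_bp = c(150L, 400L),
    coding_intron_bp = c(500L, 1500L),
    long_intron_bp = c(6000L, 9000L),
    intergenic_bp = c(80000L, 200000L),
    # planted lncRNA classes
    n_linc = 24L,
    n_antisense = 10L,
    n_host = 6L,
    n_divergent = 3L,
    n_short = 6L,
    n_intronic = 6L,
    n_coding_like = 6L,
    n_low_expression = 6L,
    lnc_exons = c(2L, 3L),
    lnc_exon_bp = c(200L, 600L),
    lnc_intron_bp = c(500L, 2000L),
    small_rna_bp = c(80L, 120L),
    isoform_prob = 0.3,
    known_fraction = 0.5,
    # expression model
    tissues = c("cochlea", "vestibule"),
    stages = c("E16.5", "P0"),
    replicates = 3L,
    nb_dispersion = 0.1,
    library_size = 2e7,
    library_size_jitter = 0.3,
    coding_median_fpkm = 5.9,
    lnc_median_fpkm = 0.3,
    fpkm_sdlog = 0.8,
    coding_floor_fpkm = 0.5,
    lnc_floor_fpkm = 0.2,
    low_expression_fpkm = 5e-4,
    condition_fraction = 0.3,
    condition_sd = 0.8,
    n_background = 20000L,
    background_median_fpkm = 12,
    background_length_bp = 2500,
    n_de = 10L,
    de_log2fc = 2,
    n_cis_pairs = 4L,
    cis_latent_sd = 2,
    # orthology
    ortholog_fraction = 0.6,
    ortholog_both_fraction = 0.2,
    ortholog_sequence_fraction = 0.2,
    anchor_inverted_fraction = 0.25,
    n_decoy_human_lnc = 5L,
    n_decoy_hits = 30L,
    n_human_samples = 6L,
    # specificity panel
    n_panel_samples = 66L,
    panel_silent_fraction = 0.46,
    panel_ubiquitous_fraction = 0.15,
    # disease annotation
    n_extra_disease = 2L,
    n_loci = 4L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop_earlinc("unknown sim_config field(s): %s",
                 paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "sim_config")
}

rint <- function(lo, hi, n = 1L) {
  if (lo >= hi) return(rep(as.integer(lo), n))
  as.integer(sample(seq.int(lo, hi), n, replace = TRUE))
}

# One spliced transcript laid left-to-right from `pos`.
mk_exons <- function(tid, gid, chrom, pos, strand, exon_w, intron_w) {
  starts <- pos + cumsum(c(0, head_(exon_w, -1L) + intron_w))
  data.frame(transcript_id = tid, gene_id = gid, chrom = chrom,
             start = starts, end = starts + exon_w, strand = strand,
             stringsAsFactors = FALSE)
}
head_ <- function(x, n) utils::head(x, n)

lnc_exon_plan <- function(cfg) {
  n_ex <- rint(cfg$lnc_exons[1], cfg$lnc_exons[2])
  list(w = rint(cfg$lnc_exon_bp[1], cfg$lnc_exon_bp[2], n_ex),
       iw = if (n_ex > 1L) rint(cfg$lnc_intron_bp[1], cfg$lnc_intron_bp[2],
                                n_ex - 1L) else integer())
}
plan_span <- function(p) sum(p$w) + sum(p$iw)

# Optional second isoform: first exon shortened by 100 bp (keeps class).
maybe_isoform <- function(cfg, exons, tid2) {
  if (stats::runif(1) > cfg$isoform_prob) return(NULL)
  iso <- exons
  iso$transcript_id <- tid2
  iso$start[1L] <- iso$start[1L] + 100L
  iso
}

#' Generate the synthetic annotation universe
#'
#' Lays out a mouse genome of protein-coding genes separated by large
#' intergenic gaps and plants one lncRNA-class feature per gap with >= 1 kb
#' safety margins, so every planted label is geometrically unambiguous:
#' lincRNAs (including divergent head-to-head lincRNAs), antisense
#' transcripts overlapping a coding exon on the opposite strand, small-RNA
#' hosts with the small RNA inside a long intron, and planted exclusion
#' classes (short, intronic-same-strand, coding-like, low-expression). A
#' mirrored human genome provides 1:1 anchor blocks of equal span length
#' (some inverted) and carries human lncRNA orthologs placed syntenically
#' between the anchors flanking their mouse counterpart.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `earlinc_simulation` with elements `assembled`
#'   (mouse transcript set as an assembler would emit it), `reference`
#'   (curated annotation: protein-coding, small RNA, known lncRNA),
#'   `human_lnc` (human lncRNA gene table), `anchors` (anchor-block
#'   table), `assessments` (coding-potential table), `truth` (planted
#'   ground truth), and `cfg`.
#' @export
generate_annotation <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  hchroms <- sprintf("hchr%d", seq_len(cfg$n_chroms))
  per_chrom <- diff(round(seq(0, cfg$n_coding, length.out = cfg$n_chroms + 1L)))

  long_intron_genes <- sort(sample.int(cfg$n_coding, cfg$n_intronic))

  coding <- list()   # one row per coding gene
  exon_rows <- list()
  g <- 0L
  for (ci in seq_along(chroms)) {
    cursor <- 100000L
    for (k in seq_len(per_chrom[ci])) {
      g <- g + 1L
      gid <- sprintf("CODG%04d", g)
      tid <- sprintf("CODT%04d", g)
      n_ex <- rint(cfg$coding_exons[1], cfg$coding_exons[2])
      w <- rint(cfg$coding_exon_bp[1], cfg$coding_exon_bp[2], n_ex)
      iw <- rint(cfg$coding_intron_bp[1], cfg$coding_intron_bp[2], n_ex - 1L)
      long_intron <- NA
      if (g %in% long_intron_genes) {
        iw[1L] <- rint(cfg$long_intron_bp[1], cfg$long_intron_bp[2])
        long_intron <- 1L
      }
      strand <- sample(c("+", "-"), 1L)
      ex <- mk_exons(tid, gid, chroms[ci], cursor, strand, w, iw)
      exon_rows[[length(exon_rows) + 1L]] <- ex
      coding[[g]] <- data.frame(
        idx = g, gene_id = gid, transcript_id = tid, chrom = chroms[ci],
        start = min(ex$start), end = max(ex$end), strand = strand,
        long_intron = long_intron, chrom_idx = ci, pos_on_chrom = k,
        gap_after = rint(cfg$intergenic_bp[1], cfg$intergenic_bp[2]),
        stringsAsFactors = FALSE)
      cursor <- max(ex$end) + coding[[g]]$gap_after
    }
  }
  coding <- do.call(rbind, coding)
  coding_exons_df <- do.call(rbind, exon_rows)

  # gaps between consecutive coding genes on the same chromosome
  gaps <- do.call(rbind, lapply(split(coding, coding$chrom_idx), function(cc) {
    cc <- cc[order(cc$pos_on_chrom), ]
    if (nrow(cc) < 2L) return(NULL)
    data.frame(chrom = cc$chrom[-nrow(cc)], left = cc$idx[-nrow(cc)],
               right = cc$idx[-1L], lo = cc$end[-nrow(cc)],
               hi = cc$start[-1L], stringsAsFactors = FALSE)
  }))
  rownames(gaps) <- NULL
  need <- cfg$n_linc + cfg$n_host + cfg$n_short + cfg$n_low_expression +
    cfg$n_coding_like + cfg$n_divergent
  if (nrow(gaps) < need + 2L) {
    stop_earlinc("chromosome too short for requested genes: %d gaps for %d features; increase n_coding or n_chroms",
                 nrow(gaps), need)
  }
  gap_order <- sample.int(nrow(gaps))

  lnc_exon_rows <- list()
  small_rnas <- list()
  truth_tx <- list()
  lnc_genes <- list()
  next_gap <- 0L
  gene_n <- 0L
  tx_n <- 0L
  take_gap <- function() {
    next_gap <<- next_gap + 1L
    gaps[gap_order[next_gap], ]
  }
  new_gid <- function() {
    gene_n <<- gene_n + 1L
    sprintf("XLOC_%06d", gene_n)
  }
  new_tid <- function() {
    tx_n <<- tx_n + 1L
    sprintf("XT_%05d", tx_n)
  }
  add_feature <- function(exons, class, gap_row = NULL,
                          partner = NA_character_, allow_isoform = TRUE) {
    gid <- exons$gene_id[1L]
    all_ex <- exons
    truth_tx[[length(truth_tx) + 1L]] <<- data.frame(
      transcript_id = exons$transcript_id[1L], gene_id = gid, class = class,
      stringsAsFactors = FALSE)
    if (allow_isoform) {
      iso <- maybe_isoform(cfg, exons, new_tid())
      if (!is.null(iso)) {
        all_ex <- rbind(all_ex, iso)
        truth_tx[[length(truth_tx) + 1L]] <<- data.frame(
          transcript_id = iso$transcript_id[1L], gene_id = gid,
          class = class, stringsAsFactors = FALSE)
      }
    }
    lnc_exon_rows[[length(lnc_exon_rows) + 1L]] <<- all_ex
    lnc_genes[[length(lnc_genes) + 1L]] <<- data.frame(
      gene_id = gid, class = class, chrom = exons$chrom[1L],
      start = min(all_ex$start), end = max(all_ex$end),
      strand = exons$strand[1L],
      gap_left = if (is.null(gap_row)) NA_integer_ else gap_row$left,
      gap_right = if (is.null(gap_row)) NA_integer_ else gap_row$right,
      partner = partner, stringsAsFactors = FALSE)
    gid
  }
  centered_feature <- function(class, allow_isoform = TRUE) {
    gp <- take_gap()
    p <- lnc_exon_plan(cfg)
    span <- plan_span(p)
    start <- gp$lo + ((gp$hi - gp$lo - span) %/% 2L)
    ex <- mk_exons(new_tid(), new_gid(), gp$chrom, start,
                   sample(c("+", "-"), 1L), p$w, p$iw)
    add_feature(ex, class, gap_row = gp, allow_isoform = allow_isoform)
  }

  for (i in seq_len(cfg$n_linc)) centered_feature("lincRNA")
  for (i in seq_len(cfg$n_coding_like)) {
    centered_feature("excluded_coding", allow_isoform = FALSE)
  }
  for (i in seq_len(cfg$n_low_expression)) {
    centered_feature("excluded_low_expression", allow_isoform = FALSE)
  }
  for (i in seq_len(cfg$n_short)) {
    gp <- take_gap()
    w <- rint(120L, 180L)
    start <- gp$lo + ((gp$hi - gp$lo - w) %/% 2L)
    ex <- mk_exons(new_tid(), new_gid(), gp$chrom, start,
                   sample(c("+", "-"), 1L), w, integer())
    add_feature(ex, "excluded_short", gap_row = gp, allow_isoform = FALSE)
  }
  for (i in seq_len(cfg$n_host)) {
    gp <- take_gap()
    n_ex <- rint(4L, 5L)
    w <- rint(cfg$lnc_exon_bp[1], cfg$lnc_exon_bp[2], n_ex)
    iw <- rint(cfg$lnc_intron_bp[1], cfg$lnc_intron_bp[2], n_ex - 1L)
    iw[1L] <- rint(4000L, 6000L)   # the hosting intron
    span <- sum(w) + sum(iw)
    start <- gp$lo + ((gp$hi - gp$lo - span) %/% 2L)
    strand <- sample(c("+", "-"), 1L)
    ex <- mk_exons(new_tid(), new_gid(), gp$chrom, start, strand, w, iw)
    gid <- add_feature(ex, "small_rna_host", gap_row = gp)
    sw <- rint(cfg$small_rna_bp[1], cfg$small_rna_bp[2])
    intron_lo <- ex$end[1L]
    intron_hi <- ex$start[2L]
    s_start <- intron_lo + ((intron_hi - intron_lo - sw) %/% 2L)
    small_rnas[[length(small_rnas) + 1L]] <- data.frame(
      gene_id = sprintf("MIRG%03d", i), transcript_id = sprintf("MIRT%03d", i),
      chrom = gp$chrom, start = s_start, end = s_start + sw, strand = strand,
      host_gene = gid, stringsAsFactors = FALSE)
  }

  # divergent head-to-head lincRNAs next to a coding gene 5' end
  divergent_done <- 0L
  while (divergent_done < cfg$n_divergent && next_gap < nrow(gaps)) {
    gp <- take_gap()
    right <- coding[gp$right, ]
    left <- coding[gp$left, ]
    p <- lnc_exon_plan(cfg)
    span <- plan_span(p)
    d <- rint(100L, 800L)
    if (right$strand == "+") {
      start <- gp$hi - d - span
      ex <- mk_exons(new_tid(), new_gid(), gp$chrom, start, "-", p$w, p$iw)
      partner <- right$gene_id
    } else if (left$strand == "-") {
      ex <- mk_exons(new_tid(), new_gid(), gp$chrom, gp$lo + d, "+",
                     p$w, p$iw)
      partner <- left$gene_id
    } else {
      next
    }
    add_feature(ex, "lincRNA", gap_row = gp, partner = partner)
    divergent_done <- divergent_done + 1L
  }
  if (divergent_done < cfg$n_divergent) {
    stop_earlinc("geometry overflow: could not place %d divergent lincRNAs; increase n_coding",
                 cfg$n_divergent)
  }

  # antisense transcripts over a coding exon, opposite strand
  used_partner <- vapply(lnc_genes, function(x) x$partner, "")
  antisense_pool <- setdiff(coding$gene_id[is.na(coding$long_intron)],
                            used_partner)
  antisense_genes <- sample(antisense_pool, cfg$n_antisense)
  for (gid_c in antisense_genes) {
    cg <- coding[coding$gene_id == gid_c, ]
    cg_ex <- coding_exons_df[coding_exons_df$gene_id == gid_c, ]
    cg_ex <- cg_ex[order(cg_ex$start), ]
    p <- lnc_exon_plan(cfg)
    if (cg$strand == "+") {
      # overlap first exon, extend upstream (leftward) on the minus strand
      e1 <- cg_ex[1L, ]
      anchor_w <- min(250L, e1$end - e1$start + 100L)
      anchor_start <- e1$start - 100L
      other_w <- p$w[-1L]
      iw <- p$iw
      starts <- anchor_start - rev(cumsum(rev(other_w + iw)))
      ex <- data.frame(
        transcript_id = new_tid(), gene_id = new_gid(), chrom = cg$chrom,
        start = c(starts, anchor_start),
        end = c(starts + other_w, anchor_start + anchor_w),
        strand = "-", stringsAsFactors = FALSE)
    } else {
      e_last <- cg_ex[nrow(cg_ex), ]
      anchor_w <- min(250L, e_last$end - e_last$start + 100L)
      anchor_start <- e_last$end - anchor_w + 100L
      other_w <- p$w[-1L]
      iw <- p$iw
      starts <- anchor_start + anchor_w + cumsum(iw) +
        cumsum(c(0L, head_(other_w, -1L)))
      ex <- data.frame(
        transcript_id = new_tid(), gene_id = new_gid(), chrom = cg$chrom,
        start = c(anchor_start, starts),
        end = c(anchor_start + anchor_w, starts + other_w),
        strand = "+", stringsAsFactors = FALSE)
    }
    add_feature(ex, "antisense", partner = cg$gene_id)
  }

  # intron-contained same-strand transcripts inside the long introns
  for (j in seq_along(long_intron_genes)) {
    cg <- coding[long_intron_genes[j], ]
    cg_ex <- coding_exons_df[coding_exons_df$gene_id == cg$gene_id, ]
    cg_ex <- cg_ex[order(cg_ex$start), ]
    intron_lo <- cg_ex$end[1L]
    intron_hi <- cg_ex$start[2L]
    n_ex <- rint(1L, 2L)
    w <- rint(250L, 450L, n_ex)
    iw <- if (n_ex > 1L) rint(500L, 1200L, n_ex - 1L) else integer()
    span <- sum(w) + sum(iw)
    start <- intron_lo + ((intron_hi - intron_lo - span) %/% 2L)
    ex <- mk_exons(new_tid(), new_gid(), cg$chrom, start, cg$strand, w, iw)
    add_feature(ex, "excluded_intronic_same_strand", partner = cg$gene_id,
                allow_isoform = FALSE)
  }

  lnc_genes <- do.call(rbind, lnc_genes)
  truth_tx <- do.call(rbind, truth_tx)
  small_rnas <- if (length(small_rnas) > 0L) do.call(rbind, small_rnas) else
    data.frame(gene_id = character(), transcript_id = character(),
               chrom = character(), start = numeric(), end = numeric(),
               strand = character(), host_gene = character())

  # assembled transcriptome: coding transcripts re-discovered by the
  # assembler (shared gene ids with the reference) plus all candidates
  assembled_exons <- rbind(
    transform(coding_exons_df,
              transcript_id = sub("CODT", "XTC_", transcript_id)),
    do.call(rbind, lnc_exon_rows))
  assembled <- transcript_set(assembled_exons)
  truth_tx <- rbind(truth_tx, data.frame(
    transcript_id = sub("CODT", "XTC_", coding$transcript_id),
    gene_id = coding$gene_id, class = "excluded_coding",
    stringsAsFactors = FALSE))

  # known lncRNAs: reference copies of a fraction of the lncRNA genes
  lnc_universe <- lnc_genes[lnc_genes$class %in%
                              c("lincRNA", "antisense", "small_rna_host"), ]
  known_ids <- sort(method = "radix", sample(lnc_universe$gene_id,
                           round(cfg$known_fraction * nrow(lnc_universe))))
  lnc_all_exons <- do.call(rbind, lnc_exon_rows)
  known_exons <- lnc_all_exons[lnc_all_exons$gene_id %in% known_ids, ]
  if (nrow(known_exons) > 0L) {
    known_exons$transcript_id <- paste0("KN_", known_exons$transcript_id)
    known_exons$gene_id <- paste0("KNLNC_", known_exons$gene_id)
  }

  ref_exons <- rbind(
    cbind(coding_exons_df, biotype = "protein_coding"),
    if (nrow(small_rnas) > 0L) data.frame(
      transcript_id = small_rnas$transcript_id, gene_id = small_rnas$gene_id,
      chrom = small_rnas$chrom, start = small_rnas$start,
      end = small_rnas$end, strand = small_rnas$strand,
      biotype = "small_rna", stringsAsFactors = FALSE),
    if (nrow(known_exons) > 0L) cbind(known_exons, biotype = "known_lncRNA"))
  reference <- transcript_set(ref_exons)

  # ---- human mirror: anchors and lncRNAs ----------------------------------
  anchors <- list()
  for (ci in seq_along(chroms)) {
    cc <- coding[coding$chrom_idx == ci, ]
    cc <- cc[order(cc$pos_on_chrom), ]
    cursor <- 100000L
    for (k in seq_len(nrow(cc))) {
      len <- cc$end[k] - cc$start[k]
      anchors[[length(anchors) + 1L]] <- data.frame(
        mouse_chrom = cc$chrom[k], mouse_start = cc$start[k],
        mouse_end = cc$end[k], mouse_gene = cc$gene_id[k],
        human_chrom = hchroms[ci], human_start = cursor,
        human_end = cursor + len,
        human_gene = sub("CODG", "HSCODG", cc$gene_id[k]),
        orientation = if (stats::runif(1) < cfg$anchor_inverted_fraction)
          "inverted" else "same",
        stringsAsFactors = FALSE)
      cursor <- cursor + len +
        as.integer(round(cc$gap_after[k] * stats::runif(1, 0.8, 1.2)))
    }
  }
  anchors <- do.call(rbind, anchors)

  # ortholog selection among plain lincRNAs (divergent ones excluded to
  # keep the cis/clustering plantings independent)
  linc_plain <- lnc_genes[lnc_genes$class == "lincRNA" &
                            is.na(lnc_genes$partner), ]
  n_orth <- round(cfg$ortholog_fraction * nrow(linc_plain))
  orth_mouse <- sample(linc_plain$gene_id, n_orth)
  n_both <- round(cfg$ortholog_both_fraction * n_orth)
  n_seq <- round(cfg$ortholog_sequence_fraction * n_orth)
  evidence <- c(rep("sequence,synteny", n_both), rep("sequence", n_seq),
                rep("synteny", n_orth - n_both - n_seq))
  evidence <- sample(evidence)

  human_window <- function(left_idx, right_idx) {
    hl <- anchors[anchors$mouse_gene == coding$gene_id[left_idx], ]
    hr <- anchors[anchors$mouse_gene == coding$gene_id[right_idx], ]
    c(lo = hl$human_end + 2000, hi = hr$human_start - 2000,
      chrom = hl$human_chrom)
  }
  used_gaps <- c(lnc_genes$gap_left[!is.na(lnc_genes$gap_left)])
  empty_gaps <- gaps[!(gaps$left %in% used_gaps), , drop = FALSE]
  empty_order <- sample.int(nrow(empty_gaps))
  next_empty <- 0L

  human_lnc <- list()
  h_n <- 0L
  place_human_lnc <- function(left_idx, right_idx, span_len) {
    hw <- human_window(left_idx, right_idx)
    lo <- as.numeric(hw["lo"]); hi <- as.numeric(hw["hi"])
    span_len <- min(span_len, floor((hi - lo) * 0.5))
    start <- lo + ((hi - lo - span_len) %/% 2)
    h_n <<- h_n + 1L
    df <- data.frame(gene_id = sprintf("HSLNC%04d", h_n),
                     chrom = hw[["chrom"]], start = start,
                     end = start + span_len,
                     strand = sample(c("+", "-"), 1L),
                     stringsAsFactors = FALSE)
    human_lnc[[length(human_lnc) + 1L]] <<- df
    df$gene_id
  }

  orth_pairs <- list()
  for (i in seq_along(orth_mouse)) {
    mg <- lnc_genes[lnc_genes$gene_id == orth_mouse[i], ]
    span_len <- mg$end - mg$start
    if (grepl("synteny", evidence[i])) {
      hg <- place_human_lnc(mg$gap_left, mg$gap_right, span_len)
    } else {
      # sequence-only: placed in a window mirroring an empty mouse gap
      next_empty <- next_empty + 1L
      if (next_empty > nrow(empty_gaps)) {
        stop_earlinc("geometry overflow: not enough empty intergenic gaps for sequence-only orthologs; increase n_coding")
      }
      eg <- empty_gaps[empty_order[next_empty], ]
      hg <- place_human_lnc(eg$left, eg$right, span_len)
    }
    orth_pairs[[i]] <- data.frame(mouse_gene = mg$gene_id, human_gene = hg,
                                  evidence = evidence[i],
                                  stringsAsFactors = FALSE)
  }
  orth_pairs <- do.call(rbind, orth_pairs)

  for (i in seq_len(cfg$n_decoy_human_lnc)) {
    next_empty <- next_empty + 1L
    if (next_empty > nrow(empty_gaps)) break
    eg <- empty_gaps[empty_order[next_empty], ]
    place_human_lnc(eg$left, eg$right, rint(3000L, 8000L))
  }
  human_lnc <- do.call(rbind, human_lnc)
  rownames(human_lnc) <- NULL

  # expression archetypes for the ortholog pairs (three planted groups)
  n_pairs <- nrow(orth_pairs)
  arche <- rep(1:3, length.out = n_pairs)[sample.int(n_pairs)]
  orth_pairs$archetype <- arche

  # ---- disease genes, cis pairs, loci -------------------------------------
  disease <- list()
  add_disease <- function(gene_id, term, chrom, start, end, strand,
                          lnc = NA, rel = NA) {
    disease[[length(disease) + 1L]] <<- data.frame(
      gene_id = gene_id, term = term, chrom = chrom, start = start,
      end = end, strand = strand, lncrna_gene = lnc,
      expected_relationship = rel, stringsAsFactors = FALSE)
  }
  div_genes <- lnc_genes[lnc_genes$class == "lincRNA" &
                           !is.na(lnc_genes$partner), ]
  for (i in seq_len(nrow(div_genes))) {
    cg <- coding[coding$gene_id == div_genes$partner[i], ]
    add_disease(cg$gene_id, "MP:0001967", cg$chrom, cg$start, cg$end,
                cg$strand, div_genes$gene_id[i], "overlapping_divergent")
  }
  as_genes <- lnc_genes[lnc_genes$class == "antisense", ]
  for (i in seq_len(min(2L, nrow(as_genes)))) {
    cg <- coding[coding$gene_id == as_genes$partner[i], ]
    add_disease(cg$gene_id, "MP:0001967", cg$chrom, cg$start, cg$end,
                cg$strand, as_genes$gene_id[i], "antisense")
  }
  for (i in seq_len(min(2L, nrow(small_rnas)))) {
    sr <- small_rnas[i, ]
    add_disease(sr$gene_id, "MP:0006325", sr$chrom, sr$start, sr$end,
                sr$strand, sr$host_gene, "host_in_intron")
  }
  # cis-correlated pairs: plain lincRNAs (non-ortholog) with their nearest
  # coding neighbour as the disease gene
  cis_pool <- linc_plain[!(linc_plain$gene_id %in% orth_mouse), ]
  n_cis <- min(cfg$n_cis_pairs, nrow(cis_pool))
  cis_lncs <- cis_pool[sample.int(nrow(cis_pool), n_cis), ]
  cis_pairs <- list()
  for (i in seq_len(n_cis)) {
    cg <- coding[cis_lncs$gap_left[i], ]   # left flanking coding gene
    add_disease(cg$gene_id, "MP:0006325", cg$chrom, cg$start, cg$end,
                cg$strand, cis_lncs$gene_id[i], "proximal")
    cis_pairs[[i]] <- data.frame(lncrna_gene = cis_lncs$gene_id[i],
                                 disease_gene = cg$gene_id,
                                 stringsAsFactors = FALSE)
  }
  cis_pairs <- if (n_cis > 0L) do.call(rbind, cis_pairs) else
    data.frame(lncrna_gene = character(), disease_gene = character())
  disease_used <- unique(vapply(disease, function(d) d$gene_id, ""))
  extra_pool <- setdiff(coding$gene_id, disease_used)
  for (gid_c in sample(extra_pool, min(cfg$n_extra_disease,
                                       length(extra_pool)))) {
    cg <- coding[coding$gene_id == gid_c, ]
    add_disease(cg$gene_id, "MP:0006325", cg$chrom, cg$start, cg$end,
                cg$strand)
  }
  disease <- do.call(rbind, disease)

  # human disease loci spanning three consecutive anchors
  loci <- list()
  for (j in seq_len(cfg$n_loci)) {
    ci <- ((j - 1L) %% cfg$n_chroms) + 1L
    cc <- coding[coding$chrom_idx == ci, ]
    cc <- cc[order(cc$pos_on_chrom), ]
    i0 <- rint(1L, nrow(cc) - 2L)
    a1 <- anchors[anchors$mouse_gene == cc$gene_id[i0], ]
    a2 <- anchors[anchors$mouse_gene == cc$gene_id[i0 + 2L], ]
    off1 <- (a1$human_end - a1$human_start) %/% 2L
    off2 <- (a2$human_end - a2$human_start) %/% 2L
    h_start <- a1$human_start + off1
    h_end <- a2$human_start + off2
    # independent truth by equal-length offset arithmetic on the mouse side
    m1 <- if (a1$orientation == "same") a1$mouse_start + off1 else
      a1$mouse_end - off1
    m2 <- if (a2$orientation == "same") a2$mouse_start + off2 else
      a2$mouse_end - off2
    loci[[j]] <- data.frame(
      locus_id = sprintf("DFN_SIM%02d", j), chrom = a1$human_chrom,
      start = h_start, end = h_end, mouse_chrom = a1$mouse_chrom,
      mouse_start = min(m1, m2), mouse_end = max(m1, m2),
      stringsAsFactors = FALSE)
  }
  loci <- do.call(rbind, loci)
  lnc_expressed <- lnc_genes[lnc_genes$class %in%
                               c("lincRNA", "antisense", "small_rna_host"), ]
  loci$lnc_genes <- vapply(seq_len(nrow(loci)), function(j) {
    hit <- lnc_expressed$chrom == loci$mouse_chrom[j] &
      lnc_expressed$start < loci$mouse_end[j] &
      lnc_expressed$end > loci$mouse_start[j]
    paste(sort(lnc_expressed$gene_id[hit], method = "radix"), collapse = ",")
  }, "")

  # coding-potential assessments for every assembled transcript
  tx_ids <- assembled$tx$transcript_id
  cls <- truth_tx$class[match(tx_ids, truth_tx$transcript_id)]
  coding_like <- cls == "excluded_coding"
  assessments <- data.frame(
    transcript_id = tx_ids,
    longest_orf_aa = ifelse(coding_like, rint(120L, 300L, length(tx_ids)),
                            rint(5L, 80L, length(tx_ids))),
    external_coding_score = ifelse(coding_like,
                                   round(stats::runif(length(tx_ids), 5, 60), 2),
                                   round(stats::runif(length(tx_ids), -40, -5), 2)),
    homology_hit = coding_like & stats::runif(length(tx_ids)) < 0.5,
    stringsAsFactors = FALSE)

  gene_classes <- lnc_genes[, c("gene_id", "class")]
  gene_classes$novel <- !(gene_classes$gene_id %in% known_ids)
  gene_classes$novel[!(gene_classes$class %in%
                         c("lincRNA", "antisense", "small_rna_host"))] <- NA

  structure(list(
    assembled = assembled,
    reference = reference,
    human_lnc = human_lnc,
    anchors = anchors,
    assessments = assessments,
    coding = coding,
    small_rnas = small_rnas,
    truth = list(
      transcript_classes = truth_tx,
      gene_classes = gene_classes,
      lnc_genes = lnc_genes,
      known_ids = known_ids,
      ortholog_pairs = orth_pairs,
      disease_genes = disease,
      cis_pairs = cis_pairs,
      loci = loci),
    cfg = cfg), class = "earlinc_simulation")
}

#' @export
print.earlinc_simulation <- function(x, ...) {
  cat(sprintf("<earlinc_simulation> seed %d: %d assembled transcripts, %d planted lncRNA genes, %d ortholog pairs\n",
              x$cfg$seed, nrow(x$assembled$tx), nrow(x$truth$lnc_genes),
              nrow(x$truth$ortholog_pairs)))
  invisible(x)
}

truncated_lnorm <- function(n, median, sdlog, floor_) {
  pmax(stats::rlnorm(n, meanlog = log(median), sdlog = sdlog), floor_)
}

nb_draw <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Generate the twelve-sample count matrix with planted signals
#'
#' Draws negative-binomial gene-level counts for the 2 tissues x 2 stages
#' x 3 replicates design. Baseline FPKM levels are log-normal with the
#' configured class medians (coding >> lncRNA); planted DE genes carry a
#' `2^de_log2fc` multiplier in the cochlea; planted cis pairs share a
#' per-sample latent log2 factor that induces a strong expression
#' correlation; a fraction of background genes receives mild condition
#' effects; library sizes jitter around `library_size`.
#'
#' @param ann An `earlinc_simulation` from [generate_annotation()].
#' @param cfg The same [sim_config()] (defaults to `ann$cfg`).
#' @return List with `counts` (an `expression_matrix`, unit counts, with
#'   sample sheet) and `truth` additions: `de_genes` (gene_id, log2fc,
#'   direction), `baseline_fpkm`.
#' @export
generate_counts <- function(ann, cfg = ann$cfg) {
  stopifnot(inherits(ann, "earlinc_simulation"))
  set.seed(cfg$seed + 1L)
  design <- expand.grid(replicate = seq_len(cfg$replicates),
                        stage = cfg$stages, tissue = cfg$tissues,
                        stringsAsFactors = FALSE)
  design <- design[, c("tissue", "stage", "replicate")]
  design$sample_id <- sprintf("%s_%s_r%d", design$tissue, design$stage,
                              design$replicate)
  design$condition <- paste(design$tissue, design$stage, sep = ":")
  n_s <- nrow(design)

  lnc <- ann$truth$lnc_genes
  # unannotated background transcriptome: carries the bulk of the library
  # so that recomputed FPKM sits on the same scale as the planted baselines
  bkg <- sprintf("BKG%05d", seq_len(cfg$n_background))
  genes <- c(ann$coding$gene_id, lnc$gene_id, bkg)
  classes <- c(rep("protein_coding", nrow(ann$coding)), lnc$class,
               rep("background", length(bkg)))
  n_g <- length(genes)

  # gene length: mature length of the longest transcript of the gene
  tx <- ann$assembled$tx
  glen <- tapply(tx$mature_length, tx$gene_id, max)
  gene_lengths <- c(as.numeric(glen[c(ann$coding$gene_id, lnc$gene_id)]),
                    pmax(200, round(stats::rlnorm(
                      length(bkg), log(cfg$background_length_bp), 0.6))))
  names(gene_lengths) <- genes

  baseline <- numeric(n_g)
  is_cod <- classes == "protein_coding"
  baseline[is_cod] <- truncated_lnorm(sum(is_cod), cfg$coding_median_fpkm,
                                      cfg$fpkm_sdlog, cfg$coding_floor_fpkm)
  is_low <- classes == "excluded_low_expression"
  is_bkg <- classes == "background"
  is_lnc <- !is_cod & !is_low & !is_bkg
  baseline[is_lnc] <- truncated_lnorm(sum(is_lnc), cfg$lnc_median_fpkm,
                                      cfg$fpkm_sdlog, cfg$lnc_floor_fpkm)
  baseline[is_low] <- cfg$low_expression_fpkm
  baseline[is_bkg] <- stats::rlnorm(sum(is_bkg),
                                    log(cfg$background_median_fpkm), 1)

  # archetype overrides for ortholog mouse genes (clustering truth)
  op <- ann$truth$ortholog_pairs
  arche_median <- c(`1` = 15, `2` = 15, `3` = 0.4)
  for (i in seq_len(nrow(op))) {
    baseline[genes == op$mouse_gene[i]] <-
      stats::rlnorm(1, log(arche_median[[as.character(op$archetype[i])]]), 0.25)
  }

  conditions <- unique(design$condition)
  mult <- matrix(1, n_g, length(conditions),
                 dimnames = list(genes, conditions))

  # planted DE genes: expressed, not cis/ortholog-planted
  protected <- c(ann$truth$cis_pairs$lncrna_gene,
                 ann$truth$cis_pairs$disease_gene, op$mouse_gene)
  de_pool <- genes[!is_low & !is_bkg & classes != "excluded_short" &
                     !(genes %in% protected)]
  de_genes <- sample(de_pool, min(cfg$n_de, length(de_pool)))
  de_dir <- sample(c(1, -1), length(de_genes), replace = TRUE)
  cochlea_conds <- conditions[startsWith(conditions, cfg$tissues[1])]
  for (i in seq_along(de_genes)) {
    mult[de_genes[i], cochlea_conds] <- 2^(de_dir[i] * cfg$de_log2fc)
  }

  # structured condition effects on a fraction of the transcriptome: a
  # dominant tissue axis and a weaker stage axis, as in the study design
  bg_pool <- setdiff(c(de_pool, bkg), de_genes)
  bg <- sample(bg_pool, round(cfg$condition_fraction * length(bg_pool)))
  tissue_of <- vapply(strsplit(conditions, ":", fixed = TRUE), `[[`, "", 1L)
  stage_of <- vapply(strsplit(conditions, ":", fixed = TRUE), `[[`, "", 2L)
  tissue_coef <- stats::rnorm(length(bg), 0, cfg$condition_sd)
  stage_coef <- stats::rnorm(length(bg), 0, cfg$condition_sd / 2)
  eff <- outer(tissue_coef, as.numeric(tissue_of == cfg$tissues[1])) +
    outer(stage_coef, as.numeric(stage_of == cfg$stages[2]))
  mult[bg, ] <- mult[bg, , drop = FALSE] * 2^eff

  # shared per-sample latent factor for each cis pair
  latent <- matrix(0, n_g, n_s, dimnames = list(genes, design$sample_id))
  cp <- ann$truth$cis_pairs
  for (i in seq_len(nrow(cp))) {
    u <- stats::rnorm(n_s, 0, cfg$cis_latent_sd)
    latent[cp$lncrna_gene[i], ] <- u
    latent[cp$disease_gene[i], ] <- u
  }

  lib <- cfg$library_size *
    stats::runif(n_s, 1 - cfg$library_size_jitter,
                 1 + cfg$library_size_jitter)
  cond_idx <- match(design$condition, conditions)
  mu <- (baseline * gene_lengths / 1e9) %o% lib *
    mult[, cond_idx, drop = FALSE] * 2^latent
  counts <- matrix(nb_draw(length(mu), as.vector(mu), cfg$nb_dispersion),
                   n_g, n_s, dimnames = list(genes, design$sample_id))

  em <- expression_matrix(counts, unit = "counts",
                          gene_lengths = gene_lengths,
                          samples = design[, c("sample_id", "tissue",
                                               "stage", "replicate")])
  list(counts = em,
       de_genes = data.frame(gene_id = de_genes,
                             log2fc = de_dir * cfg$de_log2fc,
                             stringsAsFactors = FALSE),
       baseline_fpkm = stats::setNames(baseline, genes))
}

#' Generate the multi-tissue specificity panel
#'
#' Emits an FPKM panel (default 66 samples) over the planted lncRNA
#' genes: a configurable fraction is silent everywhere (< 1 FPKM in every
#' sample), a fraction is ubiquitous (>= 1 everywhere), and the remainder
#' is expressed in a random subset of samples.
#'
#' @param ann An `earlinc_simulation`.
#' @param cfg A [sim_config()] (defaults to `ann$cfg`).
#' @return List with `panel` (an `expression_matrix`, fpkm) and `truth`
#'   (`silent`, `ubiquitous` gene-id vectors).
#' @export
generate_specificity_panel <- function(ann, cfg = ann$cfg) {
  stopifnot(inherits(ann, "earlinc_simulation"))
  set.seed(cfg$seed + 2L)
  lnc <- ann$truth$lnc_genes
  genes <- lnc$gene_id[lnc$class %in% c("lincRNA", "antisense",
                                        "small_rna_host")]
  n_g <- length(genes)
  n_s <- cfg$n_panel_samples
  n_silent <- round(cfg$panel_silent_fraction * n_g)
  n_ubiq <- round(cfg$panel_ubiquitous_fraction * n_g)
  role <- sample(c(rep("silent", n_silent), rep("ubiquitous", n_ubiq),
                   rep("patchy", n_g - n_silent - n_ubiq)))
  vals <- matrix(stats::runif(n_g * n_s, 0, 0.8), n_g, n_s,
                 dimnames = list(genes, sprintf("panel_%02d", seq_len(n_s))))
  for (i in seq_len(n_g)) {
    if (role[i] == "ubiquitous") {
      vals[i, ] <- stats::runif(n_s, 1.5, 60)
    } else if (role[i] == "patchy") {
      k <- rint(1L, n_s - 1L)
      on <- sample.int(n_s, k)
      vals[i, on] <- stats::runif(k, 1.2, 30)
    }
  }
  list(panel = expression_matrix(vals, unit = "fpkm"),
       truth = list(silent = genes[role == "silent"],
                    ubiquitous = genes[role == "ubiquitous"]))
}

#' Generate the cross-species similarity hit table
#'
#' Planted sequence-evidence ortholog pairs receive 1-2 BLAST-style local
#' alignments passing the default thresholds (with the duplicate at a
#' lower bit score, to exercise best-hit dedup); decoy hits between wrong
#' pairs fail the identity or the e-value threshold.
#'
#' @param ann An `earlinc_simulation`.
#' @param cfg A [sim_config()] (defaults to `ann$cfg`).
#' @return List with `hits` (outfmt-6-style data frame) and `truth`
#'   (pairs that must survive [sequence_matches()]).
#' @export
generate_similarity_hits <- function(ann, cfg = ann$cfg) {
  stopifnot(inherits(ann, "earlinc_simulation"))
  set.seed(cfg$seed + 3L)
  op <- ann$truth$ortholog_pairs
  seq_pairs <- op[grepl("sequence", op$evidence), , drop = FALSE]
  mk_hit <- function(q, s, pident, evalue, bitscore) {
    len <- rint(150L, 600L)
    qs <- rint(1L, 500L)
    data.frame(qseqid = q, sseqid = s, pident = pident, length = len,
               mismatch = round(len * (100 - pident) / 100),
               gapopen = rint(0L, 3L), qstart = qs, qend = qs + len - 1L,
               sstart = 1L, send = len, evalue = evalue,
               bitscore = bitscore, stringsAsFactors = FALSE)
  }
  hits <- list()
  for (i in seq_len(nrow(seq_pairs))) {
    bs <- round(stats::runif(1, 150, 400), 1)
    hits[[length(hits) + 1L]] <- mk_hit(
      seq_pairs$mouse_gene[i], seq_pairs$human_gene[i],
      round(stats::runif(1, 75, 95), 1), 10^-stats::runif(1, 15, 40), bs)
    if (stats::runif(1) < 0.5) {   # secondary, weaker alignment
      hits[[length(hits) + 1L]] <- mk_hit(
        seq_pairs$mouse_gene[i], seq_pairs$human_gene[i],
        round(stats::runif(1, 70, 90), 1), 10^-stats::runif(1, 8, 15),
        bs - round(stats::runif(1, 20, 80), 1))
    }
  }
  mouse_pool <- ann$truth$lnc_genes$gene_id
  human_pool <- ann$human_lnc$gene_id
  planted <- paste(seq_pairs$mouse_gene, seq_pairs$human_gene)
  made <- 0L
  while (made < cfg$n_decoy_hits) {
    q <- sample(mouse_pool, 1L)
    s <- sample(human_pool, 1L)
    if (paste(q, s) %in% planted) next
    if (stats::runif(1) < 0.5) {
      h <- mk_hit(q, s, round(stats::runif(1, 30, 55), 1),
                  10^-stats::runif(1, 6, 20),
                  round(stats::runif(1, 40, 90), 1))
    } else {
      h <- mk_hit(q, s, round(stats::runif(1, 65, 90), 1),
                  10^-stats::runif(1, 1, 4),
                  round(stats::runif(1, 30, 50), 1))
    }
    hits[[length(hits) + 1L]] <- h
    made <- made + 1L
  }
  hits <- do.call(rbind, hits)
  rownames(hits) <- NULL
  list(hits = hits,
       truth = seq_pairs[, c("mouse_gene", "human_gene")])
}

#' Generate human inner-ear expression for the ortholog clustering
#'
#' Human lncRNA FPKM over `n_human_samples` samples. Ortholog pairs follow
#' their planted archetype: group 1 high in human, group 2 intermediate,
#' group 3 low; decoy human lncRNAs get unremarkable low values.
#'
#' @param ann An `earlinc_simulation`.
#' @param cfg A [sim_config()] (defaults to `ann$cfg`).
#' @return An `expression_matrix` (fpkm) over all human lncRNA genes.
#' @export
generate_human_expression <- function(ann, cfg = ann$cfg) {
  stopifnot(inherits(ann, "earlinc_simulation"))
  set.seed(cfg$seed + 4L)
  genes <- ann$human_lnc$gene_id
  n_s <- cfg$n_human_samples
  med <- stats::setNames(rep(0.8, length(genes)), genes)
  op <- ann$truth$ortholog_pairs
  arche_median <- c(`1` = 20, `2` = 2, `3` = 0.3)
  med[op$human_gene] <- arche_median[as.character(op$archetype)]
  vals <- matrix(stats::rlnorm(length(genes) * n_s,
                               meanlog = rep(log(med), n_s), sdlog = 0.25),
                 length(genes), n_s,
                 dimnames = list(genes,
                                 sprintf("human_ear_%d", seq_len(n_s))))
  expression_matrix(vals, unit = "fpkm")
}

#' Break synteny by permuting human anchor positions
#'
#' Reassigns the human interval slots among the anchors of each human
#' chromosome with a permutation rejected until no mouse-adjacent anchor
#' pair remains adjacent on the human side, so conserved-adjacency synteny
#' evidence disappears entirely while sequence evidence is untouched.
#'
#' @param ann An `earlinc_simulation`.
#' @param seed Seed for the permutation draw.
#' @return The simulation with shuffled `anchors`.
#' @export
shuffle_human_anchors <- function(ann, seed = ann$cfg$seed + 5L) {
  stopifnot(inherits(ann, "earlinc_simulation"))
  set.seed(seed)
  anchors <- ann$anchors
  for (hc in unique(anchors$human_chrom)) {
    idx <- which(anchors$human_chrom == hc)
    if (length(idx) < 4L) next
    slots <- anchors[idx, c("human_start", "human_end", "orientation")]
    ord <- order(slots$human_start)
    for (try in seq_len(2000L)) {
      perm <- sample(seq_along(idx))
      # anchor i (mouse order) gets slot rank perm[i]; adjacency must break
      if (all(abs(diff(perm)) != 1L)) break
      if (try == 2000L) stop_earlinc("could not find an adjacency-breaking permutation")
    }
    slot_rows <- slots[ord, ][perm, ]
    anchors$human_start[idx] <- slot_rows$human_start
    anchors$human_end[idx] <- slot_rows$human_end
    anchors$orientation[idx] <- slot_rows$orientation
  }
  ann$anchors <- anchors
  ann
}

#' Generate nucleotide sequences with planted coding potential
#'
#' For ORF-scanner validation: noncoding sequences are stop-codon rich (no
#' long ORFs expected), coding sequences embed an ATG...stop ORF of known
#' length.
#'
#' @param n Number of sequences.
#' @param coding_fraction Fraction with a planted long ORF.
#' @param length_nt Approximate sequence length.
#' @param seed Seed.
#' @return Data frame with `sequence`, `is_coding`, `planted_orf_aa`
#'   (codons; `NA` for noncoding).
#' @export
simulate_orf_sequences <- function(n = 50, coding_fraction = 0.5,
                                   length_nt = 1000, seed = 1) {
  set.seed(seed)
  stops <- c("TAA", "TAG", "TGA")
  non_stop <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T")),
                            1L, paste0, collapse = ""), c(stops, "ATG"))
  rand_noncoding <- function(len) {
    # codon soup with stops enriched so ORFs stay short in every frame
    k <- ceiling(len / 3)
    paste0(sample(c(stops, non_stop), k, replace = TRUE,
                  prob = c(rep(0.1, 3), rep(0.7 / length(non_stop),
                                            length(non_stop)))),
           collapse = "")
  }
  out <- lapply(seq_len(n), function(i) {
    is_coding <- i <= round(n * coding_fraction)
    if (is_coding) {
      orf_aa <- rint(110L, 250L)
      body <- paste0(sample(non_stop, orf_aa - 1L, replace = TRUE),
                     collapse = "")
      seq <- paste0(rand_noncoding(rint(30L, 120L)), "ATG", body,
                    sample(stops, 1L), rand_noncoding(rint(30L, 120L)))
      data.frame(sequence = seq, is_coding = TRUE, planted_orf_aa = orf_aa,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(sequence = rand_noncoding(length_nt), is_coding = FALSE,
                 planted_orf_aa = NA_integer_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Write every synthetic input to disk
#'
#' Emits the files a real run would consume: assembled and reference GTFs,
#' gene-level counts with a sample sheet, the specificity panel, the
#' coding-assessment table, the similarity hit table, the anchor table,
#' human lncRNA genes and expression, the disease-gene table, the human
#' loci BED, plus the planted-truth tables.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with the simulation objects and a named
#'   vector of file paths.
#' @export
simulate_inputs <- function(cfg = sim_config(), dir) {
  ann <- generate_annotation(cfg)
  cnt <- generate_counts(ann, cfg)
  pan <- generate_specificity_panel(ann, cfg)
  hit <- generate_similarity_hits(ann, cfg)
  hum <- generate_human_expression(ann, cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  wtsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  wmat <- function(m, path) {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    wtsv(df, path)
  }
  paths <- c(
    assembled_gtf = write_gtf(ann$assembled, p("assembled.gtf")),
    reference_gtf = write_gtf(ann$reference, p("reference.gtf")),
    counts = wmat(cnt$counts$values, p("counts.tsv")),
    gene_lengths = wtsv(data.frame(
      gene_id = names(cnt$counts$gene_lengths),
      length_bp = as.numeric(cnt$counts$gene_lengths)), p("gene_lengths.tsv")),
    samples = wtsv(cnt$counts$samples, p("samples.tsv")),
    panel = wmat(pan$panel$values, p("panel.tsv")),
    assessments = wtsv(ann$assessments, p("assessments.tsv")),
    hits = {
      utils::write.table(hit$hits, p("hits.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      p("hits.tsv")
    },
    anchors = wtsv(ann$anchors, p("anchors.tsv")),
    human_lnc = wtsv(ann$human_lnc, p("human_lncrnas.tsv")),
    human_expression = wmat(hum$values, p("human_expression.tsv")),
    disease_genes = {
      dg <- ann$truth$disease_genes
      dg <- dg[!duplicated(dg$gene_id), c("gene_id", "term", "chrom",
                                          "start", "end", "strand")]
      wtsv(dg, p("disease_genes.tsv"))
    },
    loci_bed = write_bed(data.frame(chrom = ann$truth$loci$chrom,
                                    start = ann$truth$loci$start,
                                    end = ann$truth$loci$end,
                                    name = ann$truth$loci$locus_id),
                         p("loci.bed")),
    truth_transcripts = wtsv(ann$truth$transcript_classes,
                             p("truth", "transcript_classes.tsv")),
    truth_genes = wtsv(ann$truth$gene_classes, p("truth", "gene_classes.tsv")),
    truth_orthologs = wtsv(ann$truth$ortholog_pairs,
                           p("truth", "ortholog_pairs.tsv")),
    truth_de = wtsv(cnt$de_genes, p("truth", "de_genes.tsv")),
    truth_cis = wtsv(ann$truth$cis_pairs, p("truth", "cis_pairs.tsv")),
    truth_panel = wtsv(data.frame(
      gene_id = c(pan$truth$silent, pan$truth$ubiquitous),
      role = c(rep("silent", length(pan$truth$silent)),
               rep("ubiquitous", length(pan$truth$ubiquitous)))),
      p("truth", "panel_roles.tsv")),
    truth_loci = wtsv(ann$truth$loci, p("truth", "loci.tsv")))
  invisible(list(ann = ann, counts = cnt, panel = pan, hits = hit,
                 human_expression = hum, paths = paths))
}

#' Generate adversarial random transcripts and a toy coding annotation
#'
#' Unlike [generate_annotation()], which keeps >= 1 kb safety margins so
#' planted labels are unambiguous, this generator draws transcripts with
#' arbitrary touching/nested/overlapping geometry against a random coding
#' annotation and random small RNAs. It exists to stress the classifier
#' against a brute-force per-base oracle, not to carry planted truth.
#'
#' @param n Number of candidate transcripts.
#' @param n_coding Number of single-transcript coding genes.
#' @param n_small Number of small RNA intervals.
#' @param chrom_len Chromosome length in bp (two chromosomes are used).
#' @param seed Seed.
#' @return List with `ts` (candidate `transcript_set`), `coding` (a
#'   `gene_set`), `small_rnas` (interval data frame), and `max_fpkm`
#'   (named per-transcript maxima drawn in `[0, 2]`, some `NA`).
#' @export
simulate_adversarial_transcripts <- function(n = 500, n_coding = 60,
                                             n_small = 20,
                                             chrom_len = 200000, seed = 1) {
  set.seed(seed)
  chroms <- c("chrA", "chrB")
  rand_exons <- function(tid, gid, short = FALSE) {
    chrom <- sample(chroms, 1L)
    strand <- sample(c("+", "-"), 1L)
    k <- if (short) 1L else rint(1L, 4L)
    w <- if (short) rint(30L, 150L, k) else rint(40L, 400L, k)
    gaps <- if (k > 1L) rint(10L, 500L, k - 1L) else integer()
    start <- rint(0L, chrom_len - (sum(w) + sum(gaps)) - 1L)
    mk_exons(tid, gid, chrom, start, strand, w, gaps)
  }
  cand <- do.call(rbind, lapply(seq_len(n), function(i) {
    rand_exons(sprintf("rt%04d", i), sprintf("rg%04d", i),
               short = stats::runif(1) < 0.15)
  }))
  coding <- do.call(rbind, lapply(seq_len(n_coding), function(i) {
    rand_exons(sprintf("ct%04d", i), sprintf("cg%04d", i))
  }))
  small <- data.frame(chrom = sample(chroms, n_small, replace = TRUE),
                      start = rint(0L, chrom_len - 200L, n_small),
                      strand = sample(c("+", "-"), n_small, replace = TRUE),
                      stringsAsFactors = FALSE)
  small$end <- small$start + rint(60L, 140L, n_small)
  small$name <- sprintf("sr%03d", seq_len(n_small))
  mx <- stats::runif(n, 0, 2)
  mx[sample.int(n, round(n * 0.05))] <- NA
  names(mx) <- sprintf("rt%04d", seq_len(n))
  list(ts = transcript_set(cand), coding = as_gene_set(transcript_set(coding)),
       small_rnas = small[, c("chrom", "start", "end", "strand", "name")],
       max_fpkm = mx)
}

#' Negative-binomial benchmark counts for the DE screen
#'
#' The calibration benchmark: `n_genes` genes, the first `n_de` carrying a
#' `log2fc` effect (random sign) in group B, log-normal baseline means,
#' negative-binomial noise at the given dispersion, and two groups of
#' `n_per_group` samples.
#'
#' @param n_genes,n_de Total and planted-DE gene counts.
#' @param log2fc Planted absolute log2 fold change.
#' @param dispersion NB dispersion (0 gives Poisson).
#' @param n_per_group Samples per group.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline mean
#'   parameters.
#' @param seed Seed.
#' @return List with `counts` (an `expression_matrix`), `group_a`,
#'   `group_b`, and `de_genes` (planted gene ids).
#' @export
simulate_de_counts <- function(n_genes = 200, n_de = 20, log2fc = 2,
                               dispersion = 0.1, n_per_group = 3,
                               baseline_meanlog = log(100),
                               baseline_sdlog = 1, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  group_a <- sprintf("A%d", seq_len(n_per_group))
  group_b <- sprintf("B%d", seq_len(n_per_group))
  base <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
  fc <- rep(1, n_genes)
  if (n_de > 0L) {
    fc[seq_len(n_de)] <- 2^(log2fc * sample(c(1, -1), n_de, replace = TRUE))
  }
  mu <- cbind(matrix(base, n_genes, n_per_group),
              matrix(base * fc, n_genes, n_per_group))
  counts <- matrix(nb_draw(length(mu), as.vector(mu), dispersion),
                   n_genes, 2L * n_per_group,
                   dimnames = list(genes, c(group_a, group_b)))
  list(counts = expression_matrix(counts, unit = "counts",
                                  gene_lengths = stats::setNames(
                                    rep(1000, n_genes), genes)),
       group_a = group_a, group_b = group_b,
       de_genes = if (n_de > 0L) genes[seq_len(n_de)] else character())
}

#' Expression-vector pairs with a planted correlation
#'
#' Draws pairs of FPKM-like vectors whose log2 values are bivariate
#' normal with correlation `r` (so the correlation screen's
#' log-transformed Pearson targets `r`), plus independent null pairs.
#'
#' @param n_pairs Correlated pairs to draw.
#' @param n_null Independent (null) pairs.
#' @param n_samples Samples per vector (default 12, the study design).
#' @param r Planted log-scale correlation.
#' @param sdlog SD of the log2 values.
#' @param seed Seed.
#' @return List with `fpkm` (an `expression_matrix` holding both members
#'   of every pair) and `records` (pair table with `truth` =
#'   `"correlated"`/`"null"`), ready for [correlation_screen()].
#' @export
simulate_correlated_pairs <- function(n_pairs = 10, n_null = 10,
                                      n_samples = 12, r = 0.9, sdlog = 1.5,
                                      seed = 1) {
  set.seed(seed)
  total <- n_pairs + n_null
  rec <- list()
  vals <- list()
  for (i in seq_len(total)) {
    correlated <- i <= n_pairs
    z1 <- stats::rnorm(n_samples)
    z2 <- if (correlated) {
      r * z1 + sqrt(1 - r^2) * stats::rnorm(n_samples)
    } else {
      stats::rnorm(n_samples)
    }
    a <- sprintf("lnc%03d", i)
    b <- sprintf("cod%03d", i)
    vals[[a]] <- 2^(2 + sdlog * z1)
    vals[[b]] <- 2^(2 + sdlog * z2)
    rec[[i]] <- data.frame(lncrna_gene = a, disease_gene = b,
                           truth = if (correlated) "correlated" else "null",
                           stringsAsFactors = FALSE)
  }
  m <- do.call(rbind, vals)
  colnames(m) <- sprintf("s%02d", seq_len(n_samples))
  list(fpkm = expression_matrix(m, unit = "fpkm"),
       records = do.call(rbind, rec))
}

#' Samples drawn around well-separated condition centroids
#'
#' Generates an FPKM matrix whose samples fall into `n_conditions` groups
#' of `replicates`, each group around its own log2 centroid, with small
#' within-group noise -- the planted-partition benchmark for the
#' sample-structure diagnostics.
#'
#' @param n_genes Genes.
#' @param n_conditions Condition centroids (default 4 = 2 tissues x 2
#'   stages).
#' @param replicates Samples per condition.
#' @param centroid_sd SD of centroid log2 values (separation).
#' @param noise_sd Within-condition log2 noise.
#' @param seed Seed.
#' @return List with `fpkm` (an `expression_matrix`) and `condition`
#'   (factor of planted condition labels per sample).
#' @export
simulate_condition_matrix <- function(n_genes = 200, n_conditions = 4,
                                      replicates = 3, centroid_sd = 2,
                                      noise_sd = 0.2, seed = 1) {
  set.seed(seed)
  centroids <- matrix(stats::rnorm(n_genes * n_conditions, 3, centroid_sd),
                      n_genes, n_conditions)
  cond <- rep(seq_len(n_conditions), each = replicates)
  logv <- centroids[, cond] +
    matrix(stats::rnorm(n_genes * length(cond), 0, noise_sd),
           n_genes, length(cond))
  vals <- 2^logv
  dimnames(vals) <- list(sprintf("g%04d", seq_len(n_genes)),
                         sprintf("cond%d_r%d", cond,
                                 rep(seq_len(replicates), n_conditions)))
  list(fpkm = expression_matrix(vals, unit = "fpkm"),
       condition = factor(cond))
}
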