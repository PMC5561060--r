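config_defaults <- function() {
  list(
    # input paths (all required at run time)
    assembled_gtf = NULL, reference_gtf = NULL,
    counts = NULL, gene_lengths = NULL, samples = NULL,
    panel = NULL, assessments = NULL, hits = NULL, anchors = NULL,
    human_lnc = NULL, human_expression = NULL,
    disease_genes = NULL, loci_bed = NULL,
    # thresholds
    min_length_nt = 200, min_expression_fpkm = 0.1,
    orf_max_aa = 100, score_cutoff = 0,
    specificity_threshold = 1.0,
    de_alpha = 0.05, min_fold = 2,
    max_distance = 4e6, correlation_cutoff = 0.3, correlation_alpha = 0.05,
    divergent_window_bp = 1000, k_expression_groups = 3,
    min_identity = 60, max_evalue = 1e-5,
    grouping_mode = "same_strand_exonic", novelty_strand_mode = "ignore",
    de_group_by = "tissue",
    seed = 1)
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a named list, fills in every default,
#' rejects unknown keys, and reports all range/type errors at once.
#' Normalization is idempotent. Referenced input files, when set, must
#' exist.
#'
#' @param config Path to a YAML file, a named list, or an already
#'   normalized config.
#' @return A list of class `earlinc_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_earlinc("config file not found: %s", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  stopifnot(is.list(config))
  defaults <- config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop_earlinc("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- defaults
  cfg[names(config)] <- config

  errs <- character()
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  in_range <- function(x, lo, hi) is.numeric(x) && length(x) == 1L &&
    !is.na(x) && x > lo && x < hi
  chk(in_range(cfg$de_alpha, 0, 1), "de_alpha must be in (0, 1)")
  chk(in_range(cfg$correlation_alpha, 0, 1),
      "correlation_alpha must be in (0, 1)")
  chk(in_range(cfg$correlation_cutoff, 0, 1),
      "correlation_cutoff must be in (0, 1)")
  chk(is.numeric(cfg$min_fold) && cfg$min_fold >= 1, "min_fold must be >= 1")
  chk(is.numeric(cfg$max_distance) && cfg$max_distance > 0,
      "max_distance must be positive")
  chk(is.numeric(cfg$min_length_nt) && cfg$min_length_nt > 0,
      "min_length_nt must be positive")
  chk(is.numeric(cfg$min_expression_fpkm) && cfg$min_expression_fpkm >= 0,
      "min_expression_fpkm must be >= 0")
  chk(is.numeric(cfg$orf_max_aa) && cfg$orf_max_aa > 0,
      "orf_max_aa must be positive")
  chk(is.numeric(cfg$specificity_threshold) && cfg$specificity_threshold >= 0,
      "specificity_threshold must be >= 0")
  chk(is.numeric(cfg$k_expression_groups) && cfg$k_expression_groups >= 1,
      "k_expression_groups must be >= 1")
  chk(is.numeric(cfg$min_identity) && cfg$min_identity >= 0 &&
        cfg$min_identity <= 100, "min_identity must be in [0, 100]")
  chk(is.numeric(cfg$max_evalue) && cfg$max_evalue >= 0,
      "max_evalue must be >= 0")
  chk(cfg$grouping_mode %in% c("same_strand_exonic", "any_overlap"),
      "grouping_mode must be 'same_strand_exonic' or 'any_overlap'")
  chk(cfg$novelty_strand_mode %in% c("ignore", "same"),
      "novelty_strand_mode must be 'ignore' or 'same'")
  path_keys <- c("assembled_gtf", "reference_gtf", "counts", "gene_lengths",
                 "samples", "panel", "assessments", "hits", "anchors",
                 "human_lnc", "human_expression", "disease_genes", "loci_bed")
  for (k in path_keys) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]])) {
      chk(FALSE, sprintf("%s: file not found (%s)", k, cfg[[k]]))
    }
  }
  if (length(errs) > 0L) {
    stop_earlinc("invalid config:\n  - %s", paste(errs, collapse = "\n  - "))
  }
  structure(cfg, class = c("earlinc_config", "list"))
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Point a config at a directory written by [simulate_inputs()]
#'
#' @param dir Directory containing the generated input files.
#' @param ... Further config overrides passed to [validate_config()].
#' @return An `earlinc_config`.
#' @export
config_from_dir <- function(dir, ...) {
  p <- function(f) file.path(dir, f)
  validate_config(c(list(
    assembled_gtf = p("assembled.gtf"), reference_gtf = p("reference.gtf"),
    counts = p("counts.tsv"), gene_lengths = p("gene_lengths.tsv"),
    samples = p("samples.tsv"), panel = p("panel.tsv"),
    assessments = p("assessments.tsv"), hits = p("hits.tsv"),
    anchors = p("anchors.tsv"), human_lnc = p("human_lncrnas.tsv"),
    human_expression = p("human_expression.tsv"),
    disease_genes = p("disease_genes.tsv"), loci_bed = p("loci.bed")),
    list(...)))
}

#' Run the full discovery-and-prioritization pipeline
#'
#' Orchestrates every stage from files on disk: classification of the
#' assembled transcriptome (coding filter, PLAR-style category calls,
#' gene grouping, novelty), expression work (FPKM, panel specificity,
#' DE screen, sample structure), cross-species orthology (sequence +
#' synteny, 1:1 resolution, expression clustering), and candidate
#' prioritization (proximity/relationship labels, correlation screen,
#' locus liftover). All result tables are written to `out_dir` together
#' with `summary.json` and a `manifest.json` (file, rows, md5); a rerun
#' with the same inputs is byte-identical.
#'
#' @param config An `earlinc_config` (or anything [validate_config()]
#'   accepts) with every input path set.
#' @param out_dir Output directory.
#' @return Invisibly, a list with all in-memory results and `summary`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- validate_config(config)
  path_keys <- c("assembled_gtf", "reference_gtf", "counts", "gene_lengths",
                 "samples", "panel", "assessments", "hits", "anchors",
                 "human_lnc", "human_expression", "disease_genes", "loci_bed")
  missing <- path_keys[vapply(path_keys, function(k) is.null(cfg[[k]]), TRUE)]
  if (length(missing) > 0L) {
    stop_earlinc("config is missing input path(s): %s",
                 paste(missing, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_earlinc("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e))
    })
  }

  # ---- load --------------------------------------------------------------
  inputs <- stage("load", {
    assembled <- parse_gtf(cfg$assembled_gtf)
    reference <- parse_gtf(cfg$reference_gtf)
    glen_df <- read_tsv(cfg$gene_lengths)
    gene_lengths <- stats::setNames(glen_df$length_bp, glen_df$gene_id)
    counts <- expression_matrix(read_matrix_tsv(cfg$counts),
                                unit = "counts",
                                gene_lengths = gene_lengths,
                                samples = read_tsv(cfg$samples))
    list(assembled = assembled, reference = reference, counts = counts,
         panel = expression_matrix(read_matrix_tsv(cfg$panel), unit = "fpkm"),
         assessments = read_tsv(cfg$assessments),
         hits = read_blast_hits(cfg$hits),
         anchors = read_tsv(cfg$anchors),
         human_lnc = read_tsv(cfg$human_lnc),
         human_em = expression_matrix(read_matrix_tsv(cfg$human_expression),
                                      unit = "fpkm"),
         disease = read_tsv(cfg$disease_genes),
         loci = read_bed(cfg$loci_bed))
  })

  ref_tx <- inputs$reference$tx
  ref_coding <- as_gene_set(subset_transcripts(
    inputs$reference, ref_tx$transcript_id[ref_tx$biotype == "protein_coding"]))
  small_ids <- ref_tx$transcript_id[ref_tx$biotype == "small_rna"]
  small_rnas <- if (length(small_ids) > 0L) {
    e <- inputs$reference$exons
    e <- e[e$transcript_id %in% small_ids, ]
    data.frame(chrom = e$chrom, start = e$start, end = e$end,
               strand = e$strand, name = e$gene_id, stringsAsFactors = FALSE)
  } else NULL
  known_ids <- ref_tx$transcript_id[ref_tx$biotype == "known_lncRNA"]
  known_lnc <- if (length(known_ids) > 0L) {
    as_gene_set(subset_transcripts(inputs$reference, known_ids))
  } else NULL

  # ---- expression: FPKM --------------------------------------------------
  fpkm <- stage("fpkm", compute_fpkm(inputs$counts))
  tx_gene <- inputs$assembled$tx$gene_id
  names(tx_gene) <- inputs$assembled$tx$transcript_id
  gene_max <- apply(fpkm$values, 1L, max)
  max_fpkm <- gene_max[tx_gene]
  names(max_fpkm) <- names(tx_gene)

  # ---- classification ----------------------------------------------------
  classification <- stage("classify", {
    filt <- coding_filter(inputs$assembled$tx$transcript_id,
                          inputs$assessments,
                          orf_max_aa = cfg$orf_max_aa,
                          score_cutoff = cfg$score_cutoff)
    keep_ids <- filt$transcript_id[filt$status == "keep"]
    calls <- classify_lncrna(
      subset_transcripts(inputs$assembled, keep_ids), ref_coding,
      small_rnas = small_rnas, max_fpkm = max_fpkm,
      min_length_nt = cfg$min_length_nt,
      min_expression_fpkm = cfg$min_expression_fpkm)
    dropped <- filt[filt$status != "keep", ]
    if (nrow(dropped) > 0L) {
      calls <- rbind(calls, data.frame(
        transcript_id = dropped$transcript_id,
        category = ifelse(dropped$status == "drop", "excluded_coding",
                          "needs_assessment"),
        evidence = dropped$reason, stringsAsFactors = FALSE))
    }
    calls[match(inputs$assembled$tx$transcript_id, calls$transcript_id), ]
  })

  lnc_tx <- classification$transcript_id[
    classification$category %in% c("lincRNA", "antisense", "small_rna_host")]
  lnc_genes <- stage("group", {
    as_gene_set(subset_transcripts(inputs$assembled, lnc_tx))
  })
  grouping <- stage("group", {
    group_transcripts_into_genes(subset_transcripts(inputs$assembled, lnc_tx),
                                 mode = cfg$grouping_mode)
  })
  gene_classes <- stage("classify_gene",
                        classify_gene(lnc_genes, classification))
  novelty <- stage("novelty", {
    if (is.null(known_lnc)) {
      data.frame(gene_id = lnc_genes$genes$gene_id, novel = TRUE)
    } else {
      call_novelty(lnc_genes, known_lnc,
                   strand_mode = cfg$novelty_strand_mode)
    }
  })

  # ---- expression screens ------------------------------------------------
  spec <- stage("specificity",
                specificity_count(inputs$panel,
                                  threshold = cfg$specificity_threshold))
  ss <- stage("sample_structure", sample_structure(fpkm))
  de <- stage("de_screen", {
    groups <- split(fpkm$samples$sample_id, fpkm$samples[[cfg$de_group_by]])
    if (length(groups) != 2L) {
      stop_earlinc("de_group_by '%s' does not split the samples in two",
                   cfg$de_group_by)
    }
    de_screen(inputs$counts, groups[[1L]], groups[[2L]],
              alpha = cfg$de_alpha, min_fold = cfg$min_fold)
  })

  # ---- orthology ---------------------------------------------------------
  ortho <- stage("orthology", {
    seq_cand <- sequence_matches(inputs$hits,
                                 min_identity = cfg$min_identity,
                                 max_evalue = cfg$max_evalue)
    syn_cand <- synteny_matches(lnc_genes, inputs$human_lnc,
                                inputs$anchors, warn_unplaced = FALSE)
    resolved <- resolve_orthologs(rbind(seq_cand, syn_cand))
    groups <- cluster_ortholog_expression(resolved, fpkm, inputs$human_em,
                                          k = cfg$k_expression_groups)
    resolved$expression_group <- groups$expression_group[
      match(paste(resolved$mouse_gene, resolved$human_gene),
            paste(groups$mouse_gene, groups$human_gene))]
    list(sequence = seq_cand, synteny = syn_cand, resolved = resolved)
  })

  # ---- prioritization ----------------------------------------------------
  cand <- stage("prioritize", {
    records <- candidates_near_genes(lnc_genes, inputs$disease,
                                     max_distance = cfg$max_distance,
                                     divergent_window_bp =
                                       cfg$divergent_window_bp)
    correlation_screen(records, fpkm, r_cutoff = cfg$correlation_cutoff,
                       alpha = cfg$correlation_alpha)
  })
  loci_df <- data.frame(locus_id = inputs$loci$name %||%
                          sprintf("locus_%d", seq_len(nrow(inputs$loci))),
                        chrom = inputs$loci$chrom,
                        start = inputs$loci$start, end = inputs$loci$end,
                        stringsAsFactors = FALSE)
  loci <- stage("map_loci",
                map_locus_and_intersect(loci_df, inputs$anchors, lnc_genes))

  # ---- outputs -----------------------------------------------------------
  summary <- list(
    n_transcripts = nrow(inputs$assembled$tx),
    transcript_categories = as.list(table(classification$category)),
    n_lncrna_transcripts = length(lnc_tx),
    n_lncrna_genes = nrow(lnc_genes$genes),
    n_lncrna_genes_grouped = nrow(grouping$genes),
    gene_categories = as.list(table(gene_classes$category[
      gene_classes$category != "excluded"])),
    novelty = as.list(attr(novelty, "counts")),
    panel_fraction_silent = spec$fraction_silent,
    n_de_significant = sum(de$significant, na.rm = TRUE),
    pc_variance_fraction = round(ss$variance_fraction[1:3], 4),
    orthology = list(
      n_sequence_candidates = nrow(ortho$sequence),
      n_synteny_candidates = nrow(ortho$synteny),
      n_resolved_pairs = nrow(ortho$resolved),
      evidence = as.list(table(ortho$resolved$evidence)),
      expression_groups = as.list(table(ortho$resolved$expression_group))),
    candidates = list(
      n_records = nrow(cand),
      relationships = as.list(table(cand$relationship)),
      correlation_calls = as.list(table(cand$correlation_call))),
    loci = list(n_mapped = sum(!loci$mapped$split),
                n_lnc_gene_hits = nrow(loci$hits)))

  o <- function(f) file.path(out_dir, f)
  wtsv <- function(df, f) {
    utils::write.table(df, o(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f
  }
  spec_df <- data.frame(gene_id = names(spec$counts),
                        n_samples_expressed = as.integer(spec$counts),
                        stringsAsFactors = FALSE)
  fpkm_df <- data.frame(gene_id = rownames(fpkm$values),
                        round(fpkm$values, 4), check.names = FALSE)
  files <- c(
    wtsv(classification, "classification.tsv"),
    wtsv(merge(gene_classes, novelty, by = "gene_id"), "lncrna_genes.tsv"),
    wtsv(fpkm_df, "fpkm.tsv"),
    wtsv(spec_df, "specificity.tsv"),
    wtsv(de, "de_results.tsv"),
    wtsv(ortho$resolved, "orthologs.tsv"),
    wtsv(cand, "candidates.tsv"),
    wtsv(loci$mapped, "mapped_loci.tsv"),
    wtsv(loci$hits, "loci_lncrna_hits.tsv"))
  mapped_ok <- loci$mapped[!loci$mapped$split, , drop = FALSE]
  write_bed(data.frame(chrom = mapped_ok$chrom, start = mapped_ok$start,
                       end = mapped_ok$end, name = mapped_ok$locus_id),
            o("mapped_loci.bed"))
  files <- c(files, "mapped_loci.bed")
  jsonlite::write_json(summary, o("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  files <- c(files, "summary.json")
  manifest <- data.frame(
    file = files,
    rows = vapply(files, function(f) {
      if (endsWith(f, ".json")) NA_integer_ else
        length(readLines(o(f))) - !endsWith(f, ".bed")
    }, 0L),
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, o("manifest.json"), pretty = TRUE,
                       digits = NA)

  invisible(list(config = cfg, classification = classification,
                 lnc_genes = lnc_genes, grouping = grouping,
                 gene_classes = gene_classes, novelty = novelty,
                 fpkm = fpkm, specificity = spec, de = de,
                 sample_structure = ss, orthology = ortho,
                 candidates = cand, loci = loci, summary = summary,
                 manifest = manifest))
}
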