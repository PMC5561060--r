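#' Construct an expression matrix
#'
#' Genes-by-samples non-negative values tagged as raw `counts` or `fpkm`.
#' Gene lengths (bp of mature transcript) are required to convert counts to
#' FPKM. An optional sample sheet records the study design (tissue, stage,
#' replicate); the triple must be unique per sample.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). No negative entries.
#' @param unit `"counts"` or `"fpkm"`.
#' @param gene_lengths Named numeric vector of gene lengths in bp
#'   (>= 1; required when `unit = "counts"`).
#' @param samples Optional data frame with columns `sample_id`, `tissue`,
#'   `stage`, `replicate`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, unit = c("counts", "fpkm"),
                              gene_lengths = NULL, samples = NULL) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_earlinc("values must carry gene rownames and sample colnames")
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop_earlinc("expression values must be non-negative")
  }
  if (unit == "counts") {
    if (is.null(gene_lengths)) {
      stop_earlinc("gene_lengths are required for unit = 'counts'")
    }
    gl <- gene_lengths[rownames(values)]
    if (anyNA(gl)) {
      stop_earlinc("gene_lengths missing for gene(s): %s",
                   paste(utils::head(rownames(values)[is.na(gl)], 5L),
                         collapse = ", "))
    }
    if (any(gl < 1)) stop_earlinc("gene_lengths must be >= 1 bp")
    gene_lengths <- gl
  }
  if (!is.null(samples)) {
    assert_cols(samples, c("sample_id", "tissue", "stage", "replicate"),
                "samples")
    if (anyDuplicated(samples[, c("tissue", "stage", "replicate")])) {
      stop_earlinc("sample sheet: (tissue, stage, replicate) must be unique")
    }
    if (!setequal(samples$sample_id, colnames(values))) {
      stop_earlinc("sample sheet ids do not match value columns")
    }
    samples <- samples[match(colnames(values), samples$sample_id), ,
                       drop = FALSE]
    rownames(samples) <- NULL
  }
  structure(list(values = values, unit = unit, gene_lengths = gene_lengths,
                 samples = samples), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' Convert counts to FPKM
#'
#' `FPKM[g, s] = counts[g, s] * 1e9 / (library_size[s] * gene_length[g])`
#' with the library size taken as the column sum. Scaling all counts of one
#' sample by a constant leaves that sample's FPKM column unchanged.
#'
#' @param em `expression_matrix` with `unit = "counts"`.
#' @return `expression_matrix` with `unit = "fpkm"`.
#' @export
compute_fpkm <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$unit != "counts") stop_earlinc("compute_fpkm expects unit='counts'")
  lib <- colSums(em$values)
  if (any(lib <= 0)) {
    stop_earlinc("zero library size in sample(s): %s",
                 paste(colnames(em$values)[lib <= 0], collapse = ", "))
  }
  fpkm <- sweep(em$values, 2L, lib, "/") * 1e9 / em$gene_lengths
  expression_matrix(fpkm, unit = "fpkm", samples = em$samples)
}

#' Tissue-specificity counts against an expression panel
#'
#' For each gene, the number of panel samples in which it is expressed at
#' or above `threshold` FPKM (inclusive), plus the fraction of genes
#' expressed in no sample at all.
#'
#' @param em `expression_matrix` with `unit = "fpkm"`.
#' @param threshold Expression threshold (default 1 FPKM, inclusive).
#' @return List with `counts` (named integer vector per gene, in
#'   `[0, n_samples]`) and `fraction_silent` (share of genes with count 0).
#' @export
specificity_count <- function(em, threshold = 1) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$unit != "fpkm") stop_earlinc("specificity_count expects unit='fpkm'")
  counts <- rowSums(em$values >= threshold)
  list(counts = counts, fraction_silent = mean(counts == 0))
}

# DESeq-style median-of-ratios size factors.
size_factors <- function(counts) {
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    stop_earlinc("size factors: no gene has positive counts in every sample")
  }
  log_geo <- rowMeans(log(counts[all_pos, , drop = FALSE]))
  apply(counts[all_pos, , drop = FALSE], 2L, function(col) {
    exp(stats::median(log(col) - log_geo))
  })
}

#' Differential-expression screen
#'
#' A documented stand-in for a negative-binomial GLM fit: counts are
#' normalized with median-of-ratios size factors and each gene is tested
#' two-sided on `log2(normalized + pseudocount)`, with p-values adjusted
#' across all tested genes by Benjamini-Hochberg. The default
#' `"moderated"` test shrinks per-gene variances toward the mean-variance
#' trend (limma's empirical-Bayes moderation), which restores power at
#' the study's small group sizes (n = 3); `"welch"` is a plain Welch
#' t-test on the same transformed values. The fold change is
#' `log2((mean_b + pc) / (mean_a + pc))` on normalized counts. A gene is
#' significant when `adj_p < alpha` and `|log2FC| >= log2(min_fold)`.
#'
#' Genes with all-zero counts in both groups are reported with `p_value =
#' NA` (untested), never dropped.
#'
#' @param em `expression_matrix` with `unit = "counts"`.
#' @param group_a,group_b Disjoint character vectors of sample ids, at
#'   least two samples each.
#' @param alpha Adjusted-p significance level (default 0.05).
#' @param min_fold Minimum fold change called significant (default 2).
#' @param pseudocount Pseudocount for the fold-change and log transform
#'   (default 1).
#' @param method `"moderated"` (default) or `"welch"`.
#' @return Data frame with columns `gene_id`, `mean_a`, `mean_b`,
#'   `log2_fold_change`, `p_value`, `adj_p`, `significant`.
#' @export
de_screen <- function(em, group_a, group_b, alpha = 0.05, min_fold = 2,
                      pseudocount = 1, method = c("moderated", "welch")) {
  method <- match.arg(method)
  stopifnot(inherits(em, "expression_matrix"))
  if (em$unit != "counts") stop_earlinc("de_screen expects unit='counts'")
  if (length(intersect(group_a, group_b)) > 0L) {
    stop_earlinc("group_a and group_b overlap")
  }
  missing <- setdiff(c(group_a, group_b), colnames(em$values))
  if (length(missing) > 0L) {
    stop_earlinc("unknown sample(s): %s", paste(missing, collapse = ", "))
  }
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop_earlinc("each group needs at least two samples")
  }
  counts <- em$values[, c(group_a, group_b), drop = FALSE]
  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  a <- norm[, group_a, drop = FALSE]
  b <- norm[, group_b, drop = FALSE]
  la <- log2(a + pseudocount)
  lb <- log2(b + pseudocount)
  untested <- rowSums(counts) == 0
  if (method == "welch") {
    na_ <- ncol(a); nb_ <- ncol(b)
    ma <- rowMeans(la); mb <- rowMeans(lb)
    va <- rowSums((la - ma)^2) / (na_ - 1L)
    vb <- rowSums((lb - mb)^2) / (nb_ - 1L)
    se2 <- va / na_ + vb / nb_
    tstat <- (mb - ma) / sqrt(se2)
    df <- se2^2 / ((va / na_)^2 / (na_ - 1L) + (vb / nb_)^2 / (nb_ - 1L))
    p <- 2 * stats::pt(-abs(tstat), df)
    # degenerate: zero variance in both groups
    degen <- se2 == 0
    p[degen] <- ifelse(ma[degen] == mb[degen], 1, 0)
  } else {
    design <- cbind(intercept = 1,
                    group_b = as.numeric(colnames(counts) %in% group_b))
    lg <- cbind(la, lb)[, colnames(counts), drop = FALSE]
    # untested (all-zero) rows are excluded from the fit; zero-variance
    # rows among the tested ones are handled by the variance moderation
    fit <- suppressWarnings(
      limma::eBayes(limma::lmFit(lg[!untested, , drop = FALSE], design),
                    trend = TRUE))
    p <- rep(NA_real_, nrow(counts))
    names(p) <- rownames(counts)
    p[!untested] <- fit$p.value[, "group_b"]
  }
  p[untested] <- NA_real_
  adj <- rep(NA_real_, length(p))
  adj[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  lfc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))
  sig <- !is.na(adj) & adj < alpha & abs(lfc) >= log2(min_fold)
  data.frame(gene_id = rownames(counts), mean_a = mean_a, mean_b = mean_b,
             log2_fold_change = lfc, p_value = p, adj_p = adj,
             significant = sig, row.names = NULL, stringsAsFactors = FALSE)
}

#' Pearson correlation with a two-sided test
#'
#' @param x,y Numeric vectors of equal length (n >= 3). Constant input is
#'   flagged (`status = "constant_input"`, `r = NA`), not reported as 0.
#' @return One-row data frame with `r`, `p_value`, `n`, `status`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop_earlinc("x and y must have equal length")
  if (length(x) < 3L) stop_earlinc("correlation needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(data.frame(r = NA_real_, p_value = NA_real_, n = length(x),
                      status = "constant_input", stringsAsFactors = FALSE))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  data.frame(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
             status = "ok", stringsAsFactors = FALSE)
}

#' Sample-structure diagnostics: distances, dendrogram, PCA
#'
#' Computes pairwise Euclidean distances between samples on
#' `log2(fpkm + 1)`, an average-linkage dendrogram, and a PCA of the
#' centered (not scaled) log values with per-component variance fractions.
#'
#' @param em `expression_matrix` with `unit = "fpkm"` and >= 3 samples.
#' @return List with `distances` (a `dist`), `dendrogram` (an `hclust`),
#'   `variance_fraction` (non-increasing, sums to <= 1), and `scores`
#'   (samples x components).
#' @export
sample_structure <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$unit != "fpkm") stop_earlinc("sample_structure expects unit='fpkm'")
  if (ncol(em$values) < 3L) stop_earlinc("need at least 3 samples")
  x <- t(log2(em$values + 1))
  d <- stats::dist(x, method = "euclidean")
  hc <- stats::hclust(d, method = "average")
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  vf <- pca$sdev^2 / sum(pca$sdev^2)
  list(distances = d, dendrogram = hc, variance_fraction = vf,
       scores = pca$x)
}

#' Relative qRT-PCR expression by the 2^-ddCt method
#'
#' For each sample, `dCt = Ct_target - Ct_reference`, `ddCt = dCt -
#' dCt_calibrator`, and relative expression `2^-ddCt` (exactly 1 for the
#' calibrator sample).
#'
#' @param ct Data frame with columns `sample_id`, `target_ct`,
#'   `reference_ct`; one row per sample, no missing Ct values.
#' @param calibrator Sample id of the calibrator (e.g. newborn cochlea).
#' @return Data frame with `sample_id`, `delta_ct`, `delta_delta_ct`,
#'   `relative_expression`.
#' @export
delta_delta_ct <- function(ct, calibrator) {
  assert_cols(ct, c("sample_id", "target_ct", "reference_ct"), "ct")
  bad <- is.na(ct$target_ct) | is.na(ct$reference_ct)
  if (any(bad)) {
    stop_earlinc("missing Ct value for sample(s): %s",
                 paste(ct$sample_id[bad], collapse = ", "))
  }
  if (!calibrator %in% ct$sample_id) {
    stop_earlinc("calibrator sample '%s' not present", calibrator)
  }
  dct <- ct$target_ct - ct$reference_ct
  ddct <- dct - dct[ct$sample_id == calibrator][1L]
  data.frame(sample_id = ct$sample_id, delta_ct = dct,
             delta_delta_ct = ddct, relative_expression = 2^(-ddct),
             stringsAsFactors = FALSE)
}
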