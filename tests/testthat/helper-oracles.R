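# Independent brute-force oracles. Everything here works on plain base-R
# per-base position sets and explicit loops, deliberately avoiding the
# package's interval machinery.

# positions covered by a set of exon rows (0-based)
base_positions <- function(exons) {
  unlist(Map(function(s, e) seq.int(s, e - 1L), exons$start, exons$end),
         use.names = FALSE)
}

oracle_exonic_overlap <- function(exons_a, exons_b, strand_mode) {
  if (exons_a$chrom[1] != exons_b$chrom[1]) return(0)
  sa <- exons_a$strand[1]; sb <- exons_b$strand[1]
  ok <- switch(strand_mode,
               same = sa == sb && sa %in% c("+", "-"),
               opposite = sa != sb && sa %in% c("+", "-") &&
                 sb %in% c("+", "-"),
               ignore = TRUE)
  if (!ok) return(0)
  length(intersect(base_positions(exons_a), base_positions(exons_b)))
}

oracle_gene_distance <- function(a, b) {
  if (a$chrom != b$chrom) return(NA_real_)
  # minimum over boundary-pair differences, clipped at zero overlap
  if (a$start < b$end && b$start < a$end) return(0)
  min(abs(c(a$start - b$end, b$start - a$end)))
}

# transitive closure of the pairwise overlap relation via boolean matrix
# powering (independent of union-find)
oracle_components <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(n) > 0
  repeat {
    nxt <- (reach %*% reach) > 0
    if (all(nxt == reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  comp
}

# canonical form of a partition for comparison
partition_sets <- function(ids, labels) {
  unname(sort(vapply(split(ids, labels),
                     function(x) paste(sort(x), collapse = ","), "")))
}

# exhaustive ORF scan: walk every ATG, codon by codon, in every frame
oracle_longest_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (i in seq_len(max(0L, n - 5L))) {
    if (substr(seq, i, i + 2L) != "ATG") next
    j <- i + 3L
    len <- 1L
    while (j + 2L <= n) {
      cod <- substr(seq, j, j + 2L)
      if (cod %in% stops) {
        best <- max(best, len)
        break
      }
      len <- len + 1L
      j <- j + 3L
    }
  }
  best
}

# per-base reimplementation of the classification decision order
oracle_classify_one <- function(tx_exons, coding_tx_exons_by_gene,
                                coding_spans, small_rnas, fpkm,
                                min_length_nt = 200,
                                min_expression_fpkm = 0.1) {
  len <- sum(tx_exons$end - tx_exons$start)
  if (len <= min_length_nt) return("excluded_short")
  if (!is.na(fpkm) && fpkm < min_expression_fpkm) {
    return("excluded_low_expression")
  }
  bases <- base_positions(tx_exons)
  chrom <- tx_exons$chrom[1]
  strand <- tx_exons$strand[1]
  same_hit <- FALSE
  opp_hit <- FALSE
  for (ge in coding_tx_exons_by_gene) {
    if (ge$chrom[1] != chrom) next
    ov <- length(intersect(bases, base_positions(ge))) > 0
    if (!ov) next
    if (strand %in% c("+", "-") && ge$strand[1] %in% c("+", "-")) {
      if (ge$strand[1] == strand) same_hit <- TRUE else opp_hit <- TRUE
    }
  }
  if (same_hit) return("excluded_coding")
  if (opp_hit) return("antisense")
  t_start <- min(tx_exons$start); t_end <- max(tx_exons$end)
  for (i in seq_len(nrow(coding_spans))) {
    g <- coding_spans[i, ]
    if (g$chrom == chrom && g$strand == strand &&
        strand %in% c("+", "-") &&
        g$start <= t_start && t_end <= g$end) {
      return("excluded_intronic_same_strand")
    }
  }
  if (!is.null(small_rnas)) {
    for (i in seq_len(nrow(small_rnas))) {
      s <- small_rnas[i, ]
      if (s$chrom == chrom && s$start >= t_start && s$end <= t_end) {
        return("small_rna_host")
      }
    }
  }
  "lincRNA"
}

oracle_classify_all <- function(ts, coding, small_rnas, max_fpkm, ...) {
  coding_by_gene <- split(coding$ts$exons, coding$ts$exons$transcript_id)
  res <- vapply(ts$tx$transcript_id, function(tid) {
    oracle_classify_one(ts$exons[ts$exons$transcript_id == tid, ],
                        coding_by_gene, coding$genes, small_rnas,
                        if (is.null(max_fpkm)) NA_real_ else
                          unname(max_fpkm[tid]), ...)
  }, "")
  data.frame(transcript_id = ts$tx$transcript_id, category = unname(res),
             stringsAsFactors = FALSE)
}

# matching-property verification: `res` must be a matching, maximal, and
# greedy-consistent with the declared total rank order of `merged`
verify_matching <- function(res, merged) {
  ev_rank <- function(ev) ifelse(ev == "sequence,synteny", 3L,
                                 ifelse(ev == "sequence", 2L, 1L))
  sim <- ifelse(is.na(merged$similarity_score), -Inf, merged$similarity_score)
  syn <- ifelse(is.na(merged$synteny_score), -Inf, merged$synteny_score)
  ord <- order(-ev_rank(merged$evidence), -sim, -syn,
               merged$mouse_gene, merged$human_gene)
  key <- function(df) paste(df$mouse_gene, df$human_gene)
  in_res <- key(merged) %in% key(res)
  # matching
  if (anyDuplicated(res$mouse_gene) || anyDuplicated(res$human_gene)) {
    return(FALSE)
  }
  # walk pairs in rank order simulating availability
  used_m <- character(); used_h <- character()
  for (i in ord) {
    free <- !(merged$mouse_gene[i] %in% used_m) &&
      !(merged$human_gene[i] %in% used_h)
    if (free != in_res[i]) return(FALSE)   # must take iff both genes free
    if (in_res[i]) {
      used_m <- c(used_m, merged$mouse_gene[i])
      used_h <- c(used_h, merged$human_gene[i])
    }
  }
  TRUE
}

# long-hand Pearson r and two-sided t-test p
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# brute-force relationship labelling mirroring the documented precedence
oracle_relationship <- function(lnc, gene, window = 1000) {
  if (lnc$chrom != gene$chrom) return(NA_character_)
  le <- lnc$exons[order(lnc$exons$start), , drop = FALSE]
  if (nrow(le) > 1L) {
    for (i in seq_len(nrow(le) - 1L)) {
      if (gene$start >= le$end[i] && gene$end <= le$start[i + 1L]) {
        return("host_in_intron")
      }
    }
  }
  if (gene$start <= lnc$start && lnc$end <= gene$end) return("within")
  if (lnc$start <= gene$start && gene$end <= lnc$end) return("contains")
  both_stranded <- lnc$strand %in% c("+", "-") && gene$strand %in% c("+", "-")
  if (both_stranded && lnc$strand != gene$strand) {
    ov <- length(intersect(base_positions(lnc$exons),
                           base_positions(gene$exons))) > 0
    if (ov) return("antisense")
    p <- if (lnc$strand == "+") lnc else gene
    m <- if (lnc$strand == "-") lnc else gene
    if (p$start >= m$start && p$end >= m$end &&
        abs(p$start - m$end) <= window) {
      return("overlapping_divergent")
    }
  }
  "proximal"
}

has_mclust <- function() requireNamespace("mclust", quietly = TRUE)
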