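#' Construct a table of genomic intervals
#'
#' Intervals use 0-based half-open coordinates throughout the package: a
#' feature covering the first 100 bases of a chromosome is `start = 0`,
#' `end = 100`. GTF input/output converts from/to the 1-based inclusive
#' convention; BED is consumed natively.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start Integer vector, 0-based inclusive starts.
#' @param end Integer vector, exclusive ends; must satisfy `start < end`.
#' @param strand Strand tokens, one of `"+"`, `"-"`, `"."`. `"."` is
#'   accepted but treated as incomparable in strand-aware overlap tests.
#' @return A validated `data.frame` with columns `chrom`, `start`, `end`,
#'   `strand`.
#' @examples
#' genomic_intervals("chr1", 100, 200, "+")
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "intervals") {
  assert_cols(df, c("chrom", "start", "end"), what)
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom))) {
    stop_earlinc("%s: chromosome names must be non-empty", what)
  }
  if (any(df$start < 0)) stop_earlinc("%s: negative start coordinate", what)
  if (any(df$end <= df$start)) {
    bad <- which(df$end <= df$start)[1L]
    stop_earlinc("%s: end <= start at row %d (%s:%s-%s)", what, bad,
                 df$chrom[bad], format(df$start[bad], scientific = FALSE),
                 format(df$end[bad], scientific = FALSE))
  }
  if ("strand" %in% names(df) && !all(df$strand %in% STRAND_TOKENS)) {
    stop_earlinc("%s: strand must be one of '+', '-', '.'", what)
  }
  invisible(df)
}

#' Distance between two genomic spans
#'
#' Returns 0 for overlapping spans, the gap between nearest boundaries
#' otherwise (half-open coordinates, so abutting intervals have distance 0),
#' and `NA` when the spans sit on different chromosomes ("unlinked").
#' Vectorized over rows; shorter input is recycled.
#'
#' @param a,b Data frames (or single rows) with columns `chrom`, `start`,
#'   `end`.
#' @return Numeric vector of distances in bp, `NA` for unlinked pairs.
#' @examples
#' a <- genomic_intervals("chr1", 100, 200)
#' b <- genomic_intervals("chr1", 500, 600)
#' gene_distance(a, b)  # 300
#' @export
gene_distance <- function(a, b) {
  assert_cols(a, c("chrom", "start", "end"), "a")
  assert_cols(b, c("chrom", "start", "end"), "b")
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  gap <- pmax(b$start[bi] - a$end[ai], a$start[ai] - b$end[bi], 0)
  ifelse(a$chrom[ai] == b$chrom[bi], gap, NA_real_)
}

#' Read a BED file (BED3/BED6)
#'
#' @param path Path to a BED file. Coordinates are kept as-is (BED is
#'   already 0-based half-open).
#' @return Data frame with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_earlinc("BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop_earlinc("BED parse error at line %d of %s: fewer than 3 fields",
                 which(nf < 3L)[1L], path)
  }
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.numeric(vapply(fields, `[[`, "", 2L)),
    end = as.numeric(vapply(fields, `[[`, "", 3L)),
    stringsAsFactors = FALSE)
  if (all(nf >= 4L)) df$name <- vapply(fields, `[[`, "", 4L)
  if (all(nf >= 5L)) df$score <- vapply(fields, `[[`, "", 5L)
  if (all(nf >= 6L)) df$strand <- vapply(fields, `[[`, "", 6L)
  validate_intervals(df, what = path)
  df
}

#' Write intervals as BED6
#'
#' @param df Data frame with `chrom`, `start`, `end`; optional `name`,
#'   `score`, `strand` columns are filled with placeholders when absent.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df, "bed")
  out <- data.frame(df$chrom,
                    format(df$start, scientific = FALSE, trim = TRUE),
                    format(df$end, scientific = FALSE, trim = TRUE),
                    df$name %||% rep(".", nrow(df)),
                    df$score %||% rep(0, nrow(df)),
                    df$strand %||% rep(".", nrow(df)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
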