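#' Parse exon rows of a GTF file into a transcript set
#'
#' Reads a 9-column GTF (1-based inclusive coordinates) and assembles its
#' `exon` features into a [transcript_set()]. Coordinates are converted to
#' the package-internal 0-based half-open convention. Rows of other feature
#' types are ignored; malformed rows abort with the offending line number
#' rather than being dropped silently. Input need not be sorted.
#'
#' A `transcript_biotype` (or `gene_biotype`) attribute, when present, is
#' carried into the transcript table.
#'
#' @param path Path to a GTF file.
#' @return A `transcript_set`.
#' @examples
#' tf <- tempfile(fileext = ".gtf")
#' writeLines(paste0("chr1\tsrc\texon\t101\t200\t.\t+\t.\t",
#'                   'transcript_id "t1"; gene_id "g1";'), tf)
#' parse_gtf(tf)$exons  # exon at 0-based [100, 200)
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stop_earlinc("GTF file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(transcript_set(data.frame(
      transcript_id = character(), gene_id = character(),
      chrom = character(), start = numeric(), end = numeric(),
      strand = character(), stringsAsFactors = FALSE)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1L]
    stop_earlinc("GTF parse error at line %d of %s: expected 9 tab-separated fields, found %d",
                 lineno[bad], path, nf[bad])
  }
  feature <- vapply(fields, `[[`, "", 3L)
  is_exon <- feature == "exon"
  fields <- fields[is_exon]
  lineno <- lineno[is_exon]
  if (length(fields) == 0L) {
    stop_earlinc("GTF file %s contains no exon rows", path)
  }

  start1 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  end1 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  if (anyNA(start1) || anyNA(end1)) {
    bad <- which(is.na(start1) | is.na(end1))[1L]
    stop_earlinc("GTF parse error at line %d of %s: non-numeric coordinate",
                 lineno[bad], path)
  }
  if (any(end1 < start1)) {
    bad <- which(end1 < start1)[1L]
    stop_earlinc("GTF parse error at line %d of %s: end < start",
                 lineno[bad], path)
  }
  strand <- vapply(fields, `[[`, "", 7L)
  if (!all(strand %in% STRAND_TOKENS)) {
    bad <- which(!strand %in% STRAND_TOKENS)[1L]
    stop_earlinc("GTF parse error at line %d of %s: bad strand '%s'",
                 lineno[bad], path, strand[bad])
  }
  attrs <- vapply(fields, `[[`, "", 9L)
  get_attr <- function(key) {
    pat <- paste0(key, ' "([^"]*)"')
    m <- regexpr(pat, attrs)
    out <- rep(NA_character_, length(attrs))
    out[m > 0L] <- sub(pat, "\\1", regmatches(attrs, m))
    out
  }
  tid <- get_attr("transcript_id")
  gid <- get_attr("gene_id")
  if (anyNA(tid) || anyNA(gid)) {
    bad <- which(is.na(tid) | is.na(gid))[1L]
    stop_earlinc("GTF parse error at line %d of %s: missing transcript_id or gene_id attribute",
                 lineno[bad], path)
  }
  bt <- get_attr("transcript_biotype")
  gbt <- get_attr("gene_biotype")
  bt[is.na(bt)] <- gbt[is.na(bt)]

  exons <- data.frame(transcript_id = tid, gene_id = gid,
                      chrom = vapply(fields, `[[`, "", 1L),
                      start = start1 - 1, end = end1,
                      strand = strand, stringsAsFactors = FALSE)
  biotype <- NULL
  if (!all(is.na(bt))) {
    biotype <- bt[!duplicated(tid)]
    names(biotype) <- tid[!duplicated(tid)]
  }
  transcript_set(exons, biotype = biotype)
}

#' Write a transcript set as GTF
#'
#' Emits one `exon` row per exon with 1-based inclusive coordinates and
#' `transcript_id`/`gene_id` attributes (plus `transcript_biotype` when
#' assigned), so that `parse_gtf(write_gtf(ts, f))` reproduces `ts`.
#'
#' @param ts A `transcript_set`.
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ts, path, source = "earlinc") {
  stopifnot(inherits(ts, "transcript_set"))
  e <- ts$exons
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(e) == 0L) return(invisible(path))
  bt <- ts$tx$biotype[match(e$transcript_id, ts$tx$transcript_id)]
  attr_str <- sprintf('transcript_id "%s"; gene_id "%s";',
                      e$transcript_id, e$gene_id)
  has_bt <- !is.na(bt)
  attr_str[has_bt] <- sprintf('%s transcript_biotype "%s";',
                              attr_str[has_bt], bt[has_bt])
  rows <- sprintf("%s\t%s\texon\t%s\t%s\t.\t%s\t.\t%s",
                  e$chrom, source,
                  format(e$start + 1, scientific = FALSE, trim = TRUE),
                  format(e$end, scientific = FALSE, trim = TRUE),
                  e$strand, attr_str)
  writeLines(rows, con)
  invisible(path)
}
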