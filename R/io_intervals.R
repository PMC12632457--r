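#' Read genomic intervals from BED or GFF3
#'
#' Parses with rtracklayer and converts to the package-internal convention:
#' 0-based half-open `[start, end)`. GFF3 1-based closed records become
#' `(start - 1, end)`; BED coordinates pass through unchanged. Records that
#' are empty after conversion (`start >= end`) are dropped with a warning.
#' Strand is retained but ignored by all proximity logic.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return A data frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand` (class `genomic_intervals`).
#' @export
read_intervals <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3")) "gff3" else "bed"
  }
  if (file.exists(path) && length(readLines(path, warn = FALSE)) == 0)
    return(empty_intervals())
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  df <- as.data.frame(gr)
  nm <- if ("name" %in% names(df)) as.character(df$name)
        else if ("Name" %in% names(df)) as.character(df$Name)
        else if ("ID" %in% names(df)) as.character(df$ID)
        else rep(NA_character_, nrow(df))
  out <- data.frame(chrom = as.character(df$seqnames),
                    start = df$start - 1L, # GRanges is 1-based closed
                    end = df$end,
                    name = nm,
                    score = if ("score" %in% names(df)) as.numeric(df$score)
                            else NA_real_,
                    strand = as.character(df$strand),
                    stringsAsFactors = FALSE)
  intervals(out)
}

empty_intervals <- function() {
  intervals(data.frame(chrom = character(), start = integer(), end = integer(),
                       name = character(), score = numeric(),
                       strand = character(), stringsAsFactors = FALSE),
            validate = FALSE)
}

#' Construct a validated interval table (0-based half-open)
#'
#' @param df data frame with at least `chrom`, `start`, `end`.
#' @param validate drop degenerate records (`start >= end`) with a warning.
#' @return The data frame with class `genomic_intervals` prepended.
#' @export
intervals <- function(df, validate = TRUE) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (!"name" %in% names(df)) df$name <- NA_character_
  if (!"score" %in% names(df)) df$score <- NA_real_
  if (!"strand" %in% names(df)) df$strand <- "*"
  if (validate && nrow(df)) {
    if (any(df$start < 0)) stop("negative interval start")
    bad <- df$start >= df$end
    if (any(bad)) {
      warning(sum(bad), " degenerate interval(s) with start >= end dropped")
      df <- df[!bad, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' Write intervals as BED (0-based half-open, as BED defines)
#'
#' @param x interval table from [intervals()] or [read_intervals()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = ifelse(is.na(x$strand) | x$strand == "*", "*", x$strand))
  if (!all(is.na(x$name))) gr$name <- ifelse(is.na(x$name), ".", x$name)
  if (!all(is.na(x$score))) gr$score <- ifelse(is.na(x$score), 0, x$score)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
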