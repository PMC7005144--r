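#' Read genomic regions from BED6 or narrowPeak files
#'
#' Parses tab-separated peak or region files into a data frame of 0-based
#' half-open intervals. BED6 records take their signal from column 5 (the
#' score field, read as a float); narrowPeak (BED6+4) records take it from
#' column 7 (signalValue) and additionally carry the summit offset from
#' column 10. Input order is preserved.
#'
#' @param path Path to a tab-separated file.
#' @param dialect Either \code{"bed6"} (6 columns) or \code{"narrowpeak"}
#'   (10 columns).
#' @return A data frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{name}, \code{strand}, \code{signal} and (for narrowPeak)
#'   \code{summit_offset}, one row per input record.
#' @details Coordinates are 0-based half-open throughout the package, the
#'   native convention of every format read here. Records violating
#'   \code{0 <= start < end}, or rows with the wrong column count for the
#'   declared dialect, raise an error naming the offending line.
#' @seealso [write_regions()], [read_signal_track()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\te1\t0\t.", f)
#' read_regions(f, "bed6")
read_regions <- function(path, dialect = c("bed6", "narrowpeak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  ncol_expected <- if (dialect == "bed6") 6L else 10L
  n <- length(lines)
  if (n == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), strand = character(),
                      signal = numeric(), stringsAsFactors = FALSE)
    if (dialect == "narrowpeak") out$summit_offset <- integer()
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  lens <- lengths(fields)
  bad <- which(lens != ncol_expected)
  if (length(bad)) {
    stop(sprintf("format error in %s line %d: expected %d tab-separated columns for dialect '%s', found %d",
                 path, bad[1L], ncol_expected, dialect, lens[bad[1L]]), call. = FALSE)
  }
  m <- matrix(unlist(fields), nrow = n, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2L]))
  end <- suppressWarnings(as.numeric(m[, 3L]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    stop(sprintf("malformed record in %s line %d: start/end must satisfy 0 <= start < end (got %s, %s)",
                 path, bad[1L], m[bad[1L], 2L], m[bad[1L], 3L]), call. = FALSE)
  }
  signal_col <- if (dialect == "bed6") 5L else 7L
  signal <- suppressWarnings(as.numeric(m[, signal_col]))
  bad <- which(is.na(signal) | signal < 0)
  if (length(bad)) {
    stop(sprintf("malformed record in %s line %d: signal must be a number >= 0 (got %s)",
                 path, bad[1L], m[bad[1L], signal_col]), call. = FALSE)
  }
  out <- data.frame(
    chrom = m[, 1L], start = start, end = end,
    name = m[, 4L], strand = m[, 6L], signal = signal,
    stringsAsFactors = FALSE
  )
  if (dialect == "narrowpeak") {
    summit <- suppressWarnings(as.integer(m[, 10L]))
    bad <- which(is.na(summit) | summit < -1L |
                   (summit >= 0L & start + summit >= end))
    if (length(bad)) {
      stop(sprintf("malformed record in %s line %d: summit offset must be -1 or place the summit inside the peak",
                   path, bad[1L]), call. = FALSE)
    }
    out$summit_offset <- summit
  }
  validate_intervals(out, "peaks")
  out
}

#' Write genomic regions as BED6 or narrowPeak
#'
#' Writes tab-separated, newline-terminated records so that
#' \code{read_regions(write_regions(x))} reproduces coordinates and signal
#' exactly (for signal values of at most 15 significant digits). Missing
#' \code{name}/\code{strand}/\code{signal} columns are filled with
#' \code{"."}, \code{"."} and 0.
#'
#' @param regions Data frame of intervals as returned by [read_regions()];
#'   only \code{chrom}, \code{start}, \code{end} are mandatory.
#' @param path Output file path.
#' @param dialect \code{"bed6"} or \code{"narrowpeak"}.
#' @return Invisibly, \code{path}.
#' @export
write_regions <- function(regions, path, dialect = c("bed6", "narrowpeak")) {
  dialect <- match.arg(dialect)
  validate_intervals(regions, "regions")
  n <- nrow(regions)
  name <- if ("name" %in% names(regions)) as.character(regions$name) else rep(".", n)
  strand <- if ("strand" %in% names(regions)) as.character(regions$strand) else rep(".", n)
  signal <- if ("signal" %in% names(regions)) regions$signal else rep(0, n)
  if (n > 0 && any(signal < 0)) stop("signal must be >= 0", call. = FALSE)
  if (dialect == "bed6") {
    lines <- paste(regions$chrom, format_number(regions$start),
                   format_number(regions$end), name,
                   format_number(signal), strand, sep = "\t")
  } else {
    summit <- if ("summit_offset" %in% names(regions)) regions$summit_offset else rep(-1L, n)
    lines <- paste(regions$chrom, format_number(regions$start),
                   format_number(regions$end), name, "0", strand,
                   format_number(signal), "-1", "-1",
                   format_number(summit), sep = "\t")
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (n > 0) writeLines(lines, con)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' Reads a 4-column bedGraph file into a per-chromosome sorted,
#' non-overlapping valued interval set. Zero-value records are dropped on
#' read (they carry no signal); the library total
#' \eqn{\sum value \cdot (end - start)} is computed and attached.
#'
#' @param path Path to a bedGraph file (chrom, start, end, value; whitespace
#'   separated).
#' @return A \code{signal_track}: data frame with columns \code{chrom},
#'   \code{start}, \code{end}, \code{value}, sorted by (chrom, start), with
#'   attribute \code{library_total}.
#' @details Overlapping intervals on a chromosome are an error (bedGraph
#'   semantics require a partition), as is a track whose total signal is 0.
#'   Negative values are rejected.
#' @export
read_signal_track <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty-track error: ", path, " has no records", call. = FALSE)
  fields <- strsplit(lines, "[ \t]+")
  lens <- lengths(fields)
  bad <- which(lens != 4L)
  if (length(bad)) {
    stop(sprintf("format error in %s line %d: bedGraph requires 4 columns, found %d",
                 path, bad[1L], lens[bad[1L]]), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  df <- data.frame(
    chrom = m[, 1L],
    start = suppressWarnings(as.numeric(m[, 2L])),
    end = suppressWarnings(as.numeric(m[, 3L])),
    value = suppressWarnings(as.numeric(m[, 4L])),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 0 | df$start >= df$end)
  if (length(bad)) {
    stop(sprintf("malformed record in %s line %d: 0 <= start < end required",
                 path, bad[1L]), call. = FALSE)
  }
  bad <- which(is.na(df$value) | df$value < 0)
  if (length(bad)) {
    stop(sprintf("malformed record in %s line %d: value must be a number >= 0",
                 path, bad[1L]), call. = FALSE)
  }
  signal_track(df)
}

#' Construct a signal track from a valued-interval data frame
#'
#' Validates and normalises an in-memory track: sorts per chromosome, drops
#' zero-value intervals, rejects overlaps, and computes the library total.
#'
#' @param df Data frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{value} (0-based half-open, value >= 0).
#' @return A \code{signal_track} object.
#' @export
signal_track <- function(df) {
  validate_intervals(df, "signal track")
  if (!"value" %in% names(df)) stop("signal track needs a 'value' column", call. = FALSE)
  if (any(df$value < 0)) stop("signal track values must be >= 0", call. = FALSE)
  df <- df[df$value > 0, , drop = FALSE]
  df <- sort_intervals(df)
  rownames(df) <- NULL
  if (nrow(df) > 1) {
    same <- df$chrom[-1L] == df$chrom[-nrow(df)]
    olap <- which(same & df$start[-1L] < df$end[-nrow(df)])
    if (length(olap)) {
      stop(sprintf("overlap error: intervals %d and %d overlap on %s",
                   olap[1L], olap[1L] + 1L, df$chrom[olap[1L] + 1L]), call. = FALSE)
    }
  }
  total <- sum(df$value * (df$end - df$start))
  if (!is.finite(total) || total <= 0) {
    stop("empty-track error: library total is 0 (all records zero-valued?)", call. = FALSE)
  }
  structure(df, library_total = total, class = c("signal_track", "data.frame"))
}

#' Library total of a signal track
#' @param track A \code{signal_track}.
#' @return The total signal mass \eqn{\sum value \cdot (end-start)}.
#' @export
library_total <- function(track) {
  tot <- attr(track, "library_total")
  if (is.null(tot)) stop("not a signal_track", call. = FALSE)
  tot
}

#' Write a signal track as bedGraph
#' @param track A \code{signal_track} (or compatible data frame).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_signal_track <- function(track, path) {
  lines <- paste(track$chrom, format_number(track$start),
                 format_number(track$end), format_number(track$value),
                 sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con)
  invisible(path)
}

#' Read a strand-aware gene annotation (BED6)
#'
#' Genes must carry an explicit \code{+} or \code{-} strand; the TSS is
#' derived per [gene_tss()].
#'
#' @param path BED6 file of gene bodies.
#' @return Data frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{name}, \code{strand}, \code{tss}.
#' @export
read_genes <- function(path) {
  g <- read_regions(path, "bed6")
  bad <- which(!g$strand %in% c("+", "-"))
  if (length(bad)) {
    stop(sprintf("gene annotation %s line %d: strand must be '+' or '-'",
                 path, bad[1L]), call. = FALSE)
  }
  g$signal <- NULL
  g$tss <- gene_tss(g)
  g
}

#' Transcription start site of a gene model
#'
#' For a 0-based half-open gene body, the TSS is \code{start} on the plus
#' strand and \code{end - 1} (the last covered base) on the minus strand.
#' The TSS stands in for the promoter in all distance computations.
#'
#' @param gene Data frame with \code{start}, \code{end}, \code{strand}
#'   columns (one or more rows).
#' @return Integer vector of TSS positions.
#' @export
#' @examples
#' gene_tss(data.frame(start = 100, end = 500, strand = "+"))  # 100
#' gene_tss(data.frame(start = 100, end = 500, strand = "-"))  # 499
gene_tss <- function(gene) {
  if (any(!gene$strand %in% c("+", "-"))) {
    stop("undefined-strand error: TSS requires strand '+' or '-'", call. = FALSE)
  }
  ifelse(gene$strand == "+", gene$start, gene$end - 1)
}
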