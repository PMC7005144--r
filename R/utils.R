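# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards (the idiom of stats::simulate). Keeps generator determinism a
# local property instead of a global side effect.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single non-missing number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

# Validate a data frame of 0-based half-open intervals.
validate_intervals <- function(x, what = "regions") {
  need <- c("chrom", "start", "end")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop(sprintf("'%s' must be a data frame with columns chrom, start, end", what),
         call. = FALSE)
  }
  if (nrow(x) > 0) {
    if (any(is.na(x$chrom)) || any(!nzchar(as.character(x$chrom)))) {
      stop(sprintf("'%s' has empty chromosome names", what), call. = FALSE)
    }
    bad <- which(!(x$start >= 0 & x$start < x$end))
    if (length(bad)) {
      stop(sprintf("'%s' violates 0 <= start < end at row %d", what, bad[1L]),
           call. = FALSE)
    }
  }
  invisible(x)
}

# 0-based half-open intervals -> GRanges (1-based closed). Chromosome names
# are compared as exact strings; no aliasing is ever applied.
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# GRanges -> 0-based half-open data frame.
granges_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

sort_intervals <- function(x) {
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}

# Numbers -> text that survives a round trip through read.table for values
# with <= 15 significant digits (the precision of as.character for doubles).
format_number <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == floor(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
    as.character(v)
  }, character(1))
}
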