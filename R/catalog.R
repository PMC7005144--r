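#' Filter peaks down to regular (distal, intergenic) enhancers
#'
#' Retains exactly the peaks that (i) overlap no gene body and (ii) lie
#' strictly more than \code{min_gap} base pairs away from every gene body on
#' their chromosome. A peak whose boundary gap to the nearest gene equals
#' \code{min_gap} exactly is removed (strict inequality). Peaks on
#' chromosomes carrying no genes are retained; an empty gene list retains
#' all peaks. Input order is preserved.
#'
#' @param peaks Data frame of peak intervals (\code{chrom}, \code{start},
#'   \code{end}, ...).
#' @param genes Data frame of gene bodies (\code{chrom}, \code{start},
#'   \code{end}).
#' @param min_gap Minimum boundary-to-boundary gap in bp (default 5000); the
#'   gap is measured between interval edges, not midpoints or TSSs.
#' @return The retained subset of \code{peaks}, original order and columns.
#' @export
filter_regular_enhancers <- function(peaks, genes, min_gap = 5000) {
  validate_intervals(peaks, "peaks")
  validate_intervals(genes, "genes")
  stopifnot_scalar_number(min_gap, "min_gap")
  if (nrow(peaks) == 0L || nrow(genes) == 0L) return(peaks)
  pk <- as_granges(peaks)
  gn <- as_granges(genes)
  # distanceToNearest: 0 for overlapping or bookended ranges, else the gap.
  # Peaks on chromosomes with no genes get no hit and stay retained; the
  # disjoint-seqlevel warning GRanges emits for that case is the intended
  # behaviour here.
  hits <- suppressWarnings(GenomicRanges::distanceToNearest(pk, gn))
  keep <- rep(TRUE, nrow(peaks))
  idx <- S4Vectors::queryHits(hits)
  gap <- S4Vectors::mcols(hits)$distance
  # Overlapping pairs have distance 0 but must also be caught explicitly:
  # distance 0 covers both "inside a genic region" and "bookended".
  keep[idx] <- gap > min_gap
  ov <- suppressWarnings(GenomicRanges::findOverlaps(pk, gn))
  keep[unique(S4Vectors::queryHits(ov))] <- FALSE
  peaks[keep, , drop = FALSE]
}

#' Merge one or more interval sets into a sorted non-overlapping union
#'
#' Returns the union of covered bases as sorted, non-overlapping intervals.
#' Bookended intervals (\code{[a,b)} followed by \code{[b,c)}) are merged.
#' The operation is idempotent and commutative over its inputs.
#'
#' @param ... One or more data frames of intervals (\code{chrom},
#'   \code{start}, \code{end}).
#' @return Data frame of merged intervals sorted by (chrom, start).
#' @export
#' @examples
#' merge_regions(data.frame(chrom = "chr1", start = c(100, 150), end = c(200, 300)))
merge_regions <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) && !is.data.frame(parts[[1L]])) {
    parts <- parts[[1L]]
  }
  for (p in parts) validate_intervals(p, "regions")
  all <- do.call(rbind, lapply(parts, function(p) p[, c("chrom", "start", "end")]))
  if (is.null(all) || nrow(all) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  }
  merged <- GenomicRanges::reduce(as_granges(all))  # merges bookended runs
  out <- sort_intervals(granges_to_df(merged))      # lexicographic chrom order
  rownames(out) <- NULL
  out
}

#' Quantify track signal over regions in rpm and rpm/bp
#'
#' For each region, the raw signal is the sum over overlapping track
#' intervals of \code{value * overlap_length}. It is normalised to reads per
#' million of the track's library total, \code{rpm = raw / library_total *
#' 1e6}; when a control track is given, the control rpm is subtracted and
#' the result clipped at 0 (background subtraction). \code{rpm_per_bp}
#' divides by region length.
#'
#' @param track A \code{signal_track}.
#' @param regions Data frame of intervals.
#' @param control Optional \code{signal_track} used for background
#'   subtraction.
#' @return Data frame with columns \code{rpm} and \code{rpm_per_bp}, one row
#'   per region (input order).
#' @details Regions on chromosomes absent from the track score 0, with an
#'   aggregated warning reporting how many regions were affected.
#' @export
quantify_region_signal <- function(track, regions, control = NULL) {
  validate_intervals(regions, "regions")
  if (!inherits(track, "signal_track")) track <- signal_track(track)
  rpm <- .region_rpm(track, regions)
  if (!is.null(control)) {
    if (!inherits(control, "signal_track")) control <- signal_track(control)
    rpm <- pmax(0, rpm - .region_rpm(control, regions))
  }
  data.frame(rpm = rpm, rpm_per_bp = rpm / (regions$end - regions$start))
}

.region_rpm <- function(track, regions) {
  n <- nrow(regions)
  raw <- numeric(n)
  if (n == 0L) return(raw)
  missing_chrom <- !(regions$chrom %in% unique(track$chrom))
  if (any(missing_chrom)) {
    warning(sprintf("%d region(s) on chromosome(s) absent from track (%s); signal set to 0",
                    sum(missing_chrom),
                    paste(unique(regions$chrom[missing_chrom]), collapse = ", ")),
            call. = FALSE)
  }
  rg <- as_granges(regions)
  tg <- as_granges(track)
  # absent chromosomes already warned about above, in region terms
  hits <- suppressWarnings(GenomicRanges::findOverlaps(rg, tg))
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(rg[q], tg[s]))
    contrib <- ov * track$value[s]
    raw <- raw + as.numeric(tapply(contrib, factor(q, levels = seq_len(n)), sum, default = 0))
  }
  raw / library_total(track) * 1e6
}

#' Build an enhancer catalog (regions x samples rpm matrix)
#'
#' Assembles the hub object of the pipeline: a sorted, merged region list
#' with one library-normalised signal column per sample, in the given sample
#' order. All-zero regions are retained (they are informative for
#' differential analysis).
#'
#' @param tracks Named list of \code{signal_track}s, one per sample. Names
#'   must be unique.
#' @param regions Data frame of merged regions (will be sorted by
#'   (chrom, start)).
#' @param controls Optional named list of control \code{signal_track}s;
#'   matched to samples by name, missing entries mean no subtraction.
#' @return An \code{enhancer_catalog}: list with \code{regions},
#'   \code{samples}, \code{rpm} and \code{rpm_per_bp} matrices.
#' @export
build_catalog <- function(tracks, regions, controls = NULL) {
  if (!is.list(tracks) || length(tracks) < 1L || is.null(names(tracks)) ||
      any(!nzchar(names(tracks)))) {
    stop("'tracks' must be a non-empty named list of signal tracks", call. = FALSE)
  }
  if (anyDuplicated(names(tracks))) {
    stop("duplicate sample names: ",
         paste(unique(names(tracks)[duplicated(names(tracks))]), collapse = ", "),
         call. = FALSE)
  }
  validate_intervals(regions, "regions")
  regions <- sort_intervals(regions[, c("chrom", "start", "end")])
  rownames(regions) <- NULL
  samples <- names(tracks)
  rpm <- matrix(0, nrow = nrow(regions), ncol = length(samples),
                dimnames = list(NULL, samples))
  for (s in samples) {
    ctrl <- if (!is.null(controls) && s %in% names(controls)) controls[[s]] else NULL
    rpm[, s] <- quantify_region_signal(tracks[[s]], regions, control = ctrl)$rpm
  }
  width <- regions$end - regions$start
  structure(
    list(regions = regions, samples = samples, rpm = rpm,
         rpm_per_bp = rpm / width),
    class = "enhancer_catalog"
  )
}

#' @export
print.enhancer_catalog <- function(x, ...) {
  cat(sprintf("enhancer_catalog: %d regions x %d samples (%s)\n",
              nrow(x$regions), length(x$samples),
              paste(x$samples, collapse = ", ")))
  cat(sprintf("  chromosomes: %s\n", paste(unique(x$regions$chrom), collapse = ", ")))
  cat(sprintf("  total rpm per sample: %s\n",
              paste(sprintf("%.1f", colSums(x$rpm)), collapse = ", ")))
  invisible(x)
}

#' Write / read an enhancer catalog as TSV
#'
#' Serialisation is (chrom, start, end, one rpm column per sample); the
#' rpm/bp matrix is recomputed on read.
#' @param catalog An \code{enhancer_catalog}.
#' @param path TSV path.
#' @return \code{write_catalog}: invisibly, \code{path};
#'   \code{read_catalog}: an \code{enhancer_catalog}.
#' @export
write_catalog <- function(catalog, path) {
  df <- cbind(catalog$regions,
              as.data.frame(catalog$rpm, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  regions <- df[, c("chrom", "start", "end")]
  samples <- setdiff(names(df), c("chrom", "start", "end"))
  rpm <- as.matrix(df[, samples, drop = FALSE])
  structure(
    list(regions = regions, samples = samples, rpm = rpm,
         rpm_per_bp = rpm / (regions$end - regions$start)),
    class = "enhancer_catalog"
  )
}

#' PCA of samples over the enhancer signal matrix
#'
#' Projects samples onto principal axes of the enhancer landscape, the
#' standard diagnostic for whether chromatin states (for example parental
#' versus resistant lines) separate. Cells are transformed as
#' \code{log2(rpm + 1)}; the \code{top_k} regions of highest variance across
#' samples are selected; each selected region is centred across samples (no
#' scaling); samples are projected via singular-value decomposition.
#'
#' @param catalog An \code{enhancer_catalog} with at least two samples.
#' @param top_k Number of most-variable regions to use (default 500, the
#'   convention of regularised-log PCA plots); capped at the region count.
#' @return An \code{enhancer_pca}: list with \code{coordinates} (samples x
#'   components), \code{variance_fraction} (non-increasing, summing to 1
#'   over returned components) and \code{k_regions_used}.
#' @export
pca_samples <- function(catalog, top_k = 500) {
  if (!inherits(catalog, "enhancer_catalog")) stop("not an enhancer_catalog", call. = FALSE)
  if (length(catalog$samples) < 2L) {
    stop("PCA requires at least 2 samples", call. = FALSE)
  }
  x <- log2(catalog$rpm + 1)
  rv <- apply(x, 1L, stats::var)
  if (all(rv == 0)) stop("no-variance error: signal matrix is constant across samples", call. = FALSE)
  k <- min(as.integer(top_k), nrow(x))
  sel <- order(rv, decreasing = TRUE)[seq_len(k)]
  xc <- x[sel, , drop = FALSE]
  xc <- xc - rowMeans(xc)
  p <- stats::prcomp(t(xc), center = FALSE, scale. = FALSE)
  vf <- p$sdev^2 / sum(p$sdev^2)
  coords <- p$x
  rownames(coords) <- catalog$samples
  structure(
    list(coordinates = coords, variance_fraction = vf, k_regions_used = k),
    class = "enhancer_pca"
  )
}

#' @export
print.enhancer_pca <- function(x, ...) {
  cat(sprintf("enhancer_pca over %d regions\n", x$k_regions_used))
  vf <- x$variance_fraction
  cat(sprintf("  variance explained: %s\n",
              paste(sprintf("PC%d %.1f%%", seq_along(vf), 100 * vf), collapse = ", ")))
  print(round(x$coordinates[, seq_len(min(3L, ncol(x$coordinates))), drop = FALSE], 3))
  invisible(x)
}

#' @export
plot.enhancer_pca <- function(x, ...) {
  co <- x$coordinates
  graphics::plot(co[, 1L], co[, 2L],
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$variance_fraction[1L]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$variance_fraction[2L]),
                 pch = 19, ...)
  graphics::text(co[, 1L], co[, 2L], labels = rownames(co), pos = 3, cex = 0.8)
  invisible(x)
}
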