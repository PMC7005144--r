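#' Rank background-subtracted enhancer occupancy
#'
#' Clips negative values to 0 and sorts ascending (stable order for ties),
#' producing the hockey-stick curve on which the super-enhancer cutoff is
#' defined. The mapping back to the original enhancer order is retained.
#'
#' @param signals Numeric vector of background-subtracted occupancy (for
#'   example rpm/bp per enhancer).
#' @return A \code{ranked_curve}: list with \code{signals} (non-decreasing,
#'   all >= 0), \code{order} (original indices in rank order), \code{n} and
#'   the scaled-axes slope \code{m = (max - min) / n}.
#' @export
rank_signals <- function(signals) {
  if (length(signals) == 0L) stop("rank_signals: empty input", call. = FALSE)
  if (any(!is.finite(signals))) stop("rank_signals: non-finite signals", call. = FALSE)
  s <- pmax(0, as.numeric(signals))
  o <- order(s)  # stable radix/shell sort: ties keep original index order
  s <- s[o]
  n <- length(s)
  structure(
    list(signals = s, order = o, n = n, m = (max(s) - min(s)) / n),
    class = "ranked_curve"
  )
}

#' Tangent cutoff on the ranked occupancy curve
#'
#' Finds the point where a line of slope 1 -- after scaling both axes of
#' the ranked curve to the unit square -- is tangent to the curve. In rank
#' versus signal units that slope is \code{m = (max - min) / n}. Every rank
#' \code{i} is tried as the tangent point: the line of slope \code{m}
#' through \code{(i, s[i])} is drawn and the number of curve points lying on
#' or below it is counted; the tangent is the candidate with the fewest such
#' points (smallest index on ties). The search is exhaustive by
#' construction, so the cutoff is deterministic and free of the local optima
#' a numeric optimiser could land in.
#'
#' @param curve A \code{ranked_curve} from [rank_signals()].
#' @return List with \code{cutoff_index} (1-based rank) and
#'   \code{cutoff_signal}. A flat curve (max = min, slope 0) yields
#'   \code{cutoff_index} 1, so nothing exceeds the cutoff downstream.
#' @export
#' @examples
#' tangent_cutoff(rank_signals(c(0, 0, 1, 2, 10)))  # cutoff_signal 2
tangent_cutoff <- function(curve) {
  if (!inherits(curve, "ranked_curve")) curve <- rank_signals(curve)
  s <- curve$signals
  n <- curve$n
  m <- curve$m
  ranks <- seq_len(n)
  line_at <- m * ranks
  intercept <- s - line_at               # b_i for candidate i
  # counts[i] = #{ j : s[j] <= m*j + b_i + tol }; O(n^2) is trivial at desk
  # scale. tol is proportional to the curve's range so the on-the-line test
  # (in particular each candidate against its own tangent) is immune to
  # rounding and the cutoff is invariant to positive rescaling.
  tol <- 1e-9 * (max(s) - min(s))
  below <- outer(line_at, intercept, "+") # [j, i] = m*j + b_i
  counts <- colSums(s <= below + tol)
  i <- which.min(counts)                  # which.min takes the smallest index on ties
  list(cutoff_index = i, cutoff_signal = s[i])
}

#' Stitch nearby regions before ranking
#'
#' Joins intervals separated by at most \code{gap} bp on the same
#' chromosome (the classic pre-step of super-enhancer pipelines, typically
#' 12500 bp). Stitching is an explicit, optional transformation -- the
#' tangent-cutoff definition itself never stitches -- so apply it to the
#' region list before [build_catalog()] when wanted.
#'
#' @param regions Data frame of intervals.
#' @param gap Maximum separation to bridge, in bp (default 12500).
#' @return Merged data frame of stitched intervals, sorted.
#' @export
stitch_regions <- function(regions, gap = 12500) {
  validate_intervals(regions, "regions")
  stopifnot_scalar_number(gap, "gap")
  if (nrow(regions) == 0L) return(regions[, c("chrom", "start", "end")])
  merged <- GenomicRanges::reduce(as_granges(regions), min.gapwidth = gap + 1)
  out <- sort_intervals(granges_to_df(merged))
  rownames(out) <- NULL
  out
}

#' Call super-enhancers for one catalog sample
#'
#' Runs [rank_signals()] and [tangent_cutoff()] on a sample's rpm/bp column
#' (optionally background-subtracted against a control sample, clipped at
#' 0) and labels as super-enhancers the enhancers whose signal is strictly
#' greater than the cutoff signal.
#'
#' @param catalog An \code{enhancer_catalog}.
#' @param sample Sample name to rank.
#' @param control Optional control sample name whose rpm/bp is subtracted
#'   before ranking.
#' @return An \code{se_call}: list with the per-enhancer table
#'   (\code{regions} plus \code{signal}, \code{rank}, \code{is_super}),
#'   \code{cutoff_index}, \code{cutoff_signal} and \code{n_super}.
#' @export
call_super_enhancers <- function(catalog, sample, control = NULL) {
  if (!inherits(catalog, "enhancer_catalog")) stop("not an enhancer_catalog", call. = FALSE)
  if (!sample %in% catalog$samples) {
    stop("unknown sample: ", sample, call. = FALSE)
  }
  sig <- catalog$rpm_per_bp[, sample]
  if (!is.null(control)) {
    if (!control %in% catalog$samples) stop("unknown control sample: ", control, call. = FALSE)
    sig <- pmax(0, sig - catalog$rpm_per_bp[, control])
  }
  curve <- rank_signals(sig)
  cut <- tangent_cutoff(curve)
  rank_of <- integer(curve$n)
  rank_of[curve$order] <- seq_len(curve$n)
  is_super <- pmax(0, sig) > cut$cutoff_signal   # strictly above the cutoff
  tab <- cbind(catalog$regions,
               data.frame(signal = pmax(0, sig), rank = rank_of,
                          is_super = is_super))
  structure(
    list(table = tab, sample = sample, cutoff_index = cut$cutoff_index,
         cutoff_signal = cut$cutoff_signal, n_super = sum(is_super)),
    class = "se_call"
  )
}

#' @export
print.se_call <- function(x, ...) {
  cat(sprintf("se_call for sample '%s': %d / %d enhancers above the tangent cutoff\n",
              x$sample, x$n_super, nrow(x$table)))
  cat(sprintf("  cutoff at rank %d, signal %.4g (rpm/bp)\n",
              x$cutoff_index, x$cutoff_signal))
  invisible(x)
}

#' Hockey-stick plot of a super-enhancer call
#'
#' Ranked occupancy with the cutoff marked; super-enhancers are the points
#' right of the vertical line.
#' @param x An \code{se_call}.
#' @param ... Passed to \code{plot}.
#' @export
plot.se_call <- function(x, ...) {
  s <- sort(x$table$signal)
  graphics::plot(seq_along(s), s, type = "l",
                 xlab = "enhancer rank", ylab = "occupancy (rpm/bp)",
                 main = sprintf("%s: %d super-enhancers", x$sample, x$n_super), ...)
  graphics::abline(v = x$cutoff_index, h = x$cutoff_signal, lty = 2, col = "grey40")
  graphics::points(which(s > x$cutoff_signal), s[s > x$cutoff_signal],
                   col = "red3", pch = 19, cex = 0.5)
  invisible(x)
}
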