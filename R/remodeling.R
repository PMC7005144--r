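#' Pseudocounted log2 fold change of normalised signal
#'
#' \code{log2((a + pseudocount) / (b + pseudocount))}. The pseudocount
#' keeps empty regions finite and at fold change 0 when both sides are 0.
#'
#' @param a,b Non-negative rpm values (vectors recycle as usual).
#' @param pseudocount Added to both sides, in rpm units (> 0, default 1).
#' @return log2 fold change(s) of \code{a} over \code{b}.
#' @export
#' @examples
#' log2_fold_change(4, 1)  # log2(5/2)
log2_fold_change <- function(a, b, pseudocount = 1.0) {
  stopifnot_scalar_number(pseudocount, "pseudocount", positive = TRUE)
  if (any(a < 0) || any(b < 0)) stop("rpm inputs must be >= 0", call. = FALSE)
  log2((a + pseudocount) / (b + pseudocount))
}

.remodel_classes <- c("GAINED_BRD4_INDEPENDENT", "GAINED_BRD4_DEPENDENT",
                      "LOST", "UNCHANGED")

#' Classify enhancer remodeling from paired H3K27ac and BRD4 signal
#'
#' The quadrant analysis of paired-condition differential ChIP signal: per
#' region, log2 fold changes (resistant over parental) of H3K27ac and BRD4
#' rpm are computed with a pseudocount, and each region is assigned exactly
#' one class. With threshold \code{t} (log2 units):
#' \itemize{
#'   \item \code{UNCHANGED} if \code{|lfc_k27| < t};
#'   \item \code{LOST} if \code{lfc_k27 <= -t};
#'   \item for \code{lfc_k27 >= t}: \code{GAINED_BRD4_DEPENDENT} when
#'     \code{lfc_brd4 >= t}, else \code{GAINED_BRD4_INDEPENDENT} -- the
#'     "H3K27ac up, BRD4 unchanged or down" quadrant that marks enhancer
#'     gains not mediated by BRD4 recruitment.
#' }
#'
#' @param catalog An \code{enhancer_catalog} holding all four samples.
#' @param k27_pair Character vector \code{c(resistant, parental)} of H3K27ac
#'   sample names.
#' @param brd4_pair Character vector \code{c(resistant, parental)} of BRD4
#'   sample names.
#' @param t Differential threshold in log2 units (> 0, default 1).
#' @param pseudocount rpm pseudocount (> 0, default 1).
#' @return A \code{remodeling_table}: the catalog regions with
#'   \code{lfc_k27}, \code{lfc_brd4} and \code{class} columns, carrying
#'   \code{t} and \code{pseudocount} as attributes.
#' @export
classify_regions <- function(catalog, k27_pair, brd4_pair, t = 1.0,
                             pseudocount = 1.0) {
  if (!inherits(catalog, "enhancer_catalog")) stop("not an enhancer_catalog", call. = FALSE)
  stopifnot_scalar_number(t, "t", positive = TRUE)
  pair_ok <- function(p) is.character(p) && length(p) == 2L
  if (!pair_ok(k27_pair) || !pair_ok(brd4_pair)) {
    stop("k27_pair and brd4_pair must each be c(resistant, parental) sample names",
         call. = FALSE)
  }
  missing <- setdiff(c(k27_pair, brd4_pair), catalog$samples)
  if (length(missing)) {
    stop("unknown sample(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  lfc_k27 <- log2_fold_change(catalog$rpm[, k27_pair[1L]],
                              catalog$rpm[, k27_pair[2L]], pseudocount)
  lfc_brd4 <- log2_fold_change(catalog$rpm[, brd4_pair[1L]],
                               catalog$rpm[, brd4_pair[2L]], pseudocount)
  class <- ifelse(abs(lfc_k27) < t, "UNCHANGED",
           ifelse(lfc_k27 <= -t, "LOST",
           ifelse(lfc_brd4 >= t, "GAINED_BRD4_DEPENDENT",
                  "GAINED_BRD4_INDEPENDENT")))
  out <- cbind(catalog$regions,
               data.frame(lfc_k27 = lfc_k27, lfc_brd4 = lfc_brd4,
                          class = factor(class, levels = .remodel_classes)))
  structure(out, t = t, pseudocount = pseudocount,
            class = c("remodeling_table", "data.frame"))
}

#' Class fractions of a remodeling table
#'
#' Fractions of regions per remodeling class, either among differential
#' regions only (the three non-UNCHANGED classes; the headline "x% of
#' differential regions are BRD4-independent gains" statistic) or among all
#' regions.
#'
#' @param table A \code{remodeling_table}.
#' @param denominator \code{"all_differential"} (default) or
#'   \code{"all_regions"}.
#' @return Named numeric vector of fractions summing to 1 over the chosen
#'   denominator's classes.
#' @export
class_fractions <- function(table, denominator = c("all_differential", "all_regions")) {
  denominator <- match.arg(denominator)
  if (!nrow(table)) stop("empty remodeling table", call. = FALSE)
  cls <- factor(table$class, levels = .remodel_classes)
  if (denominator == "all_differential") {
    keep <- cls != "UNCHANGED"
    if (!any(keep)) {
      stop("empty denominator: no differential regions", call. = FALSE)
    }
    counts <- table(factor(cls[keep], levels = setdiff(.remodel_classes, "UNCHANGED")))
  } else {
    counts <- table(cls)
  }
  stats::setNames(as.numeric(counts) / sum(counts), names(counts))
}

#' @export
summary.remodeling_table <- function(object, ...) {
  counts <- table(factor(object$class, levels = .remodel_classes))
  cat(sprintf("remodeling_table: %d regions (t = %g, pseudocount = %g)\n",
              nrow(object), attr(object, "t"), attr(object, "pseudocount")))
  for (k in names(counts)) {
    cat(sprintf("  %-24s %6d (%.1f%%)\n", k, counts[[k]],
                100 * counts[[k]] / nrow(object)))
  }
  if (any(object$class != "UNCHANGED")) {
    fr <- class_fractions(object, "all_differential")
    cat(sprintf("  among differential: %s\n",
                paste(sprintf("%s %.1f%%", names(fr), 100 * fr), collapse = ", ")))
  }
  invisible(counts)
}

#' Distance from regions to the nearest transcription start site
#'
#' Per region, the distance is the minimum over same-chromosome TSSs of
#' \code{|midpoint - tss|}, with \code{midpoint = floor((start + end) / 2)}
#' -- the summary behind "how distal are these regulatory elements"
#' histograms. Regions on chromosomes without any gene have no defined
#' distance and are reported separately rather than silently dropped.
#'
#' @param regions Data frame of intervals.
#' @param genes Gene data frame with \code{chrom}, \code{start}, \code{end},
#'   \code{strand} (TSS derived via [gene_tss()]) or an explicit \code{tss}
#'   column.
#' @param bin_width Histogram bin width in bp (default 10000), bins anchored
#'   at 0.
#' @return A \code{distance_summary}: list with \code{distances} (NA where
#'   undefined), \code{histogram} (\code{breaks}, \code{counts} over defined
#'   distances), \code{mean_bp}, and \code{n_undefined}.
#' @export
distance_to_nearest_tss <- function(regions, genes, bin_width = 10000) {
  validate_intervals(regions, "regions")
  if (nrow(genes) == 0L) stop("no genes supplied", call. = FALSE)
  stopifnot_scalar_number(bin_width, "bin_width", positive = TRUE)
  tss <- if ("tss" %in% names(genes)) genes$tss else gene_tss(genes)
  mid <- floor((regions$start + regions$end) / 2)
  n <- nrow(regions)
  dist <- rep(NA_real_, n)
  for (ch in unique(regions$chrom)) {
    ti <- tss[genes$chrom == ch]
    if (!length(ti)) next
    ri <- which(regions$chrom == ch)
    ti <- sort(ti)
    # nearest sorted-TSS lookup per midpoint
    idx <- findInterval(mid[ri], ti)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(ti))
    dist[ri] <- pmin(abs(mid[ri] - ti[lo]), abs(mid[ri] - ti[hi]))
  }
  defined <- dist[!is.na(dist)]
  if (!length(defined)) {
    stop("no region shares a chromosome with any gene", call. = FALSE)
  }
  breaks <- seq(0, (floor(max(defined) / bin_width) + 1) * bin_width, by = bin_width)
  h <- graphics::hist(defined, breaks = breaks, plot = FALSE, right = FALSE)
  structure(
    list(distances = dist,
         histogram = list(breaks = breaks, counts = h$counts),
         mean_bp = mean(defined),
         n_undefined = sum(is.na(dist))),
    class = "distance_summary"
  )
}

#' @export
print.distance_summary <- function(x, ...) {
  n_def <- sum(!is.na(x$distances))
  cat(sprintf("distance_summary: %d regions (%d without a same-chromosome gene)\n",
              length(x$distances), x$n_undefined))
  cat(sprintf("  mean distance to nearest TSS: %.1f kb\n", x$mean_bp / 1000))
  invisible(x)
}

#' @export
plot.distance_summary <- function(x, ...) {
  h <- x$histogram
  graphics::barplot(h$counts, names.arg = sprintf("%g", h$breaks[-1L] / 1000),
                    xlab = "distance to nearest TSS (kb)", ylab = "regions", ...)
  invisible(x)
}
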