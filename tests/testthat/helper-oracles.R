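# Independent brute-force oracles. These deliberately share no code with
# the package internals: plain loops, base-wise coverage vectors, all-pairs
# scans.

# Tangent cutoff by literal exhaustive search: for every candidate rank i,
# draw the slope-m line through (i, s[i]) and count points on or below it.
oracle_tangent <- function(signals) {
  s <- sort(pmax(0, signals))
  n <- length(s)
  m <- (max(s) - min(s)) / n
  tol <- 1e-9 * (max(s) - min(s))  # same on-the-line tolerance as the package
  counts <- integer(n)
  for (i in seq_len(n)) {
    b <- s[i] - m * i
    cnt <- 0L
    for (j in seq_len(n)) {
      if (s[j] <= m * j + b + tol) cnt <- cnt + 1L
    }
    counts[i] <- cnt
  }
  i <- which(counts == min(counts))[1L]
  list(cutoff_index = i, cutoff_signal = s[i])
}

# Base-wise merge oracle: mark covered bases in a coverage vector per
# chromosome, then read off maximal runs. Only usable on small coordinates.
oracle_merge <- function(df) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    cov <- logical(max(sub$end))
    for (k in seq_len(nrow(sub))) {
      cov[(sub$start[k] + 1):sub$end[k]] <- TRUE
    }
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (any(keep)) {
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep] - 1L,
                              end = ends[keep], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# All-pairs gap oracle for the regular-enhancer filter.
oracle_filter <- function(peaks, genes, min_gap = 5000) {
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ok <- TRUE
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      if (peaks$start[i] < genes$end[j] && genes$start[j] < peaks$end[i]) {
        ok <- FALSE; break           # overlap: inside a genic region
      }
      gap <- if (peaks$end[i] <= genes$start[j]) genes$start[j] - peaks$end[i]
             else peaks$start[i] - genes$end[j]
      if (gap <= min_gap) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  peaks[keep, , drop = FALSE]
}

# All-pairs midpoint-to-TSS distance oracle.
oracle_distance <- function(regions, genes) {
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  d <- rep(NA_real_, nrow(regions))
  for (i in seq_len(nrow(regions))) {
    mid <- floor((regions$start[i] + regions$end[i]) / 2)
    best <- Inf
    for (j in seq_len(nrow(genes))) {
      if (regions$chrom[i] != genes$chrom[j]) next
      best <- min(best, abs(mid - tss[j]))
    }
    if (is.finite(best)) d[i] <- best
  }
  d
}

# Sample-PCA oracle via explicit eigendecomposition of the region-space
# covariance: rows = samples, columns = centred regions.
oracle_pca_coords <- function(rpm, top_k) {
  x <- log2(rpm + 1)
  rv <- apply(x, 1, var)
  sel <- order(rv, decreasing = TRUE)[seq_len(min(top_k, nrow(x)))]
  xc <- x[sel, , drop = FALSE]
  xc <- xc - rowMeans(xc)
  d <- t(xc)                                   # samples x regions
  ev <- eigen(crossprod(d), symmetric = TRUE)  # region-space covariance (unscaled)
  coords <- d %*% ev$vectors
  coords[, seq_len(min(dim(d))), drop = FALSE]
}

# random interval fixtures on a small coordinate space
random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 100000,
                             max_len = 5000) {
  start <- sample.int(max_pos - max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

random_genes <- function(n, ...) {
  g <- random_intervals(n, ...)
  g$strand <- sample(c("+", "-"), n, replace = TRUE)
  g$name <- paste0("g", seq_len(n))
  g
}

covered_bases <- function(df) {
  if (nrow(df) == 0) return(0)
  sum(vapply(sort(unique(df$chrom)), function(ch) {
    sub <- df[df$chrom == ch, ]
    cov <- logical(max(sub$end))
    for (k in seq_len(nrow(sub))) cov[(sub$start[k] + 1):sub$end[k]] <- TRUE
    sum(cov)
  }, numeric(1)))
}

# assemble an enhancer_catalog directly from an rpm matrix (bypassing
# tracks) for unit tests of downstream operations
build_catalog_from_matrix <- function(rpm, regions, samples) {
  rpm <- as.matrix(rpm)
  colnames(rpm) <- samples
  structure(
    list(regions = regions, samples = samples, rpm = rpm,
         rpm_per_bp = rpm / (regions$end - regions$start)),
    class = "enhancer_catalog"
  )
}

write_tmp <- function(lines, ext = ".bed") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
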