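#' Fraction Affected from viability readouts
#'
#' The standard luminescent-viability convention:
#' \code{FA = clamp(1 - treated / control, 0, 1)}. Untreated wells give 0,
#' fully killed wells 1; readouts above control clamp to 0.
#'
#' @param signal_treated Viability readout(s) of treated wells (>= 0).
#' @param signal_control Readout of the untreated control (> 0).
#' @return Fraction Affected in \code{[0, 1]} (vectorised).
#' @export
#' @examples
#' fraction_affected(2500, 10000)  # 0.75
fraction_affected <- function(signal_treated, signal_control) {
  if (any(signal_control <= 0)) stop("control readout must be > 0", call. = FALSE)
  if (any(signal_treated < 0)) stop("treated readout must be >= 0", call. = FALSE)
  pmin(1, pmax(0, 1 - signal_treated / signal_control))
}

#' Bliss-independence expected Fraction Affected
#'
#' The reference model for a non-interacting drug pair:
#' \code{E = fa_a + fa_b - fa_a * fa_b}. Symmetric, monotone in each
#' argument, and maps the unit square into the unit interval.
#'
#' @param fa_a,fa_b Single-agent Fraction Affected values in \code{[0, 1]}
#'   (vectorised).
#' @return Expected combination FA under independence.
#' @export
#' @examples
#' bliss_expected(0.5, 0.5)  # 0.75
bliss_expected <- function(fa_a, fa_b) {
  if (any(fa_a < 0 | fa_a > 1) || any(fa_b < 0 | fa_b > 1)) {
    stop("Fraction Affected must lie in [0, 1]", call. = FALSE)
  }
  fa_a + fa_b - fa_a * fa_b
}

#' Construct a dose-response combination matrix
#'
#' @param doses_a,doses_b Strictly increasing dose grids beginning at 0.
#' @param fa Fraction Affected matrix, rows indexed by \code{doses_a},
#'   columns by \code{doses_b}; \code{fa[1, 1]} (the double-untreated cell)
#'   must be 0 and all entries must lie in \code{[0, 1]}.
#' @return A \code{dose_matrix}.
#' @export
dose_matrix <- function(doses_a, doses_b, fa) {
  fa <- as.matrix(fa)
  if (doses_a[1L] != 0 || doses_b[1L] != 0) {
    stop("dose grids must begin at 0 (untreated row/column)", call. = FALSE)
  }
  if (any(diff(doses_a) <= 0) || any(diff(doses_b) <= 0)) {
    stop("dose grids must be strictly increasing", call. = FALSE)
  }
  if (nrow(fa) != length(doses_a) || ncol(fa) != length(doses_b)) {
    stop("fa matrix dimensions must match the dose grids", call. = FALSE)
  }
  if (fa[1L, 1L] != 0) stop("fa[0, 0] must be 0 (untreated cells unaffected)", call. = FALSE)
  if (any(fa < 0 | fa > 1)) stop("all fa must lie in [0, 1]", call. = FALSE)
  structure(list(doses_a = doses_a, doses_b = doses_b, fa = fa),
            class = "dose_matrix")
}

#' Read / write a combination dose matrix as TSV
#'
#' Layout: header row of drug-B doses, first column of drug-A doses, FA in
#' the body; the dose-0 row and column are mandatory.
#' @param path TSV path.
#' @param x A \code{dose_matrix} (for writing).
#' @return \code{read_dose_matrix}: a \code{dose_matrix};
#'   \code{write_dose_matrix}: invisibly, \code{path}.
#' @export
read_dose_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  doses_a <- as.numeric(df[[1L]])
  doses_b <- as.numeric(names(df)[-1L])
  dose_matrix(doses_a, doses_b, as.matrix(df[, -1L, drop = FALSE]))
}

#' @rdname read_dose_matrix
#' @export
write_dose_matrix <- function(x, path) {
  df <- data.frame(dose_a = format_number(x$doses_a), check.names = FALSE)
  body <- x$fa
  colnames(body) <- format_number(x$doses_b)
  utils::write.table(cbind(df, body), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Excess-over-Bliss scoring of a combination matrix
#'
#' For every combination cell (both doses > 0) the Bliss expectation is
#' computed from the measured single-agent row and column,
#' \code{E = fa(i,0) + fa(0,j) - fa(i,0) fa(0,j)}, and the excess
#' \code{fa(i,j) - E} is scored: excess > \code{epsilon} is synergy,
#' < \code{-epsilon} antagonism, otherwise additivity. Single-agent rows
#' and columns have excess 0 by definition.
#'
#' @param matrix A \code{dose_matrix}.
#' @param epsilon Verdict dead-band (default 0, the plain sign rule; raise
#'   it for noise-aware calls).
#' @return A \code{bliss_result}: list with \code{expected}, \code{excess}
#'   and \code{verdict} matrices (verdict NA outside combination cells).
#' @export
bliss_excess <- function(matrix, epsilon = 0) {
  x <- matrix
  if (!inherits(x, "dose_matrix")) stop("input must be a dose_matrix", call. = FALSE)
  if (epsilon < 0) stop("'epsilon' must be >= 0", call. = FALSE)
  fa <- x$fa
  fa_a <- fa[, 1L]   # drug A alone (column of dose_b = 0)
  fa_b <- fa[1L, ]   # drug B alone
  expected <- outer(fa_a, fa_b, function(a, b) a + b - a * b)
  excess <- fa - expected
  excess[1L, ] <- 0  # single-agent margins: no combination to score
  excess[, 1L] <- 0
  verdict <- matrix(NA_character_, nrow(fa), ncol(fa))
  combo <- cbind(rep(seq(2L, nrow(fa)), times = ncol(fa) - 1L),
                 rep(seq(2L, ncol(fa)), each = nrow(fa) - 1L))
  e <- excess[combo]
  verdict[combo] <- ifelse(e > epsilon, "synergy",
                    ifelse(e < -epsilon, "antagonism", "additivity"))
  structure(list(doses_a = x$doses_a, doses_b = x$doses_b, fa = fa,
                 expected = expected, excess = excess, verdict = verdict,
                 epsilon = epsilon),
            class = "bliss_result")
}

#' @export
print.bliss_result <- function(x, ...) {
  combo <- x$excess[-1L, -1L, drop = FALSE]
  cat(sprintf("bliss_result: %d x %d combination cells (epsilon = %g)\n",
              nrow(combo), ncol(combo), x$epsilon))
  v <- table(factor(x$verdict[-1L, -1L], levels = c("synergy", "additivity", "antagonism")))
  cat(sprintf("  verdicts: %s\n",
              paste(sprintf("%s %d", names(v), v), collapse = ", ")))
  cat(sprintf("  mean excess over combination cells: %+.4f\n", mean(combo)))
  invisible(x)
}

#' Paired FA / excess heatmaps of a Bliss result
#' @param x A \code{bliss_result}.
#' @param ... Unused.
#' @export
plot.bliss_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  lab_a <- format_number(x$doses_a)
  lab_b <- format_number(x$doses_b)
  draw <- function(m, main, zlim, col) {
    graphics::image(seq_along(x$doses_b), seq_along(x$doses_a), t(m),
                    axes = FALSE, xlab = "drug B dose", ylab = "drug A dose",
                    main = main, zlim = zlim, col = col)
    graphics::axis(1, at = seq_along(x$doses_b), labels = lab_b, cex.axis = 0.7)
    graphics::axis(2, at = seq_along(x$doses_a), labels = lab_a, cex.axis = 0.7)
  }
  draw(x$fa, "Fraction Affected", c(0, 1), grDevices::hcl.colors(21, "YlOrRd", rev = TRUE))
  draw(x$excess, "Excess over Bliss", c(-1, 1), grDevices::hcl.colors(21, "RdBu", rev = TRUE))
  invisible(x)
}

#' IC50 by log-dose linear interpolation
#'
#' Finds the dose at which the Fraction Affected crosses 0.5, by linear
#' interpolation of FA against log dose after an isotonic (monotone
#' non-decreasing) cleanup of the response. Exact grid hits are returned
#' exactly. If the cleaned response never brackets 0.5 within the dose
#' range, the estimate is flagged not reached.
#'
#' @param doses Strictly positive, ascending dose vector (length >= 2).
#' @param fa Fraction Affected at each dose, in \code{[0, 1]}.
#' @return An \code{ic50_estimate}: list with \code{ic50} (NA when not
#'   reached), \code{reached}, and \code{method = "interpolation"}.
#' @export
#' @examples
#' estimate_ic50(c(1, 4), c(1/3, 2/3))$ic50  # 2 (Hill midpoint)
estimate_ic50 <- function(doses, fa) {
  if (length(doses) < 2L) stop("need at least 2 doses", call. = FALSE)
  if (any(doses <= 0)) stop("doses must be > 0 for log-dose interpolation", call. = FALSE)
  if (any(diff(doses) <= 0)) stop("doses must be strictly ascending", call. = FALSE)
  if (any(fa < 0 | fa > 1)) stop("fa must lie in [0, 1]", call. = FALSE)
  ld <- log(doses)
  y <- stats::isoreg(ld, fa)$yf   # monotone non-decreasing cleanup
  hit <- which(y == 0.5)
  if (length(hit)) {
    ic50 <- doses[hit[1L]]
  } else if (min(y) > 0.5 || max(y) < 0.5) {
    return(structure(list(ic50 = NA_real_, reached = FALSE,
                          method = "interpolation"), class = "ic50_estimate"))
  } else {
    j <- which(y > 0.5)[1L]       # first dose above the midpoint
    frac <- (0.5 - y[j - 1L]) / (y[j] - y[j - 1L])
    ic50 <- exp(ld[j - 1L] + frac * (ld[j] - ld[j - 1L]))
  }
  structure(list(ic50 = ic50, reached = TRUE, method = "interpolation"),
            class = "ic50_estimate")
}

#' @export
print.ic50_estimate <- function(x, ...) {
  if (x$reached) {
    cat(sprintf("IC50 = %.4g (log-dose interpolation)\n", x$ic50))
  } else {
    cat("IC50 not reached within the dose range\n")
  }
  invisible(x)
}
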