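#' Simulate a toy genome with genes and truth-labelled enhancer regions
#'
#' Lays out non-overlapping gene bodies and enhancer regions on one or more
#' chromosomes so that every enhancer passes the regular-enhancer filter
#' (boundary gap to every gene body strictly greater than 5 kb), assigns
#' each enhancer a planted remodeling class, and draws per-region expected
#' parental counts from a heavy-tailed Pareto distribution so that a small
#' minority of regions carries a large share of signal -- the hockey-stick
#' shape the super-enhancer tangent cutoff assumes.
#'
#' Planted log2 fold changes (resistant over parental) follow the class
#' semantics: \code{UNCHANGED} has both lfcs 0; \code{GAINED_*} classes have
#' \code{lfc_k27 = +effect_lfc}; \code{GAINED_BRD4_DEPENDENT} additionally
#' gains BRD4 (\code{lfc_brd4 = +effect_lfc}) while
#' \code{GAINED_BRD4_INDEPENDENT} draws \code{lfc_brd4} uniformly in
#' \code{[-1.5, 0]} ("no change or decreased" BRD4); \code{LOST} has both
#' lfcs \code{-effect_lfc}.
#'
#' @param n_chroms Number of chromosomes (named chr1, chr2, ...).
#' @param chrom_length Length of each chromosome in bp.
#' @param n_genes,n_enhancers Feature counts across the whole genome.
#' @param class_proportions Named or ordered numeric vector over
#'   (UNCHANGED, GAINED_BRD4_INDEPENDENT, GAINED_BRD4_DEPENDENT, LOST)
#'   summing to 1 (tolerance 1e-9). Default 0.90/0.04/0.03/0.03:
#'   differential regions a minority, as in genome-wide paired ChIP
#'   comparisons.
#' @param min_gene_gap Minimum gap between genes in bp (default 5000).
#' @param seed RNG seed; identical seeds give identical output.
#' @param effect_lfc Magnitude of planted log2 fold changes (default 2).
#' @param base_mean Expected parental count per region; the per-region means
#'   are Pareto draws with this expectation (default 100).
#' @param dispersion Negative-binomial dispersion for the count draws
#'   (default 0.05); 0 means deterministic counts.
#' @param tail_shape Pareto shape of the base-mean distribution (default 3;
#'   smaller is heavier-tailed).
#' @param n_distractors Number of extra distractor peaks placed inside gene
#'   bodies (default 0); they carry class \code{DISTRACTOR}, lfc 0, and are
#'   meant to be removed by the regular-enhancer filter.
#' @return List with \code{genes} (BED6-style data frame with \code{tss})
#'   and \code{truth} (a \code{synthetic_truth} data frame: region
#'   coordinates, \code{region_id}, \code{class}, \code{lfc_k27},
#'   \code{lfc_brd4}, \code{base_mean}, with \code{dispersion},
#'   \code{seed} and \code{class_proportions} attributes).
#' @export
simulate_genome <- function(n_chroms = 1, chrom_length = 4e7,
                            n_genes = 200, n_enhancers = 2000,
                            class_proportions = c(
                              UNCHANGED = 0.90,
                              GAINED_BRD4_INDEPENDENT = 0.04,
                              GAINED_BRD4_DEPENDENT = 0.03,
                              LOST = 0.03),
                            min_gene_gap = 5000, seed = 1,
                            effect_lfc = 2, base_mean = 100,
                            dispersion = 0.05, tail_shape = 3,
                            n_distractors = 0) {
  classes <- c("UNCHANGED", "GAINED_BRD4_INDEPENDENT",
               "GAINED_BRD4_DEPENDENT", "LOST")
  p <- class_proportions
  if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("class_proportions must be 4 non-negative values summing to 1", call. = FALSE)
  }
  if (is.null(names(p))) names(p) <- classes
  p <- p[classes]
  if (any(is.na(p))) stop("class_proportions names must be the four remodeling classes",
                          call. = FALSE)
  stopifnot_scalar_number(tail_shape, "tail_shape", positive = TRUE)
  if (tail_shape <= 1) stop("'tail_shape' must be > 1 (finite mean)", call. = FALSE)
  stopifnot_scalar_number(base_mean, "base_mean", positive = TRUE)
  if (dispersion < 0) stop("'dispersion' must be >= 0", call. = FALSE)

  gene_len <- c(2000, 10000)       # gene body length range, bp
  enh_len <- c(500, 2000)          # enhancer length range, bp
  margin <- max(2501, ceiling(min_gene_gap / 2))  # slot margin: gaps > 5000 and >= min_gene_gap
  n_feat <- n_genes + n_enhancers + n_distractors

  with_seed(seed, {
    # round-robin feature allocation over chromosomes, then random slot order
    chrom_of_slot <- rep(paste0("chr", seq_len(n_chroms)), length.out = n_feat)
    per_chrom <- table(chrom_of_slot)
    slot_width <- chrom_length / max(per_chrom)
    if (slot_width < max(gene_len) + 2 * margin) {
      stop(sprintf(
        "placement error: genome too small for %d features (need slot width >= %d bp, have %.0f)",
        n_feat, max(gene_len) + 2 * margin, slot_width), call. = FALSE)
    }
    type <- sample(c(rep("gene", n_genes), rep("enhancer", n_enhancers),
                     rep("distractor_host", n_distractors)))
    # slot index within chromosome, in order of appearance
    slot_idx <- stats::ave(seq_len(n_feat), chrom_of_slot, FUN = seq_along)
    len <- numeric(n_feat)
    is_gene <- type != "enhancer"
    len[is_gene] <- floor(stats::runif(sum(is_gene), gene_len[1L], gene_len[2L] + 1))
    len[!is_gene] <- floor(stats::runif(sum(!is_gene), enh_len[1L], enh_len[2L] + 1))
    slack <- slot_width - 2 * margin - len
    start <- floor((slot_idx - 1) * slot_width + margin + stats::runif(n_feat) * slack)
    end <- start + len

    gi <- which(type == "gene")
    genes <- data.frame(
      chrom = chrom_of_slot[gi], start = start[gi], end = end[gi],
      name = paste0("gene", seq_along(gi)),
      strand = sample(c("+", "-"), length(gi), replace = TRUE),
      stringsAsFactors = FALSE
    )
    genes <- sort_intervals(genes)
    rownames(genes) <- NULL
    genes$name <- paste0("gene", seq_len(nrow(genes)))
    genes$tss <- gene_tss(genes)

    ei <- which(type == "enhancer")
    enh <- data.frame(chrom = chrom_of_slot[ei], start = start[ei], end = end[ei],
                      stringsAsFactors = FALSE)
    enh <- sort_intervals(enh)
    rownames(enh) <- NULL
    cls <- sample(classes, n_enhancers, replace = TRUE, prob = p)
    lfc_k27 <- numeric(n_enhancers)
    lfc_brd4 <- numeric(n_enhancers)
    lfc_k27[cls == "GAINED_BRD4_INDEPENDENT"] <- effect_lfc
    lfc_brd4[cls == "GAINED_BRD4_INDEPENDENT"] <-
      stats::runif(sum(cls == "GAINED_BRD4_INDEPENDENT"), -1.5, 0)
    lfc_k27[cls == "GAINED_BRD4_DEPENDENT"] <- effect_lfc
    lfc_brd4[cls == "GAINED_BRD4_DEPENDENT"] <- effect_lfc
    lfc_k27[cls == "LOST"] <- -effect_lfc
    lfc_brd4[cls == "LOST"] <- -effect_lfc
    # Pareto(shape, xm) with xm chosen so that E[base_mean] = base_mean
    xm <- base_mean * (tail_shape - 1) / tail_shape
    bm <- xm / stats::runif(n_enhancers)^(1 / tail_shape)

    truth <- cbind(enh, data.frame(
      region_id = paste0("enh", seq_len(n_enhancers)),
      class = cls, lfc_k27 = lfc_k27, lfc_brd4 = lfc_brd4,
      base_mean = bm, distractor = FALSE, stringsAsFactors = FALSE
    ))

    if (n_distractors > 0) {
      # distractor peaks sit inside randomly chosen gene bodies
      host <- genes[sample(nrow(genes), n_distractors, replace = TRUE), ]
      dlen <- floor(stats::runif(n_distractors, enh_len[1L], enh_len[2L] + 1))
      dlen <- pmin(dlen, host$end - host$start - 2)
      dstart <- host$start + 1 +
        floor(stats::runif(n_distractors) * (host$end - host$start - dlen - 1))
      dtruth <- data.frame(
        chrom = host$chrom, start = dstart, end = dstart + dlen,
        region_id = paste0("distractor", seq_len(n_distractors)),
        class = "DISTRACTOR", lfc_k27 = 0, lfc_brd4 = 0,
        base_mean = xm / stats::runif(n_distractors)^(1 / tail_shape),
        distractor = TRUE, stringsAsFactors = FALSE
      )
      truth <- rbind(truth, dtruth)
      truth <- sort_intervals(truth)
      rownames(truth) <- NULL
    }

    structure(
      list(genes = genes,
           truth = structure(truth, dispersion = dispersion, seed = seed,
                             class_proportions = p, effect_lfc = effect_lfc,
                             class = c("synthetic_truth", "data.frame"))),
      class = "synthetic_genome"
    )
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic_genome: %d genes, %d regions on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$truth), length(unique(x$genes$chrom))))
  print(table(x$truth$class))
  invisible(x)
}

.mark_condition_offset <- function(condition, mark) {
  # fixed seed offsets so each (condition, mark) experiment is an
  # independent but reproducible draw from the same truth
  grid <- c(parental.h3k27ac = 101L, resistant.h3k27ac = 102L,
            parental.brd4 = 103L, resistant.brd4 = 104L)
  grid[[paste(condition, mark, sep = ".")]]
}

#' Simulate one ChIP experiment (signal track + peak calls) from truth
#'
#' Per-region counts are negative-binomial with mean
#' \code{base_mean * 2^(lfc * [condition == resistant]) * depth_scale},
#' using the mark's planted lfc (\code{lfc_k27} for H3K27ac, \code{lfc_brd4}
#' for BRD4) and the truth's dispersion (0 means deterministic counts, the
#' noiseless limit). Counts are spread uniformly over each region to form a
#' bedGraph-style track; a low constant background (default 1\% of the mean
#' per-bp region density) fills the gaps between regions so library totals
#' are exercised honestly; the matching peak list carries the region counts
#' as narrowPeak signal.
#'
#' @param truth A \code{synthetic_truth} from [simulate_genome()].
#' @param condition \code{"parental"} or \code{"resistant"}.
#' @param mark \code{"h3k27ac"} or \code{"brd4"}.
#' @param depth_scale Sequencing-depth multiplier (> 0, default 1).
#' @param seed RNG seed; default derives a fixed per-(condition, mark)
#'   offset from the truth's seed, so the four experiments of a paired
#'   design are independent draws. Pass explicit seeds for replicates.
#' @param background_rate Per-bp background value between regions; default
#'   \code{NULL} means 1\% of the mean region density; 0 disables.
#' @param chrom_length Chromosome length used to close the final background
#'   interval (default: 10 kb past the last feature).
#' @return List with \code{track} (a \code{signal_track}) and \code{peaks}
#'   (narrowPeak-style data frame with the region counts as signal).
#' @export
simulate_chip_experiment <- function(truth,
                                     condition = c("parental", "resistant"),
                                     mark = c("h3k27ac", "brd4"),
                                     depth_scale = 1, seed = NULL,
                                     background_rate = NULL,
                                     chrom_length = NULL) {
  condition <- match.arg(condition)
  mark <- match.arg(mark)
  stopifnot_scalar_number(depth_scale, "depth_scale", positive = TRUE)
  if (!inherits(truth, "synthetic_truth")) stop("not a synthetic_truth", call. = FALSE)
  dispersion <- attr(truth, "dispersion")
  if (is.null(seed)) {
    seed <- attr(truth, "seed") + .mark_condition_offset(condition, mark)
  }
  lfc <- if (mark == "h3k27ac") truth$lfc_k27 else truth$lfc_brd4
  mu <- truth$base_mean * 2^(lfc * (condition == "resistant")) * depth_scale
  counts <- with_seed(seed, {
    if (dispersion <= 0) mu else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  })
  width <- truth$end - truth$start
  if (is.null(background_rate)) {
    background_rate <- 0.01 * mean(counts / width)
  }
  segs <- vector("list", length(unique(truth$chrom)))
  names(segs) <- unique(truth$chrom)
  for (ch in names(segs)) {
    i <- which(truth$chrom == ch)
    i <- i[order(truth$start[i])]
    reg <- data.frame(chrom = ch, start = truth$start[i], end = truth$end[i],
                      value = counts[i] / width[i], stringsAsFactors = FALSE)
    if (background_rate > 0) {
      last <- if (is.null(chrom_length)) max(truth$end[i]) + 10000 else chrom_length
      gap_start <- c(0, truth$end[i])
      gap_end <- c(truth$start[i], last)
      keep <- gap_end > gap_start
      bg <- data.frame(chrom = ch, start = gap_start[keep], end = gap_end[keep],
                       value = background_rate, stringsAsFactors = FALSE)
      reg <- rbind(reg, bg)
    }
    segs[[ch]] <- reg
  }
  track_df <- do.call(rbind, segs)
  track_df <- track_df[track_df$value > 0, , drop = FALSE]
  peaks <- data.frame(
    chrom = truth$chrom, start = truth$start, end = truth$end,
    name = truth$region_id, strand = ".", signal = counts,
    summit_offset = -1L, stringsAsFactors = FALSE
  )
  list(track = signal_track(track_df), peaks = peaks,
       condition = condition, mark = mark, counts = counts)
}

#' Define the ground truth of a synthetic drug-combination experiment
#'
#' Single agents follow Hill curves
#' \eqn{fa(d) = d^h / (d^h + IC50^h)}; combination cells equal the Bliss
#' expectation plus an additive interaction term (positive = planted
#' synergy) plus Gaussian noise, clipped to \code{[0, 1]}.
#'
#' @param ic50_a,ic50_b Single-agent IC50s (> 0).
#' @param hill_a,hill_b Hill slopes (> 0, default 1).
#' @param interaction Additive excess over Bliss in FA units, in
#'   \code{[-1, 1]} (default 0 = exact independence).
#' @param noise_sd Gaussian noise SD on every measured cell except the
#'   double-zero dose (default 0).
#' @param seed RNG seed.
#' @return A \code{combo_truth} list.
#' @export
combo_truth <- function(ic50_a, ic50_b, hill_a = 1, hill_b = 1,
                        interaction = 0, noise_sd = 0, seed = 1) {
  stopifnot_scalar_number(ic50_a, "ic50_a", positive = TRUE)
  stopifnot_scalar_number(ic50_b, "ic50_b", positive = TRUE)
  stopifnot_scalar_number(hill_a, "hill_a", positive = TRUE)
  stopifnot_scalar_number(hill_b, "hill_b", positive = TRUE)
  if (interaction < -1 || interaction > 1) {
    stop("'interaction' must lie in [-1, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  structure(list(ic50_a = ic50_a, ic50_b = ic50_b, hill_a = hill_a,
                 hill_b = hill_b, interaction = interaction,
                 noise_sd = noise_sd, seed = seed),
            class = "combo_truth")
}

.hill_fa <- function(d, ic50, h) ifelse(d <= 0, 0, d^h / (d^h + ic50^h))

#' Simulate a drug-combination Fraction-Affected matrix
#'
#' Dose grids are geometric series (ratio 4) bracketing each drug's IC50,
#' preceded by the mandatory dose-0 row/column whose FA is 0 before noise.
#'
#' @param combo A \code{combo_truth}.
#' @param n_doses_a,n_doses_b Number of non-zero doses per drug (>= 2,
#'   default 5, the five-point design of combination screens).
#' @return A \code{dose_matrix}.
#' @export
simulate_dose_matrix <- function(combo, n_doses_a = 5, n_doses_b = 5) {
  if (!inherits(combo, "combo_truth")) stop("not a combo_truth", call. = FALSE)
  if (n_doses_a < 2 || n_doses_b < 2) stop("need at least 2 doses per drug", call. = FALSE)
  geom_grid <- function(ic50, n) ic50 * 4^(seq_len(n) - ceiling(n / 2))
  da <- c(0, geom_grid(combo$ic50_a, n_doses_a))
  db <- c(0, geom_grid(combo$ic50_b, n_doses_b))
  fa_a <- .hill_fa(da, combo$ic50_a, combo$hill_a)
  fa_b <- .hill_fa(db, combo$ic50_b, combo$hill_b)
  fa <- outer(fa_a, fa_b, function(a, b) a + b - a * b)
  fa[1L, ] <- fa_b   # single agents: no Bliss combination on the margins
  fa[, 1L] <- fa_a
  combo_cells <- outer(da > 0, db > 0, "&")
  fa[combo_cells] <- fa[combo_cells] + combo$interaction
  if (combo$noise_sd > 0) {
    noise <- with_seed(combo$seed,
                       matrix(stats::rnorm(length(fa), 0, combo$noise_sd),
                              nrow(fa), ncol(fa)))
    noise[1L, 1L] <- 0   # untreated cell stays exactly 0
    fa <- fa + noise
  }
  fa <- pmax(pmin(fa, 1), 0)   # matrix first: pmin/pmax keep its dim
  dose_matrix(da, db, fa)
}
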