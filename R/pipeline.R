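#' Run the enhancer-remodeling pipeline from a config
#'
#' Orchestrates the full analysis: regular-enhancer filtering of every
#' sample's peaks against the gene annotation, cross-sample merging,
#' catalog construction from the signal tracks, sample PCA, per-sample
#' super-enhancer calls, paired H3K27ac/BRD4 classification, and
#' distance-to-TSS summaries of the BRD4-independent gained class. All
#' tabular outputs are written as TSV into the output directory together
#' with a manifest recording parameters and content hashes, so an identical
#' config reproduces identical outputs.
#'
#' @param config Either a named list or a path to a YAML file with fields:
#'   \describe{
#'     \item{genes}{path to a BED6 gene annotation (strand mandatory).}
#'     \item{peaks}{named list sample -> peak file.}
#'     \item{signal}{named list sample -> bedGraph file.}
#'     \item{peak_dialect}{\code{"narrowpeak"} (default) or \code{"bed6"}.}
#'     \item{k27_pair, brd4_pair}{each \code{c(resistant, parental)} sample
#'       names; classification runs only when both are present.}
#'     \item{se_samples}{samples to call super-enhancers on (default: the
#'       k27 pair, else all samples).}
#'     \item{params}{optional list: \code{min_gap} (5000), \code{top_k}
#'       (500), \code{t} (1), \code{pseudocount} (1), \code{bin_width}
#'       (10000), \code{epsilon} (0).}
#'     \item{out_dir}{output directory (created if missing).}
#'   }
#' @return Invisibly, a result bundle: list with \code{catalog},
#'   \code{pca}, \code{se_calls}, \code{classes}, \code{distances},
#'   \code{manifest}, \code{params}.
#' @export
run_remodeling_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- .validate_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  par <- cfg$params
  log_stage <- function(stage, fmt, ...) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  genes <- run_stage("genes", read_genes(cfg$genes))
  log_stage("genes", "%d genes", nrow(genes))

  peak_sets <- run_stage("peaks", lapply(cfg$peaks, read_regions, dialect = cfg$peak_dialect))
  filtered <- run_stage("filter", lapply(peak_sets, filter_regular_enhancers,
                                         genes = genes, min_gap = par$min_gap))
  for (s in names(filtered)) {
    log_stage("filter", "%s: %d / %d peaks pass the regular-enhancer filter",
              s, nrow(filtered[[s]]), nrow(peak_sets[[s]]))
  }

  merged <- run_stage("merge", merge_regions(lapply(filtered, function(p)
    p[, c("chrom", "start", "end")])))
  log_stage("merge", "%d merged regular-enhancer regions", nrow(merged))

  tracks <- run_stage("signal", lapply(cfg$signal, read_signal_track))
  catalog <- run_stage("catalog", build_catalog(tracks, merged))
  write_catalog(catalog, file.path(out_dir, "catalog.tsv"))

  pca <- NULL
  if (length(catalog$samples) >= 2L) {
    pca <- run_stage("pca", pca_samples(catalog, top_k = par$top_k))
    pca_df <- data.frame(sample = rownames(pca$coordinates),
                         pca$coordinates, check.names = FALSE)
    utils::write.table(pca_df, file.path(out_dir, "pca.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    vf <- data.frame(component = seq_along(pca$variance_fraction),
                     variance_fraction = pca$variance_fraction)
    utils::write.table(vf, file.path(out_dir, "pca_variance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_stage("pca", "PC1 explains %.1f%% of variance over %d regions",
              100 * pca$variance_fraction[1L], pca$k_regions_used)
  }

  se_samples <- cfg$se_samples
  se_calls <- run_stage("superenhancer", lapply(stats::setNames(se_samples, se_samples),
                                                function(s) call_super_enhancers(catalog, s)))
  se_tab <- do.call(rbind, lapply(se_samples, function(s) {
    cbind(sample = s, se_calls[[s]]$table)
  }))
  utils::write.table(se_tab, file.path(out_dir, "superenhancers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (s in se_samples) {
    log_stage("superenhancer", "%s: %d super-enhancers (cutoff %.4g rpm/bp)",
              s, se_calls[[s]]$n_super, se_calls[[s]]$cutoff_signal)
  }

  classes <- NULL
  distances <- NULL
  if (!is.null(cfg$k27_pair) && !is.null(cfg$brd4_pair)) {
    classes <- run_stage("classify",
                         classify_regions(catalog, cfg$k27_pair, cfg$brd4_pair,
                                          t = par$t, pseudocount = par$pseudocount))
    utils::write.table(as.data.frame(classes), file.path(out_dir, "classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts <- table(classes$class)
    summ <- data.frame(class = names(counts), count = as.integer(counts),
                       fraction_all = as.integer(counts) / nrow(classes))
    utils::write.table(summ, file.path(out_dir, "class_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_stage("classify", "%s", paste(sprintf("%s=%d", names(counts), counts),
                                      collapse = " "))
    gained_ind <- as.data.frame(classes)[classes$class == "GAINED_BRD4_INDEPENDENT", ]
    if (nrow(gained_ind) > 0) {
      distances <- run_stage("distances",
                             distance_to_nearest_tss(gained_ind, genes,
                                                     bin_width = par$bin_width))
      ddf <- data.frame(gained_ind[, c("chrom", "start", "end")],
                        distance_bp = distances$distances)
      utils::write.table(ddf, file.path(out_dir, "distances.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      log_stage("distances", "mean distance of gained BRD4-independent regions to TSS: %.1f kb",
                distances$mean_bp / 1000)
    }
  }

  manifest <- .write_manifest(out_dir, par)
  bundle <- list(catalog = catalog, pca = pca, se_calls = se_calls,
                 classes = classes, distances = distances,
                 manifest = manifest, params = par, out_dir = out_dir)
  invisible(bundle)
}

.default_params <- function() {
  list(min_gap = 5000, top_k = 500, t = 1, pseudocount = 1,
       bin_width = 10000, epsilon = 0)
}

.validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a list or a YAML path", call. = FALSE)
  need <- c("genes", "peaks", "signal", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss)) {
    stop("config validation error: missing field(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  paths <- c(config$genes, unlist(config$peaks), unlist(config$signal))
  absent <- paths[!file.exists(paths)]
  if (length(absent)) {
    stop("config validation error: missing input file(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (is.null(names(config$peaks)) || is.null(names(config$signal))) {
    stop("config validation error: peaks and signal must be named by sample",
         call. = FALSE)
  }
  if (!setequal(names(config$peaks), names(config$signal))) {
    stop("config validation error: peaks and signal sample names differ", call. = FALSE)
  }
  par <- utils::modifyList(.default_params(), config$params %||% list())
  for (nm in c("min_gap", "top_k", "t", "pseudocount", "bin_width")) {
    stopifnot_scalar_number(par[[nm]], nm, positive = nm %in% c("t", "pseudocount", "bin_width"))
  }
  pair <- function(p, nm) {
    if (is.null(p)) return(NULL)
    p <- unlist(p)
    if (length(p) != 2L || !all(p %in% names(config$signal))) {
      stop(sprintf("config validation error: %s must name two signal samples", nm),
           call. = FALSE)
    }
    p
  }
  k27 <- pair(config$k27_pair, "k27_pair")
  brd4 <- pair(config$brd4_pair, "brd4_pair")
  se_samples <- config$se_samples %||% (if (!is.null(k27)) k27 else names(config$signal))
  se_samples <- unlist(se_samples)
  if (!all(se_samples %in% names(config$signal))) {
    stop("config validation error: se_samples must name signal samples", call. = FALSE)
  }
  list(genes = config$genes, peaks = config$peaks, signal = config$signal,
       peak_dialect = config$peak_dialect %||% "narrowpeak",
       k27_pair = k27, brd4_pair = brd4, se_samples = se_samples,
       params = par, out_dir = config$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_manifest <- function(out_dir, params) {
  files <- sort(setdiff(list.files(out_dir), "manifest.tsv"))
  md5 <- unname(tools::md5sum(file.path(out_dir, files)))
  manifest <- data.frame(file = files, md5 = md5, stringsAsFactors = FALSE)
  header <- sprintf("# %s", paste(sprintf("%s=%s", names(params),
                                          vapply(params, format, "")), collapse = " "))
  con <- file(file.path(out_dir, "manifest.tsv"), "w")
  writeLines(header, con)
  utils::write.table(manifest, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  manifest
}

#' One-command synthetic demonstration of the full analysis
#'
#' Generates a truth-labelled synthetic dataset (toy genome, paired
#' parental/resistant H3K27ac and BRD4 experiments with PCA replicates,
#' drug-combination matrices with and without planted interaction), writes
#' it to disk in the standard formats, runs the full remodeling pipeline
#' plus Bliss scoring and IC50 estimation on those files, and reports
#' planted truth against what the pipeline recovered. Deterministic under a
#' fixed seed.
#'
#' @param seed Master seed driving every random draw (default 1).
#' @param dir Working directory for inputs and outputs (default: fresh
#'   tempdir subdirectory).
#' @param n_enhancers,n_genes,chrom_length Genome size knobs passed to
#'   [simulate_genome()].
#' @param interaction Planted excess over Bliss for the synergy
#'   demonstration (default 0.2).
#' @param noise_sd Dose-matrix noise (default 0.02).
#' @param ic50_shift Planted fold shift between the two simulated
#'   dose-response curves (default 3).
#' @return A result bundle: everything [run_remodeling_pipeline()] returns
#'   plus \code{truth}, \code{recovery} (class-recovery statistics),
#'   \code{bliss} (null and planted-interaction results), \code{ic50}
#'   (planted and recovered fold shift), and \code{report} (a data frame of
#'   headline numbers, also written to \code{report.tsv}).
#' @export
run_demo <- function(seed = 1, dir = NULL, n_enhancers = 2000, n_genes = 200,
                     chrom_length = 4e7, interaction = 0.2, noise_sd = 0.02,
                     ic50_shift = 3) {
  if (is.null(dir)) {
    dir <- file.path(tempdir(), sprintf("enhancer_demo_%d", as.integer(seed)))
    unlink(dir, recursive = TRUE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  in_dir <- file.path(dir, "inputs")
  dir.create(in_dir, showWarnings = FALSE)

  genome <- simulate_genome(n_chroms = 1, chrom_length = chrom_length,
                            n_genes = n_genes, n_enhancers = n_enhancers,
                            seed = seed)
  truth <- genome$truth
  write_regions(genome$genes, file.path(in_dir, "genes.bed"), "bed6")
  utils::write.table(as.data.frame(truth), file.path(in_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # paired design: one H3K27ac + one BRD4 experiment per condition for
  # classification, plus two extra H3K27ac replicates per condition so the
  # PCA has 3 + 3 samples
  samples <- list(
    k27_parental = list(mark = "h3k27ac", condition = "parental", seed = NULL),
    k27_resistant = list(mark = "h3k27ac", condition = "resistant", seed = NULL),
    brd4_parental = list(mark = "brd4", condition = "parental", seed = NULL),
    brd4_resistant = list(mark = "brd4", condition = "resistant", seed = NULL),
    k27_parental_rep2 = list(mark = "h3k27ac", condition = "parental", seed = seed + 201),
    k27_parental_rep3 = list(mark = "h3k27ac", condition = "parental", seed = seed + 202),
    k27_resistant_rep2 = list(mark = "h3k27ac", condition = "resistant", seed = seed + 203),
    k27_resistant_rep3 = list(mark = "h3k27ac", condition = "resistant", seed = seed + 204)
  )
  peak_files <- list()
  signal_files <- list()
  for (s in names(samples)) {
    sp <- samples[[s]]
    exp <- simulate_chip_experiment(truth, condition = sp$condition,
                                    mark = sp$mark, seed = sp$seed,
                                    chrom_length = chrom_length)
    pf <- file.path(in_dir, paste0(s, ".narrowPeak"))
    sf <- file.path(in_dir, paste0(s, ".bedGraph"))
    write_regions(exp$peaks, pf, "narrowpeak")
    write_signal_track(exp$track, sf)
    peak_files[[s]] <- pf
    signal_files[[s]] <- sf
  }

  config <- list(
    genes = file.path(in_dir, "genes.bed"),
    peaks = peak_files, signal = signal_files,
    peak_dialect = "narrowpeak",
    k27_pair = c("k27_resistant", "k27_parental"),
    brd4_pair = c("brd4_resistant", "brd4_parental"),
    se_samples = c("k27_parental", "k27_resistant"),
    out_dir = file.path(dir, "results")
  )
  bundle <- run_remodeling_pipeline(config)

  recovery <- evaluate_recovery(bundle$classes, truth)

  # synergy: a null matrix, a planted-interaction matrix, and a planted
  # IC50 shift between two curves sampled on a common dose grid
  null_bliss <- bliss_excess(simulate_dose_matrix(
    combo_truth(ic50_a = 1, ic50_b = 0.05, interaction = 0, noise_sd = 0,
                seed = seed + 301)))
  planted_bliss <- bliss_excess(simulate_dose_matrix(
    combo_truth(ic50_a = 1, ic50_b = 0.05, interaction = interaction,
                noise_sd = noise_sd, seed = seed + 302)))
  write_dose_matrix(dose_matrix(planted_bliss$doses_a, planted_bliss$doses_b,
                                planted_bliss$fa),
                    file.path(in_dir, "combo_matrix.tsv"))
  unclipped <- planted_bliss$expected + interaction <= 1
  unclipped[1L, ] <- FALSE
  unclipped[, 1L] <- FALSE

  base_curve <- simulate_dose_matrix(combo_truth(ic50_a = 1, ic50_b = 1,
                                                 seed = seed + 303), 7, 2)
  doses <- base_curve$doses_a[-1L]
  fa_sensitive <- .hill_fa(doses, 1, 1)
  fa_resistant <- .hill_fa(doses, ic50_shift, 1)
  ic50_sens <- estimate_ic50(doses, fa_sensitive)
  ic50_res <- estimate_ic50(doses, fa_resistant)
  ic50 <- list(planted_shift = ic50_shift,
               recovered_shift = ic50_res$ic50 / ic50_sens$ic50,
               sensitive = ic50_sens$ic50, resistant = ic50_res$ic50)

  report <- data.frame(
    quantity = c("class_recovery_accuracy",
                 "planted_gained_independent_fraction_of_gained",
                 "recovered_gained_independent_fraction_of_gained",
                 "gained_independent_pct_of_differential",
                 "mean_tss_distance_kb",
                 "n_super_parental", "n_super_resistant",
                 "pc1_variance_pct", "pc1_separates_conditions",
                 "bliss_null_max_abs_excess",
                 "bliss_planted_mean_excess_unclipped",
                 "ic50_recovered_fold_shift"),
    value = c(recovery$accuracy,
              recovery$planted_gained_ind_fraction,
              recovery$recovered_gained_ind_fraction,
              100 * class_fractions(bundle$classes)[["GAINED_BRD4_INDEPENDENT"]],
              bundle$distances$mean_bp / 1000,
              bundle$se_calls$k27_parental$n_super,
              bundle$se_calls$k27_resistant$n_super,
              100 * bundle$pca$variance_fraction[1L],
              as.numeric(.pc1_separates(bundle$pca)),
              max(abs(null_bliss$excess[-1L, -1L])),
              mean(planted_bliss$excess[unclipped]),
              ic50$recovered_shift)
  )
  utils::write.table(report, file.path(bundle$out_dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bundle$manifest <- .write_manifest(bundle$out_dir, bundle$params)

  c(bundle, list(truth = truth, recovery = recovery,
                 bliss = list(null = null_bliss, planted = planted_bliss,
                              unclipped = unclipped),
                 ic50 = ic50, report = report, dir = dir, seed = seed))
}

# do parental and resistant samples fall on opposite signs of PC1?
.pc1_separates <- function(pca) {
  pc1 <- pca$coordinates[, 1L]
  res <- grepl("resistant", rownames(pca$coordinates))
  all(sign(pc1[res]) == sign(pc1[res][1L])) &&
    all(sign(pc1[!res]) == -sign(pc1[res][1L]))
}

#' Compare recovered remodeling classes against planted truth
#'
#' Matches classified regions to truth regions by coordinates and computes
#' the recovery accuracy plus the planted and recovered fractions of
#' BRD4-independent gains among gained regions. Distractor regions are
#' excluded from the comparison (they are planted to be filtered out).
#'
#' @param classes A \code{remodeling_table}.
#' @param truth A \code{synthetic_truth}.
#' @return List with \code{accuracy}, \code{n_matched},
#'   \code{planted_gained_ind_fraction},
#'   \code{recovered_gained_ind_fraction}, \code{confusion} (table).
#' @export
evaluate_recovery <- function(classes, truth) {
  truth <- as.data.frame(truth)
  truth <- truth[!truth$distractor, , drop = FALSE]
  key <- function(d) paste(d$chrom, d$start, d$end, sep = ":")
  cls <- as.data.frame(classes)
  idx <- match(key(cls), key(truth))
  matched <- !is.na(idx)
  planted <- truth$class[idx[matched]]
  recovered <- as.character(cls$class[matched])
  gained_planted <- grepl("^GAINED", planted)
  gained_recovered <- grepl("^GAINED", recovered)
  list(
    accuracy = mean(recovered == planted),
    n_matched = sum(matched),
    planted_gained_ind_fraction =
      mean(planted[gained_planted] == "GAINED_BRD4_INDEPENDENT"),
    recovered_gained_ind_fraction =
      if (any(gained_recovered))
        mean(recovered[gained_recovered] == "GAINED_BRD4_INDEPENDENT")
      else NA_real_,
    confusion = table(planted = planted, recovered = recovered)
  )
}
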