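#' Pipeline configuration with study defaults
#'
#' Assembles and validates the parameters of the full analysis chain. Every
#' stage parameter defaults to the study's stated value where one exists:
#' rhythm period window 12-24 h, fuzzy c-means c = 12 and m = 1.25, DEG
#' thresholds FDR < 0.01 with ratio > 2 / < 0.5, 3 kb upstream windows with
#' 300 bp histogram bins, and photoperiod ZT0-ZT12. Synthetic-study
#' defaults plant the observed class proportions (0.645/0.259/0.096) and
#' per-class E-box densities (2.54/1.77/0.57 per gene), an LD feeding
#' acrophase of ZT18, a defecation acrophase of ZT9, and free-running
#' periods of 25 h (locomotion) and 23 h (feeding).
#'
#' @param ... overrides of the defaults listed below.
#' @return validated config list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # inputs (NULL = simulate)
    expression_tsv = NULL, genome_fasta = NULL, annotation_gff = NULL,
    # synthetic expression
    n_genes = 300, timepoints = seq(0, 69, by = 3),
    class_fractions = c(DAY = 0.645, NIGHT = 0.259, ARRHYTHMIC = 0.096),
    amplitude_range = c(0.4, 0.9), noise_sd = 0.1, acrophase_grid = 3,
    # rhythm test
    period_window = c(12, 24), q_threshold = 0.05,
    # clustering
    c = 12, m = 1.25, fcm_tol = 1e-6, fcm_max_iter = 1000,
    # DEG filter
    fdr_cut = 0.01, ratio_up = 2, ratio_down = 0.5,
    # promoters / E-boxes
    upstream = 3000, bin_width = 300, n_perm = 999, mask_background = TRUE,
    class_ebox_means = list(
      DAY = c(canonical = 1.27, noncanonical = 1.27),
      NIGHT = c(canonical = 0.885, noncanonical = 0.885),
      ARRHYTHMIC = c(canonical = 0.285, noncanonical = 0.285)),
    # behavior
    photoperiod = c(0, 12), feeding_acrophase = 18, defecation_acrophase = 9,
    tau_locomotion = 25, tau_feeding = 23, behavior_days = 3,
    behavior_noise_sd = 1, behavior_groups = 9, period_search = c(20, 28),
    # master seed
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  .assert(length(unknown) == 0,
          paste("unknown config fields:", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  .assert(cfg$c >= 2, "cluster count c must be >= 2")
  .assert(cfg$m > 1, "fuzzifier m must be > 1")
  .assert(cfg$upstream >= 6, "upstream length must be >= 6")
  .assert(cfg$fdr_cut > 0 && cfg$fdr_cut < 1, "fdr_cut must be in (0,1)")
  .assert(abs(sum(cfg$class_fractions) - 1) < 1e-8,
          "class_fractions must sum to 1")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis chain
#'
#' Executes the stages in dependency order: expression (simulated or read
#' from TSV), rhythm detection, soft clustering, phase classification,
#' promoter E-box analysis (promoters simulated or extracted from
#' user-supplied FASTA + GFF3), behavioral analysis, and the report. Every
#' output file is written under \code{out_dir} and listed in a manifest
#' with parameters, seed and content hashes; a run log records stage
#' timings and record counts. Per-stage seeds derive from the master seed
#' via \code{\link{stage_seed}}.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory (created if missing).
#' @return the report list, invisibly (see \code{\link{write_report}});
#'   attribute \code{"files"} holds the manifest paths.
#' @export
run_pipeline <- function(config, out_dir = tempfile("circadetox_run_")) {
  .assert(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) cat(sprintf(paste0("[%s] ", fmt, "\n"),
                                         format(Sys.time(), "%H:%M:%S"), ...),
                                 file = log_path, append = TRUE)
  files <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files <<- c(files, path)
    path
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    logf("stage %-10s done in %.2f s", name, proc.time()[["elapsed"]] - t0)
    res
  }

  # --- expression -----------------------------------------------------------
  truth <- NULL
  expr <- stage("expression", {
    if (!is.null(config$expression_tsv)) {
      read_expression_tsv(config$expression_tsv)
    } else {
      sim <- simulate_expression(config$n_genes, config$timepoints,
                                 config$class_fractions,
                                 config$amplitude_range,
                                 noise_sd = config$noise_sd,
                                 acrophase_grid = config$acrophase_grid,
                                 seed = stage_seed(config$seed, "expression"))
      truth <- sim$truth  # evaluated in this function's frame (lazy promise)
      emit("truth.tsv", function(p) write.table(sim$truth, p, sep = "\t",
                                                quote = FALSE, row.names = FALSE))
      list(matrix = sim$matrix, timepoints = sim$timepoints, condition = "LD")
    }
  })
  emit("expression.tsv", function(p) write_expression_tsv(expr$matrix, p))
  logf("expression: %d genes x %d timepoints", nrow(expr$matrix),
       ncol(expr$matrix))

  # --- rhythm ---------------------------------------------------------------
  calls <- stage("rhythm", {
    refs <- reference_waveforms(expr$timepoints, config$period_window)
    rhythm_test(expr$matrix, refs, q_threshold = config$q_threshold)
  })
  emit("rhythm_calls.tsv", function(p) write.table(calls, p, sep = "\t",
                                                   quote = FALSE, row.names = FALSE))
  logf("rhythm: %d/%d genes rhythmic at q < %g", sum(calls$rhythmic),
       nrow(calls), config$q_threshold)

  # --- clustering -----------------------------------------------------------
  clust <- stage("cluster", {
    std <- standardize_profiles(expr$matrix)
    fc <- fuzzy_cmeans(std$profiles, c = config$c, m = config$m,
                       tol = config$fcm_tol, max_iter = config$fcm_max_iter,
                       seed = stage_seed(config$seed, "cluster"))
    summ <- cluster_phase_summary(fc, std$profiles, expr$timepoints)
    list(std = std, fit = fc, summary = summ)
  })
  emit("memberships.tsv", function(p) write.table(
    data.frame(gene_id = rownames(clust$fit$memberships),
               clust$fit$memberships), p, sep = "\t", quote = FALSE,
    row.names = FALSE))
  emit("centers.tsv", function(p) write.table(clust$fit$centers, p, sep = "\t",
                                              quote = FALSE))
  emit("cluster_summary.tsv", function(p) write.table(clust$summary, p,
                                                      sep = "\t", quote = FALSE,
                                                      row.names = FALSE))
  logf("cluster: c = %d, %d iterations", config$c, clust$fit$iterations)

  # --- phase classes --------------------------------------------------------
  labels <- stage("classify", {
    bins <- vapply(seq_len(nrow(expr$matrix)), function(g)
      assign_peak_bin(expr$matrix[g, ], expr$timepoints)$peak_bin %||% NA_character_,
      character(1))
    classify_phase(calls, config$photoperiod, peak_bins = bins)
  })
  dist <- phase_distribution(labels)
  emit("labels.tsv", function(p) write.table(labels, p, sep = "\t",
                                             quote = FALSE, row.names = FALSE))
  emit("distribution.json", function(p) jsonlite::write_json(
    dist, p, auto_unbox = TRUE, digits = NA))
  logf("classify: %s", paste(names(dist$class_fractions),
                             round(dist$class_fractions, 3),
                             sep = "=", collapse = " "))

  # --- promoter E-boxes -----------------------------------------------------
  ebox <- stage("ebox", {
    if (!is.null(config$genome_fasta)) {
      .assert(!is.null(config$annotation_gff),
              "genome_fasta requires annotation_gff")
      promoters <- extract_promoters(config$genome_fasta,
                                     config$annotation_gff, config$upstream)
      planted <- NULL; truth_ebox <- NULL
    } else {
      .assert(!is.null(truth), "simulated promoters need simulated truth")
      psim <- simulate_promoters(truth, config$upstream,
                                 config$class_ebox_means,
                                 mask_background = config$mask_background,
                                 seed = stage_seed(config$seed, "promoters"))
      write_promoter_files(psim, file.path(out_dir, "genome.fa"),
                           file.path(out_dir, "genes.gff3"))
      files <- c(files, file.path(out_dir, c("genome.fa", "genes.gff3")))
      promoters <- extract_promoters(psim$genome, psim$annotation,
                                     config$upstream)
      planted <- psim$planted; truth_ebox <- psim$truth_ebox
    }
    hits <- scan_eboxes(promoters)
    use <- labels[labels$gene_id %in% promoters$gene_id, , drop = FALSE]
    dens <- ebox_density_by_class(hits, use)
    hist <- positional_histogram(hits, config$bin_width, config$upstream)
    counts <- table(factor(hits$gene_id, levels = use$gene_id))
    enr <- permutation_enrichment(setNames(as.numeric(counts), names(counts)),
                                  use, n_perm = config$n_perm,
                                  seed = stage_seed(config$seed, "permutation"))
    list(promoters = promoters, hits = hits, densities = dens, hist = hist,
         enrichment = enr, planted = planted, truth_ebox = truth_ebox)
  })
  if (!is.null(ebox$truth_ebox)) {
    emit("truth_ebox.tsv", function(p) write.table(ebox$truth_ebox, p,
                                                   sep = "\t", quote = FALSE,
                                                   row.names = FALSE))
    emit("planted_ebox.tsv", function(p) write.table(ebox$planted, p,
                                                     sep = "\t", quote = FALSE,
                                                     row.names = FALSE))
  }
  emit("ebox_hits.tsv", function(p) {
    h <- ebox$hits
    pr <- ebox$promoters[match(h$gene_id, ebox$promoters$gene_id), ]
    # BED-like: 0-based half-open promoter-window coordinates
    write.table(data.frame(contig = pr$contig, start = h$start - 1L,
                           end = h$start + 5L, gene_id = h$gene_id,
                           motif = h$motif, category = h$category,
                           distance_bp = h$distance_bp), p, sep = "\t",
                quote = FALSE, row.names = FALSE)
  })
  emit("ebox_densities.tsv", function(p) write.table(ebox$densities, p,
                                                     sep = "\t", quote = FALSE,
                                                     row.names = FALSE))
  emit("ebox_histogram.tsv", function(p) write.table(ebox$hist$bins, p,
                                                     sep = "\t", quote = FALSE,
                                                     row.names = FALSE))
  emit("ebox_enrichment.tsv", function(p) write.table(ebox$enrichment, p,
                                                      sep = "\t", quote = FALSE,
                                                      row.names = FALSE))
  logf("ebox: %d hits over %d promoters", nrow(ebox$hits),
       nrow(ebox$promoters))

  # --- behavior -------------------------------------------------------------
  behav <- stage("behavior", {
    bseed <- stage_seed(config$seed, "behavior")
    feeding <- simulate_behavior(config$behavior_days, "LD",
                                 config$feeding_acrophase,
                                 n_groups = config$behavior_groups,
                                 noise_sd = config$behavior_noise_sd,
                                 seed = bseed)
    defecation <- simulate_behavior(config$behavior_days, "LD",
                                    config$defecation_acrophase,
                                    n_groups = config$behavior_groups,
                                    noise_sd = config$behavior_noise_sd,
                                    seed = bseed + 1L)
    dd_loc <- simulate_behavior(config$behavior_days, "DD",
                                config$feeding_acrophase,
                                period_hours = config$tau_locomotion,
                                n_groups = config$behavior_groups,
                                noise_sd = config$behavior_noise_sd,
                                seed = bseed + 2L)
    dd_feed <- simulate_behavior(config$behavior_days, "DD",
                                 config$feeding_acrophase,
                                 period_hours = config$tau_feeding,
                                 n_groups = config$behavior_groups,
                                 noise_sd = config$behavior_noise_sd,
                                 seed = bseed + 3L)
    list(feeding = rhythm_summary(feeding),
         defecation = rhythm_summary(defecation),
         tau_locomotion = estimate_period(dd_loc, config$period_search),
         tau_feeding = estimate_period(dd_feed, config$period_search),
         series = list(feeding = feeding, defecation = defecation,
                       dd_locomotion = dd_loc, dd_feeding = dd_feed))
  })
  for (nm in names(behav$series)) {
    local({
      n <- nm
      emit(paste0("behavior_", n, ".tsv"), function(p) write.table(
        behav$series[[n]], p, sep = "\t", quote = FALSE, row.names = FALSE))
    })
  }
  logf("behavior: feeding acrophase ZT%g, tau(DD locomotion) %.2f h",
       behav$feeding$acrophase_zt, behav$tau_locomotion$tau_hours)

  # --- report ---------------------------------------------------------------
  report <- write_report(
    list(calls = calls, distribution = dist, densities = ebox$densities,
         hist = ebox$hist, enrichment = ebox$enrichment, behavior = behav,
         truth = truth, truth_ebox = ebox$truth_ebox),
    out_dir)
  files <- c(files, attr(report, "files"))

  manifest <- list(
    created = format(Sys.time()),
    seed = config$seed,
    parameters = unclass(config)[setdiff(names(config),
                                         c("expression_tsv", "genome_fasta",
                                           "annotation_gff"))],
    inputs = Filter(Negate(is.null),
                    config[c("expression_tsv", "genome_fasta", "annotation_gff")]),
    outputs = lapply(setNames(nm = basename(files)), function(f)
      list(md5 = unname(tools::md5sum(file.path(out_dir, f)))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(report, "files") <- c(files, file.path(out_dir, "manifest.json"))
  attr(report, "out_dir") <- out_dir
  invisible(report)
}

#' Write the pipeline report
#'
#' Collects the headline quantities of the completed stages — rhythmic
#' fraction, phase-class fractions, per-class E-box densities, positional
#' mass in the 300-1800 bp window, behavioral acrophases and the
#' free-running period estimates — into machine-readable JSON and a short
#' human-readable summary. Numbers are taken from the stage outputs
#' directly; nothing is recomputed.
#'
#' @param stages list with calls, distribution, densities, hist, enrichment,
#'   behavior (and optionally truth / truth_ebox from simulation).
#' @param out_dir directory for \code{report.json} / \code{report.txt}.
#' @return the report list, invisibly; attribute \code{"files"} names the
#'   two files written.
#' @export
write_report <- function(stages, out_dir) {
  dens <- stages$densities
  dn <- function(cl, col) {
    v <- dens[dens$phase_class == cl, col]
    if (length(v)) v else NA_real_
  }
  report <- list(
    n_genes = nrow(stages$calls),
    rhythmic_fraction = mean(stages$calls$rhythmic),
    class_fractions = as.list(stages$distribution$class_fractions),
    ebox_density_per_gene = list(DAY = dn("DAY", "total"),
                                 NIGHT = dn("NIGHT", "total"),
                                 ARRHYTHMIC = dn("ARRHYTHMIC", "total")),
    positional_mass_300_1800 = stages$hist$mass_fraction_focus,
    enrichment_p = setNames(as.list(stages$enrichment$p_value),
                            stages$enrichment$comparison),
    behavior = list(
      feeding_acrophase_zt = stages$behavior$feeding$acrophase_zt,
      feeding_trough_zt = stages$behavior$feeding$trough_zt,
      defecation_acrophase_zt = stages$behavior$defecation$acrophase_zt,
      tau_locomotion_hours = stages$behavior$tau_locomotion$tau_hours,
      tau_locomotion_class = stages$behavior$tau_locomotion$classification,
      tau_feeding_hours = stages$behavior$tau_feeding$tau_hours,
      tau_feeding_class = stages$behavior$tau_feeding$classification))
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  txt_path <- file.path(out_dir, "report.txt")
  txt <- c(
    sprintf("genes analysed:            %d", report$n_genes),
    sprintf("rhythmic fraction:         %.3f", report$rhythmic_fraction),
    sprintf("class fractions:           DAY %.3f / NIGHT %.3f / ARRHYTHMIC %.3f",
            report$class_fractions$DAY, report$class_fractions$NIGHT,
            report$class_fractions$ARRHYTHMIC),
    sprintf("E-box per gene:            DAY %.2f / NIGHT %.2f / ARRHYTHMIC %.2f",
            report$ebox_density_per_gene$DAY,
            report$ebox_density_per_gene$NIGHT,
            report$ebox_density_per_gene$ARRHYTHMIC),
    sprintf("E-box mass in 300-1800 bp: %.3f", report$positional_mass_300_1800),
    sprintf("feeding acrophase/trough:  ZT%g / ZT%g",
            report$behavior$feeding_acrophase_zt,
            report$behavior$feeding_trough_zt),
    sprintf("defecation acrophase:      ZT%g",
            report$behavior$defecation_acrophase_zt),
    sprintf("tau locomotion (DD):       %.2f h (%s)",
            report$behavior$tau_locomotion_hours,
            report$behavior$tau_locomotion_class),
    sprintf("tau feeding (DD):          %.2f h (%s)",
            report$behavior$tau_feeding_hours,
            report$behavior$tau_feeding_class))
  writeLines(txt, txt_path)
  attr(report, "files") <- c(json_path, txt_path)
  invisible(report)
}
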