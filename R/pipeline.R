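# YAML-configured orchestration. Stages communicate through files on disk
# (each independently resumable); every output directory gets a JSON
# metadata sidecar with the parameters, seed, and input checksums.

pipeline_defaults <- function() {
  list(
    stages = NULL, seed = 1L, out_dir = NULL, log_level = "info",
    simulate = list(
      screen = list(), genome = list(),
      traces = list(n_traces = 8, fs = 240, duration = 10,
                    true_frequency = 8, amplitude = 3, noise_sd = 1,
                    drift_slope = 0)
    ),
    screen = list(
      matrix_dir = NULL, annotation = NULL, network = NULL,
      basal_label = "basal", term = "GO:0043565", top_k = 100, cap = 250,
      min_confidence = 0, pseudocount = 0.01, n_perm = 1000,
      alternative = "two.sided", aggregation = "mean"
    ),
    chip = list(
      peaks = NULL, gtf = NULL, fasta = NULL, motif = NULL,
      motif_consensus = NULL, p_threshold = 1e-4,
      window_upstream = -20000, window_downstream = 500,
      profile_window = 20000, profile_bin = 500, smooth_bins = 5,
      promoter_upstream = 2000, promoter_downstream = 500,
      coverage_control = NULL, coverage_treated = NULL
    ),
    cbf = list(traces_dir = NULL, fs = NULL, band = c(2, 40))
  )
}

merge_block <- function(defaults, given, block) {
  if (is.null(given)) return(defaults)
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf("unknown key(s) in '%s': %s", block,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  defaults[names(given)] <- given
  defaults
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes an equivalent list), fills documented
#' defaults, rejects unknown keys, and range-checks every parameter with the
#' offending field named in the error.
#'
#' @param cfg path to a YAML file or a named list.
#' @return a validated `run_config` list with defaults filled.
#' @export
validate_config <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  def <- pipeline_defaults()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown) > 0) {
    stop(sprintf("unknown top-level key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  stages <- cfg$stages
  valid_stages <- c("simulate", "screen", "chip", "cbf")
  if (is.null(stages) || length(stages) == 0) {
    stop("'stages' must select at least one of simulate, screen, chip, cbf",
         call. = FALSE)
  }
  if (!all(stages %in% valid_stages)) {
    stop(sprintf("unknown stage(s): %s",
                 paste(setdiff(stages, valid_stages), collapse = ", ")),
         call. = FALSE)
  }
  out <- def
  out$stages <- valid_stages[valid_stages %in% stages]
  out$seed <- check_count(if (is.null(cfg$seed)) def$seed else cfg$seed,
                          "seed", min = 0)
  if (is.null(cfg$out_dir)) stop("'out_dir' is required", call. = FALSE)
  out$out_dir <- check_string(cfg$out_dir, "out_dir")
  out$log_level <- check_string(
    if (is.null(cfg$log_level)) def$log_level else cfg$log_level, "log_level")

  sim <- merge_block(def$simulate, cfg$simulate, "simulate")
  sim$traces <- merge_block(def$simulate$traces, cfg$simulate$traces,
                            "simulate.traces")
  out$simulate <- sim

  scr <- merge_block(def$screen, cfg$screen, "screen")
  scr$top_k <- check_count(scr$top_k, "top_k")
  scr$cap <- check_count(scr$cap, "cap")
  scr$min_confidence <- check_number(scr$min_confidence, "min_confidence", 0, 1)
  scr$pseudocount <- check_number(scr$pseudocount, "pseudocount", 1e-12, Inf)
  scr$n_perm <- check_count(scr$n_perm, "n_perm")
  if (!scr$alternative %in% c("two.sided", "greater", "less")) {
    stop("'alternative' must be two.sided, greater or less", call. = FALSE)
  }
  if (!scr$aggregation %in% c("mean", "sum")) {
    stop("'aggregation' must be mean or sum", call. = FALSE)
  }
  out$screen <- scr

  chp <- merge_block(def$chip, cfg$chip, "chip")
  chp$p_threshold <- check_number(chp$p_threshold, "p_threshold", 1e-300, 1)
  chp$window_upstream <- check_number(chp$window_upstream, "window_upstream",
                                      -Inf, 0)
  chp$window_downstream <- check_number(chp$window_downstream,
                                        "window_downstream", 0, Inf)
  chp$profile_window <- check_count(chp$profile_window, "profile_window")
  chp$profile_bin <- check_count(chp$profile_bin, "profile_bin")
  chp$smooth_bins <- check_count(chp$smooth_bins, "smooth_bins")
  out$chip <- chp

  cb <- merge_block(def$cbf, cfg$cbf, "cbf")
  if (length(cb$band) != 2 || cb$band[1] <= 0 || cb$band[1] >= cb$band[2]) {
    stop("'band' must be c(low, high) with 0 < low < high", call. = FALSE)
  }
  out$cbf <- cb

  # explicit input paths must exist now; simulate-stage wiring is deferred
  for (p in c(scr$matrix_dir, scr$annotation, scr$network, chp$peaks, chp$gtf,
              chp$fasta, chp$motif, chp$coverage_control, chp$coverage_treated,
              cb$traces_dir)) {
    if (!is.null(p) && !file.exists(p)) {
      stop(sprintf("input path does not exist: %s", p), call. = FALSE)
    }
  }
  structure(out, class = "run_config")
}

checksums <- function(paths) {
  paths <- paths[!vapply(paths, is.null, TRUE)]
  paths <- unlist(paths)
  if (length(paths) == 0) return(list())
  paths <- paths[file.exists(paths) & !dir.exists(paths)]
  if (length(paths) == 0) return(list())
  sums <- tools::md5sum(paths)
  as.list(sums)
}

stage_meta <- function(dir, params, seed, inputs = list()) {
  write_json_file(
    list(parameters = params, seed = seed, inputs = checksums(inputs),
         package_version = as.character(utils::packageVersion("airscreen"))),
    file.path(dir, "metadata.json")
  )
}

#' Run the pipeline
#'
#' Executes the selected stages in canonical order (simulate, screen, chip,
#' cbf). Each stage reads and writes the documented file formats under
#' `out_dir/<stage>/`; when the simulate stage runs first, later stages are
#' wired to its outputs automatically unless explicit paths are configured.
#' A stage failure stops the run with the stage name attached, leaving prior
#' outputs intact.
#'
#' @param cfg a validated [validate_config()] result (a path or list is
#'   validated first).
#' @return an object of class `run_report`: per-stage status, parameter echo,
#'   and headline outputs (top TFs, candidate-gene count, CBF summary). Also
#'   written as `out_dir/report.json`.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(stages = list(), seed = cfg$seed, out_dir = cfg$out_dir)
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }

  if ("simulate" %in% cfg$stages) {
    report$stages$simulate <- run_stage("simulate", function() {
      dir <- file.path(cfg$out_dir, "simulate")
      scfg <- do.call(screen_sim_config,
                      c(cfg$simulate$screen, list(seed = cfg$seed)))
      sim <- simulate_screen_inputs(scfg)
      write_screen_inputs(sim, dir)
      gcfg <- do.call(genome_sim_config,
                      c(cfg$simulate$genome, list(seed = derive_seed(cfg$seed, 1))))
      gsim <- simulate_genome_inputs(gcfg)
      write_genome_inputs(gsim, dir)
      tr <- cfg$simulate$traces
      n_traces <- check_count(tr$n_traces, "n_traces")
      tr$n_traces <- NULL
      trace_dir <- file.path(dir, "traces")
      dir.create(trace_dir, showWarnings = FALSE)
      for (i in seq_len(n_traces)) {
        tcfg <- do.call(trace_sim_config,
                        c(tr, list(bead_id = sprintf("bead%02d", i),
                                   seed = derive_seed(cfg$seed, 100 + i))))
        write_trace(simulate_trace(tcfg),
                    file.path(trace_dir, sprintf("bead%02d.csv", i)))
      }
      stage_meta(dir, cfg$simulate, cfg$seed)
      list(status = "ok", dir = dir,
           planted_tf = sim$ground_truth$planted_tf, n_traces = n_traces)
    })
  }

  if ("screen" %in% cfg$stages) {
    report$stages$screen <- run_stage("screen", function() {
      dir <- file.path(cfg$out_dir, "screen")
      dir.create(dir, showWarnings = FALSE)
      p <- cfg$screen
      sim_dir <- file.path(cfg$out_dir, "simulate")
      matrix_dir <- if (is.null(p$matrix_dir)) sim_dir else p$matrix_dir
      annotation <- if (is.null(p$annotation)) {
        file.path(sim_dir, "annotation.tsv")
      } else p$annotation
      network <- if (is.null(p$network)) {
        file.path(sim_dir, "network.tsv")
      } else p$network
      mat <- read_expression_matrix(matrix_dir, p$basal_label)
      ann <- read_gene_annotation(annotation)
      net <- read_network(network)
      res <- suppressMessages(run_screen(
        mat, ann, net, term = p$term, k = p$top_k, cap = p$cap,
        min_confidence = p$min_confidence, pseudocount = p$pseudocount,
        n_perm = p$n_perm, seed = cfg$seed, alternative = p$alternative,
        aggregation = p$aggregation
      ))
      write_screen_result(res, file.path(dir, "screen_results.tsv"))
      stage_meta(dir, p, cfg$seed,
                 list(annotation, network,
                      file.path(matrix_dir, "matrix.mtx")))
      top <- head(as.data.frame(res)[res$n_interactors > 0, ], 5)
      list(status = "ok", dir = dir, n_tested = sum(res$n_interactors > 0),
           top_tfs = top$tf_id, top_p_combined = top$p_combined)
    })
  }

  if ("chip" %in% cfg$stages) {
    report$stages$chip <- run_stage("chip", function() {
      dir <- file.path(cfg$out_dir, "chip")
      dir.create(dir, showWarnings = FALSE)
      p <- cfg$chip
      sim_dir <- file.path(cfg$out_dir, "simulate")
      peaks_path <- if (is.null(p$peaks)) {
        file.path(sim_dir, "peaks.narrowPeak")
      } else p$peaks
      gtf_path <- if (is.null(p$gtf)) file.path(sim_dir, "transcripts.gtf") else p$gtf
      fasta_path <- if (is.null(p$fasta)) file.path(sim_dir, "genome.fa") else p$fasta
      peaks <- read_peaks(peaks_path)
      tx <- read_transcripts(gtf_path)
      m <- if (!is.null(p$motif)) {
        read_jaspar_motif(p$motif, p_threshold = p$p_threshold)
      } else if (!is.null(p$motif_consensus)) {
        consensus_pwm(p$motif_consensus, p_threshold = p$p_threshold)
      } else {
        stop("chip stage needs 'motif' (file) or 'motif_consensus'", call. = FALSE)
      }
      scan <- scan_peaks_for_motif(peaks, fasta_path, m)
      cand <- select_candidate_genes(
        peaks, scan, tx, window = c(p$window_upstream, p$window_downstream))
      profile <- tss_density_profile(peaks, tx, window = p$profile_window,
                                     bin = p$profile_bin,
                                     smooth_bins = p$smooth_bins)
      regions <- classify_peak_regions(
        peaks, tx, promoter_window = c(p$promoter_upstream, p$promoter_downstream))
      write_tsv_file(cand$candidates, file.path(dir, "candidate_genes.tsv"))
      write_tsv_file(cand$support, file.path(dir, "candidate_support.tsv"))
      write_tsv_file(profile, file.path(dir, "tss_profile.tsv"))
      write_tsv_file(regions$fractions, file.path(dir, "region_fractions.tsv"))
      write_tsv_file(scan$hits, file.path(dir, "motif_hits.tsv"))
      depth_summary <- NULL
      if (!is.null(p$coverage_control) && !is.null(p$coverage_treated)) {
        cmp <- compare_peak_depth(read_coverage(p$coverage_control),
                                  read_coverage(p$coverage_treated), peaks)
        write_tsv_file(cmp$depths, file.path(dir, "peak_depths.tsv"))
        depth_summary <- cmp$median_log2_ratio
      }
      stage_meta(dir, c(p, list(motif_threshold_bits = scan$threshold,
                                offset_sign_convention =
                                  "negative = upstream of TSS, strand-aware")),
                 cfg$seed, list(peaks_path, gtf_path, fasta_path, p$motif))
      list(status = "ok", dir = dir,
           n_candidate_genes = nrow(cand$candidates),
           motif_peak_fraction = scan$fraction,
           median_depth_log2_ratio = depth_summary)
    })
  }

  if ("cbf" %in% cfg$stages) {
    report$stages$cbf <- run_stage("cbf", function() {
      dir <- file.path(cfg$out_dir, "cbf")
      dir.create(dir, showWarnings = FALSE)
      p <- cfg$cbf
      traces_dir <- if (is.null(p$traces_dir)) {
        file.path(cfg$out_dir, "simulate", "traces")
      } else p$traces_dir
      files <- sort(list.files(traces_dir, pattern = "\\.csv$",
                               full.names = TRUE))
      if (length(files) == 0) stop("no trace CSVs found", call. = FALSE)
      traces <- lapply(files, read_trace, fs = p$fs)
      batch <- batch_cbf(traces, band = p$band)
      write_tsv_file(batch$estimates, file.path(dir, "cbf_estimates.tsv"))
      write_json_file(batch$summary, file.path(dir, "cbf_summary.json"))
      stage_meta(dir, p, cfg$seed, as.list(files))
      list(status = "ok", dir = dir, n = batch$summary$n,
           mean_hz = batch$summary$mean_hz, sd_hz = batch$summary$sd_hz)
    })
  }

  report$parameters <- cfg[c("stages", "seed", "simulate", "screen", "chip", "cbf")]
  class(report) <- "run_report"
  write_json_file(unclass(report), file.path(cfg$out_dir, "report.json"))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (seed %d) -> %s\n", x$seed, x$out_dir))
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    extra <- switch(s,
      screen = sprintf("top TF %s (p=%g)",
                       st$top_tfs[1], st$top_p_combined[1]),
      chip = sprintf("%d candidate genes, motif fraction %.3f",
                     st$n_candidate_genes, st$motif_peak_fraction),
      cbf = sprintf("n=%d, mean %.2f Hz", st$n, st$mean_hz),
      "")
    cat(sprintf("  %-9s %s  %s\n", s, st$status, extra))
  }
  invisible(x)
}
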