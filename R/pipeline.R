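## End-to-end orchestration: a validated run configuration, a file-based
## runner, and a demo mode that simulates a study and analyzes it in one
## call. All thresholds default to the values the analysis is defined with.

#' Run configuration
#'
#' Collects the input paths and every numeric threshold of the pipeline,
#' with validation. All arguments have defaults; paths may be `NULL` when
#' the corresponding stage is skipped or objects are passed directly.
#'
#' @param peaks,annotation,counts_ip,counts_input,libsizes,expression,accessibility,tf_binding
#'   Input file paths (BED / GTF or TSV / TSVs).
#' @param min_input Input-count filter threshold (default 5).
#' @param mod_threshold Modified-call threshold (default 1.5).
#' @param fc_threshold Fold-change threshold (default 1.2).
#' @param alpha Chi-square significance level (default 0.05).
#' @param m6a_group_low,m6a_group_high Thresholds of the low/medium/high m6A
#'   groups (defaults 1.5 and 4).
#' @param access_frac Extreme accessibility group fraction (default 0.1,
#'   i.e. a 10/80/10 split).
#' @param extreme_frac Correlation extreme-class fraction (default 0.05).
#' @param not_cor_band Not-correlated band half-width (default 0.1).
#' @param min_expr Low-expression filter (default 1).
#' @param k Number of k-means clusters (default 8).
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return A validated `run_config` list.
#' @export
run_config <- function(peaks = NULL, annotation = NULL, counts_ip = NULL,
                       counts_input = NULL, libsizes = NULL, expression = NULL,
                       accessibility = NULL, tf_binding = NULL,
                       min_input = 5, mod_threshold = 1.5, fc_threshold = 1.2,
                       alpha = 0.05, m6a_group_low = 1.5, m6a_group_high = 4,
                       access_frac = 0.1, extreme_frac = 0.05,
                       not_cor_band = 0.1, min_expr = 1, k = 8, seed = 1,
                       out_dir = "m6adyn_results") {
  cfg <- list(peaks = peaks, annotation = annotation, counts_ip = counts_ip,
              counts_input = counts_input, libsizes = libsizes,
              expression = expression, accessibility = accessibility,
              tf_binding = tf_binding, min_input = min_input,
              mod_threshold = mod_threshold, fc_threshold = fc_threshold,
              alpha = alpha, m6a_group_low = m6a_group_low,
              m6a_group_high = m6a_group_high, access_frac = access_frac,
              extreme_frac = extreme_frac, not_cor_band = not_cor_band,
              min_expr = min_expr, k = k, seed = seed, out_dir = out_dir)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) abort(paste0("invalid config: ", msg))
  chk(cfg$fc_threshold > 1, "fc_threshold must exceed 1")
  chk(cfg$mod_threshold > 0, "mod_threshold must be positive")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must lie in (0, 1)")
  chk(cfg$min_input >= 0, "min_input must be non-negative")
  chk(cfg$access_frac > 0 && cfg$access_frac < 0.5,
      "access_frac must lie in (0, 0.5)")
  chk(cfg$extreme_frac > 0 && cfg$extreme_frac < 0.5,
      "extreme_frac must lie in (0, 0.5)")
  chk(cfg$not_cor_band > 0, "not_cor_band must be positive")
  chk(cfg$m6a_group_low > 0 && cfg$m6a_group_high > cfg$m6a_group_low,
      "m6A group thresholds must satisfy 0 < low < high")
  chk(cfg$k >= 1, "k must be at least 1")
  cfg
}

#' Read and validate a YAML run configuration
#'
#' Unknown fields are rejected with their names; missing fields take the
#' [run_config()] defaults. An empty file yields the all-defaults
#' configuration.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @export
validate_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' Run the full analysis
#'
#' Executes quantification, dynamics, target discovery and (when
#' accessibility is available) chromatin integration on in-memory inputs,
#' writes all result tables plus a machine-readable JSON manifest into
#' `config$out_dir`, and returns the result bundle. On failure, partial
#' outputs are removed.
#'
#' @param config A [run_config()].
#' @param inputs Optional named list of in-memory inputs (`peaks`,
#'   `counts` as [stage_counts()], `expression`, `accessibility`,
#'   `tf_binding`, `regulators`, `annotation`); anything missing is read
#'   from the paths in `config`.
#' @return Invisibly, a list with `profile`, `dynamics`, `clusters`,
#'   `dispersion`, `targets`, `chromatin`, `manifest`.
#' @export
run_m6a_pipeline <- function(config, inputs = list()) {
  out_dir <- config$out_dir
  fresh <- !dir.exists(out_dir)
  res <- tryCatch(
    run_pipeline_impl(config, inputs),
    error = function(e) {
      if (fresh && dir.exists(out_dir)) unlink(out_dir, recursive = TRUE)
      abort(paste0("pipeline failed (partial outputs removed): ",
                   conditionMessage(e)))
    })
  invisible(res)
}

run_pipeline_impl <- function(config, inputs) {
  annotation <- inputs$annotation %||% {
    if (is.null(config$annotation)) abort("no annotation supplied")
    if (grepl("\\.gtf$", config$annotation)) {
      read_gene_annotation(config$annotation)
    } else {
      read_annotation_table(config$annotation)
    }
  }
  peaks <- inputs$peaks %||% read_peak_bed(config$peaks, annotation)
  counts <- inputs$counts %||% read_counts_files(config)
  expression <- inputs$expression %||%
    read_stage_matrix(config$expression, key = "gene_id")
  regulators <- inputs$regulators %||% regulator_templates()

  missing_peaks <- setdiff(counts$ip$peak_id, peaks$peak_id)
  if (length(missing_peaks) > 0) {
    abort(paste0("count matrix peaks absent from the peak catalog: ",
                 paste(head(missing_peaks, 5), collapse = ", ")))
  }

  profile <- m6a_profile(counts, peaks, min_input = config$min_input)
  dyn <- peak_dynamics(profile, fc_threshold = config$fc_threshold,
                       alpha = config$alpha,
                       mod_threshold = config$mod_threshold)
  clus <- cluster_profiles(profile$peak_level, k = config$k, seed = config$seed)
  disp <- dispersion_scores(expression)
  dyn_genes <- dynamic_genes(profile$gene_level,
                             fc_threshold = config$fc_threshold)
  counts_tbl <- count_m6a_genes(profile$gene_level, expression,
                                threshold = config$mod_threshold,
                                min_expr = config$min_expr)
  meta <- metagene_density(profile$peaks, annotation)

  present <- intersect(c("METTL14", "RBM15", "ALKBH5"), regulators$name)
  targets <- regulator_target_analysis(profile$gene_level, expression,
                                       regulators = regulators,
                                       which = present,
                                       extreme_frac = config$extreme_frac,
                                       not_cor_band = config$not_cor_band)

  accessibility <- inputs$accessibility %||% {
    if (is.null(config$accessibility) || !file.exists(config$accessibility %||% "")) {
      NULL
    } else {
      read_stage_matrix(config$accessibility, key = "gene_id")
    }
  }
  chromatin <- NULL
  if (is.null(accessibility)) {
    warn("no accessibility matrix supplied; chromatin stage skipped")
  } else {
    cod <- co_dynamics(profile$gene_level, accessibility,
                       fc_threshold = config$fc_threshold)
    all_targets <- sort(unique(unlist(lapply(targets, `[[`, "targets"))))
    chromatin <- list(
      co_dynamics = cod,
      target_access = compare_target_accessibility(accessibility, all_targets,
                                                   seed = config$seed),
      access_groups = m6a_by_accessibility_group(accessibility,
                                                 profile$gene_level,
                                                 frac = config$access_frac),
      pcc_bins = pcc_bins(profile$gene_level, accessibility),
      overlaps = category_overlap(cod$windows))
    tfb <- inputs$tf_binding %||% {
      if (is.null(config$tf_binding) || !file.exists(config$tf_binding %||% "")) {
        NULL
      } else {
        readr::read_tsv(config$tf_binding, show_col_types = FALSE, progress = FALSE)
      }
    }
    if (!is.null(tfb)) {
      chromatin$tf_binding <- tf_binding_by_m6a_group(
        tfb, profile$gene_level,
        low = config$m6a_group_low, high = config$m6a_group_high)
    }
  }

  tables <- list(
    peak_levels = profile$peak_level,
    gene_levels = profile$gene_level,
    region_levels = profile$region_level,
    sample_levels = profile$sample_level,
    metagene = meta,
    peak_dynamics = dyn$peaks,
    differential_transitions = dyn$transitions,
    change_class_summary = dyn$summary,
    origin_summary = dyn$origin_summary,
    clusters = clus$clusters,
    dispersion = disp,
    dynamic_genes = tibble(gene_id = dyn_genes),
    gene_counts = counts_tbl)
  for (reg in names(targets)) {
    tables[[paste0("targets_", reg)]] <- tibble(gene_id = targets[[reg]]$targets)
  }
  if (!is.null(chromatin)) {
    tables$co_dynamics <- chromatin$co_dynamics$genes
    tables$co_dynamics_windows <- chromatin$co_dynamics$windows
    tables$accessibility_groups <- chromatin$access_groups$medians
    tables$pcc_bins <- chromatin$pcc_bins$bins
    tables$overlaps <- chromatin$overlaps$counts
  }
  write_result_tables(tables, config$out_dir)

  manifest <- list(
    package_version = as.character(utils::packageVersion("m6adyn")),
    seed = config$seed,
    thresholds = config[c("min_input", "mod_threshold", "fc_threshold",
                          "alpha", "extreme_frac", "not_cor_band",
                          "access_frac", "k")],
    peaks_in = nrow(counts$ip),
    peaks_retained = nrow(profile$peak_level),
    peaks_removed = profile$n_removed,
    n_genes = nrow(profile$gene_level),
    n_dynamic_genes = length(dyn_genes),
    n_targets = lapply(targets, function(t) length(t$targets)),
    chromatin_ran = !is.null(chromatin))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  list(profile = profile, dynamics = dyn, clusters = clus, dispersion = disp,
       dynamic_genes = dyn_genes, gene_counts = counts_tbl, metagene = meta,
       targets = targets, chromatin = chromatin, manifest = manifest)
}

read_counts_files <- function(config) {
  for (f in c("counts_ip", "counts_input", "libsizes")) {
    if (is.null(config[[f]])) abort(paste0("no ", f, " file supplied"))
  }
  ip <- read_stage_matrix(config$counts_ip, key = "peak_id")
  input <- read_stage_matrix(config$counts_input, key = "peak_id")
  ls <- readr::read_tsv(config$libsizes, show_col_types = FALSE, progress = FALSE)
  stage_counts(ip, input,
               ip_libsize = setNames(ls$ip_libsize, ls$stage),
               input_libsize = setNames(ls$input_libsize, ls$stage))
}

#' Simulate a study and analyze it end to end
#'
#' The self-contained demo mode: generates a synthetic study under
#' `sim_config(seed = seed)` (optionally overridden), then runs the full
#' pipeline on it. No external data required.
#'
#' @param seed Integer seed for both simulation and analysis.
#' @param out_dir Output directory for the result tables and manifest.
#' @param config Optional [sim_config()] overriding the defaults.
#' @param ... Passed to [run_config()].
#' @return List with `sim` (the simulated study) and `result` (the pipeline
#'   bundle).
#' @export
demo_m6a <- function(seed = 42, out_dir = tempfile("m6adyn_demo"),
                     config = NULL, ...) {
  scfg <- config %||% sim_config(seed = seed)
  sim <- simulate_study(scfg)
  rcfg <- run_config(seed = seed, out_dir = out_dir, ...)
  res <- run_m6a_pipeline(rcfg, inputs = list(
    peaks = sim$peaks, annotation = sim$annotation, counts = sim$counts,
    expression = sim$expression, accessibility = sim$accessibility,
    tf_binding = sim$tf_binding, regulators = sim$regulators))
  list(sim = sim, result = res)
}
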