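SCHEMA_VERSION <- "sersga/1"

default_pipeline_config <- function() {
  list(
    seed = 1,
    input = NULL,  # path to a wide CSV; NULL = simulate a synthetic cohort
    synthetic = list(n_normal = 36, n_cancer = 55, grid_lo = 400, grid_hi = 1800,
                     n_points = 1270, effect_size = 0.15, peak_width = 9,
                     peak_jitter_sd = 0.08, baseline_coef_sd = 2,
                     baseline_offset_lo = 2, baseline_offset_hi = 6,
                     scale_sdlog = 0.2, noise_sd = 0.06),
    preprocess = list(poly_order = 5, max_iterations = 100, tol = 1e-6,
                      window = 5, sg_order = 3,
                      normalize_before_smoothing = FALSE),
    segments = list(seg_len = 5),
    ga = list(population_size = 20, generations = 100, crossover_prob = 0.70,
              mutation_prob = 0.05, copy_fraction = 0.25, k_segments = 6,
              n_runs = 100, ridge = 1e-8, balanced = FALSE),
    classify = list(k_bands = 6, n_components = 20, ridge = 1e-8)
  )
}

merge_config <- function(defaults, user, path = character(0)) {
  if (is.null(user)) return(defaults)
  extra <- setdiff(names(user), names(defaults))
  if (length(extra)) {
    stop(sprintf("unknown config key(s): %s",
                 paste(paste(c(path, ""), collapse = "/"), extra, sep = "",
                       collapse = ", ")), call. = FALSE)
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      merge_config(defaults[[k]], user[[k]], c(path, k))
    } else user[[k]]
  }
  defaults
}

#' Load (or complete) a pipeline configuration
#'
#' Reads a YAML config file and merges it over the package defaults; keys
#' absent from the file take their default value, unknown keys raise a
#' schema error naming their path.
#'
#' @param path Path to a YAML file, a named list of overrides, or `NULL` for
#'   pure defaults.
#' @return Full configuration list.
#' @export
pipeline_config <- function(path = NULL) {
  user <- if (is.null(path)) NULL
  else if (is.character(path)) yaml::read_yaml(path)
  else if (is.list(path)) path
  else stop("path must be a file path, a list, or NULL", call. = FALSE)
  merge_config(default_pipeline_config(), user)
}

config_to_synthetic <- function(cfg, seed) {
  s <- cfg$synthetic
  synthetic_config(n_normal = s$n_normal, n_cancer = s$n_cancer,
                   grid_lo = s$grid_lo, grid_hi = s$grid_hi, n_points = s$n_points,
                   peaks = default_peaks(effect_size = s$effect_size, width = s$peak_width),
                   peak_jitter_sd = s$peak_jitter_sd,
                   baseline_coef_sd = s$baseline_coef_sd,
                   baseline_offset_range = c(s$baseline_offset_lo, s$baseline_offset_hi),
                   scale_sdlog = s$scale_sdlog, noise_sd = s$noise_sd,
                   seed = seed)
}

config_to_preprocess <- function(cfg) {
  p <- cfg$preprocess
  preprocess_config(poly_order = p$poly_order, max_iterations = p$max_iterations,
                    tol = p$tol, window = p$window, sg_order = p$sg_order,
                    normalize_before_smoothing = p$normalize_before_smoothing)
}

config_to_ga <- function(cfg, seed) {
  g <- cfg$ga
  ga_config(population_size = g$population_size, generations = g$generations,
            crossover_prob = g$crossover_prob, mutation_prob = g$mutation_prob,
            copy_fraction = g$copy_fraction, k_segments = g$k_segments,
            n_runs = g$n_runs, ridge = g$ridge, balanced = g$balanced,
            seed = seed)
}

#' Run the full diagnostic pipeline
#'
#' Executes, in order: (1) simulate a synthetic cohort (or read `input`);
#' (2) preprocess (baseline, smoothing, area normalization); (3) GA band
#' selection with consensus counting over repeated runs; (4) LOOCV-LDA on
#' the consensus bands and the PCA-LDA comparator; (5) ROC/AUC and per-band
#' t-tests. All artifacts are written under `out_dir` as wide CSV / JSON,
#' plus a manifest recording the config, the master seed and the per-stage
#' substream seeds; re-running from the same manifest reproduces every
#' output bit-identically.
#'
#' @param config A config list or YAML path (see [pipeline_config()]).
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @param seed Master seed overriding `config$seed`.
#' @param verbose Log stage progress.
#' @return List: `raw`, `clean` (spectra sets), `counts`, `bands`,
#'   `cv_ga`, `cv_pca`, `metrics_ga`, `metrics_pca`, `roc_ga`, `roc_pca`,
#'   `ttest`, `manifest`.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, seed = NULL,
                         verbose = FALSE) {
  cfg <- pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- list(simulate = substream_seed(cfg$seed, 101),
                ga = substream_seed(cfg$seed, 202))

  if (is.null(cfg$input)) {
    say("stage simulate: %d + %d spectra", cfg$synthetic$n_normal, cfg$synthetic$n_cancer)
    raw <- simulate_dataset(config_to_synthetic(cfg, seeds$simulate))
  } else {
    say("stage read: %s", cfg$input)
    raw <- read_spectra(cfg$input)
  }
  check_two_classes(raw, min_per_class = 3)

  say("stage preprocess: %d spectra", nrow(raw$spectra))
  clean <- preprocess_set(raw, config_to_preprocess(cfg))

  idx <- build_segment_index(length(clean$grid), cfg$segments$seg_len, grid = clean$grid)
  ga <- config_to_ga(cfg, seeds$ga)
  say("stage select: %d GA runs x %d generations over %d segments",
      ga$n_runs, ga$generations, n_segments(idx))
  counts <- consensus_counts(clean, ga, idx, verbose = verbose)
  bands <- top_bands(counts, idx, k = cfg$classify$k_bands)

  say("stage classify: GA-LDA on %d band(s) + PCA-LDA(%d)",
      nrow(bands), cfg$classify$n_components)
  band_segments <- unlist(lapply(seq_len(nrow(bands)),
                                 function(i) bands$seg_lo[i]:bands$seg_hi[i]))
  vars <- expand_chromosome(band_segments, idx)
  cv_ga <- loocv(clean, variables = vars, ridge = cfg$classify$ridge)
  cv_pca <- pca_lda_loocv(clean, n_components = cfg$classify$n_components,
                          ridge = cfg$classify$ridge)

  say("stage evaluate")
  metrics_ga <- compute_metrics(cv_ga)
  metrics_pca <- compute_metrics(cv_pca)
  roc_ga <- roc_curve(cv_ga$score, cv_ga$label)
  roc_pca <- roc_curve(cv_pca$score, cv_pca$label)
  ttest <- band_ttest_table(clean, bands)

  manifest <- list(package_version = as.character(utils::packageVersion("sersga")),
                   master_seed = cfg$seed, stage_seeds = seeds, config = cfg)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    art <- function(f) file.path(out_dir, f)
    write_spectra(raw, art("spectra_raw.csv"))
    write_spectra(clean, art("spectra_clean.csv"))
    write_result_json(list(counts = counts$counts, n_runs = counts$n_runs,
                           k_segments = counts$k_segments, runs = counts$runs,
                           bands = bands),
                      art("counts.json"), schema = paste0(SCHEMA_VERSION, "/counts"))
    write_result_json(list(model = "ga_lda", cv = cv_ga,
                           metrics = unclass(metrics_ga)),
                      art("cv_ga.json"), schema = paste0(SCHEMA_VERSION, "/cv"))
    write_result_json(list(model = "pca_lda", cv = cv_pca,
                           metrics = unclass(metrics_pca)),
                      art("cv_pca.json"), schema = paste0(SCHEMA_VERSION, "/cv"))
    write_result_json(list(ga_lda = unclass(roc_ga), pca_lda = unclass(roc_pca)),
                      art("roc.json"), schema = paste0(SCHEMA_VERSION, "/roc"))
    write_result_json(list(bands = ttest), art("ttest.json"),
                      schema = paste0(SCHEMA_VERSION, "/ttest"))
    manifest$artifacts <- list(raw = "spectra_raw.csv", clean = "spectra_clean.csv",
                               counts = "counts.json", cv_ga = "cv_ga.json",
                               cv_pca = "cv_pca.json", roc = "roc.json",
                               ttest = "ttest.json")
    write_result_json(manifest, art("manifest.json"),
                      schema = paste0(SCHEMA_VERSION, "/manifest"))
  }

  list(raw = raw, clean = clean, counts = counts, bands = bands,
       cv_ga = cv_ga, cv_pca = cv_pca,
       metrics_ga = metrics_ga, metrics_pca = metrics_pca,
       roc_ga = roc_ga, roc_pca = roc_pca, ttest = ttest,
       manifest = manifest)
}
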