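#' Pipeline configuration
#'
#' @param spec a [cohort_spec()] (used unless `input` points at a stored
#'   cohort).
#' @param input optional path to a cohort (CSV directory or `.h5` file).
#' @param bands bands to analyse; bands above the data's Nyquist are
#'   skipped with a warning.
#' @param contrasts list of 2-vectors of condition labels, or the strings
#'   `"<a>-vs-<b>"`; `"fast-vs-slow"` decodes RT classes within each
#'   condition.
#' @param pth_grid proportional thresholds scanned per band/contrast.
#' @param decoding a [decoding_config()].
#' @param n_shuffles permutation shuffles per contrast (0 disables the
#'   permutation stage).
#' @param r_perm per-shuffle repeats (see [permutation_test()]).
#' @param contrast_mode `"pooled"` (one decoder across subjects) or
#'   `"within_subject"` (per-subject decoding, accuracies averaged).
#' @param out_dir output directory (`NULL`: in-memory results only).
#' @param seed master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = cohort_spec(), input = NULL,
                            bands = c("theta", "alpha", "beta"),
                            contrasts = list(c("spatial", "identity"),
                                             c("temporal", "identity"),
                                             c("spatial", "temporal")),
                            pth_grid = seq(0.06, 0.20, by = 0.01),
                            decoding = decoding_config(),
                            n_shuffles = 0L, r_perm = 10L,
                            contrast_mode = c("pooled", "within_subject"),
                            out_dir = NULL, seed = 1L) {
  contrasts <- lapply(contrasts, function(ct)
    if (is.character(ct) && length(ct) == 1L) strsplit(ct, "-vs-")[[1]] else ct)
  for (ct in contrasts)
    if (length(ct) != 2L) stop("each contrast must name two classes")
  structure(list(spec = spec, input = input, bands = bands,
                 contrasts = contrasts, pth_grid = pth_grid,
                 decoding = decoding, n_shuffles = as.integer(n_shuffles),
                 r_perm = as.integer(r_perm),
                 contrast_mode = match.arg(contrast_mode),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

load_or_generate <- function(config) {
  if (!is.null(config$input)) {
    if (dir.exists(config$input)) read_cohort_csv(config$input)
    else read_cohort_h5(config$input)
  } else generate_cohort(config$spec)
}

decode_contrast <- function(feats, labels, config, band_pths) {
  tables <- stats::setNames(lapply(band_pths, function(p)
    feats[feats$pth == p, , drop = FALSE]), as.character(band_pths))
  labs <- lapply(band_pths, function(p) labels[feats$pth == p])
  cfg <- config$decoding
  runs <- mapply(function(tab, lb) run_decoding(tab, lb, cfg),
                 tables, labs, SIMPLIFY = FALSE)
  accs <- vapply(runs, `[[`, 0, "mean_accuracy")
  best <- order(-accs, band_pths)[1]
  perm <- NULL
  if (config$n_shuffles > 0)
    perm <- permutation_test(tables[[best]], labs[[best]], cfg,
                             n_shuffles = config$n_shuffles,
                             r_perm = config$r_perm,
                             observed = runs[[best]])
  list(pth = band_pths[best], run = runs[[best]], perm = perm,
       scan = data.frame(pth = band_pths, mean_accuracy = accs))
}

#' Run the full replication pipeline
#'
#' Simulates (or loads) a cohort, filters to correct trials, computes
#' per-trial band-averaged DTF connectivity, proportionally thresholded
#' graph features, and for every band x contrast runs the Relief + SVM
#' decoder over the threshold grid, keeping the threshold with peak mean
#' accuracy; optionally a permutation null. Selection counts are flagged
#' with the binomial criterion. Idempotent given the seed.
#'
#' @param config a [pipeline_config()].
#' @return List of class `pipeline_result`: `summary` (data.frame with one
#'   row per band x contrast), `details` (per-cell runs and selection
#'   counts), `manifest` (when `out_dir` is set).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cohort <- load_or_generate(config)
  fs <- cohort$trials[[1]]$sampling_rate
  bands <- config$bands
  drop <- vapply(bands, function(b) dtf_bands[[b]][2] > fs / 2, TRUE)
  if (any(drop)) {
    warning("skipping band(s) above Nyquist for fs = ", fs, " Hz: ",
            paste(bands[drop], collapse = ", "))
    bands <- bands[!drop]
  }
  if (!length(bands)) stop("no analysable bands below Nyquist")
  feats <- cohort_features(cohort, bands = bands, pth = config$pth_grid,
                           correct_only = TRUE)
  base_rows <- feats$band == bands[1] & feats$pth == config$pth_grid[1]
  rtl <- rt_classes(feats$rt_ms[base_rows], feats$subject[base_rows],
                    feats$condition[base_rows])
  rt_by_trial <- stats::setNames(rtl, feats$trial[base_rows])
  feats$rt_class <- rt_by_trial[as.character(feats$trial)]
  summary <- NULL
  details <- list()
  for (b in bands) {
    fb <- feats[feats$band == b, , drop = FALSE]
    for (ct in config$contrasts) {
      key <- paste(b, paste(ct, collapse = "-vs-"), sep = ":")
      if (identical(sort(ct), c("fast", "slow"))) {
        sub <- fb[fb$rt_class %in% c("fast", "slow"), , drop = FALSE]
        labels <- sub$rt_class
      } else {
        sub <- fb[fb$condition %in% ct, , drop = FALSE]
        labels <- sub$condition
      }
      res <- decode_contrast(sub, labels, config, config$pth_grid)
      sig <- flag_significant_features(res$run$selection_counts,
                                       n = res$run$config$n_repeats,
                                       p = res$run$config$n_selected /
                                         length(res$run$selection_counts))
      row <- data.frame(band = b, contrast = paste(ct, collapse = "-vs-"),
                        pth = res$pth,
                        mean_accuracy = res$run$mean_accuracy,
                        p_value = if (is.null(res$perm)) NA_real_
                                  else res$perm$p_value,
                        n_significant_features = sum(sig))
      summary <- rbind(summary, row)
      details[[key]] <- c(res, list(significant = sig))
    }
  }
  result <- structure(list(summary = summary, details = details,
                           features = feats, config = config),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) result$manifest <-
      write_pipeline_outputs(result, config$out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  f <- file.path(out_dir, "summary.csv")
  utils::write.csv(result$summary, f, row.names = FALSE); paths <- c(paths, f)
  f <- file.path(out_dir, "features.csv")
  utils::write.csv(result$features, f, row.names = FALSE); paths <- c(paths, f)
  for (key in names(result$details)) {
    d <- result$details[[key]]
    safe <- gsub("[^A-Za-z0-9_.-]", "_", key)
    f <- file.path(out_dir, paste0("selection_", safe, ".csv"))
    utils::write.csv(data.frame(feature = names(d$run$selection_counts),
                                count = as.integer(d$run$selection_counts),
                                significant = as.logical(d$significant)),
                     f, row.names = FALSE)
    paths <- c(paths, f)
    f <- file.path(out_dir, paste0("accuracies_", safe, ".csv"))
    utils::write.csv(data.frame(repeat_ = seq_along(d$run$accuracies),
                                accuracy = d$run$accuracies),
                     f, row.names = FALSE)
    paths <- c(paths, f)
  }
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  jsonlite::write_json(list(seed = result$config$seed, files = manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result (", nrow(x$summary), " band x contrast cells)\n",
      sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
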