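#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are rejected so
#' typos fail loudly; the resolved configuration is written next to the
#' outputs of every run.
#'
#' @param mode "fast" (per-patient feature draws) or "image" (full phantom ->
#'   ADC fit -> segmentation -> feature extraction per patient).
#' @param n_pca,n_bph simulated class sizes.
#' @param master_seed master seed; every stage derives its own seed from it.
#' @param phantom named list of [phantom_spec()] overrides applied to both
#'   class templates (e.g. `grid_shape`, `noise_sigma`).
#' @param segmentation list: `beta`, `tol`, `source_b` (b-value of the DWI
#'   volume that guides the walker, default 1500 s/mm^2), `level`.
#' @param features list: `n_bins`, `log_base`.
#' @param stats list: `test` ("t"/"mannwhitney"), `var_equal`,
#'   `combinations` (list of character vectors).
#' @param write_images write NIfTI volumes/masks per patient (image mode).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("fast", "image"),
                            n_pca = 90, n_bph = 112,
                            master_seed = 1L,
                            phantom = list(),
                            segmentation = list(),
                            features = list(),
                            stats = list(),
                            write_images = FALSE) {
  mode <- match.arg(mode)
  seg <- utils::modifyList(list(beta = 130, tol = 1e-8, source_b = 1500,
                                level = 0.5), segmentation)
  fea <- utils::modifyList(list(n_bins = 32, log_base = "natural"), features)
  sta <- utils::modifyList(list(test = "t", var_equal = FALSE,
                                combinations = list(
                                  c("ADC_p5", "T2W_kurtosis"),
                                  c("ADC_p5", "ADC_diff_variance"))),
                           stats)
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad) > 0)
      stop("unknown ", where, " key(s): ", paste(bad, collapse = ", "))
  }
  check_keys(seg, c("beta", "tol", "source_b", "level"), "segmentation")
  check_keys(fea, c("n_bins", "log_base"), "features")
  check_keys(sta, c("test", "var_equal", "combinations"), "stats")
  check_keys(phantom, setdiff(names(formals(phantom_spec)), "class_label"),
             "phantom")
  structure(list(mode = mode, n_pca = n_pca, n_bph = n_bph,
                 master_seed = as.integer(master_seed), phantom = phantom,
                 segmentation = seg, features = fea, stats = sta,
                 write_images = isTRUE(write_images)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file whose top-level keys match the
#'   arguments of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path, simplifyVector = TRUE)
  allowed <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Read and validate a per-patient features table
#'
#' @param path CSV with a header row, one patient per row, and a `label`
#'   column restricted to "PCa"/"BPH".
#' @return data.frame.
#' @export
read_features_csv <- function(path) {
  if (!file.exists(path)) stop("features file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"label" %in% names(df)) stop("features CSV must have a 'label' column")
  bad <- setdiff(unique(df$label), c("PCa", "BPH"))
  if (length(bad) > 0)
    stop("unknown label value(s): ", paste(bad, collapse = ", "))
  df
}

# Seeds derived from a ground-truth mask, emulating manually drawn points:
# the lesion centroid and its in-mask axis neighbors as foreground, the
# eight grid corners as background.
auto_seeds <- function(mask) {
  d <- dim(mask)
  m <- as.array(mask)
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("truth mask is empty")
  ctr <- pmin(pmax(round(colMeans(idx)), 1), d)
  fg <- rbind(ctr,
              t(ctr + t(rbind(diag(3), -diag(3)))))
  ok <- fg[, 1] >= 1 & fg[, 1] <= d[1] & fg[, 2] >= 1 & fg[, 2] <= d[2] &
    fg[, 3] >= 1 & fg[, 3] <= d[3]
  fg <- fg[ok, , drop = FALSE]
  fg <- fg[m[fg], , drop = FALSE]
  if (nrow(fg) == 0L) fg <- matrix(idx[1, ], nrow = 1)
  corners <- as.matrix(expand.grid(c(1, d[1]), c(1, d[2]), c(1, d[3])))
  seed_labels(fg, corners, d)
}

#' Run the whole-lesion analysis pipeline
#'
#' Executes the full workflow: cohort simulation, then (in image mode) ADC
#' fitting, random-walker segmentation on the configured DWI b-value volume,
#' mask propagation to the ADC map and T2W image, and feature extraction for
#' both modalities; finally the cohort comparison/ROC report. Everything is
#' deterministic given the master seed. Each stage failure is re-thrown with
#' a stage tag; outputs of completed stages are retained.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed). Receives
#'   `config.json`, `features.csv`, `report_comparison.csv`,
#'   `report_roc.csv`, `pipeline.log`, and per-patient images when
#'   `write_images` is on.
#' @return invisibly, a list with `features` (data.frame), `report`
#'   (from [cohort_report()]), and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  cat(sprintf("wholelesion %s | R %s | master_seed %d\n",
              as.character(utils::packageVersion("wholelesion")),
              getRversion(), config$master_seed),
      file = log_path)
  log_line <- function(...) cat(sprintf(...), "\n", sep = "",
                                file = log_path, append = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
    log_line("stage %-10s %.2fs", name, proc.time()[["elapsed"]] - t0)
    res
  }
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)

  feats <- if (config$mode == "fast") {
    stage("simulate", {
      cs <- cohort_spec(n_pca = config$n_pca, n_bph = config$n_bph,
                        master_seed = config$master_seed)
      generate_cohort(cs, mode = "fast")
    })
  } else {
    records <- stage("simulate", {
      tpl <- lapply(c(PCa = "PCa", BPH = "BPH"), function(cl)
        do.call(phantom_spec, c(list(class_label = cl), config$phantom)))
      cs <- cohort_spec(n_pca = config$n_pca, n_bph = config$n_bph,
                        template_pca = tpl$PCa, template_bph = tpl$BPH,
                        master_seed = config$master_seed)
      generate_cohort(cs, mode = "image")
    })
    rows <- lapply(records, function(rec) {
      adc <- stage("fit-adc", fit_adc(rec$dwi))
      msk <- stage("segment", {
        bi <- which.min(abs(rec$dwi$b_values - config$segmentation$source_b))
        guide <- image_volume(rec$dwi$data[, , , bi],
                              spacing = rec$dwi$spacing, modality = "DWI")
        segment_lesion(guide, auto_seeds(rec$mask),
                       beta = config$segmentation$beta,
                       tol = config$segmentation$tol,
                       level = config$segmentation$level)
      })
      stage("extract", {
        m_adc <- propagate_mask(msk, adc)
        m_t2 <- propagate_mask(msk, rec$t2w)
        fa <- extract_features(adc, m_adc, n_bins = config$features$n_bins,
                               log_base = config$features$log_base,
                               modality = "ADC")
        ft <- extract_features(rec$t2w, m_t2,
                               n_bins = config$features$n_bins,
                               log_base = config$features$log_base,
                               modality = "T2W")
        if (config$write_images) {
          pdir <- file.path(out_dir, rec$patient_id)
          dir.create(pdir, showWarnings = FALSE)
          for (i in seq_along(rec$dwi$b_values))
            write_volume(image_volume(rec$dwi$data[, , , i],
                                      spacing = rec$dwi$spacing,
                                      modality = "DWI"),
                         file.path(pdir, sprintf("dwi_b%04d.nii.gz",
                                                 rec$dwi$b_values[i])))
          write_volume(adc, file.path(pdir, "adc.nii.gz"))
          write_volume(rec$t2w, file.path(pdir, "t2w.nii.gz"))
          write_volume(msk, file.path(pdir, "mask.nii.gz"))
        }
        wide <- function(f, tag) {
          v <- f[, setdiff(names(f), "modality"), drop = FALSE]
          names(v) <- ifelse(names(v) == "volume_ml", "volume_ml",
                             paste(tag, names(v), sep = "_"))
          v
        }
        cbind(data.frame(patient_id = rec$patient_id, label = rec$label,
                         stringsAsFactors = FALSE),
              wide(fa, "ADC"),
              wide(ft, "T2W")[, -1, drop = FALSE])  # one shared volume_ml
      })
    })
    do.call(rbind, rows)
  }
  utils::write.csv(feats, file.path(out_dir, "features.csv"),
                   row.names = FALSE)

  report <- stage("report", {
    avail <- function(cols) cols[cols %in% names(feats)]
    combos <- Filter(function(cb) all(cb %in% names(feats)),
                     config$stats$combinations)
    cohort_report(feats,
                  test = config$stats$test,
                  var_equal = config$stats$var_equal,
                  combinations = combos)
  })
  utils::write.csv(report$comparison,
                   file.path(out_dir, "report_comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(report$roc, file.path(out_dir, "report_roc.csv"),
                   row.names = FALSE)
  log_line("done: %d patients, %d features", nrow(feats),
           ncol(feats) - 2L)
  invisible(list(features = feats, report = report, out_dir = out_dir))
}
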