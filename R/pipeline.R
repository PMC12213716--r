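# Top-level pipeline: generate -> register -> downsample -> super-resolve ->
# metrics -> evaluate. All randomness flows from one global seed through
# derive_seed(), so each stage is independently reproducible, and the whole
# configuration round-trips through a YAML file.

#' Pipeline configuration
#'
#' Declarative configuration of the whole benchmark; every degradation
#' parameter is recorded so a cohort is reproducible from the config alone.
#'
#' @param subjects Named vendor counts, e.g. `c(A = 4, B = 2, C = 2)`.
#' @param size_px,n_slices Phantom geometry.
#' @param degradation Named list of [degradation_params()] scalar fields
#'   (`noise_sigma`, `blur_fwhm_px`, `bias_amplitude`, `contrast_scale`,
#'   `vendor_gain`).
#' @param scale Super-resolution factor between the low-field grid and the
#'   high-field grid (default 2).
#' @param methods Character vector of methods among
#'   `"nearest", "bicubic", "lanczos", "espcn", "srgan", "tcgan", "oracle"`.
#'   The `orig1.5_vs_3` baseline (nearest-neighbour upsampling of the
#'   registered low stack) is always computed.
#' @param metrics Metrics among `"psnr", "ssim", "perceptual", "idp"`.
#' @param psi_sweep IDP thresholds.
#' @param train List: `n_pairs` training pairs and `epochs` for the learned
#'   methods.
#' @param registration List: `tol`, `max_restarts`, `check_threshold`.
#' @param evaluation List: `alpha`, `stat_method`, `n_repeat_subjects`.
#' @param seed Global integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(subjects = c(A = 4, B = 2, C = 2),
                            size_px = 64L, n_slices = 8L,
                            degradation = list(noise_sigma = 0.03,
                                               blur_fwhm_px = 1.5,
                                               bias_amplitude = 0.1,
                                               contrast_scale = 0.85,
                                               vendor_gain = 1),
                            scale = 2L,
                            methods = c("bicubic", "lanczos"),
                            metrics = c("psnr", "ssim", "idp"),
                            psi_sweep = default_psi_sweep(),
                            train = list(n_pairs = 50L, epochs = 15L),
                            registration = list(tol = 1e-4, max_restarts = 3L,
                                                check_threshold = 0.9),
                            evaluation = list(alpha = 0.001,
                                              stat_method = "paired_t",
                                              n_repeat_subjects = 9L),
                            seed = 1L) {
  known <- c("nearest", "bicubic", "lanczos", "espcn", "srgan", "tcgan", "oracle")
  methods <- as.character(unlist(methods))
  metrics <- as.character(unlist(metrics))
  psi_sweep <- as.numeric(unlist(psi_sweep))
  subjects <- stats::setNames(as.integer(subjects), names(subjects))
  if (!all(methods %in% known))
    stopf("unknown method(s): %s", paste(setdiff(methods, known), collapse = ", "))
  structure(list(subjects = subjects, size_px = as.integer(size_px),
                 n_slices = as.integer(n_slices), degradation = degradation,
                 scale = as.integer(scale), methods = methods,
                 metrics = metrics, psi_sweep = psi_sweep, train = train,
                 registration = registration, evaluation = evaluation,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline config
#'
#' YAML round-trip: `read_config(write_config(cfg, path))` reproduces the
#' configuration exactly.
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns the
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  obj <- unclass(config)
  obj$subjects <- as.list(obj$subjects)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$subjects <- unlist(obj$subjects)
  do.call(pipeline_config, obj)
}

#' Read / write a slice stack as NIfTI or PNG
#'
#' NIfTI-1 (`.nii` / `.nii.gz`) volumes store the slice axis third with pixel
#' spacing in the header; integer data round-trips bit-exactly and float data
#' within single-precision tolerance. A directory path writes one 8-bit PNG
#' per slice (exact round-trip for quantized data).
#'
#' @param stack A `slice_stack`.
#' @param path Output `.nii`/`.nii.gz` path, or a directory for PNG slices.
#' @param field_strength,vendor Tags to apply on read (NIfTI headers do not
#'   carry them).
#' @return `write_volume` returns `path` invisibly; `read_volume` a
#'   `slice_stack`.
#' @export
write_volume <- function(stack, path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    d <- slice_dim(stack)
    arr <- array(0, c(d[1], d[2], n_slices(stack)))
    for (k in seq_len(n_slices(stack))) arr[, , k] <- stack$slices[[k]]
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(stack$pixel_spacing_mm, 1)
    RNifti::writeNifti(img, path)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (k in seq_len(n_slices(stack))) {
      png_mat <- quantize(stack$slices[[k]])
      png::writePNG(png_mat / 255, file.path(path, sprintf("slice_%03d.png", k)))
    }
  }
  invisible(path)
}

#' @rdname write_volume
#' @param subject_id Subject id to attach on read.
#' @export
read_volume <- function(path, subject_id = basename(path),
                        field_strength = "high", vendor = "A") {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!file.exists(path)) stopf("cannot read volume: %s", path)
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
    if (length(dim(arr)) != 3) stopf("ambiguous volume dimensionality in %s", path)
    pd <- RNifti::pixdim(img)[1:2]
    slices <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
  } else {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0) stopf("no PNG slices found in %s", path)
    slices <- lapply(files, function(f) {
      m <- png::readPNG(f)
      if (length(dim(m)) == 3) m <- m[, , 1]
      m
    })
    pd <- c(1, 1)
  }
  slice_stack(slices, subject_id, pd, field_strength, vendor)
}

train_method <- function(arch, config) {
  spec <- sr_model_spec(arch, scale = config$scale,
                        seed = derive_seed(config$seed, "train", arch))
  model <- build_model(spec)
  tr_seed <- derive_seed(config$seed, "trainset", arch)
  size <- config$size_px
  n_need <- config$train$n_pairs
  pairs <- list()
  sub <- 0L
  while (length(pairs) < n_need) {
    sub <- sub + 1L
    high <- make_high_field_subject(sprintf("TR%03d", sub), 4L, size, "A",
                                    seed = derive_seed(tr_seed, sub))
    p <- degradation_params(noise_sigma = config$degradation$noise_sigma,
                            blur_fwhm_px = config$degradation$blur_fwhm_px,
                            bias_amplitude = config$degradation$bias_amplitude,
                            contrast_scale = config$degradation$contrast_scale,
                            seed = derive_seed(tr_seed, "deg", sub))
    low <- degrade_to_low_field(high, p)
    for (k in seq_len(n_slices(high))) {
      if (length(pairs) >= n_need) break
      pairs[[length(pairs) + 1L]] <-
        list(low = downsample_block(low$slices[[k]], config$scale),
             high = high$slices[[k]])
    }
  }
  train_sr(model, pairs, epochs = config$train$epochs)
}

method_output <- function(method, low_ds, high, config, models) {
  switch(method,
    nearest = upsample_stack(low_ds, config$scale, "nearest"),
    bicubic = upsample_stack(low_ds, config$scale, "bicubic"),
    lanczos = upsample_stack(low_ds, config$scale, "lanczos"),
    espcn = ,
    srgan = ,
    tcgan = apply_sr(models[[method]], low_ds),
    oracle = high,
    stopf("unknown method '%s'", method))
}

slice_metric_rows <- function(config, sid, vendor, comparison, ref, cand) {
  rows <- NULL
  for (k in seq_len(n_slices(ref))) {
    pr <- quantized_pair(ref$slices[[k]], cand$slices[[k]])
    for (m in config$metrics) {
      if (m == "idp") {
        for (res in idp_sweep(pr, config$psi_sweep))
          rows <- rbind(rows, metric_records(sid, vendor, comparison, "idp",
                                             res$psi, k, res$idp))
      } else {
        v <- switch(m, psnr = psnr(pr), ssim = ssim(pr),
                    perceptual = perceptual_distance(pr))
        rows <- rbind(rows, metric_records(sid, vendor, comparison, m, NA, k, v))
      }
    }
  }
  rows
}

#' Run the full benchmark pipeline
#'
#' Generates the synthetic cohort, registers each low-field stack to its
#' high-field pair, emulates the coarser low-field acquisition matrix by
#' block-mean downsampling, applies every configured super-resolution method,
#' scores each result against the high-field reference with the configured
#' metrics, and runs the aggregation / anchor / pairwise-comparison layer.
#' Fully reproducible from the config (and its seed) alone.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: per-stage artifacts (aligned volumes,
#'   metric CSV, report JSON) are written there.
#' @return A list of class `evaluation_report`: `records` (slice-level),
#'   `aggregates` (per metric/psi), `rankings`, `pairwise`, `anchors`,
#'   `registration` (per-subject transforms), `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) stopf("config must be a pipeline_config")
  stage <- "generate"
  result <- tryCatch({
    defaults <- do.call(degradation_params, c(config$degradation,
                                              list(seed = config$seed)))
    cohort <- make_cohort(config$subjects, defaults, seed = config$seed,
                          n_slices = config$n_slices, size_px = config$size_px)

    stage <- "train"
    learned <- intersect(config$methods, c("espcn", "srgan", "tcgan"))
    models <- list()
    for (arch in learned) models[[arch]] <- train_method(arch, config)

    stage <- "register"
    reg_log <- list()
    records <- NULL
    repeat_records <- NULL
    for (i in seq_along(cohort)) {
      subj <- cohort[[i]]
      sid <- subj$high$subject_id
      stage <- paste0("register:", sid)
      reg <- register_rigid(subj$low, subj$high,
                            max_restarts = config$registration$max_restarts,
                            tol = config$registration$tol,
                            check_threshold = config$registration$check_threshold,
                            seed = derive_seed(config$seed, "reg", sid))
      reg_log[[sid]] <- reg
      stage <- paste0("superresolve:", sid)
      low_ds <- slice_stack(lapply(reg$aligned$slices, downsample_block,
                                   factor = config$scale),
                            sid, subj$low$pixel_spacing_mm * config$scale,
                            "low", subj$low$vendor)
      baseline_out <- upsample_stack(low_ds, config$scale, "nearest")
      stage <- paste0("metrics:", sid)
      records <- rbind(records,
                       slice_metric_rows(config, sid, subj$high$vendor,
                                         "orig1.5_vs_3", subj$high, baseline_out))
      for (method in setdiff(config$methods, "nearest")) {
        out <- method_output(method, low_ds, subj$high, config, models)
        records <- rbind(records,
                         slice_metric_rows(config, sid, subj$high$vendor,
                                           paste0(method, "_vs_3"),
                                           subj$high, out))
      }
      if ("nearest" %in% config$methods) {
        records <- rbind(records,
                         slice_metric_rows(config, sid, subj$high$vendor,
                                           "nearest_vs_3", subj$high, baseline_out))
      }
      if (i <= config$evaluation$n_repeat_subjects && "idp" %in% config$metrics) {
        stage <- paste0("repeat:", sid)
        r1 <- make_repeat_scan(subj$low, repeat_seed = derive_seed(config$seed, "rep1", sid))
        r2 <- make_repeat_scan(subj$low, repeat_seed = derive_seed(config$seed, "rep2", sid))
        for (k in seq_len(n_slices(r1))) {
          pr <- quantized_pair(r1$slices[[k]], r2$slices[[k]])
          res <- idp(pr, 0)
          repeat_records <- rbind(repeat_records,
                                  metric_records(sid, subj$high$vendor,
                                                 "repeat1.5_vs_repeat1.5", "idp",
                                                 0, k, res$idp))
        }
      }
    }

    stage <- "evaluate"
    keys <- unique(records[, c("metric", "psi")])
    aggregates <- list()
    rankings <- list()
    for (i in seq_len(nrow(keys))) {
      sel <- records$metric == keys$metric[i] &
        psi_key(records$psi) == psi_key(keys$psi[i])
      kn <- paste0(keys$metric[i],
                   ifelse(is.na(keys$psi[i]), "", paste0("_psi", keys$psi[i])))
      aggregates[[kn]] <- aggregate_records(records[sel, ])
      if (length(unique(records$comparison[sel])) >= 2)
        rankings[[kn]] <- rank_methods(records[sel, ], keys$metric[i], keys$psi[i])
    }
    pairwise <- list()
    comps <- setdiff(unique(records$comparison), character(0))
    for (i in seq_len(nrow(keys))) {
      sel <- records$metric == keys$metric[i] &
        psi_key(records$psi) == psi_key(keys$psi[i])
      kn <- paste0(keys$metric[i],
                   ifelse(is.na(keys$psi[i]), "", paste0("_psi", keys$psi[i])))
      pw <- list()
      cb <- utils::combn(sort(unique(records$comparison[sel])), 2, simplify = FALSE)
      for (pair_names in cb) {
        a <- records[sel & records$comparison == pair_names[1], ]
        b <- records[sel & records$comparison == pair_names[2], ]
        pw[[paste(pair_names, collapse = "|")]] <-
          compare_pairwise(a, b, method = config$evaluation$stat_method)
      }
      raw_p <- vapply(pw, function(x) x$p_value, 0)
      adj <- stats::p.adjust(raw_p, method = "holm")
      for (j in seq_along(pw)) pw[[j]]$p_holm <- adj[j]
      pairwise[[kn]] <- pw
    }
    anchors <- if (!is.null(repeat_records))
      anchor_analysis(records, repeat_records, alpha = config$evaluation$alpha)
    structure(list(records = records, repeat_records = repeat_records,
                   aggregates = aggregates, rankings = rankings,
                   pairwise = pairwise, anchors = anchors,
                   registration = reg_log, config = config),
              class = "evaluation_report")
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  if (!is.null(out_dir)) write_report(result, out_dir)
  result
}

#' Write an evaluation report to disk
#'
#' Writes the slice-level records as CSV, cohort/per-vendor summaries as CSV,
#' and a JSON report (rankings, pairwise comparisons, anchor verdicts).
#'
#' @param report An `evaluation_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(report$records, file.path(out_dir, "metrics_slice_level.csv"),
                   row.names = FALSE)
  coh <- do.call(rbind, lapply(report$aggregates, function(a) a$cohort))
  byv <- do.call(rbind, lapply(report$aggregates, function(a) a$by_vendor))
  utils::write.csv(coh, file.path(out_dir, "cohort_means.csv"), row.names = FALSE)
  utils::write.csv(byv, file.path(out_dir, "vendor_means.csv"), row.names = FALSE)
  js <- list(
    config = unclass(report$config),
    rankings = lapply(report$rankings, function(r) as.list(r)),
    pairwise = lapply(report$pairwise, function(pws)
      lapply(pws, function(p) p[c("metric", "psi", "method_a", "method_b",
                                  "mean_difference", "ci95", "p_value",
                                  "p_holm", "n_subjects")])),
    anchors = if (!is.null(report$anchors))
      list(repeat_scan_idp = report$anchors$repeat_scan_idp,
           verdicts = report$anchors$verdicts))
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(out_dir)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: %d subjects, %d slice records, methods: %s\n",
              length(unique(x$records$subject_id)), nrow(x$records),
              paste(setdiff(unique(x$records$comparison), "orig1.5_vs_3"),
                    collapse = ", ")))
  if (!is.null(x$rankings$idp_psi0)) {
    cat("ranking by IDP(psi=0):\n")
    print(x$rankings$idp_psi0, row.names = FALSE)
  }
  invisible(x)
}
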