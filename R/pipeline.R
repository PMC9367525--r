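#' Run the batch analysis pipeline on a directory of images
#'
#' For every PNG image in `config$input_dir` (mask sidecars `*_mask.png`
#' are skipped): read image, predict a score map, binarize, quantify the
#' four morphometric readouts and write the predicted mask plus a purple
#' overlay.  Per-sample failures are recorded and the run continues;
#' the exit status is nonzero only if every sample failed.
#'
#' @param config list with fields `input_dir`, `model` (a `vascam_model`
#'   or checkpoint path), `out_dir`, and optionally `threshold`,
#'   `min_component` (default 10), `seed` (recorded in provenance),
#'   `overlay` (default TRUE).
#' @return (invisibly) list with `status` (0 ok, 1 all failed),
#'   `results` data frame and `failures` data frame.
#' @export
run_pipeline <- function(config) {
  t_start <- Sys.time()
  stopifnot(!is.null(config$input_dir), !is.null(config$model),
            !is.null(config$out_dir))
  model <- config$model
  if (is.character(model)) model <- read_model(model)
  threshold <- if (!is.null(config$threshold)) config$threshold
               else model$config$threshold
  min_component <- if (!is.null(config$min_component)) config$min_component
                   else 10
  overlay <- if (!is.null(config$overlay)) config$overlay else TRUE
  seed <- if (!is.null(config$seed)) config$seed else NA
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  files <- list.files(config$input_dir, pattern = "\\.png$",
                      full.names = TRUE)
  files <- files[!grepl("_mask\\.png$|_overlay\\.png$", files)]
  cfg_hash <- hash_obj(list(threshold = threshold,
                            min_component = min_component,
                            model_hash = model$config_hash, seed = seed))
  log_lines <- c(
    sprintf("vascam %s", as.character(utils::packageVersion("vascam"))),
    sprintf("config_hash=%s seed=%s", cfg_hash, seed),
    sprintf("model: depth=%d base=%d best_val_dice=%.4f",
            model$config$depth, model$config$base_channels,
            model$best_val_dice),
    sprintf("%d input image(s) in %s", length(files), config$input_dir))

  results <- list()
  failures <- list()
  purple <- c(0.55, 0.20, 0.60)
  for (f in files) {
    id <- sub("\\.png$", "", basename(f))
    t0 <- Sys.time()
    res <- tryCatch({
      img <- read_image(f)
      if (dim(img)[3] == 1) img <- array(rep(img, 3), c(dim(img)[1:2], 3))
      sc <- predict_scoremap(model, img)
      mask <- binarize(sc, threshold)
      m <- quantify(mask, min_component)
      write_mask(mask, file.path(config$out_dir, paste0(id, "_mask.png")))
      if (overlay) {
        ov <- img
        sel <- mask == 1
        for (ch in 1:3) {
          pl <- ov[, , ch]
          pl[sel] <- 0.5 * pl[sel] + 0.5 * purple[ch]
          ov[, , ch] <- pl
        }
        write_image(ov, file.path(config$out_dir,
                                  paste0(id, "_overlay.png")))
      }
      cbind(data.frame(sample_id = id), as.data.frame(m))
    }, error = function(e) e)
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        data.frame(sample_id = id, error = conditionMessage(res))
      log_lines <- c(log_lines,
                     sprintf("FAIL %s (%.2fs): %s", id, dt,
                             conditionMessage(res)))
    } else {
      results[[length(results) + 1]] <- res
      log_lines <- c(log_lines, sprintf("ok   %s (%.2fs)", id, dt))
    }
  }
  results <- if (length(results)) do.call(rbind, results)
             else data.frame()
  failures <- if (length(failures)) do.call(rbind, failures)
              else data.frame()
  if (nrow(results) > 0)
    write_results(results, file.path(config$out_dir, "morphometrics.csv"),
                  list(config_hash = cfg_hash, seed = seed))
  log_lines <- c(log_lines,
                 sprintf("total %.2fs",
                         as.numeric(difftime(Sys.time(), t_start,
                                             units = "secs"))))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  status <- if (length(files) > 0 && nrow(results) == 0) 1L else 0L
  invisible(list(status = status, results = results, failures = failures))
}
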