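# One-command orchestration: simulate -> extract -> screen -> rank ->
# evaluate, with every artifact (config, manifest, feature tables, ranked
# lists, sweep curves, reports, plots, JSON summary) written to an output
# directory so a run can be replayed bit-identically from its saved config.

#' Pipeline configuration
#'
#' A fully serialisable description of one end-to-end run. A run replayed
#' from its saved config and seed reproduces every output byte-for-byte.
#'
#' @param out_dir output directory for artifacts.
#' @param seed master seed; fanned out to per-stage child seeds.
#' @param n_cases,n_controls cohort sizes (defaults 64 / 46).
#' @param effect_size,effect_orientation,effect_scale class-effect parameters,
#'   see [cohort_spec()].
#' @param roi_size,bg_smoothness,speckle_grain,log_compress speckle
#'   parameters, see [speckle_params()].
#' @param alpha t-test gate level.
#' @param k_neighbors Relief-F neighbours.
#' @param top_n,k_max ranked features kept / sweep bound.
#' @param train_counts per-class training counts.
#' @param write_images write the simulated PNGs (default FALSE; the manifest
#'   records per-image seeds either way).
#' @param plots write accuracy-vs-k curves and the 2-feature scatter
#'   (default TRUE).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_cases = 64L,
                            n_controls = 46L, effect_size = 1,
                            effect_orientation = 90, effect_scale = 8,
                            roi_size = 256L, bg_smoothness = 32,
                            speckle_grain = 2, log_compress = FALSE,
                            alpha = 0.05, k_neighbors = 5L, top_n = 10L,
                            k_max = 10L,
                            train_counts = c(case = 50, control = 38),
                            write_images = FALSE, plots = TRUE) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline and write its artifacts
#'
#' Executes simulate, extract, screen, rank and evaluate, writing to
#' `config$out_dir`: `config.json`, `manifest.csv`, `features_R.csv` /
#' `features_T.csv`, `ranked_R.csv` / `ranked_T.csv` (Group/Rank/Feature/
#' Score), `sweep_R.csv` / `sweep_T.csv`, `report_R.csv` / `report_T.csv`
#' (per-classifier training-LOOCV and test metrics at the best k),
#' `summary.json` (all 4 classifiers x 2 phases x 2 stages = 16 metric rows
#' plus seeds), and PNG plots of accuracy vs k and the top-2-feature scatter.
#' A stage failure aborts with a stage-tagged message; artifacts written
#' before the failure are preserved.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) the [run_full_protocol()] result, with `summary` and
#'   `out_dir` attached.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  jsonlite::write_json(unclass(config),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  cohort <- stage("simulate", {
    spec <- cohort_spec(config$n_cases, config$n_controls,
                        config$effect_size, config$effect_orientation,
                        config$effect_scale,
                        seed = derive_seed(config$seed, 10L))
    params <- speckle_params(config$roi_size, config$bg_smoothness,
                             config$speckle_grain, config$log_compress)
    generate_cohort(spec, params,
                    dir = if (config$write_images)
                      file.path(config$out_dir, "images") else NULL)
  })
  utils::write.csv(cohort$manifest,
                   file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)

  features <- stage("extract", extract_cohort(cohort))
  tables <- list(R = features[features$phase == "R", ],
                 T = features[features$phase == "T", ])
  for (ph in c("R", "T")) {
    utils::write.csv(tables[[ph]],
                     file.path(config$out_dir,
                               sprintf("features_%s.csv", ph)),
                     row.names = FALSE)
  }

  protocol <- stage("evaluate", run_full_protocol(
    tables, train_counts = config$train_counts, alpha = config$alpha,
    k_neighbors = config$k_neighbors, top_n = config$top_n,
    k_max = config$k_max, seed = derive_seed(config$seed, 20L)))

  summary_rows <- list()
  for (ph in c("R", "T")) {
    utils::write.csv(protocol[[ph]]$ranked,
                     file.path(config$out_dir, sprintf("ranked_%s.csv", ph)),
                     row.names = FALSE)
    utils::write.csv(protocol[[ph]]$sweep,
                     file.path(config$out_dir, sprintf("sweep_%s.csv", ph)),
                     row.names = FALSE)
    utils::write.csv(protocol[[ph]]$report,
                     file.path(config$out_dir, sprintf("report_%s.csv", ph)),
                     row.names = FALSE)
    rep <- protocol[[ph]]$report
    rep$phase <- ph
    summary_rows[[ph]] <- rep
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  jsonlite::write_json(
    list(seed = config$seed,
         split = list(train = protocol$split$train,
                      test = protocol$split$test),
         metrics = summary),
    file.path(config$out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")

  if (isTRUE(config$plots)) {
    stage("plots", pipeline_plots(protocol, tables, config$out_dir))
  }
  attr(protocol, "summary") <- summary
  attr(protocol, "out_dir") <- config$out_dir
  invisible(protocol)
}

# Accuracy-vs-k curves per classifier and phase, and the scatter of the two
# top-ranked features of each phase.
pipeline_plots <- function(protocol, tables, out_dir) {
  for (ph in c("R", "T")) {
    sw <- protocol[[ph]]$sweep
    long <- rbind(
      data.frame(classifier = sw$classifier, k = sw$k,
                 accuracy = sw$test_accuracy, stage = "test"),
      if (!is.null(sw$train_accuracy))
        data.frame(classifier = sw$classifier, k = sw$k,
                   accuracy = sw$train_accuracy, stage = "training"))
    p <- ggplot2::ggplot(long, ggplot2::aes(x = k, y = accuracy,
                                            colour = stage)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
      ggplot2::facet_wrap(~classifier) +
      ggplot2::labs(x = "number of top-ranked features",
                    y = "accuracy (%)",
                    title = sprintf("%s-wave accuracy vs feature count", ph)) +
      ggplot2::theme_bw()
    ggplot2::ggsave(file.path(out_dir, sprintf("sweep_%s.png", ph)), p,
                    width = 7, height = 5, dpi = 120)

    top2 <- utils::head(protocol[[ph]]$ranked$Feature, 2)
    if (length(top2) == 2) {
      tab <- tables[[ph]]
      sc <- data.frame(x = tab[[top2[1]]], y = tab[[top2[2]]],
                       class = tab$class)
      p2 <- ggplot2::ggplot(sc, ggplot2::aes(x = x, y = y,
                                             colour = class)) +
        ggplot2::geom_point(alpha = 0.8) +
        ggplot2::labs(x = top2[1], y = top2[2],
                      title = sprintf("%s-wave: top two ranked features",
                                      ph)) +
        ggplot2::theme_bw()
      ggplot2::ggsave(file.path(out_dir, sprintf("scatter_%s.png", ph)), p2,
                      width = 5.5, height = 4.5, dpi = 120)
    }
  }
  invisible(NULL)
}
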