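#' End-to-end pipeline configuration
#'
#' Defaults follow the package's standard non-tumor setting: `subj_var =
#' 0.05`, `batch_size = 64`, `epochs = 250`; for tumor tissues `subj_var =
#' 0.1` is the recommended override. Unknown keys in `overrides` (or a YAML
#' file read through [read_pipeline_config()]) are rejected.
#'
#' @param k Number of cell types.
#' @param modality2 Non-RNA modality name.
#' @param subj_var Between-sample composition heterogeneity.
#' @param jnmf Named list of [jnmf_config()] overrides (step_size, tol,
#'   max_iter, shared_size_factors).
#' @param sim Named list of [sim_config()] overrides.
#' @param train Named list of [train_config()] overrides.
#' @param feature_selection Named list for [select_nonrna_features()]
#'   (top_n_variance, min_detect_fraction, min_mean).
#' @param seed Master seed; stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(k, modality2 = "atac", subj_var = 0.05,
                            jnmf = list(), sim = list(), train = list(),
                            feature_selection = list(), seed = 1L) {
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop(sprintf("unknown %s key(s): %s", where, paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    x
  }
  jnmf <- check_keys(jnmf, c("step_size", "tol", "max_iter", "shared_size_factors"),
                     "jnmf")
  sim <- check_keys(sim, c("N", "xi0", "knockout_rate", "shift_low",
                           "shift_high", "n_cells", "hetero_boost"), "sim")
  train <- check_keys(train, c("epochs", "batch_size", "learning_rate",
                               "adapt_steps", "adapt_lr", "celu_alpha",
                               "hidden", "dec_hidden"), "train")
  feature_selection <- check_keys(feature_selection,
                                  c("top_n_variance", "min_detect_fraction",
                                    "min_mean"), "feature_selection")
  structure(list(k = as.integer(k), modality2 = modality2, subj_var = subj_var,
                 jnmf = jnmf, sim = sim, train = train,
                 feature_selection = feature_selection, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML path.
#' @param config A `pipeline_config`.
#' @return `read_pipeline_config` returns a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- c("k", "modality2", "subj_var", "jnmf", "sim", "train",
               "feature_selection", "seed")
  bad <- setdiff(names(y), allowed)
  if (length(bad)) {
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full deconvolution pipeline
#'
#' prior -> joint factorization -> pseudo-bulk simulation -> training ->
#' per-sample adaptation (-> evaluation when truth is supplied). Writes
#' per-modality proportion TSVs, latent fractions, purified per-sample
#' profiles, metric reports and a log of the resolved configuration and
#' seeds into `out_dir`.
#'
#' @param bulk A [bulk_multiome()] target cohort (transformed scale).
#' @param sc_ref An [single_cell_reference()] subset to the RNA features of
#'   `bulk`.
#' @param config A [pipeline_config()].
#' @param cell_counts Optional multi-subject cell-count table for the
#'   Dirichlet-Multinomial prior; a flat prior is used when absent.
#' @param truth Optional list with `Theta1`, `Theta2` ground-truth
#'   proportions; enables the evaluation stage.
#' @param out_dir Output directory (`NULL` to skip writing).
#' @return A `pipeline_run`: list with `prior`, `jnmf`, `training_set` sizes,
#'   `model`, `result` (a `deconv_result`) and `metrics` (when truth given).
#' @export
run_pipeline <- function(bulk, sc_ref, config, cell_counts = NULL,
                         truth = NULL, out_dir = NULL) {
  stopifnot(inherits(bulk, "bulk_multiome"), inherits(sc_ref, "sc_reference"),
            inherits(config, "pipeline_config"))
  k <- config$k
  seed <- config$seed

  if (length(config$feature_selection)) {
    bulk <- run_stage("feature_selection", {
      keep <- do.call(select_nonrna_features,
                      c(list(Y2 = bulk$Y2), config$feature_selection))
      bulk_multiome(bulk$Y1, bulk$Y2[, keep, drop = FALSE],
                    bulk$spec1, bulk$spec2, bulk$sample_ids)
    })
  }

  prior <- run_stage("prior", {
    if (is.null(cell_counts)) uniform_prior(k)
    else estimate_dm_prior(cell_counts)
  })

  jfit <- run_stage("jnmf", {
    ct0 <- prior$cell_types %||% sort(unique(sc_ref$cell_types))
    ref_means <- vapply(ct0, function(ct) {
      transform_forward(colMeans(sc_ref$counts[sc_ref$cell_types == ct, ,
                                               drop = FALSE]), bulk$spec1)
    }, numeric(ncol(sc_ref$counts)))
    ref_means <- ref_means * mean(bulk$Y1) / mean(ref_means)
    jcfg <- do.call(jnmf_config, c(list(k = k, prior = prior,
                                        subj_var = config$subj_var,
                                        X1_init = ref_means,
                                        seed = seed),
                                   config$jnmf))
    jnmf_fit(bulk, jcfg)
  })
  sig <- run_stage("jnmf", {
    s <- extract_internal_reference(jfit, bulk$spec1, bulk$spec2)
    ct <- prior$cell_types %||% sort(unique(sc_ref$cell_types))
    align_internal_reference(s, sc_ref, ct)
  })

  tset <- run_stage("simulate", {
    scfg <- do.call(sim_config, c(list(subj_var = config$subj_var,
                                       seed = seed + 1L),
                                  config$sim))
    if (length(sig$cell_types) != k) {
      stop("cell-type labels do not match k", call. = FALSE)
    }
    generate_training_set(sc_ref, sig$X2, sig$cell_types, scfg,
                          bulk$spec1, bulk$spec2)
  })

  model <- run_stage("train", {
    tcfg <- do.call(train_config, c(list(seed = seed + 2L), config$train))
    train_deconvolver(tset, tcfg)
  })

  result <- run_stage("adapt", purify_cohort(model, bulk))

  metrics <- NULL
  if (!is.null(truth)) {
    metrics <- run_stage("evaluate", {
      list(modality1 = proportion_metrics(result$Theta1, truth$Theta1),
           modality2 = proportion_metrics(result$Theta2, truth$Theta2))
    })
  }

  run <- structure(list(prior = prior, jnmf = jfit, model = model,
                        result = result, metrics = metrics, config = config),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_pipeline_outputs(run, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  print(x$result)
  if (!is.null(x$metrics)) {
    cat("  modality 1: "); print(x$metrics$modality1)
    cat("  modality 2: "); print(x$metrics$modality2)
  }
  invisible(x)
}

write_pipeline_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- run$result
  write_bulk_matrix(res$Theta1, file.path(out_dir, "proportions_modality1.tsv"))
  write_bulk_matrix(res$Theta2, file.path(out_dir, "proportions_modality2.tsv"))
  write_bulk_matrix(res$P, file.path(out_dir, "proportions_latent.tsv"))
  for (mod in 1:2) {
    pd <- file.path(out_dir, sprintf("purified_modality%d", mod))
    dir.create(pd, showWarnings = FALSE)
    src <- if (mod == 1) res$purified1 else res$purified2
    for (j in seq_along(src)) {
      df <- data.frame(feature = rownames(src[[j]]) %||%
                         paste0("f", seq_len(nrow(src[[j]]))),
                       src[[j]], check.names = FALSE)
      utils::write.table(df, file.path(pd, paste0(res$sample_ids[j], ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(run$metrics)) {
    jsonlite::write_json(
      list(modality1 = run$metrics$modality1[c("ccc", "mae", "pearson_r")],
           modality2 = run$metrics$modality2[c("ccc", "mae", "pearson_r")]),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  }
  write_pipeline_config(run$config, file.path(out_dir, "resolved_config.yaml"))
  log <- c(sprintf("seed: %d", run$config$seed),
           sprintf("prior: pi = %s, v = %.6g",
                   paste(sprintf("%.4f", run$prior$pi), collapse = " "),
                   run$prior$v),
           sprintf("jnmf iterations: %d, final loss: %.6g",
                   length(run$jnmf$loss_trace) - 1L,
                   run$jnmf$loss_trace[length(run$jnmf$loss_trace)]),
           sprintf("training epochs: %d", nrow(run$model$history)),
           sprintf("mean reconstruction L1 before/after adaptation: %.6g / %.6g",
                   mean(res$recon_before), mean(res$recon_after)))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
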