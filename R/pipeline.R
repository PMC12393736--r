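#' Validate and normalise a pipeline run configuration
#'
#' A run configuration is a named list (typically read from YAML) with
#' sections:
#' \describe{
#'   \item{input}{`ref`, `ref_format`, `labels` (two-column CSV: cell id,
#'     cell type), `st`, `st_format`, optional `truth` (CSV proportion matrix
#'     for evaluation). Omit the whole section to run on a synthetic
#'     fixture.}
#'   \item{fixture}{Any [fixture_spec()] fields; used when `input` is absent.}
#'   \item{preprocess}{`n_top` (default 200), `target_sum` (default 1e4).}
#'   \item{pseudo}{Any [pseudo_spot_params()] fields.}
#'   \item{training}{Any [training_config()] fields.}
#'   \item{seed}{Master seed; sub-seeds for simulation, pseudo-spots and
#'     training derive from it unless given explicitly.}
#'   \item{out_dir}{Output directory.}
#' }
#' Unknown keys anywhere are rejected before any computation.
#'
#' @param config Named list.
#' @return A validated `run_config` with all defaults filled in and a
#'   `hash` field (md5 of the canonicalised configuration).
#' @export
run_config <- function(config) {
  known_top <- c("input", "fixture", "preprocess", "pseudo", "training",
                 "seed", "out_dir")
  check_keys <- function(x, known, where) {
    extra <- setdiff(names(x), known)
    if (length(extra)) {
      stop(sprintf("unknown configuration key(s) in %s: %s", where,
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
  }
  check_keys(config, known_top, "top level")
  seed <- as.integer(config$seed %||% 0)
  check_keys(config$input, c("ref", "ref_format", "labels", "st", "st_format",
                             "truth"), "input")
  check_keys(config$fixture, names(formals(fixture_spec)), "fixture")
  check_keys(config$preprocess, c("n_top", "target_sum"), "preprocess")
  check_keys(config$pseudo, names(formals(pseudo_spot_params)), "pseudo")
  check_keys(config$training, names(formals(training_config)), "training")
  fx <- config$fixture %||% list()
  if (is.null(fx$seed)) fx$seed <- seed
  ps <- config$pseudo %||% list()
  if (is.null(ps$seed)) ps$seed <- seed + 1L
  tr <- config$training %||% list()
  if (is.null(tr$seed)) tr$seed <- seed + 2L
  out <- list(
    input = config$input,
    fixture = do.call(fixture_spec, fx),
    preprocess = list(n_top = config$preprocess$n_top %||% 200,
                      target_sum = config$preprocess$target_sum %||% 1e4),
    pseudo = do.call(pseudo_spot_params, ps),
    training = do.call(training_config, tr),
    seed = seed,
    out_dir = config$out_dir %||% "spadama_run")
  # hash covers the semantic configuration, not where outputs land
  hashed <- config[setdiff(names(config), "out_dir")]
  canon <- tempfile(fileext = ".yaml")
  yaml::write_yaml(hashed[order(names(hashed))], canon)
  out$hash <- unname(tools::md5sum(canon))
  unlink(canon)
  structure(out, class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file.
#' @return A validated [run_config()].
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

#' Write a proportion matrix as CSV
#'
#' First column `spot_id`, remaining columns the cell-type names, values to 6
#' decimals. An optional configuration hash is stamped as a leading comment
#' line.
#'
#' @param Y Proportion matrix with spot rownames and type colnames.
#' @param path Output CSV.
#' @param config_hash Optional hash string.
#' @return `path`, invisibly.
#' @export
write_proportions <- function(Y, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash)) writeLines(sprintf("# config_hash=%s", config_hash), con)
  df <- data.frame(spot_id = rownames(Y) %||% paste0("spot", seq_len(nrow(Y))),
                   format(round(Y, 6), nsmall = 6, trim = TRUE),
                   check.names = FALSE)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a proportion matrix written by [write_proportions()]
#' @param path CSV file.
#' @return Numeric matrix with spot rownames and type colnames.
#' @export
read_proportions <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Run the full deconvolution pipeline
#'
#' Stages: simulate (or load) inputs, marker selection and gene-panel
#' preparation, pseudo-spot generation, training, inference, and (when ground
#' truth is available) evaluation. Artifacts written to `out_dir`:
#' `pseudo_expression.csv`, `pseudo_proportions.csv`, `model.ckpt`,
#' `trace.csv`, `proportions.csv`, `report.json` (fixture or `truth` input
#' only) and `run.log`. Every artifact carries the configuration hash.
#'
#' @param config A [run_config()] (or plain list passed through it).
#' @param quiet Suppress progress messages (default FALSE).
#' @return The output directory, invisibly; the inferred proportion matrix is
#'   attached as attribute `proportions` and the metric report (if computed)
#'   as `report`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    writeLines(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg), log_con)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      say("stage '%s' FAILED: %s", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  say("config hash %s", config$hash)

  truth <- NULL; regions <- NULL
  if (is.null(config$input)) {
    say("stage simulate: synthetic fixture (K=%d, G=%d, %d spots)",
        config$fixture$K, config$fixture$G, config$fixture$n_spots)
    fx <- stage("simulate", make_fixture(config$fixture))
    ref <- fx$ref; labels <- fx$labels; st_raw <- fx$st
    truth <- fx$truth; regions <- fx$regions
  } else {
    say("stage load: reading inputs")
    ref <- stage("load", read_expression(config$input$ref,
                                         config$input$ref_format %||% "csv",
                                         obs_kind = "cells"))
    lab_df <- stage("load", utils::read.csv(config$input$labels))
    labels <- stage("load", cell_type_labels(lab_df[[2]]))
    st_raw <- stage("load", read_expression(config$input$st,
                                            config$input$st_format %||% "csv",
                                            obs_kind = "spots"))
    if (!is.null(config$input$truth)) {
      truth <- stage("load", read_proportions(config$input$truth))
    }
  }

  say("stage prepare: marker selection (n_top=%d) and gene panel",
      config$preprocess$n_top)
  prep <- stage("prepare", {
    markers <- select_marker_genes(ref, labels, n_top = config$preprocess$n_top)
    sub <- intersect_and_subset(st_raw, ref, markers)
    list(markers = markers, st = sub$st, ref = sub$ref)
  })
  say("gene panel: %d genes", ncol(prep$st))

  say("stage pseudo: %d pseudo-spots", config$pseudo$n_spots)
  pseudo <- stage("pseudo", generate_pseudo_spots(prep$ref, labels, config$pseudo,
                                                  target_sum = config$preprocess$target_sum))
  write_expression(pseudo$X_S, file.path(config$out_dir, "pseudo_expression.csv"))
  write_proportions(pseudo$Y_r, file.path(config$out_dir, "pseudo_proportions.csv"),
                    config$hash)

  say("stage train: %d epochs, batch %d", config$training$epochs,
      config$training$batch_size)
  st_norm <- normalize_expression(prep$st, config$preprocess$target_sum)
  fit <- stage("train", train(st_norm, pseudo, config$training))
  utils::write.csv(fit$trace, file.path(config$out_dir, "trace.csv"), row.names = FALSE)
  save_model(fit$model, file.path(config$out_dir, "model.ckpt"), config$hash)
  say("final losses: L_P=%.4f L_MSE=%.4f",
      utils::tail(fit$trace$L_P, 1), utils::tail(fit$trace$L_MSE, 1))

  say("stage deconvolve: inferring proportions for %d spots", nrow(st_norm))
  Y <- stage("deconvolve", infer(st_norm, fit$model))
  write_proportions(Y, file.path(config$out_dir, "proportions.csv"), config$hash)

  report <- NULL
  if (!is.null(truth)) {
    say("stage evaluate: scoring against ground truth")
    report <- stage("evaluate", evaluate_deconvolution(truth, Y))
    jsonlite::write_json(
      list(config_hash = config$hash,
           means = as.list(report$means),
           per_type = report$per_type),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    say("mean PCC %.3f, mean RMSE %.3f", report$means["mean_pcc"],
        report$means["mean_rmse"])
  }
  say("done")
  out <- config$out_dir
  attr(out, "proportions") <- Y
  attr(out, "report") <- report
  invisible(out)
}
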