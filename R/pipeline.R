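#' Pipeline configuration
#'
#' One object driving the whole encode -> balance -> select -> train ->
#' evaluate pipeline. Input files may be omitted, in which case data are
#' simulated from `synthetic` (a [synthetic_params()] or preset name).
#' The defaults mirror the reference configuration: cumulative k-mers to
#' k = 4, PseAAC property groups A-F (lambda = 30, omega = 0.05), NCL
#' balancing, 300-tree depth-9 forest ranking keeping 193 features, and
#' the seven-layer MLP, evaluated by stratified fivefold CV.
#'
#' @param aptamers,proteins,pairs input file paths (all three or none).
#' @param synthetic [synthetic_params()] or preset name used when no
#'   input files are given.
#' @param kmax,mode,groups,lambda,omega feature parameters
#'   (see [build_feature_matrix()]).
#' @param property_table optional property-table CSV path.
#' @param balance `"ncl"`, `"random"` or `"none"`; `ncl_k` neighbours.
#' @param select_n features kept after ranking (NULL = keep all).
#' @param rf_trees,rf_depth ranking-forest parameters.
#' @param model `"mlp"` or a baseline name (see [cross_validate()]).
#' @param mlp optional [mlp_config()].
#' @param folds,seed,threshold evaluation parameters.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(aptamers = NULL, proteins = NULL, pairs = NULL,
                            synthetic = "strong", kmax = 4L,
                            mode = c("plain", "revc"), groups = LETTERS[1:6],
                            lambda = 30L, omega = 0.05, property_table = NULL,
                            balance = c("ncl", "random", "none"), ncl_k = 3L,
                            select_n = 193L, rf_trees = 300L, rf_depth = 9L,
                            model = "mlp", mlp = NULL, folds = 5L, seed = 1L,
                            threshold = 0.5) {
  mode <- match.arg(mode)
  balance <- match.arg(balance)
  files <- c(!is.null(aptamers), !is.null(proteins), !is.null(pairs))
  if (any(files) && !all(files)) {
    stop("provide aptamers, proteins and pairs together (or none)")
  }
  structure(list(aptamers = aptamers, proteins = proteins, pairs = pairs,
                 synthetic = synthetic, kmax = as.integer(kmax), mode = mode,
                 groups = groups, lambda = as.integer(lambda), omega = omega,
                 property_table = property_table, balance = balance,
                 ncl_k = as.integer(ncl_k),
                 select_n = if (is.null(select_n)) NULL else as.integer(select_n),
                 rf_trees = as.integer(rf_trees), rf_depth = as.integer(rf_depth),
                 model = model, mlp = mlp, folds = as.integer(folds),
                 seed = as.integer(seed), threshold = threshold),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

log_stage <- function(...) {
  if (isTRUE(getOption("aptaml.quiet", FALSE))) return(invisible())
  message(format(Sys.time(), "[%H:%M:%S] "), sprintf(...))
}

pipeline_data <- function(config) {
  if (!is.null(config$pairs)) {
    apt <- rna_to_dna(read_fasta(config$aptamers, "nucleotide"))
    prot <- read_fasta(config$proteins, "protein")
    read_pair_table(config$pairs, apt, prot)
  } else if (inherits(config$synthetic, "synthetic_params")) {
    generate_dataset(config$synthetic)
  } else {
    generate_dataset(synthetic_preset(config$synthetic, seed = config$seed))
  }
}

#' Run the full pipeline
#'
#' Executes the stages in order -- load/simulate, encode, then
#' cross-validated balance/select/train/evaluate -- and optionally
#' writes every artifact (feature matrix, removed-row provenance,
#' ranking, final model plus training history, CV report and ROC
#' points, and the configuration with its hash) to `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional artifact directory.
#' @return the [cross_validate()] report, with the dataset, feature
#'   matrix and config hash attached as attributes.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  t0 <- Sys.time()
  log_stage("pipeline start (config %s)", hash)
  ds <- pipeline_data(config)
  log_stage("data: %d pairs (%d positive), %d aptamers, %d proteins",
            nrow(ds$pairs), sum(ds$pairs$label == 1),
            length(ds$aptamers), length(ds$proteins))
  table <- if (is.null(config$property_table)) load_property_table()
           else load_property_table(config$property_table)
  fm <- build_feature_matrix(ds, kmax = config$kmax, mode = config$mode,
                             groups = config$groups, lambda = config$lambda,
                             omega = config$omega, table = table)
  log_stage("features: %d x %d", nrow(fm$x), ncol(fm$x))
  report <- cross_validate(fm, balance = config$balance, ncl_k = config$ncl_k,
                           select_n = config$select_n,
                           rf_trees = config$rf_trees,
                           rf_depth = config$rf_depth, model = config$model,
                           mlp = config$mlp, folds = config$folds,
                           seed = config$seed, threshold = config$threshold)
  log_stage("cv: mean accuracy %.3f, mean AUC %.3f",
            report$mean$accuracy, report$mean_auc)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_matrix(fm, file.path(out_dir, "features.csv"))
    bal <- switch(config$balance,
                  ncl = ncl_resample(fm, k_neighbors = config$ncl_k),
                  random = random_undersample(fm, seed = config$seed),
                  none = fm)
    removed <- attr(bal, "removed")
    writeLines(c("removed_pair_id", removed %||% character()),
               file.path(out_dir, "removed_rows.csv"))
    sel <- bal
    if (!is.null(config$select_n)) {
      rk <- rank_features(bal, n_trees = config$rf_trees,
                          max_depth = config$rf_depth, seed = config$seed)
      write_ranking(rk, file.path(out_dir, "ranking.csv"))
      sel <- select_top(bal, rk, config$select_n)
    }
    if (identical(config$model, "mlp")) {
      cfg <- config$mlp %||% mlp_config(seed = config$seed)
      final <- train(build_mlp(cfg, ncol(sel$x)), sel)
      save_model(final, file.path(out_dir, "model.rds"))
      write.csv(final$history, file.path(out_dir, "history.csv"),
                row.names = FALSE)
    }
    write_cv_report(report, file.path(out_dir, "report.json"),
                    roc_dir = out_dir)
    jsonlite::write_json(
      c(list(config_hash = hash),
        lapply(unclass(config)[!vapply(config, is.null, TRUE)],
               function(v) if (is.list(v)) unclass(v) else v)),
      file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
  }
  log_stage("pipeline done in %.1fs", as.numeric(Sys.time() - t0, units = "secs"))
  attr(report, "dataset") <- ds
  attr(report, "features") <- fm
  attr(report, "config_hash") <- hash
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
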