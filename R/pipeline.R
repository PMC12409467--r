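#' Pipeline configuration
#'
#' One configuration object for the full maturity-assessment workflow:
#' simulate a labelled study, impute and normalize features, train and
#' evaluate the classifier, explain it, and score samples by hyperplane
#' distance. A single global seed is expanded into per-stage seeds with
#' [derive_seed()] (stage index 1 = simulate, 2 = split, 3 = search,
#' 4 = explain), so stages can be re-run in isolation.
#'
#' @param out_dir Output directory for artifacts.
#' @param seed Global seed.
#' @param n_per_class Recordings per class of the simulated study.
#' @param stages Character vector of stages to run, in order, a subset of
#'   `c("simulate", "features", "train", "explain", "score")`.
#' @param search `"grid"` (default; reference grid), `"random"`, or
#'   `"none"` (use `svm` as given).
#' @param svm An [svm_config()] used when `search = "none"`.
#' @param n_random Iterations for the random search.
#' @param presets Phenotype presets for the simulation (default:
#'   immature and mature from [default_presets()]).
#' @param intermediate Logical: also simulate and score the intermediate
#'   phenotype (default `TRUE` when the score stage runs).
#' @param explain_n Number of test samples to explain (default 16; exact
#'   enumeration is exponential in features but linear here).
#' @param config_overrides Named list merged over the
#'   [synthetic_study_config()] arguments.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("cmmaturity_run_"),
                            seed = 42L, n_per_class = 115L,
                            stages = c("simulate", "features", "train",
                                       "explain", "score"),
                            search = c("grid", "random", "none"),
                            svm = svm_config(), n_random = 200L,
                            presets = NULL, intermediate = TRUE,
                            explain_n = 16L,
                            config_overrides = list()) {
  search <- match.arg(search)
  allowed <- c("simulate", "features", "train", "explain", "score")
  if (!all(stages %in% allowed))
    stop_("unknown stage(s): %s",
          paste(setdiff(stages, allowed), collapse = ", "))
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         n_per_class = as.integer(n_per_class),
         stages = stages, search = search, svm = svm,
         n_random = as.integer(n_random), presets = presets,
         intermediate = isTRUE(intermediate),
         explain_n = as.integer(explain_n),
         config_overrides = config_overrides),
    class = "pipeline_config"
  )
}

#' Run the maturity-assessment pipeline
#'
#' Executes the configured stages in order and writes every artifact under
#' `out_dir`, returning a manifest that records, per artifact, the file,
#' its MD5 hash, the producing stage and the stage seed. Deterministic
#' stages reproduce identical hashes for identical configurations.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_manifest`: `artifacts` (data frame),
#'   `results` (in-memory stage outputs), `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  results <- list()
  add <- function(stage, name, path, seed = NA_integer_) {
    artifacts[[length(artifacts) + 1L]] <<- data.frame(
      stage = stage, name = name, file = basename(path),
      md5 = unname(tools::md5sum(path)), seed = seed,
      stringsAsFactors = FALSE)
  }
  presets <- config$presets %||% {
    pr <- default_presets()
    if (config$intermediate) pr else pr[c("immature", "mature")]
  }

  table <- NULL
  if ("simulate" %in% config$stages) {
    sim_seed <- derive_seed(config$seed, 1L)
    args <- utils::modifyList(
      list(n_per_class = config$n_per_class, seed = sim_seed),
      config$config_overrides)
    study <- do.call(synthetic_study_config, args)
    two_class <- presets[vapply(presets, `[[`, character(1), "label") %in%
                           c("immature", "mature")]
    ds <- generate_dataset(study, two_class)
    table <- ds$table
    path <- file.path(config$out_dir, "features.csv")
    write_feature_table(table, path)
    add("simulate", "feature_table", path, sim_seed)
    results$dataset <- ds
    if (config$intermediate &&
          "intermediate" %in% vapply(presets, `[[`, character(1), "label")) {
      n_int <- max(4L, as.integer(round(config$n_per_class / 2)))
      study_int <- do.call(synthetic_study_config, utils::modifyList(
        list(n_per_class = n_int, seed = derive_seed(config$seed, 11L)),
        config$config_overrides))
      ds_int <- generate_dataset(study_int, c(
        presets["intermediate"],
        presets[vapply(presets, `[[`, character(1), "label") == "mature"]))
      ds_int$table <- ds_int$table[ds_int$table$class == "intermediate", ]
      results$intermediate <- ds_int
      path <- file.path(config$out_dir, "features_intermediate.csv")
      write_feature_table(ds_int$table, path)
      add("simulate", "intermediate_feature_table", path,
          derive_seed(config$seed, 11L))
    }
  }

  if ("features" %in% config$stages) {
    if (is.null(table)) stop_("the features stage needs a simulated table")
    table <- impute_time_01(table)
    results$table_imputed <- table
  }

  if ("train" %in% config$stages) {
    split_seed <- derive_seed(config$seed, 2L)
    balanced <- balance_dataset(table, seed = split_seed)
    parts <- stratified_split(balanced,
                              split_spec(seed = split_seed))
    norm <- znormalize(parts$train)
    train_n <- norm$table
    test_n <- znormalize(parts$test, norm$stats)$table
    search_seed <- derive_seed(config$seed, 3L)
    sel <- switch(config$search,
      grid = grid_search(train_n, seed = search_seed),
      random = random_search(train_n, n_iter = config$n_random,
                             seed = search_seed),
      none = NULL)
    best <- if (is.null(sel)) config$svm else sel$best_config
    model <- train_svm(train_n, train_n$class, best)
    report <- holdout_evaluate(train_n, test_n, best, seed = search_seed)
    path <- file.path(config$out_dir, "model.json")
    write_svm_json(model, norm$stats, path)
    add("train", "model", path, search_seed)
    rpt_path <- file.path(config$out_dir, "evaluation.json")
    jsonlite::write_json(list(
      metrics = report$metrics, confusion = report$confusion,
      n_train = nrow(train_n), n_test = nrow(test_n)),
      rpt_path, auto_unbox = TRUE, digits = NA)
    add("train", "evaluation", rpt_path, search_seed)
    results$model <- model
    results$search <- sel
    results$norm_stats <- norm$stats
    results$train <- train_n
    results$test <- test_n
    results$evaluation <- report
  }

  if ("explain" %in% config$stages) {
    if (is.null(results$model)) stop_("the explain stage needs a model")
    exp_seed <- derive_seed(config$seed, 4L)
    n_exp <- min(config$explain_n, nrow(results$test))
    idx <- withr::with_seed(exp_seed,
                            sort(sample(nrow(results$test), n_exp)))
    expl <- explain_samples(results$model, results$test[idx, ],
                            results$train)
    csv <- file.path(config$out_dir, "shap.csv")
    write_explanations(expl, csv,
                       file.path(config$out_dir, "shap_meta.json"))
    add("explain", "shap", csv, exp_seed)
    results$explanations <- expl
    results$importance <- global_importance(expl)
  }

  if ("score" %in% config$stages) {
    if (is.null(results$model)) stop_("the score stage needs a model")
    tabs <- list(results$test)
    grps <- list(results$test$class)
    if (!is.null(results$intermediate)) {
      int_n <- znormalize(impute_time_01(results$intermediate$table),
                          results$norm_stats)$table
      tabs <- c(tabs, list(int_n))
      grps <- c(grps, list(int_n$class))
    }
    all_tab <- do.call(rbind, tabs)
    scores <- maturity_score(results$model, all_tab,
                             groups = unlist(grps))
    path <- file.path(config$out_dir, "scores.csv")
    utils::write.csv(
      data.frame(recording_id = all_tab$recording_id,
                 group = unlist(grps), score = scores$score,
                 predicted = scores$predicted),
      path, row.names = FALSE, quote = FALSE)
    add("score", "scores", path)
    results$scores <- scores
  }

  manifest <- structure(
    list(artifacts = do.call(rbind, artifacts), results = results,
         config = config),
    class = "pipeline_manifest"
  )
  jsonlite::write_json(
    list(seed = config$seed, stages = config$stages,
         artifacts = manifest$artifacts),
    file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA)
  manifest
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("Pipeline run:", x$config$out_dir, "\n")
  print(x$artifacts[c("stage", "name", "file", "md5")])
  invisible(x)
}

#' Serialize a trained SVM (with normalization statistics) to JSON
#'
#' @param model A [train_svm()] model.
#' @param norm_stats Normalization statistics used for its inputs.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_svm_json <- function(model, norm_stats, path) {
  jsonlite::write_json(list(
    config = unclass(model$config), gamma = model$gamma,
    rho = model$rho, dual_coefs = model$dual_coefs,
    support_vectors = model$support_vectors,
    positive_class = model$positive_class,
    negative_class = model$negative_class,
    feature_names = model$feature_names,
    norm_stats = list(mean = as.list(norm_stats$mean),
                      sd = as.list(norm_stats$sd))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a trained SVM from JSON
#'
#' @param path File written by [write_svm_json()].
#' @return List with `model` (a `trained_svm`) and `norm_stats`.
#' @export
read_svm_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- svm_config(C = raw$config$C, kernel = raw$config$kernel,
                    gamma = if (is.character(raw$config$gamma))
                      raw$config$gamma else as.numeric(raw$config$gamma),
                    degree = raw$config$degree, coef0 = raw$config$coef0)
  model <- structure(
    list(config = cfg, gamma = raw$gamma,
         support_vectors = as.matrix(raw$support_vectors),
         dual_coefs = as.numeric(raw$dual_coefs), rho = raw$rho,
         positive_class = raw$positive_class,
         negative_class = raw$negative_class,
         feature_names = raw$feature_names),
    class = "trained_svm")
  colnames(model$support_vectors) <- raw$feature_names
  list(model = model,
       norm_stats = list(mean = unlist(raw$norm_stats$mean),
                         sd = unlist(raw$norm_stats$sd)))
}
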