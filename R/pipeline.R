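# Pipeline orchestration: YAML config, derived stage seeds, manifest
# files, artifact caching, and an end-to-end runner.

.pipeline_stages <- c("generate", "tune", "train", "explain", "optimize",
                      "assess")

#' Build (or read) a pipeline configuration
#'
#' @param path Optional YAML file; entries override the defaults below.
#' @param ... Named overrides applied after the file.
#' @return A list of class `pipeline_config` with sections `sampling`
#'   (`n_samples`, `law`), `kinetics` (passed to [kinetics_config()]),
#'   `split` (fractions), `tuning` (`n_pop`, `n_iter`), `moo`
#'   (`pop_size`, `generations`), `uncertainty` (`sigma`, `replicates`),
#'   plus the global `seed` and `out_dir`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    seed = 1L,
    out_dir = "ibuopt_artifacts",
    sampling = list(n_samples = 2000, law = "log-uniform"),
    kinetics = list(),
    split = c(0.7, 0.15, 0.15),
    tuning = list(n_pop = 15, n_iter = 20),
    moo = list(pop_size = 200, generations = 100),
    uncertainty = list(sigma = 0.2, replicates = 30)
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  dots <- list(...)
  if (length(dots)) cfg <- utils::modifyList(cfg, dots)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1,
            is.character(cfg$out_dir),
            cfg$sampling$n_samples >= 1,
            cfg$sampling$law %in% c("log-uniform", "uniform", "lhs-log"),
            length(cfg$split) == 3, abs(sum(cfg$split) - 1) < 1e-8,
            cfg$tuning$n_pop >= 2, cfg$tuning$n_iter >= 0,
            cfg$moo$pop_size >= 4, cfg$moo$generations >= 1,
            cfg$uncertainty$sigma >= 0, cfg$uncertainty$replicates >= 1)
  invisible(cfg)
}

# one global seed deterministically derives every stage seed
stage_seed <- function(cfg, stage) {
  idx <- match(stage, .pipeline_stages)
  as.integer((as.integer(cfg$seed) * 7919L + idx * 104729L) %% 2147483647L)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

manifest_path <- function(cfg, stage)
  file.path(cfg$out_dir, paste0(stage, ".manifest.json"))

write_manifest <- function(cfg, stage, artifacts, extra = list()) {
  man <- c(list(stage = stage,
                config_hash = config_hash(cfg),
                seed = stage_seed(cfg, stage),
                artifacts = artifacts,
                artifact_hashes = as.list(tools::md5sum(unlist(artifacts))),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           extra)
  jsonlite::write_json(man, manifest_path(cfg, stage), auto_unbox = TRUE,
                       digits = NA)
  invisible(man)
}

stage_current <- function(cfg, stage) {
  mp <- manifest_path(cfg, stage)
  if (!file.exists(mp)) return(FALSE)
  man <- jsonlite::read_json(mp)
  if (!identical(man$config_hash, unname(config_hash(cfg)))) return(FALSE)
  arts <- unlist(man$artifacts)
  if (!all(file.exists(arts))) return(FALSE)
  hashes <- unname(unlist(man$artifact_hashes))
  identical(unname(tools::md5sum(arts)), hashes)
}

require_stage <- function(cfg, stage) {
  if (!stage_current(cfg, stage))
    stop("missing or stale upstream artifacts: run stage '", stage,
         "' first", call. = FALSE)
}

#' Run one pipeline stage
#'
#' Stages (in dependency order): `generate` (sample + label the dataset
#' and split it), `tune` (SAO hyperparameter search per output), `train`
#' (fit and evaluate the three surrogates), `explain` (SHAP importance),
#' `optimize` (NSGA-II front + strategies), `assess` (robustness
#' scores).  Each stage writes its artifacts plus a manifest with config
#' hash, derived seed, and artifact checksums; rerunning a stage whose
#' manifest is current is a no-op unless `force = TRUE`.  A checksum
#' mismatch in an upstream artifact aborts before any work.
#'
#' @param stage Stage name.
#' @param cfg A `pipeline_config`.
#' @param force Re-run even when the manifest is current.
#' @return Invisibly, the manifest list.
#' @export
run_stage <- function(stage, cfg, force = FALSE) {
  stage <- match.arg(stage, .pipeline_stages)
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!force && stage_current(cfg, stage)) {
    message("stage '", stage, "' is current; skipping (force = TRUE to rerun)")
    return(invisible(jsonlite::read_json(manifest_path(cfg, stage))))
  }
  t0 <- Sys.time()
  seed <- stage_seed(cfg, stage)
  out <- file.path(cfg$out_dir, "%s")
  p <- function(name) sprintf(out, name)

  man <- switch(stage,
    generate = {
      scfg <- sampling_config(n_samples = cfg$sampling$n_samples,
                              law = cfg$sampling$law, seed = seed)
      kcfg <- do.call(kinetics_config, cfg$kinetics)
      ds <- generate_dataset(scfg, kcfg = kcfg)
      write_dataset(ds, p("dataset.csv"))
      splits <- split_dataset(ds, cfg$split, seed = seed)
      for (nm in names(splits))
        write.csv(splits[[nm]], p(paste0(nm, ".csv")), row.names = FALSE)
      cm <- summarize_correlations(ds)
      write.csv(cm, p("correlations.csv"))
      write_manifest(cfg, stage,
                     list(dataset = p("dataset.csv"), train = p("train.csv"),
                          validation = p("validation.csv"),
                          test = p("test.csv"),
                          correlations = p("correlations.csv")),
                     extra = list(n_censored = sum(ds$censored),
                                  n_failed = sum(ds$failed)))
    },
    tune = {
      require_stage(cfg, "generate")
      train <- read.csv(p("train.csv"))
      validation <- read.csv(p("validation.csv"))
      scfg <- sao_config(n_pop = cfg$tuning$n_pop,
                         n_iter = cfg$tuning$n_iter, seed = seed)
      arts <- list()
      for (outc in c("y1", "y2", "y3")) {
        res <- tune_hyperparameters(train, validation, outcome = outc,
                                    cfg = scfg)
        hp_path <- p(paste0("hp_", outc, ".json"))
        jsonlite::write_json(unclass(res$hyperparameters), hp_path,
                             auto_unbox = TRUE, digits = NA)
        write.csv(res$trace, p(paste0("trace_", outc, ".csv")),
                  row.names = FALSE)
        arts[[paste0("hp_", outc)]] <- hp_path
        arts[[paste0("trace_", outc)]] <- p(paste0("trace_", outc, ".csv"))
      }
      write_manifest(cfg, stage, arts)
    },
    train = {
      require_stage(cfg, "generate")
      require_stage(cfg, "tune")
      train <- read.csv(p("train.csv"))
      test <- read.csv(p("test.csv"))
      arts <- list()
      metrics <- list()
      for (outc in c("y1", "y2", "y3")) {
        hp <- do.call(hyperparameters,
                      jsonlite::read_json(p(paste0("hp_", outc, ".json"))))
        model <- train_surrogate(train, outcome = outc, hp = hp, seed = seed)
        mp <- p(paste0("surrogate_", outc, ".json"))
        save_surrogate(model, mp)
        rep <- evaluate_surrogate(model, test)
        metrics[[outc]] <- list(R2 = rep$R2, RMSE = rep$RMSE,
                                MAE = rep$MAE, MAPE = rep$MAPE)
        arts[[paste0("surrogate_", outc)]] <- mp
      }
      jsonlite::write_json(metrics, p("test_metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      arts$test_metrics <- p("test_metrics.json")
      write_manifest(cfg, stage, arts)
    },
    explain = {
      require_stage(cfg, "generate")
      require_stage(cfg, "train")
      models <- load_pipeline_surrogates(cfg)
      test <- read.csv(p("test.csv"))
      arts <- list()
      for (m in names(models)) {
        attr <- attribute_shap(models[[m]], test)
        rk <- rank_importance(attr)
        rp <- p(paste0("importance_", m, ".json"))
        importance_to_json(rk, rp)
        arts[[paste0("importance_", m)]] <- rp
      }
      write_manifest(cfg, stage, arts)
    },
    optimize = {
      require_stage(cfg, "train")
      models <- load_pipeline_surrogates(cfg)
      problem <- moo_problem(models)
      front <- run_nsga2(problem, pop_size = cfg$moo$pop_size,
                         generations = cfg$moo$generations, seed = seed)
      write.csv(as.data.frame(front), p("pareto_front.csv"),
                row.names = FALSE)
      sel <- select_strategies(front)
      write.csv(sel$strategies, p("strategies.csv"), row.names = FALSE)
      jsonlite::write_json(list(similarity = sel$similarity),
                           p("similarity.json"), digits = NA)
      write_manifest(cfg, stage,
                     list(front = p("pareto_front.csv"),
                          strategies = p("strategies.csv"),
                          similarity = p("similarity.json")),
                     extra = list(front_size = nrow(front)))
    },
    assess = {
      require_stage(cfg, "train")
      require_stage(cfg, "optimize")
      models <- load_pipeline_surrogates(cfg)
      strategies <- read.csv(p("strategies.csv"))
      rob <- assess_robustness(strategies, models,
                               sigma = cfg$uncertainty$sigma,
                               replicates = cfg$uncertainty$replicates,
                               seed = seed)
      write.csv(rob, p("robustness.csv"), row.names = FALSE)
      write_manifest(cfg, stage, list(robustness = p("robustness.csv")))
    })
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  message(sprintf("stage '%s' done in %.1f s", stage, elapsed))
  invisible(man)
}

# reload the three surrogates saved by the train stage
load_pipeline_surrogates <- function(cfg) {
  p <- function(name) file.path(cfg$out_dir, name)
  models <- list()
  for (outc in c("y1", "y2", "y3")) {
    meta <- jsonlite::read_json(p(paste0("surrogate_", outc, ".json.meta.json")))
    booster <- xgboost::xgb.load(p(paste0("surrogate_", outc, ".json")))
    models[[outc]] <- structure(
      list(booster = booster, features = unlist(meta$features),
           outcome = meta$outcome,
           hp = do.call(hyperparameters, meta$hp),
           seed = meta$seed, n_train = meta$n_train,
           backend = meta$backend, data_hash = meta$data_hash),
      class = "surrogate_model")
  }
  list(rt = models$y1, cr = models$y2, cost = models$y3)
}

#' Run the full pipeline
#'
#' Executes every stage in dependency order; stages with current
#' manifests are skipped unless `force = TRUE`, so the pipeline is
#' reproducible (and resumable) from the config alone.
#'
#' @param cfg A `pipeline_config`.
#' @param force Re-run all stages.
#' @return Invisibly, the list of stage manifests.
#' @export
run_pipeline <- function(cfg = pipeline_config(), force = FALSE) {
  mans <- lapply(.pipeline_stages, run_stage, cfg = cfg, force = force)
  names(mans) <- .pipeline_stages
  invisible(mans)
}
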