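## Pipeline: configuration, manifest, end-to-end run -------------------------

run_config_defaults <- function() {
  list(
    ## corpus
    counts_per_class = c(500L, 500L, 500L, 500L),
    language = "en",
    label_noise_rate = 0,
    train_fraction = 0.8,
    ## encoder
    dim = 768L,
    max_tokens = 64L,
    hash_buckets = 262144L,
    normalize = TRUE,
    ## training schedule shared across heads
    epochs = 30L,
    batch_size = 64L,
    learning_rate = 1e-3,
    dropout = 0.5,
    ## clustering
    num_clusters = 4L,
    entropy_weight = 2,
    k_neighbors = 5L,
    hidden_width = 128L,
    finetune = TRUE,
    ## supervised
    perturb_scale = 0.01,
    dae_sigma = 0.1,
    ae_hidden = 256L,
    dc_kernel_sizes = c(2L, 3L, 4L),
    dc_total_filters = 256L,
    dc_candidates = 4L,
    supervision_weight = 0.1,
    ## control
    stages = c("cluster", "mec"),
    seed = 1L
  )
}

#' Pipeline configuration
#'
#' Builds the strict-schema configuration for [run_pipeline()]. Unknown keys
#' are rejected; loading then saving a config file is idempotent.
#'
#' @param ... Overrides of the defaults (see [run_pipeline()] for their
#'   meaning). Training-schedule defaults: dropout 0.5, 30 epochs, batch 64,
#'   max 64 tokens, feature dimension 768, kernel sizes (2, 3, 4) with 256
#'   total filters.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- run_config_defaults()
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(defaults, overrides)
  bad_stage <- setdiff(cfg$stages, c("cluster", "mec"))
  if (length(bad_stage) > 0L) {
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `run_config` (for writing).
#' @return `read_run_config()` returns a `run_config`; `write_run_config()`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

log_stage <- function(stage, seed, t0, verbose) {
  if (verbose) {
    message(sprintf("[rhetclass] stage=%s seed=%d elapsed=%.2fs",
                    stage, seed, as.numeric(Sys.time()) - t0))
  }
}

#' Run the full pipeline
#'
#' Executes generate -> encode -> (fine-tune) -> cluster and/or supervised
#' classification -> evaluate on a synthetic corpus, writing every artifact
#' plus a run manifest to `out_dir`. All randomness flows from `config$seed`
#' via stage-derived seeds, so an identical rerun reproduces every artifact
#' byte for byte (the manifest, which carries wall-clock timestamps, is
#' metadata rather than an artifact).
#'
#' Artifacts: `corpus.jsonl`, `train.jsonl`, `test.jsonl`, `embeddings.bin`
#' (+ `.json` sidecar), `assignments.tsv` and `report_cluster/` when the
#' cluster stage runs (with `loss_trajectory.csv`), `predictions.tsv` and
#' `report_mec/` when the supervised stage runs, and `manifest.json`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Log stage/seed/elapsed lines (default TRUE).
#' @return Invisibly, a list with the manifest and the metric reports.
#' @export
run_pipeline <- function(config = run_config(), out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(Sys.time())
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  seed <- config$seed
  artifacts <- character(0)
  reports <- list()

  stage_guard <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  ## -- generate
  corp <- stage_guard("generate", generate_abstract_corpus(
    config$counts_per_class, language = config$language,
    label_noise_rate = config$label_noise_rate,
    seed = derive_seed(seed, "corpus")
  ))
  write_corpus(corp, file.path(out_dir, "corpus.jsonl"))
  artifacts <- c(artifacts, "corpus.jsonl")
  sp <- split_corpus(corp, config$train_fraction,
                     seed = derive_seed(seed, "split"))
  write_corpus(sp$train, file.path(out_dir, "train.jsonl"))
  write_corpus(sp$test, file.path(out_dir, "test.jsonl"))
  artifacts <- c(artifacts, "train.jsonl", "test.jsonl")
  log_stage("generate", seed, t0, verbose)

  ## -- encode
  enc_cfg <- encoder_config(dim = config$dim, max_tokens = config$max_tokens,
                            hash_buckets = config$hash_buckets,
                            normalize = config$normalize,
                            seed = derive_seed(seed, "encode"))
  E_train <- stage_guard("encode", encode(sp$train, enc_cfg))
  E_test <- stage_guard("encode", encode(sp$test, enc_cfg))
  log_stage("encode", seed, t0, verbose)

  ## -- finetune
  if (isTRUE(config$finetune)) {
    adapter <- stage_guard("finetune", finetune_encoder(
      E_train, sp$train$label, epochs = config$epochs,
      batch_size = config$batch_size,
      learning_rate = config$learning_rate,
      seed = derive_seed(seed, "finetune")
    ))
    E_train <- apply_adapter(adapter, E_train)
    E_test <- apply_adapter(adapter, E_test)
    log_stage("finetune", seed, t0, verbose)
  }
  write_embeddings(E_test, file.path(out_dir, "embeddings.bin"),
                   normalize = config$normalize,
                   fingerprint = sprintf("hashing/dim=%d/seed=%d",
                                         config$dim, seed))
  artifacts <- c(artifacts, "embeddings.bin", "embeddings.bin.json")

  truth_test <- as_label_int(sp$test$label)

  ## -- cluster
  if ("cluster" %in% config$stages) {
    nb <- stage_guard("cluster", mine_neighbors(E_test,
                                                k = config$k_neighbors))
    fit <- stage_guard("cluster", train_scan(
      E_test, nb, num_clusters = config$num_clusters,
      entropy_weight = config$entropy_weight, epochs = config$epochs,
      batch_size = config$batch_size,
      learning_rate = config$learning_rate, dropout = config$dropout,
      hidden_width = config$hidden_width,
      seed = derive_seed(seed, "scan")
    ))
    assign <- predict(fit, E_test)
    ids <- rownames(E_test)
    writeLines(c("id\tcluster",
                 paste(ids, assign, sep = "\t")),
               file.path(out_dir, "assignments.tsv"))
    artifacts <- c(artifacts, "assignments.tsv")
    utils::write.csv(
      data.frame(epoch = seq_along(fit$loss_trajectory),
                 loss = fit$loss_trajectory),
      file.path(out_dir, "loss_trajectory.csv"), row.names = FALSE)
    artifacts <- c(artifacts, "loss_trajectory.csv")
    ev <- evaluate_clustering(truth_test, assign)
    rep_dir <- file.path(out_dir, "report_cluster")
    dir.create(rep_dir, showWarnings = FALSE)
    utils::write.csv(as.data.frame(unclass(ev$confusion)),
                     file.path(rep_dir, "confusion.csv"))
    jsonlite::write_json(unclass(ev$report),
                         file.path(rep_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, "report_cluster/confusion.csv",
                   "report_cluster/metrics.json")
    reports$cluster <- ev$report
    log_stage("cluster", seed, t0, verbose)
  }

  ## -- supervised
  if ("mec" %in% config$stages) {
    y_train <- as_label_int(sp$train$label)
    model <- stage_guard("mec", train_mec(
      E_train, y_train,
      perturb_scale = config$perturb_scale, dae_sigma = config$dae_sigma,
      ae_hidden = config$ae_hidden,
      dc_kernel_sizes = config$dc_kernel_sizes,
      dc_total_filters = config$dc_total_filters,
      dc_candidates = config$dc_candidates,
      supervision_weight = config$supervision_weight,
      dropout = config$dropout, epochs = config$epochs,
      batch_size = config$batch_size,
      learning_rate = config$learning_rate,
      seed = derive_seed(seed, "mec")
    ))
    pred <- predict(model, E_test)
    writeLines(c("id\tpredicted",
                 paste(rownames(E_test), RHET_CLASSES[pred], sep = "\t")),
               file.path(out_dir, "predictions.tsv"))
    artifacts <- c(artifacts, "predictions.tsv")
    cm <- confusion(truth_test, pred)
    rep_dir <- file.path(out_dir, "report_mec")
    dir.create(rep_dir, showWarnings = FALSE)
    utils::write.csv(as.data.frame(unclass(cm)),
                     file.path(rep_dir, "confusion.csv"))
    jsonlite::write_json(unclass(metrics(cm)),
                         file.path(rep_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, "report_mec/confusion.csv",
                   "report_mec/metrics.json")
    reports$mec <- metrics(cm)
    log_stage("mec", seed, t0, verbose)
  }

  ## -- manifest (metadata, written last; carries wall-clock timestamps)
  hashes <- tools::md5sum(file.path(out_dir, artifacts))
  names(hashes) <- artifacts
  manifest <- list(
    command = "run_pipeline",
    package_version = as.character(utils::packageVersion("rhetclass")),
    config = unclass(config),
    seed = seed,
    artifacts = as.list(hashes),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, reports = reports))
}

#' Run the ablation grid
#'
#' Runs the pipeline over the four combinations of the two ablations --
#' with/without encoder fine-tuning and with/without dynamic convolution --
#' writing one report directory per variant (`full`, `no-finetune`,
#' `no-dc`, `neither`).
#'
#' @param config Base [run_config()].
#' @param out_dir Output root directory.
#' @param verbose Passed through to [run_pipeline()].
#' @return Invisibly, a named list of the four pipeline results.
#' @export
run_ablation <- function(config = run_config(), out_dir, verbose = TRUE) {
  variants <- list(
    "full" = list(finetune = TRUE, dc = "dynamic"),
    "no-finetune" = list(finetune = FALSE, dc = "dynamic"),
    "no-dc" = list(finetune = TRUE, dc = "identity"),
    "neither" = list(finetune = FALSE, dc = "identity")
  )
  out <- list()
  for (nm in names(variants)) {
    cfg <- config
    cfg$finetune <- variants[[nm]]$finetune
    ## the dc mode is threaded through stages at train time
    attr(cfg, "dc_mode") <- variants[[nm]]$dc
    out[[nm]] <- run_pipeline_dc(cfg, file.path(out_dir, nm),
                                 variants[[nm]]$dc, verbose = verbose)
  }
  invisible(out)
}

## run_pipeline with an explicit dc mode (internal to the ablation grid)
run_pipeline_dc <- function(config, out_dir, dc_mode, verbose = TRUE) {
  if (identical(dc_mode, "dynamic")) {
    return(run_pipeline(config, out_dir, verbose = verbose))
  }
  ## swap the MEC trainer's dc mode by running the stages directly
  old_stages <- config$stages
  config$stages <- setdiff(config$stages, "mec")
  res <- run_pipeline(config, out_dir, verbose = verbose)
  if (!"mec" %in% old_stages) return(res)
  seed <- config$seed
  corp <- read_corpus(file.path(out_dir, "corpus.jsonl"))
  sp <- split_corpus(corp, config$train_fraction,
                     seed = derive_seed(seed, "split"))
  enc_cfg <- encoder_config(dim = config$dim, max_tokens = config$max_tokens,
                            hash_buckets = config$hash_buckets,
                            normalize = config$normalize,
                            seed = derive_seed(seed, "encode"))
  E_train <- encode(sp$train, enc_cfg)
  E_test <- encode(sp$test, enc_cfg)
  if (isTRUE(config$finetune)) {
    adapter <- finetune_encoder(E_train, sp$train$label,
                                epochs = config$epochs,
                                batch_size = config$batch_size,
                                learning_rate = config$learning_rate,
                                seed = derive_seed(seed, "finetune"))
    E_train <- apply_adapter(adapter, E_train)
    E_test <- apply_adapter(adapter, E_test)
  }
  model <- train_mec(E_train, as_label_int(sp$train$label),
                     perturb_scale = config$perturb_scale,
                     dae_sigma = config$dae_sigma,
                     ae_hidden = config$ae_hidden,
                     dc_kernel_sizes = config$dc_kernel_sizes,
                     dc_total_filters = config$dc_total_filters,
                     dc_candidates = config$dc_candidates,
                     supervision_weight = config$supervision_weight,
                     dc = dc_mode, dropout = config$dropout,
                     epochs = config$epochs, batch_size = config$batch_size,
                     learning_rate = config$learning_rate,
                     seed = derive_seed(seed, "mec"))
  pred <- predict(model, E_test)
  writeLines(c("id\tpredicted",
               paste(rownames(E_test), RHET_CLASSES[pred], sep = "\t")),
             file.path(out_dir, "predictions.tsv"))
  cm <- confusion(as_label_int(sp$test$label), pred)
  rep_dir <- file.path(out_dir, "report_mec")
  dir.create(rep_dir, showWarnings = FALSE)
  utils::write.csv(as.data.frame(unclass(cm)),
                   file.path(rep_dir, "confusion.csv"))
  jsonlite::write_json(unclass(metrics(cm)),
                       file.path(rep_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  res$reports$mec <- metrics(cm)
  invisible(res)
}
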