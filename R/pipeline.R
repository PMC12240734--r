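#' Default end-to-end run configuration
#'
#' A plain nested list gathering every stage's parameters; serializes
#' losslessly to YAML via [write_config()] / [read_config()].
#'
#' @param out_dir output directory for run artifacts.
#' @param seed master seed; stage seeds default to values derived from it.
#' @return A list of class `run_config`.
#' @export
default_config <- function(out_dir = "kmerattn_run", seed = 7L) {
  seed <- as.integer(seed)
  structure(list(
    out_dir = out_dir,
    simulate = list(profiles = "default", n_per_class = 300L, seed = seed),
    input = list(fasta = character(), labels = character()),
    curate = list(min_len = 200L, identity_threshold = 0.8, word_size = 8L,
                  train_frac = 0.70, val_frac = 0.15, test_frac = 0.15,
                  split_seed = seed + 1L),
    features = list(ks = c(3L, 4L, 5L)),
    model = list(embed_dim = 128L, n_heads = 4L, hidden_dims = c(256L, 64L),
                 dropout = 0.1),
    train = list(lr = 1e-4, weight_decay = 1e-4, momentum = 0.9,
                 epochs = 100L, batch_size = 128L, seed = seed + 2L,
                 clip_norm = 5),
    analyze = list(enabled = TRUE, embed = FALSE, n_neighbors = 80L,
                   min_dist = 0.005, metric = "chebyshev", seed = seed + 3L),
    ablate = list(enabled = FALSE, subsets = list(3L, 4L, 5L, c(3L, 4L, 5L)))
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' Checks presence and basic types of every required field before any work
#' is done; errors name the offending field.
#'
#' @param config a `run_config` (or plain list).
#' @return The validated config, invisibly.
#' @export
validate_config <- function(config) {
  required <- c("out_dir", "simulate", "input", "curate", "features",
                "model", "train", "analyze", "ablate")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop("config is missing required field(s): ",
         paste(missing, collapse = ", "))
  }
  if (!is.character(config$out_dir) || !nzchar(config$out_dir)) {
    stop("config field 'out_dir' must be a non-empty path")
  }
  use_input <- length(config$input$fasta) > 0
  if (use_input) {
    if (length(config$input$labels) != length(config$input$fasta)) {
      stop("config: input$labels must match input$fasta in length")
    }
    absent <- config$input$fasta[!file.exists(config$input$fasta)]
    if (length(absent)) {
      stop("config: input FASTA path(s) not found: ",
           paste(absent, collapse = ", "))
    }
  } else if (is.null(config$simulate$n_per_class)) {
    stop("config: either input$fasta or simulate$n_per_class is required")
  }
  fr <- config$curate
  if (abs(fr$train_frac + fr$val_frac + fr$test_frac - 1) > 1e-9) {
    stop("config: curate split fractions must sum to 1")
  }
  invisible(config)
}

#' Write / read a run configuration (YAML)
#'
#' @param config a `run_config`.
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` the
#'   restored `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$ablate$subsets <- lapply(cfg$ablate$subsets, as.integer)
  # empty YAML sequences come back as list(); restore character vectors
  cfg$input$fasta <- as.character(unlist(cfg$input$fasta))
  cfg$input$labels <- as.character(unlist(cfg$input$labels))
  structure(cfg, class = "run_config")
}

#' Run the full pipeline
#'
#' Executes: data acquisition (simulate or read FASTA), curation,
#' multi-scale featurization, training, evaluation on the validation and
#' test splits, the GC/ORF/Kruskal-Wallis analysis, and (optionally) the
#' scale ablation. Every artifact is written under `config$out_dir` along
#' with the config snapshot; a rerun with the same config reproduces the
#' metric outputs byte-for-byte. A stage failure aborts with the stage name
#' and leaves a `FAILED` marker in the run directory.
#'
#' @param config a `run_config` (see [default_config()]).
#' @param verbose log one line per stage with record counts.
#' @return Invisibly, a list with `dataset`, `state`, `report_val`,
#'   `report_test`, `analysis`, `ablation` and `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), verbose = TRUE) {
  validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(out_dir, "config.yaml"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "setup"
  on.exit({
    if (!is.null(stage)) {
      writeLines(paste("failed at stage:", stage),
                 file.path(out_dir, "FAILED"))
    }
  })

  stage <- "data"
  if (length(config$input$fasta)) {
    sets <- Map(read_fasta, config$input$fasta, config$input$labels)
    cls <- config$input$labels
    sets <- lapply(sets, function(s) { attr(s, "class_names") <- cls; s })
  } else {
    profiles <- switch(config$simulate$profiles,
                       default = default_profiles(),
                       scale_split = scale_split_profiles(),
                       stop("unknown profile set: ", config$simulate$profiles))
    spec <- generator_spec(profiles, config$simulate$n_per_class,
                           config$simulate$seed)
    full <- generate_dataset(spec)
    sets <- lapply(class_names(full), function(cl) {
      as_rna_set(full[full$label == cl, , drop = FALSE], class_names(full))
    })
  }
  say("data: %s records in %d class set(s)",
      sum(vapply(sets, nrow, 0L)), length(sets))

  stage <- "curate"
  dataset <- curate(
    sets, min_len = config$curate$min_len,
    redundancy = redundancy_params(config$curate$identity_threshold,
                                   config$curate$word_size),
    spec = split_spec(config$curate$train_frac, config$curate$val_frac,
                      config$curate$test_frac, config$curate$split_seed))
  report <- attr(dataset, "curation_report")
  write.table(report, file.path(out_dir, "curation_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (st in unique(report$stage)) {
    say("curate/%s: %s", st,
        paste(report$count[report$stage == st], collapse = "/"))
  }
  write_fasta(dataset, file.path(out_dir, "curated.fa"))

  stage <- "featurize"
  kspec <- kmer_spec(config$features$ks)
  fm <- featurize(dataset, "multiscale", spec = kspec)
  spl <- attr(fm, "splits")
  say("featurize: %d x %d (train %d / val %d / test %d)",
      nrow(fm), ncol(fm), sum(spl == "train"), sum(spl == "val"),
      sum(spl == "test"))

  stage <- "train"
  mcfg <- model_config(config$model$embed_dim, config$model$n_heads,
                       length(class_names(dataset)),
                       config$model$hidden_dims, config$model$dropout)
  tcfg <- train_config(config$train$lr, config$train$weight_decay,
                       config$train$momentum, config$train$epochs,
                       config$train$batch_size, config$train$seed,
                       config$train$clip_norm)
  state <- train_classifier(fm_subset(fm, spl == "train"),
                            fm_subset(fm, spl == "val"),
                            mcfg, tcfg, class_names = class_names(dataset))
  write.table(state$history, file.path(out_dir, "history.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  say("train: best epoch %d (val F1w %.4f)", state$best_epoch,
      max(state$history$val_f1_weighted))

  stage <- "evaluate"
  report_val <- evaluate_classifier(state, fm_subset(fm, spl == "val"))
  report_test <- evaluate_classifier(state, fm_subset(fm, spl == "test"))
  pred <- predict(state, fm_subset(fm, spl == "test"))
  pred$truth <- attr(fm, "labels")[spl == "test"]
  write.table(pred, file.path(out_dir, "predictions_test.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  say("evaluate: val F1w %.4f | test F1w %.4f",
      report_val$f1_weighted, report_test$f1_weighted)

  stage <- "analyze"
  analysis <- NULL
  if (isTRUE(config$analyze$enabled)) {
    analysis <- class_feature_report(dataset)
    write.table(analysis$per_record,
                file.path(out_dir, "per_record_features.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (isTRUE(config$analyze$embed)) {
      emb <- embed_2d(fm, n_neighbors = config$analyze$n_neighbors,
                      min_dist = config$analyze$min_dist,
                      metric = config$analyze$metric,
                      seed = config$analyze$seed)
      coords <- data.frame(id = rownames(emb$coords), emb$coords,
                           label = attr(fm, "labels"))
      write.table(coords, file.path(out_dir, "embedding.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      analysis$embedding <- emb
    }
    say("analyze: KW H = %.2f (p = %.3g)", analysis$kruskal$H,
        analysis$kruskal$p)
  }

  stage <- "ablate"
  ablation <- NULL
  if (isTRUE(config$ablate$enabled)) {
    ablation <- ablate_scales(dataset, config$ablate$subsets, mcfg, tcfg)
    write.table(ablation, file.path(out_dir, "ablation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  stage <- "report"
  strip <- function(r) {
    r <- unclass(r)
    r$per_class$precision <- round(r$per_class$precision, 10)
    lapply(r, function(x) if (is.numeric(x)) round(x, 10) else x)
  }
  report_json <- list(
    classes = class_names(dataset),
    best_epoch = state$best_epoch,
    validation = strip(report_val),
    test = strip(report_test),
    gc_kruskal = if (!is.null(analysis)) {
      list(H = round(analysis$kruskal$H, 10), p = analysis$kruskal$p)
    }
  )
  jsonlite::write_json(report_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage <- NULL  # completed; cancel the failure marker
  say("done: %s", out_dir)
  invisible(list(dataset = dataset, state = state, report_val = report_val,
                 report_test = report_test, analysis = analysis,
                 ablation = ablation, out_dir = out_dir))
}
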