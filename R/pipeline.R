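# End-to-end orchestration: reduce -> weaklabel -> train -> predict ->
# groups -> de, with every stage's output written as CSV (plus model
# directories) and a manifest recording the configuration, the effective
# seeds and md5 checksums, so reruns are verifiably identical and stages can
# resume from intermediates.

#' Default pipeline configuration
#'
#' @param input Directory with a feature-barcode triplet and `labels.csv`,
#'   or `NULL` when `counts`/`labels` objects are passed to
#'   [run_pipeline()] directly.
#' @param out_dir Output directory.
#' @param stages Stages to run, in pipeline order.
#' @param seed Master seed; each stochastic stage derives its own seed from
#'   it (logged in the manifest).
#' @param phenotype Phenotype to convert and score.
#' @param qc Apply [qc_filter()] with default thresholds.
#' @param reduce_mode `"ae"` or `"vae"`.
#' @param ae_budget Tuning budget for the reducer; 0 = skip tuning and use
#'   `ae_cfg`.
#' @param ae_cfg [ae_config()] used when not tuning.
#' @param repeats Weak-label repeats.
#' @param clf_budget Classifier tuning budget; 0 = use `clf_cfg`.
#' @param clf_cfg [classifier_config()] used when not tuning.
#' @param holdout_frac Optional holdout fraction for the classifier report.
#' @param thresholds Score thresholds for [assign_groups()].
#' @param de_groups Length-2 character vector: groups to contrast (defaults
#'   to highest vs lowest).
#' @param pretrained_encoder,pretrained_classifier Optional model
#'   directories for transfer runs.
#' @return A `RunConfig` list.
#' @export
run_config <- function(input = NULL, out_dir = tempfile("scprogress_run"),
                       stages = c("reduce", "weaklabel", "train", "groups",
                                  "de"),
                       seed = 1L, phenotype = "disease", qc = TRUE,
                       reduce_mode = "ae", ae_budget = 0L,
                       ae_cfg = ae_config(), repeats = 10L,
                       clf_budget = 0L, clf_cfg = classifier_config(),
                       holdout_frac = NULL, thresholds = 0.5,
                       de_groups = NULL, pretrained_encoder = NULL,
                       pretrained_classifier = NULL) {
  structure(as.list(environment()), class = "RunConfig")
}

#' Run the scoring pipeline
#'
#' @param config A [run_config()].
#' @param counts,labels Optional in-memory `CountMatrix` /
#'   `PhenotypeLabels` (otherwise read from `config$input`).
#' @return The output directory, invisibly; `manifest.json` there lists
#'   every artifact with its checksum and the seeds used.
#' @export
run_pipeline <- function(config, counts = NULL, labels = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message("[scProgress] ", ...)

  if (is.null(counts)) {
    if (is.null(config$input))
      stop("run_pipeline needs either config$input or in-memory counts",
           call. = FALSE)
    counts <- read_feature_barcode_matrix(config$input)
    labels <- read_binary_labels(file.path(config$input, "labels.csv"),
                                 counts$barcodes)
  }
  if (isTRUE(config$qc)) {
    counts <- qc_filter(counts)
    labels <- labels[counts$barcodes, , drop = FALSE]
    class(labels) <- c("PhenotypeLabels", "data.frame")
    utils::write.csv(attr(counts, "qc_report"),
                     file.path(out, "qc_report.csv"), row.names = FALSE)
  }

  set.seed(config$seed)
  stage_seeds <- stats::setNames(
    as.list(sample.int(.Machine$integer.max - 1L, 4L)),
    c("reduce", "weaklabel", "train", "holdout"))

  enc_model <- NULL; latent <- NULL
  if ("reduce" %in% config$stages) {
    log_msg("stage reduce (", config$reduce_mode, ")")
    if (!is.null(config$pretrained_encoder)) {
      enc_model <- load_model(config$pretrained_encoder)
      norm <- normalize_counts(counts, scaling = enc_model$scaling_params)
      latent <- encode(norm, enc_model)
    } else {
      norm <- normalize_counts(counts)
      cfg <- config$ae_cfg
      if (config$ae_budget > 0L)
        cfg <- tune_autoencoder(norm, budget = config$ae_budget,
                                seed = stage_seeds$reduce,
                                mode = config$reduce_mode)
      cfg$seed <- stage_seeds$reduce
      fit <- if (config$reduce_mode == "vae") train_vae(norm, cfg)
             else train_autoencoder(norm, cfg)
      enc_model <- fit$model; latent <- fit$latent
      save_model(enc_model, file.path(out, "encoder_model"))
    }
    write_latent_csv(latent, file.path(out, "latent.csv"))
    saveRDS(norm, file.path(out, "normalized.rds"))
  } else {
    latent <- read_latent_csv(file.path(out, "latent.csv"))
    norm <- readRDS(file.path(out, "normalized.rds"))
  }

  plab <- NULL
  if ("weaklabel" %in% config$stages) {
    log_msg("stage weaklabel (", config$repeats, " repeats)")
    plab <- repeat_and_average(latent, labels, config$phenotype,
                               n_repeats = config$repeats,
                               seed = stage_seeds$weaklabel)
    df <- data.frame(barcode = plab$barcodes, value = plab$values,
                     covered = plab$covered)
    names(df)[2L] <- config$phenotype
    utils::write.csv(df, file.path(out, "probabilistic.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  scores <- NULL
  if ("train" %in% config$stages) {
    if (!is.null(config$pretrained_classifier)) {
      log_msg("stage predict (pretrained)")
      clf <- load_model(config$pretrained_classifier)
      scores <- predict_scores(latent, clf)
    } else {
      log_msg("stage train")
      if (is.null(plab))
        stop("train stage needs weak labels; run the weaklabel stage or ",
             "supply a pretrained classifier", call. = FALSE)
      clf_cfg <- config$clf_cfg
      clf_cfg$seed <- stage_seeds$train
      fit <- if (config$clf_budget > 0L)
        tune_and_train(latent, plab, budget = config$clf_budget,
                       holdout_frac = config$holdout_frac,
                       seed = stage_seeds$train)
      else train_fixed(latent, plab, config = clf_cfg,
                       holdout_frac = config$holdout_frac,
                       seed = stage_seeds$holdout)
      save_model(fit$model, file.path(out, "classifier_model"))
      scores <- fit$scores
      if (!is.null(fit$holdout))
        utils::write.csv(fit$holdout, file.path(out, "holdout.csv"),
                         row.names = FALSE)
    }
    write_scores_csv(scores, file.path(out, "scores.csv"))
  }

  groups <- NULL
  if ("groups" %in% config$stages) {
    if (is.null(scores))
      scores <- read_scores_csv(file.path(out, "scores.csv"))
    log_msg("stage groups")
    groups <- assign_groups(scores, config$phenotype, config$thresholds)
    utils::write.csv(groups, file.path(out, "groups.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  if ("de" %in% config$stages) {
    log_msg("stage de")
    if (is.null(groups)) {
      g <- utils::read.csv(file.path(out, "groups.csv"))
      g$group <- factor(g$group)
      class(g) <- c("GroupAssignment", "data.frame")
      groups <- g
    }
    # default contrast: the most extreme groups that actually hold cells
    tab <- table(groups$group)
    lv <- names(tab)[tab >= 2L]
    if (length(lv) < 2L)
      stop("fewer than two score groups have >= 2 cells; adjust thresholds",
           call. = FALSE)
    gg <- config$de_groups %||% c(lv[length(lv)], lv[1L])
    de <- differential_expression(norm, groups, gg[1L], gg[2L])
    utils::write.csv(de, file.path(out, "de.csv"), row.names = FALSE)
  }

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    tool = "scProgress",
    version = as.character(utils::packageVersion("scProgress")),
    seed = config$seed,
    stage_seeds = stage_seeds,
    stages = config$stages,
    phenotype = config$phenotype,
    checksums = as.list(tools::md5sum(files))
  )
  names(manifest$checksums) <- sub(paste0("^", out, "/?"), "",
                                   names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}
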