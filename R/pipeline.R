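#' Configure an end-to-end experiment
#'
#' Bundles the generator settings and the analysis choices (methods,
#' modalities, seeds, histogram bins, split ratio) for [run_experiment()].
#' The two modality generators share the master `seed`, so the same synthetic
#' patients (anatomy, covariates, labels) are imaged on both CT and MRI.
#'
#' @param modalities Subset of `c("CT", "MRI")`.
#' @param methods Subset of `c("otsu", "kmeans", "gmm")`.
#' @param n_non_sarcopenia,n_sarcopenia Group sizes passed to the generators.
#' @param seed Master seed for cohort generation.
#' @param split_seed,cv_seed Seeds for the train/validation split and the CV
#'   fold assignment.
#' @param train_fraction Training fraction of the stratified split.
#' @param n_bins Histogram bins for thresholding.
#' @param clinical_covariates Covariate columns for the clinical model.
#' @param ... Further arguments forwarded to [generator_config()] (e.g.
#'   `roi_shape`, `fat_fraction_mean`).
#' @return A `run_config` object.
#' @export
run_config <- function(modalities = c("CT", "MRI"),
                       methods = c("otsu", "kmeans", "gmm"),
                       n_non_sarcopenia = 100,
                       n_sarcopenia = 100,
                       seed = 1L,
                       split_seed = 1L,
                       cv_seed = 1L,
                       train_fraction = 0.6,
                       n_bins = 256L,
                       clinical_covariates = c("age", "bmi", "albumin",
                                               "hemoglobin", "rbc"),
                       ...) {
  if (length(modalities) < 1 || length(methods) < 1) {
    abort("select at least one modality and one method",
      class = "sarcohab_config_error"
    )
  }
  modalities <- match.arg(modalities, several.ok = TRUE)
  methods <- match.arg(methods, several.ok = TRUE)
  generators <- lapply(modalities, function(m) {
    generator_config(
      modality = m, n_non_sarcopenia = n_non_sarcopenia,
      n_sarcopenia = n_sarcopenia, seed = seed, ...
    )
  })
  names(generators) <- modalities
  structure(
    list(
      modalities = modalities, methods = methods, generators = generators,
      seed = as.integer(seed), split_seed = as.integer(split_seed),
      cv_seed = as.integer(cv_seed), train_fraction = train_fraction,
      n_bins = as.integer(n_bins), clinical_covariates = clinical_covariates
    ),
    class = "run_config"
  )
}

#' Read/write a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  plain <- unclass(config)
  plain$generators <- lapply(plain$generators, unclass)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- y$generators[[y$modalities[1]]]
  do.call(run_config, c(
    list(
      modalities = y$modalities, methods = y$methods,
      n_non_sarcopenia = gen$n_non_sarcopenia,
      n_sarcopenia = gen$n_sarcopenia,
      seed = y$seed, split_seed = y$split_seed, cv_seed = y$cv_seed,
      train_fraction = y$train_fraction, n_bins = y$n_bins,
      clinical_covariates = y$clinical_covariates
    )
  ))
}

habitat_feature_names <- function(modality) {
  paste0(modality, c(
    "_fat_Mean", "_fat_Volume", "_fat_Percent",
    "_muscle_Mean", "_muscle_Volume", "_muscle_Percent"
  ))
}

evaluate_model_set <- function(train_tbl, valid_tbl, outcome, predictors,
                               cv_seed, alpha = 0.05) {
  recipe <- fit_recipe(train_tbl, outcome, predictors, alpha = alpha)
  score_tr <- predict(recipe$final, train_tbl)
  score_va <- predict(recipe$final, valid_tbl)
  ok_tr <- !is.na(score_tr)
  ok_va <- !is.na(score_va)
  list(
    screen = recipe$screen,
    stepwise = recipe$stepwise,
    model = recipe$final,
    roc_train = roc_summary(score_tr[ok_tr], train_tbl[[outcome]][ok_tr]),
    roc_validation = roc_summary(score_va[ok_va], valid_tbl[[outcome]][ok_va]),
    cv = five_fold_cv(train_tbl, outcome, predictors, seed = cv_seed,
                      alpha = alpha)
  )
}

#' Run the full habitat-imaging experiment
#'
#' Orchestrates the pipeline end to end: generate the synthetic cohorts (one
#' per modality, shared anatomy), split subjects 6:4 stratified by label,
#' pool training-set ROI intensities, fit each requested cluster model and
#' derive its muscle/fat threshold, classify every subject and extract
#' habitat features, then run the modelling protocol (univariate screen,
#' backward stepwise logistic regression, training/validation ROC with
#' Youden cutoffs, five-fold CV) per modality-method combination plus a
#' clinical covariate model. A failure in one combination is recorded in the
#' results table without aborting the others.
#'
#' @param config A [run_config()].
#' @param output_dir Optional directory; when given, feature tables, model
#'   summaries, the AUC table and a JSON manifest are written there.
#' @return A `habitat_experiment` object: `subjects` (records + split),
#'   `features` (per modality), `cluster_models`, `results` (tibble with one
#'   row per model incl. the clinical model), `config`, `manifest`.
#' @export
run_experiment <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  outcome <- "sarcopenia"

  cohorts <- lapply(config$generators, generate_cohort)
  records <- tibble::as_tibble(cohorts[[1]])
  records <- records[, !vapply(records, is.list, logical(1)), drop = FALSE]
  records <- split_cohort(records,
    train_fraction = config$train_fraction,
    seed = config$split_seed, label_col = outcome
  )

  features <- list()
  cluster_models <- list()
  rows <- list()

  for (mod in config$modalities) {
    cohort <- cohorts[[mod]]
    train_ids <- records$subject_id[records$split == "train"]
    pooled <- pool_cohort(cohort[cohort$subject_id %in% train_ids, ])
    for (met in config$methods) {
      key <- paste(mod, met, sep = "_")
      res <- tryCatch(
        {
          cm <- fit_cluster_model(pooled,
            method = met, n_bins = config$n_bins,
            seed = config$seed
          )
          feats <- habitat_features(cohort, cm)
          tbl <- feature_table(feats, records, modality = mod)
          features[[key]] <- tbl
          cluster_models[[key]] <- cm
          train_tbl <- tbl[tbl$split == "train", ]
          valid_tbl <- tbl[tbl$split == "validation", ]
          ev <- evaluate_model_set(
            train_tbl, valid_tbl, outcome,
            habitat_feature_names(mod), config$cv_seed
          )
          c(list(modality = mod, method = met, status = "ok",
                 threshold = cm$threshold), ev)
        },
        error = function(e) {
          list(
            modality = mod, method = met, status = "error",
            threshold = NA_real_, message = conditionMessage(e)
          )
        }
      )
      rows[[key]] <- res
    }
  }

  clinical <- tryCatch(
    c(
      list(modality = "clinical", method = "clinical", status = "ok",
           threshold = NA_real_),
      evaluate_model_set(
        records[records$split == "train", ],
        records[records$split == "validation", ],
        outcome, config$clinical_covariates, config$cv_seed
      )
    ),
    error = function(e) {
      list(modality = "clinical", method = "clinical", status = "error",
           threshold = NA_real_, message = conditionMessage(e))
    }
  )
  rows[["clinical"]] <- clinical

  results <- tibble::tibble(
    modality = unname(vapply(rows, `[[`, character(1), "modality")),
    method = unname(vapply(rows, `[[`, character(1), "method")),
    status = unname(vapply(rows, `[[`, character(1), "status")),
    threshold = unname(vapply(rows, `[[`, numeric(1), "threshold")),
    detail = unname(rows)
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("sarcohab")),
    seeds = list(
      generator = config$seed, split = config$split_seed, cv = config$cv_seed
    ),
    modalities = config$modalities,
    methods = config$methods,
    n_subjects = nrow(records),
    config_hash = rlang::hash(unclass_deep(config))
  )

  exp <- structure(
    list(
      subjects = records, features = features,
      cluster_models = cluster_models, results = results,
      config = config, manifest = manifest
    ),
    class = "habitat_experiment"
  )
  if (!is.null(output_dir)) {
    write_experiment(exp, output_dir)
  }
  exp
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

#' Tabulate experiment performance
#'
#' One row per model with training and validation AUC (95% CI), sensitivity,
#' specificity, accuracy, Youden index, cutoff and cross-validated mean AUC
#' — the standard comparison table for this protocol.
#'
#' @param experiment A `habitat_experiment`.
#' @return A tibble.
#' @export
auc_table <- function(experiment) {
  purrr::map_dfr(experiment$results$detail, function(d) {
    base <- tibble::tibble(
      modality = d$modality, method = d$method, status = d$status,
      threshold = d$threshold
    )
    if (d$status != "ok") {
      return(base)
    }
    add <- function(r, prefix) {
      out <- tibble::tibble(
        auc = r$auc, auc_low = r$ci[1], auc_high = r$ci[2],
        sensitivity = r$sensitivity, specificity = r$specificity,
        accuracy = r$accuracy, youden = r$youden, cutoff = r$cutoff
      )
      names(out) <- paste(prefix, names(out), sep = "_")
      out
    }
    dplyr::bind_cols(
      base, add(d$roc_train, "train"), add(d$roc_validation, "validation"),
      tibble::tibble(cv_mean_auc = d$cv$mean_auc)
    )
  })
}

#' @export
print.habitat_experiment <- function(x, ...) {
  cat(sprintf(
    "<habitat_experiment> %d subjects, %s; %s\n",
    nrow(x$subjects), paste(x$config$modalities, collapse = "+"),
    paste(x$config$methods, collapse = "/")
  ))
  tab <- auc_table(x)
  cols <- intersect(
    c("modality", "method", "status", "train_auc", "validation_auc",
      "cv_mean_auc"),
    names(tab)
  )
  print(tab[, cols])
  invisible(x)
}

write_experiment <- function(exp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(exp$subjects, file.path(dir, "subjects.csv"))
  for (key in names(exp$features)) {
    readr::write_csv(
      exp$features[[key]],
      file.path(dir, sprintf("features_%s.csv", key))
    )
  }
  for (key in names(exp$cluster_models)) {
    write_cluster_model(
      exp$cluster_models[[key]],
      file.path(dir, sprintf("cluster_model_%s.json", key))
    )
  }
  or_rows <- purrr::map_dfr(exp$results$detail, function(d) {
    if (d$status != "ok") return(NULL)
    dplyr::bind_cols(
      tibble::tibble(modality = d$modality, method = d$method),
      d$model$terms
    )
  })
  readr::write_csv(or_rows, file.path(dir, "odds_ratios.csv"))
  readr::write_csv(auc_table(exp), file.path(dir, "auc_table.csv"))
  jsonlite::write_json(exp$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
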