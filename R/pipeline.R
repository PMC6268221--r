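default_pipeline_config <- function() {
  list(
    dataset = list(n_di = 154, n_tri = 119, noise_sd = 0.3),
    n_test = NULL,              # default: round(n / 4)
    methods = c("rf", "cart", "cpgnn"),
    tasks = task_names(),
    rf = list(n_trees = 1000, mtry = 4),
    cart = list(min_split = 20, complexity = 0.01, cv_folds = 10),
    cpgnn = list(epochs = 100),
    seed = 7,
    out_dir = NULL,
    input = NULL                # path to an existing dataset instead of simulation
  )
}

#' Run the full spectra-to-structure pipeline
#'
#' Simulate (or load) a labelled dataset, perform the SOM-assisted 3:1
#' diversity split, train the requested methods for the nine tasks, and
#' evaluate internal and external performance: out-of-bag for the random
#' forest, seeded 10-fold cross-validation for the CPGNN, and both
#' resubstitution of the CV-pruned tree and explicit 10-fold
#' cross-validation for CART (the tree's internal column is reported under
#' both labels so neither convention is silently assumed). All randomness
#' derives from `config$seed`; rerunning with an identical configuration
#' reproduces every artifact byte for byte.
#'
#' @param config A (partial) list merged over the defaults; fields:
#'   `dataset` (`n_di`, `n_tri`, `noise_sd`), `input` (path to a dataset
#'   read with [read_dataset()] instead of simulating), `n_test` (default a
#'   quarter of the records), `methods` (subset of `"rf"`, `"cart"`,
#'   `"cpgnn"`), `tasks`, per-method parameter lists, `seed`, and `out_dir`
#'   for TSV/JSON artifacts. A YAML file path is also accepted.
#' @return A list of class `glyco_pipeline`: `records`, `split`, `models`,
#'   `reports` (named `task_report`s), `comparison` (tibble), `log`.
#' @examples
#' \donttest{
#' res <- run_pipeline(list(dataset = list(n_di = 20, n_tri = 20),
#'                          rf = list(n_trees = 100),
#'                          cpgnn = list(epochs = 20), seed = 1))
#' res$comparison
#' }
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  t0 <- Sys.time()

  records <- if (!is.null(cfg$input)) {
    read_dataset(cfg$input)
  } else {
    model <- increment_model(noise_sd = cfg$dataset$noise_sd)
    generate_dataset(n_di = cfg$dataset$n_di, n_tri = cfg$dataset$n_tri,
                     model = model, seed = cfg$seed)
  }
  if (anyNA(records[task_names()])) {
    abort("pipeline requires fully labelled records",
          class = "glyco_validation_error")
  }

  n_test <- cfg$n_test %||% round(nrow(records) / 4)
  split <- if (n_test > 0) {
    diversity_split(records, n_test = n_test, seed = cfg$seed)
  } else {
    list(train = records, test = records[0, ],
         train_ids = records$id, test_ids = character(0))
  }
  train <- split$train; test <- split$test

  models <- list()
  reports <- list()

  if ("rf" %in% cfg$methods) {
    models$rf <- lapply(setNames(cfg$tasks, cfg$tasks), function(t) {
      train_rf(train, task = t, n_trees = cfg$rf$n_trees,
               mtry = cfg$rf$mtry, seed = cfg$seed)
    })
    reports$rf_train_oob <- merge_reports(lapply(models$rf, oob_report))
    if (nrow(test) > 0) {
      reports$rf_test <- merge_reports(lapply(models$rf, evaluate_model,
                                              records = test))
    }
  }
  if ("cart" %in% cfg$methods) {
    models$cart <- lapply(setNames(cfg$tasks, cfg$tasks), function(t) {
      train_cart(train, task = t, min_split = cfg$cart$min_split,
                 complexity = cfg$cart$complexity,
                 cv_folds = cfg$cart$cv_folds, seed = cfg$seed)
    })
    reports$cart_train_resub <- merge_reports(lapply(models$cart,
                                                     evaluate_model,
                                                     records = train))
    reports$cart_train_cv <- cart_crossvalidate(train, tasks = cfg$tasks,
                                                cfg = cfg$cart,
                                                seed = cfg$seed)
    if (nrow(test) > 0) {
      reports$cart_test <- merge_reports(lapply(models$cart, evaluate_model,
                                                records = test))
    }
  }
  if ("cpgnn" %in% cfg$methods) {
    models$cpgnn <- train_cpgnn(train, epochs = cfg$cpgnn$epochs,
                                seed = cfg$seed)
    reports$cpgnn_train_cv <- cpgnn_crossvalidate(train,
                                                  epochs = cfg$cpgnn$epochs,
                                                  seed = cfg$seed)
    if (nrow(test) > 0) {
      reports$cpgnn_test <- evaluate_model(models$cpgnn, test)
    }
  }

  comparison <- compare_reports(reports)
  log <- list(
    seed = cfg$seed, n_records = nrow(records),
    n_train = nrow(train), n_test = nrow(test),
    methods = cfg$methods, tasks = cfg$tasks,
    config_hash = rlang::hash(cfg),
    package_version = as.character(utils::packageVersion("glycoshift")),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  out <- structure(list(records = records, split = split, models = models,
                        reports = reports, comparison = comparison, log = log),
                   class = "glyco_pipeline")
  if (!is.null(cfg$out_dir)) write_pipeline_artifacts(out, cfg$out_dir)
  out
}

#' @export
print.glyco_pipeline <- function(x, ...) {
  cat(sprintf("<glyco_pipeline> %d records (%d train / %d test), methods: %s\n",
              x$log$n_records, x$log$n_train, x$log$n_test,
              paste(x$log$methods, collapse = ", ")))
  print(x$comparison)
  invisible(x)
}

# stack single-task reports into one multi-task task_report
merge_reports <- function(reports) {
  summary <- purrr::map_dfr(reports, ~ .x$summary)
  mp <- purrr::map_dfr(reports, glance)
  confusions <- unlist(lapply(reports, `[[`, "confusions"), recursive = FALSE)
  names(confusions) <- summary$task[!duplicated(summary$task)]
  structure(list(summary = summary, mean_predictability = mp,
                 confusions = confusions),
            class = "task_report")
}

cart_crossvalidate <- function(records, tasks = task_names(),
                               cfg = list(min_split = 20, complexity = 0.01,
                                          cv_folds = 10),
                               folds = 10, seed = 1) {
  labels <- check_labels(records)
  n <- nrow(records)
  fold_id <- integer(n)
  ord <- withr::with_seed(as.integer(seed), {
    unlist(lapply(split(seq_len(n), labels$chain_type), sample),
           use.names = FALSE)
  })
  fold_id[ord] <- rep(seq_len(folds), length.out = n)
  single <- lapply(setNames(tasks, tasks), function(t) {
    pred <- character(n)
    for (f in seq_len(folds)) {
      hold <- fold_id == f
      fit <- train_cart(records[!hold, ], task = t,
                        min_split = cfg$min_split,
                        complexity = cfg$complexity,
                        cv_folds = cfg$cv_folds, seed = seed + f)
      pred[hold] <- predict(fit, records[hold, ])
    }
    task_report(labels[[t]], pred, task = t)
  })
  merge_reports(single)
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_dataset(res$split$train, file.path(out_dir, "train.tsv"))
  if (nrow(res$split$test) > 0) {
    write_dataset(res$split$test, file.path(out_dir, "test.tsv"))
  }
  for (nm in names(res$reports)) {
    readr::write_tsv(tidy(res$reports[[nm]]),
                     file.path(out_dir, paste0("report_", nm, ".tsv")),
                     progress = FALSE)
  }
  readr::write_tsv(res$comparison, file.path(out_dir, "comparison.tsv"),
                   progress = FALSE)
  jsonlite::write_json(res$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
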