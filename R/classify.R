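# Probabilistic classification of gene features onto the interaction-profile
# taxonomy: Random Forest (primary), Linear Discriminant Analysis and the
# deterministic matcher as baselines.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Predictor matrix in fixed schema order; unbounded t-statistics are capped
# so downstream fitters never see infinities.
feature_matrix <- function(features) {
  cols <- feature_columns()
  missing_cols <- setdiff(cols, colnames(features))
  if (length(missing_cols)) {
    stop("feature table lacks column(s): ", paste(missing_cols, collapse = ", "),
         " (schema mismatch)")
  }
  m <- as.matrix(features[, cols])
  m[m > 1e6] <- 1e6
  m[m < -1e6] <- -1e6
  m
}

#' Train a taxonomy classifier
#'
#' Fits a probabilistic classifier mapping the 19 gene features to the 123
#' taxonomy profiles. Supported model kinds: `"random_forest"` (probability
#' forest; the primary model), `"lda"` (linear discriminant analysis
#' baseline) and `"deterministic"` (the tolerance-based deterministic matcher
#' applied to the estimated means, producing one-hot probabilities; requires
#' no training data).
#'
#' @param features tibble containing the 19 feature columns (extra columns
#'   are ignored). May be `NULL` for `model_kind = "deterministic"`.
#' @param labels integer vector of true profile ids, one per feature row.
#' @param taxonomy a `cs_taxonomy`; defines the class set.
#' @param model_kind one of `"random_forest"`, `"lda"`, `"deterministic"`.
#' @param hyperparams list; for the forest: `num_trees` (default 500), `mtry`
#'   (default floor(sqrt(19))); for the matcher: `tolerance` (default: the
#'   taxonomy's).
#' @param seed integer seed (mandatory for the forest's reproducibility).
#' @return object of class `cs_classifier`.
#' @export
train_classifier <- function(features, labels, taxonomy,
                             model_kind = c("random_forest", "lda",
                                            "deterministic"),
                             hyperparams = list(), seed = NULL) {
  stopifnot(inherits(taxonomy, "cs_taxonomy"))
  model_kind <- match.arg(model_kind)
  classes <- taxonomy$profiles$id

  meta <- list(seed = seed, hyperparams = hyperparams,
               schema = features_schema_version)
  if (model_kind == "deterministic") {
    fit <- list(tolerance = hyperparams$tolerance %||% taxonomy$tolerance)
  } else {
    stopifnot(!is.null(features), !is.null(labels),
              nrow(features) == length(labels))
    unknown <- setdiff(unique(labels), classes)
    if (length(unknown)) {
      stop("labels contain unknown profile id(s): ",
           paste(sort(unknown), collapse = ", "))
    }
    absent <- setdiff(classes, unique(labels))
    if (length(absent)) {
      stop("no training instances for profile id(s): ",
           paste(sort(absent), collapse = ", "))
    }
    fm <- feature_matrix(features)
    y <- factor(labels, levels = classes)
    meta$n_per_class <- as.integer(table(y))
    if ("regime" %in% colnames(features)) {
      meta$regimes <- sort(unique(features$regime))
    }
    if (model_kind == "random_forest") {
      # subsampled probability forest: each tree sees a 25% draw of the
      # training set, which regularises the class probabilities and keeps
      # training tractable at the default 123 x 3 x 400 training size
      fit <- ranger::ranger(
        x = fm, y = y, probability = TRUE,
        num.trees = hyperparams$num_trees %||% 500,
        mtry = hyperparams$mtry %||% floor(sqrt(ncol(fm))),
        sample.fraction = hyperparams$sample_fraction %||% 0.25,
        min.node.size = hyperparams$min_node_size %||% 10,
        seed = seed, num.threads = 1, verbose = FALSE
      )
    } else {
      df <- as.data.frame(fm)
      fit <- suppressWarnings(MASS::lda(x = df, grouping = y))
    }
  }
  structure(
    list(model_kind = model_kind, fit = fit, classes = classes,
         taxonomy = if (model_kind == "deterministic") taxonomy else NULL,
         meta = meta),
    class = "cs_classifier"
  )
}

#' Class probabilities over the taxonomy
#'
#' @param model a `cs_classifier`.
#' @param features feature tibble (19 schema columns).
#' @return numeric matrix, one row per input row and one column per profile id
#'   (id order); rows are nonnegative and sum to 1.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "cs_classifier"))
  fm <- feature_matrix(features)
  cls <- as.character(model$classes)
  if (model$model_kind == "deterministic") {
    ids <- match_deterministic(fm[, c("m_e0", "m_eX", "m_eY", "m_eXY"),
                                  drop = FALSE],
                               model$taxonomy,
                               tolerance = model$fit$tolerance)
    P <- matrix(0, nrow(fm), length(cls), dimnames = list(NULL, cls))
    P[cbind(seq_len(nrow(fm)), match(ids, model$classes))] <- 1
  } else if (model$model_kind == "random_forest") {
    P <- stats::predict(model$fit, data = fm, num.threads = 1)$predictions
  } else {
    P <- stats::predict(model$fit, newdata = as.data.frame(fm))$posterior
  }
  P <- P[, cls, drop = FALSE]
  sw <- rowSums(P)
  P / ifelse(sw > 0, sw, 1)
}

#' Predict profiles (and their class probability)
#'
#' @param object a `cs_classifier`.
#' @param features feature tibble.
#' @param type `"class"` for a tibble of predicted ids and probabilities,
#'   `"prob"` for the full probability matrix.
#' @param ... unused.
#' @return tibble with `profile_id` (argmax; probability ties resolved to the
#'   lowest id) and `p` (probability of the predicted class), or the
#'   probability matrix.
#' @export
predict.cs_classifier <- function(object, features, type = c("class", "prob"),
                                  ...) {
  type <- match.arg(type)
  P <- predict_proba(object, features)
  if (type == "prob") return(P)
  best <- max.col(P, ties.method = "first")
  tibble::tibble(
    profile_id = object$classes[best],
    p = P[cbind(seq_len(nrow(P)), best)]
  )
}

#' Evaluate a classifier on a labelled test set
#'
#' Computes overall and per-profile accuracy, the multiclass log gain (mean
#' negative log-probability assigned to the true class, probability floored
#' at 1e-15), and per-profile precision and recall.
#'
#' @param model a `cs_classifier`.
#' @param features labelled test features.
#' @param labels true profile ids.
#' @return object of class `cs_evaluation` with elements `overall_accuracy`,
#'   `macro_accuracy`, `log_gain`, `per_class` (tibble: profile_id, n,
#'   accuracy, precision, recall) and `confusion` (tibble of counts).
#' @export
evaluate_classifier <- function(model, features, labels) {
  stopifnot(nrow(features) >= 1, length(labels) == nrow(features))
  if (length(setdiff(unique(labels), model$classes))) {
    stop("test labels contain unknown profile id(s)")
  }
  P <- predict_proba(model, features)
  best <- max.col(P, ties.method = "first")
  pred <- model$classes[best]
  p_true <- P[cbind(seq_along(labels), match(labels, model$classes))]
  log_gain <- mean(-log(pmax(p_true, 1e-15)))

  cls <- model$classes
  truth <- factor(labels, levels = cls)
  predf <- factor(pred, levels = cls)
  conf <- table(truth = truth, pred = predf)
  tp <- diag(conf)
  n_true <- rowSums(conf)
  n_pred <- colSums(conf)
  per_class <- tibble::tibble(
    profile_id = cls,
    n = as.integer(n_true),
    accuracy = ifelse(n_true > 0, tp / n_true, NA_real_),
    precision = ifelse(n_pred > 0, tp / n_pred, NA_real_),
    recall = ifelse(n_true > 0, tp / n_true, NA_real_)
  )
  conf_tbl <- tibble::as_tibble(as.data.frame(conf, stringsAsFactors = FALSE))
  conf_tbl <- conf_tbl[conf_tbl$Freq > 0, ]
  structure(
    list(
      overall_accuracy = mean(pred == labels),
      macro_accuracy = mean(per_class$accuracy, na.rm = TRUE),
      log_gain = log_gain,
      per_class = per_class,
      confusion = tibble::tibble(
        truth = as.integer(as.character(conf_tbl$truth)),
        pred = as.integer(as.character(conf_tbl$pred)),
        n = conf_tbl$Freq
      ),
      model_kind = model$model_kind,
      n = length(labels)
    ),
    class = "cs_evaluation"
  )
}

#' @export
print.cs_evaluation <- function(x, ...) {
  cat(sprintf(
    "Classifier evaluation (%s, n = %d)\n  accuracy %.3f (macro %.3f), log gain %.3f\n",
    x$model_kind, x$n, x$overall_accuracy, x$macro_accuracy, x$log_gain))
  invisible(x)
}

#' Tidy per-class evaluation metrics
#' @param x a `cs_evaluation`.
#' @param ... unused.
#' @return tibble with one row per profile: accuracy, precision, recall.
#' @export
tidy.cs_evaluation <- function(x, ...) x$per_class

#' One-row evaluation summary
#' @param x a `cs_evaluation`.
#' @param ... unused.
#' @return tibble with overall/macro accuracy, log gain and n.
#' @export
glance.cs_evaluation <- function(x, ...) {
  tibble::tibble(
    model_kind = x$model_kind,
    accuracy = x$overall_accuracy,
    macro_accuracy = x$macro_accuracy,
    log_gain = x$log_gain,
    median_precision = stats::median(x$per_class$precision, na.rm = TRUE),
    median_recall = stats::median(x$per_class$recall, na.rm = TRUE),
    n = x$n
  )
}

#' @export
print.cs_classifier <- function(x, ...) {
  cat("Taxonomy classifier:", x$model_kind, "over", length(x$classes),
      "profiles\n")
  invisible(x)
}

#' Compare classifiers across noise regimes
#'
#' Evaluates each model on each regime's shared test set and tabulates
#' accuracy, macro accuracy, log gain and median precision/recall.
#'
#' @param models named list of `cs_classifier` objects.
#' @param test_sets named list (one element per regime) of lists with
#'   elements `features` and `labels`.
#' @return tibble with one row per (model, regime).
#' @export
compare_models <- function(models, test_sets) {
  stopifnot(length(models) >= 1, length(test_sets) >= 1)
  purrr::map_dfr(names(models), function(mn) {
    purrr::map_dfr(names(test_sets), function(rg) {
      ev <- evaluate_classifier(models[[mn]], test_sets[[rg]]$features,
                                test_sets[[rg]]$labels)
      dplyr::bind_cols(tibble::tibble(model = mn, regime = rg),
                       glance(ev)[, -1])
    })
  })
}

#' Serialise / restore a trained classifier
#'
#' @param model a `cs_classifier`.
#' @param path file path for the model artifact.
#' @return `save_classifier()`: `path`, invisibly; `load_classifier()`: the
#'   restored `cs_classifier`.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "cs_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cs_classifier")) stop("not a classifier artifact: ", path)
  model
}
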