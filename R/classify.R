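# Signature-based disease-stage classification: feature assembly from
# exposure tables (optionally resolved by clonality/timing compartment) and a
# train/validate pipeline with cross-validated hyperparameters, one-vs-rest
# AUC and permutation feature importance.

#' Assemble stage-classification features
#'
#' `overall` mode: one column per signature exposure plus the sample's
#' subclonal fraction and early fraction (share of timed mutations labelled
#' clonal-early). `compartment_split` mode: one column per signature and
#' compartment (clonal_early, clonal_late, subclonal). Missing compartments
#' contribute zeros plus a missingness indicator column.
#'
#' @param exposures `exposure_table` of overall exposures.
#' @param clonality Optional `clonality_assignment` (for subclonal/early
#'   fractions in `overall` mode).
#' @param compartment_exposures Named list of `exposure_table`s keyed by
#'   compartment (for `compartment_split` mode).
#' @param mode `"overall"` or `"compartment_split"`.
#' @return Tibble `sample` + numeric feature columns, aligned to
#'   `exposures$sample` order.
#' @export
build_stage_features <- function(exposures, clonality = NULL,
                                 compartment_exposures = NULL,
                                 mode = c("overall", "compartment_split")) {
  mode <- match.arg(mode)
  sigs <- attr(exposures, "signatures") %||% setdiff(names(exposures),
    c("sample", "n_mutations", "residual", "flag"))
  samples <- exposures$sample
  if (mode == "overall") {
    out <- tibble::as_tibble(exposures)[c("sample", sigs)]
    if (!is.null(clonality)) {
      sm <- clonality$samples
      early <- clonality$mutations |>
        dplyr::group_by(sample = .data$sample_id) |>
        dplyr::summarise(early_fraction = mean(.data$timing == "clonal_early"),
                         .groups = "drop")
      out <- out |>
        dplyr::left_join(sm[c("sample", "subclonal_fraction")], by = "sample") |>
        dplyr::left_join(early, by = "sample") |>
        dplyr::mutate(subclonal_fraction = tidyr::replace_na(.data$subclonal_fraction, 0),
                      early_fraction = tidyr::replace_na(.data$early_fraction, 0))
    } else {
      out$subclonal_fraction <- 0
      out$early_fraction <- 0
      out$clonality_missing <- 1
    }
    out
  } else {
    comps <- c("clonal_early", "clonal_late", "subclonal")
    out <- tibble::tibble(sample = samples)
    for (cp in comps) {
      tab <- compartment_exposures[[cp]]
      if (is.null(tab)) {
        for (s in sigs) out[[paste(s, cp, sep = "_")]] <- 0
        out[[paste0("missing_", cp)]] <- 1
      } else {
        sub <- tibble::as_tibble(tab)[c("sample", intersect(sigs, names(tab)))]
        names(sub)[-1] <- paste(names(sub)[-1], cp, sep = "_")
        out <- dplyr::left_join(out, sub, by = "sample")
        miss <- !stats::complete.cases(out[grep(paste0("_", cp, "$"), names(out))])
        out[is.na(out)] <- 0
        if (any(miss)) out[[paste0("missing_", cp)]] <- as.numeric(miss)
      }
    }
    out
  }
}

learner_spec <- function(learner, n_classes, cv_folds) {
  switch(learner,
    boosted_trees = list(
      grid = tidyr::expand_grid(eta = c(0.1, 0.3), max_depth = c(2L, 4L),
                                nrounds = 60L),
      train = function(x, y, params) {
        xgboost::xgboost(x, y, nrounds = params$nrounds,
                         max_depth = params$max_depth,
                         learning_rate = params$eta,
                         nthreads = 1, verbosity = 0)
      },
      predict = function(model, x) {
        p <- stats::predict(model, x, type = "response")
        if (is.matrix(p)) p else cbind(1 - p, p)  # binary: P(second level)
      }),
    random_forest = list(
      grid = tibble::tibble(mtry = c(2L, 4L)),
      train = function(x, y, params) {
        randomForest::randomForest(x, y, ntree = 300,
                                   mtry = min(params$mtry, ncol(x)))
      },
      predict = function(model, x) {
        unclass(stats::predict(model, x, type = "prob"))
      }),
    multinomial_logit = list(
      grid = tibble::tibble(alpha = 0),
      train = function(x, y, params) {
        cv <- glmnet::cv.glmnet(x, y, family = "multinomial",
                                alpha = params$alpha, nfolds = max(cv_folds, 3))
        cv
      },
      predict = function(model, x) {
        p <- stats::predict(model, x, s = "lambda.min", type = "response")
        p[, , 1]
      }),
    abort(sprintf("unknown learner '%s'", learner))
  )
}

macro_auc <- function(y, prob, classes) {
  aucs <- vapply(seq_along(classes), function(k) {
    resp <- as.integer(y == classes[k])
    if (length(unique(resp)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(resp, prob[, k], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, numeric(1))
  names(aucs) <- classes
  aucs
}

#' Train and validate a disease-stage classifier
#'
#' Stratified 70/30 discovery/validation split; hyperparameters chosen by
#' repeated k-fold cross-validation on the discovery set (mean held-out
#' multiclass accuracy over `cv_iters` repetitions); the final model is
#' refitted on the full discovery set and evaluated on the held-out 30% with
#' one-vs-rest AUC (macro-averaged across classes) and permutation feature
#' importance (mean AUC drop over `n_perm` permutations of each feature
#' column on the held-out set). Learners are pluggable: a learner is a list
#' with a hyperparameter `grid` tibble and `train(x, y, params)` /
#' `predict(model, x)` functions returning class-probability columns.
#'
#' @param features Tibble from [build_stage_features()] (`sample` + numeric
#'   columns).
#' @param labels Factor (or character) of stage labels aligned with
#'   `features` rows; at least 2 classes.
#' @param learner `"boosted_trees"`, `"random_forest"`,
#'   `"multinomial_logit"`, or a custom learner list.
#' @param split Discovery fraction (default 0.70).
#' @param cv_folds Cross-validation folds (default 5).
#' @param cv_iters Cross-validation repetitions (default 100; reduce for
#'   small cohorts or quick runs).
#' @param n_perm Permutations per feature for importance (default 5).
#' @param seed Seed controlling split, folds and permutations.
#' @return Object of class `stage_model` with `auc` (macro), `auc_per_class`,
#'   `importance`, `confusion`, `cv` (config echo) and the fitted model.
#' @export
train_stage_model <- function(features, labels,
                              learner = c("boosted_trees", "random_forest",
                                          "multinomial_logit"),
                              split = 0.70, cv_folds = 5L, cv_iters = 100L,
                              n_perm = 5L, seed = 1L) {
  if (is.character(learner)) learner <- match.arg(learner)
  y <- factor(labels)
  classes <- levels(y)
  if (length(classes) < 2) abort("need at least 2 classes")
  x <- as.matrix(features[setdiff(names(features), "sample")])
  storage.mode(x) <- "double"
  counts <- table(y)
  if (min(counts) < 2 * cv_folds)
    abort(paste("too few samples per class for this configuration;",
                "reduce `cv_folds`/`cv_iters` or supply more samples"))
  set.seed(seed)
  spec <- if (is.list(learner)) learner
          else learner_spec(learner, length(classes), cv_folds)
  # stratified split
  train_idx <- unlist(lapply(classes, function(k) {
    i <- which(y == k)
    sample(i, max(1L, round(split * length(i))))
  }))
  x_tr <- x[train_idx, , drop = FALSE]; y_tr <- y[train_idx]
  x_te <- x[-train_idx, , drop = FALSE]; y_te <- y[-train_idx]

  grid <- spec$grid
  if (nrow(grid) > 1) {
    scores <- vapply(seq_len(nrow(grid)), function(gi) {
      params <- as.list(grid[gi, ])
      accs <- replicate(cv_iters, {
        folds <- sample(rep_len(seq_len(cv_folds), length(y_tr)))
        mean(vapply(seq_len(cv_folds), function(f) {
          tr <- folds != f
          m <- spec$train(x_tr[tr, , drop = FALSE], droplevels(y_tr[tr]), params)
          p <- spec$predict(m, x_tr[!tr, , drop = FALSE])
          mean(classes[max.col(p)] == as.character(y_tr[!tr]))
        }, numeric(1)))
      })
      mean(accs)
    }, numeric(1))
    best <- as.list(grid[which.max(scores), ])
  } else best <- as.list(grid[1, ])

  model <- spec$train(x_tr, y_tr, best)
  prob <- spec$predict(model, x_te)
  colnames(prob) <- classes
  auc_k <- macro_auc(y_te, prob, classes)
  auc <- mean(auc_k, na.rm = TRUE)
  pred <- factor(classes[max.col(prob)], levels = classes)
  confusion <- table(truth = y_te, predicted = pred)
  # permutation importance: AUC drop on the held-out set
  imp <- vapply(seq_len(ncol(x)), function(j) {
    drops <- replicate(n_perm, {
      xp <- x_te
      xp[, j] <- sample(xp[, j])
      auc - mean(macro_auc(y_te, {
        p <- spec$predict(model, xp); colnames(p) <- classes; p
      }, classes), na.rm = TRUE)
    })
    mean(drops)
  }, numeric(1))
  importance <- tibble::tibble(feature = colnames(x), importance = imp) |>
    dplyr::arrange(dplyr::desc(.data$importance))
  structure(list(learner = if (is.list(learner)) "custom" else learner,
                 auc = auc, auc_per_class = auc_k, importance = importance,
                 confusion = confusion, best_params = best,
                 cv = list(split = split, cv_folds = cv_folds,
                           cv_iters = cv_iters, seed = seed),
                 classes = classes, model = model,
                 n_train = length(train_idx), n_test = length(y_te)),
            class = "stage_model")
}

#' @export
print.stage_model <- function(x, ...) {
  cat("<stage_model>", x$learner, "|", paste(x$classes, collapse = " vs "), "\n")
  cat(sprintf("  held-out macro AUC %.3f (n_train %d, n_test %d)\n",
              x$auc, x$n_train, x$n_test))
  cat("  top features:", paste(head(x$importance$feature, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.stage_model <- function(x, ...) x$importance

#' @export
glance.stage_model <- function(x, ...) {
  tibble::tibble(learner = x$learner, auc = x$auc,
                 n_train = x$n_train, n_test = x$n_test,
                 cv_folds = x$cv$cv_folds, cv_iters = x$cv$cv_iters)
}
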