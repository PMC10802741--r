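#' Matthews correlation coefficient of a 2x2 confusion
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as 0 when
#' any marginal is zero.
#'
#' @param tp,tn,fp,fn non-negative confusion counts; alternatively pass a
#'   2x2 matrix as `tp` with layout `rbind(c(TP, FN), c(FP, TN))`.
#' @return value in [-1, 1].
#' @export
mcc <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.matrix(tp)) {
    m <- tp; tp <- m[1, 1]; fn <- m[1, 2]; fp <- m[2, 1]; tn <- m[2, 2]
  }
  stopifnot(all(c(tp, tn, fp, fn) >= 0))
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Patient-grouped, class-stratified cross-validation folds
#'
#' Groups (patients) are assigned whole to folds -- no patient's samples
#' ever span training and test of a split -- by a greedy balancer: groups
#' are visited from largest to smallest (ties broken by a seeded shuffle)
#' and each goes to the fold where it least disturbs the per-fold class
#' targets `class_total / k`.
#'
#' @param labels binary outcome per sample (factor or character).
#' @param groups group (patient) id per sample.
#' @param k number of folds.
#' @param seed integer seed (tie-breaking only; the plan is deterministic
#'   given the seed).
#' @return An `lnr_folds` list: `fold` (integer per sample), `group_fold`
#'   tibble, `k`, `seed`.
#' @export
make_grouped_stratified_folds <- function(labels, groups, k = 5, seed = 1L) {
  labels <- as.character(labels)
  groups <- as.character(groups)
  stopifnot(length(labels) == length(groups), k >= 2)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stopf("need exactly two classes")
  n_groups <- length(unique(groups))
  if (k > n_groups) stopf("k = %d exceeds the %d groups", k, n_groups)
  for (cl in classes) {
    if (length(unique(groups[labels == cl])) < 2)
      stopf("class '%s' is confined to one group; folds would lose it", cl)
  }
  cnt <- table(factor(groups), factor(labels, classes))
  target <- colSums(cnt) / k
  ord <- with_seed(seed, {
    sizes <- rowSums(cnt)
    order(-sizes, sample(nrow(cnt)))
  })
  fold_cnt <- matrix(0, k, 2)
  assign <- integer(nrow(cnt))
  for (gi in ord) {
    cost <- vapply(seq_len(k), function(f)
      sum((fold_cnt[f, ] + cnt[gi, ] - target)^2), 0)
    # ties go to the emptiest fold, not the lowest index
    f <- order(cost, rowSums(fold_cnt))[1]
    assign[gi] <- f
    fold_cnt[f, ] <- fold_cnt[f, ] + cnt[gi, ]
  }
  group_fold <- tibble::tibble(group = rownames(cnt), fold = assign)
  fold <- assign[match(groups, rownames(cnt))]
  structure(list(fold = fold, group_fold = group_fold, k = k, seed = seed,
                 labels = labels, groups = groups),
            class = "lnr_folds")
}

#' The classifier zoo for response prediction
#'
#' Named model specifications (fit/predict closures plus a small
#' hyperparameter grid) delegating to standard implementations: logistic
#' regression, linear discriminant analysis, gradient-boosted trees,
#' random forest, k-nearest neighbours, linear and radial kernel machines,
#' a single-hidden-layer neural network, naive Bayes, boosted stumps and a
#' boosted additive (linear-booster) model.
#'
#' @param names subset of models to return; default all eleven.
#' @return named list of model specs for [nested_cv()].
#' @export
model_zoo <- function(names = NULL) {
  mk_xgb <- function(booster = "gbtree", max_depth = 3) {
    list(
      grid = list(list(nrounds = 30), list(nrounds = 60)),
      fit = function(x, y, p) {
        args <- list(x = as.matrix(x), y = y, nrounds = p$nrounds,
                     verbosity = 0, nthreads = 1, seed = 1,
                     booster = booster)
        if (booster == "gbtree") args$max_depth <- max_depth
        do.call(xgboost::xgboost, args)
      },
      predict = function(m, x)
        as.integer(predict(m, as.matrix(x), type = "class"))
    )
  }
  zoo <- list(
    glm = list(
      grid = list(list()),
      fit = function(x, y, p)
        suppressWarnings(stats::glm(y ~ ., data.frame(x, y = y),
                                    family = stats::binomial())),
      predict = function(m, x)
        as.integer(predict(m, data.frame(x), type = "response") > 0.5) + 1L
    ),
    lda = list(
      grid = list(list()),
      fit = function(x, y, p) MASS::lda(as.matrix(x), grouping = y),
      predict = function(m, x) as.integer(predict(m, as.matrix(x))$class)
    ),
    xgb_tree = mk_xgb("gbtree", max_depth = 3),
    random_forest = list(
      grid = list(list(num.trees = 200)),
      fit = function(x, y, p)
        ranger::ranger(y = y, x = data.frame(x), num.trees = p$num.trees,
                       num.threads = 1, seed = 1),
      predict = function(m, x)
        as.integer(predict(m, data.frame(x),
                           num.threads = 1)$predictions)
    ),
    knn = list(
      grid = list(list(k = 3), list(k = 7)),
      fit = function(x, y, p) list(x = as.matrix(x), y = y, k = p$k),
      predict = function(m, x)
        as.integer(class::knn(m$x, as.matrix(x), m$y, k = m$k))
    ),
    svm_linear = list(
      grid = list(list(cost = 1)),
      fit = function(x, y, p)
        e1071::svm(as.matrix(x), y, kernel = "linear", cost = p$cost),
      predict = function(m, x) as.integer(predict(m, as.matrix(x)))
    ),
    svm_radial = list(
      grid = list(list(cost = 1), list(cost = 10)),
      fit = function(x, y, p)
        e1071::svm(as.matrix(x), y, kernel = "radial", cost = p$cost),
      predict = function(m, x) as.integer(predict(m, as.matrix(x)))
    ),
    neural_net = list(
      grid = list(list(size = 3, decay = 0.1)),
      fit = function(x, y, p)
        nnet::nnet(as.matrix(x), class.ind_(y), size = p$size,
                   decay = p$decay, softmax = TRUE, trace = FALSE,
                   maxit = 200),
      predict = function(m, x)
        max.col(predict(m, as.matrix(x)))
    ),
    naive_bayes = list(
      grid = list(list()),
      fit = function(x, y, p) e1071::naiveBayes(data.frame(x), y),
      predict = function(m, x) as.integer(predict(m, data.frame(x)))
    ),
    boosted_stumps = mk_xgb("gbtree", max_depth = 1),
    boosted_additive = mk_xgb("gblinear")
  )
  if (!is.null(names)) {
    bad <- setdiff(names, base::names(zoo))
    if (length(bad)) stopf("unknown models: %s", paste(bad, collapse = ", "))
    zoo <- zoo[names]
  }
  zoo
}

class.ind_ <- function(y) {
  y <- as.factor(y)
  m <- matrix(0, length(y), nlevels(y),
              dimnames = list(NULL, levels(y)))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}

#' Patient-grouped stratified nested cross-validation scored by MCC
#'
#' Outer loop: `k_outer` grouped class-balanced folds; inner loop on each
#' outer training set: `k_inner`-fold grouped CV repeated `inner_reps` times
#' with fresh fold randomizations, selecting each model's hyperparameters by
#' mean inner MCC; the tuned model is refit on the full outer-train and
#' scored by MCC on the held-out outer fold. Models are ranked by their mean
#' outer MCC. Patients never span the train/test side of any split.
#'
#' @param features samples x features matrix or data frame.
#' @param labels binary outcome per sample.
#' @param groups patient id per sample.
#' @param models model list from [model_zoo()].
#' @param k_outer,k_inner,inner_reps fold plan (defaults 5, 10, 5).
#' @param seed integer seed controlling every fold randomization.
#' @return An `lnr_cv` list: `report` tibble (model, mean_mcc, fold MCCs and
#'   chosen hyperparameters per outer fold), `folds` (the outer plan),
#'   ranked by mean MCC.
#' @export
nested_cv <- function(features, labels, groups, models = model_zoo(),
                      k_outer = 5, k_inner = 10, inner_reps = 5, seed = 1L) {
  if (!length(models)) stopf("model grid is empty")
  x <- as.data.frame(features)
  y <- factor(as.character(labels))
  stopifnot(nrow(x) == length(y), length(groups) == length(y))
  outer <- make_grouped_stratified_folds(y, groups, k_outer, seed)

  eval_setting <- function(spec, p, xtr, ytr, xte, yte) {
    fit <- spec$fit(xtr, ytr, p)
    pred <- spec$predict(fit, xte)
    conf <- table(factor(as.integer(yte), 1:2), factor(pred, 1:2))
    mcc(conf[2, 2], conf[1, 1], conf[1, 2], conf[2, 1])
  }

  rows <- list()
  for (mn in names(models)) {
    spec <- models[[mn]]
    fold_mcc <- rep(NA_real_, k_outer)
    chosen <- vector("list", k_outer)
    for (f in seq_len(k_outer)) {
      tr <- outer$fold != f
      if (all(tr) || !any(tr)) {
        warnf("outer fold %d is empty; skipped", f)
        next
      }
      if (length(unique(y[tr])) < 2) {
        warnf("outer fold %d: single-class training set; skipped", f)
        next
      }
      if (length(spec$grid) > 1) {
        inner_scores <- vapply(seq_along(spec$grid), function(pi) {
          p <- spec$grid[[pi]]
          reps <- vapply(seq_len(inner_reps), function(r) {
            ki <- min(k_inner, length(unique(groups[tr])))
            inner <- tryCatch(
              make_grouped_stratified_folds(y[tr], groups[tr], ki,
                                            seed + 1000L * r + f),
              error = function(e) NULL)
            if (is.null(inner)) return(NA_real_)
            ms <- vapply(seq_len(ki), function(g) {
              itr <- inner$fold != g
              if (all(itr) || !any(itr)) return(NA_real_)
              if (length(unique(y[tr][itr])) < 2) return(NA_real_)
              tryCatch(
                eval_setting(spec, p, x[tr, , drop = FALSE][itr, , drop = FALSE],
                             y[tr][itr],
                             x[tr, , drop = FALSE][!itr, , drop = FALSE],
                             y[tr][!itr]),
                error = function(e) NA_real_)
            }, 0)
            mean(ms, na.rm = TRUE)
          }, 0)
          mean(reps, na.rm = TRUE)
        }, 0)
        best <- which.max(inner_scores)
      } else best <- 1L
      chosen[[f]] <- spec$grid[[best]]
      fold_mcc[f] <- eval_setting(spec, spec$grid[[best]],
                                  x[tr, , drop = FALSE], y[tr],
                                  x[!tr, , drop = FALSE], y[!tr])
    }
    rows[[mn]] <- tibble::tibble(
      model = mn,
      mean_mcc = mean(fold_mcc, na.rm = TRUE),
      fold_mcc = list(fold_mcc),
      chosen_params = list(chosen))
  }
  report <- dplyr::arrange(purrr::list_rbind(rows), dplyr::desc(.data$mean_mcc))
  structure(list(report = report, folds = outer, seed = seed),
            class = "lnr_cv")
}

#' @export
print.lnr_cv <- function(x, ...) {
  cat("<lnr_cv> models ranked by mean outer MCC:\n")
  print(x$report[, c("model", "mean_mcc")])
  invisible(x)
}
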