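#' Classifier registry for the voting ensemble
#'
#' A diverse set of binary classifiers spanning the major families: linear
#' models (logistic, ridge), discriminant analysis (LDA, QDA), support
#' vector machines (linear, RBF, nu-SVM), Gaussian naive Bayes, Gaussian
#' process, nearest neighbor (kNN, nearest centroid), and tree ensembles
#' (random forest, extremely randomized trees, gradient boosting). Each
#' entry provides \code{fit(x, y, pars)}, \code{predict(model, x)} and
#' \code{sample_pars(void)} for the budgeted random hyperparameter search.
#' The registry is configurable by name: third-party classifier behavior is
#' version-dependent, and the ensemble's claims rest on aggregate
#' (weighted-vote) properties, not any single member.
#'
#' @param names optional character subset of registry names.
#' @return named list of classifier definitions.
#' @export
classifier_registry <- function(names = NULL) {
  lev <- c("Intact", "Scrambled")
  as_f <- function(y) factor(y, levels = lev)
  reg <- list(
    logistic = list(
      fit = function(x, y, pars) {
        df <- data.frame(y = as_f(y) == "Intact", x)
        suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
      },
      predict = function(m, x)
        ifelse(suppressWarnings(
          stats::predict(m, newdata = data.frame(x), type = "response")) > 0.5,
          "Intact", "Scrambled"),
      sample_pars = function() list()),
    ridge = list(
      fit = function(x, y, pars) {
        lam <- pars$lambda %||% 0.1
        glmnet::glmnet(x, as_f(y), family = "binomial", alpha = 0,
                       lambda = lam)
      },
      predict = function(m, x)
        as.character(stats::predict(m, as.matrix(x), type = "class")),
      sample_pars = function() list(lambda = 10^stats::runif(1, -3, 1))),
    lda = list(
      fit = function(x, y, pars) MASS::lda(x, as_f(y)),
      predict = function(m, x) as.character(stats::predict(m, x)$class),
      sample_pars = function() list()),
    qda = list(
      fit = function(x, y, pars) MASS::qda(x, as_f(y)),
      predict = function(m, x) as.character(stats::predict(m, x)$class),
      sample_pars = function() list()),
    svm_linear = list(
      fit = function(x, y, pars)
        e1071::svm(x, as_f(y), kernel = "linear",
                   cost = pars$cost %||% 1, scale = FALSE),
      predict = function(m, x) as.character(stats::predict(m, x)),
      sample_pars = function() list(cost = 10^stats::runif(1, -2, 2))),
    svm_rbf = list(
      fit = function(x, y, pars)
        e1071::svm(x, as_f(y), kernel = "radial",
                   cost = pars$cost %||% 1,
                   gamma = pars$gamma %||% (1 / ncol(x)), scale = FALSE),
      predict = function(m, x) as.character(stats::predict(m, x)),
      sample_pars = function() list(cost = 10^stats::runif(1, -2, 2),
                                    gamma = 10^stats::runif(1, -3, 1))),
    nu_svm = list(
      fit = function(x, y, pars)
        e1071::svm(x, as_f(y), type = "nu-classification",
                   nu = pars$nu %||% 0.4, kernel = "radial", scale = FALSE),
      predict = function(m, x) as.character(stats::predict(m, x)),
      sample_pars = function() list(nu = stats::runif(1, 0.15, 0.55))),
    gaussian_nb = list(
      fit = function(x, y, pars) e1071::naiveBayes(x, as_f(y)),
      predict = function(m, x) as.character(stats::predict(m, x)),
      sample_pars = function() list()),
    knn = list(
      fit = function(x, y, pars)
        list(x = x, y = as_f(y), k = pars$k %||% 3),
      predict = function(m, x)
        as.character(class::knn(m$x, x, m$y, k = min(m$k, nrow(m$x)))),
      sample_pars = function() list(k = sample(c(1L, 3L, 5L, 7L), 1))),
    nearest_centroid = list(
      fit = function(x, y, pars) {
        y <- as_f(y)
        list(centroids = rbind(Intact = colMeans(x[y == "Intact", ,
                                                   drop = FALSE]),
                               Scrambled = colMeans(x[y == "Scrambled", ,
                                                      drop = FALSE])))
      },
      predict = function(m, x) {
        d <- apply(m$centroids, 1, function(ct)
          rowSums((sweep(as.matrix(x), 2, ct))^2))
        if (is.null(dim(d))) d <- matrix(d, nrow = 1,
                                         dimnames = list(NULL, names(d)))
        colnames(d)[max.col(-d, ties.method = "last")]
      },
      sample_pars = function() list()),
    random_forest = list(
      fit = function(x, y, pars)
        randomForest::randomForest(x, as_f(y),
                                   ntree = pars$ntree %||% 100,
                                   mtry = pars$mtry %||%
                                     max(1, floor(sqrt(ncol(x))))),
      predict = function(m, x) as.character(stats::predict(m, x)),
      sample_pars = function() list(ntree = sample(c(50L, 100L, 200L), 1),
                                    mtry = sample.int(3, 1)),
      seeded = TRUE),
    extra_trees = list(
      fit = function(x, y, pars) {
        df <- data.frame(y = as_f(y), x)
        ranger::ranger(y ~ ., data = df, splitrule = "extratrees",
                       num.trees = pars$ntree %||% 100,
                       num.random.splits = 1, seed = pars$.seed %||% 1)
      },
      predict = function(m, x)
        as.character(stats::predict(m, data.frame(x))$predictions),
      sample_pars = function() list(ntree = sample(c(50L, 100L, 200L), 1)),
      seeded = TRUE),
    gradient_boost = list(
      fit = function(x, y, pars) {
        dtrain <- xgboost::xgb.DMatrix(as.matrix(x),
                                       label = as.integer(as_f(y) == "Intact"))
        xgboost::xgb.train(params = list(objective = "binary:logistic",
                                         max_depth = pars$max_depth %||% 2,
                                         eta = pars$eta %||% 0.3,
                                         nthread = 1),
                           data = dtrain, nrounds = pars$nrounds %||% 30,
                           verbose = 0)
      },
      predict = function(m, x)
        ifelse(stats::predict(m, xgboost::xgb.DMatrix(as.matrix(x))) > 0.5,
               "Intact", "Scrambled"),
      sample_pars = function() list(nrounds = sample(c(10L, 30L, 60L), 1),
                                    max_depth = sample(2:4, 1),
                                    eta = stats::runif(1, 0.05, 0.5)),
      seeded = TRUE),
    gauss_process = list(
      fit = function(x, y, pars)
        suppressMessages(kernlab::gausspr(x, as_f(y),
                                          kpar = list(sigma = pars$sigma %||%
                                                        (1 / ncol(x))))),
      predict = function(m, x)
        as.character(kernlab::predict(m, x)),
      sample_pars = function() list(sigma = 10^stats::runif(1, -2, 1)))
  )
  if (!is.null(names)) {
    missing <- setdiff(names, base::names(reg))
    if (length(missing))
      abort_nirsisc(sprintf("unknown classifier(s): %s",
                            paste(missing, collapse = ", ")),
                    "nirsisc_parameter")
    reg <- reg[names]
  }
  reg
}

#' Balanced accuracy, recall and precision from a confusion matrix
#'
#' Intact is the positive class. Balanced accuracy is the mean of the two
#' per-class recalls; recall = TP / (TP + FN); precision = TP / (TP + FP).
#'
#' @param confusion 2x2 matrix, rows = actual, columns = predicted, with
#'   dimnames Intact/Scrambled.
#' @return list with \code{balanced_accuracy}, \code{recall},
#'   \code{precision}.
#' @export
confusion_metrics <- function(confusion) {
  tp <- confusion["Intact", "Intact"]
  fn <- confusion["Intact", "Scrambled"]
  fp <- confusion["Scrambled", "Intact"]
  tn <- confusion["Scrambled", "Scrambled"]
  rec_i <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  rec_s <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(balanced_accuracy = mean(c(rec_i, rec_s)),
       recall = rec_i,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

balanced_accuracy_vec <- function(actual, predicted) {
  conf <- table(factor(actual, c("Intact", "Scrambled")),
                factor(predicted, c("Intact", "Scrambled")))
  confusion_metrics(unclass(conf))$balanced_accuracy
}

# Stratified k-fold indices (list of test-index vectors).
stratified_folds <- function(y, k) {
  y <- as.character(y)
  folds <- vector("list", k)
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    grp <- rep_len(seq_len(k), length(idx))
    for (f in seq_len(k))
      folds[[f]] <- c(folds[[f]], idx[grp == f])
  }
  folds
}

#' Train the weighted-voting classifier ensemble
#'
#' Every registered classifier is tuned by a budgeted random hyperparameter
#' search maximizing the median balanced accuracy over stratified k-fold
#' cross-validation on the training data, then refit on the full training
#' set. Its vote weight is that tuned training score. Classifiers that fail
#' to fit (e.g. QDA with singular within-class covariance on tiny samples)
#' are dropped with weight NA.
#'
#' @param x training feature matrix (rows = ISC vectors).
#' @param y labels ("Intact"/"Scrambled"), both classes present.
#' @param config an \code{\link{analysis_config}} (registry subset, search
#'   budget, CV folds).
#' @param seed integer seed; same seed and data give the identical tuned
#'   configuration.
#' @param budget optional override of \code{config$search_budget}.
#' @return object of class \code{vote_ensemble}: fitted models, weights,
#'   chosen hyperparameters.
#' @export
train_vote_ensemble <- function(x, y, config = analysis_config(), seed = 1L,
                                budget = NULL) {
  if (length(unique(y)) < 2)
    abort_nirsisc("training data must contain both classes",
                  "nirsisc_validation")
  x <- as.matrix(x)
  reg <- classifier_registry(config$classifiers)
  budget <- budget %||% config$search_budget
  k <- min(config$cv_folds, min(table(y)))
  with_seed(seed, {
    folds <- stratified_folds(y, k)
    fitted <- list()
    for (nm in names(reg)) {
      def <- reg[[nm]]
      cand <- c(list(list()),
                lapply(seq_len(max(0, budget - 1)),
                       function(i) def$sample_pars()))
      best <- NULL; best_score <- -Inf
      for (pars in cand) {
        if (isTRUE(def$seeded)) pars$.seed <- seed
        scores <- rep(NA_real_, k)
        for (f in seq_len(k)) {
          te <- folds[[f]]; tr <- setdiff(seq_len(nrow(x)), te)
          if (length(unique(y[tr])) < 2) next
          scores[f] <- suppressWarnings(tryCatch({
            m <- def$fit(x[tr, , drop = FALSE], y[tr], pars)
            balanced_accuracy_vec(y[te],
                                  def$predict(m, x[te, , drop = FALSE]))
          }, error = function(e) NA_real_))
        }
        med <- stats::median(scores, na.rm = TRUE)
        if (!is.na(med) && med > best_score) {
          best_score <- med; best <- pars
        }
      }
      if (is.null(best)) next
      model <- suppressWarnings(tryCatch(def$fit(x, y, best),
                                         error = function(e) NULL))
      if (is.null(model)) next
      fitted[[nm]] <- list(model = model, weight = best_score,
                           pars = best, def = def)
    }
    if (!length(fitted))
      abort_nirsisc("no classifier could be fitted", "nirsisc_numerical")
    structure(list(members = fitted), class = "vote_ensemble")
  })
}

#' Predict with a weighted-voting ensemble
#'
#' Each member votes for a class with weight equal to its tuned training
#' balanced accuracy; the class with the larger weight sum wins. Ties
#' predict Scrambled (the conservative outcome).
#'
#' @param ensemble a \code{vote_ensemble}.
#' @param x feature matrix.
#' @return character vector of predicted labels.
#' @export
predict_ensemble <- function(ensemble, x) {
  x <- as.matrix(x)
  w_int <- w_scr <- rep(0, nrow(x))
  for (mem in ensemble$members) {
    pred <- suppressWarnings(tryCatch(unname(mem$def$predict(mem$model, x)),
                                      error = function(e) NULL))
    if (is.null(pred)) next
    w <- max(mem$weight, 0)
    w_int <- w_int + w * (pred == "Intact")
    w_scr <- w_scr + w * (pred == "Scrambled")
  }
  ifelse(w_int > w_scr, "Intact", "Scrambled")
}

# One leave-one-out fold's feature data: training ISCs recomputed without
# the left-out participant, test ISCs from the full-cohort matrices.
decode_fold_data <- function(p, cc_i, cc_s, isc_int_full, isc_scr_full,
                             loo_masks, fisher_clip) {
  feats <- union(loo_masks[[p]]$intact, loo_masks[[p]]$scrambled)
  if (!length(feats)) {
    warning("empty feature union for a LOO dataset; using all channels")
    feats <- colnames(isc_int_full)
  }
  isc_i <- isc_from_cov(cc_i, p, fisher_clip)
  isc_s <- isc_from_cov(cc_s, p, fisher_clip)
  list(x_train = rbind(isc_i[, feats, drop = FALSE],
                       isc_s[, feats, drop = FALSE]),
       y_train = rep(c("Intact", "Scrambled"), each = nrow(isc_i)),
       train_ids = rep(rownames(isc_i), 2),
       x_test = rbind(isc_int_full[p, feats, drop = FALSE],
                      isc_scr_full[p, feats, drop = FALSE]),
       y_test = c("Intact", "Scrambled"))
}

run_decode_pass <- function(fold_data, config, seed, budget,
                            flip = character(0)) {
  conf <- matrix(0, 2, 2, dimnames = list(actual = c("Intact", "Scrambled"),
                                          predicted = c("Intact", "Scrambled")))
  weights <- list()
  for (p in seq_along(fold_data)) {
    fd <- fold_data[[p]]
    y_tr <- fd$y_train
    sw <- fd$train_ids %in% flip
    y_tr[sw] <- ifelse(y_tr[sw] == "Intact", "Scrambled", "Intact")
    y_te <- fd$y_test
    if (names(fold_data)[p] %in% flip) y_te <- rev(y_te)
    ens <- train_vote_ensemble(fd$x_train, y_tr, config,
                               seed = derive_seed(seed, p), budget = budget)
    pred <- predict_ensemble(ens, fd$x_test)
    for (i in seq_along(pred)) conf[y_te[i], pred[i]] <- conf[y_te[i], pred[i]] + 1
    weights[[names(fold_data)[p]]] <-
      vapply(ens$members, `[[`, numeric(1), "weight")
  }
  list(confusion = conf, metrics = confusion_metrics(conf), weights = weights)
}

#' Leave-one-out ensemble decoding of stimulus condition
#'
#' For every left-out participant, trains the weighted-voting ensemble on
#' the remaining participants' Intact and Scrambled ISC vectors (recomputed
#' within the leave-one-out dataset; features are the union of the LOO
#' mask's Intact- and Scrambled-significant channels) and predicts the two
#' held-out vectors. Predictions are pooled into one confusion matrix;
#' balanced accuracy, recall and precision are tested by permutation,
#' shuffling condition labels within participant (add-one p-values).
#'
#' @param cohort_hb list with \code{intact} and \code{scrambled} named
#'   lists of \code{hb_series}.
#' @param loo_masks \code{loo_masks} from \code{\link{build_loo_masks}}.
#' @param config an \code{\link{analysis_config}}; \code{n_permutations}
#'   and \code{permutation_budget} control the permutation test (pass
#'   \code{n_permutations = 0} to skip it).
#' @param seed integer seed.
#' @return list of class \code{decoding_result}: confusion matrix (rows =
#'   actual, columns = predicted), the three metrics, their permutation
#'   p-values, per-fold classifier weights and the permutation null matrix.
#' @export
decode_cohort <- function(cohort_hb, loo_masks, config = analysis_config(),
                          seed = 1L) {
  pts <- names(cohort_hb$intact)
  if (length(pts) < 4)
    abort_nirsisc("need at least 4 participants", "nirsisc_validation")
  cc_i <- cohort_cov(fast_cohort(cohort_hb$intact))
  cc_s <- cohort_cov(fast_cohort(cohort_hb$scrambled))
  isc_int_full <- isc_from_cov(cc_i, NULL, config$fisher_clip)
  isc_scr_full <- isc_from_cov(cc_s, NULL, config$fisher_clip)
  fold_data <- lapply(seq_along(pts), decode_fold_data,
                      cc_i = cc_i, cc_s = cc_s,
                      isc_int_full = isc_int_full,
                      isc_scr_full = isc_scr_full,
                      loo_masks = loo_masks,
                      fisher_clip = config$fisher_clip)
  names(fold_data) <- pts
  obs <- run_decode_pass(fold_data, config, seed, config$search_budget)
  B <- config$n_permutations
  null_mat <- NULL
  pvals <- list(balanced_accuracy = NA_real_, recall = NA_real_,
                precision = NA_real_)
  if (B > 0) {
    null_mat <- matrix(NA_real_, B, 3,
                       dimnames = list(NULL, c("balanced_accuracy",
                                               "recall", "precision")))
    flips <- with_seed(derive_seed(seed, 911L), {
      lapply(seq_len(B), function(b)
        pts[stats::runif(length(pts)) < 0.5])
    })
    for (b in seq_len(B)) {
      perm <- run_decode_pass(fold_data, config, derive_seed(seed, 1000L + b),
                              config$permutation_budget, flip = flips[[b]])
      null_mat[b, ] <- unlist(perm$metrics)
    }
    for (met in colnames(null_mat)) {
      ob <- obs$metrics[[met]]
      pvals[[met]] <- (1 + sum(null_mat[, met] >= ob, na.rm = TRUE)) / (B + 1)
    }
  }
  structure(list(confusion = obs$confusion,
                 balanced_accuracy = obs$metrics$balanced_accuracy,
                 recall = obs$metrics$recall,
                 precision = obs$metrics$precision,
                 p_balanced_accuracy = pvals$balanced_accuracy,
                 p_recall = pvals$recall,
                 p_precision = pvals$precision,
                 weights = obs$weights,
                 null_metrics = null_mat),
            class = "decoding_result")
}

#' Single-channel decoding
#'
#' Repeats the leave-one-out ensemble decoding with each long channel's ISC
#' as the sole feature and reports the average balanced accuracy across LOO
#' datasets per channel (each fold's balanced accuracy is computed on its
#' two held-out vectors). No permutation test is run at the channel level.
#'
#' @inheritParams decode_cohort
#' @return named numeric vector: mean balanced accuracy per channel.
#' @export
per_channel_decoding <- function(cohort_hb, loo_masks,
                                 config = analysis_config(), seed = 1L) {
  pts <- names(cohort_hb$intact)
  cc_i <- cohort_cov(fast_cohort(cohort_hb$intact))
  cc_s <- cohort_cov(fast_cohort(cohort_hb$scrambled))
  isc_int_full <- isc_from_cov(cc_i, NULL, config$fisher_clip)
  isc_scr_full <- isc_from_cov(cc_s, NULL, config$fisher_clip)
  chans <- colnames(isc_int_full)
  loo_train <- lapply(seq_along(pts), function(p)
    list(i = isc_from_cov(cc_i, p, config$fisher_clip),
         s = isc_from_cov(cc_s, p, config$fisher_clip)))
  acc <- vapply(chans, function(ch) {
    fold_ba <- vapply(seq_along(pts), function(p) {
      tr <- loo_train[[p]]
      x_train <- cbind(rbind(tr$i[, ch, drop = FALSE],
                             tr$s[, ch, drop = FALSE]))
      colnames(x_train) <- ch
      y_train <- rep(c("Intact", "Scrambled"), each = nrow(tr$i))
      x_test <- rbind(isc_int_full[p, ch, drop = FALSE],
                      isc_scr_full[p, ch, drop = FALSE])
      colnames(x_test) <- ch
      ens <- train_vote_ensemble(x_train, y_train, config,
                                 seed = derive_seed(seed, p))
      balanced_accuracy_vec(c("Intact", "Scrambled"),
                            predict_ensemble(ens, x_test))
    }, numeric(1))
    mean(fold_ba)
  }, numeric(1))
  acc
}
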