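test_that("weighted voting follows the heavier classifier and ties go to Scrambled", {
  mk <- function(label, w) list(model = NULL, weight = w,
                                def = list(predict = function(m, x)
                                  rep(label, nrow(x))))
  ens <- structure(list(members = list(a = mk("Intact", 0.9),
                                       b = mk("Scrambled", 0.6))),
                   class = "vote_ensemble")
  expect_identical(predict_ensemble(ens, matrix(0, 2, 1)),
                   c("Intact", "Intact"))
  tie <- structure(list(members = list(a = mk("Intact", 0.7),
                                       b = mk("Scrambled", 0.7))),
                   class = "vote_ensemble")
  expect_identical(predict_ensemble(tie, matrix(0, 1, 1)), "Scrambled")
})

test_that("confusion metrics equal their independent definitions", {
  conf <- matrix(c(17, 9, 1, 25), 2, 2, byrow = TRUE,
                 dimnames = list(actual = c("Intact", "Scrambled"),
                                 predicted = c("Intact", "Scrambled")))
  m <- confusion_metrics(conf)
  sens <- 17 / 26; spec <- 25 / 26
  expect_equal(m$balanced_accuracy, (sens + spec) / 2)
  expect_equal(m$recall, 17 / (17 + 9))
  expect_equal(m$precision, 17 / (17 + 1))
})

test_that("linear classifiers separate linearly separable ISC classes", {
  set.seed(5)
  n <- 12
  x <- rbind(matrix(rnorm(n * 4, mean = 2), n),
             matrix(rnorm(n * 4, mean = -2), n))
  colnames(x) <- paste0("ch", 1:4)
  y <- rep(c("Intact", "Scrambled"), each = n)
  cfg <- analysis_config(classifiers = c("lda", "logistic", "svm_linear"),
                         search_budget = 2)
  ens <- train_vote_ensemble(x, y, cfg, seed = 1)
  expect_true(all(vapply(ens$members, `[[`, numeric(1), "weight") >= 0.9))
  expect_identical(predict_ensemble(ens, x), y)
  expect_error(train_vote_ensemble(x, rep("Intact", nrow(x)), cfg),
               "both classes")
})

test_that("training is deterministic given seed and data", {
  set.seed(6)
  x <- matrix(rnorm(20 * 3), 20, dimnames = list(NULL, paste0("c", 1:3)))
  y <- rep(c("Intact", "Scrambled"), 10)
  cfg <- analysis_config(classifiers = c("ridge", "svm_rbf", "knn"),
                         search_budget = 5)
  e1 <- train_vote_ensemble(x, y, cfg, seed = 4)
  e2 <- train_vote_ensemble(x, y, cfg, seed = 4)
  expect_identical(lapply(e1$members, `[[`, "pars"),
                   lapply(e2$members, `[[`, "pars"))
  expect_identical(vapply(e1$members, `[[`, numeric(1), "weight"),
                   vapply(e2$members, `[[`, numeric(1), "weight"))
})

test_that("the full registry instantiates, fits and predicts", {
  set.seed(8)
  reg <- classifier_registry()
  expect_gte(length(reg), 14L)
  x <- rbind(matrix(rnorm(8 * 3, 1.5), 8), matrix(rnorm(8 * 3, -1.5), 8))
  colnames(x) <- paste0("ch", 1:3)
  y <- rep(c("Intact", "Scrambled"), each = 8)
  for (nm in names(reg)) {
    def <- reg[[nm]]
    m <- def$fit(x, y, def$sample_pars())
    pred <- def$predict(m, x)
    expect_gte(mean(pred == y), 0.75)
  }
  expect_error(classifier_registry("not_a_classifier"), "unknown")
})

test_that("cohort decoding separates conditions and its permutations do not", {
  co <- small_effect_cohort(seed = 19, n = 8, nch = 12, n_signal = 4,
                            duration_s = 150)
  chb_d <- list(intact = cohort_hb(co, "Intact"),
                scrambled = cohort_hb(co, "Scrambled"))
  cfg_d <- analysis_config(n_surrogates = 120, seed = 3,
                           classifiers = c("lda", "svm_linear",
                                           "nearest_centroid"),
                           search_budget = 2, n_permutations = 19,
                           permutation_budget = 1)
  masks_d <- build_loo_masks(chb_d, cfg_d)
  dec <- decode_cohort(chb_d, masks_d, cfg_d, seed = 2)
  expect_gte(dec$balanced_accuracy, 0.8)
  expect_lt(dec$p_balanced_accuracy, 0.1)   # min possible p = 1/20
  expect_equal(sum(dec$confusion), 2 * length(chb_d$intact))
  expect_identical(rownames(dec$confusion), c("Intact", "Scrambled"))
  # permutation nulls hover near chance
  expect_lt(abs(mean(dec$null_metrics[, "balanced_accuracy"]) - 0.5), 0.15)
})

test_that("single-channel decoding ranks the informative channels on top", {
  co <- small_effect_cohort(seed = 23, n = 8, nch = 8, n_signal = 4,
                            duration_s = 150)
  chb_1 <- list(intact = cohort_hb(co, "Intact"),
                scrambled = cohort_hb(co, "Scrambled"))
  cfg_1 <- analysis_config(n_surrogates = 100, seed = 5,
                           classifiers = c("lda", "nearest_centroid"),
                           search_budget = 1, n_permutations = 0)
  masks_1 <- build_loo_masks(chb_1, cfg_1)
  acc <- per_channel_decoding(chb_1, masks_1, cfg_1, seed = 4)
  expect_length(acc, 8L)                    # one score per long channel
  # channels 3:4 carry the intact-only effect; channels 5:8 are pure noise
  expect_gt(mean(acc[3:4]), mean(acc[5:8]))
  expect_true(which.max(acc) %in% 3:4)
  expect_lt(abs(mean(acc[5:8]) - 0.5), 0.15)
})
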