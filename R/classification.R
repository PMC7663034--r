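#' Construct a split configuration
#'
#' @param testFraction held-out proportion (default 0.30, the 70-30
#'   protocol).
#' @param stratified preserve per-class proportions (default `TRUE`).
#' @param groupAware keep all rows sharing a `source` case on one side of
#'   the split. Off by default, reproducing the augment-then-split
#'   procedure; turning it on measures the leakage that procedure causes.
#' @param seed integer seed.
#' @return a [SplitConfig-class].
#' @export
SplitConfig <- function(testFraction = 0.30, stratified = TRUE,
                        groupAware = FALSE, seed = 1L) {
  new("SplitConfig", testFraction = testFraction, stratified = stratified,
      groupAware = groupAware, seed = as.integer(seed))
}

#' Construct a forest configuration
#'
#' Defaults follow the reference protocol: 400 trees, entropy criterion,
#' bootstrap resampling.
#'
#' @param nTrees number of trees (default 400).
#' @param splitCriterion requested impurity measure (recorded; the ranger
#'   backend uses Gini impurity for classification).
#' @param bootstrap bootstrap resampling flag.
#' @param seed integer seed.
#' @return a [ForestConfig-class].
#' @export
ForestConfig <- function(nTrees = 400L, splitCriterion = "entropy",
                         bootstrap = TRUE, seed = 1L) {
  new("ForestConfig", nTrees = as.integer(nTrees),
      splitCriterion = splitCriterion, bootstrap = bootstrap,
      seed = as.integer(seed))
}

#' Stratified (optionally group-aware) train/test split
#'
#' Splits a labeled feature table into train and test sets. The test set
#' has `round(testFraction * n)` rows; with stratification the per-class
#' proportions are preserved within one row. With `groupAware = TRUE`
#' whole source-case groups (original + augmented siblings) are assigned to
#' one side, so group counts take priority over the exact row count.
#'
#' @param table a [LabeledFeatureTable-class] or its `data.frame`.
#' @param config a [SplitConfig-class].
#' @return list with `data.frame` elements `train` and `test`.
#' @export
stratifiedSplit <- function(table, config = SplitConfig()) {
  tab <- if (is(table, "LabeledFeatureTable")) featureTable(table) else table
  if (!all(c(0L, 1L) %in% tab$label))
    stop("cannot stratify: a class is absent from the table")
  if (any(table(tab$label) < 2L))
    stop("need at least 2 rows per class")
  nTest <- round(config@testFraction * nrow(tab))
  testIdx <- withr::with_seed(config@seed, {
    if (config@groupAware) {
      .groupedTestIndices(tab, config@testFraction)
    } else if (config@stratified) {
      idx <- integer(0)
      classes <- sort(unique(tab$label))
      quota <- round(config@testFraction * tabulate(tab$label + 1L,
                                                    nbins = 2L))
      take <- quota[classes + 1L]
      # keep the overall test size at round(testFraction * n)
      off <- sum(take) - nTest
      if (off != 0) take[which.max(take)] <- take[which.max(take)] - off
      for (i in seq_along(classes))
        idx <- c(idx, sample(which(tab$label == classes[i]), take[i]))
      idx
    } else {
      sample(seq_len(nrow(tab)), nTest)
    }
  })
  list(train = tab[-testIdx, , drop = FALSE],
       test = tab[testIdx, , drop = FALSE])
}

# assign whole source-case groups to the test side, per class, until the
# class test quota is covered
.groupedTestIndices <- function(tab, testFraction) {
  grp <- if ("source_tag" %in% names(tab) && any(tab$source_tag == "augmented"))
    sub("_aug[01]_[0-9]+$", "", tab$case_id) else tab$case_id
  idx <- integer(0)
  for (cls in sort(unique(tab$label))) {
    rows <- which(tab$label == cls)
    quota <- testFraction * length(rows)
    groups <- sample(unique(grp[rows]))
    got <- 0L
    for (g in groups) {
      if (got >= quota) break
      pick <- rows[grp[rows] == g]
      idx <- c(idx, pick)
      got <- got + length(pick)
    }
  }
  idx
}

#' Train the random-forest nodule classifier
#'
#' Fits a bootstrap ensemble of `nTrees` classification trees on the
#' feature columns of the training table (majority vote aggregation),
#' deterministically for a given seed.
#'
#' @param train training `data.frame`: numeric feature columns plus a
#'   binary `label`; provenance columns (`case_id`, `source_tag`) are
#'   ignored.
#' @param config a [ForestConfig-class].
#' @return a [NoduleForest-class].
#' @export
trainForest <- function(train, config = ForestConfig()) {
  if (is(train, "LabeledFeatureTable")) train <- featureTable(train)
  if (nrow(train) == 0L) stop("empty training set")
  if (length(unique(train$label)) < 2L)
    stop("training set contains a single class")
  feats <- setdiff(names(train), c("case_id", "source_tag", "label"))
  d <- train[c(feats, "label")]
  d$label <- factor(d$label, levels = c(0, 1))
  fit <- ranger::ranger(
    label ~ ., data = d,
    num.trees = config@nTrees,
    replace = config@bootstrap,
    sample.fraction = if (config@bootstrap) 1 else 0.632,
    seed = config@seed, num.threads = 1
  )
  new("NoduleForest", forest = fit, featureNames = feats, config = config)
}

#' Evaluate a fitted classifier on a test table
#'
#' Predicts the held-out rows and reports the confusion matrix (positive =
#' malignant, label 1) with accuracy, sensitivity and specificity. A metric
#' whose denominator is empty is reported as `NA` with a warning, never as
#' a silent zero.
#'
#' @param model a [NoduleForest-class].
#' @param test test `data.frame` with the same feature columns and a
#'   binary `label`.
#' @return a [ClassificationReport-class].
#' @export
evaluateModel <- function(model, test) {
  if (is(test, "LabeledFeatureTable")) test <- featureTable(test)
  if (nrow(test) == 0L) stop("empty test set")
  absent <- setdiff(model@featureNames, names(test))
  if (length(absent))
    stop("feature schema mismatch: test set lacks ",
         paste(absent, collapse = ", "))
  if (nrow(test) < 5L)
    warning("test set has only ", nrow(test), " row(s); metrics are noisy")
  pred <- stats::predict(model@forest,
                         data = test[model@featureNames])$predictions
  pred <- as.integer(as.character(pred))
  truth <- as.integer(test$label)
  conf <- c(TN = sum(pred == 0 & truth == 0),
            FP = sum(pred == 1 & truth == 0),
            FN = sum(pred == 0 & truth == 1),
            TP = sum(pred == 1 & truth == 1))
  classificationReport(conf)
}

#' Build a classification report from a confusion matrix
#'
#' @param confusion named vector or list with entries `TN`, `FP`, `FN`,
#'   `TP`.
#' @return a [ClassificationReport-class] with accuracy
#'   \eqn{(TP+TN)/n}, sensitivity \eqn{TP/(TP+FN)} and specificity
#'   \eqn{TN/(TN+FP)}; undefined metrics are `NA` with a warning.
#' @export
classificationReport <- function(confusion) {
  conf <- vapply(c("TN", "FP", "FN", "TP"), function(k)
    as.integer(confusion[[k]]), 1L)
  n <- sum(conf)
  rate <- function(num, den, what) {
    if (den == 0L) {
      warning(what, " undefined: empty denominator class in the test set")
      NA_real_
    } else num / den
  }
  new("ClassificationReport", confusion = conf,
      accuracy = rate(conf["TP"] + conf["TN"], n, "accuracy"),
      sensitivity = rate(conf["TP"], conf["TP"] + conf["FN"], "sensitivity"),
      specificity = rate(conf["TN"], conf["TN"] + conf["FP"], "specificity"))
}

#' @describeIn classificationReport the three metrics as a named numeric
#'   vector.
#' @param report a `ClassificationReport`.
#' @export
reportMetrics <- function(report) {
  stopifnot(is(report, "ClassificationReport"))
  c(accuracy = unname(report@accuracy),
    sensitivity = unname(report@sensitivity),
    specificity = unname(report@specificity))
}

#' Run the end-to-end classification experiment
#'
#' Selects a feature arm from a labeled feature table, performs the
#' stratified 70-30 split, trains the forest and evaluates it: the
#' one-call version of the pipeline used for the selected-versus-global-
#' versus-discounted comparison.
#'
#' @param table a [LabeledFeatureTable-class] (or its `data.frame`).
#' @param arm feature arm: `"tirads11"` (the 11 selected features,
#'   default), `"global27"` (all features) or `"discounted16"` (the
#'   complementary 16).
#' @param splitConfig a [SplitConfig-class].
#' @param forestConfig a [ForestConfig-class].
#' @return a [ClassificationReport-class].
#' @export
runExperiment <- function(table, arm = c("tirads11", "global27",
                                         "discounted16"),
                          splitConfig = SplitConfig(),
                          forestConfig = ForestConfig()) {
  arm <- match.arg(arm)
  tab <- if (is(table, "LabeledFeatureTable")) featureTable(table) else table
  cols <- selectedColumnNames(arm)
  keep <- c(intersect(c("case_id", "source_tag"), names(tab)), cols, "label")
  sp <- stratifiedSplit(tab[keep], splitConfig)
  model <- trainForest(sp$train, forestConfig)
  evaluateModel(model, sp$test)
}
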