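#' Specify a supervised learner
#'
#' The five learners of the framework, behind one score interface: a fitted
#' model yields one real score per example, higher = more likely infectious.
#' Logistic regression, the naive Bayes variants and the random forest score
#' with class-1 probabilities in (0, 1); the SVM scores with the signed RBF
#' margin.
#'
#' @param kind One of `"logistic_l1"`, `"svm_rbf"`, `"random_forest"`,
#'   `"gaussian_nb"`, `"bernoulli_nb"`.
#' @param lambda L1 penalty for the logistic learner, on the summed
#'   log-likelihood scale (default 1; converted internally to glmnet's
#'   per-observation scale).
#' @param gamma RBF kernel width; default `NULL` means 1 / feature dimension.
#' @param ntree Number of random-forest trees (fully grown), default 100.
#' @param binarize Binarization rule for Bernoulli naive Bayes: currently
#'   `"mean"` (threshold each feature at its training-set mean).
#' @param seed Learner seed; if `NULL`, the evaluation protocol supplies one.
#' @return An object of class `learner_spec`.
#' @export
learner_spec <- function(kind = c("random_forest", "logistic_l1", "svm_rbf",
                                  "gaussian_nb", "bernoulli_nb"),
                         lambda = 1, gamma = NULL, ntree = 100,
                         binarize = "mean", seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(lambda > 0, is.null(gamma) || gamma > 0, ntree >= 1)
  binarize <- match.arg(binarize, "mean")
  structure(list(kind = kind, lambda = lambda, gamma = gamma,
                 ntree = as.integer(ntree), binarize = binarize, seed = seed),
            class = "learner_spec")
}

#' Train a host-association model
#'
#' Fits the learner described by `spec` on a feature matrix with binary
#' labels (1 = infects the host). Learner internals delegate to glmnet,
#' e1071 and randomForest; this function owns the uniform score contract and
#' the recipe bookkeeping.
#'
#' @param features Numeric matrix (rows = viruses); a `"recipe"` attribute,
#'   if present, is recorded and enforced at prediction time.
#' @param labels Binary vector (0/1 or logical), one per row.
#' @param spec A [learner_spec()].
#' @param host Optional host genus label stored with the model.
#' @return An object of class `host_model`.
#' @export
train_model <- function(features, labels, spec = learner_spec(), host = NULL) {
  stopifnot(inherits(spec, "learner_spec"), is.matrix(features))
  labels <- as.integer(labels)
  if (length(labels) != nrow(features)) stop("labels/features size mismatch")
  if (length(unique(labels)) < 2L) stop("training labels contain a single class")
  if (any(!is.finite(features))) stop("features contain non-finite values")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  p <- ncol(features)
  y <- factor(ifelse(labels == 1L, "pos", "neg"), levels = c("neg", "pos"))
  fit <- switch(spec$kind,
    logistic_l1 = glmnet::glmnet(features, y, family = "binomial", alpha = 1,
                                 lambda = spec$lambda / nrow(features),
                                 standardize = FALSE),
    svm_rbf = e1071::svm(features, y, kernel = "radial",
                         gamma = spec$gamma %||% (1 / p), scale = FALSE,
                         probability = FALSE),
    random_forest = randomForest::randomForest(features, y,
                                               ntree = spec$ntree),
    gaussian_nb = floor_nb_sd(e1071::naiveBayes(features, y)),
    bernoulli_nb = {
      thresholds <- colMeans(features)
      xb <- binarize_frame(features, thresholds)
      m <- e1071::naiveBayes(xb, y, laplace = 1)
      m$thresholds <- thresholds
      m
    })
  structure(list(host_genus = host, recipe = attr(features, "recipe"),
                 spec = spec, fit = fit,
                 training_ids = rownames(features)),
            class = "host_model")
}

# e1071's Gaussian NB stores per-class (mean, sd) tables; constant features
# yield sd = 0 and non-finite densities, so floor the sd
floor_nb_sd <- function(m) {
  m$tables <- lapply(m$tables, function(tab) {
    tab[, 2] <- pmax(tab[, 2], 1e-9)
    tab
  })
  m
}

binarize_frame <- function(features, thresholds) {
  xb <- as.data.frame(lapply(seq_len(ncol(features)), function(j) {
    factor(ifelse(features[, j] > thresholds[j], "1", "0"),
           levels = c("0", "1"))
  }))
  names(xb) <- colnames(features) %||% paste0("V", seq_len(ncol(features)))
  xb
}

#' @export
print.host_model <- function(x, ...) {
  cat("host model (", x$spec$kind, ")",
      if (!is.null(x$host_genus)) paste0(" for genus ", x$host_genus),
      ", trained on ", length(x$training_ids %||% character()),
      " viruses\n", sep = "")
  invisible(x)
}

#' Score new viruses with a trained model
#'
#' Returns one finite score per feature row; higher scores mean the virus is
#' more likely to infect the host. Probability-type learners return values in
#' \[0, 1\]; the SVM returns the signed margin. If both the model and the
#' matrix carry a feature recipe, they must match.
#'
#' @param model A `host_model`.
#' @param features Numeric matrix with the same columns the model was
#'   trained on.
#' @return Numeric vector of scores, one per row.
#' @export
predict_scores <- function(model, features) {
  stopifnot(inherits(model, "host_model"), is.matrix(features))
  mr <- model$recipe
  fr <- attr(features, "recipe")
  if (!is.null(mr) && !is.null(fr) && !identical(mr, fr)) {
    stop("feature recipe mismatch: model was trained on ",
         recipe_label(mr), " but features are ", recipe_label(fr))
  }
  if (nrow(features) == 0L) return(numeric(0))
  spec <- model$spec
  switch(spec$kind,
    logistic_l1 = as.numeric(predict(model$fit, features, type = "response")),
    svm_rbf = {
      pr <- predict(model$fit, features, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # e1071 orients the margin toward the first-seen class; flip if needed
      s <- as.numeric(dv[, 1])
      if (!startsWith(colnames(dv)[1], "pos")) s <- -s
      s
    },
    random_forest = as.numeric(predict(model$fit, features,
                                       type = "prob")[, "pos"]),
    gaussian_nb = as.numeric(predict(model$fit, features,
                                     type = "raw")[, "pos"]),
    bernoulli_nb = {
      xb <- binarize_frame(features, model$fit$thresholds)
      as.numeric(predict(model$fit, xb, type = "raw")[, "pos"])
    })
}

recipe_label <- function(r) {
  paste0(r$kind, "(k=", r$k,
         if (!is.null(r$order)) paste0(", order=", r$order), ")")
}

#' Rank (Mann-Whitney) AUC
#'
#' The probability that a random positive outscores a random negative, with
#' ties counted 1/2: `AUC = (sum over pos x neg pairs of [pos > neg] + 0.5
#' [pos == neg]) / (n_pos * n_neg)`, computed via midranks. Equals the area
#' under the empirical ROC curve by trapezoidal integration.
#'
#' @param pos_scores,neg_scores Non-empty numeric score vectors.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.9, 0.8), c(0.85, 0.1)) # 3 of 4 pairs correctly ordered
#' @export
auc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores)
  nn <- length(neg_scores)
  if (np == 0L || nn == 0L) stop("both score sets must be non-empty")
  if (anyNA(pos_scores) || anyNA(neg_scores)) stop("scores contain NA")
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Draw repeated negative training/testing sets
#'
#' Each repeat draws `n_train + n_test` ids uniformly without replacement
#' from the negative pool and splits them into disjoint training and testing
#' sets; repeats are independent draws from a seeded generator, so the whole
#' sequence reproduces under the same seed.
#'
#' @param pool Character vector of candidate negative ids.
#' @param n_train,n_test Set sizes per repeat.
#' @param repeats Number of repeats (the protocol uses 50).
#' @param seed Master seed.
#' @return List of `repeats` elements, each `list(train, test)`.
#' @export
sample_negative_sets <- function(pool, n_train, n_test, repeats = 50,
                                 seed = 1) {
  need <- n_train + n_test
  if (need > length(pool)) {
    stop("negative pool too small: need ", need, " but only ",
         length(pool), " available")
  }
  seeds <- derive_seeds(seed, repeats)
  lapply(seq_len(repeats), function(r) {
    with_preserved_seed({
      set.seed(seeds[r])
      drawn <- sample(pool, need)
      list(train = drawn[seq_len(n_train)],
           test = drawn[n_train + seq_len(n_test)])
    })
  })
}

#' Evaluate a learner on one host partition
#'
#' The full protocol for one host genus: for each repeat, draw negative
#' training/testing sets of the same sizes as the positive ones, train the
#' learner on positive-train plus negative-train, score positive-test plus
#' negative-test, and record the AUC. One master seed expands into
#' per-repeat sampler and learner seeds, so any repeat reproduces in
#' isolation.
#'
#' @param records Data frame of genome records (with metadata).
#' @param partition A `host_partition`.
#' @param kind,k,order Feature recipe (see [feature_matrix()]).
#' @param learner A [learner_spec()].
#' @param repeats Number of negative resamples (default 50).
#' @param seed Master seed.
#' @param features Optional precomputed feature matrix covering all ids in
#'   the partition (skips recomputation).
#' @return An object of class `evaluation_result` with the per-repeat AUCs,
#'   their mean and SD, and the full provenance (recipe, learner, seed).
#' @export
evaluate_host <- function(records, partition, kind = "F1", k = 6,
                          order = NULL, learner = learner_spec("random_forest"),
                          repeats = 50, seed = 1, features = NULL) {
  stopifnot(inherits(partition, "host_partition"))
  if (length(partition$positive_train) == 0L ||
      length(partition$positive_test) == 0L) {
    stop("partition needs non-empty positive training and testing sets")
  }
  if (is.null(features)) {
    features <- feature_matrix(records, kind = kind, k = k, order = order)
  }
  ids <- rownames(features)
  evaluate_core(train_features = features, train_parent = ids,
                test_features = features, test_parent = ids,
                partition = partition, learner = learner,
                repeats = repeats, seed = seed,
                recipe = attr(features, "recipe"))
}

# Shared engine for whole-genome and contig-level evaluation. Feature rows
# may be contigs; `*_parent` maps each row to its parent genome id, and
# negative sampling / labelling happen at the genome level so a genome's own
# contigs never straddle train and test.
evaluate_core <- function(train_features, train_parent, test_features,
                          test_parent, partition, learner, repeats, seed,
                          recipe = NULL) {
  pos_train <- partition$positive_train
  pos_test <- partition$positive_test
  pool <- intersect(partition$negative_pool, unique(train_parent))
  n_train <- length(pos_train)
  n_test <- length(pos_test)
  neg_sets <- sample_negative_sets(pool, n_train, n_test, repeats = repeats,
                                   seed = seed)
  learner_seeds <- derive_seeds(seed + 1L, repeats)
  aucs <- vapply(seq_len(repeats), function(r) {
    tr_ids <- c(pos_train, neg_sets[[r]]$train)
    te_ids <- c(pos_test, neg_sets[[r]]$test)
    tr_rows <- which(train_parent %in% tr_ids)
    te_rows <- which(test_parent %in% te_ids)
    if (length(tr_rows) == 0L || length(te_rows) == 0L) {
      stop("no usable training or testing rows for host ",
           partition$host_genus, " (sequences shorter than the contig length?)")
    }
    x_tr <- train_features[tr_rows, , drop = FALSE]
    y_tr <- as.integer(train_parent[tr_rows] %in% pos_train)
    spec_r <- learner
    spec_r$seed <- learner_seeds[r]
    model <- with_preserved_seed(
      train_model(structure(x_tr, recipe = recipe), y_tr, spec_r,
                  host = partition$host_genus))
    x_te <- test_features[te_rows, , drop = FALSE]
    s <- predict_scores(model, structure(x_te, recipe = recipe))
    y_te <- test_parent[te_rows] %in% pos_test
    auc(s[y_te], s[!y_te])
  }, numeric(1))
  structure(list(auc = aucs,
                 mean_auc = mean(aucs),
                 sd_auc = if (repeats > 1) sd(aucs) else 0,
                 degenerate_sd = repeats == 1,
                 host = partition$host_genus,
                 recipe = recipe, learner = learner,
                 repeats = repeats, seed = seed),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("Evaluation for host '", x$host %||% "?", "': mean AUC ",
      sprintf("%.3f", x$mean_auc), " (SD ", sprintf("%.3f", x$sd_auc),
      ") over ", x$repeats, " negative resample(s)",
      if (isTRUE(x$degenerate_sd)) " [single repeat: SD reported as 0]",
      "\n", sep = "")
  invisible(x)
}
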