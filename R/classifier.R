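#' Default geometric feature specification (Src-family kinase numbering)
#'
#' The 16-descriptor set used for state classification on the study
#' protein's numbering (residues 60-502): the named residue-pair distances
#' central to ATP coordination, activation-loop geometry and domain
#' cross-talk, four region-centroid distances, the R-spine angle (over
#' three configurable C-alpha positions), and two padding distances to
#' reach 16 features.
#'
#' @param r_spine three residue ids defining the R-spine angle.
#' @export
lyn_feature_spec <- function(r_spine = c(294L, 317L, 385L)) {
  list(
    feat_distance("K275-E290", 275, 290),
    feat_distance("E290-D385", 290, 385),
    feat_distance("D385-K275", 385, 275),
    feat_distance("K275-M294", 275, 294),
    feat_distance("Y397-R366", 397, 366),
    feat_distance("Y397-E289", 397, 289),
    feat_distance("I77-N449", 77, 449),
    feat_distance("D498-K137", 498, 137),
    feat_distance("R390-K361", 390, 361),
    feat_centroid_distance("SH3-SH1N", "SH3", "SH1N"),
    feat_centroid_distance("SH2-SH1C", "SH2", "SH1C"),
    feat_centroid_distance("SH3-SH2", "SH3", "SH2"),
    feat_centroid_distance("SH1-lobes", "SH1N", "SH1C"),
    feat_angle(sprintf("R-spine-angle"), r_spine[1], r_spine[2], r_spine[3]),
    feat_distance("hinge-E320-adenine-proxy", 320, 385),
    feat_distance("SH2-linker-K137-L231-proxy", 137, 231))
}

#' Generic feature specification for arbitrary selections
#'
#' Builds a 16-descriptor spec (pair distances across and within regions,
#' the four region-centroid distances, one angle) resolvable on any domain
#' map; used for synthetic study systems.
#'
#' @param map a [domain_map()].
#' @param seed seed for the residue-pair draw.
#' @export
synthetic_feature_spec <- function(map, seed = 1L) {
  ids_of <- function(reg) map$residue_id[map$region == reg]
  pick <- withr::with_seed(seed, {
    regs <- sample(REGION_LEVELS[c(1, 2, 4, 5)], 11, replace = TRUE)
    purrr::map(regs, function(r) sample(ids_of(r), 1))
  })
  pairs <- purrr::map2(pick[1:11], c(pick[2:11], pick[1]), c)
  dists <- purrr::imap(pairs, function(p, i)
    feat_distance(sprintf("dist_%02d_%d_%d", i, p[1], p[2]), p[1], p[2]))
  c(dists,
    list(feat_centroid_distance("SH3-SH1N", "SH3", "SH1N"),
         feat_centroid_distance("SH2-SH1C", "SH2", "SH1C"),
         feat_centroid_distance("SH3-SH2", "SH3", "SH2"),
         feat_centroid_distance("SH1-lobes", "SH1N", "SH1C"),
         feat_angle("spine-angle", ids_of("SH1N")[1],
                    ids_of("SH1N")[length(ids_of("SH1N"))], ids_of("SH1C")[1])))
}

#' Assemble a per-frame feature table from a study manifest
#'
#' Evaluates a geometric feature spec (see [geometry_series()]) over every
#' replicate of every system and attaches the system id and activity label.
#'
#' @param manifest a [system_manifest()].
#' @param spec feature spec (list of descriptor definitions).
#' @param map a [domain_map()].
#' @return Tibble: one row per frame with feature columns, `system`,
#'   `replicate`, `label`.
#' @export
assemble_features <- function(manifest, spec, map) {
  purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    purrr::map_dfr(manifest_ensembles(manifest, i), function(e) {
      g <- geometry_series(e, spec, map)
      g$system <- manifest$system[i]
      g$replicate <- e$replicate
      g$label <- manifest$label[i]
      g
    })
  })
}

# ---- SMOTE -----------------------------------------------------------------

#' Synthetic minority oversampling (SMOTE)
#'
#' Interpolates new minority-class samples between each drawn minority
#' point and one of its k nearest minority neighbours until the
#' minority/majority ratio reaches `ratio`. A no-op when the data already
#' satisfy the ratio.
#'
#' @param X numeric feature matrix.
#' @param y binary labels aligned to rows of `X`.
#' @param ratio target minority/majority ratio.
#' @param k neighbours used for interpolation.
#' @param seed RNG seed.
#' @return list `X`, `y` with synthetic rows appended.
#' @export
smote <- function(X, y, ratio = 0.5, k = 5L, seed = 1L) {
  X <- as.matrix(X)
  tabs <- table(y)
  minority <- names(tabs)[which.min(tabs)]
  n_min <- min(tabs); n_maj <- max(tabs)
  target <- ceiling(ratio * n_maj)
  if (n_min >= target) return(list(X = X, y = y))
  idx_min <- which(y == minority)
  Xm <- X[idx_min, , drop = FALSE]
  k_use <- min(k, n_min - 1L)
  if (k_use < 1) abort("SMOTE needs at least 2 minority samples")
  d <- as.matrix(stats::dist(Xm))
  diag(d) <- Inf
  nn <- apply(d, 1, function(r) order(r)[seq_len(k_use)])
  nn <- matrix(nn, nrow = k_use)
  n_new <- target - n_min
  new_rows <- withr::with_seed(seed, {
    base_i <- sample(n_min, n_new, replace = TRUE)
    nb_j <- vapply(base_i, function(i) nn[sample(k_use, 1), i], integer(1))
    u <- stats::runif(n_new)
    Xm[base_i, , drop = FALSE] +
      u * (Xm[nb_j, , drop = FALSE] - Xm[base_i, , drop = FALSE])
  })
  list(X = rbind(X, new_rows),
       y = c(y, rep(minority, n_new)))
}

# matrix -> data.frame preserving column names verbatim
to_df <- function(X) {
  df <- as.data.frame(X)
  colnames(df) <- colnames(X)
  df
}

# min-max scaler fitted on training rows only
fit_scaler <- function(X) {
  rng <- apply(X, 2, range)
  list(min = rng[1, ], max = rng[2, ])
}

apply_scaler <- function(X, scaler) {
  span <- pmax(scaler$max - scaler$min, 1e-12)
  sweep(sweep(as.matrix(X), 2, scaler$min), 2, span, "/")
}

# ---- classifier ------------------------------------------------------------

#' Train the random-forest state classifier
#'
#' Pipeline: stratified 80/20 train/test split, Min-Max scaling fitted on
#' the training rows only, SMOTE oversampling of the minority class at
#' ratio `smote_ratio` on the training rows only, then a random forest
#' (1000 trees, unlimited depth). Evaluation on the held-out test rows
#' reports accuracy, per-class precision/recall/F1, macro and weighted
#' averages, AUC and the confusion matrix; Gini importances are normalized
#' to sum to 1.
#'
#' @param table feature table with numeric feature columns plus `label`
#'   (0/1); columns `system`, `replicate`, `frame` are ignored as features.
#' @param n_trees,smote_ratio,smote_k,train_frac pipeline hyperparameters.
#' @param max_depth tree depth cap (`NULL` = unlimited).
#' @param seed RNG seed controlling split, SMOTE and forest.
#' @return Object of class `state_classifier`.
#' @export
train_classifier <- function(table, n_trees = 1000L, smote_ratio = 0.5,
                             smote_k = 5L, train_frac = 0.8,
                             max_depth = NULL, seed = 1L) {
  meta_cols <- intersect(c("label", "system", "replicate", "frame"),
                         names(table))
  feats <- setdiff(names(table), meta_cols)
  if (anyNA(table[feats])) abort("feature table contains missing values")
  y <- as.integer(table$label)
  if (length(unique(y)) < 2) abort("both classes must be present")
  split <- stratified_split(y, train_frac, seed)
  if (min(table(y[split$train])) < 2)
    abort("a class has fewer than 2 training samples")
  X <- as.matrix(table[feats])
  scaler <- fit_scaler(X[split$train, , drop = FALSE])
  Xtr <- apply_scaler(X[split$train, , drop = FALSE], scaler)
  Xte <- apply_scaler(X[split$test, , drop = FALSE], scaler)
  ytr <- y[split$train]; yte <- y[split$test]
  sm <- smote(Xtr, ytr, ratio = smote_ratio, k = smote_k, seed = seed + 1L)
  train_df <- to_df(sm$X)
  train_df$.label <- factor(sm$y, levels = c(0, 1))
  model <- ranger::ranger(
    dependent.variable.name = ".label", data = train_df,
    num.trees = n_trees, max.depth = max_depth %||% 0,
    probability = TRUE, importance = "impurity", seed = seed,
    num.threads = 1)
  prob <- predict(model, data = to_df(Xte),
                  num.threads = 1)$predictions[, "1"]
  pred <- as.integer(prob > 0.5)
  metrics <- classification_metrics(yte, pred, prob)
  gini <- model$variable.importance
  gini <- gini / sum(gini)
  out <- list(model = model, scaler = scaler, features = feats,
              split = split, metrics = metrics$per_class,
              summary = metrics$summary, confusion = metrics$confusion,
              auc = metrics$summary$auc,
              gini_importance = tibble(feature = names(gini),
                                       importance = unname(gini)),
              test = list(X = Xte, y = yte, prob = prob),
              params = list(n_trees = n_trees, smote_ratio = smote_ratio,
                            smote_k = smote_k, train_frac = train_frac,
                            max_depth = max_depth, seed = seed))
  class(out) <- "state_classifier"
  out
}

# deterministic stratified split preserving class proportions
stratified_split <- function(y, train_frac, seed) {
  withr::with_seed(seed, {
    train <- integer(0)
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      n_tr <- round(train_frac * length(idx))
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(y), train))
  })
}

classification_metrics <- function(y, pred, prob) {
  conf <- table(factor(y, levels = c(0, 1)), factor(pred, levels = c(0, 1)),
                dnn = c("truth", "prediction"))
  per_class <- purrr::map_dfr(c(`inactive-like` = 0L, `active-like` = 1L),
                              function(cls) {
    tp <- sum(y == cls & pred == cls)
    fp <- sum(y != cls & pred == cls)
    fn <- sum(y == cls & pred != cls)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    tibble(precision = precision, recall = recall, f1 = f1,
           support = sum(y == cls))
  }, .id = "class")
  w <- per_class$support / sum(per_class$support)
  roc <- pROC::roc(response = y, predictor = prob, levels = c(0, 1),
                   direction = "<", quiet = TRUE)
  summary <- tibble(
    accuracy = mean(y == pred),
    auc = as.numeric(pROC::auc(roc)),
    macro_precision = mean(per_class$precision),
    macro_recall = mean(per_class$recall),
    macro_f1 = mean(per_class$f1),
    weighted_precision = sum(w * per_class$precision),
    weighted_recall = sum(w * per_class$recall),
    weighted_f1 = sum(w * per_class$f1))
  list(per_class = per_class, summary = summary, confusion = conf)
}

#' @export
print.state_classifier <- function(x, ...) {
  cat(sprintf("<state_classifier> %d features, accuracy %.3f, AUC %.3f\n",
              length(x$features), x$summary$accuracy, x$auc))
  invisible(x)
}

#' @exportS3Method broom::tidy
tidy.state_classifier <- function(x, ...) x$metrics

#' @exportS3Method broom::glance
glance.state_classifier <- function(x, ...) x$summary

#' Feature importance (Gini or permutation)
#'
#' Gini importances come from the forest (normalized to sum to 1);
#' permutation importance is the mean drop in held-out test AUC over
#' `repeats` random permutations of each feature column.
#'
#' @param fit a `state_classifier`.
#' @param method `"permutation"` or `"gini"`.
#' @param repeats permutation repeats per feature.
#' @param seed RNG seed.
#' @return Tibble `feature`, `importance` (and `sd` for permutation),
#'   sorted decreasing, with `rank`.
#' @export
feature_importance <- function(fit, method = c("permutation", "gini"),
                               repeats = 10L, seed = 1L) {
  method <- match.arg(method)
  if (!inherits(fit, "state_classifier")) abort("untrained model")
  if (method == "gini") {
    out <- dplyr::arrange(fit$gini_importance, dplyr::desc(.data$importance))
  } else {
    Xte <- fit$test$X; yte <- fit$test$y
    base_auc <- auc_of(fit, Xte, yte)
    drops <- withr::with_seed(seed, {
      purrr::map(fit$features, function(f) {
        vapply(seq_len(repeats), function(r) {
          Xp <- Xte
          Xp[, f] <- sample(Xp[, f])
          base_auc - auc_of(fit, Xp, yte)
        }, numeric(1))
      })
    })
    out <- tibble(feature = fit$features,
                  importance = purrr::map_dbl(drops, mean),
                  sd = purrr::map_dbl(drops, sd)) |>
      dplyr::arrange(dplyr::desc(.data$importance))
  }
  out$rank <- seq_len(nrow(out))
  out$method <- method
  out
}

auc_of <- function(fit, X, y) {
  prob <- predict(fit$model, data = to_df(X),
                  num.threads = 1)$predictions[, "1"]
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = prob,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}
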