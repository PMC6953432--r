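# ---- pipeline stages ------------------------------------------------------

# rank-based quantile transform to a uniform output distribution;
# n_quantiles landmark quantiles are stored from the training data
.fit_qt <- function(X, n_quantiles) {
  probs <- seq(0, 1, length.out = max(2, min(n_quantiles, nrow(X))))
  lapply(seq_len(ncol(X)), function(j) {
    q <- unname(stats::quantile(X[, j], probs, type = 7))
    list(q = q, p = probs)
  })
}

.apply_qt <- function(qt, X) {
  out <- X
  for (j in seq_len(ncol(X))) {
    q <- qt[[j]]$q; p <- qt[[j]]$p
    if (diff(range(q)) == 0) {
      out[, j] <- 0.5
    } else {
      out[, j] <- stats::approx(q, p, xout = X[, j], rule = 2, ties = "ordered")$y
    }
  }
  out
}

# mutual information between a continuous feature and the class label,
# via equal-frequency discretization of the feature
.mi_score <- function(x, y, n_bins = 6) {
  n <- length(x)
  n_bins <- max(2, min(n_bins, floor(n / 4)))
  br <- unique(stats::quantile(x, seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 3) return(0)
  xb <- cut(x, br, include.lowest = TRUE)
  tab <- table(xb, y) / n
  px <- rowSums(tab); py <- colSums(tab)
  nzv <- tab > 0
  sum(tab[nzv] * log(tab[nzv] / outer(px, py)[nzv]))
}

# kNN prediction on explicit distances; ties in distance resolve by smallest
# training index (stable order), ties in votes by smallest class level
.knn_predict <- function(TXtr, ytr, TXte, k, weights) {
  lev <- levels(ytr)
  k <- min(k, nrow(TXtr))
  d2 <- outer(rowSums(TXte^2), rep(1, nrow(TXtr))) +
    outer(rep(1, nrow(TXte)), rowSums(TXtr^2)) - 2 * TXte %*% t(TXtr)
  d2[d2 < 0] <- 0
  pred <- character(nrow(TXte))
  for (i in seq_len(nrow(TXte))) {
    o <- order(d2[i, ])[seq_len(k)]
    w <- if (weights == "distance") {
      di <- sqrt(d2[i, o])
      if (any(di == 0)) as.numeric(di == 0) else 1 / di
    } else rep(1, k)
    votes <- vapply(lev, function(l) sum(w[ytr[o] == l]), numeric(1))
    pred[i] <- lev[which.max(votes)]
  }
  factor(pred, levels = lev)
}

# stratified fold assignment
.strat_folds <- function(y, n_folds) {
  f <- integer(length(y))
  for (l in levels(y)) {
    idx <- which(y == l)
    f[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
  }
  f
}

#' Default hyper-parameter grid for the kNN pipeline
#'
#' Spans the tuned stages: number of landmark quantiles of the quantile
#' transform, percentage of features kept by mutual-information selection,
#' number of neighbors and the neighbor weighting. (Leaf size, a search-tree
#' implementation detail, cannot change exact-kNN predictions and is not
#' part of the grid.)
#'
#' @return Tibble of grid rows.
#' @export
knn_grid <- function() {
  tidyr::expand_grid(
    n_quantiles = c(5, 10, 25),
    percentile = c(40, 60, 80, 100),
    k = c(1, 3, 5, 7),
    weights = c("uniform", "distance"))
}

.fit_pipeline <- function(X, y, params) {
  qt <- .fit_qt(X, params$n_quantiles)
  TX <- .apply_qt(qt, X)
  mi <- vapply(seq_len(ncol(TX)), function(j) .mi_score(TX[, j], y), numeric(1))
  n_keep <- max(1, ceiling(params$percentile / 100 * ncol(TX)))
  sel <- order(mi, decreasing = TRUE)[seq_len(n_keep)]
  sel <- sort(sel)
  list(qt = qt, sel = sel, TX = TX[, sel, drop = FALSE], y = y,
       params = params)
}

.predict_pipeline <- function(model, Xnew) {
  TX <- .apply_qt(model$qt, Xnew)[, model$sel, drop = FALSE]
  .knn_predict(model$TX, model$y, TX, model$params$k, model$params$weights)
}

# inner cross-validated grid search; returns the best grid row
.grid_search <- function(X, y, grid, n_folds) {
  folds <- .strat_folds(y, n_folds)
  acc <- matrix(0, nrow(grid), n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    Xte <- X[!tr, , drop = FALSE]; yte <- y[!tr]
    for (nq in unique(grid$n_quantiles)) {
      qt <- .fit_qt(Xtr, nq)
      TXtr <- .apply_qt(qt, Xtr)
      TXte <- .apply_qt(qt, Xte)
      mi <- vapply(seq_len(ncol(TXtr)), function(j) .mi_score(TXtr[, j], ytr),
                   numeric(1))
      for (pc in unique(grid$percentile)) {
        n_keep <- max(1, ceiling(pc / 100 * ncol(TXtr)))
        sel <- sort(order(mi, decreasing = TRUE)[seq_len(n_keep)])
        rows <- which(grid$n_quantiles == nq & grid$percentile == pc)
        for (r in rows) {
          pred <- .knn_predict(TXtr[, sel, drop = FALSE], ytr,
                               TXte[, sel, drop = FALSE],
                               grid$k[r], grid$weights[r])
          acc[r, f] <- mean(pred == yte)
        }
      }
    }
  }
  grid[which.max(rowMeans(acc)), ]
}

.feature_matrix <- function(table, feature_cols) {
  X <- as.matrix(table[, feature_cols, drop = FALSE])
  if (anyNA(X)) stop("feature table contains missing values")
  storage.mode(X) <- "double"
  X
}

#' Repeated cross-validated kNN phenotype classification
#'
#' The labeled cohort is repeatedly (`n_iter` times) split into a stratified
#' training set (2/3) and a held-out evaluation set (1/3). On each training
#' set a pipeline of quantile transformation, mutual-information feature
#' selection and k-nearest-neighbors classification is tuned by an inner
#' stratified 3-fold grid search ([knn_grid()]), refitted, and scored on the
#' held-out third; the reported performance is the median accuracy over all
#' iterations. All fitted pipelines are retained as an ensemble for
#' [predict_heldout()].
#'
#' @param table feature tibble; one row per animal.
#' @param label_col name of the two-class label column.
#' @param feature_cols feature column names (default: all numeric columns
#'   except the label and any `*_id` column).
#' @param n_iter number of outer train/evaluation splits.
#' @param inner_folds inner CV folds for hyper-parameter tuning.
#' @param grid hyper-parameter grid tibble.
#' @param seed master integer seed; every split and search derives from it.
#' @return A `knn_cv` object: per-iteration `accuracies`, `median_accuracy`,
#'   chosen hyper-parameters (`params`), the fitted ensemble and metadata.
#' @export
tune_and_score <- function(table, label_col = "group", feature_cols = NULL,
                           n_iter = 500, inner_folds = 3, grid = knn_grid(),
                           seed = 1) {
  if (is.null(feature_cols)) {
    num <- names(table)[vapply(table, is.numeric, logical(1))]
    feature_cols <- setdiff(num, c(label_col, grep("_id$", names(table),
                                                   value = TRUE)))
  }
  if (anyDuplicated(feature_cols)) stop("feature names must be unique")
  y <- factor(table[[label_col]])
  if (nlevels(y) != 2) stop("exactly two classes are required")
  if (min(table(y)) < inner_folds) {
    stop("every class needs at least ", inner_folds,
         " members for the inner ", inner_folds, "-fold grid search")
  }
  X <- .feature_matrix(table, feature_cols)
  seeds <- .child_seeds(seed, n_iter)
  accuracies <- numeric(n_iter)
  params <- vector("list", n_iter)
  models <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    set.seed(seeds[it])
    tr_idx <- unlist(lapply(levels(y), function(l) {
      idx <- which(y == l)
      sample(idx, round(2 / 3 * length(idx)))
    }))
    te_idx <- setdiff(seq_along(y), tr_idx)
    best <- .grid_search(X[tr_idx, , drop = FALSE], droplevels(y[tr_idx]),
                         grid, inner_folds)
    model <- .fit_pipeline(X[tr_idx, , drop = FALSE], y[tr_idx], best)
    pred <- .predict_pipeline(model, X[te_idx, , drop = FALSE])
    accuracies[it] <- mean(pred == y[te_idx])
    params[[it]] <- best
    models[[it]] <- model
  }
  structure(
    list(accuracies = accuracies,
         median_accuracy = stats::median(accuracies),
         params = dplyr::bind_rows(params),
         models = models, feature_cols = feature_cols,
         label_col = label_col, label_levels = levels(y),
         n_iter = n_iter, seed = seed),
    class = "knn_cv")
}

#' @export
print.knn_cv <- function(x, ...) {
  cat(sprintf(
    "<knn_cv> %d iterations, median accuracy %.3f (IQR %.3f-%.3f)\n",
    x$n_iter, x$median_accuracy,
    stats::quantile(x$accuracies, 0.25), stats::quantile(x$accuracies, 0.75)))
  invisible(x)
}

#' Ensemble prediction for a held-out cohort
#'
#' Every fitted pipeline of a [tune_and_score()] ensemble votes on each new
#' animal; per animal the majority class and its vote fraction are reported,
#' and per class the fraction of animals whose majority vote lands there
#' (the group-level assignment, e.g. the fraction of rescue-treated animals
#' classified as control).
#'
#' @param cv a `knn_cv` object.
#' @param new_table feature tibble with the same feature columns as the
#'   training table.
#' @return List with `animals` (tibble: `majority_class`, `vote_fraction`
#'   per animal) and `groups` (tibble: `class`, `fraction`).
#' @export
predict_heldout <- function(cv, new_table) {
  missing <- setdiff(cv$feature_cols, names(new_table))
  if (length(missing)) {
    stop("new table lacks training feature column(s): ",
         paste(missing, collapse = ", "))
  }
  X <- .feature_matrix(new_table, cv$feature_cols)
  votes <- vapply(cv$models, function(m) {
    as.character(.predict_pipeline(m, X))
  }, character(nrow(X)))
  votes <- matrix(votes, nrow = nrow(X))
  lev <- cv$label_levels
  frac <- t(apply(votes, 1, function(v) {
    vapply(lev, function(l) mean(v == l), numeric(1))
  }))
  maj <- lev[max.col(frac, ties.method = "first")]
  animals <- tibble::tibble(
    row = seq_len(nrow(X)),
    majority_class = maj,
    vote_fraction = frac[cbind(seq_len(nrow(X)), match(maj, lev))])
  if ("animal_id" %in% names(new_table)) {
    animals$animal_id <- new_table$animal_id
  }
  groups <- tibble::tibble(
    class = lev,
    fraction = vapply(lev, function(l) mean(maj == l), numeric(1)))
  list(animals = animals, groups = groups)
}

#' Two-dimensional decision map of a fitted classifier
#'
#' Embeds the cohort's feature vectors in two dimensions with t-SNE and
#' approximates the classifier's decision space by a Voronoi-style
#' tessellation: a dense grid over the embedded bounding box is colored by
#' nearest-neighbor regression (k = 1) of the ensemble-predicted classes on
#' the embedded coordinates.
#'
#' @param cv a `knn_cv` ensemble from [tune_and_score()].
#' @param table the feature tibble to embed (>= 5 animals).
#' @param grid_n grid resolution per axis.
#' @param perplexity t-SNE perplexity (default adapts to cohort size).
#' @param seed integer seed for the embedding.
#' @return A `decision_map`: list of `points` (tibble with `dim1`, `dim2`,
#'   `label`, `predicted`) and `grid` (tibble with `dim1`, `dim2`, `class`).
#' @export
decision_map <- function(cv, table, grid_n = 60, perplexity = NULL, seed = 1) {
  if (nrow(table) < 5) stop("at least 5 animals are required for an embedding")
  X <- .feature_matrix(table, cv$feature_cols)
  perplexity <- perplexity %||% max(2, min(10, floor((nrow(X) - 1) / 3)))
  set.seed(seed)
  emb <- Rtsne::Rtsne(scale(X), perplexity = perplexity, theta = 0,
                      check_duplicates = FALSE, pca = FALSE, max_iter = 500)$Y
  pred <- predict_heldout(cv, table)$animals$majority_class
  pts <- tibble::tibble(dim1 = emb[, 1], dim2 = emb[, 2],
                        predicted = pred)
  if (cv$label_col %in% names(table)) {
    pts$label <- as.character(table[[cv$label_col]])
  }
  pad <- function(r) r + c(-0.05, 0.05) * diff(r)
  rx <- pad(range(emb[, 1])); ry <- pad(range(emb[, 2]))
  gr <- tidyr::expand_grid(dim1 = seq(rx[1], rx[2], length.out = grid_n),
                           dim2 = seq(ry[1], ry[2], length.out = grid_n))
  nn <- vapply(seq_len(nrow(gr)), function(i) {
    which.min((emb[, 1] - gr$dim1[i])^2 + (emb[, 2] - gr$dim2[i])^2)
  }, integer(1))
  gr$class <- pred[nn]
  structure(list(points = pts, grid = gr), class = "decision_map")
}
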