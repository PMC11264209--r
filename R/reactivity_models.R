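#' Reactive-conformation classifiers
#'
#' Logistic-regression (with LASSO feature selection) and single-hidden-layer
#' neural-network classifiers that predict, from prereaction feature vectors
#' in sliding time windows, whether a turnover attempt will succeed.
#' Training data are single time points per path, weighted by the path's
#' Monte-Carlo multiplicity; cross-validation folds are split by unique path
#' so no path's frames straddle train and test.
#'
#' @name reactivity_models
NULL

#' Build a labeled dataset from pathway ensembles
#'
#' Aligns every path at t = 0 (last compression of the breaking bond),
#' samples one frame per unique path (by default) from the half-open time
#' window, evaluates the feature schema, and labels rows by ensemble type
#' with weight equal to path multiplicity.
#'
#' @param r_ensembles,nr_ensembles Lists of reactive / nonreactive
#'   `path_ensemble`s (frames required).
#' @param schema A `feature_schema`.
#' @param window `c(t_lo, t_hi)` in fs.
#' @param breaking Breaking-bond particle pair for alignment (`NULL` for
#'   scalar-lambda systems).
#' @param frames_per_path Frames sampled per unique path.
#' @param seed Integer seed.
#' @param align Set to `FALSE` if the ensembles are already aligned.
#' @return A `labeled_dataset` tibble: `path_uid`, `label` (`"R"`/`"NR"`),
#'   `weight`, `time`, plus one column per feature; schema and window kept
#'   as attributes.
#' @export
build_dataset <- function(r_ensembles, nr_ensembles, schema,
                          window = c(-160, -130), breaking = NULL,
                          frames_per_path = 1L, seed = 1L, align = TRUE) {
  if (align) {
    r_ensembles <- align_ensembles(r_ensembles, breaking)
    nr_ensembles <- align_ensembles(nr_ensembles, breaking)
  }
  fr_r <- sample_window_frames(r_ensembles, window, frames_per_path,
                               seed = seed_stream(seed, 1))
  fr_nr <- sample_window_frames(nr_ensembles, window, frames_per_path,
                                seed = seed_stream(seed, 2))
  fr_r$label <- "R"; fr_nr$label <- "NR"
  fr <- dplyr::bind_rows(fr_r, fr_nr)
  if (nrow(fr) == 0)
    stop("empty dataset: the window lies outside the aligned time support",
         call. = FALSE)
  out <- compute_feature_matrix(fr, schema)
  out <- dplyr::select(out, "path_uid", "frame_index", "label", "weight",
                       "time", dplyr::all_of(names(schema)))
  structure(out, schema = schema, window = window,
            class = c("labeled_dataset", class(out)))
}

#' Align every path of one or more ensembles at t = 0
#' @param ensembles A `path_ensemble` or list of them.
#' @param breaking Breaking-bond pair (or `NULL`).
#' @return The ensembles with aligned paths.
#' @export
align_ensembles <- function(ensembles, breaking = NULL) {
  single <- inherits(ensembles, "path_ensemble")
  if (single) ensembles <- list(ensembles)
  dropped <- 0L
  out <- lapply(ensembles, function(ens) {
    aligned <- lapply(ens$paths, function(p)
      tryCatch(align_time_zero(p, breaking = breaking),
               error = function(e) NULL))
    keep <- !vapply(aligned, is.null, logical(1))
    dropped <<- dropped + sum(!keep)
    ens$paths <- aligned[keep]
    ens
  })
  if (dropped > 0)
    warning(sprintf("%d path(s) could not be time-aligned and were dropped",
                    dropped), call. = FALSE)
  if (single) out[[1]] else out
}

# ---- metrics ----------------------------------------------------------------

#' Weighted area under the ROC curve
#'
#' @param scores Classifier scores (higher = more reactive-like).
#' @param labels Logical or `"R"`/`"NR"` labels (positive = reactive).
#' @param weights Nonnegative sample weights.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels, weights = NULL) {
  y <- if (is.logical(labels)) labels else labels == "R"
  w <- weights %||% rep(1, length(y))
  sp <- scores[y]; wp <- w[y]
  sn <- scores[!y]; wn <- w[!y]
  if (length(sp) == 0 || length(sn) == 0) return(NA_real_)
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  ww <- outer(wp, wn)
  sum(cmp * ww) / sum(ww)
}

weighted_accuracy <- function(scores, labels, weights, threshold = 0.5) {
  y <- if (is.logical(labels)) labels else labels == "R"
  pred <- scores >= threshold
  sum(weights * (pred == y)) / sum(weights)
}

# fold ids splitting by unique path (all frames of a path share a fold)
path_folds <- function(path_uid, n_folds, seed) {
  paths <- unique(path_uid)
  set.seed(as.integer(seed %% 2147483647))
  shuffled <- sample(paths)
  fold_of <- setNames(rep_len(seq_len(n_folds), length(shuffled)), shuffled)
  unname(fold_of[path_uid])
}

standardizer <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl,
       apply = function(M) sweep(sweep(M, 2, ctr), 2, scl, "/"))
}

# exact-k LASSO selection along the glmnet path; ties by |coef| then order
select_lasso_k <- function(X, y, w, k) {
  if (k >= ncol(X)) return(colnames(X))
  fit <- glmnet::glmnet(X, y, family = "binomial", weights = w, alpha = 1,
                        nlambda = 200, standardize = FALSE)
  df <- fit$df
  hit <- which(df == k)
  if (length(hit) > 0) {
    beta <- fit$beta[, hit[1]]
    return(names(beta)[beta != 0])
  }
  over <- which(df >= k)
  if (length(over) == 0) {   # path never reaches k: rank at the loosest fit
    over <- length(df)
  }
  beta <- fit$beta[, over[1]]
  ord <- order(-abs(beta), seq_along(beta))
  names(beta)[ord[seq_len(k)]]
}

new_trained_model <- function(kind, features, selected, params, center, scale,
                              cv_metrics, window, schema, threshold = 0.5) {
  structure(list(kind = kind, features = features, selected = selected,
                 params = params, center = center, scale = scale,
                 cv_metrics = cv_metrics, window = window, schema = schema,
                 threshold = threshold),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat("<trained_model> ", x$kind, ", ", length(x$selected), "/",
      length(x$features), " features",
      if (!is.null(x$cv_metrics))
        paste0(", CV AUROC ", round(mean(x$cv_metrics$auroc), 3)),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.trained_model <- function(x, ...) x$cv_metrics

#' @export
glance.trained_model <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_features = length(x$selected),
                 cv_auroc = mean(x$cv_metrics$auroc),
                 cv_accuracy = mean(x$cv_metrics$accuracy))
}

#' Predict reactive probabilities
#'
#' @param object A `trained_model`.
#' @param newdata A matrix/tibble with the model's feature columns, or a
#'   frames tibble with a `positions` list-column (features are computed
#'   from the stored schema).
#' @param ... Unused.
#' @return Numeric vector of reactive-class probabilities.
#' @export
predict.trained_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata) && !all(object$selected %in% names(newdata)) &&
      "positions" %in% names(newdata))
    newdata <- compute_feature_matrix(newdata, object$schema)
  X <- as.matrix(as.data.frame(newdata)[, object$selected, drop = FALSE])
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  if (object$kind == "LR") {
    eta <- object$params$intercept + drop(Xs %*% object$params$beta)
    1 / (1 + exp(-eta))
  } else {
    as.numeric(cpp_mlp_predict(Xs, object$params$W1, object$params$b1,
                               object$params$W2, object$params$b2))
  }
}

# ---- LR ---------------------------------------------------------------------

#' Train the logistic-regression classifier
#'
#' When `n_features` is smaller than the schema, a LASSO regularization path
#' is searched so that exactly that many features survive (ties broken by
#' coefficient magnitude, then schema order), and the model is then
#' retrained without regularization on the selected subset. Metrics are
#' reported per fold under path-split cross-validation.
#'
#' @param dataset A `labeled_dataset`.
#' @param n_features `"all"`, 5, 10 or 20 (any positive integer accepted).
#' @param n_folds Cross-validation folds (default 5).
#' @param seed Integer seed (fold assignment).
#' @return A `trained_model` (kind `"LR"`).
#' @export
train_lr <- function(dataset, n_features = "all", n_folds = 5, seed = 1L) {
  d <- prepare_training(dataset)
  k <- if (identical(n_features, "all")) ncol(d$X) else as.integer(n_features)
  folds <- path_folds(d$path_uid, n_folds, seed_stream(seed, 17))
  cv <- purrr::map_dfr(seq_len(n_folds), function(f) {
    tr <- folds != f; te <- !tr
    if (!any(te) || length(unique(d$y[tr])) < 2) return(NULL)
    std <- standardizer(d$X[tr, , drop = FALSE])
    Xtr <- std$apply(d$X[tr, , drop = FALSE])
    sel <- select_lasso_k(Xtr, d$y[tr], d$w[tr], k)
    fitted <- fit_lr(Xtr[, sel, drop = FALSE], d$y[tr], d$w[tr])
    Xte <- std$apply(d$X[te, , drop = FALSE])[, sel, drop = FALSE]
    p <- 1 / (1 + exp(-(fitted$intercept + drop(Xte %*% fitted$beta))))
    tibble::tibble(fold = f, auroc = auroc(p, d$y[te], d$w[te]),
                   accuracy = weighted_accuracy(p, d$y[te], d$w[te]))
  })
  std <- standardizer(d$X)
  Xs <- std$apply(d$X)
  sel <- select_lasso_k(Xs, d$y, d$w, k)
  fitted <- fit_lr(Xs[, sel, drop = FALSE], d$y, d$w)
  new_trained_model("LR", colnames(d$X), sel, fitted,
                    std$center[sel], std$scale[sel], cv,
                    attr(dataset, "window"), attr(dataset, "schema"))
}

fit_lr <- function(X, y, w) {
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial(),
                              weights = w))
  cf <- coef(fit)
  cf[!is.finite(cf)] <- 0
  list(intercept = cf[1], beta = cf[-1])
}

prepare_training <- function(dataset) {
  feat <- setdiff(names(dataset),
                  c("path_uid", "frame_index", "label", "weight", "time"))
  y <- dataset$label == "R"
  if (length(unique(y)) < 2)
    stop("training error: only one class present", call. = FALSE)
  X <- as.matrix(as.data.frame(dataset)[, feat, drop = FALSE])
  if (anyNA(X)) stop("missing feature values", call. = FALSE)
  list(X = X, y = y, w = dataset$weight, path_uid = dataset$path_uid)
}

# ---- NN ---------------------------------------------------------------------

#' Train the neural-network classifier
#'
#' One hidden layer with 70 ReLU nodes, trained with Adam at learning rate
#' 0.001, L2 penalty 1e-4 and batch size 200 (all configurable). For
#' `n_features` below the schema size, greedy forward selection by
#' cross-validated AUROC chooses the subset. Training is fully seeded: the
#' same data and seed give identical metrics.
#'
#' @param dataset A `labeled_dataset`.
#' @param n_features `"all"` or a subset size.
#' @param hidden Hidden-layer width.
#' @param learning_rate,l2,batch_size,epochs Optimizer settings.
#' @param n_folds Cross-validation folds.
#' @param seed Integer seed.
#' @param selection_epochs Epoch budget during greedy selection (defaults to
#'   `epochs`).
#' @return A `trained_model` (kind `"NN"`).
#' @export
train_nn <- function(dataset, n_features = "all", hidden = 70,
                     learning_rate = 0.001, l2 = 1e-4, batch_size = 200,
                     epochs = 200, n_folds = 5, seed = 1L,
                     selection_epochs = NULL) {
  d <- prepare_training(dataset)
  k <- if (identical(n_features, "all")) ncol(d$X) else as.integer(n_features)
  folds <- path_folds(d$path_uid, n_folds, seed_stream(seed, 17))
  sel_epochs <- selection_epochs %||% epochs
  cv_for <- function(sel, eps) {
    res <- purrr::map_dfr(seq_len(n_folds), function(f) {
      tr <- folds != f; te <- !tr
      if (!any(te) || length(unique(d$y[tr])) < 2) return(NULL)
      std <- standardizer(d$X[tr, sel, drop = FALSE])
      Xtr <- std$apply(d$X[tr, sel, drop = FALSE])
      fit <- cpp_mlp_train(Xtr, as.double(d$y[tr]), d$w[tr], hidden,
                           learning_rate, l2, batch_size, eps,
                           seed_stream(seed, 23, f))
      Xte <- std$apply(d$X[te, sel, drop = FALSE])
      p <- as.numeric(cpp_mlp_predict(Xte, fit$W1, fit$b1, fit$W2, fit$b2))
      tibble::tibble(fold = f, auroc = auroc(p, d$y[te], d$w[te]),
                     accuracy = weighted_accuracy(p, d$y[te], d$w[te]))
    })
    res
  }
  feats <- colnames(d$X)
  if (k < length(feats)) {
    sel <- character(0)
    pool <- feats
    while (length(sel) < k) {
      scores <- vapply(pool, function(cand)
        mean(cv_for(c(sel, cand), sel_epochs)$auroc), numeric(1))
      best <- pool[which.max(scores)]
      sel <- c(sel, best)
      pool <- setdiff(pool, best)
    }
  } else sel <- feats
  cv <- cv_for(sel, epochs)
  std <- standardizer(d$X[, sel, drop = FALSE])
  Xs <- std$apply(d$X[, sel, drop = FALSE])
  fit <- cpp_mlp_train(Xs, as.double(d$y), d$w, hidden, learning_rate, l2,
                       batch_size, epochs, seed_stream(seed, 29))
  new_trained_model("NN", feats, sel,
                    list(W1 = fit$W1, b1 = fit$b1, W2 = fit$W2, b2 = fit$b2),
                    std$center, std$scale, cv,
                    attr(dataset, "window"), attr(dataset, "schema"))
}

# ---- window scan ------------------------------------------------------------

#' Scan classifiers over sliding time windows
#'
#' Trains one model per (window, kind, feature count) over 30-fs windows
#' shifted in 5-fs increments across -200 to 0 fs by default (35
#' placements), reporting cross-validated AUROC and accuracy.
#'
#' @param r_ensembles,nr_ensembles Pathway ensembles (frames required).
#' @param schema A `feature_schema`.
#' @param t_range `c(t_lo, t_hi)` fs.
#' @param width,step Window width and shift, fs.
#' @param kinds Subset of `c("LR", "NN")`.
#' @param feature_counts List of `"all"` or integers.
#' @param breaking Breaking-bond pair for alignment.
#' @param seed Integer seed.
#' @param ... Passed to [train_lr()] / [train_nn()].
#' @return A tibble with one row per (window, kind, k): `window_lo`,
#'   `window_hi`, `kind`, `k`, `auroc`, `accuracy`, `n_rows`.
#' @export
scan_windows <- function(r_ensembles, nr_ensembles, schema,
                         t_range = c(-200, 0), width = 30, step = 5,
                         kinds = c("LR", "NN"), feature_counts = list("all"),
                         breaking = NULL, seed = 1L, ...) {
  r_al <- align_ensembles(r_ensembles, breaking)
  nr_al <- align_ensembles(nr_ensembles, breaking)
  los <- seq(t_range[1], t_range[2] - width, by = step)
  purrr::map_dfr(seq_along(los), function(i) {
    win <- c(los[i], los[i] + width)
    ds <- tryCatch(
      suppressWarnings(build_dataset(r_al, nr_al, schema, window = win,
                                     seed = seed_stream(seed, 3, i),
                                     align = FALSE)),
      error = function(e) NULL)
    if (is.null(ds)) return(NULL)
    purrr::map_dfr(kinds, function(kind) {
      purrr::map_dfr(feature_counts, function(kf) {
        m <- if (kind == "LR")
          train_lr(ds, n_features = kf, seed = seed_stream(seed, 4, i), ...)
        else
          train_nn(ds, n_features = kf, seed = seed_stream(seed, 4, i), ...)
        tibble::tibble(window_lo = win[1], window_hi = win[2], kind = kind,
                       k = if (identical(kf, "all")) NA_integer_
                           else as.integer(kf),
                       auroc = mean(m$cv_metrics$auroc),
                       accuracy = mean(m$cv_metrics$accuracy),
                       n_rows = nrow(ds))
      })
    })
  })
}

#' Plot a window-scan metrics table
#' @param scan The tibble from [scan_windows()].
#' @return A ggplot object.
#' @export
plot_window_scan <- function(scan) {
  ggplot2::ggplot(scan, ggplot2::aes(x = (.data$window_lo + .data$window_hi) / 2,
                                     y = .data$auroc,
                                     colour = .data$kind)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "window center (fs)", y = "CV AUROC") +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
}

# ---- population fractions ---------------------------------------------------

#' Weighted reactive-like fraction under a trained model
#'
#' The weighted fraction of frames whose predicted reactive probability is
#' at or above the decision threshold (default 0.5).
#'
#' @param model A `trained_model`.
#' @param frames A frames tibble (with feature columns or a `positions`
#'   list-column) and optional `weight` column.
#' @param weights Optional weights override.
#' @return Fraction in \[0, 1\].
#' @export
reactive_fraction <- function(model, frames, weights = NULL) {
  w <- weights %||% (if (is.data.frame(frames)) frames$weight else NULL) %||%
    rep(1, NROW(frames))
  if (sum(w) <= 0) abort_param("zero total weight")
  p <- predict(model, frames)
  sum(w * (p >= model$threshold)) / sum(w)
}

#' Normalize a fraction by a reference variant
#' @param fraction,ref_fraction Fractions; `ref_fraction` must be > 0.
#' @return The ratio.
#' @export
normalize_by_reference <- function(fraction, ref_fraction) {
  if (ref_fraction <= 0) abort_param("reference fraction must be > 0")
  fraction / ref_fraction
}
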