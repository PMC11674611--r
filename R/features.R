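#' Hybrid brain network of a window
#'
#' Column-wise concatenation of a window's causal matrix (`c x c`, directed
#' region-to-region Granger strengths) and coupling matrix (`c x d`,
#' source-to-fNIRS-channel strengths): the `c x (c+d)` hybrid network treats
#' the source regions as shared nodes carrying both kinds of connectivity.
#'
#' @param gs A [causal_matrix()].
#' @param cs A [coupling_matrix()].
#' @return An object of class `hybrid_network`: list with `h` (`c x (c+d)`),
#'   the block widths `c` and `d`, and the window's `t_start`, `trial_id`,
#'   `label`.
#' @export
hybrid <- function(gs, cs) {
  if (!inherits(gs, "causal_matrix") || !inherits(cs, "coupling_matrix"))
    stop_hbnet("`gs`/`cs` must be causal_matrix / coupling_matrix", "hbnet_argument_error")
  if (nrow(gs$g) != nrow(cs$cs))
    stop_hbnet("causal and coupling matrices disagree on the region count", "hbnet_alignment_error")
  same_window <- function(a, b) is.na(a) || is.na(b) || isTRUE(all.equal(a, b))
  if (!same_window(gs$t_start, cs$t_start) || !same_window(gs$trial_id, cs$trial_id))
    stop_hbnet("causal and coupling matrices come from different windows", "hbnet_alignment_error")
  structure(list(h = cbind(gs$g, cs$cs), c = nrow(gs$g), d = ncol(cs$cs),
                 t_start = gs$t_start, trial_id = gs$trial_id, label = gs$label),
            class = "hybrid_network")
}

#' @export
print.hybrid_network <- function(x, ...) {
  cat(sprintf("<hybrid_network> %d x %d (c = %d, d = %d), t_start = %g s\n",
              nrow(x$h), ncol(x$h), x$c, x$d, x$t_start))
  invisible(x)
}

#' Vectorize a network matrix into a feature vector
#'
#' Row-major flattening (row 1 first), a fixed and documented order so that
#' feature columns mean the same edge in every sample and every run.
#'
#' @param h A `hybrid_network`, `causal_matrix`, `coupling_matrix`, or bare
#'   numeric matrix.
#' @return Numeric vector of length `prod(dim)`.
#' @export
vectorize_network <- function(h) {
  m <- if (inherits(h, "hybrid_network")) h$h
       else if (inherits(h, "causal_matrix")) h$g
       else if (inherits(h, "coupling_matrix")) h$cs
       else h
  if (!is.matrix(m) || !is.numeric(m))
    stop_hbnet("`h` must be (or carry) a numeric matrix", "hbnet_argument_error")
  if (anyNA(m)) stop_hbnet("NaN in network matrix", "hbnet_data_error")
  as.vector(t(m))
}

#' Assemble a feature set from per-window networks
#'
#' Builds the sample-by-feature matrix for one feature kind: `"SG"`
#' vectorizes the causal matrices (F = c^2), `"SC"` the coupling matrices
#' (F = c*d), `"SG_SC"` the hybrid networks (F = c*(c+d)).
#'
#' @param causal List of `causal_matrix` (one per window), or `NULL`.
#' @param coupling List of `coupling_matrix` aligned with `causal`, or `NULL`.
#' @param kind One of `"SG"`, `"SC"`, `"SG_SC"`.
#' @param subject Optional subject identifier.
#' @return An object of class `feature_set`: list with `x` (N x F matrix,
#'   no NaN), integer `labels`, `feature_kind`, `subject`.
#' @export
feature_set <- function(causal = NULL, coupling = NULL,
                        kind = c("SG_SC", "SG", "SC"), subject = NA_character_) {
  kind <- match.arg(kind)
  if (kind %in% c("SG", "SG_SC") && is.null(causal))
    stop_hbnet(sprintf("feature kind %s needs causal matrices", kind), "hbnet_capability_error")
  if (kind %in% c("SC", "SG_SC") && is.null(coupling))
    stop_hbnet(sprintf("feature kind %s needs coupling matrices (fNIRS)", kind),
               "hbnet_capability_error")
  nets <- switch(kind,
    SG = causal,
    SC = coupling,
    SG_SC = {
      if (length(causal) != length(coupling))
        stop_hbnet("causal and coupling window lists differ in length", "hbnet_alignment_error")
      mapply(hybrid, causal, coupling, SIMPLIFY = FALSE)
    })
  x <- do.call(rbind, lapply(nets, vectorize_network))
  labels <- vapply(nets, function(nw) as.integer(nw$label), integer(1L))
  if (anyNA(labels)) stop_hbnet("windows carry no labels", "hbnet_data_error")
  structure(list(x = x, labels = labels, feature_kind = kind, subject = subject),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set:%s> %d samples x %d features, %d classes\n",
              x$feature_kind, nrow(x$x), ncol(x$x), length(unique(x$labels))))
  invisible(x)
}

#' Feature set as a tibble
#'
#' @param x A `feature_set`.
#' @param ... Unused.
#' @return A tibble with a `label` column followed by feature columns `f1..fF`.
#' @method as_tibble feature_set
#' @export
as_tibble.feature_set <- function(x, ...) {
  m <- x$x
  colnames(m) <- paste0("f", seq_len(ncol(m)))
  tb <- tibble::as_tibble(as.data.frame(m))
  tibble::add_column(tb, label = x$labels, .before = 1L)
}

# Stratified fold ids: per class, shuffled round-robin assignment.
.stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

.fit_predict <- function(classifier, x_tr, y_tr, x_te) {
  if (classifier == "svm_linear") {
    fit <- e1071::svm(x_tr, factor(y_tr), kernel = "linear", cost = 1, scale = FALSE)
    as.character(stats::predict(fit, x_te))
  } else {
    as.character(class::knn(x_tr, x_te, cl = factor(y_tr), k = 10L))
  }
}

#' Cross-validated classification of a feature set
#'
#' Reproduces the evaluation protocol: stratified k-fold cross-validation
#' (default 5 folds) repeated `repeats` times with reseeded fold
#' assignments, a linear-kernel SVM (C = 1) or a 10-nearest-neighbor
#' classifier, features z-scored with training-fold statistics only, and a
#' row-normalized confusion matrix pooled over all folds and repeats. Fold
#' assignment is at the window-sample level by default (matching the
#' protocol the networks are built for); `fold_unit = "trial"` keeps all
#' windows of a trial in one fold, avoiding the leakage the 1.5 s overlap
#' otherwise creates across folds.
#'
#' @param fs A [feature_set()].
#' @param classifier `"svm_linear"` or `"knn10"`.
#' @param k_folds Number of folds (default 5).
#' @param repeats Number of repetitions (default 5).
#' @param seed Integer seed for fold assignment.
#' @param fold_unit `"sample"` (default) or `"trial"`.
#' @param trial_ids Required for `fold_unit = "trial"`: one id per sample.
#' @return An object of class `hbn_eval`: accuracy mean and sd over repeats,
#'   per-repeat accuracies, per-class accuracies, row-normalized confusion
#'   matrix, and the protocol settings.
#' @export
evaluate_features <- function(fs, classifier = c("svm_linear", "knn10"),
                              k_folds = 5L, repeats = 5L, seed = 1L,
                              fold_unit = c("sample", "trial"),
                              trial_ids = NULL) {
  stopifnot(inherits(fs, "feature_set"))
  classifier <- match.arg(classifier)
  fold_unit <- match.arg(fold_unit)
  labels <- fs$labels
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop_hbnet("need at least 2 classes", "hbnet_protocol_error")
  if (min(table(labels)) < k_folds)
    stop_hbnet("a class has fewer samples than folds", "hbnet_protocol_error")
  if (fold_unit == "trial" && is.null(trial_ids))
    stop_hbnet("`trial_ids` required for trial-level folds", "hbnet_argument_error")
  conf <- matrix(0, length(classes), length(classes),
                 dimnames = list(true = classes, predicted = classes))
  acc <- numeric(repeats)
  with_seed(seed, {
    for (rep_i in seq_len(repeats)) {
      folds <- if (fold_unit == "sample") {
        .stratified_folds(labels, k_folds)
      } else {
        tr_lab <- vapply(split(labels, trial_ids), `[`, integer(1L), 1L)
        tf <- .stratified_folds(tr_lab, k_folds)
        tf[match(as.character(trial_ids), names(tr_lab))]
      }
      pred <- character(length(labels))
      for (fk in seq_len(k_folds)) {
        te <- folds == fk
        mu <- colMeans(fs$x[!te, , drop = FALSE])
        sg <- apply(fs$x[!te, , drop = FALSE], 2L, stats::sd)
        sg[sg == 0] <- 1
        x_tr <- sweep(sweep(fs$x[!te, , drop = FALSE], 2L, mu), 2L, sg, "/")
        x_te <- sweep(sweep(fs$x[te, , drop = FALSE], 2L, mu), 2L, sg, "/")
        pred[te] <- .fit_predict(classifier, x_tr, labels[!te], x_te)
      }
      acc[rep_i] <- mean(pred == as.character(labels))
      conf <- conf + unclass(table(factor(labels, classes), factor(pred, classes)))
    }
  })
  conf_norm <- conf / rowSums(conf)
  structure(list(accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
                 per_repeat = acc, per_class = diag(conf_norm),
                 confusion = conf_norm, counts = unclass(table(labels)),
                 classifier = classifier, feature_kind = fs$feature_kind,
                 k_folds = k_folds, repeats = repeats, seed = seed,
                 fold_unit = fold_unit),
            class = "hbn_eval")
}

#' @export
print.hbn_eval <- function(x, ...) {
  cat(sprintf("<hbn_eval> %s on %s: accuracy %.1f%% +/- %.2f (%d-fold CV x %d)\n",
              x$classifier, x$feature_kind, 100 * x$accuracy_mean,
              100 * x$accuracy_sd, x$k_folds, x$repeats))
  invisible(x)
}
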