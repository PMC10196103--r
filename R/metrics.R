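# Dice coefficients, one-vs-rest classification metrics and the stratified
# k-fold cross-validation harness.

#' Dice overlap coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)` between a reference and a predicted voxel set.
#' When both masks are empty the class is legitimately absent from both
#' volumes (the suprasellar cistern can be effaced entirely), so the
#' default convention scores 1; set `empty_value` to change this.
#'
#' @param a,b Logical (or 0/1) arrays of identical shape.
#' @param empty_value Value returned when both masks are empty.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b, empty_value = 1) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stop("masks must have identical shape", call. = FALSE)
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(empty_value)
  2 * sum(a & b) / denom
}

#' Per-class Dice report for two label maps
#'
#' Binary Dice for each foreground class 1..6 (background excluded) plus
#' their arithmetic mean, the summary used to judge multi-tissue
#' segmentation quality.
#'
#' @param pred,ref [label_map()]s of identical shape and spacing.
#' @param empty_value Passed to [dice()].
#' @return A list of class `dice_report` with `per_class` (named numeric,
#'   length 6) and `mean`.
#' @export
multiclass_dice <- function(pred, ref, empty_value = 1) {
  stopifnot(inherits(pred, "label_map"), inherits(ref, "label_map"))
  if (!identical(dim(pred$voxels), dim(ref$voxels)))
    stop("label maps must have identical shape", call. = FALSE)
  classes <- 1:6
  d <- vapply(classes, function(c)
    dice(pred$voxels == c, ref$voxels == c, empty_value), numeric(1))
  names(d) <- names(qst_labels())[-1]
  structure(list(per_class = d, mean = mean(d)), class = "dice_report")
}

#' @export
print.dice_report <- function(x, ...) {
  cat("<dice_report>\n")
  print(round(x$per_class, 4))
  cat("mean:", round(x$mean, 4), "\n")
  invisible(x)
}

#' One-vs-rest performance report for QST predictions
#'
#' Builds the 3x3 confusion matrix and, for each subtype, the one-vs-rest
#' sensitivity, specificity, Youden index (sensitivity + specificity - 1)
#' and accuracy, plus the overall three-class accuracy.
#'
#' @param y_true,y_pred Character vectors of `"Q"/"S"/"T"`, equal length.
#' @return A list of class `classification_report` with `confusion`
#'   (3x3 matrix, rows = truth), `per_type` (data frame) and `accuracy`.
#' @export
classification_report <- function(y_true, y_pred) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred))
    stop("`y_true` and `y_pred` must be nonempty and of equal length",
         call. = FALSE)
  types <- qst_types()
  y_true <- factor(as.character(y_true), levels = types)
  y_pred <- factor(as.character(y_pred), levels = types)
  if (anyNA(y_true) || anyNA(y_pred))
    stop("labels must be Q, S or T", call. = FALSE)
  cm <- table(truth = y_true, prediction = y_pred)
  n <- sum(cm)
  per <- do.call(rbind, lapply(types, function(t) {
    tp <- cm[t, t]
    fn <- sum(cm[t, ]) - tp
    fp <- sum(cm[, t]) - tp
    tn <- n - tp - fn - fp
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    data.frame(type = t, sensitivity = sens, specificity = spec,
               youden = sens + spec - 1, accuracy = (tp + tn) / n)
  }))
  structure(list(confusion = unclass(cm), per_type = per,
                 accuracy = sum(diag(cm)) / n),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> overall accuracy",
      round(x$accuracy, 4), "\n")
  print(x$confusion)
  print(x$per_type, row.names = FALSE, digits = 4)
  invisible(x)
}

#' k-fold cross-validation splits
#'
#' Partitions indices `1..n` into `k` folds with sizes differing by at most
#' one. When `labels` are supplied, folds are stratified: each class's
#' shuffled indices are dealt greedily to the currently smallest folds, so
#' per-class counts across folds also differ by at most one.
#'
#' @param n Number of samples.
#' @param k Number of folds (`2 <= k <= n`).
#' @param labels Optional vector of class labels, length `n`.
#' @param seed Integer seed; identical seeds give identical folds.
#' @return A list of `k` integer index vectors.
#' @export
make_cv_folds <- function(n, k = 5L, labels = NULL, seed = 1L) {
  if (k < 2 || k > n) stop("need 2 <= k <= n", call. = FALSE)
  with_seed(seed, {
    folds <- vector("list", k)
    if (is.null(labels)) {
      sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
      folds <- unname(split(sample.int(n), rep(seq_len(k), sizes)))
    } else {
      stopifnot(length(labels) == n)
      load <- integer(k)
      for (cls in names(sort(table(labels), decreasing = TRUE))) {
        idx <- sample(which(labels == cls))
        # cycle the folds, least-loaded first, so the class spreads +-1
        # and any partial cycle lands on the smallest folds
        perm <- order(load, runif(k))
        fseq <- rep(perm, length.out = length(idx))
        for (a in seq_along(idx)) {
          f <- fseq[a]
          folds[[f]] <- c(folds[[f]], idx[a])
          load[f] <- load[f] + 1L
        }
      }
    }
    lapply(folds, function(ix) sort(unname(as.integer(ix))))
  })
}

#' Write a report as CSV or JSON
#'
#' Serializes a [multiclass_dice()] or [classification_report()] result.
#' CSV mirrors a metric-by-type table; JSON keeps the full structure.
#'
#' @param report A `dice_report` or `classification_report`.
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    x <- if (inherits(report, "dice_report"))
      list(per_class = as.list(report$per_class), mean = report$mean)
    else list(confusion = report$confusion, per_type = report$per_type,
              accuracy = report$accuracy)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else if (inherits(report, "dice_report")) {
    write.csv(data.frame(class = c(names(report$per_class), "mean"),
                         dice = c(report$per_class, report$mean)),
              path, row.names = FALSE)
  } else {
    df <- report$per_type
    df$overall_accuracy <- report$accuracy
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
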