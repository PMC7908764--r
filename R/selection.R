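# Feature normalization, per-feature inter-class distance
# d(Ci, Cj) = |m_i - m_j| - s(Ci) - s(Cj), descending ranking and top-k
# selection. The scatter s() is the per-class sample standard deviation
# (n - 1 denominator); distances can be negative (overlapping classes) and
# are reported as such -- they still carry ranking information.

#' Pooled z-score normalization of a feature matrix
#'
#' Each column is centered and scaled by its pooled (both classes) mean
#' and sample standard deviation. Zero-variance columns map to all zeros
#' with a warning. `NA` entries are ignored in the statistics and
#' propagated.
#'
#' @param X numeric matrix or data.frame of feature columns (samples in
#'   rows, >= 2 rows).
#' @param method `"zscore"` (default) or `"minmax"` (to [0, 1]).
#' @return numeric matrix of the same shape.
#' @export
normalize_features <- function(X, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("feature matrix must be numeric", call. = FALSE)
  if (nrow(X) < 2L)
    stop("need at least 2 samples to normalize", call. = FALSE)
  out <- X
  degenerate <- character(0)
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    if (method == "zscore") {
      s <- stats::sd(v, na.rm = TRUE)
      if (!is.finite(s) || s == 0) {
        out[, j] <- ifelse(is.na(v), NA_real_, 0)
        degenerate <- c(degenerate, colnames(X)[j] %||% as.character(j))
      } else {
        out[, j] <- (v - mean(v, na.rm = TRUE)) / s
      }
    } else {
      r <- suppressWarnings(range(v, na.rm = TRUE))
      if (!all(is.finite(r)) || r[2] == r[1]) {
        out[, j] <- ifelse(is.na(v), NA_real_, 0)
        degenerate <- c(degenerate, colnames(X)[j] %||% as.character(j))
      } else {
        out[, j] <- (v - r[1]) / (r[2] - r[1])
      }
    }
  }
  if (length(degenerate))
    warning("zero-variance feature column(s) mapped to zeros: ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inter-class distance of one feature
#'
#' d = |m_i - m_j| - s(Ci) - s(Cj), with m the class mean and s the class
#' sample standard deviation. Larger is better: the classes are far apart
#' relative to their scatter. `NA` values are dropped per class; a class
#' with fewer than 2 non-missing values is an error (its scatter is
#' undefined).
#'
#' @param values numeric vector (one feature across samples).
#' @param labels class label per sample; exactly 2 classes.
#' @return scalar distance (may be negative).
#' @export
inter_class_distance <- function(values, labels) {
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) != 2L)
    stop("need exactly 2 classes, got ", length(cls), call. = FALSE)
  a <- values[labels == cls[1] & !is.na(values)]
  b <- values[labels == cls[2] & !is.na(values)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each class needs >= 2 non-missing samples", call. = FALSE)
  abs(mean(a) - mean(b)) - stats::sd(a) - stats::sd(b)
}

#' Rank features by inter-class distance and select the top k
#'
#' Normalizes the feature matrix (pooled z-score by default), computes the
#' inter-class distance of every column, sorts descending (ties broken by
#' canonical column order) and returns the top `k` feature names together
#' with the full per-feature table.
#'
#' @param X numeric matrix / data.frame, one named column per feature.
#' @param labels class label per row; exactly 2 classes.
#' @param k number of features to select (default 25).
#' @param normalize normalize first (default TRUE; set FALSE when `X` is
#'   already normalized or for raw-scale diagnostics).
#' @param method normalization method, see [normalize_features()].
#' @return An `icd_result`: list with `table` (data.frame: feature,
#'   mean_<class1>, mean_<class2>, s_<class1>, s_<class2>, distance, rank,
#'   selected -- in canonical column order) and `selected` (character
#'   vector of `k` names in rank order).
#' @export
rank_and_select <- function(X, labels, k = 25L, normalize = TRUE,
                            method = "zscore") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("feature", seq_len(ncol(X)))
  k <- as.integer(k)
  if (k < 1L || k > ncol(X))
    stop(sprintf("`k` must be in 1 .. %d", ncol(X)), call. = FALSE)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2L)
    stop("need exactly 2 classes", call. = FALSE)
  Xn <- if (normalize)
    suppressWarnings(normalize_features(X, method = method)) else X
  stat <- function(j) {
    v <- Xn[, j]
    a <- v[labels == cls[1] & !is.na(v)]
    b <- v[labels == cls[2] & !is.na(v)]
    if (length(a) < 2L || length(b) < 2L)
      stop("each class needs >= 2 non-missing samples for feature ",
           colnames(X)[j], call. = FALSE)
    c(mean(a), mean(b), stats::sd(a), stats::sd(b),
      abs(mean(a) - mean(b)) - stats::sd(a) - stats::sd(b))
  }
  s <- vapply(seq_len(ncol(Xn)), stat, numeric(5))
  dist <- s[5, ]
  # descending distance; order() on -dist with index tiebreak = canonical
  rk <- integer(ncol(Xn))
  rk[order(-dist, seq_along(dist))] <- seq_along(dist)
  tab <- data.frame(feature = colnames(X),
                    m1 = s[1, ], m2 = s[2, ], s1 = s[3, ], s2 = s[4, ],
                    distance = dist, rank = rk, selected = rk <= k,
                    stringsAsFactors = FALSE)
  names(tab)[2:5] <- c(paste0("mean_", cls), paste0("s_", cls))
  structure(list(table = tab,
                 selected = tab$feature[order(tab$rank)][seq_len(k)],
                 k = k, classes = cls),
            class = "icd_result")
}

#' @export
print.icd_result <- function(x, ...) {
  cat(sprintf("<icd_result> %d features ranked (%s vs %s), top %d selected\n",
              nrow(x$table), x$classes[1], x$classes[2], x$k))
  top <- x$table[order(x$table$rank), c("feature", "distance", "rank")]
  print(utils::head(top, 10), row.names = FALSE)
  invisible(x)
}
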