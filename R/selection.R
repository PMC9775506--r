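#' Min-max normalize feature columns
#'
#' Linearly maps every column onto \[0, 1\]:
#' `X' = (X - min(X)) / (max(X) - min(X))`. Constant columns map to 0.
#' Missing values are ignored when computing the extremes and propagate
#' unchanged. Idempotent.
#'
#' @param x Numeric matrix or data frame of features (rows = participants).
#' @return Object of the same shape with normalized columns.
#' @export
minmax_normalize <- function(x) {
  is_df <- is.data.frame(x)
  m <- as.matrix(x)
  out <- apply(m, 2, function(col) {
    if (all(is.na(col))) stop("column with no finite values cannot be normalized")
    lo <- min(col, na.rm = TRUE); hi <- max(col, na.rm = TRUE)
    if (hi == lo) return(rep(0, length(col)) + col * 0)  # keeps NAs
    (col - lo) / (hi - lo)
  })
  out <- matrix(out, nrow = nrow(m), dimnames = dimnames(m))
  if (is_df) as.data.frame(out) else out
}

#' Impute missing feature values by the column median
#'
#' Undefined features (e.g. a latency/mean ratio at zero mean amplitude)
#' are replaced by the median of the observed values in their column.
#'
#' @param x Numeric matrix or data frame.
#' @return Same shape, no `NA`s (errors if a column is entirely missing).
#' @export
impute_median <- function(x) {
  is_df <- is.data.frame(x)
  m <- as.matrix(x)
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (all(miss)) stop("column ", colnames(m)[j], " is entirely missing")
    if (any(miss)) m[miss, j] <- stats::median(m[, j], na.rm = TRUE)
  }
  if (is_df) as.data.frame(m) else m
}

#' ReliefF feature weights
#'
#' Distance-based feature weighting: for every sample (all samples are used
#' as anchors, making the procedure deterministic), find its `k` nearest
#' same-class neighbors (hits) and `k` nearest different-class neighbors
#' (misses) under the Manhattan distance on range-normalized features; the
#' weight of a feature is the average over anchors of (mean absolute
#' feature difference to the misses) minus (mean absolute difference to the
#' hits). Informative features separate classes, so their miss-differences
#' exceed their hit-differences and their weights are positive.
#'
#' @param x Numeric matrix/data frame (rows = samples); normalize first
#'   (see [minmax_normalize()]).
#' @param labels Class labels (length `nrow(x)`), two or more classes.
#' @param k Number of neighbors; must be smaller than every class size.
#' @return List of class `gsat_ranking`: `method = "ReliefF"`, `scores`
#'   (named, descending), `ranking` (feature names, best first; ties broken
#'   by ascending feature name).
#' @export
relieff_rank <- function(x, labels, k = 10) {
  m <- as.matrix(x)
  labels <- as.character(labels)
  n <- nrow(m); p <- ncol(m)
  cls_sizes <- table(labels)
  if (k >= min(cls_sizes))
    stop("k_neighbors (", k, ") must be smaller than the smallest class size (",
         min(cls_sizes), ")")
  rng <- apply(m, 2, function(col) diff(range(col)))
  rng[rng == 0] <- 1                   # constant features contribute 0 anyway
  mn <- sweep(m, 2, rng, "/")
  d <- as.matrix(stats::dist(mn, method = "manhattan"))
  w <- numeric(p)
  for (i in seq_len(n)) {
    same <- which(labels == labels[i]); same <- setdiff(same, i)
    diff_cls <- which(labels != labels[i])
    hits <- same[order(d[i, same], same)][seq_len(k)]
    misses <- diff_cls[order(d[i, diff_cls], diff_cls)][seq_len(k)]
    dh <- abs(mn[hits, , drop = FALSE] -
                matrix(mn[i, ], k, p, byrow = TRUE))
    dm <- abs(mn[misses, , drop = FALSE] -
                matrix(mn[i, ], k, p, byrow = TRUE))
    w <- w + colMeans(dm) - colMeans(dh)
  }
  scores <- w / n
  names(scores) <- colnames(m)
  make_ranking("ReliefF", scores)
}

# entropy (bits) of a label vector
label_entropy <- function(y) {
  p <- table(y) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' GainRatio feature scores
#'
#' For each (continuous) feature, the best binary split threshold is chosen
#' to maximize the information gain
#' `Gain = H(S) - sum_v |S_v|/|S| * H(S_v)` over candidate thresholds
#' (midpoints of consecutive distinct values). The split information
#' `SplitInfo = -sum_v |S_v|/|S| * log2(|S_v|/|S|)` of that split then
#' normalizes the gain: `GainRatio = Gain / SplitInfo`, defined as 0 when
#' `SplitInfo = 0` (constant feature).
#'
#' @inheritParams relieff_rank
#' @return `gsat_ranking` with `method = "GainRatio"`.
#' @export
gainratio_rank <- function(x, labels) {
  m <- as.matrix(x)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("GainRatio requires at least two classes")
  h_s <- label_entropy(labels)
  n <- nrow(m)
  scores <- apply(m, 2, function(col) {
    vals <- sort(unique(col))
    if (length(vals) < 2) return(0)
    thr <- (vals[-1] + vals[-length(vals)]) / 2
    best_gain <- -Inf; best_split <- NULL
    for (t in thr) {
      left <- col <= t
      nl <- sum(left)
      gain <- h_s - (nl / n) * label_entropy(labels[left]) -
        ((n - nl) / n) * label_entropy(labels[!left])
      if (gain > best_gain + 1e-12) {
        best_gain <- gain
        best_split <- nl
      }
    }
    pl <- best_split / n
    split_info <- -(pl * log2(pl) + (1 - pl) * log2(1 - pl))
    if (split_info == 0) 0 else best_gain / split_info
  })
  names(scores) <- colnames(m)
  make_ranking("GainRatio", scores)
}

make_ranking <- function(method, scores) {
  ord <- order(-scores, names(scores))
  structure(list(method = method, scores = scores[ord],
                 ranking = names(scores)[ord]),
            class = "gsat_ranking")
}

#' Intersect the top-k features of two rankings
#'
#' The final feature subset is the set intersection of the two methods' top
#' `k` lists (k = 18 of 36 by default), ordered by the first ranking
#' (ReliefF, by convention).
#'
#' @param r1,r2 `gsat_ranking` objects over the same feature universe.
#' @param k Depth of each top list.
#' @return Character vector of selected feature names, ordered by `r1`.
#' @export
intersect_top_k <- function(r1, r2, k = 18) {
  stopifnot(inherits(r1, "gsat_ranking"), inherits(r2, "gsat_ranking"))
  if (!setequal(r1$ranking, r2$ranking))
    stop("rankings cover different feature universes")
  top1 <- utils::head(r1$ranking, k)
  top2 <- utils::head(r2$ranking, k)
  sel <- top1[top1 %in% top2]
  if (!length(sel))
    stop("top-", k, " lists of ", r1$method, " and ", r2$method,
         " have an empty intersection; raise k")
  sel
}
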