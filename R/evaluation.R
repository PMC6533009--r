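## Detection scoring: greedy one-to-one point matching at radius rho,
## precision/recall/F1, pixel-wise ROC AUC, and counting error.

#' Match detections to ground-truth points
#'
#' One-to-one matching at radius `rho`: candidate pairs closer than `rho`
#' are first paired greedily in increasing distance order (ties broken by
#' detection confidence, then by index), and the pairing is then completed
#' by augmenting paths so that the number of matched pairs is the maximum
#' possible — a pure greedy pass can strand matchable pairs when one
#' detection sits between two truths.  Each detection and each truth is
#' matched at most once; unmatched detections are false positives,
#' unmatched truths false negatives.
#'
#' @param detections Data frame with columns `x`, `y` (and optionally
#'   `confidence`) in the same units as `truth`.
#' @param truth Data frame with columns `x`, `y`.
#' @param rho Matching radius (default 0.6, micrometers when coordinates
#'   are in micrometers).
#' @return A `match_result` list: `pairs` (data frame of det/truth indices
#'   and distances), `fp`, `fn` (index vectors), counts `tp`/`fp_n`/`fn_n`,
#'   and `rho`.
#' @export
match_detections <- function(detections, truth, rho = 0.6) {
  nd <- if (is.null(detections)) 0L else nrow(detections)
  nt <- if (is.null(truth)) 0L else nrow(truth)
  pairs <- data.frame(det = integer(), truth = integer(), dist = numeric())
  if (nd > 0 && nt > 0) {
    dd <- outer(detections$x, truth$x, `-`)^2 + outer(detections$y, truth$y, `-`)^2
    cand <- which(dd < rho^2, arr.ind = TRUE)
    if (nrow(cand)) {
      conf <- if (!is.null(detections$confidence)) detections$confidence else
        numeric(nd)
      d <- sqrt(dd[cand])
      ord <- order(d, -conf[cand[, 1]], cand[, 1], cand[, 2])
      ## candidate truths per detection, nearest first
      adj <- vector("list", nd)
      for (i in ord) adj[[cand[i, 1]]] <- c(adj[[cand[i, 1]]], cand[i, 2])
      match_t <- integer(nt)   # truth -> detection (0 = free)
      ## greedy pass in increasing distance order
      for (i in ord) {
        di <- cand[i, 1]; ti <- cand[i, 2]
        if (!di %in% match_t && match_t[ti] == 0L) match_t[ti] <- di
      }
      ## augmenting-path completion (maximum cardinality)
      augment <- function(di, visited) {
        for (ti in adj[[di]]) {
          if (visited[ti]) next
          visited[ti] <- TRUE
          if (match_t[ti] == 0L) { match_t[ti] <<- di; return(TRUE) }
          prev <- match_t[ti]
          match_t[ti] <<- di
          if (augment(prev, visited)) return(TRUE)
          match_t[ti] <<- prev
        }
        FALSE
      }
      for (di in seq_len(nd))
        if (!di %in% match_t && length(adj[[di]]))
          augment(di, logical(nt))
      ti <- which(match_t > 0L)
      if (length(ti))
        pairs <- data.frame(det = match_t[ti], truth = ti,
                            dist = sqrt(dd[cbind(match_t[ti], ti)]))
    }
  }
  fp <- setdiff(seq_len(nd), pairs$det)
  fn <- setdiff(seq_len(nt), pairs$truth)
  structure(list(pairs = pairs, fp = fp, fn = fn, tp = nrow(pairs),
                 fp_n = length(fp), fn_n = length(fn), rho = rho),
            class = "match_result")
}

#' Precision, recall and F1 from a match result
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`; empty denominators
#' yield 0 by convention.
#'
#' @param match A [match_detections()] result (or a list with `tp`,
#'   `fp_n`, `fn_n`).
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(match) {
  tp <- match$tp; fp <- match$fp_n; fn <- match$fn_n
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Pixel-wise ROC AUC of a probability map
#'
#' Treats every pixel as one sample with score equal to the map value and
#' label from the binary mask, and computes the exact rank-statistic
#' (Mann-Whitney) form of the area under the ROC curve, which is free of
#' any threshold-grid choice and invariant under strictly monotone
#' transforms of the map.
#'
#' @param map Matrix of scores.
#' @param gt_mask Binary matrix of the same shape with both classes present.
#' @return Scalar AUC in \[0, 1\].
#' @export
pixel_auc <- function(map, gt_mask) {
  if (!identical(dim(map), dim(gt_mask))) stop("shapes differ")
  lab <- gt_mask > 0
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0 || n0 == 0)
    stop("ground-truth mask must contain both classes")
  r <- rank(map)
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Absolute difference in counting
#'
#' `| number of detections - number of annotated synapses |`.
#'
#' @param detections Data frame of detections (or its row count).
#' @param truth Data frame of ground-truth points (or its row count).
#' @return Non-negative integer.
#' @export
dic <- function(detections, truth) {
  nd <- if (is.data.frame(detections)) nrow(detections) else
    if (is.null(detections)) 0L else as.integer(detections)
  nt <- if (is.data.frame(truth)) nrow(truth) else
    if (is.null(truth)) 0L else as.integer(truth)
  abs(nd - nt)
}

#' Aggregate metric reports over independent runs
#'
#' Training is stochastic (initialization jitter, patch sampling), so
#' benchmark values are reported as the arithmetic mean over independent
#' runs of each per-run metric — the mean of per-run F1 values, not the F1
#' of pooled counts.
#'
#' @param reports List of named numeric vectors (per-run metrics).
#' @return A `metrics_report` list with `mean` (named vector) and `runs`
#'   (matrix, one row per run).
#' @export
aggregate_runs <- function(reports) {
  stopifnot(length(reports) >= 1)
  runs <- do.call(rbind, reports)
  structure(list(mean = colMeans(runs), runs = runs, n_runs = nrow(runs)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Metrics over", x$n_runs, "run(s):\n")
  print(round(x$mean, 4))
  invisible(x)
}

#' Score a detection table against ground truth
#'
#' Convenience wrapper combining [match_detections()],
#' [precision_recall_f1()] and [dic()].
#'
#' @inheritParams match_detections
#' @return Named numeric vector with precision, recall, f1, tp, fp, fn, dic.
#' @export
evaluate_detections <- function(detections, truth, rho = 0.6) {
  m <- match_detections(detections, truth, rho)
  c(precision_recall_f1(m), tp = m$tp, fp = m$fp_n, fn = m$fn_n,
    dic = dic(detections, truth))
}
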