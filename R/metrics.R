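#' Classification metrics
#'
#' `metric_auroc()` is the Mann-Whitney rank statistic (tied scores get half
#' credit); it returns `NA` when only one class is present. `metric_acc()`
#' and `metric_f1()` threshold scores at 0.5.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 labels.
#' @return A single number (or `NA`).
#' @export
#' @examples
#' metric_auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))  # 1
metric_auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0L || nneg == 0L) return(NA_real_)
  r <- rank(scores)  # average ranks: ties count half
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' @rdname metric_auroc
#' @export
metric_acc <- function(scores, labels) {
  mean((scores >= 0.5) == (labels == 1))
}

#' @rdname metric_auroc
#' @export
metric_f1 <- function(scores, labels) {
  pred <- scores >= 0.5
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

metric_row <- function(scores, labels) {
  tibble::tibble(
    acc = metric_acc(scores, labels),
    auroc = metric_auroc(scores, labels),
    f1 = metric_f1(scores, labels),
    n = length(labels)
  )
}
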