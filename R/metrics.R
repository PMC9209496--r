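#' Set-based multi-label metrics
#'
#' Example-based metrics for multi-label prediction, computed on label sets:
#' \describe{
#'   \item{IoU}{`|pred n truth| / |pred u truth|`; 1 iff the sets are equal;
#'     reduces to 0/1 accuracy for single-label tasks.}
#'   \item{Precision}{`|pred n truth| / |pred|`; an empty prediction is
#'     scored 0.}
#'   \item{Recall}{`|pred n truth| / |truth|`.}
#'   \item{F1}{`2PR / (P + R)`, 0 when `P + R = 0`.}
#' }
#' The ground-truth set must be non-empty.
#'
#' @param prediction character vector (treated as a set).
#' @param truth non-empty character vector (treated as a set).
#' @return a real in \[0, 1\].
#' @export
set_iou <- function(prediction, truth) {
  truth <- unique(truth)
  if (length(truth) == 0) psp_abort("truth set is empty; IoU undefined", "psp_empty_truth")
  prediction <- unique(prediction)
  length(intersect(prediction, truth)) / length(union(prediction, truth))
}

#' @rdname set_iou
#' @export
set_precision <- function(prediction, truth) {
  truth <- unique(truth)
  if (length(truth) == 0) psp_abort("truth set is empty", "psp_empty_truth")
  prediction <- unique(prediction)
  if (length(prediction) == 0) return(0)
  length(intersect(prediction, truth)) / length(prediction)
}

#' @rdname set_iou
#' @export
set_recall <- function(prediction, truth) {
  truth <- unique(truth)
  if (length(truth) == 0) psp_abort("truth set is empty", "psp_empty_truth")
  length(intersect(unique(prediction), truth)) / length(truth)
}

#' @rdname set_iou
#' @export
set_f1 <- function(prediction, truth) {
  p <- set_precision(prediction, truth)
  r <- set_recall(prediction, truth)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}
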