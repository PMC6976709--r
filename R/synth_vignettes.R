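#' Confusion specification for synthetic classifier output
#'
#' Describes a probabilistic classifier acting on `n_fine` fine classes that
#' are mapped onto broader groups. A row-stochastic confusion matrix gives
#' `P(predicted fine | true fine)`; the classifier's top-1 confidence is drawn
#' from one of two Beta distributions depending on whether the prediction is
#' correct. Beta confidences are a modelling assumption (deep-net confidence
#' shapes vary); the defaults place the correct-prediction mode near 0.9 and
#' the incorrect-prediction mode near 0.6, so that probability filtering is
#' informative but not trivial.
#'
#' @param confusion square row-stochastic matrix, `confusion[i, j] =
#'   P(pred = j | true = i)`; row and column names are the fine class ids.
#' @param mapping data.frame with columns `fine` and `group`; must cover
#'   every fine class (total mapping). The group id `"unknown"` is reserved
#'   for filtered vignettes and may not be a mapping target.
#' @param class_abundances named vector of expected vignette counts per true
#'   fine class (names = fine class ids). Classes may have abundance 0.
#' @param conf_correct,conf_incorrect length-2 vectors of Beta shape
#'   parameters for the top-1 confidence of correct and incorrect
#'   predictions. Support must be (0, 1), i.e. both shapes > 0 and finite.
#' @param seed integer seed.
#' @return An object of class `confusion_spec`.
#' @seealso [gen_classified_vignettes()]
#' @export
confusion_spec <- function(confusion, mapping, class_abundances,
                           conf_correct = c(9, 2), conf_incorrect = c(4, 3),
                           seed = 1L) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
  fine <- rownames(confusion)
  if (is.null(fine)) {
    fine <- as.character(seq_len(nrow(confusion)))
    dimnames(confusion) <- list(fine, fine)
  }
  if (any(abs(rowSums(confusion) - 1) > 1e-9))
    stop("confusion rows must each sum to 1 (tolerance 1e-9)")
  if (any(confusion < 0)) stop("confusion entries must be non-negative")
  stopifnot(is.data.frame(mapping), all(c("fine", "group") %in% names(mapping)))
  if (!all(fine %in% mapping$fine))
    stop("mapping must be total: every fine class needs a group")
  if ("unknown" %in% mapping$group)
    stop('"unknown" is reserved and may not be a mapping target')
  if (is.null(names(class_abundances)) ||
      !all(names(class_abundances) %in% fine))
    stop("class_abundances must be named by fine class ids")
  if (any(class_abundances < 0)) stop("class abundances must be >= 0")
  check_beta <- function(sh, what) {
    if (length(sh) != 2 || any(!is.finite(sh)) || any(sh <= 0))
      stop(sprintf("%s Beta shapes must be two finite positive numbers (support (0,1))", what))
  }
  check_beta(conf_correct, "conf_correct")
  check_beta(conf_incorrect, "conf_incorrect")
  ab <- stats::setNames(numeric(length(fine)), fine)
  ab[names(class_abundances)] <- class_abundances
  structure(list(confusion = confusion, mapping = mapping,
                 class_abundances = ab,
                 conf_correct = conf_correct, conf_incorrect = conf_incorrect,
                 n_fine = length(fine), fine_classes = fine,
                 seed = as.integer(seed)),
            class = "confusion_spec")
}

#' Generate a table of classified vignettes from a confusion specification
#'
#' For each vignette, a true fine class is drawn in proportion to
#' `class_abundances`, a predicted fine class from the true class's confusion
#' row, and a top-1 confidence from the correct or incorrect Beta
#' distribution. The confidence is clamped above `1/n_fine` so that a
#' probability vector with that maximum and the remaining mass spread evenly
#' over the other classes has its argmax at the predicted class. Positions
#' (depth, along-track) are uniform and independent of class; the confusion
#' structure is homogeneous along the transect.
#'
#' @param spec a [confusion_spec()].
#' @param n number of vignettes; defaults to `round(sum(class_abundances))`.
#' @param depth_range,along_range uniform position ranges (m).
#' @param return_probs if `TRUE`, attach the full probability matrix
#'   (rows = vignettes, cols = fine classes) as attribute `"probs"`. The
#'   matrix satisfies: rows sum to 1, argmax equals `pred_fine`, max equals
#'   `max_prob`. Off for large `n` (memory).
#' @return data.frame of class `classified_vignettes` with columns `id`,
#'   `true_fine`, `pred_fine`, `max_prob`, `depth_m`, `along_track_m`.
#' @export
gen_classified_vignettes <- function(spec, n = NULL,
                                     depth_range = c(0, 80),
                                     along_range = c(0, 40000),
                                     return_probs = FALSE) {
  stopifnot(inherits(spec, "confusion_spec"))
  set.seed(spec$seed)
  if (is.null(n)) n <- round(sum(spec$class_abundances))
  stopifnot(n >= 0)
  K <- spec$n_fine
  fine <- spec$fine_classes
  p_true <- spec$class_abundances / sum(spec$class_abundances)
  true_idx <- sample.int(K, n, replace = TRUE, prob = p_true)
  # draw predictions row by row of the confusion matrix (vectorised per class)
  pred_idx <- integer(n)
  for (i in seq_len(K)) {
    sel <- which(true_idx == i)
    if (length(sel))
      pred_idx[sel] <- sample.int(K, length(sel), replace = TRUE,
                                  prob = spec$confusion[i, ])
  }
  correct <- pred_idx == true_idx
  conf <- numeric(n)
  conf[correct] <- stats::rbeta(sum(correct), spec$conf_correct[1],
                                spec$conf_correct[2])
  conf[!correct] <- stats::rbeta(sum(!correct), spec$conf_incorrect[1],
                                 spec$conf_incorrect[2])
  # argmax consistency: max prob must exceed the share any other class gets
  conf <- pmin(pmax(conf, 1 / K + 1e-6), 1 - 1e-9)
  out <- data.frame(id = seq_len(n),
                    true_fine = fine[true_idx],
                    pred_fine = fine[pred_idx],
                    max_prob = conf,
                    depth_m = stats::runif(n, depth_range[1], depth_range[2]),
                    along_track_m = stats::runif(n, along_range[1], along_range[2]))
  class(out) <- c("classified_vignettes", "data.frame")
  if (return_probs) {
    probs <- matrix((1 - conf) / (K - 1), n, K, dimnames = list(NULL, fine))
    probs[cbind(seq_len(n), pred_idx)] <- conf
    attr(out, "probs") <- probs
  }
  out
}
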