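#' Map fine class labels onto broader groups
#'
#' Deterministic relabelling through a two-column mapping table (e.g. 124
#' morphological classes onto 40 ecological groups). The label `"unknown"`
#' passes through unchanged: it marks vignettes removed by probability
#' filtering and is never itself a mapping target.
#'
#' @param labels character vector of fine class ids.
#' @param class_map data.frame with columns `fine`, `group`.
#' @return character vector of group ids.
#' @export
map_to_groups <- function(labels, class_map) {
  stopifnot(is.data.frame(class_map),
            all(c("fine", "group") %in% names(class_map)))
  if ("unknown" %in% class_map$group)
    stop('"unknown" is reserved and may not be a mapping target')
  idx <- match(labels, class_map$fine)
  pass <- labels == "unknown"
  bad <- which(is.na(idx) & !pass)
  if (length(bad))
    stop("unmapped fine class label(s): ",
         paste(unique(labels[bad]), collapse = ", "))
  out <- class_map$group[idx]
  out[pass] <- "unknown"
  out
}

#' Confusion matrix and per-group classification metrics
#'
#' Builds the group-level confusion matrix from true and predicted labels
#' and derives, per group: true positives, false positives, false
#' negatives, precision `P = TP/(TP+FP)`, recall `R = TP/(TP+FN)`, F1
#' `= 2PR/(P+R)`, the abundance correction factor `P/R`, and support (true
#' count). Predictions labelled `"unknown"` (filtered vignettes) count as
#' false negatives for their true group and as false positives for none.
#'
#' Weighted averages weight each group by its support. Groups with no
#' predictions (`TP+FP = 0`) have undefined precision; they are reported as
#' `NA` and excluded from the weighted precision/F1 means.
#'
#' @param true_group,pred_group character vectors of group labels
#'   (`pred_group` may contain `"unknown"`).
#' @return list with `confusion` (true x predicted count matrix), `metrics`
#'   (data.frame, one row per true group) and `weighted` (named vector of
#'   support-weighted mean precision, recall, f1).
#' @export
group_metrics <- function(true_group, pred_group) {
  stopifnot(length(true_group) == length(pred_group))
  groups <- sort(unique(true_group))
  all_lv <- sort(unique(c(groups, pred_group)))
  confusion <- table(factor(true_group, levels = all_lv),
                     factor(pred_group, levels = all_lv))
  confusion <- unclass(confusion)
  names(dimnames(confusion)) <- c("true", "predicted")
  tp <- vapply(groups, function(g) sum(true_group == g & pred_group == g),
               numeric(1))
  fp <- vapply(groups, function(g) sum(true_group != g & pred_group == g),
               numeric(1))
  fn <- vapply(groups, function(g) sum(true_group == g & pred_group != g),
               numeric(1))
  support <- tp + fn
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(support > 0, tp / (tp + fn), NA_real_)
  f1 <- f1_score(precision, recall)
  cf <- correction_factor(precision, recall)
  metrics <- data.frame(group = groups, TP = tp, FP = fp, FN = fn,
                        support = support, precision = precision,
                        recall = recall, f1 = f1, correction_factor = cf,
                        row.names = NULL)
  ok_p <- !is.na(metrics$precision)
  weighted <- c(
    precision = stats::weighted.mean(metrics$precision[ok_p],
                                     metrics$support[ok_p]),
    recall = stats::weighted.mean(metrics$recall, metrics$support,
                                  na.rm = TRUE),
    f1 = stats::weighted.mean(metrics$f1[ok_p], metrics$support[ok_p],
                              na.rm = TRUE))
  list(confusion = confusion, metrics = metrics, weighted = weighted)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `F1 = 2PR/(P+R)`; satisfies `min(P,R) <= F1 <= max(P,R)`.
#'
#' @param precision,recall numeric vectors in `[0, 1]` (or percentages —
#'   the formula is scale-free up to the common factor).
#' @return numeric vector, `NA` where either input is `NA` or `P + R = 0`.
#' @export
f1_score <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall) | precision + recall == 0,
         NA_real_, 2 * precision * recall / (precision + recall))
}

#' Abundance correction factor from precision and recall
#'
#' `CF = P/R`. Classified counts multiplied by the factor estimate true
#' abundance: multiplying by precision removes the false-positive share and
#' dividing by recall restores the missed share. Undefined (`NA`) when
#' recall is zero or missing; such groups are uncorrectable.
#'
#' @param precision,recall numeric vectors on the same scale.
#' @return numeric vector of factors.
#' @export
correction_factor <- function(precision, recall) {
  ifelse(is.na(recall) | recall == 0 | is.na(precision),
         NA_real_, precision / recall)
}

#' Fit per-class probability thresholds for a target group precision
#'
#' For every fine class, vignettes predicted as that class are filtered at
#' each threshold `t` on a grid, the precision of the class's broad group
#' over the kept vignettes (fraction whose true group matches) is
#' recomputed, the precision-versus-threshold curve is smoothed by local
#' regression, and the threshold is the smallest `t` at which the smoothed
#' precision reaches `target_precision`. Classes whose smoothed curve never
#' reaches the target are marked unattainable and get a threshold equal to
#' their largest observed confidence, so that strict filtering removes all
#' their vignettes.
#'
#' Classes with fewer than `min_support` test vignettes inherit the
#' threshold fitted on their group's pooled curve (with a warning): a
#' per-class curve estimated from a handful of points is noise.
#'
#' @param vignettes `classified_vignettes` data.frame with `true_fine`,
#'   `pred_fine`, `max_prob`.
#' @param class_map fine-to-group mapping data.frame.
#' @param target_precision target broad-group precision (default 0.90).
#' @param grid_step threshold grid spacing.
#' @param loess_span local-regression span.
#' @param min_support minimum predicted-count per fine class for a
#'   class-specific curve.
#' @return data.frame of class `threshold_table`: `fine`, `group`,
#'   `threshold`, `attainable`, `n_pred`, `pooled` (TRUE when inherited
#'   from the group curve).
#' @export
fit_thresholds <- function(vignettes, class_map, target_precision = 0.90,
                           grid_step = 0.01, loess_span = 0.5,
                           min_support = 20) {
  stopifnot(all(c("true_fine", "pred_fine", "max_prob") %in% names(vignettes)),
            !anyNA(vignettes$true_fine))
  true_grp <- map_to_groups(vignettes$true_fine, class_map)
  grid <- seq(0, 1 - grid_step, by = grid_step)

  curve_threshold <- function(conf, correct) {
    # precision of the kept set as the cut-off rises, loess-smoothed
    prec <- vapply(grid, function(t) {
      kept <- conf > t
      if (!any(kept)) NA_real_ else mean(correct[kept])
    }, numeric(1))
    ok <- !is.na(prec)
    if (sum(ok) < 4) return(list(threshold = NA_real_, attainable = FALSE))
    sm <- tryCatch(
      stats::predict(stats::loess(prec[ok] ~ grid[ok], span = loess_span,
                                  degree = 1)),
      error = function(e) prec[ok])
    hit <- which(sm >= target_precision)
    if (length(hit))
      list(threshold = grid[ok][hit[1]], attainable = TRUE)
    else
      list(threshold = NA_real_, attainable = FALSE)
  }

  fine_classes <- sort(unique(class_map$fine))
  grp_of <- stats::setNames(class_map$group, class_map$fine)
  # pooled per-group curves, for low-support classes
  pooled_cache <- new.env(parent = emptyenv())
  pooled_threshold <- function(g) {
    if (!is.null(pooled_cache[[g]])) return(pooled_cache[[g]])
    sel <- grp_of[vignettes$pred_fine] == g
    res <- if (any(sel))
      curve_threshold(vignettes$max_prob[sel], true_grp[sel] == g)
    else list(threshold = NA_real_, attainable = FALSE)
    pooled_cache[[g]] <- res
    res
  }

  rows <- lapply(fine_classes, function(cl) {
    g <- grp_of[[cl]]
    sel <- vignettes$pred_fine == cl
    n_pred <- sum(sel)
    pooled <- FALSE
    if (n_pred < min_support) {
      warning(sprintf(
        "fine class '%s' has %d predicted test vignettes (< %d); using its group's pooled curve",
        cl, n_pred, min_support))
      res <- pooled_threshold(g)
      pooled <- TRUE
      max_conf <- if (n_pred) max(vignettes$max_prob[sel]) else 1
    } else {
      res <- curve_threshold(vignettes$max_prob[sel], true_grp[sel] == g)
      max_conf <- max(vignettes$max_prob[sel])
    }
    thr <- if (res$attainable) res$threshold else max_conf
    data.frame(fine = cl, group = g, threshold = thr,
               attainable = res$attainable, n_pred = n_pred, pooled = pooled)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("threshold_table", "data.frame")
  out
}

#' Apply probability thresholds and map to broad groups
#'
#' A vignette is kept iff its top-1 probability strictly exceeds the
#' threshold of its predicted fine class; vignettes at or below the
#' threshold are re-classified as `"unknown"`. Kept vignettes are mapped to
#' their broad group. Conservation: kept + unknown = total.
#'
#' @param vignettes data.frame with `pred_fine`, `max_prob`.
#' @param thresholds a [fit_thresholds()] table (or any data.frame with
#'   `fine`, `threshold` covering all predicted classes).
#' @param class_map fine-to-group mapping.
#' @return character vector of group labels (`"unknown"` for filtered).
#' @export
apply_thresholds <- function(vignettes, thresholds, class_map) {
  idx <- match(vignettes$pred_fine, thresholds$fine)
  if (anyNA(idx))
    stop("thresholds missing for predicted class(es): ",
         paste(unique(vignettes$pred_fine[is.na(idx)]), collapse = ", "))
  thr <- thresholds$threshold[idx]
  out <- rep("unknown", nrow(vignettes))
  keep <- vignettes$max_prob > thr
  out[keep] <- map_to_groups(vignettes$pred_fine[keep], class_map)
  out
}

#' Correction factors from a metrics table
#'
#' Convenience wrapper: extracts `precision / recall` per group from a
#' [group_metrics()] metrics data.frame. Groups with zero or missing recall
#' are flagged uncorrectable (`NA` factor).
#'
#' @param metrics data.frame with `group`, `precision`, `recall`.
#' @return data.frame `group`, `correction_factor`, `uncorrectable`.
#' @export
correction_factors <- function(metrics) {
  cf <- correction_factor(metrics$precision, metrics$recall)
  data.frame(group = metrics$group, correction_factor = cf,
             uncorrectable = is.na(cf))
}
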