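#' Compare taxa concentrations between water masses
#'
#' One-way ANOVA per taxon of concentration against the water-mass label;
#' where the ANOVA is significant at `alpha`, Tukey HSD pairwise
#' comparisons with family-wise adjusted p-values identify which water
#' masses differ. Water masses with fewer than two observations are
#' dropped from that taxon's comparison (flagged).
#'
#' @param concentrations data.frame (or matrix) of per-cell taxa
#'   concentrations, one column per taxon.
#' @param labels water-mass label per cell (character/factor).
#' @param alpha significance level gating the post-hoc tests.
#' @param log1p_transform analyse `log1p(conc)` instead of raw
#'   concentrations (off by default).
#' @return list with `anova` (data.frame: `taxon`, `F`, `p`,
#'   `groups_used`) and `tukey` (data.frame: `taxon`, `pair`, `diff`,
#'   `lwr`, `upr`, `p_adj`; rows only for significant ANOVAs).
#' @export
compare_water_masses <- function(concentrations, labels, alpha = 0.05,
                                 log1p_transform = FALSE) {
  concentrations <- as.data.frame(concentrations)
  labels <- as.character(labels)
  stopifnot(nrow(concentrations) == length(labels))
  anova_rows <- list(); tukey_rows <- list()
  for (taxon in names(concentrations)) {
    y <- concentrations[[taxon]]
    if (log1p_transform) y <- log1p(y)
    tab <- table(labels)
    keep_lv <- names(tab)[tab >= 2]
    if (length(keep_lv) < 2) {
      anova_rows[[taxon]] <- data.frame(taxon = taxon, F = NA_real_,
                                        p = NA_real_,
                                        groups_used = length(keep_lv))
      next
    }
    sel <- labels %in% keep_lv
    g <- factor(labels[sel])
    fit <- stats::aov(y[sel] ~ g)
    s <- summary(fit)[[1]]
    Fv <- s$`F value`[1]; pv <- s$`Pr(>F)`[1]
    anova_rows[[taxon]] <- data.frame(taxon = taxon, F = Fv, p = pv,
                                      groups_used = length(keep_lv))
    if (!is.na(pv) && pv < alpha) {
      tk <- stats::TukeyHSD(fit)$g
      tukey_rows[[taxon]] <- data.frame(taxon = taxon,
                                        pair = rownames(tk),
                                        diff = tk[, "diff"],
                                        lwr = tk[, "lwr"],
                                        upr = tk[, "upr"],
                                        p_adj = tk[, "p adj"],
                                        row.names = NULL)
    }
  }
  list(anova = do.call(rbind, c(anova_rows, make.row.names = FALSE)),
       tukey = if (length(tukey_rows))
         do.call(rbind, c(tukey_rows, make.row.names = FALSE))
       else data.frame(taxon = character(0), pair = character(0),
                       diff = numeric(0), lwr = numeric(0),
                       upr = numeric(0), p_adj = numeric(0)))
}

#' Fit a random-forest regression of a taxon's concentration on its drivers
#'
#' Bagged regression-tree ensemble (`randomForest`), by default 500 trees
#' with 14 candidate predictors per split — the settings used throughout
#' so that models with different predictor sets stay comparable.
#' Categorical predictors (water mass) are handled natively as factors.
#' Out-of-bag variance explained is `1 - MSE_OOB / Var(response)`; both
#' importance measures are returned: total decrease in node impurity
#' (residual sum of squares) per predictor, and the permutation increase
#' in out-of-bag MSE.
#'
#' @param table data.frame of predictors plus the response column; no
#'   missing values.
#' @param response name of the response column.
#' @param n_trees number of trees.
#' @param mtry candidate predictors per split; capped at the number of
#'   predictors is an error (the setting defines the model).
#' @param seed RNG seed; identical seed and settings give identical fits.
#' @return list of class `rf_fit`: `forest` (the randomForest object),
#'   `response`, `n_trees`, `mtry`, `variance_explained`, `importance`
#'   (data.frame: `predictor`, `mse_increase_pct`, `node_purity`).
#' @export
fit_rf <- function(table, response, n_trees = 500, mtry = 14, seed = 1L) {
  stopifnot(is.data.frame(table), response %in% names(table))
  if (anyNA(table)) stop("predictor table contains missing values")
  x <- table[, setdiff(names(table), response), drop = FALSE]
  x[] <- lapply(x, function(col) if (is.character(col)) factor(col) else col)
  y <- table[[response]]
  if (mtry > ncol(x))
    stop(sprintf("mtry (%d) exceeds the number of predictors (%d)",
                 mtry, ncol(x)))
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                   mtry = mtry, importance = TRUE)
  imp <- randomForest::importance(rf)
  importance <- data.frame(predictor = rownames(imp),
                           mse_increase_pct = imp[, "%IncMSE"],
                           node_purity = imp[, "IncNodePurity"],
                           row.names = NULL)
  structure(list(forest = rf, response = response, n_trees = n_trees,
                 mtry = mtry,
                 variance_explained = 1 - rf$mse[n_trees] / stats::var(y),
                 importance = importance),
            class = "rf_fit")
}

#' Rank predictors by importance
#'
#' Orders predictors primarily by permutation MSE increase, node-purity
#' gain breaking ties; both measures are reported for every predictor.
#'
#' @param fit an [fit_rf()] object.
#' @param top_n how many leading predictors to flag (attribute `"top"`).
#' @return the importance data.frame, ordered, with a `rank` column.
#' @export
importance_ranking <- function(fit, top_n = 5) {
  stopifnot(inherits(fit, "rf_fit"))
  imp <- fit$importance
  ord <- order(-imp$mse_increase_pct, -imp$node_purity)
  imp <- imp[ord, ]
  imp$rank <- seq_len(nrow(imp))
  rownames(imp) <- NULL
  attr(imp, "top") <- utils::head(imp$predictor, top_n)
  imp
}

#' Accumulated local effects of one predictor
#'
#' For a continuous predictor: the observed range is cut at quantile
#' boundaries into `n_bins` bins (empty bins are merged with their
#' neighbour); within each bin the prediction difference between the
#' predictor set to the bin's upper versus lower boundary — all other
#' columns untouched — is averaged over the observations in the bin;
#' differences are accumulated across bins and the curve is centred so its
#' data-weighted mean is zero. Because only local differences enter, the
#' curve is not inflated by correlated covariates, unlike partial
#' dependence.
#'
#' For a categorical predictor: levels are ordered by similarity of their
#' covariate distributions (sum over numeric covariates of
#' Kolmogorov-Smirnov distances, embedded to 1-D by classical MDS);
#' effects between consecutive levels are averaged over observations of
#' both levels, accumulated along the ordering, and centred by level
#' frequencies.
#'
#' @param predict_fun function taking a data.frame and returning numeric
#'   predictions (e.g. `function(d) predict(fit$forest, d)`).
#' @param table data.frame of predictor values (the training data).
#' @param predictor column name.
#' @param n_bins number of quantile bins for continuous predictors.
#' @return list of class `ale_curve`. Continuous: `x` (bin boundaries),
#'   `effect` (centred, same length), `bin_n` (observations per bin).
#'   Categorical: `levels` (in effect order), `effect`, `level_n`.
#' @export
compute_ale <- function(predict_fun, table, predictor, n_bins = 20) {
  stopifnot(predictor %in% names(table))
  x <- table[[predictor]]
  if (is.numeric(x)) {
    qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                                 names = FALSE, type = 7))
    if (length(qs) < 2) stop("predictor is constant; ALE undefined")
    # bin index per observation; first boundary closed
    bin <- findInterval(x, qs, rightmost.closed = TRUE, all.inside = TRUE)
    nb <- length(qs) - 1
    local <- numeric(nb); nobs <- integer(nb)
    for (j in seq_len(nb)) {
      sel <- bin == j
      nobs[j] <- sum(sel)
      if (!nobs[j]) next                  # empty bin: zero local effect,
      d_hi <- table[sel, , drop = FALSE]  # absorbed by the neighbour below
      d_lo <- d_hi
      d_hi[[predictor]] <- qs[j + 1]
      d_lo[[predictor]] <- qs[j]
      local[j] <- mean(predict_fun(d_hi) - predict_fun(d_lo))
    }
    ale <- c(0, cumsum(local))            # at boundaries qs
    # data-weighted centring: an observation's effect is its bin midpoint
    mids <- (ale[-1] + ale[-length(ale)]) / 2
    center <- sum(nobs * mids) / sum(nobs)
    structure(list(type = "continuous", x = qs, effect = ale - center,
                   bin_n = nobs),
              class = "ale_curve")
  } else {
    x <- factor(x)
    lv <- levels(x)
    if (length(lv) < 2) stop("categorical predictor has a single level")
    num_cols <- names(table)[vapply(table, is.numeric, logical(1))]
    ks_dist <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
    for (a in seq_along(lv)) for (b in seq_along(lv)) {
      if (a >= b) next
      d <- 0
      for (cc in num_cols) {
        d <- d + suppressWarnings(
          stats::ks.test(table[[cc]][x == lv[a]],
                         table[[cc]][x == lv[b]])$statistic)
      }
      ks_dist[a, b] <- ks_dist[b, a] <- d
    }
    ord <- order(stats::cmdscale(ks_dist, k = 1)[, 1])
    lv_ord <- lv[ord]
    local <- numeric(length(lv_ord) - 1)
    for (j in seq_along(local)) {
      sel <- x %in% lv_ord[c(j, j + 1)]
      d_hi <- table[sel, , drop = FALSE]; d_lo <- d_hi
      d_hi[[predictor]] <- factor(lv_ord[j + 1], levels = lv)
      d_lo[[predictor]] <- factor(lv_ord[j], levels = lv)
      local[j] <- mean(predict_fun(d_hi) - predict_fun(d_lo))
    }
    ale <- c(0, cumsum(local))
    nlev <- as.numeric(table(x)[lv_ord])
    center <- sum(nlev * ale) / sum(nlev)
    structure(list(type = "categorical", levels = lv_ord,
                   effect = ale - center, level_n = nlev),
              class = "ale_curve")
  }
}

#' Change in variance explained when a predictor is removed
#'
#' Fits the random forest with and without the predictor under identical
#' settings and seed, and reports `delta = VE_with - VE_without`. A
#' positive delta means the predictor carries information the remaining
#' predictors do not; near-zero delta under an existing strong fit
#' indicates the predictor is redundant with the others (e.g. a prey field
#' already explained by the shared physics).
#'
#' @param table,response,n_trees,mtry,seed as in [fit_rf()]. `mtry` is
#'   reduced by one for the ablated fit only if it would otherwise exceed
#'   the reduced predictor count.
#' @param predictor column to remove.
#' @return list: `delta`, `ve_with`, `ve_without`, `predictor`.
#' @export
ablate_predictor <- function(table, response, predictor, n_trees = 500,
                             mtry = 14, seed = 1L) {
  stopifnot(predictor %in% names(table), predictor != response)
  fit_with <- fit_rf(table, response, n_trees = n_trees, mtry = mtry,
                     seed = seed)
  reduced <- table[, setdiff(names(table), predictor), drop = FALSE]
  mtry2 <- min(mtry, ncol(reduced) - 1)
  fit_without <- fit_rf(reduced, response, n_trees = n_trees, mtry = mtry2,
                        seed = seed)
  list(delta = fit_with$variance_explained - fit_without$variance_explained,
       ve_with = fit_with$variance_explained,
       ve_without = fit_without$variance_explained,
       predictor = predictor)
}

#' Assemble the per-cell predictor table from gridded fields
#'
#' Flattens matched gridded fields (taxa concentrations, current speed and
#' direction, distance to the boundary current, water-mass label, and
#' sensor fields) into the one-row-per-grid-cell table the random-forest
#' models consume.
#'
#' @param taxa named list of concentration matrices.
#' @param speed,direction,dist_to_fc_km matrices matching the taxa grids.
#' @param labels water-mass label matrix.
#' @param sensors named list of additional matrices (e.g. `chl`, `oxygen`,
#'   `sigma_t`).
#' @return data.frame, one row per grid cell; `water_mass` is a factor.
#' @export
predictor_table <- function(taxa, speed, direction, dist_to_fc_km, labels,
                            sensors = list()) {
  out <- data.frame(lapply(taxa, as.numeric), check.names = FALSE)
  out$current_speed <- as.numeric(speed)
  out$current_direction <- as.numeric(direction)
  out$dist_to_fc_km <- as.numeric(dist_to_fc_km)
  out$water_mass <- factor(as.character(labels))
  for (s in names(sensors)) out[[s]] <- as.numeric(sensors[[s]])
  if (anyNA(out)) stop("assembled predictor table contains missing values")
  out
}
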