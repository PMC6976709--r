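# Shared fixtures, built in code at test time.

# five fine classes in three broad groups
fixture_class_map <- function() {
  data.frame(fine = c("a1", "a2", "b1", "b2", "c1"),
             group = c("A", "A", "B", "B", "C"))
}

# moderately confused classifier: 80% diagonal, rest spread evenly
fixture_confusion_spec <- function(diag_p = 0.8, n_per_class = 20000,
                                   seed = 1L, ...) {
  cmap <- fixture_class_map()
  K <- nrow(cmap)
  conf <- matrix((1 - diag_p) / (K - 1), K, K)
  diag(conf) <- diag_p
  dimnames(conf) <- list(cmap$fine, cmap$fine)
  confusion_spec(conf, cmap,
                 stats::setNames(rep(n_per_class, K), cmap$fine),
                 seed = seed, ...)
}

# closed-form group-level precision/recall implied by a fine-level
# confusion matrix and class abundances (the independent oracle for the
# generator: no sampling, pure expectation arithmetic)
expected_group_pr <- function(confusion, cmap, abundances) {
  groups <- unique(cmap$group)
  grp <- stats::setNames(cmap$group, cmap$fine)
  fine <- rownames(confusion)
  out <- list()
  for (g in groups) {
    gf <- fine[grp[fine] == g]
    # E[TP]: true in g predicted into g; E[FP]: true outside predicted in
    tp <- sum(abundances[gf] * rowSums(confusion[gf, gf, drop = FALSE]))
    pred_in_g <- sum(abundances * rowSums(confusion[, gf, drop = FALSE]))
    true_in_g <- sum(abundances[gf])
    out[[g]] <- c(precision = tp / pred_in_g, recall = tp / true_in_g)
  }
  do.call(rbind, out)
}

fixture_scene <- function(seed = 7, n_frames = 10, ...) {
  gen_frames(scene_spec(n_frames = n_frames, seed = seed, ...))
}

# predictor table from a transect scenario (optionally subsampled)
fixture_predictor_table <- function(scenario, n = NULL, seed = 1L) {
  sd <- uv_to_speed_dir(scenario$u, scenario$v)
  tab <- predictor_table(scenario$taxa, scenario$speed, sd$direction,
                         scenario$dist_to_fc_km, scenario$labels,
                         sensors = list(chl = scenario$chl,
                                        oxygen = scenario$oxygen,
                                        sigma_t = scenario$sigma_t))
  if (!is.null(n) && n < nrow(tab)) {
    set.seed(seed)
    tab <- tab[sample.int(nrow(tab), n), ]
  }
  tab
}
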