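# Shared fixtures, all generated in code.

# one subject's labeled, preprocessed windows from a scripted session
subject_windows <- function(id, reps = 2, noise = noise_spec(), seed = 1,
                            movement_s = 4) {
  scr <- bafa_wubu_script(reps = reps, movement_s = movement_s, transition_s = 1)
  synth_session(scr, rate_hz = 200, noise = noise, seed = seed) |>
    low_pass() |>
    resample_to(50) |>
    segment_windows(subject_id = id) |>
    label_windows()
}

# small multi-subject windowed dataset
small_dataset <- function(n_subjects = 3, reps = 1, noise = noise_spec(),
                          seed0 = 10) {
  bind_windows(lapply(seq_len(n_subjects), function(i) {
    subject_windows(sprintf("S%02d", i), reps = reps, noise = noise, seed = seed0 + i)
  }))
}

# a quickly trained small TCN fit (deterministic); used where only a valid
# tcn_fit object is needed, not a converged one
quick_fit <- function(windows = NULL, epochs = 2, seed = 1) {
  if (is.null(windows)) windows <- small_dataset(2)
  tr <- standardize_windows(windows)
  cfg <- tcn_config(
    n_blocks = 2, filters = 8, dilations = c(17, 33),
    dropout = 0.1, epochs = epochs, seed = seed
  )
  fit_tcn(build_tcn(cfg), tr)
}

# nearest-centroid classifier on per-window channel means and variances:
# the independent separability oracle for the synthetic generator
nearest_centroid_accuracy <- function(windows) {
  feats <- scale(cbind(
    apply(windows$x, c(1, 3), mean),
    apply(windows$x, c(1, 3), stats::var)
  ))
  labs <- windows$label
  classes <- unique(labs)
  centroids <- t(vapply(
    classes,
    function(cl) colMeans(feats[labs == cl, , drop = FALSE]),
    numeric(ncol(feats))
  ))
  d2 <- outer(rowSums(feats^2), rep(1, nrow(centroids))) -
    2 * feats %*% t(centroids) +
    outer(rep(1, nrow(feats)), rowSums(centroids^2))
  mean(classes[max.col(-d2)] == labs)
}

# definitional sums-of-squares for a balanced 2 (group) x 2 (time) mixed
# design: the independent brute-force oracle
brute_force_mixed_anova <- function(pre1, post1, pre2, post2) {
  y <- rbind(
    cbind(pre1, post1),
    cbind(pre2, post2)
  )
  g <- rep(1:2, c(length(pre1), length(pre2)))
  N <- nrow(y)
  grand <- mean(y)
  m_i <- rowMeans(y)
  m_g <- c(tapply(m_i, g, mean))
  cell <- rbind(colMeans(y[g == 1, , drop = FALSE]), colMeans(y[g == 2, , drop = FALSE]))
  t_mean <- colMeans(y)
  n_g <- tabulate(g)
  ss_group <- 2 * sum(n_g * (m_g - grand)^2)
  ss_subj <- 2 * sum((m_i - m_g[g])^2)
  ss_time <- N * sum((t_mean - grand)^2)
  ss_int <- sum(n_g * (cell - outer(m_g, rep(1, 2)) -
    outer(rep(1, 2), t_mean) + grand)^2)
  ss_err <- sum((y - m_i - cell[g, ] + m_g[g])^2)
  list(
    f_group = (ss_group / 1) / (ss_subj / (N - 2)),
    f_time = (ss_time / 1) / (ss_err / (N - 2)),
    f_int = (ss_int / 1) / (ss_err / (N - 2)),
    ss = c(ss_group, ss_subj, ss_time, ss_int, ss_err),
    pes_int = ss_int / (ss_int + ss_err)
  )
}

toy_cohort <- function(pre1, post1, pre2, post2) {
  tibble::tibble(
    subject_id = seq_len(length(pre1) + length(pre2)),
    group = rep(c("precision", "standard"), c(length(pre1), length(pre2))),
    pre = c(pre1, pre2),
    post = c(post1, post2)
  )
}

# single-measure generator specs for the null and shifted-alternative
# cohort simulations (marginals from the published balance summaries)
null_cohort_spec <- function() {
  cohort_spec(params = tibble::tibble(
    measure = "balance_s",
    group = c("precision", "standard"),
    pre_mean = 8.61, pre_sd = 4.21,
    post_mean = 8.61, post_sd = 4.21
  ))
}

shifted_cohort_spec <- function() {
  params <- tibble::tibble(
    measure = "balance_s",
    group = c("precision", "standard"),
    pre_mean = 8.61, pre_sd = 4.21,
    post_mean = c(8.61 + 4.21, 8.61), post_sd = 4.21
  )
  cohort_spec(params = params)
}

# the scaled end-to-end recognition experiment: simulate sessions for
# n_subjects, preprocess, split subject-wise 2/3-1/3, train a scaled TCN
# (4 blocks, 16 filters, 100 epochs), return validation metrics
run_scaled_pipeline <- function(noise, subject_seeds, split_seed = 1,
                                tcn_seed = 1, reps = 2, epochs = 100) {
  windows <- bind_windows(lapply(seq_along(subject_seeds), function(i) {
    subject_windows(sprintf("S%02d", i),
      reps = reps, noise = noise,
      seed = subject_seeds[i]
    )
  }))
  sp <- split_windows(windows, unit = "subject", seed = split_seed)
  tr <- standardize_windows(sp$train)
  va <- standardize_windows(sp$validation, tr$channel_stats)
  cfg <- tcn_config(
    n_blocks = 4, filters = 16, epochs = epochs, seed = tcn_seed
  )
  fit <- fit_tcn(build_tcn(cfg), tr, va)
  pred <- predict(fit, va)
  cm <- confusion_matrix(va$label, pred$.pred_class)
  pca <- per_class_accuracy(cm)
  list(
    fit = fit, cm = cm,
    macro_accuracy = mean(pca$accuracy_pct, na.rm = TRUE) / 100,
    overall_accuracy = overall_accuracy(cm) / 100,
    majority_baseline = max(table(va$label)) / n_windows(va),
    n_validation = n_windows(va)
  )
}
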