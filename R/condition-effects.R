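# --- fast cell-sum algebra for the pointwise 2x2 between-trials ANOVA ---
#
# For any model whose design matrix depends only on the 2x2 cell, the
# residual sum of squares of every time point can be computed from per-cell
# sums S (4 x T), per-cell counts n, and the column sums of squares of the
# data. Type-II sums of squares: SS(A | B) = RSS(B) - RSS(A+B), etc., with
# the error term from the full (interaction) model.

cell_codes <- function(emotion, gaze) {
  av <- ifelse(gaze %in% c("left", "right", "averted"), "averted", "direct")
  factor(paste(emotion, av, sep = "."),
         levels = c("fearful.averted", "fearful.direct",
                    "happy.averted", "happy.direct"))
}

# RSS per column for a cell-level design G (4 x p), given counts and sums
rss_cell_model <- function(G, n_c, S, css) {
  XtX <- t(G) %*% (G * n_c)
  beta <- solve(XtX, t(G) %*% S)       # p x T
  f <- G %*% beta                      # fitted value per cell, 4 x T
  css - colSums((2 * S - n_c * f) * f)
}

# pointwise F maps for emotion, gaze and interaction given a cell assignment
factorial_f_maps <- function(cells, x, css = colSums(x^2)) {
  n_c <- as.numeric(table(cells))
  if (any(n_c == 0)) {
    empty <- levels(cells)[n_c == 0]
    stop("empty condition cell: ", paste(empty, collapse = ", "))
  }
  S <- rowsum(x, cells, reorder = TRUE)     # 4 x T cell sums
  n <- nrow(x)
  # cell-level design matrices (rows ordered as levels(cells))
  A <- c(1, 1, -1, -1)       # emotion contrast (fearful vs happy)
  B <- c(1, -1, 1, -1)       # gaze contrast (averted vs direct)
  G_full <- cbind(1, A, B, A * B)
  G_add <- cbind(1, A, B)
  G_a <- cbind(1, A)
  G_b <- cbind(1, B)
  rss_full <- css - colSums(S^2 / n_c)
  rss_add <- rss_cell_model(G_add, n_c, S, css)
  rss_a <- rss_cell_model(G_a, n_c, S, css)
  rss_b <- rss_cell_model(G_b, n_c, S, css)
  mse <- rss_full / (n - 4)
  list(emotion = pmax(rss_b - rss_add, 0) / mse,
       gaze = pmax(rss_a - rss_add, 0) / mse,
       interaction = pmax(rss_add - rss_full, 0) / mse,
       df2 = n - 4,
       fitted_add = (G_add %*% solve(t(G_add) %*% (G_add * n_c),
                                     t(G_add) %*% S)))
}

#' Pointwise 2x2 gaze-by-emotion ANOVA with cluster-based correction
#'
#' At every sample in the 0-400 ms window, a two-way between-trials ANOVA
#' with factors emotion (happy/fearful) and gaze (direct/averted; leftward
#' and rightward changes pooled as averted) yields F statistics for the two
#' main effects and their interaction (Type-II sums of squares, robust to
#' mild trial-count imbalance). Suprathreshold samples (pointwise
#' `F(1, n-4)` at `cluster_alpha`) are grouped into contiguous clusters with
#' mass = sum of F. Null distributions of the maximum cluster mass are built
#' by permutation: main effects permute that factor's labels across trials;
#' the interaction permutes the residuals of the additive (main-effects-only)
#' model and adds them back to the additive fit, so both main effects are
#' preserved under the interaction null.
#'
#' @param epochs An `epoch_set` whose trial table has `emotion` and `gaze`.
#' @param site Site index or name.
#' @param n_perm Permutation draws per effect.
#' @param cluster_alpha Pointwise cluster-forming level.
#' @param rng_seed Integer seed.
#' @param window Analysis window (ms).
#' @param effects Which effects to test (subset of `"emotion"`, `"gaze"`,
#'   `"interaction"`); restricting skips the other effects' permutation
#'   nulls.
#' @return A list of class `factorial_cluster_test` with one entry per
#'   effect (`emotion`, `gaze`, `interaction`), each a data frame of
#'   clusters (`t_start_ms`, `t_end_ms`, `mass`, `p`), plus `n_perm`,
#'   `rng_seed`, `cell_counts`.
#' @export
pointwise_factorial_anova <- function(epochs, site = 1L, n_perm = 1000,
                                      cluster_alpha = 0.05, rng_seed = 1L,
                                      window = c(0, 400),
                                      effects = c("emotion", "gaze",
                                                  "interaction")) {
  effects <- match.arg(effects, several.ok = TRUE)
  x <- site_matrix(epochs, resolve_site(epochs, site))
  idx <- time_index(epochs$time_ms, window[1], window[2])
  x <- x[, idx, drop = FALSE]
  tvec <- epochs$time_ms[idx]
  cells <- cell_codes(epochs$trials$emotion, epochs$trials$gaze)
  cnt <- table(cells)
  if (any(cnt < 2)) stop("need >= 2 trials in every cell; counts: ",
                         paste(cnt, collapse = ", "))
  n <- nrow(x)
  css <- colSums(x^2)
  obs <- factorial_f_maps(cells, x, css)
  thr <- stats::qf(1 - cluster_alpha, 1, obs$df2)

  emo <- factor(epochs$trials$emotion)
  gaz <- ifelse(epochs$trials$gaze %in% c("left", "right"),
                "averted", "direct")

  local_rng(rng_seed)
  null_max <- list(emotion = numeric(n_perm), gaze = numeric(n_perm),
                   interaction = numeric(n_perm))
  fitted_add <- obs$fitted_add[as.integer(cells), , drop = FALSE]
  resid_add <- x - fitted_add
  for (b in seq_len(n_perm)) {
    if ("emotion" %in% effects) {
      pe <- cell_codes(emo[sample.int(n)], gaz)
      null_max$emotion[b] <-
        max_cluster_mass(factorial_f_maps(pe, x, css)$emotion, thr)
    }
    if ("gaze" %in% effects) {
      pg <- cell_codes(emo, gaz[sample.int(n)])
      null_max$gaze[b] <-
        max_cluster_mass(factorial_f_maps(pg, x, css)$gaze, thr)
    }
    if ("interaction" %in% effects) {
      xi <- fitted_add + resid_add[sample.int(n), , drop = FALSE]
      null_max$interaction[b] <-
        max_cluster_mass(factorial_f_maps(cells, xi)$interaction, thr)
    }
  }

  out <- lapply(stats::setNames(effects, effects), function(eff) {
    cl <- find_clusters(obs[[eff]], thr)
    if (nrow(cl))
      cl$p <- vapply(abs(cl$mass), function(m)
        (1 + sum(null_max[[eff]] >= m)) / (1 + n_perm), 0)
    else cl$p <- numeric()
    data.frame(t_start_ms = tvec[cl$start], t_end_ms = tvec[cl$end],
               mass = cl$mass, p = cl$p)
  })
  structure(c(out, list(n_perm = n_perm, rng_seed = rng_seed,
                        cluster_alpha = cluster_alpha,
                        cell_counts = as.vector(cnt))),
            class = "factorial_cluster_test")
}

#' @export
print.factorial_cluster_test <- function(x, ...) {
  for (eff in intersect(c("emotion", "gaze", "interaction"), names(x))) {
    cat(eff, ": ", nrow(x[[eff]]), " cluster(s)",
        if (nrow(x[[eff]])) sprintf(", min p = %.4g", min(x[[eff]]$p)), "\n",
        sep = "")
  }
  invisible(x)
}

#' Two-sample Cohen's d with pooled standard deviation
#'
#' `d = (mu_A - mu_B) / s_p` with
#' `s_p = sqrt(((n_A-1) s_A^2 + (n_B-1) s_B^2) / (n_A + n_B - 2))`.
#'
#' @param a,b Numeric samples for the two conditions.
#' @return The signed d (NA with a warning when the pooled SD is zero).
#' @export
cohens_d_two_sample <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (is.na(sp2) || sp2 == 0) {
    warning("zero pooled variance; d undefined")
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Effect size over the dominant cluster window
#'
#' For a site with a significant emotion or gaze effect, extracts the
#' trial-by-trial activity averaged over the time window of the cluster with
#' the largest |mass|, and computes the two-sample Cohen's d between the two
#' levels of the effect (averted vs direct for gaze; fearful vs happy for
#' emotion) with the pooled-SD formula.
#'
#' @param epochs An `epoch_set` with `emotion`/`gaze` trial metadata.
#' @param site Site index or name.
#' @param effect `"gaze"` or `"emotion"`.
#' @param test A `factorial_cluster_test` for this site (or a data frame of
#'   clusters with `t_start_ms`, `t_end_ms`, `mass`).
#' @return List of class `condition_effect_size`: `d`, `abs_d`, `band`,
#'   `window_ms`, `level_means`, `n_per_level`.
#' @export
cluster_effect_size <- function(epochs, site = 1L,
                                effect = c("gaze", "emotion"), test) {
  effect <- match.arg(effect)
  cl <- if (inherits(test, "factorial_cluster_test")) test[[effect]] else test
  if (!nrow(cl)) stop("no cluster available for effect '", effect, "'")
  b <- which.max(abs(cl$mass))
  w <- c(cl$t_start_ms[b], cl$t_end_ms[b])
  m <- site_matrix(epochs, resolve_site(epochs, site))
  idx <- time_index(epochs$time_ms, w[1], w[2])
  tm <- rowMeans(m[, idx, drop = FALSE])
  lev <- if (effect == "gaze")
    ifelse(epochs$trials$gaze %in% c("left", "right"), "averted", "direct")
  else epochs$trials$emotion
  hi <- if (effect == "gaze") "averted" else "fearful"
  lo <- if (effect == "gaze") "direct" else "happy"
  a <- tm[lev == hi]; bb <- tm[lev == lo]
  d <- cohens_d_two_sample(a, bb)
  structure(list(d = d, abs_d = abs(d), band = effect_band(abs(d)),
                 window_ms = w,
                 level_means = c(stats::setNames(mean(a), hi),
                                 stats::setNames(mean(bb), lo)),
                 n_per_level = c(length(a), length(bb))),
            class = "condition_effect_size")
}

# equal-variance two-sample t; a 0/0 (identical constant samples) is t = 0
pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  dif <- mean(a) - mean(b)
  tval <- if (se == 0) { if (dif == 0) 0 else sign(dif) * Inf } else dif / se
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Compare gaze and emotion effect sizes across sites and ROIs
#'
#' Within each ROI, a two-sample t-test across sites compares |d| for gaze
#' versus |d| for emotion. Across ROIs, a one-way ANOVA per effect tests for
#' ROI differences in |d|, followed by post-hoc pairwise two-sample t-tests.
#'
#' @param effect_sizes Data frame with columns `site`, `roi`, `effect`
#'   (`"gaze"`/`"emotion"`), `abs_d`.
#' @return List of class `effect_size_comparison`: `within_roi` (data frame
#'   of per-ROI gaze-vs-emotion t-tests), `anova` (per-effect one-way ANOVA
#'   across ROIs), `posthoc` (pairwise ROI t-tests per effect). Groups with
#'   fewer than 2 sites are skipped with a log entry in `skipped`.
#' @export
compare_effects_across_rois <- function(effect_sizes) {
  es <- effect_sizes
  skipped <- character()
  within <- list()
  for (r in unique(es$roi)) {
    g <- es$abs_d[es$roi == r & es$effect == "gaze"]
    e <- es$abs_d[es$roi == r & es$effect == "emotion"]
    if (length(g) < 2 || length(e) < 2) {
      skipped <- c(skipped, paste0("within:", r))
      next
    }
    tt <- pooled_t(e, g)
    within[[length(within) + 1L]] <-
      data.frame(roi = r, mean_emotion = mean(e), mean_gaze = mean(g),
                 t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
  }
  within <- if (length(within)) do.call(rbind, within) else NULL

  anovas <- list(); posthoc <- list()
  for (eff in c("emotion", "gaze")) {
    sub <- es[es$effect == eff, ]
    cnt <- table(sub$roi)
    use <- names(cnt)[cnt >= 2]
    if (length(use) < 2) {
      skipped <- c(skipped, paste0("anova:", eff))
      next
    }
    sub <- sub[sub$roi %in% use, ]
    if (stats::var(sub$abs_d) == 0) {
      # degenerate all-equal case: no effect by definition
      anovas[[eff]] <- list(F = 0, df1 = length(use) - 1,
                            df2 = nrow(sub) - length(use), p = 1)
    } else {
      fit <- stats::anova(stats::lm(abs_d ~ roi, data = sub))
      anovas[[eff]] <- list(F = fit$`F value`[1], df1 = fit$Df[1],
                            df2 = fit$Df[2], p = fit$`Pr(>F)`[1])
    }
    prs <- utils::combn(use, 2)
    ph <- lapply(seq_len(ncol(prs)), function(k) {
      a <- sub$abs_d[sub$roi == prs[1, k]]
      b <- sub$abs_d[sub$roi == prs[2, k]]
      tt <- pooled_t(a, b)
      data.frame(effect = eff, roi_a = prs[1, k], roi_b = prs[2, k],
                 t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
    })
    posthoc[[eff]] <- do.call(rbind, ph)
  }
  structure(list(within_roi = within, anova = anovas,
                 posthoc = if (length(posthoc)) do.call(rbind, posthoc)
                 else NULL,
                 skipped = skipped),
            class = "effect_size_comparison")
}
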