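library(stats)

# build an epoch_set with planted per-cell offsets over a window
cell_epochs <- function(n_per_cell, offsets = c(0, 0, 0, 0),
                        window = c(150, 250), noise_sd = 1, seed = 1) {
  set.seed(seed)
  tr <- balanced_trials(n_per_cell)
  time_ms <- seq(-100, 400, by = 2.5)
  m <- matrix(rnorm(nrow(tr) * length(time_ms), 0, noise_sd), nrow(tr))
  cells <- paste(tr$emotion,
                 ifelse(tr$gaze == "direct", "direct", "averted"))
  lv <- c("fearful averted", "fearful direct", "happy averted",
          "happy direct")
  widx <- which(time_ms >= window[1] & time_ms <= window[2])
  for (i in seq_len(nrow(tr)))
    m[i, widx] <- m[i, widx] + offsets[match(cells[i], lv)]
  make_epochs(m, time_ms, trials = tr)
}

test_that("pointwise F maps match an independent car::Anova type-II fit", {
  skip_if_not_installed("car")
  set.seed(41)
  tr <- balanced_trials(8)
  tr <- tr[-c(1, 2, 9), ]   # unbalanced cells exercise type-II sums
  time_ms <- seq(0, 100, by = 2.5)
  m <- matrix(rnorm(nrow(tr) * length(time_ms)), nrow(tr))
  es <- make_epochs(m, time_ms, trials = tr)
  cells <- faceflow:::cell_codes(tr$emotion, tr$gaze)
  fm <- faceflow:::factorial_f_maps(cells, m)
  emo <- factor(tr$emotion)
  gaz <- factor(ifelse(tr$gaze == "direct", "direct", "averted"))
  for (j in c(1, 17, 41)) {
    fit <- car::Anova(lm(m[, j] ~ emo * gaz), type = "II")
    expect_equal(fm$emotion[j], fit["emo", "F value"], tolerance = 1e-8)
    expect_equal(fm$gaze[j], fit["gaz", "F value"], tolerance = 1e-8)
    expect_equal(fm$interaction[j], fit["emo:gaz", "F value"],
                 tolerance = 1e-8)
  }
})

test_that("a planted gaze effect produces a gaze cluster and no emotion cluster", {
  # averted cells raised by 1 z in 150-250 ms
  es <- cell_epochs(20, offsets = c(1, 0, 1, 0), noise_sd = 0.7, seed = 42)
  ft <- pointwise_factorial_anova(es, n_perm = 300, rng_seed = 2)
  expect_gt(nrow(ft$gaze), 0)
  best <- which.max(abs(ft$gaze$mass))
  expect_lt(ft$gaze$p[best], 0.01)
  expect_lt(ft$gaze$t_start_ms[best], 250)
  expect_gt(ft$gaze$t_end_ms[best], 150)
  no_emo <- !nrow(ft$emotion) || min(ft$emotion$p) > 0.05
  expect_true(no_emo)
})

test_that("swapping the factor roles swaps the F maps exactly", {
  set.seed(43)
  tr <- balanced_trials(10)
  time_ms <- seq(0, 200, by = 2.5)
  m <- matrix(rnorm(nrow(tr) * length(time_ms)), nrow(tr))
  cells <- faceflow:::cell_codes(tr$emotion, tr$gaze)
  f1 <- faceflow:::factorial_f_maps(cells, m)
  # exchange the two factors: emotion' = gaze level, gaze' = emotion level
  emo2 <- ifelse(tr$gaze == "direct", "happy", "fearful")
  gaz2 <- ifelse(tr$emotion == "happy", "direct", "left")
  f2 <- faceflow:::factorial_f_maps(faceflow:::cell_codes(emo2, gaz2), m)
  expect_equal(f2$emotion, f1$gaze, tolerance = 1e-10)
  expect_equal(f2$gaze, f1$emotion, tolerance = 1e-10)
  expect_equal(f2$interaction, f1$interaction, tolerance = 1e-10)
})

test_that("empty cells are reported by name", {
  tr <- balanced_trials(3)
  tr$gaze[tr$gaze == "direct"] <- "left"
  time_ms <- seq(0, 50, by = 2.5)
  es <- make_epochs(matrix(rnorm(nrow(tr) * length(time_ms)), nrow(tr)),
                    time_ms, trials = tr)
  expect_error(pointwise_factorial_anova(es, n_perm = 10), "cell")
})

test_that("two-sample pooled d matches hand arithmetic and the brute-force oracle", {
  # equal means give d = 0; a difference equal to the pooled SD gives d = 1
  a <- c(1, 2, 3, 4); b <- a
  expect_equal(cohens_d_two_sample(a, b), 0)
  sp <- sqrt(var(a))          # pooled SD of two equal-variance samples
  expect_equal(cohens_d_two_sample(a + sp, a), 1)
  set.seed(44)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8, 0.5)
    expect_equal(cohens_d_two_sample(x, y), oracle_pooled_d(x, y),
                 tolerance = 1e-12)
  }
  expect_warning(d0 <- cohens_d_two_sample(c(1, 1), c(1, 1)), "undefined")
  expect_true(is.na(d0))
})

test_that("cluster-window effect size uses the largest-|mass| cluster", {
  es <- cell_epochs(25, offsets = c(1.2, 0, 1.2, 0), noise_sd = 0.7,
                    seed = 45)
  ft <- pointwise_factorial_anova(es, n_perm = 200, rng_seed = 3)
  ce <- cluster_effect_size(es, 1, "gaze", ft)
  expect_gt(ce$abs_d, 0.5)
  expect_gt(ce$level_means[["averted"]], ce$level_means[["direct"]])
  m <- faceflow:::site_matrix(es, 1)
  idx <- which(es$time_ms >= ce$window_ms[1] & es$time_ms <= ce$window_ms[2])
  tm <- rowMeans(m[, idx])
  averted <- es$trials$gaze %in% c("left", "right")
  expect_equal(ce$d, oracle_pooled_d(tm[averted], tm[!averted]),
               tolerance = 1e-12)
  expect_error(cluster_effect_size(es, 1, "emotion",
                                   data.frame(t_start_ms = numeric(),
                                              t_end_ms = numeric(),
                                              mass = numeric())),
               "no cluster")
})

test_that("effect-size comparisons handle null and planted STC-dominant cases", {
  # all |d| identical: every t = 0, ANOVA F = 0
  es_null <- data.frame(site = paste0("s", 1:40),
                        roi = rep(c("IOC", "FC", "ITC", "STC"), each = 10),
                        effect = rep(c("gaze", "emotion"), 20),
                        abs_d = 0.4)
  cmp <- compare_effects_across_rois(es_null)
  expect_true(all(cmp$within_roi$t == 0))
  expect_equal(cmp$anova$gaze$F, 0)
  expect_true(all(cmp$posthoc$t == 0))
  # STC gaze |d| planted high: STC-vs-other post hocs significant
  set.seed(46)
  rois <- rep(c("IOC", "FC", "ITC", "STC"), each = 10)
  esg <- data.frame(site = paste0("g", 1:40), roi = rois, effect = "gaze",
                    abs_d = rnorm(40, ifelse(rois == "STC", 0.8, 0.3), 0.1))
  ese <- data.frame(site = paste0("e", 1:40), roi = rois, effect = "emotion",
                    abs_d = rnorm(40, 0.3, 0.1))
  cmp2 <- compare_effects_across_rois(rbind(esg, ese))
  expect_lt(cmp2$anova$gaze$p, 0.01)
  ph <- cmp2$posthoc
  stc_pairs <- ph$effect == "gaze" & (ph$roi_a == "STC" | ph$roi_b == "STC")
  expect_true(all(ph$p[stc_pairs] < 0.05))
  wr <- cmp2$within_roi
  expect_lt(wr$p[wr$roi == "STC"], 0.05)
  expect_true(all(wr$p[wr$roi != "STC"] > 0.05))
})

test_that("with two ROIs the one-way ANOVA reduces to the two-sample t (F = t^2)", {
  set.seed(47)
  es <- data.frame(site = paste0("s", 1:12),
                   roi = rep(c("IOC", "STC"), each = 6),
                   effect = "gaze", abs_d = rnorm(12, 0.5, 0.2))
  cmp <- compare_effects_across_rois(es)
  expect_equal(cmp$anova$gaze$F, cmp$posthoc$t[1]^2, tolerance = 1e-10)
})

test_that("null factorial data keep the significant-cluster rate near nominal", {
  # small-scale; the 1000-simulation version runs in the acceptance suite
  set.seed(48)
  hits <- vapply(1:100, function(i) {
    es <- cell_epochs(10, seed = 9000 + i)
    ft <- pointwise_factorial_anova(es, n_perm = 199, rng_seed = 100 + i)
    any(nrow(ft$gaze) > 0 && min(ft$gaze$p) < 0.05)
  }, NA)
  expect_gte(mean(hits), 0.005)
  expect_lte(mean(hits), 0.12)
})
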