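#' Liberal amplitude screen for a minimal evoked response
#'
#' First step of the two-step responsiveness test: a site passes the screen
#' if its trial-averaged z-scored waveform exceeds |Z| = 1 (strictly) at any
#' sample in the 0-400 ms poststimulus window.
#'
#' @param epochs An `epoch_set` of z-scored data.
#' @param site Site index or name.
#' @return Logical flag.
#' @export
screen_minimal_response <- function(epochs, site = 1L) {
  m <- site_matrix(epochs, resolve_site(epochs, site))
  idx <- time_index(epochs$time_ms, 0, 400)
  avg <- colMeans(m[, idx, drop = FALSE])
  max(abs(avg)) > 1
}

resolve_site <- function(epochs, site) {
  if (is.character(site)) {
    i <- match(site, epochs$sites$site)
    if (is.na(i)) stop("unknown site '", site, "'")
    i
  } else as.integer(site)
}

# contiguous same-sign suprathreshold clusters of a statistic trace.
# Returns data.frame(start, end (indices), mass, sign); opposite-sign
# clusters never merge even when temporally adjacent.
find_clusters <- function(stat, threshold) {
  stat[!is.finite(stat)] <- 0
  lab <- ifelse(stat > threshold, 1L, ifelse(stat < -threshold, -1L, 0L))
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values != 0L)
  if (!length(keep))
    return(data.frame(start = integer(), end = integer(),
                      mass = numeric(), sign = integer()))
  data.frame(start = starts[keep], end = ends[keep],
             mass = vapply(keep, function(k)
               sum(stat[starts[k]:ends[k]]), 0),
             sign = r$values[keep])
}

# max |cluster mass| of a statistic trace (0 when no cluster)
max_cluster_mass <- function(stat, threshold) {
  cl <- find_clusters(stat, threshold)
  if (!nrow(cl)) 0 else max(abs(cl$mass))
}

# pointwise one-sample t for all sign-flip assignments in `signs`
# (matrix n_draws x n_trials of +/-1); col sums of squares are flip-invariant.
signflip_t <- function(x, signs) {
  n <- nrow(x)
  css <- colSums(x^2)
  mns <- (signs %*% x) / n
  se <- sqrt(sweep(-(n) * mns^2, 2, css, "+") / (n - 1) / n)
  mns / se
}

#' Cluster-based sign-flip permutation t-test against zero
#'
#' Second step of the responsiveness test. A pointwise one-sample t statistic
#' is computed across trials at every sample in the 0-400 ms window; samples
#' whose |t| exceeds the two-sided cluster-forming threshold (t distribution
#' with `n_trials - 1` df at level `cluster_alpha`) are grouped into
#' temporally contiguous, same-sign clusters whose mass is the sum of t
#' values. The null distribution of the maximum |mass| is built by randomly
#' flipping the sign of whole trials (`n_perm` draws); each cluster's Monte
#' Carlo p is `(1 + #(null >= observed)) / (1 + n_perm)`, which intrinsically
#' corrects for multiple comparisons over time and can never be exactly zero.
#'
#' @param epochs An `epoch_set` of z-scored data.
#' @param site Site index or name.
#' @param n_perm Number of sign-flip draws (warning below 100).
#' @param cluster_alpha Two-sided pointwise level of the cluster-forming
#'   threshold.
#' @param rng_seed Integer seed for the draws.
#' @param window Analysis window in ms (default 0-400).
#' @return A list of class `cluster_test` with `clusters` (data frame:
#'   `t_start_ms`, `t_end_ms`, `mass`, `sign`, `p`), `n_perm`,
#'   `cluster_alpha`, `threshold`, `rng_seed`, `n_trials`, and `min_p` (1
#'   when no cluster formed).
#' @export
cluster_permutation_vs_zero <- function(epochs, site = 1L, n_perm = 1000,
                                        cluster_alpha = 0.05, rng_seed = 1L,
                                        window = c(0, 400)) {
  x <- site_matrix(epochs, resolve_site(epochs, site))
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  idx <- time_index(epochs$time_ms, window[1], window[2])
  x <- x[, idx, drop = FALSE]
  n <- nrow(x)
  if (n == 0) stop("no trials")
  if (n < 2) stop("need at least 2 trials for a t-test")
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse Monte Carlo p")

  thr <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  t_obs <- drop(signflip_t(x, matrix(1, 1, n)))
  cl <- find_clusters(t_obs, thr)

  local_rng(rng_seed)
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  t_null <- signflip_t(x, signs)
  null_max <- apply(t_null, 1L, max_cluster_mass, threshold = thr)

  p <- if (nrow(cl)) vapply(abs(cl$mass), function(m)
    (1 + sum(null_max >= m)) / (1 + n_perm), 0) else numeric()
  out <- data.frame(t_start_ms = epochs$time_ms[idx][cl$start],
                    t_end_ms = epochs$time_ms[idx][cl$end],
                    mass = cl$mass, sign = cl$sign, p = p)
  structure(list(clusters = out, n_perm = n_perm,
                 cluster_alpha = cluster_alpha, threshold = thr,
                 rng_seed = rng_seed, n_trials = n,
                 min_p = if (nrow(out)) min(out$p) else 1),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("Cluster sign-flip test: %d trials, %d permutations, %d cluster(s)\n",
              x$n_trials, x$n_perm, nrow(x$clusters)))
  if (nrow(x$clusters)) print(format(x$clusters, digits = 3))
  invisible(x)
}

#' Run the two-step responsiveness test over all sites of an epoch set
#'
#' Applies [screen_minimal_response()] and, for screened-in sites,
#' [cluster_permutation_vs_zero()]. Screened-out sites get `p = NA` and do
#' not count toward the Bonferroni N.
#'
#' @inheritParams cluster_permutation_vs_zero
#' @param epochs An `epoch_set` whose `sites` table has `roi` and
#'   `hemisphere` columns.
#' @return Data frame with one row per site: `site`, `roi`, `hemisphere`,
#'   `n_trials`, `screened_in`, `best_start_ms`, `best_end_ms`, `best_mass`,
#'   `p` (minimum cluster Monte Carlo p).
#' @export
test_responsiveness <- function(epochs, n_perm = 1000, cluster_alpha = 0.05,
                                rng_seed = 1L) {
  sites <- epochs$sites
  res <- lapply(seq_len(nrow(sites)), function(i) {
    scr <- screen_minimal_response(epochs, i)
    row <- data.frame(site = sites$site[i], roi = sites$roi[i],
                      hemisphere = sites$hemisphere[i],
                      n_trials = dim(epochs)[1], screened_in = scr,
                      best_start_ms = NA_real_, best_end_ms = NA_real_,
                      best_mass = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
    if (scr) {
      ct <- cluster_permutation_vs_zero(epochs, i, n_perm, cluster_alpha,
                                        rng_seed + i)
      if (nrow(ct$clusters)) {
        b <- which.max(abs(ct$clusters$mass))
        row$best_start_ms <- ct$clusters$t_start_ms[b]
        row$best_end_ms <- ct$clusters$t_end_ms[b]
        row$best_mass <- ct$clusters$mass[b]
        row$p <- ct$min_p
      } else row$p <- 1
    }
    row
  })
  do.call(rbind, res)
}

#' Bonferroni correction across sites within ROI and hemisphere
#'
#' A site's smallest cluster Monte Carlo p is significant when it is strictly
#' below `0.05 / N`, where `N` is the number of sites *tested* (screened-in)
#' in the same ROI and hemisphere.
#'
#' @param results Data frame from [test_responsiveness()].
#' @param alpha Family-wise level before division.
#' @return The input with `n_tested`, `alpha_corrected` and `significant`
#'   columns added.
#' @export
bonferroni_across_sites <- function(results, alpha = 0.05) {
  grp <- interaction(results$roi, results$hemisphere, drop = TRUE)
  n_tested <- stats::ave(as.numeric(results$screened_in), grp, FUN = sum)
  results$n_tested <- as.integer(n_tested)
  results$alpha_corrected <- ifelse(results$n_tested > 0,
                                    alpha / results$n_tested, NA_real_)
  results$significant <- !is.na(results$p) &
    results$p < results$alpha_corrected
  results
}

#' Classify sites by responsiveness to Face 1 and Face 2
#'
#' Combines corrected significance flags from the two locked analyses into
#' the categories `Face1_only`, `Face2_only`, `both`, `unresponsive`.
#' Screened-out sites are unresponsive without running the permutation step.
#'
#' @param face1,face2 Results from [bonferroni_across_sites()] for the
#'   Face 1- and Face 2-locked epoch sets, over the same sites.
#' @return Data frame: `site`, `roi`, `hemisphere`, `face1_responsive`,
#'   `face2_responsive`, `category`.
#' @export
classify_sites <- function(face1, face2) {
  if (!identical(face1$site, face2$site))
    stop("Face 1 and Face 2 results cover different site sets")
  f1 <- face1$significant; f2 <- face2$significant
  category <- ifelse(f1 & f2, "both",
                     ifelse(f1, "Face1_only",
                            ifelse(f2, "Face2_only", "unresponsive")))
  data.frame(site = face1$site, roi = face1$roi,
             hemisphere = face1$hemisphere,
             face1_responsive = f1, face2_responsive = f2,
             category = category, stringsAsFactors = FALSE)
}
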