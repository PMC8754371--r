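#' Synthetic streamline sets for white-matter tracts
#'
#' Generates per-subject streamline collections running between two endpoint
#' centroids per tract, with Gaussian scatter on both endpoints and smooth
#' interpolation in between — a stand-in fixture for whole-brain tractography
#' segmented into named tracts, which is out of scope here.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param tract_specs List of tract descriptions, each a list with `name`,
#'   `from`, `to` (MNI mm endpoint centroids), and optionally
#'   `n_streamlines` (default 50) and `n_points` (default 20).
#' @param scatter_sd Gaussian scatter SD (mm) applied to each endpoint
#'   (>= 0).
#' @param rng_seed Integer seed; per-subject sets are independent draws.
#' @return A list of `streamline_set` objects (fields `tract`, `subject`,
#'   `streamlines`: list of n_points x 3 matrices), one per subject x tract.
#' @export
simulate_tract_endpoints <- function(n_subjects, tract_specs, scatter_sd = 2,
                                     rng_seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (!length(tract_specs)) stop("tract_specs must not be empty")
  if (scatter_sd < 0) stop("scatter_sd must be >= 0")
  local_rng(rng_seed)
  out <- list()
  for (s in seq_len(n_subjects)) {
    for (ts in tract_specs) {
      n_sl <- if (is.null(ts$n_streamlines)) 50L else ts$n_streamlines
      n_pt <- if (is.null(ts$n_points)) 20L else ts$n_points
      sls <- lapply(seq_len(n_sl), function(i) {
        p0 <- ts$from + stats::rnorm(3, 0, scatter_sd)
        p1 <- ts$to + stats::rnorm(3, 0, scatter_sd)
        w <- seq(0, 1, length.out = n_pt)
        cbind(p0[1] + w * (p1[1] - p0[1]),
              p0[2] + w * (p1[2] - p0[2]),
              p0[3] + w * (p1[3] - p0[3]))
      })
      out[[length(out) + 1L]] <-
        structure(list(tract = ts$name, subject = paste0("sub", s),
                       streamlines = sls),
                  class = "streamline_set")
    }
  }
  out
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("Streamline set: tract '%s', subject '%s', %d streamlines\n",
              x$tract, x$subject, length(x$streamlines)))
  invisible(x)
}

streamline_length <- function(m) {
  if (nrow(m) < 2) return(0)
  sum(sqrt(rowSums(diff(m)^2)))
}

#' Remove outlier streamlines from a tract
#'
#' Removes streamlines whose centroid lies more than 4 standard deviations
#' from the tract centroid, or whose length deviates more than 4 standard
#' deviations from the mean streamline length. Both criteria are applied;
#' degenerate (zero-SD) criteria remove nothing.
#'
#' @param set A `streamline_set` with >= 2 streamlines.
#' @param n_sd Deviation threshold in SD units.
#' @return The cleaned `streamline_set` with an attribute `"removed"`
#'   (indices removed). Errors if all streamlines would be removed.
#' @export
clean_streamline_outliers <- function(set, n_sd = 4) {
  sls <- set$streamlines
  if (length(sls) < 2) stop("need at least 2 streamlines")
  cents <- t(vapply(sls, colMeans, numeric(3)))
  tract_cent <- colMeans(cents)
  cd <- sqrt(rowSums(sweep(cents, 2, tract_cent)^2))
  lens <- vapply(sls, streamline_length, 0)
  out_c <- if (stats::sd(cd) > 0) abs(cd - mean(cd)) > n_sd * stats::sd(cd)
  else rep(FALSE, length(cd))
  out_l <- if (stats::sd(lens) > 0)
    abs(lens - mean(lens)) > n_sd * stats::sd(lens)
  else rep(FALSE, length(lens))
  rm_idx <- which(out_c | out_l)
  if (length(rm_idx) == length(sls))
    stop("outlier cleaning would remove every streamline")
  set$streamlines <- sls[setdiff(seq_along(sls), rm_idx)]
  attr(set, "removed") <- rm_idx
  set
}

#' Reorient streamlines so first points share an endpoint collection
#'
#' The first streamline serves as the reference; every other streamline is
#' reversed (point order flipped, coordinates untouched) when doing so
#' brings its two ends closer to the reference's ends (i.e. the end
#' assignment minimizing total distance, equivalently the total number of
#' flips against the reference). After reorientation all "first" nodes
#' belong to one endpoint collection and all "last" nodes to the other.
#'
#' @param set A `streamline_set` with >= 1 streamline.
#' @return The reoriented `streamline_set`.
#' @export
reorient_streamlines <- function(set) {
  sls <- set$streamlines
  if (!length(sls)) stop("empty streamline set")
  ref_first <- sls[[1]][1, ]
  ref_last <- sls[[1]][nrow(sls[[1]]), ]
  set$streamlines <- lapply(sls, function(m) {
    a <- m[1, ]; b <- m[nrow(m), ]
    keep <- sum((a - ref_first)^2) + sum((b - ref_last)^2)
    flip <- sum((b - ref_first)^2) + sum((a - ref_last)^2)
    if (flip < keep) m[rev(seq_len(nrow(m))), , drop = FALSE] else m
  })
  set
}

#' Write / read streamline sets as plain-text TSV
#'
#' Text interchange format: columns `streamline`, `point`, `x`, `y`, `z`.
#'
#' @param set A `streamline_set`.
#' @param path File path.
#' @param tract,subject Identifiers used when reading.
#' @return `read_streamlines_tsv` returns a `streamline_set`.
#' @export
write_streamlines_tsv <- function(set, path) {
  rows <- do.call(rbind, lapply(seq_along(set$streamlines), function(i) {
    m <- set$streamlines[[i]]
    data.frame(streamline = i, point = seq_len(nrow(m)),
               x = m[, 1], y = m[, 2], z = m[, 3])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_streamlines_tsv
#' @export
read_streamlines_tsv <- function(path, tract = NA_character_,
                                 subject = NA_character_) {
  d <- utils::read.delim(path)
  sls <- lapply(split(d, d$streamline), function(s)
    as.matrix(s[order(s$point), c("x", "y", "z")]))
  names(sls) <- NULL
  sls <- lapply(sls, function(m) { dimnames(m) <- NULL; m })
  structure(list(tract = tract, subject = subject, streamlines = sls),
            class = "streamline_set")
}
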