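#' Assign an anatomical label to a region of interest
#'
#' Maps the controlled anatomical vocabulary onto the four occipitotemporal
#' regions of interest plus the intraparietal sulcus:
#' \describe{
#'   \item{FC}{fusiform gyrus, occipitotemporal sulcus, collateral sulcus,
#'     midfusiform sulcus}
#'   \item{IOC}{inferior occipital gyrus, inferior occipital sulcus, lateral
#'     occipital sulcus, midoccipital gyrus, fourth occipital gyrus,
#'     transverse posterior collateral sulcus}
#'   \item{STC}{superior temporal sulcus, middle temporal gyrus, superior
#'     temporal gyrus}
#'   \item{ITC}{inferior temporal sulcus, inferior temporal gyrus}
#'   \item{IPS}{intraparietal sulcus}
#' }
#' Any other label maps to `"other"` (with a warning, never silently).
#' Hemisphere is the sign of the MNI x coordinate (x < 0 is left; x = 0 is
#' assigned right by convention).
#'
#' @param label Anatomical label string.
#' @param mni Optional MNI coordinate (length-3, mm) for hemisphere
#'   assignment.
#' @param warn Warn on labels outside the vocabulary.
#' @return List with `roi` and (when `mni` given) `hemisphere`.
#' @export
assign_roi <- function(label, mni = NULL, warn = TRUE) {
  vocab <- list(
    FC = c("fusiform gyrus", "occipitotemporal sulcus", "collateral sulcus",
           "midfusiform sulcus"),
    IOC = c("inferior occipital gyrus", "inferior occipital sulcus",
            "lateral occipital sulcus", "midoccipital gyrus",
            "fourth occipital gyrus", "transverse posterior collateral sulcus"),
    STC = c("superior temporal sulcus", "middle temporal gyrus",
            "superior temporal gyrus"),
    ITC = c("inferior temporal sulcus", "inferior temporal gyrus"),
    IPS = c("intraparietal sulcus"))
  lab <- tolower(trimws(label))
  roi <- "other"
  for (r in names(vocab)) if (lab %in% vocab[[r]]) { roi <- r; break }
  if (roi == "other" && warn && !lab %in% c("scalp", "white matter", "other"))
    warning("label '", label, "' not in the ROI vocabulary; assigned 'other'")
  out <- list(roi = roi)
  if (!is.null(mni)) out$hemisphere <- if (mni[1] < 0) "L" else "R"
  out
}

#' Re-express epochs as bipolar derivations
#'
#' Forms one virtual recording site per pair of adjacent retained contacts on
#' the same depth-electrode shaft, with signal `deeper - shallower` (contacts
#' are ordered deep to shallow by index). Pairs spanning an excluded contact
#' are not formed. The site coordinate is the arithmetic midpoint of the two
#' contacts, the anatomical label is taken from the deeper contact, and ROI
#' and hemisphere follow [assign_roi()]. Subtracting adjacent contacts
#' cancels signal common to the shaft (e.g. volume-conducted and reference
#' activity) and emphasizes local generators.
#'
#' @param x A `long_epochs` or `contact_recording`.
#' @param patient Optional patient id stored on each site.
#' @return Same class as `x`, with channels replaced by bipolar sites; the
#'   site table (class `bipolar_sites`) has columns `site`, `shaft`,
#'   `deep_index`, `shallow_index`, `label`, `roi`, `hemisphere`,
#'   `x`, `y`, `z`, `patient`.
#' @export
derive_bipolar <- function(x, patient = NA_character_) {
  meta <- if (inherits(x, "long_epochs")) x$channels else x$contact_meta
  ok <- !meta$excluded & meta$in_brain & !isTRUE_col(meta$is_scalp)

  pairs <- list()
  for (sh in unique(meta$shaft[ok])) {
    rows <- which(meta$shaft == sh & ok)
    rows <- rows[order(meta$index[rows])]
    if (length(rows) < 2) {
      warning("shaft '", sh, "' has fewer than 2 retained contacts; no sites")
      next
    }
    for (j in seq_len(length(rows) - 1)) {
      a <- rows[j]; b <- rows[j + 1]
      if (meta$index[b] != meta$index[a] + 1L) next   # spans an excluded contact
      pairs[[length(pairs) + 1L]] <- c(a, b)
    }
  }
  if (!length(pairs)) stop("no bipolar sites could be formed")

  sites <- do.call(rbind, lapply(pairs, function(p) {
    deep <- p[1]; shal <- p[2]
    mid <- c(meta$x[deep] + meta$x[shal], meta$y[deep] + meta$y[shal],
             meta$z[deep] + meta$z[shal]) / 2
    ra <- assign_roi(meta$label[deep], mni = mid, warn = FALSE)
    data.frame(site = paste0(meta$shaft[deep], ".", meta$index[deep], "-",
                             meta$index[shal]),
               shaft = meta$shaft[deep], deep_index = meta$index[deep],
               shallow_index = meta$index[shal], label = meta$label[deep],
               roi = ra$roi, hemisphere = ra$hemisphere,
               x = mid[1], y = mid[2], z = mid[3], patient = patient,
               stringsAsFactors = FALSE)
  }))
  class(sites) <- c("bipolar_sites", "data.frame")

  reexpress <- function(m) {
    out <- matrix(0, length(pairs), ncol(m))
    for (k in seq_along(pairs))
      out[k, ] <- m[pairs[[k]][1], ] - m[pairs[[k]][2], ]
    out
  }
  if (inherits(x, "long_epochs")) {
    x$epochs <- lapply(x$epochs, function(m) if (is.null(m)) NULL else
      reexpress(m))
    x$channels <- sites
  } else {
    x$signal <- reexpress(x$signal)
    x$contact_meta <- sites
  }
  x
}
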