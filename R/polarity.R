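# Endothelial planar-polarity quantification from two-channel fluorescence
# images: background thresholding, despeckling, object identification,
# nucleus-to-Golgi pairing, orientation classes, polarity metrics.
#
# Image convention: matrices indexed [row, col]; x runs along columns and
# y along rows, both in increasing index direction; centroids are reported
# in micrometers with the pixel at [1, 1] centered on (0.5, 0.5) px.

#' Estimate background mean and SD of a fluorescence channel
#'
#' Fits a Gaussian to the dominant low-intensity mode of the grey-level
#' histogram (a weighted parabola on log bin counts around the modal bin),
#' which is robust to a sparse bright foreground. Falls back to the
#' whole-image mean and SD when the mode fit is degenerate (too few
#' populated bins or non-concave log-histogram).
#'
#' @param channel numeric matrix of intensities (8-bit integers or any
#'   numeric scale).
#' @return A list with `mean`, `sd`, and `method` (`"mode_fit"` or
#'   `"global"`).
#' @export
estimate_background <- function(channel) {
  v <- as.numeric(channel)
  if (length(v) == 0 || any(!is.finite(v))) {
    stop("`channel` must be a non-empty finite numeric matrix", call. = FALSE)
  }
  global <- list(mean = mean(v), sd = stats::sd(v), method = "global")
  if (length(unique(v)) < 8) return(global)

  integerish <- all(v == round(v)) && diff(range(v)) <= 512
  breaks <- if (integerish) {
    seq(min(v) - 0.5, max(v) + 0.5, by = 1)
  } else {
    seq(min(v), max(v), length.out = 257)
  }
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  mids <- h$mids
  cts <- h$counts
  # background = lowest-intensity dominant mode (robust to a bright
  # foreground mode, which sits at higher intensity)
  pad <- c(-Inf, cts, -Inf)
  is_max <- cts >= pad[seq_along(cts)] & cts >= pad[seq_along(cts) + 2]
  cand <- which(is_max & cts >= 0.2 * max(cts))
  i0 <- if (length(cand)) min(cand) else which.max(cts)
  keep <- cts >= 0.2 * cts[i0]
  # contiguous run of well-populated bins around the mode
  lo <- i0; while (lo > 1 && keep[lo - 1]) lo <- lo - 1
  hi <- i0; while (hi < length(cts) && keep[hi + 1]) hi <- hi + 1
  idx <- lo:hi
  if (length(idx) < 5) return(global)
  fit <- stats::lm(log(cts[idx]) ~ mids[idx] + I(mids[idx]^2),
                   weights = cts[idx])
  a2 <- stats::coef(fit)[3]
  a1 <- stats::coef(fit)[2]
  if (!is.finite(a2) || a2 >= 0) return(global)
  mu <- -a1 / (2 * a2)
  sigma <- sqrt(-1 / (2 * a2))
  if (!is.finite(mu) || !is.finite(sigma) || mu < min(v) || mu > max(v)) {
    return(global)
  }
  list(mean = unname(mu), sd = unname(sigma), method = "mode_fit")
}

#' Threshold a channel against its Gaussian background
#'
#' Marks as foreground every pixel strictly above mean + k·SD of the
#' background distribution. With the default k = 3.89 a pure Gaussian
#' background retains 99.995\% of its pixels (one-sided normal tail).
#'
#' @inheritParams estimate_background
#' @param k positive multiplier of the background SD (default 3.89).
#' @param background optional list with `mean` and `sd` overriding
#'   [estimate_background()].
#' @return Logical matrix, `TRUE` for foreground. A constant image yields
#'   an all-`FALSE` mask.
#' @export
gaussian_background_threshold <- function(channel, k = 3.89,
                                          background = NULL) {
  .check_positive(k, "k")
  if (is.null(background)) background <- estimate_background(channel)
  if (!is.finite(background$sd) || background$sd == 0) {
    # constant image: nothing exceeds the background
    return(matrix(FALSE, nrow(channel), ncol(channel)))
  }
  channel > background$mean + k * background$sd
}

#' Remove isolated foreground pixels with a 3x3 median filter
#'
#' One pass of a binary 3x3 median (majority of the 9-pixel neighbourhood,
#' zero-padded at the borders): isolated single foreground pixels vanish,
#' solid regions keep their interior.
#'
#' @param mask logical (or 0/1) matrix.
#' @return Logical matrix of the same dimension.
#' @export
despeckle <- function(mask) {
  m <- (mask != 0) * 1L
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  s <- matrix(0L, nr, nc)
  for (dr in 0:2) for (dc in 0:2) {
    s <- s + p[(1L + dr):(nr + dr), (1L + dc):(nc + dc)]
  }
  s >= 5L
}

.union_find <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Label connected foreground components (8-connectivity)
#'
#' Labels 4-connected components with `EBImage::bwlabel`, then merges
#' labels that touch diagonally, yielding 8-connected components with
#' consecutive integer labels.
#'
#' @param mask logical (or 0/1) matrix.
#' @return Integer matrix of labels, 0 for background.
#' @export
label_components <- function(mask) {
  m <- (mask != 0) * 1
  L <- matrix(as.integer(EBImage::imageData(EBImage::bwlabel(m))),
              nrow(m), ncol(m))
  n <- max(L)
  if (n <= 1L) return(L)
  nr <- nrow(L); nc <- ncol(L)
  a1 <- L[-nr, -nc]; b1 <- L[-1, -1]    # down-right diagonal
  a2 <- L[-nr, -1];  b2 <- L[-1, -nc]   # down-left diagonal
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  root <- .union_find(n, pairs)
  relab <- match(root, sort(unique(root)))
  out <- L
  out[L > 0L] <- relab[L[L > 0L]]
  out
}

#' Identify organelles from a binary mask
#'
#' Labels connected components (8-connectivity), discards components below
#' the size-segmentation threshold, and measures each survivor: centroid,
#' area, and ellipse-equivalent major/minor axis lengths from second-order
#' moments (axes of the ellipse with the same normalized second central
#' moments as the pixel set, including the 1/12 px² pixel-extent term).
#'
#' @param mask logical matrix (foreground `TRUE`).
#' @param pixel_size_um pixel edge length, µm.
#' @param channel `"nucleus"` or `"golgi"`; sets the default `min_area_um2`
#'   (10 µm² for nuclei, 2 µm² for Golgi).
#' @param min_area_um2 minimum component area kept, µm².
#' @return A tibble with columns `id`, `channel`, `x_um`, `y_um`,
#'   `major_axis_um`, `minor_axis_um`, `area_um2`, `n_pixels`; zero rows
#'   for an empty mask.
#' @export
identify_objects <- function(mask, pixel_size_um = wss_defaults()$pixel_size_um,
                             channel = c("nucleus", "golgi"),
                             min_area_um2 = NULL) {
  channel <- match.arg(channel)
  .check_positive(pixel_size_um, "pixel_size_um")
  if (is.null(min_area_um2)) {
    min_area_um2 <- if (channel == "nucleus") {
      wss_defaults()$min_area_nucleus_um2
    } else {
      wss_defaults()$min_area_golgi_um2
    }
  }
  empty <- tibble::tibble(
    id = integer(), channel = character(), x_um = numeric(),
    y_um = numeric(), major_axis_um = numeric(), minor_axis_um = numeric(),
    area_um2 = numeric(), n_pixels = integer()
  )
  if (!any(mask != 0)) return(empty)
  L <- label_components(mask)
  idx <- which(L > 0L)
  lab <- L[idx]
  nr <- nrow(L)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  x <- col - 0.5
  y <- row - 0.5
  mom <- rowsum(cbind(1, x, y, x * x, y * y, x * y), lab)
  n <- mom[, 1]
  keep <- n * pixel_size_um^2 >= min_area_um2
  if (!any(keep)) return(empty)
  mom <- mom[keep, , drop = FALSE]
  n <- mom[, 1]
  mx <- mom[, 2] / n
  my <- mom[, 3] / n
  # central second moments + 1/12 pixel-extent term
  cxx <- mom[, 4] / n - mx^2 + 1 / 12
  cyy <- mom[, 5] / n - my^2 + 1 / 12
  cxy <- mom[, 6] / n - mx * my
  tr2 <- (cxx + cyy) / 2
  dd <- sqrt(((cxx - cyy) / 2)^2 + cxy^2)
  l1 <- pmax(tr2 + dd, 0)
  l2 <- pmax(tr2 - dd, 0)
  tibble::tibble(
    id = seq_along(n), channel = channel,
    x_um = mx * pixel_size_um, y_um = my * pixel_size_um,
    major_axis_um = 4 * sqrt(l1) * pixel_size_um,
    minor_axis_um = 4 * sqrt(l2) * pixel_size_um,
    area_um2 = n * pixel_size_um^2, n_pixels = as.integer(n)
  )
}

#' Pair each nucleus with its nearest Golgi apparatus
#'
#' Builds the nucleus-to-Golgi (N-G) vector of every cell: from the nucleus
#' centroid to the centroid of the nearest Golgi (Euclidean distance). By
#' default a Golgi may serve several nuclei; ties are broken by the lowest
#' Golgi id. With `one_to_one = TRUE` pairs are assigned greedily by
#' increasing distance and each Golgi is used at most once.
#'
#' @param nuclei,golgi tibbles from [identify_objects()].
#' @param one_to_one logical; restrict each Golgi to one nucleus.
#' @return A tibble with one row per paired nucleus: `nucleus_id`,
#'   `golgi_id`, `dx_um`, `dy_um`, `ng_length_um`, `nucleus_elongation`.
#'   Zero rows when either input is empty.
#' @export
pair_nucleus_to_golgi <- function(nuclei, golgi, one_to_one = FALSE) {
  empty <- tibble::tibble(
    nucleus_id = integer(), golgi_id = integer(), dx_um = numeric(),
    dy_um = numeric(), ng_length_um = numeric(),
    nucleus_elongation = numeric()
  )
  if (nrow(nuclei) == 0 || nrow(golgi) == 0) return(empty)
  dmat <- outer(nuclei$x_um, golgi$x_um, "-")^2 +
    outer(nuclei$y_um, golgi$y_um, "-")^2
  ord_g <- order(golgi$id)
  dmat <- dmat[, ord_g, drop = FALSE]
  gid <- golgi$id[ord_g]
  if (!one_to_one) {
    j <- apply(dmat, 1, which.min)  # first minimum = lowest golgi id
  } else {
    j <- rep(NA_integer_, nrow(nuclei))
    free <- rep(TRUE, length(gid))
    ord <- order(dmat)
    for (k in ord) {
      i <- (k - 1) %% nrow(dmat) + 1
      jj <- (k - 1) %/% nrow(dmat) + 1
      if (is.na(j[i]) && free[jj]) {
        j[i] <- jj
        free[jj] <- FALSE
      }
    }
  }
  ok <- !is.na(j)
  gx <- golgi$x_um[ord_g][j[ok]]
  gy <- golgi$y_um[ord_g][j[ok]]
  tibble::tibble(
    nucleus_id = nuclei$id[ok],
    golgi_id = gid[j[ok]],
    dx_um = gx - nuclei$x_um[ok],
    dy_um = gy - nuclei$y_um[ok],
    ng_length_um = sqrt((gx - nuclei$x_um[ok])^2 + (gy - nuclei$y_um[ok])^2),
    nucleus_elongation = nuclei$major_axis_um[ok] / nuclei$minor_axis_um[ok]
  )
}

#' Angle between the N-G vector and the blood-flow direction
#'
#' Reported on a semicircle: 0° means the vector points with the flow
#' (dromic extreme), 180° against it (antidromic extreme).
#'
#' @param dx,dy N-G vector components (any common unit).
#' @param flow_direction length-2 non-zero vector giving the blood-flow
#'   direction in image coordinates.
#' @return Angles in degrees in \[0, 180\]; `NA` for zero-length N-G
#'   vectors (flagged with a warning, excluded from classification).
#' @export
#' @examples
#' angle_to_flow(1, sqrt(3), c(1, 0))  # 60
angle_to_flow <- function(dx, dy, flow_direction) {
  if (length(flow_direction) != 2 || all(flow_direction == 0)) {
    stop("`flow_direction` must be a non-zero length-2 vector", call. = FALSE)
  }
  nv <- sqrt(dx^2 + dy^2)
  nf <- sqrt(sum(flow_direction^2))
  zero <- nv == 0
  if (any(zero)) {
    warning(sum(zero), " zero-length N-G vector(s) excluded", call. = FALSE)
  }
  ct <- (dx * flow_direction[1] + dy * flow_direction[2]) / (nv * nf)
  out <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
  out[zero] <- NA_real_
  out
}

#' Classify an orientation angle into dromic / lateral / antidromic
#'
#' Half-open classes on the semicircle: dromic (with the flow) on
#' \[0°, 60°), lateral (perpendicular) on \[60°, 120°), antidromic
#' (against the flow) on \[120°, 180°\].
#'
#' @param angle_deg angles in degrees in \[0, 180\]; `NA` allowed
#'   (propagated).
#' @param breaks two class boundaries, default `c(60, 120)`.
#' @return Factor with levels `dromic`, `lateral`, `antidromic`.
#' @export
#' @examples
#' classify_orientation(c(10, 60, 150))
classify_orientation <- function(angle_deg,
                                 breaks = wss_defaults()$angle_breaks_deg) {
  ok <- is.na(angle_deg) | (angle_deg >= 0 & angle_deg <= 180)
  if (!all(ok)) stop("`angle_deg` must lie in [0, 180]", call. = FALSE)
  cut(angle_deg, breaks = c(-Inf, breaks, Inf), right = FALSE,
      labels = c("dromic", "lateral", "antidromic"))
}

#' Orientation class frequencies
#'
#' @param orientation_class factor from [classify_orientation()] (or a
#'   tibble with an `orientation_class` column). Under the no-orientation
#'   null each class holds one third of the cells.
#' @return A tibble with `orientation_class`, `n`, `pct` (percent, summing
#'   to 100) over non-missing classes.
#' @export
orientation_summary <- function(orientation_class) {
  if (is.data.frame(orientation_class)) {
    orientation_class <- orientation_class$orientation_class
  }
  orientation_class <- orientation_class[!is.na(orientation_class)]
  if (length(orientation_class) == 0) {
    stop("no classified cells", call. = FALSE)
  }
  tab <- table(factor(orientation_class,
                      levels = c("dromic", "lateral", "antidromic")))
  tibble::tibble(
    orientation_class = names(tab),
    n = as.integer(tab),
    pct = 100 * as.integer(tab) / sum(tab)
  )
}

#' Planar-polarity summary metrics
#'
#' The two polarity parameters: mean N-G vector length and mean nucleus
#' elongation (major/minor axis ratio), with their SEM.
#'
#' @param cells tibble with `ng_length_um` and `nucleus_elongation` columns
#'   (as produced by [pair_nucleus_to_golgi()] or [quantify_polarity()]).
#' @return A one-row tibble: `n`, `mean_ng_length_um`, `sem_ng_length_um`,
#'   `mean_elongation`, `sem_elongation`.
#' @export
polarity_metrics <- function(cells) {
  if (nrow(cells) == 0) stop("no paired cells", call. = FALSE)
  n <- nrow(cells)
  tibble::tibble(
    n = n,
    mean_ng_length_um = mean(cells$ng_length_um),
    sem_ng_length_um = stats::sd(cells$ng_length_um) / sqrt(n),
    mean_elongation = mean(cells$nucleus_elongation),
    sem_elongation = stats::sd(cells$nucleus_elongation) / sqrt(n)
  )
}

#' End-to-end EC polarity quantification of one image
#'
#' Runs the full pipeline on a two-channel endothelium image: per-channel
#' Gaussian-background thresholding, despeckling, size-filtered object
#' identification, nucleus-to-Golgi pairing, angle-to-flow computation and
#' orientation classification.
#'
#' @param nucleus,golgi numeric matrices of the two channels (same
#'   dimensions).
#' @param pixel_size_um pixel edge length, µm.
#' @param flow_direction length-2 blood-flow direction vector in image
#'   coordinates.
#' @param k background threshold multiplier.
#' @param min_area_nucleus_um2,min_area_golgi_um2 size thresholds, µm².
#' @param one_to_one passed to [pair_nucleus_to_golgi()].
#' @return A list with `cells` (per-cell tibble: ids, N-G vector, angle,
#'   class, elongation), `nuclei`, `golgi` (object tables), `summary`
#'   (class frequencies) and `metrics` (polarity metrics); `summary` and
#'   `metrics` are `NULL` when no cell was paired.
#' @export
quantify_polarity <- function(nucleus, golgi,
                              pixel_size_um = wss_defaults()$pixel_size_um,
                              flow_direction = c(1, 0),
                              k = wss_defaults()$threshold_k,
                              min_area_nucleus_um2 = wss_defaults()$min_area_nucleus_um2,
                              min_area_golgi_um2 = wss_defaults()$min_area_golgi_um2,
                              one_to_one = FALSE) {
  if (!all(dim(nucleus) == dim(golgi))) {
    stop("channel dimensions differ", call. = FALSE)
  }
  masks <- lapply(list(nucleus = nucleus, golgi = golgi), function(ch) {
    despeckle(gaussian_background_threshold(ch, k = k))
  })
  nuc <- identify_objects(masks$nucleus, pixel_size_um, "nucleus",
                          min_area_um2 = min_area_nucleus_um2)
  gol <- identify_objects(masks$golgi, pixel_size_um, "golgi",
                          min_area_um2 = min_area_golgi_um2)
  cells <- pair_nucleus_to_golgi(nuc, gol, one_to_one = one_to_one)
  if (nrow(cells) > 0) {
    cells$angle_deg <- angle_to_flow(cells$dx_um, cells$dy_um, flow_direction)
    cells$orientation_class <- classify_orientation(cells$angle_deg)
  } else {
    cells$angle_deg <- numeric()
    cells$orientation_class <- factor(character(),
                                      levels = c("dromic", "lateral",
                                                 "antidromic"))
  }
  list(
    cells = cells, nuclei = nuc, golgi = gol,
    summary = if (nrow(cells)) orientation_summary(cells) else NULL,
    metrics = if (nrow(cells)) polarity_metrics(cells) else NULL
  )
}
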