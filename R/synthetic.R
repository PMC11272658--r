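# Ground-truthed synthetic data: hemodynamic cohorts drawn from the
# reference group means, and endothelium images with elliptical nuclei and
# Golgi blobs at controlled angles over Gaussian background noise.

.rtruncnorm_pos <- function(n, mean, sd, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- out <= 0 | out >= upper
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out <= 0 | out >= upper
  }
  out
}

#' Specify a synthetic hemodynamic cohort
#'
#' Defaults draw every quantity from the reference group means and SDs of
#' [carotid_reference_groups()] (truncated normal at zero; hematocrit also
#' truncated below one). Hematocrit, blood viscosity and heart rate are
#' per-animal; diameter and velocity are per animal x cardiac phase.
#'
#' @param n_per_group animals per sex group.
#' @param groups group-level parameter table in the layout of
#'   [carotid_reference_groups()].
#' @param viscosity_coupling if `TRUE`, draw each animal's total blood
#'   viscosity from the hematocrit-viscosity regression line plus Gaussian
#'   noise instead of its marginal distribution.
#' @param coupling_noise_sd_cP residual SD around the line, cP. The default
#'   0.43 cP makes the population R² of viscosity on hematocrit about 0.35
#'   given the reference hematocrit spread.
#' @param model [viscosity_model()] supplying the regression coefficients.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 8,
                        groups = carotid_reference_groups(),
                        viscosity_coupling = FALSE,
                        coupling_noise_sd_cP = 0.43,
                        model = viscosity_model(),
                        seed = 1L) {
  stopifnot(n_per_group >= 1)
  sds <- unlist(groups[grep("_sd", names(groups))])
  if (any(sds < 0)) stop("group SDs must be >= 0", call. = FALSE)
  structure(
    list(n_per_group = n_per_group, groups = groups,
         viscosity_coupling = viscosity_coupling,
         coupling_noise_sd_cP = coupling_noise_sd_cP,
         model = model, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic hemodynamic cohort
#'
#' @param spec a [cohort_spec()].
#' @return A list with `records` (tibble of per-animal x phase rows:
#'   `animal_id`, `sex`, `phase`, `diameter_mm`, `vmax_mm_s`, `hematocrit`,
#'   `eta_b_cP`, `heart_rate_bpm`, `eta_p_cP`), `groups` (per-sex pooled
#'   plasma viscosity), and `spec`. Bit-identical under a fixed seed.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_per_group = 4, seed = 7))
#' head(coh$records)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  g <- spec$groups
  recs <- lapply(unique(g$sex), function(sx) {
    gs <- g[g$sex == sx, ]
    n <- spec$n_per_group
    ht <- .rtruncnorm_pos(n, gs$hematocrit[1], gs$hematocrit_sd[1], upper = 1)
    eta_b <- if (spec$viscosity_coupling) {
      vapply(ht, function(h) {
        .rtruncnorm_pos(1,
          blood_viscosity_from_hematocrit(h, spec$model),
          spec$coupling_noise_sd_cP)
      }, numeric(1))
    } else {
      .rtruncnorm_pos(n, gs$eta_b_cP[1], gs$eta_b_sd_cP[1])
    }
    hr <- .rtruncnorm_pos(n, gs$heart_rate_bpm[1], gs$heart_rate_sd_bpm[1])
    phase_rows <- lapply(seq_len(nrow(gs)), function(i) {
      hemodynamic_records(
        animal_id = sprintf("%s_%02d", substr(sx, 1, 1), seq_len(n)),
        sex = sx, phase = gs$phase[i],
        diameter_mm = .rtruncnorm_pos(n, gs$diameter_mm[i],
                                      gs$diameter_sd_mm[i]),
        vmax_mm_s = .rtruncnorm_pos(n, gs$vmax_mm_s[i], gs$vmax_sd_mm_s[i]),
        hematocrit = ht, eta_b_cP = eta_b, heart_rate_bpm = hr
      )
    })
    out <- dplyr::bind_rows(phase_rows)
    out$eta_p_cP <- gs$eta_p_cP[1]
    out
  })
  records <- dplyr::bind_rows(recs)
  groups <- dplyr::distinct(g[, c("sex", "eta_p_cP")])
  list(records = records, groups = groups, spec = spec)
}

#' Specify a synthetic endothelium image
#'
#' Emulates the imaging geometry of the polarity assay: a square field
#' (default 160 x 160 µm at 78 nm pixels), elliptical nuclei with random
#' in-plane orientation, one Golgi blob per cell placed at the prescribed
#' N-G distance and class-controlled angle from the flow direction, over
#' Gaussian 8-bit background noise. Foreground intensity must exceed the
#' background mean by more than six background SDs so that detection
#' failures are pipeline defects, not ambiguity.
#'
#' @param image_size image side, pixels.
#' @param pixel_size_um pixel edge, µm.
#' @param n_cells cells per image.
#' @param class_fractions named fractions (`dromic`, `lateral`,
#'   `antidromic`) summing to 1.
#' @param class_exact if `TRUE` (default) class counts are deterministic
#'   (`round(n_cells * fractions)` adjusted to total `n_cells`); otherwise
#'   multinomial.
#' @param ng_length_mean_um,ng_length_sd_um N-G vector length distribution.
#' @param nucleus_major_mean_um,nucleus_major_sd_um,nucleus_minor_mean_um,nucleus_minor_sd_um
#'   nucleus full axis lengths, µm.
#' @param golgi_area_mean_um2,golgi_area_sd_um2 Golgi blob area, µm².
#' @param bg_mean,bg_sd Gaussian background noise parameters (8-bit scale).
#' @param fg_intensity,fg_sd foreground mean intensity and noise SD
#'   (8-bit scale).
#' @param flow_direction length-2 flow vector in image coordinates.
#' @param min_separation_um minimum distance between nucleus centroids
#'   (rejection sampling); must exceed twice the N-G length so that
#'   nearest-Golgi pairing is unambiguous.
#' @param max_retries placement attempts per cell before a packing error.
#' @param seed integer seed.
#' @return An object of class `image_spec`.
#' @export
image_spec <- function(image_size = 2051,
                       pixel_size_um = wss_defaults()$pixel_size_um,
                       n_cells = 50,
                       class_fractions = c(dromic = 0.2, lateral = 0.2,
                                           antidromic = 0.6),
                       class_exact = TRUE,
                       ng_length_mean_um = 5, ng_length_sd_um = 1,
                       nucleus_major_mean_um = 12, nucleus_major_sd_um = 1,
                       nucleus_minor_mean_um = 6, nucleus_minor_sd_um = 0.5,
                       golgi_area_mean_um2 = 4, golgi_area_sd_um2 = 1,
                       bg_mean = 20, bg_sd = 8, fg_intensity = 200,
                       fg_sd = 8,
                       flow_direction = c(1, 0),
                       min_separation_um = 14,
                       max_retries = 5000L,
                       seed = 1L) {
  stopifnot(image_size >= 8, n_cells >= 0, max_retries >= 1)
  .check_positive(pixel_size_um, "pixel_size_um")
  if (abs(sum(class_fractions) - 1) > 1e-8 || any(class_fractions < 0)) {
    stop("`class_fractions` must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (!setequal(names(class_fractions),
                c("dromic", "lateral", "antidromic"))) {
    stop("`class_fractions` must be named dromic/lateral/antidromic",
         call. = FALSE)
  }
  if (fg_intensity <= bg_mean + 6 * bg_sd) {
    stop("`fg_intensity` must exceed bg_mean + 6*bg_sd", call. = FALSE)
  }
  structure(
    list(image_size = as.integer(image_size),
         pixel_size_um = pixel_size_um, n_cells = as.integer(n_cells),
         class_fractions = class_fractions[c("dromic", "lateral",
                                             "antidromic")],
         class_exact = class_exact,
         ng_length_mean_um = ng_length_mean_um,
         ng_length_sd_um = ng_length_sd_um,
         nucleus_major_mean_um = nucleus_major_mean_um,
         nucleus_major_sd_um = nucleus_major_sd_um,
         nucleus_minor_mean_um = nucleus_minor_mean_um,
         nucleus_minor_sd_um = nucleus_minor_sd_um,
         golgi_area_mean_um2 = golgi_area_mean_um2,
         golgi_area_sd_um2 = golgi_area_sd_um2,
         bg_mean = bg_mean, bg_sd = bg_sd, fg_intensity = fg_intensity,
         fg_sd = fg_sd,
         flow_direction = flow_direction,
         min_separation_um = min_separation_um,
         max_retries = as.integer(max_retries), seed = as.integer(seed)),
    class = "image_spec"
  )
}

.fill_ellipse <- function(img, cx_um, cy_um, a_um, b_um, alpha, px,
                          value, value_sd = 0) {
  # cx, cy centroid; a, b semi-axes (µm); alpha major-axis angle (rad)
  nr <- nrow(img); nc <- ncol(img)
  r_um <- max(a_um, b_um)
  cmin <- max(1L, floor((cx_um - r_um) / px))
  cmax <- min(nc, ceiling((cx_um + r_um) / px) + 1L)
  rmin <- max(1L, floor((cy_um - r_um) / px))
  rmax <- min(nr, ceiling((cy_um + r_um) / px) + 1L)
  cols <- cmin:cmax; rows <- rmin:rmax
  x <- (cols - 0.5) * px - cx_um
  y <- (rows - 0.5) * px - cy_um
  X <- matrix(x, length(rows), length(cols), byrow = TRUE)
  Y <- matrix(y, length(rows), length(cols))
  u <- (X * cos(alpha) + Y * sin(alpha)) / a_um
  w <- (-X * sin(alpha) + Y * cos(alpha)) / b_um
  inside <- u^2 + w^2 <= 1
  sub <- img[rows, cols, drop = FALSE]
  val <- value + if (value_sd > 0) {
    stats::rnorm(sum(inside), 0, value_sd)
  } else {
    0
  }
  sub[inside] <- as.integer(pmin(255, pmax(0, round(val))))
  img[rows, cols] <- sub
  img
}

#' Generate a ground-truthed synthetic endothelium image
#'
#' @param spec an [image_spec()].
#' @return A list with `nucleus` and `golgi` (integer matrices, 8-bit
#'   range), `pixel_size_um`, `flow_direction`, `truth` (per-cell tibble:
#'   `cell_id`, `orientation_class`, `angle_deg`, `ng_length_um`, nucleus
#'   centroid/axes/elongation, Golgi centroid/area) and `spec`.
#'   Bit-identical under a fixed seed; infeasible packing raises an error.
#' @export
#' @examples
#' img <- generate_endothelium_image(image_spec(image_size = 400,
#'   n_cells = 3, seed = 2))
#' img$truth$orientation_class
generate_endothelium_image <- function(spec) {
  stopifnot(inherits(spec, "image_spec"))
  set.seed(spec$seed)
  px <- spec$pixel_size_um
  side_um <- spec$image_size * px
  n <- spec$n_cells

  noise_img <- function() {
    m <- matrix(stats::rnorm(spec$image_size^2, spec$bg_mean, spec$bg_sd),
                spec$image_size, spec$image_size)
    matrix(as.integer(pmin(255, pmax(0, round(m)))),
           spec$image_size, spec$image_size)
  }
  nucleus <- noise_img()
  golgi <- noise_img()

  if (n == 0) {
    return(list(nucleus = nucleus, golgi = golgi, pixel_size_um = px,
                flow_direction = spec$flow_direction,
                truth = tibble::tibble(), spec = spec))
  }

  # per-cell geometry
  major <- .rtruncnorm_pos(n, spec$nucleus_major_mean_um,
                           spec$nucleus_major_sd_um)
  minor <- .rtruncnorm_pos(n, spec$nucleus_minor_mean_um,
                           spec$nucleus_minor_sd_um)
  swap <- minor > major
  if (any(swap)) {
    tmp <- major[swap]; major[swap] <- minor[swap]; minor[swap] <- tmp
  }
  ng_len <- .rtruncnorm_pos(n, spec$ng_length_mean_um, spec$ng_length_sd_um)
  golgi_area <- .rtruncnorm_pos(n, spec$golgi_area_mean_um2,
                                spec$golgi_area_sd_um2)
  golgi_r <- sqrt(golgi_area / pi)

  classes <- names(spec$class_fractions)
  counts <- if (spec$class_exact) {
    ct <- round(n * spec$class_fractions)
    while (sum(ct) > n) ct[which.max(ct)] <- ct[which.max(ct)] - 1
    while (sum(ct) < n) ct[which.min(ct)] <- ct[which.min(ct)] + 1
    ct
  } else {
    stats::rmultinom(1, n, spec$class_fractions)[, 1]
  }
  cls <- sample(rep(classes, times = counts))
  lohi <- list(dromic = c(0, 60), lateral = c(60, 120),
               antidromic = c(120, 180))
  theta <- vapply(cls, function(cl) {
    stats::runif(1, lohi[[cl]][1], lohi[[cl]][2])
  }, numeric(1))

  flow_ang <- atan2(spec$flow_direction[2], spec$flow_direction[1])
  side_sign <- sample(c(-1, 1), n, replace = TRUE)
  phi <- flow_ang + side_sign * theta * pi / 180
  alpha <- stats::runif(n, 0, pi)

  margin <- max(major) / 2 + max(ng_len) + max(golgi_r) + 2 * px
  if (2 * margin >= side_um) stop("image too small for cell geometry",
                                  call. = FALSE)

  # sequential rejection placement: besides the base centroid separation,
  # enforce (i) non-touching nuclei (bounding circles), (ii) non-merging
  # Golgi blobs, (iii) pairing dominance: every foreign Golgi lies farther
  # from a nucleus than its own, so ground-truth pairing is unambiguous.
  cx <- numeric(n); cy <- numeric(n)
  gx <- numeric(n); gy <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(spec$max_retries)) {
      px_ <- stats::runif(1, margin, side_um - margin)
      py_ <- stats::runif(1, margin, side_um - margin)
      gx_ <- px_ + ng_len[i] * cos(phi[i])
      gy_ <- py_ + ng_len[i] * sin(phi[i])
      if (i > 1) {
        jj <- seq_len(i - 1)
        d_cc <- sqrt((cx[jj] - px_)^2 + (cy[jj] - py_)^2)
        d_gg <- sqrt((gx[jj] - gx_)^2 + (gy[jj] - gy_)^2)
        d_cg <- sqrt((cx[jj] - gx_)^2 + (cy[jj] - gy_)^2)  # others vs new golgi
        d_gc <- sqrt((gx[jj] - px_)^2 + (gy[jj] - py_)^2)  # new nucleus vs other golgi
        ok <- all(d_cc >= spec$min_separation_um) &&
          all(d_cc >= (major[jj] + major[i]) / 2 + 1) &&
          all(d_gg >= golgi_r[jj] + golgi_r[i] + 1) &&
          all(d_cg > ng_len[jj] + 0.5) &&
          all(d_gc > ng_len[i] + 0.5)
      } else {
        ok <- TRUE
      }
      if (ok) {
        cx[i] <- px_; cy[i] <- py_; gx[i] <- gx_; gy[i] <- gy_
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place ", n, " cells at min separation ",
           spec$min_separation_um, " µm: reduce density", call. = FALSE)
    }
  }

  for (i in seq_len(n)) {
    nucleus <- .fill_ellipse(nucleus, cx[i], cy[i], major[i] / 2,
                             minor[i] / 2, alpha[i], px,
                             spec$fg_intensity, spec$fg_sd)
    golgi <- .fill_ellipse(golgi, gx[i], gy[i], golgi_r[i], golgi_r[i], 0,
                           px, spec$fg_intensity, spec$fg_sd)
  }

  truth <- tibble::tibble(
    cell_id = seq_len(n),
    orientation_class = factor(cls, levels = classes),
    angle_deg = theta,
    ng_length_um = ng_len,
    nucleus_x_um = cx, nucleus_y_um = cy,
    nucleus_major_um = major, nucleus_minor_um = minor,
    nucleus_elongation = major / minor,
    nucleus_angle_rad = alpha,
    golgi_x_um = gx, golgi_y_um = gy,
    golgi_area_um2 = golgi_area
  )
  list(nucleus = nucleus, golgi = golgi, pixel_size_um = px,
       flow_direction = spec$flow_direction, truth = truth, spec = spec)
}
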