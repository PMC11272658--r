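# Tabular I/O and end-to-end drivers: cohort CSV in, tidy WSS tables and
# grouped summaries out.

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Read a cohort CSV of per-animal hemodynamic records
#'
#' Expected columns: `animal_id`, `sex`, `phase`, `diameter_mm`,
#' `vmax_mm_s`, `hematocrit`; optional `eta_b_cP`, `eta_p_cP`,
#' `heart_rate_bpm`.
#'
#' @param path CSV file path.
#' @return Validated records tibble.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE)
  .require_columns(df, c("animal_id", "sex", "phase", "diameter_mm",
                         "vmax_mm_s", "hematocrit"), "cohort CSV")
  rec <- hemodynamic_records(
    df$animal_id, df$sex, df$phase, df$diameter_mm, df$vmax_mm_s,
    df$hematocrit,
    eta_b_cP = if ("eta_b_cP" %in% names(df)) df$eta_b_cP else NA_real_,
    heart_rate_bpm = if ("heart_rate_bpm" %in% names(df)) {
      df$heart_rate_bpm
    } else {
      NA_real_
    }
  )
  if ("eta_p_cP" %in% names(df)) rec$eta_p_cP <- df$eta_p_cP
  rec
}

#' Compute WSS for a cohort under the selected methods
#'
#' Runs the chosen WSS methods over every record. The theoretical
#' Newtonian method uses each record's measured total blood viscosity; the
#' corrected Newtonian method is evaluated for the requested viscosity
#' variants (plasma, total blood, apparent = factor x plasma); the
#' plug/sheath method uses the group plasma viscosity and the record's
#' hematocrit.
#'
#' @param records records tibble (from [hemodynamic_records()],
#'   [read_cohort_csv()] or [generate_cohort()]), with an `eta_p_cP`
#'   column or a `groups` table supplying it per sex.
#' @param methods subset of `c("tN", "cN", "F")`.
#' @param cn_variants corrected-method viscosity variants, subset of
#'   `c("apparent", "blood", "plasma")`.
#' @param groups optional tibble with `sex` and `eta_p_cP`.
#' @param correction_factor apparent-viscosity multiplier.
#' @param vmax_vm_ratio,use_exact_coefficient passed to
#'   [wss_corrected_newtonian()].
#' @return Tidy tibble of WSS results with a `viscosity_variant` column.
#' @export
compute_wss <- function(records, methods = c("tN", "cN", "F"),
                        cn_variants = "apparent", groups = NULL,
                        correction_factor = wss_defaults()$correction_factor,
                        vmax_vm_ratio = wss_defaults()$vmax_vm_ratio,
                        use_exact_coefficient = FALSE) {
  methods <- match.arg(methods, c("tN", "cN", "F"), several.ok = TRUE)
  cn_variants <- match.arg(cn_variants, c("apparent", "blood", "plasma"),
                           several.ok = TRUE)
  if (!is.null(groups)) {
    .require_columns(groups, c("sex", "eta_p_cP"), "groups table")
    records$eta_p_cP <- groups$eta_p_cP[match(records$sex, groups$sex)]
  }
  needs_p <- "F" %in% methods || ("cN" %in% methods &&
                                    any(cn_variants != "blood"))
  if (needs_p) .require_columns(records, "eta_p_cP", "records")
  out <- list()
  if ("tN" %in% methods) {
    .require_columns(records, "eta_b_cP", "records")
    r <- wss_theoretical_newtonian(records)
    r$viscosity_variant <- "blood"
    out <- c(out, list(r))
  }
  if ("cN" %in% methods) {
    for (v in cn_variants) {
      eta <- switch(v,
        apparent = apparent_viscosity(records$eta_p_cP, correction_factor),
        blood = records$eta_b_cP,
        plasma = records$eta_p_cP
      )
      r <- wss_corrected_newtonian(records, eta_cP = eta,
                                   vmax_vm_ratio = vmax_vm_ratio,
                                   use_exact_coefficient = use_exact_coefficient)
      r$viscosity_variant <- v
      out <- c(out, list(r))
    }
  }
  if ("F" %in% methods) {
    r <- wss_fahraeus(records, eta_p_cP = records$eta_p_cP)
    r$viscosity_variant <- "plasma"
    out <- c(out, list(r))
  }
  dplyr::bind_rows(out)
}

#' Summarize WSS results per sex, phase, method and viscosity variant
#'
#' @param wss tidy WSS tibble from [compute_wss()].
#' @return Tibble with `sex`, `phase`, `method`, `viscosity_variant`, `n`,
#'   `mean_wss_Pa`, `sd_wss_Pa`.
#' @export
summarize_wss <- function(wss) {
  dplyr::summarise(
    dplyr::group_by(wss, .data$sex, .data$phase, .data$method,
                    .data$viscosity_variant),
    n = dplyr::n(),
    mean_wss_Pa = mean(.data$wss_Pa),
    sd_wss_Pa = stats::sd(.data$wss_Pa),
    .groups = "drop"
  )
}

#' Write a WSS summary as JSON
#'
#' @param summary tibble from [summarize_wss()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wss_summary_json <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' End-to-end WSS driver
#'
#' Reads a cohort CSV (and optional per-sex plasma-viscosity table),
#' computes WSS under the selected methods, and writes a tidy per-record
#' CSV and a grouped JSON summary.
#'
#' @param input_csv cohort CSV path.
#' @param out_dir output directory (created if needed).
#' @param groups_csv optional CSV with `sex`, `eta_p_cP`.
#' @inheritParams compute_wss
#' @return A list with `wss` and `summary` tibbles and the written paths.
#' @export
run_wss <- function(input_csv, out_dir = ".", groups_csv = NULL,
                    methods = c("tN", "cN", "F"),
                    cn_variants = "apparent") {
  records <- read_cohort_csv(input_csv)
  groups <- if (!is.null(groups_csv)) {
    readr::read_csv(groups_csv, show_col_types = FALSE)
  }
  wss <- compute_wss(records, methods = methods, cn_variants = cn_variants,
                     groups = groups)
  summ <- summarize_wss(wss)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wss_path <- file.path(out_dir, "wss_records.csv")
  summ_path <- file.path(out_dir, "wss_summary.json")
  readr::write_csv(wss, wss_path)
  write_wss_summary_json(summ, summ_path)
  list(wss = wss, summary = summ, paths = c(wss_path, summ_path))
}

#' Read a two-channel endothelium image from TIFF
#'
#' Accepts either one two-channel/two-page TIFF or two single-channel
#' TIFFs (nucleus first). Intensities are rescaled to the 0-255 range.
#'
#' @param nucleus_path TIFF path (nucleus channel, or both channels).
#' @param golgi_path optional TIFF path for the Golgi channel.
#' @return A list with `nucleus` and `golgi` matrices.
#' @export
read_endothelium_tiff <- function(nucleus_path, golgi_path = NULL) {
  read1 <- function(p) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
    img <- tryCatch(tiff::readTIFF(p, all = TRUE),
                    error = function(e) {
                      stop("not a readable TIFF: ", p, call. = FALSE)
                    })
    lapply(img, function(m) {
      if (length(dim(m)) == 3) {
        # planar RGB/multichannel page: split channels
        lapply(seq_len(dim(m)[3]), function(k) m[, , k] * 255)
      } else {
        list(m * 255)
      }
    })
  }
  chans <- unlist(read1(nucleus_path), recursive = FALSE)
  if (!is.null(golgi_path)) {
    chans <- c(chans[1], unlist(read1(golgi_path), recursive = FALSE)[1])
  }
  if (length(chans) < 2) {
    stop("need two channels (two pages/channels or two files)",
         call. = FALSE)
  }
  list(nucleus = chans[[1]], golgi = chans[[2]])
}

#' Write a synthetic endothelium image pair as TIFFs + ground truth CSV
#'
#' @param image list from [generate_endothelium_image()].
#' @param out_dir output directory.
#' @param prefix file-name prefix.
#' @return Written paths, invisibly.
#' @export
write_endothelium_tiff <- function(image, out_dir = ".",
                                   prefix = "endothelium") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  np <- file.path(out_dir, paste0(prefix, "_nucleus.tif"))
  gp <- file.path(out_dir, paste0(prefix, "_golgi.tif"))
  tp <- file.path(out_dir, paste0(prefix, "_truth.csv"))
  tiff::writeTIFF(image$nucleus / 255, np, bits.per.sample = 8)
  tiff::writeTIFF(image$golgi / 255, gp, bits.per.sample = 8)
  if (nrow(image$truth)) readr::write_csv(image$truth, tp)
  invisible(c(np, gp, tp))
}

#' End-to-end polarity driver over image files
#'
#' @param nucleus_paths,golgi_paths vectors of TIFF paths (paired by
#'   position).
#' @param pixel_size_um pixel edge, µm.
#' @param flow_direction length-2 flow vector.
#' @param out_dir optional output directory for the per-cell CSV and JSON
#'   summary.
#' @return A list with `cells` (pooled per-cell tibble with an `image`
#'   column), `summary` and `metrics`.
#' @export
run_polarity <- function(nucleus_paths, golgi_paths,
                         pixel_size_um = wss_defaults()$pixel_size_um,
                         flow_direction = c(1, 0), out_dir = NULL) {
  stopifnot(length(nucleus_paths) == length(golgi_paths))
  cells <- lapply(seq_along(nucleus_paths), function(i) {
    ch <- read_endothelium_tiff(nucleus_paths[i], golgi_paths[i])
    res <- quantify_polarity(ch$nucleus, ch$golgi,
                             pixel_size_um = pixel_size_um,
                             flow_direction = flow_direction)
    if (nrow(res$cells)) res$cells$image <- basename(nucleus_paths[i])
    res$cells
  })
  cells <- dplyr::bind_rows(cells)
  summ <- if (nrow(cells)) orientation_summary(cells) else NULL
  metr <- if (nrow(cells)) polarity_metrics(cells) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(cells, file.path(out_dir, "polarity_cells.csv"))
    jsonlite::write_json(
      list(summary = summ, metrics = metr),
      file.path(out_dir, "polarity_summary.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE
    )
  }
  list(cells = cells, summary = summ, metrics = metr)
}
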