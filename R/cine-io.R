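# Reading and writing cine cavity segmentations.
#
# A cine study holds one binary cavity mask per (slice, phase) as a 4-D
# logical array (x, y, slice, phase), slices ordered apex -> base, plus the
# geometry metadata needed downstream (pixel size, slice spacing, sector
# convention).

#' Construct a cine study
#'
#' @param subject_id subject identifier.
#' @param masks 4-D logical/numeric array `(x, y, slice, phase)`; nonzero
#'   pixels are cavity.
#' @param pixel_mm pixel size in mm.
#' @param slice_spacing_mm inter-slice spacing in mm.
#' @param slice_order apex-to-base ordering of the slice dimension (default
#'   already apex to base).
#' @param sector_labels circumferential sector names (default the six
#'   standard 60-degree sectors).
#' @param reference_angle_deg angle of the first sector's start boundary:
#'   0 = image "up", increasing clockwise in image coordinates.
#' @return object of class `cine_study`.
#' @export
new_cine_study <- function(subject_id, masks, pixel_mm, slice_spacing_mm,
                           slice_order = NULL,
                           sector_labels = DEFAULT_SECTORS,
                           reference_angle_deg = 0) {
  if (length(dim(masks)) != 4L)
    stop("masks must be a 4-D array (x, y, slice, phase)")
  masks <- masks != 0
  if (!is.null(slice_order)) masks <- masks[, , slice_order, , drop = FALSE]
  st <- structure(list(
    subject_id = subject_id, masks = masks, pixel_mm = pixel_mm,
    slice_spacing_mm = slice_spacing_mm,
    n_sectors = length(sector_labels), sector_labels = sector_labels,
    reference_angle_deg = reference_angle_deg), class = "cine_study")
  validate_cine_study(st)
  st
}

validate_cine_study <- function(st) {
  d <- dim(st$masks)
  counts <- apply(st$masks, c(3, 4), sum)
  if (any(counts == 0)) {
    bad <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty cavity mask at slice %d, phase %d", bad[1], bad[2]))
  }
  if (st$pixel_mm <= 0 || st$slice_spacing_mm <= 0)
    stop("pixel_mm and slice_spacing_mm must be positive")
  invisible(st)
}

#' @export
print.cine_study <- function(x, ...) {
  d <- dim(x$masks)
  cat(sprintf(
    "cine_study '%s': %dx%d px (%.3f mm), %d slices (%.2f mm apart), %d phases\n",
    x$subject_id, d[1], d[2], x$pixel_mm, d[3], x$slice_spacing_mm, d[4]))
  invisible(x)
}

#' Load a cine segmentation study from disk
#'
#' Supported containers: a 4-D NIfTI volume (`.nii`/`.nii.gz`; dimensions
#' x, y, slice, phase), a multi-page TIFF with a declared page layout, or a
#' contour CSV with columns `slice, phase, vertex_index, x_px, y_px`
#' describing one closed polygon per (slice, phase), rasterized at pixel
#' centers with the even-odd rule.
#'
#' @param path file to read.
#' @param pixel_mm,slice_spacing_mm geometry metadata (not stored in TIFF or
#'   CSV containers; for NIfTI the header pixdim is used when these are
#'   missing).
#' @param format `"auto"` (by extension), `"nifti"`, `"tiff"` or `"csv"`.
#' @param layout for TIFF: list with `n_slices`, `n_phases` and `order`
#'   (`"slice_major"`: all phases of slice 1 first, or `"phase_major"`).
#' @param matrix_px for CSV: output grid side length in pixels.
#' @param subject_id,sector_labels,reference_angle_deg see [new_cine_study()].
#' @return a `cine_study`.
#' @export
load_cine <- function(path, pixel_mm = NULL, slice_spacing_mm = NULL,
                      format = c("auto", "nifti", "tiff", "csv"),
                      layout = NULL, matrix_px = NULL,
                      subject_id = basename(path),
                      sector_labels = DEFAULT_SECTORS,
                      reference_angle_deg = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
      else if (grepl("\\.tiff?$", path)) "tiff"
      else if (grepl("\\.csv$", path)) "csv"
      else stop("cannot infer format from extension: ", path)
  }
  masks <- switch(format,
    nifti = {
      img <- RNifti::readNifti(path)
      arr <- as.array(img)
      if (length(dim(arr)) != 4L) stop("NIfTI volume must be 4-D")
      pd <- RNifti::pixdim(img)
      if (is.null(pixel_mm)) pixel_mm <- pd[1]
      if (is.null(slice_spacing_mm)) slice_spacing_mm <- pd[3]
      arr
    },
    tiff = {
      if (is.null(layout) || is.null(layout$n_slices) || is.null(layout$n_phases))
        stop("TIFF input needs layout = list(n_slices, n_phases, order)")
      pages <- tiff::readTIFF(path, all = TRUE)
      if (is.list(pages) == FALSE) pages <- list(pages)
      ns <- layout$n_slices; np <- layout$n_phases
      if (length(pages) != ns * np)
        stop(sprintf("TIFF has %d pages but layout declares %d slices x %d phases",
                     length(pages), ns, np))
      ord <- layout$order %||% "slice_major"
      as_page <- function(p) {
        if (length(dim(p)) == 3L) p <- p[, , 1]   # drop channel dim
        p
      }
      d <- dim(as_page(pages[[1]]))
      arr <- array(0, c(d[1], d[2], ns, np))
      k <- 1L
      if (ord == "slice_major") {
        for (s in seq_len(ns)) for (t in seq_len(np)) {
          arr[, , s, t] <- as_page(pages[[k]]); k <- k + 1L
        }
      } else {
        for (t in seq_len(np)) for (s in seq_len(ns)) {
          arr[, , s, t] <- as_page(pages[[k]]); k <- k + 1L
        }
      }
      arr > 0.5
    },
    csv = {
      if (is.null(matrix_px)) stop("CSV input needs matrix_px")
      df <- utils::read.csv(path)
      need <- c("slice", "phase", "vertex_index", "x_px", "y_px")
      if (!all(need %in% names(df)))
        stop("contour CSV needs columns: ", paste(need, collapse = ", "))
      ns <- max(df$slice); np <- max(df$phase)
      arr <- array(FALSE, c(matrix_px, matrix_px, ns, np))
      for (s in seq_len(ns)) for (t in seq_len(np)) {
        sub <- df[df$slice == s & df$phase == t, , drop = FALSE]
        if (!nrow(sub)) stop(sprintf("no contour for slice %d, phase %d", s, t))
        sub <- sub[order(sub$vertex_index), ]
        arr[, , s, t] <- rasterize_polygon(cbind(sub$x_px, sub$y_px),
                                           matrix_px, matrix_px)
      }
      arr
    })
  if (is.null(pixel_mm) || is.null(slice_spacing_mm))
    stop("pixel_mm and slice_spacing_mm are required for this container")
  new_cine_study(subject_id, masks, pixel_mm, slice_spacing_mm,
                 sector_labels = sector_labels,
                 reference_angle_deg = reference_angle_deg)
}

#' Write a cine study to disk
#'
#' NIfTI output stores the masks as a 4-D volume with pixdim carrying the
#' pixel size and slice spacing; TIFF output writes one page per
#' (slice, phase) in slice-major order. A JSON sidecar with the geometry
#' metadata (and the phantom ground truth, when present) is written next to
#' the image when `sidecar = TRUE`.
#'
#' @param study a `cine_study`.
#' @param path output file (`.nii.gz`, `.nii` or `.tif`/`.tiff`).
#' @param sidecar write `<path>.json` with geometry/ground-truth metadata.
#' @return `path`, invisibly.
#' @export
write_cine <- function(study, path, sidecar = TRUE) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(array(as.numeric(study$masks), dim(study$masks)))
    RNifti::pixdim(img) <- c(study$pixel_mm, study$pixel_mm,
                             study$slice_spacing_mm, 1)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.tiff?$", path)) {
    d <- dim(study$masks)
    pages <- vector("list", d[3] * d[4])
    k <- 1L
    for (s in seq_len(d[3])) for (t in seq_len(d[4])) {
      pages[[k]] <- matrix(as.numeric(study$masks[, , s, t]), d[1], d[2])
      k <- k + 1L
    }
    tiff::writeTIFF(pages, path)
  } else stop("unsupported output extension: ", path)
  if (sidecar) {
    meta <- list(subject_id = study$subject_id, pixel_mm = study$pixel_mm,
                 slice_spacing_mm = study$slice_spacing_mm,
                 sector_labels = study$sector_labels,
                 reference_angle_deg = study$reference_angle_deg)
    if (!is.null(study$ground_truth)) {
      gt <- study$ground_truth
      meta$ground_truth <- list(rfac_pct = gt$rfac_pct,
                                ed_phase = gt$ed_phase,
                                es_phase = gt$es_phase)
    }
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Write a sector-area table as tidy CSV
#' @param table a `sector_area_table` (see [sector_areas()]).
#' @param path output CSV path.
#' @export
write_sector_areas <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a sector-area table written by [write_sector_areas()]
#' @param path CSV path.
#' @return a `sector_area_table`.
#' @export
read_sector_areas <- function(path) {
  df <- utils::read.csv(path)
  need <- c("subject", "slice", "phase", "sector", "area_mm2")
  if (!all(need %in% names(df)))
    stop("sector-area CSV needs columns: ", paste(need, collapse = ", "))
  as_sector_area_table(df)
}
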