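# Sector decomposition of the cavity about the end-diastolic centroid.
#
# Every cavity pixel is assigned, by the polar angle of its center about the
# slice centroid, to exactly one of six 60-degree wedges (half-open angular
# intervals), so sector areas sum to the total cavity area exactly.

#' Pixel-area-weighted centroid of a cavity mask
#'
#' @param study a `cine_study`.
#' @param slice slice index.
#' @param phase phase index (by default the global end-diastolic phase,
#'   i.e. the phase of maximal summed cavity area across slices).
#' @return numeric `(x, y)` in 0-based pixel-center coordinates.
#' @export
cavity_centroid <- function(study, slice, phase = NULL) {
  if (is.null(phase)) phase <- ed_phase_of(study)
  m <- study$masks[, , slice, phase]
  idx <- which(m, arr.ind = TRUE)
  if (!nrow(idx))
    stop(sprintf("empty cavity mask at slice %d, phase %d", slice, phase))
  c(x = mean(idx[, 1]) - 1, y = mean(idx[, 2]) - 1)
}

# ED phase from the masks alone: maximal summed cavity area, earlier phase
# on ties.
ed_phase_of <- function(study) {
  totals <- apply(study$masks, 4, sum)
  which.max(totals)
}

#' Per-sector cavity areas for every slice and phase
#'
#' Divides each slice's cavity into `n_sectors` equal angular wedges about
#' the slice's end-diastolic centroid (held fixed across phases by default)
#' and tabulates the cavity area falling in each wedge. Angles follow the
#' image convention: 0 at image "up", increasing clockwise, offset by the
#' study's `reference_angle_deg`; wedge `j` is the half-open interval
#' `[ref + (j-1)*w, ref + j*w)` with `w = 360 / n_sectors`.
#'
#' @param study a `cine_study`.
#' @param centroid `"ed"` (fixed at the end-diastolic frame, default) or
#'   `"per_phase"` (recomputed every phase).
#' @return a `sector_area_table`: data frame with columns
#'   `subject, slice, phase, sector, area_mm2` and attributes `total_area_mm2`
#'   (slice x phase matrix), `centroids` (slice x 2), `sector_labels`,
#'   `pixel_mm`, `slice_spacing_mm`.
#' @export
sector_areas <- function(study, centroid = c("ed", "per_phase")) {
  centroid <- match.arg(centroid)
  d <- dim(study$masks)
  ns <- study$n_sectors
  w <- 360 / ns
  edp <- ed_phase_of(study)
  px2 <- study$pixel_mm^2
  labels <- study$sector_labels
  total <- matrix(0, d[3], d[4])
  cents <- matrix(NA_real_, d[3], 2, dimnames = list(NULL, c("x", "y")))
  rows <- vector("list", d[3] * d[4])
  k <- 1L
  for (s in seq_len(d[3])) {
    ctr_ed <- cavity_centroid(study, s, edp)
    cents[s, ] <- ctr_ed
    for (t in seq_len(d[4])) {
      ctr <- if (centroid == "ed") ctr_ed else cavity_centroid(study, s, t)
      idx <- which(study$masks[, , s, t], arr.ind = TRUE)
      th <- image_angle_deg(idx[, 1] - 1 - ctr[1], idx[, 2] - 1 - ctr[2])
      rel <- (th - study$reference_angle_deg) %% 360
      sec <- pmin(floor(rel / w) + 1L, ns)
      cnt <- tabulate(sec, nbins = ns)
      total[s, t] <- nrow(idx) * px2
      rows[[k]] <- data.frame(subject = study$subject_id, slice = s,
                              phase = t, sector = labels,
                              area_mm2 = cnt * px2)
      k <- k + 1L
    }
  }
  df <- do.call(rbind, rows)
  as_sector_area_table(df, total_area_mm2 = total, centroids = cents,
                       sector_labels = labels, pixel_mm = study$pixel_mm,
                       slice_spacing_mm = study$slice_spacing_mm)
}

as_sector_area_table <- function(df, total_area_mm2 = NULL, centroids = NULL,
                                 sector_labels = NULL, pixel_mm = NULL,
                                 slice_spacing_mm = NULL) {
  if (is.null(sector_labels)) sector_labels <- unique(df$sector)
  if (is.null(total_area_mm2)) {
    ns <- max(df$slice); np <- max(df$phase)
    total_area_mm2 <- matrix(0, ns, np)
    agg <- stats::aggregate(area_mm2 ~ slice + phase, df, sum)
    total_area_mm2[cbind(agg$slice, agg$phase)] <- agg$area_mm2
  }
  structure(df, class = c("sector_area_table", "data.frame"),
            total_area_mm2 = total_area_mm2, centroids = centroids,
            sector_labels = sector_labels, pixel_mm = pixel_mm,
            slice_spacing_mm = slice_spacing_mm)
}

#' Sector areas as a slice x phase x sector array
#' @param table a `sector_area_table`.
#' @return numeric array with dimnames on the sector axis.
#' @export
sector_area_array <- function(table) {
  labels <- attr(table, "sector_labels")
  ns <- max(table$slice); np <- max(table$phase)
  arr <- array(NA_real_, c(ns, np, length(labels)),
               dimnames = list(NULL, NULL, labels))
  arr[cbind(table$slice, table$phase, match(table$sector, labels))] <-
    table$area_mm2
  arr
}
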