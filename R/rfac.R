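# Regional fractional area change: phase detection, per-cell RFAC,
# 10-slice spline resampling, mid-apical summaries, global volumetrics.
#
# RFAC per (slice, sector) = 100 * (EDA - ESA) / EDA, where EDA/ESA are the
# sector cavity areas at the ventricle's end-diastolic / end-systolic phases
# (chosen globally from total cavity volume). Ejection fraction computed
# from stacked-disk volumes equals the EDA-weighted mean of per-cell RFAC
# when slice spacing is uniform.

#' Detect the end-diastolic and end-systolic phases
#'
#' ED is the phase maximizing and ES the phase minimizing the summed cavity
#' area over all slices; ties go to the earlier phase index.
#'
#' @param table a `sector_area_table`.
#' @return list with `ed_phase`, `es_phase` and `degenerate` (TRUE, with a
#'   warning, when all phases have identical total area; both phases are then
#'   the first phase).
#' @export
detect_ed_es <- function(table) {
  total <- attr(table, "total_area_mm2")
  per_phase <- colSums(total)
  if (length(per_phase) < 2L) stop("need at least 2 phases")
  if (diff(range(per_phase)) == 0) {
    warning("total cavity area identical across phases; ED/ES undefined")
    return(list(ed_phase = 1L, es_phase = 1L, degenerate = TRUE))
  }
  list(ed_phase = which.max(per_phase), es_phase = which.min(per_phase),
       degenerate = FALSE)
}

#' Compute RFAC per (slice, sector)
#'
#' @param table a `sector_area_table`.
#' @param ed_phase,es_phase phase indices; detected via [detect_ed_es()]
#'   when omitted.
#' @return an `rfac_map`: list with `rfac_pct` (slice x sector matrix, `NA`
#'   where the end-diastolic area is zero), `eda_mm2`, `esa_mm2`,
#'   `slice_pos` (normalized apex->base positions in `[0, 1]`), `resampled`
#'   flag, `ed_phase`, `es_phase`, `sector_labels`, `slice_spacing_mm`.
#' @export
compute_rfac <- function(table, ed_phase = NULL, es_phase = NULL) {
  if (is.null(ed_phase) || is.null(es_phase)) {
    ph <- detect_ed_es(table)
    ed_phase <- ed_phase %||% ph$ed_phase
    es_phase <- es_phase %||% ph$es_phase
  }
  arr <- sector_area_array(table)
  eda <- arr[, ed_phase, , drop = FALSE][, 1, , drop = TRUE]
  esa <- arr[, es_phase, , drop = FALSE][, 1, , drop = TRUE]
  labels <- attr(table, "sector_labels")
  if (is.null(dim(eda))) {  # single slice
    eda <- matrix(eda, 1, dimnames = list(NULL, labels))
    esa <- matrix(esa, 1, dimnames = list(NULL, labels))
  }
  rfac <- 100 * (eda - esa) / eda
  zero <- !is.na(eda) & eda == 0
  if (any(zero)) {
    warning(sprintf("%d cell(s) with zero end-diastolic area marked missing",
                    sum(zero)))
    rfac[zero] <- NA_real_
  }
  n_slices <- nrow(rfac)
  new_rfac_map(rfac_pct = rfac, eda_mm2 = eda, esa_mm2 = esa,
               slice_pos = if (n_slices > 1)
                 seq(0, 1, length.out = n_slices) else 0.5,
               resampled = FALSE, ed_phase = ed_phase, es_phase = es_phase,
               sector_labels = labels,
               slice_spacing_mm = attr(table, "slice_spacing_mm"))
}

new_rfac_map <- function(rfac_pct, slice_pos, resampled, ed_phase, es_phase,
                         sector_labels, eda_mm2 = NULL, esa_mm2 = NULL,
                         slice_spacing_mm = NULL) {
  structure(list(rfac_pct = rfac_pct, eda_mm2 = eda_mm2, esa_mm2 = esa_mm2,
                 slice_pos = slice_pos, resampled = resampled,
                 ed_phase = ed_phase, es_phase = es_phase,
                 sector_labels = sector_labels,
                 slice_spacing_mm = slice_spacing_mm),
            class = "rfac_map")
}

#' @export
print.rfac_map <- function(x, ...) {
  cat(sprintf("rfac_map: %d slices x %d sectors%s (ED phase %d, ES phase %d)\n",
              nrow(x$rfac_pct), ncol(x$rfac_pct),
              if (x$resampled) " [resampled]" else "", x$ed_phase, x$es_phase))
  print(round(x$rfac_pct, 1))
  invisible(x)
}

#' Resample an RFAC map to a common slice grid by cubic splines
#'
#' Per sector, an interpolating cubic spline through `(slice_pos, rfac)` is
#' evaluated at `n_out` equally spaced positions spanning `[0, 1]`. Sectors
#' with fewer than 4 non-missing slices fall back to linear interpolation
#' (with a warning); all-missing sectors stay missing.
#'
#' @param map an `rfac_map` on the original slice grid.
#' @param n_out number of output slices (default 10).
#' @param method spline end condition: `"notaknot"` (default) or
#'   `"natural"`; see [cubic_spline()].
#' @return a resampled `rfac_map`.
#' @export
resample_slices <- function(map, n_out = 10L, method = c("notaknot", "natural")) {
  method <- match.arg(method)
  if (map$resampled) return(map)
  pos_out <- seq(0, 1, length.out = n_out)
  rf <- map$rfac_pct
  out <- matrix(NA_real_, n_out, ncol(rf), dimnames = list(NULL, colnames(rf)))
  for (j in seq_len(ncol(rf))) {
    ok <- !is.na(rf[, j])
    if (!any(ok)) next
    x <- map$slice_pos[ok]; y <- rf[ok, j]
    if (sum(ok) < 4L) {
      warning(sprintf(
        "sector '%s': %d usable slice(s); linear interpolation used",
        colnames(rf)[j], sum(ok)))
      out[, j] <- if (sum(ok) == 1L) rep(y, n_out)
        else stats::approx(x, y, xout = pos_out, rule = 2)$y
    } else {
      out[, j] <- cubic_spline(x, y, pos_out, method = method)
    }
  }
  new_rfac_map(rfac_pct = out, slice_pos = pos_out, resampled = TRUE,
               ed_phase = map$ed_phase, es_phase = map$es_phase,
               sector_labels = map$sector_labels,
               slice_spacing_mm = map$slice_spacing_mm)
}

#' Mid-apical remote-wall summary indices
#'
#' On the resampled 10-slice grid, the apex slice (slice 1, unreliable from
#' apex motion) and the three basal slices (8-10) are excluded; iRFAC and
#' pRFAC are the means of the inferior and posterior sectors over slices
#' 2-7 and ipRFAC is their mean.
#'
#' @param map a resampled `rfac_map` (10 slices by default).
#' @param window slice indices averaged (1-based on the resampled grid).
#' @return list with `irfac_pct`, `prfac_pct`, `iprfac_pct`.
#' @export
regional_summary <- function(map, window = 2:7) {
  if (!map$resampled)
    stop("regional_summary expects a resampled map; see resample_slices()")
  rf <- map$rfac_pct
  need <- c("inferior", "posterior")
  if (!all(need %in% colnames(rf)))
    stop("map lacks inferior/posterior sectors")
  win <- rf[window, need, drop = FALSE]
  if (anyNA(win))
    warning("missing cells inside the mid-apical window; mean over available")
  irfac <- mean(win[, "inferior"], na.rm = TRUE)
  prfac <- mean(win[, "posterior"], na.rm = TRUE)
  list(irfac_pct = irfac, prfac_pct = prfac,
       iprfac_pct = (irfac + prfac) / 2)
}

#' Global chamber volumes and ejection fraction
#'
#' Stacked-disk volumetrics: EDV (ESV) is the sum over slices of the total
#' cavity area at the end-diastolic (end-systolic) phase times the slice
#' spacing; SV = EDV - ESV and EF = 100 * SV / EDV. With uniform spacing EF
#' equals the EDA-weighted mean of per-cell RFAC on the original grid.
#'
#' @param table a `sector_area_table`.
#' @param ed_phase,es_phase phase indices; detected when omitted.
#' @return list with `edv_ul`, `esv_ul`, `sv_ul`, `ef_pct`.
#' @export
global_function <- function(table, ed_phase = NULL, es_phase = NULL) {
  if (is.null(ed_phase) || is.null(es_phase)) {
    ph <- detect_ed_es(table)
    ed_phase <- ed_phase %||% ph$ed_phase
    es_phase <- es_phase %||% ph$es_phase
  }
  spacing <- attr(table, "slice_spacing_mm")
  if (is.null(spacing) || spacing <= 0) stop("slice_spacing_mm must be > 0")
  total <- attr(table, "total_area_mm2")
  edv <- sum(total[, ed_phase]) * spacing   # mm^3 == ul
  esv <- sum(total[, es_phase]) * spacing
  if (edv == 0) stop("end-diastolic volume is zero")
  list(edv_ul = edv, esv_ul = esv, sv_ul = edv - esv,
       ef_pct = 100 * (edv - esv) / edv)
}

#' EDA-weighted mean RFAC (the regional decomposition of EF)
#'
#' @param map an un-resampled `rfac_map` carrying `eda_mm2`.
#' @return weighted mean of `rfac_pct` with end-diastolic-area weights.
#' @export
weighted_mean_rfac <- function(map) {
  if (is.null(map$eda_mm2)) stop("map lacks end-diastolic areas")
  ok <- !is.na(map$rfac_pct)
  sum(map$eda_mm2[ok] * map$rfac_pct[ok]) / sum(map$eda_mm2[ok])
}

#' Write an RFAC map as tidy CSV
#' @param map an `rfac_map`.
#' @param path output path.
#' @param subject subject identifier column value.
#' @export
write_rfac_map <- function(map, path, subject = "subject") {
  df <- data.frame(subject = subject,
                   slice = rep(seq_len(nrow(map$rfac_pct)),
                               ncol(map$rfac_pct)),
                   sector = rep(colnames(map$rfac_pct),
                                each = nrow(map$rfac_pct)),
                   slice_pos = rep(map$slice_pos, ncol(map$rfac_pct)),
                   rfac_pct = as.vector(map$rfac_pct))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
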