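# Shared fixture builders: everything is generated in code at test time.

# cine study containing a single centered disk per (slice, phase)
disk_study <- function(radius_px = 10, matrix_px = 32, n_slices = 1,
                       n_phases = 2, shift = c(0, 0), pixel_mm = 0.1,
                       reference_angle_deg = 0) {
  ctr <- (matrix_px - 1) / 2
  px <- seq_len(matrix_px) - 1
  dx <- outer(px - ctr - shift[1], rep(1, matrix_px))
  dy <- outer(rep(1, matrix_px), px - ctr - shift[2])
  disk <- sqrt(dx^2 + dy^2) <= radius_px
  masks <- array(disk, c(matrix_px, matrix_px, n_slices, n_phases))
  new_cine_study("disk", masks, pixel_mm = pixel_mm, slice_spacing_mm = 1,
                 reference_angle_deg = reference_angle_deg)
}

# sector-area table built directly from a slice x phase x sector array
table_from_array <- function(arr, spacing = 1,
                             labels = dimnames(arr)[[3]]) {
  df <- expand.grid(slice = seq_len(dim(arr)[1]),
                    phase = seq_len(dim(arr)[2]),
                    sector = labels, stringsAsFactors = FALSE)
  df$subject <- "toy"
  df$area_mm2 <- arr[cbind(df$slice, df$phase,
                           match(df$sector, labels))]
  df <- df[, c("subject", "slice", "phase", "sector", "area_mm2")]
  rfackit:::as_sector_area_table(df, sector_labels = labels,
                                 slice_spacing_mm = spacing)
}

SECTORS6 <- c("anterior", "antero-septal", "septal",
              "inferior", "posterior", "lateral")

# resampled rfac_map with prescribed constant sector values
flat_map <- function(values_by_sector, n_slices = 10) {
  m <- matrix(rep(values_by_sector, each = n_slices), n_slices,
              length(values_by_sector),
              dimnames = list(NULL, names(values_by_sector)))
  rfackit:::new_rfac_map(rfac_pct = m,
                         slice_pos = seq(0, 1, length.out = n_slices),
                         resampled = TRUE, ed_phase = 1, es_phase = 2,
                         sector_labels = names(values_by_sector))
}
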