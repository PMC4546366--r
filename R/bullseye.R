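# Bull's-eye polar map of regional function.
#
# Apex at the center, consecutive slices as rings outward to the base, six
# 60-degree wedges in the circumferential sector order. Red tones mark low
# and green tones high RFAC over a fixed color range so maps of different
# groups are comparable; per-cell p-values are annotated with the display
# marks "." (0.05 < p < 0.1), "*" (p < 0.05), "**" (p < 0.01).

#' Construct a bull's-eye grid
#'
#' @param mean_rfac rings x 6 matrix of values, ring 1 = apex; column names
#'   are taken as sector labels when present.
#' @param p_value optional matrix of the same shape with per-cell p-values.
#' @param sector_labels sector names (defaults to `colnames(mean_rfac)` or
#'   the standard six).
#' @param vmin,vmax color scale bounds (percent RFAC).
#' @return object of class `bullseye_grid`.
#' @export
bullseye_grid <- function(mean_rfac, p_value = NULL,
                          sector_labels = NULL, vmin = 0, vmax = 100) {
  mean_rfac <- as.matrix(mean_rfac)
  if (is.null(sector_labels))
    sector_labels <- colnames(mean_rfac) %||% DEFAULT_SECTORS
  if (ncol(mean_rfac) != length(sector_labels))
    stop("mean_rfac must have one column per sector")
  if (!is.null(p_value)) {
    p_value <- as.matrix(p_value)
    if (!all(dim(p_value) == dim(mean_rfac)))
      stop("p_value must match mean_rfac in shape")
  }
  if (!is.finite(vmin) || !is.finite(vmax) || vmax <= vmin)
    stop("color bounds must be finite with vmax > vmin")
  structure(list(mean_rfac = mean_rfac, p_value = p_value,
                 sector_labels = sector_labels, vmin = vmin, vmax = vmax),
            class = "bullseye_grid")
}

#' Red-to-green color for values on a fixed scale
#' @param x values.
#' @param vmin,vmax scale bounds; values are clamped.
#' @return vector of hex colors.
#' @export
bullseye_palette <- function(x, vmin = 0, vmax = 100) {
  ramp <- grDevices::colorRamp(
    c("#a50026", "#d73027", "#f46d43", "#fdae61", "#fee08b",
      "#d9ef8b", "#a6d96a", "#66bd63", "#1a9850", "#006837"))
  u <- pmin(pmax((x - vmin) / (vmax - vmin), 0), 1)
  cols <- rep(NA_character_, length(x))
  ok <- is.finite(u)
  if (any(ok))
    cols[ok] <- grDevices::rgb(ramp(u[ok]), maxColorValue = 255)
  cols
}

significance_mark <- function(p) {
  if (!is.finite(p)) "" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else if (p < 0.1) "•" else ""
}

#' Render a bull's-eye polar map to PNG or SVG
#'
#' @param grid a [bullseye_grid()].
#' @param path output file; extension selects the device (`.png` or `.svg`).
#' @param reference_angle_deg angular placement of the first sector's start
#'   boundary, mirroring the geometry convention (0 = up, clockwise).
#' @param apex_center if `TRUE` (default) ring 1 is drawn at the center;
#'   `FALSE` flips the ring order radially.
#' @param title plot title.
#' @param width,height device size in pixels (PNG) or inches (SVG).
#' @return `path`, invisibly.
#' @export
render_bullseye <- function(grid, path, reference_angle_deg = 0,
                            apex_center = TRUE, title = NULL,
                            width = 640, height = 640) {
  stopifnot(inherits(grid, "bullseye_grid"))
  if (grepl("\\.png$", path)) {
    if (capabilities("cairo")) {
      grDevices::png(path, width = width, height = height, type = "cairo")
    } else {
      grDevices::png(path, width = width, height = height)
    }
  } else if (grepl("\\.svg$", path)) {
    grDevices::svg(path, width = width / 96, height = height / 96)
  } else stop("unsupported output extension: ", path)
  on.exit(grDevices::dev.off())

  vals <- grid$mean_rfac
  n_ring <- nrow(vals); n_sec <- ncol(vals)
  wdeg <- 360 / n_sec
  op <- graphics::par(mar = c(1, 1, if (is.null(title)) 1 else 3, 6),
                      xaxs = "i", yaxs = "i")
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot.new()
  graphics::plot.window(xlim = c(-1.25, 1.55), ylim = c(-1.25, 1.25),
                        asp = 1)
  if (!is.null(title)) graphics::title(main = title)

  # image convention angle -> plot angle (plot y is up): phi = 90 - theta
  arc <- function(theta_deg) {
    phi <- (90 - theta_deg) * pi / 180
    cbind(cos(phi), sin(phi))
  }
  for (ri in seq_len(n_ring)) {
    ring <- if (apex_center) ri else n_ring - ri + 1L
    r0 <- (ring - 1) / n_ring; r1 <- ring / n_ring
    for (j in seq_len(n_sec)) {
      a0 <- reference_angle_deg + (j - 1) * wdeg
      th <- seq(a0, a0 + wdeg, length.out = 25)
      poly <- rbind(r0 * arc(th), r1 * arc(rev(th)))
      v <- vals[ri, j]
      if (is.finite(v)) {
        graphics::polygon(poly, col = bullseye_palette(v, grid$vmin, grid$vmax),
                          border = "grey30", lwd = 0.5)
      } else {
        graphics::polygon(poly, col = "white", border = "grey30", lwd = 0.5)
        graphics::polygon(poly, density = 12, angle = 45, col = "grey40",
                          border = NA)
      }
      if (!is.null(grid$p_value)) {
        mk <- significance_mark(grid$p_value[ri, j])
        if (nzchar(mk)) {
          ctr <- (r0 + r1) / 2 * arc(a0 + wdeg / 2)
          graphics::text(ctr[1], ctr[2], mk, cex = 1.1, font = 2)
        }
      }
    }
  }
  # sector labels around the rim
  for (j in seq_len(n_sec)) {
    pos <- 1.12 * arc(reference_angle_deg + (j - 0.5) * wdeg)
    graphics::text(pos[1], pos[2], grid$sector_labels[j], cex = 0.85)
  }
  # color bar legend
  nleg <- 50
  ly <- seq(-0.9, 0.9, length.out = nleg + 1)
  lv <- seq(grid$vmin, grid$vmax, length.out = nleg)
  graphics::rect(1.3, ly[-length(ly)], 1.4, ly[-1],
                 col = bullseye_palette(lv, grid$vmin, grid$vmax),
                 border = NA)
  graphics::rect(1.3, -0.9, 1.4, 0.9, border = "grey30")
  at <- pretty(c(grid$vmin, grid$vmax), 5)
  at <- at[at >= grid$vmin & at <= grid$vmax]
  aty <- -0.9 + 1.8 * (at - grid$vmin) / (grid$vmax - grid$vmin)
  graphics::text(1.46, aty, at, cex = 0.75, adj = 0)
  graphics::text(1.35, 1.05, "RFAC (%)", cex = 0.8)
  invisible(path)
}

#' Group-mean bull's-eye grid from per-subject resampled maps
#'
#' @param maps list of resampled `rfac_map` objects (same grid).
#' @param p_value optional per-cell p-value matrix (e.g. from
#'   [sectorwise_tests()]).
#' @param vmin,vmax color bounds.
#' @return a `bullseye_grid` with the cellwise mean across subjects.
#' @export
bullseye_from_maps <- function(maps, p_value = NULL, vmin = 0, vmax = 100) {
  arr <- simplify2array(lapply(maps, function(m) m$rfac_pct))
  mean_rfac <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  colnames(mean_rfac) <- maps[[1]]$sector_labels
  bullseye_grid(mean_rfac, p_value = p_value, vmin = vmin, vmax = vmax)
}
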