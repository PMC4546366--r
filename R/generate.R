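# Synthetic cohort, atrial-trace and expression generators.
#
# The cohort emulates the study design: 12 sham, 12 infarcted untreated
# (MI) and 12 infarcted treated (MI+Val) mice followed at baseline, 24 h,
# 1 and 4 weeks. Infarction depresses the contraction amplitude of the
# anterior / antero-septal / lateral territory from apex to mid-ventricle,
# with milder remote-wall (inferior / posterior) hypokinesis that the
# treated group partially escapes; amplitudes per group and timepoint are
# back-solved from target regional RFAC levels via c = 1 - sqrt(1 - RFAC/100).

TIMEPOINT_DAYS <- c(baseline = 0, "24h" = 1, "1w" = 7, "4w" = 28)

# target remote-wall (inferior/posterior mid-apical) and infarct-territory
# RFAC (%) per group and timepoint
default_rfac_targets <- function() {
  list(
    sham       = list(remote = c(baseline = 72, "24h" = 74, "1w" = 75, "4w" = 77),
                      infarct = c(baseline = 72, "24h" = 74, "1w" = 75, "4w" = 77)),
    MI         = list(remote = c(baseline = 72, "24h" = 28, "1w" = 20, "4w" = 20),
                      infarct = c(baseline = 72, "24h" = 6, "1w" = 4, "4w" = 3)),
    "MI+Val"   = list(remote = c(baseline = 72, "24h" = 35, "1w" = 32, "4w" = 34),
                      infarct = c(baseline = 72, "24h" = 6, "1w" = 5, "4w" = 5)))
}

# target end-diastolic volume (ul) per group and timepoint: infarcted
# ventricles dilate over the follow-up, treated ones less so
default_edv_targets <- function() {
  list(sham     = c(baseline = 42, "24h" = 38, "1w" = 41, "4w" = 47),
       MI       = c(baseline = 42, "24h" = 58, "1w" = 96, "4w" = 117),
       "MI+Val" = c(baseline = 42, "24h" = 53, "1w" = 80, "4w" = 90))
}

# target atrial indices per group and timepoint:
# (LA Vmin ul, LA Vmax ul, LAA length mm, LAA duct FS %)
default_atrial_targets <- function() {
  list(
    sham = list(vmin = c(baseline = 2.0, "24h" = 2.1, "1w" = 2.3, "4w" = 2.6),
                vmax = c(baseline = 4.7, "24h" = 4.6, "1w" = 4.9, "4w" = 5.6),
                laa_len = c(baseline = 3.5, "24h" = 3.4, "1w" = 3.5, "4w" = 3.5),
                duct_fs = c(baseline = 47.9, "24h" = 51.4, "1w" = 48.2, "4w" = 43.3)),
    MI = list(vmin = c(baseline = 2.0, "24h" = 2.8, "1w" = 4.2, "4w" = 5.2),
              vmax = c(baseline = 4.7, "24h" = 5.6, "1w" = 7.6, "4w" = 8.8),
              laa_len = c(baseline = 3.5, "24h" = 3.5, "1w" = 4.2, "4w" = 4.8),
              duct_fs = c(baseline = 47.9, "24h" = 43.6, "1w" = 32.2, "4w" = 19.2)),
    "MI+Val" = list(vmin = c(baseline = 2.0, "24h" = 2.9, "1w" = 3.7, "4w" = 3.6),
                    vmax = c(baseline = 4.7, "24h" = 5.5, "1w" = 7.5, "4w" = 7.3),
                    laa_len = c(baseline = 3.5, "24h" = 3.8, "1w" = 4.1, "4w" = 4.0),
                    duct_fs = c(baseline = 47.9, "24h" = 38.9, "1w" = 30.8, "4w" = 40.6)))
}

#' Design of a synthetic three-group longitudinal cohort
#'
#' @param n_per_group subjects per group (default 12, the study size).
#' @param groups group labels.
#' @param timepoints follow-up labels among baseline, 24h, 1w, 4w.
#' @param rfac_targets per-group target remote / infarct-territory RFAC per
#'   timepoint (see `default_rfac_targets`).
#' @param edv_targets per-group target end-diastolic volume (ul) per
#'   timepoint; the phantom radius profile is scaled to match, modeling
#'   post-infarction dilation.
#' @param subject_sd between-subject SD of the contraction amplitude.
#' @param edv_cv between-subject coefficient of variation of the
#'   end-diastolic volume.
#' @param mortality_hazard per-group death hazard per day over the first
#'   week after randomization (deaths later than one week are not modeled).
#' @param followup_days administrative censoring time.
#' @param atrial_targets per-group atrial index targets (see
#'   `default_atrial_targets`).
#' @param n_slices,n_phases,matrix_px,pixel_mm,jitter_px phantom geometry
#'   passed to [phantom_spec()].
#' @param seed RNG seed.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = 12L,
                          groups = c("sham", "MI", "MI+Val"),
                          timepoints = c("baseline", "24h", "1w", "4w"),
                          rfac_targets = default_rfac_targets(),
                          edv_targets = default_edv_targets(),
                          subject_sd = 0.05, edv_cv = 0.05,
                          mortality_hazard = c(sham = 0, MI = 0.03,
                                               "MI+Val" = 0.012),
                          followup_days = 28,
                          atrial_targets = default_atrial_targets(),
                          n_slices = 7L, n_phases = 12L, matrix_px = 96L,
                          pixel_mm = 10.24 / matrix_px, jitter_px = 0.5,
                          seed = NULL) {
  if (any(n_per_group < 2L)) stop("need n >= 2 per group")
  if (subject_sd < 0) stop("subject_sd must be >= 0")
  stopifnot(all(timepoints %in% names(TIMEPOINT_DAYS)),
            all(groups %in% names(rfac_targets)),
            all(groups %in% names(mortality_hazard)))
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 timepoints = timepoints, rfac_targets = rfac_targets,
                 edv_targets = edv_targets, subject_sd = subject_sd,
                 edv_cv = edv_cv,
                 mortality_hazard = mortality_hazard,
                 followup_days = followup_days,
                 atrial_targets = atrial_targets,
                 n_slices = as.integer(n_slices),
                 n_phases = as.integer(n_phases),
                 matrix_px = as.integer(matrix_px), pixel_mm = pixel_mm,
                 jitter_px = jitter_px, seed = seed),
            class = "cohort_design")
}

# mean contraction field (6 x n_slices) for one group/timepoint
contraction_field_for <- function(group, timepoint, targets, n_slices,
                                  sector_labels = DEFAULT_SECTORS) {
  remote_c <- contraction_for_rfac(targets[[group]]$remote[[timepoint]])
  infarct_c <- contraction_for_rfac(targets[[group]]$infarct[[timepoint]])
  healthy_c <- contraction_for_rfac(72)
  pos <- seq(0, 1, length.out = n_slices)
  midapical <- pos <= 0.7
  cf <- matrix(healthy_c, length(sector_labels), n_slices,
               dimnames = list(sector_labels, NULL))
  infarct_sectors <- c("anterior", "antero-septal", "lateral")
  remote_sectors <- c("inferior", "posterior", "septal")
  cf[infarct_sectors, midapical] <- infarct_c
  cf[remote_sectors, midapical] <- remote_c
  cf
}

#' Generate a synthetic cohort of cine studies with survival and atrial data
#'
#' Simulates per-subject contraction fields (group mean field plus a
#' subject-level random offset), rasterizes one phantom per surviving
#' subject and timepoint, runs the full measurement pipeline on it, and
#' returns the tidy cohort table of global and regional indices together
#' with survival records and echo-style atrial indices. Reproducible under
#' the design seed.
#'
#' @param design a [cohort_design()].
#' @param keep_studies return the raw `cine_study` objects (memory-heavy;
#'   default `FALSE` keeps only the measured maps and tables).
#' @return list with `table` (subject, group, timepoint, index, value),
#'   `maps` (resampled `rfac_map` per subject/timepoint, named
#'   `group.subject.timepoint`), `survival` (subject, group, time_days,
#'   event), `atrial` (tidy atrial indices), and optionally `studies`.
#' @export
generate_cohort <- function(design, keep_studies = FALSE) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(design$seed, {
    n <- design$n_per_group
    subjects <- data.frame(
      subject = sprintf("%s_%02d", rep(design$groups, each = n),
                        rep(seq_len(n), length(design$groups))),
      group = rep(design$groups, each = n))
    # survival over the first week post-randomization (exponential), then
    # administrative censoring at followup_days
    haz <- design$mortality_hazard[subjects$group]
    t_death <- rep(Inf, nrow(subjects))
    pos <- haz > 0
    if (any(pos)) t_death[pos] <- stats::rexp(sum(pos), haz[pos])
    t_death[t_death > 7] <- Inf
    event <- as.integer(is.finite(t_death))
    time_days <- ifelse(event == 1, t_death, design$followup_days)
    survival_df <- data.frame(subject = subjects$subject,
                              group = subjects$group,
                              time_days = time_days, event = event)
    rows <- list(); maps <- list(); studies <- list(); atr <- list()
    for (i in seq_len(nrow(subjects))) {
      grp <- subjects$group[i]; sid <- subjects$subject[i]
      subj_off <- stats::rnorm(1, 0, design$subject_sd)
      for (tp in design$timepoints) {
        if (TIMEPOINT_DAYS[[tp]] > time_days[i] && event[i] == 1) next
        cf <- contraction_field_for(grp, tp, design$rfac_targets,
                                    design$n_slices)
        cf <- cf + subj_off +
          stats::rnorm(length(cf), 0, design$subject_sd / 2)
        cf <- pmin(pmax(cf, -0.25), 0.88)
        rp <- default_radius_profile(design$n_slices)
        edv_ref <- sum(pi * rp^2)      # 1 mm spacing
        edv_t <- design$edv_targets[[grp]][[tp]] *
          exp(stats::rnorm(1, 0, design$edv_cv))
        rp <- rp * sqrt(edv_t / edv_ref)
        spec <- phantom_spec(
          n_slices = design$n_slices, n_phases = design$n_phases,
          matrix_px = design$matrix_px, pixel_mm = design$pixel_mm,
          radius_profile = rp,
          contraction_field = cf, jitter_px = design$jitter_px,
          seed = sample.int(.Machine$integer.max, 1),
          subject_id = sid)
        st <- generate_lv_phantom(spec)
        tab <- sector_areas(st)
        map <- compute_rfac(tab)
        rs <- resample_slices(map)
        summ <- regional_summary(rs)
        gf <- global_function(tab)
        key <- paste(grp, sid, tp, sep = ".")
        maps[[key]] <- rs
        if (keep_studies) studies[[key]] <- st
        rows[[key]] <- data.frame(
          subject = sid, group = grp, timepoint = tp,
          index = c("iRFAC", "pRFAC", "ipRFAC", "LVEF", "LVEDV", "LVESV",
                    "LVSV"),
          value = c(summ$irfac_pct, summ$prfac_pct, summ$iprfac_pct,
                    gf$ef_pct, gf$edv_ul, gf$esv_ul, gf$sv_ul))
        atr[[key]] <- cbind(
          data.frame(subject = sid, group = grp, timepoint = tp),
          atrial_indices(generate_atrial_trace(
            grp, tp, design$atrial_targets)))
      }
    }
    out <- list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                maps = maps,
                survival = survival_df,
                atrial = do.call(rbind, c(atr, make.row.names = FALSE)))
    if (keep_studies) out$studies <- studies
    out
  })
}

#' Generate one subject's synthetic atrial trace
#'
#' The atrial contour is an ellipse whose solid of revolution about the
#' supero-inferior axis matches a target volume drawn around the group mean
#' (axis ratio 1.3); the appendage midline is a shallow arc of the target
#' length; duct diameters follow the target fractional shortening.
#'
#' @param group,timepoint cohort cell.
#' @param targets atrial target list (see `default_atrial_targets`).
#' @param cv between-subject coefficient of variation (default 0.1).
#' @param n_vertices contour vertices.
#' @return an atrial trace list suitable for [atrial_indices()].
#' @export
generate_atrial_trace <- function(group, timepoint,
                                  targets = default_atrial_targets(),
                                  cv = 0.1, n_vertices = 96L) {
  tg <- targets[[group]]
  vmax <- max(stats::rnorm(1, tg$vmax[[timepoint]],
                           cv * tg$vmax[[timepoint]]), 0.5)
  vmin <- min(max(stats::rnorm(1, tg$vmin[[timepoint]],
                               cv * tg$vmin[[timepoint]]), 0.2),
              0.95 * vmax)
  laa_len <- max(stats::rnorm(1, tg$laa_len[[timepoint]],
                              cv * tg$laa_len[[timepoint]]), 1)
  fs <- min(max(stats::rnorm(1, tg$duct_fs[[timepoint]],
                             cv * tg$duct_fs[[timepoint]]), 0), 95)
  ellipse_for_volume <- function(v, ratio = 1.3) {
    b <- (3 * v / (4 * pi * ratio))^(1 / 3)    # V = 4/3 pi b^2 (ratio b)
    a <- ratio * b
    th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
    cbind(b * cos(th), a * sin(th))            # long axis along y
  }
  a_max <- 1.3 * (3 * vmax / (4 * pi * 1.3))^(1 / 3)
  arc_t <- seq(0, pi / 3, length.out = 64)
  r_arc <- laa_len / (pi / 3)                  # quarter-ish arc of that length
  d_max <- 1.0
  list(la_polygon_min = ellipse_for_volume(vmin),
       la_polygon_max = ellipse_for_volume(vmax),
       long_axis = rbind(c(0, -a_max), c(0, a_max)),
       laa_midline = cbind(r_arc * sin(arc_t), -r_arc * (1 - cos(arc_t))),
       duct_d_max = d_max, duct_d_min = d_max * (1 - fs / 100))
}

#' Generate a synthetic expression matrix with known structure
#'
#' Log-normal intensity model: `intensity = exp(b_g + class effect +
#' beta_g * z(trait) + noise)`. A block of genes carries class effects (up
#' in MI, partially restored in MI+Val), a block is linearly coupled to the
#' trait with negative slopes (the remote-wall coupling seen in quantitative
#' trait screens), and the rest are null. A fraction of probes is
#' low-expressed (exercising the intensity filter) and some genes carry two
#' probes (exercising the per-gene collapse).
#'
#' @param classes class label per sample (>= 2 per class).
#' @param trait optional numeric trait per sample (standardized internally).
#' @param n_genes total genes.
#' @param n_class_effect genes with class effects.
#' @param n_trait genes coupled to the trait (requires `trait`).
#' @param class_effect log-scale effect size of MI vs sham (MI+Val restores
#'   60% of it).
#' @param trait_beta log-scale slope per trait SD (negative by default).
#' @param noise_sd log-scale noise SD (>= 0).
#' @param frac_low fraction of low-expressed probes.
#' @param n_dup_genes genes carrying a duplicate probe.
#' @param seed RNG seed (same seed, identical matrix).
#' @return an `expression_matrix`; attribute `truth` lists the class-effect
#'   and trait-coupled gene names.
#' @export
generate_expression <- function(classes, trait = NULL, n_genes = 500L,
                                n_class_effect = 60L, n_trait = 40L,
                                class_effect = 0.6, trait_beta = -0.35,
                                noise_sd = 0.25, frac_low = 0.15,
                                n_dup_genes = 25L, seed = NULL) {
  classes <- factor(classes)
  if (any(table(classes) < 2L)) stop("need >= 2 samples per class")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_trait > 0L && is.null(trait))
    stop("trait-coupled genes requested without a trait")
  n_samp <- length(classes)
  with_seed(seed, {
    genes <- sprintf("GENE%04d", seq_len(n_genes))
    base <- stats::rnorm(n_genes, log(400), 0.8)
    low <- seq_len(floor(frac_low * n_genes))
    base[low] <- stats::rnorm(length(low), log(40), 0.4)
    usable <- setdiff(seq_len(n_genes), low)
    idx_class <- if (n_class_effect > 0)
      usable[seq_len(n_class_effect)] else integer(0)
    idx_trait <- if (n_trait > 0)
      usable[n_class_effect + seq_len(n_trait)] else integer(0)
    z <- if (!is.null(trait)) {
      if (stats::sd(trait) > 0) as.vector(scale(trait)) else trait * 0
    } else numeric(n_samp)
    # class effect pattern: sham 0, MI +e, MI+Val +0.4 e (alternating sign)
    eff <- numeric(n_samp)
    lv <- levels(classes)
    class_shift <- stats::setNames(numeric(length(lv)), lv)
    if ("MI" %in% lv) class_shift["MI"] <- 1
    if ("MI+Val" %in% lv) class_shift["MI+Val"] <- 0.4
    if (!any(class_shift != 0) && length(lv) > 1)
      class_shift[2] <- 1                      # generic second-class effect
    logx <- matrix(rep(base, n_samp), n_genes, n_samp)
    if (length(idx_class)) {
      sgn <- rep(c(1, -1), length.out = length(idx_class))
      logx[idx_class, ] <- logx[idx_class, ] +
        outer(sgn * class_effect, class_shift[as.character(classes)])
    }
    if (length(idx_trait)) {
      beta <- rep(trait_beta, length(idx_trait))
      logx[idx_trait, ] <- logx[idx_trait, ] + outer(beta, z)
    }
    logx <- logx + matrix(stats::rnorm(n_genes * n_samp, 0, noise_sd),
                          n_genes, n_samp)
    probes <- data.frame(probe_id = sprintf("ILMN_%04d", seq_len(n_genes)),
                         gene_symbol = genes)
    x <- exp(logx)
    # duplicate probes for some genes (independent noise, same signal)
    if (n_dup_genes > 0) {
      dup_idx <- usable[seq_len(min(n_dup_genes, length(usable)))]
      dup <- exp(logx[dup_idx, , drop = FALSE] +
                   matrix(stats::rnorm(length(dup_idx) * n_samp, 0,
                                       noise_sd * 1.5),
                          length(dup_idx), n_samp))
      x <- rbind(x, dup)
      probes <- rbind(probes, data.frame(
        probe_id = sprintf("ILMN_%04d", n_genes + seq_along(dup_idx)),
        gene_symbol = genes[dup_idx]))
    }
    rownames(x) <- probes$probe_id
    colnames(x) <- sprintf("S%02d", seq_len(n_samp))
    m <- expression_matrix(x, probes, classes = classes, trait = trait)
    attr(m, "truth") <- list(class_genes = genes[idx_class],
                             trait_genes = genes[idx_trait])
    m
  })
}
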