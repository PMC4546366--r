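# Microarray expression statistics: probe filtering, multivariate
# permutation testing with FDR-and-confidence control, pairwise
# fold-change-gated t-tests, and quantitative-trait correlation screens.
#
# The multivariate permutation procedure ranks genes by their per-gene
# p-value (one-way F across classes, or Pearson correlation against a
# quantitative trait), then uses the permutation distribution of
# false-discovery counts to pick the largest list size k whose false
# discovery proportion is <= `fdr` with probability >= `conf`. Class labels
# (or trait values) are permuted across arrays; when the permutation space
# is small it is enumerated exhaustively instead of sampled.

#' Construct an expression matrix object
#'
#' @param intensity probes x samples numeric matrix of non-negative
#'   post-normalization intensities (linear scale).
#' @param probes data frame with columns `probe_id` and `gene_symbol`
#'   (missing symbols allowed), or `NULL` to use rownames as both.
#' @param classes class label per sample.
#' @param trait optional numeric trait per sample (e.g. ipRFAC).
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(intensity, probes = NULL, classes,
                              trait = NULL) {
  intensity <- as.matrix(intensity)
  if (any(intensity < 0)) stop("negative intensities")
  if (is.null(rownames(intensity)))
    rownames(intensity) <- sprintf("probe_%05d", seq_len(nrow(intensity)))
  if (is.null(probes)) {
    probes <- data.frame(probe_id = rownames(intensity),
                         gene_symbol = rownames(intensity))
  }
  stopifnot(all(c("probe_id", "gene_symbol") %in% names(probes)),
            nrow(probes) == nrow(intensity))
  if (length(classes) != ncol(intensity))
    stop("one class label per sample required")
  if (!is.null(trait) && length(trait) != ncol(intensity))
    stop("one trait value per sample required")
  structure(list(intensity = intensity, probes = probes,
                 classes = factor(classes), trait = trait,
                 filter_audit = NULL),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probes x %d samples, %d classes%s\n",
              nrow(x$intensity), ncol(x$intensity), nlevels(x$classes),
              if (is.null(x$trait)) "" else ", with trait"))
  invisible(x)
}

#' Filter probes by intensity, log-variation and per-gene redundancy
#'
#' Three rules applied in order: (a) exclude a probe whose `pct`-th
#' percentile of intensities is below `intensity_cut`; (b) exclude a probe
#' whose log-intensity variance is not significantly larger than the median
#' probe variance (chi-squared test `(n-1) s^2 / median(s^2)` on `n-1` df;
#' retain if p <= `logvar_alpha`); (c) collapse multiple probes of one gene
#' symbol to the probe with the largest interquartile range. The median
#' reference variance is stored in the filter audit and reused when a
#' filtered matrix is filtered again, making the operation idempotent.
#'
#' @param m an `expression_matrix`.
#' @param intensity_cut intensity floor for rule (a) (default 125).
#' @param pct percentile used by rule (a) (default 33).
#' @param logvar_alpha retention threshold for rule (b) (default 0.05).
#' @param drop_unannotated drop probes lacking a gene symbol (default
#'   `FALSE`: retained under their probe ID).
#' @return the filtered `expression_matrix`; element `filter_audit` records
#'   per-rule exclusion counts and the reference variance.
#' @export
filter_probes <- function(m, intensity_cut = 125, pct = 33,
                          logvar_alpha = 0.05, drop_unannotated = FALSE) {
  x <- m$intensity
  n <- ncol(x)
  # (a) percentile-intensity floor
  q <- apply(x, 1, stats::quantile, probs = pct / 100, names = FALSE)
  pass_a <- q >= intensity_cut
  # (b) log-variation vs the median probe variance
  lx <- log2(pmax(x, .Machine$double.eps))
  v <- apply(lx, 1, stats::var)
  ref_var <- m$filter_audit$ref_var %||% stats::median(v)
  if (ref_var <= 0) stop("degenerate reference variance")
  p_var <- stats::pchisq((n - 1) * v / ref_var, df = n - 1,
                         lower.tail = FALSE)
  pass_b <- p_var <= logvar_alpha
  keep <- pass_a & pass_b
  probes <- m$probes[keep, , drop = FALSE]
  x <- x[keep, , drop = FALSE]
  lx <- lx[keep, , drop = FALSE]
  # (c) one probe per gene symbol: largest IQR wins
  sym <- probes$gene_symbol
  unann <- is.na(sym) | sym == ""
  n_unann_dropped <- 0L
  if (drop_unannotated && any(unann)) {
    n_unann_dropped <- sum(unann)
    probes <- probes[!unann, , drop = FALSE]
    x <- x[!unann, , drop = FALSE]; lx <- lx[!unann, , drop = FALSE]
    sym <- probes$gene_symbol
    unann <- rep(FALSE, length(sym))
  }
  sym[unann] <- probes$probe_id[unann]
  iqr <- apply(lx, 1, stats::IQR)
  ord <- order(sym, -iqr, probes$probe_id)
  dup <- duplicated(sym[ord])
  keep_c <- ord[!dup]
  keep_c <- sort(keep_c)
  out <- m
  out$intensity <- x[keep_c, , drop = FALSE]
  out$probes <- probes[keep_c, , drop = FALSE]
  rownames(out$intensity) <- out$probes$probe_id
  out$filter_audit <- list(
    n_input = nrow(m$intensity),
    n_fail_intensity = sum(!pass_a),
    n_fail_logvar = sum(pass_a & !pass_b),
    n_collapsed = sum(dup) + n_unann_dropped,
    n_output = nrow(out$intensity),
    ref_var = ref_var)
  out
}

# ---- per-gene statistics (vectorized across probes) ------------------------

row_f_stats <- function(lx, classes) {
  g <- factor(classes)
  G <- nlevels(g); N <- ncol(lx)
  M <- stats::model.matrix(~ 0 + g)
  ng <- colSums(M)
  S <- lx %*% M
  tot <- rowSums(lx)
  tss <- rowSums(lx^2) - tot^2 / N
  ssb <- rowSums(sweep(S^2, 2, ng, "/")) - tot^2 / N
  ssw <- pmax(tss - ssb, 0)
  f <- (ssb / (G - 1)) / (ssw / (N - G))
  p <- stats::pf(f, G - 1, N - G, lower.tail = FALSE)
  list(f = f, p = p, df = c(G - 1, N - G))
}

# F p-values for many label permutations at once: `perm` is a B x N matrix
# of class indices in 1..G. Returns a probes x B matrix of p-values.
perm_f_pvalues <- function(lx, perm, G) {
  N <- ncol(lx); B <- nrow(perm)
  ind <- matrix(0, N, G * B)
  for (b in seq_len(B))
    ind[cbind(seq_len(N), (b - 1L) * G + perm[b, ])] <- 1
  S <- lx %*% ind                         # probes x (G*B)
  ng <- colSums(ind)
  SS <- sweep(S^2, 2, ng, "/")
  ssb_tot <- Reduce(`+`, lapply(seq_len(G), function(g)
    SS[, seq(g, G * B, by = G), drop = FALSE]))   # probes x B
  tot <- rowSums(lx)
  tss <- rowSums(lx^2) - tot^2 / N
  ssb <- ssb_tot - tot^2 / N
  ssw <- pmax(tss - ssb, 0)
  f <- (ssb / (G - 1)) / (ssw / (N - G))
  stats::pf(f, G - 1, N - G, lower.tail = FALSE)
}

row_pearson <- function(lx, trait) {
  r <- as.vector(stats::cor(t(lx), trait))
  n <- length(trait)
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  list(r = r, p = p)
}

# ---- permutation plumbing --------------------------------------------------

count_label_perms <- function(classes) {
  tb <- table(classes)
  exp(lgamma(sum(tb) + 1) - sum(lgamma(tb + 1)))
}

# all distinct arrangements of a label multiset, as a matrix (rows =
# arrangements, values = class indices)
enumerate_label_perms <- function(idx_counts) {
  G <- length(idx_counts)
  rec <- function(counts) {
    n <- sum(counts)
    if (n == 0L) return(matrix(integer(0), 1, 0))
    out <- NULL
    for (g in seq_len(G)) {
      if (counts[g] == 0L) next
      cc <- counts; cc[g] <- cc[g] - 1L
      sub <- rec(cc)
      out <- rbind(out, cbind(g, sub))
    }
    out
  }
  rec(as.integer(idx_counts))
}

enumerate_full_perms <- function(n) {
  rec <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1, 1))
    out <- NULL
    for (i in seq_along(v))
      out <- rbind(out, cbind(v[i], rec(v[-i])))
    out
  }
  rec(seq_len(n))
}

# Largest list size k whose false-discovery proportion is <= fdr with
# probability >= conf under the permutation distribution.
fdp_confident_k <- function(p_obs, p_perm, fdr, conf) {
  o <- sort(p_obs)
  B <- ncol(p_perm)
  counts <- matrix(0L, B, length(o))
  for (b in seq_len(B))
    counts[b, ] <- findInterval(o, sort(p_perm[, b]))
  ok <- vapply(seq_along(o), function(k)
    mean(counts[, k] / k <= fdr) >= conf, logical(1))
  # step-down: grow the list only while every smaller size is acceptable
  sum(cumprod(ok))
}

#' Class-comparison screen by multivariate permutation F test
#'
#' Per-gene one-way F p-values across classes; the returned gene list is the
#' largest p-ranked list whose false-discovery proportion is below `fdr`
#' with confidence `conf` under permutation of the class labels.
#'
#' @param m an `expression_matrix` with >= 2 classes of >= 2 samples.
#' @param fdr false-discovery-rate bound (default 0.10).
#' @param conf confidence that the FDP is below `fdr` (default 0.80).
#' @param n_perm random label permutations (default 1000); exhaustive
#'   enumeration is used instead when the number of distinct label
#'   arrangements is <= `n_perm`.
#' @param seed RNG seed for the sampled permutations.
#' @return list: `significant` (data frame `gene, f, p, perm_p` of the
#'   selected genes, ordered by p), `n_significant`, `stats` (all genes),
#'   `n_perm_used`, `exhaustive`.
#' @export
multivariate_permutation_f <- function(m, fdr = 0.10, conf = 0.80,
                                       n_perm = 1000L, seed = NULL) {
  g <- m$classes
  if (nlevels(droplevels(g)) < 2L || any(table(g) < 2L))
    stop("need >= 2 classes with >= 2 samples each")
  if (n_perm < 100L) warning("fewer than 100 permutations is unreliable")
  lx <- log2(pmax(m$intensity, .Machine$double.eps))
  obs <- row_f_stats(lx, g)
  N <- ncol(lx); G <- nlevels(g)
  gi <- as.integer(g)
  n_distinct <- count_label_perms(g)
  exhaustive <- n_distinct <= n_perm
  perm <- if (exhaustive) {
    enumerate_label_perms(tabulate(gi, G))
  } else {
    # the observed labeling is always part of the sampled permutation set
    rbind(gi, with_seed(seed, t(replicate(n_perm - 1L, sample(gi)))))
  }
  p_perm <- perm_f_pvalues(lx, perm, G)
  k <- fdp_confident_k(obs$p, p_perm, fdr, conf)
  perm_p <- (rowSums(p_perm <= obs$p) + 1) / (ncol(p_perm) + 1)
  stats_df <- data.frame(gene = m$probes$gene_symbol,
                         probe_id = m$probes$probe_id,
                         f = obs$f, p = obs$p, perm_p = perm_p)
  ord <- order(stats_df$p, stats_df$probe_id)
  sig <- stats_df[ord[seq_len(k)], , drop = FALSE]
  rownames(sig) <- NULL
  list(significant = sig, n_significant = k, stats = stats_df,
       n_perm_used = nrow(perm), exhaustive = exhaustive,
       fdr = fdr, conf = conf)
}

#' Pairwise class t-tests gated by mean fold change
#'
#' For each listed comparison, a two-sample t-test on log2 intensities and
#' the signed linear-scale fold change of group means (ratio if >= 1, else
#' the negative reciprocal). A gene survives when `p < alpha` and
#' `|FC| >= fc` in at least one comparison; direction is up/down in the
#' second level of `direction_pair` relative to the first.
#'
#' @param m an `expression_matrix`.
#' @param comparisons list of length-2 character vectors of class labels.
#' @param alpha per-test significance threshold (default 0.01).
#' @param fc fold-change gate, > 1 (default 1.2).
#' @param direction_pair length-2 classes defining the direction label,
#'   default `c("MI", "MI+Val")` (up = higher in the treated group).
#' @param var_equal pooled-variance t-test (default `TRUE`).
#' @return list: `survivors` (data frame with per-comparison p and FC,
#'   `direction`), `up`, `down` (gene vectors), `all` (per-gene table).
#' @export
pairwise_fc_filter <- function(m,
                               comparisons = list(c("MI", "sham"),
                                                  c("MI", "MI+Val")),
                               alpha = 0.01, fc = 1.2,
                               direction_pair = c("MI", "MI+Val"),
                               var_equal = TRUE) {
  if (fc < 1) stop("fc must be >= 1 (signed fold-change convention)")
  lv <- levels(m$classes)
  for (cmp in comparisons)
    if (!all(cmp %in% lv)) stop("unknown class in comparison: ",
                                paste(cmp, collapse = " vs "))
  lx <- log2(pmax(m$intensity, .Machine$double.eps))
  res <- data.frame(gene = m$probes$gene_symbol,
                    probe_id = m$probes$probe_id)
  pass <- rep(FALSE, nrow(lx))
  for (cmp in comparisons) {
    ia <- m$classes == cmp[1]; ib <- m$classes == cmp[2]
    ta <- row_t_stats(lx[, ia, drop = FALSE], lx[, ib, drop = FALSE],
                      var_equal)
    fc_lin <- rowMeans(m$intensity[, ia, drop = FALSE]) /
      rowMeans(m$intensity[, ib, drop = FALSE])
    fc_signed <- ifelse(fc_lin >= 1, fc_lin, -1 / fc_lin)
    tag <- paste(cmp, collapse = "_vs_")
    res[[paste0("p_", tag)]] <- ta$p
    res[[paste0("fc_", tag)]] <- fc_signed
    pass <- pass | (ta$p < alpha & abs(fc_signed) >= fc)
  }
  iu <- m$classes == direction_pair[2]; ir <- m$classes == direction_pair[1]
  dirn <- ifelse(rowMeans(m$intensity[, iu, drop = FALSE]) >=
                   rowMeans(m$intensity[, ir, drop = FALSE]), "up", "down")
  res$direction <- dirn
  res$survives <- pass
  surv <- res[pass, , drop = FALSE]
  rownames(surv) <- NULL
  list(survivors = surv,
       up = surv$gene[surv$direction == "up"],
       down = surv$gene[surv$direction == "down"],
       all = res)
}

row_t_stats <- function(xa, xb, var_equal = TRUE) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tt <- (ma - mb) / se
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Quantitative-trait correlation screen with permutation FDP control
#'
#' Per-gene Pearson correlation (and parametric p) between log2 expression
#' and a numeric trait; the significant list is chosen by the same
#' FDR-with-confidence machinery, permuting the trait values across arrays.
#'
#' @param m an `expression_matrix` whose `trait` is set (or supply `trait`).
#' @param trait numeric trait per sample; defaults to `m$trait`.
#' @inheritParams multivariate_permutation_f
#' @return list: `significant` (data frame `gene, r, p, perm_p`),
#'   `n_significant`, `stats`, `n_perm_used`, `exhaustive`.
#' @export
quantitative_trait_corr <- function(m, trait = m$trait, fdr = 0.10,
                                    conf = 0.80, n_perm = 1000L,
                                    seed = NULL) {
  if (is.null(trait)) stop("no trait available")
  n <- ncol(m$intensity)
  if (length(trait) != n) stop("one trait value per sample required")
  if (n < 4L) stop("need at least 4 samples")
  if (stats::sd(trait) == 0) stop("zero-variance trait")
  lx <- log2(pmax(m$intensity, .Machine$double.eps))
  obs <- row_pearson(lx, trait)
  exhaustive <- factorial(n) <= n_perm
  tmat <- if (exhaustive) {
    pm <- enumerate_full_perms(n)
    apply(pm, 1, function(ix) trait[ix])     # n x B
  } else {
    # the observed trait order is always part of the sampled set
    cbind(trait, with_seed(seed, replicate(n_perm - 1L, sample(trait))))
  }
  r_perm <- stats::cor(t(lx), tmat)           # probes x B
  t_perm <- abs(r_perm) * sqrt(n - 2) /
    sqrt(pmax(1 - r_perm^2, .Machine$double.eps))
  p_perm <- 2 * stats::pt(-t_perm, n - 2)
  k <- fdp_confident_k(obs$p, p_perm, fdr, conf)
  perm_p <- (rowSums(p_perm <= obs$p) + 1) / (ncol(p_perm) + 1)
  stats_df <- data.frame(gene = m$probes$gene_symbol,
                         probe_id = m$probes$probe_id,
                         r = obs$r, p = obs$p, perm_p = perm_p)
  ord <- order(stats_df$p, stats_df$probe_id)
  sig <- stats_df[ord[seq_len(k)], , drop = FALSE]
  rownames(sig) <- NULL
  list(significant = sig, n_significant = k, stats = stats_df,
       n_perm_used = ncol(p_perm), exhaustive = exhaustive,
       fdr = fdr, conf = conf)
}

#' Write a gene list as TSV
#' @param df data frame (e.g. `$significant` from a screen).
#' @param path output path.
#' @export
write_gene_list <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probes x samples expression TSV with a sample annotation CSV
#'
#' The TSV holds probe IDs in the first column and one column per sample;
#' an optional `gene_symbol` column supplies the probe-to-gene map. The
#' annotation CSV needs columns `sample`, `class` and optionally `trait`.
#'
#' @param matrix_path TSV of intensities.
#' @param annotation_path CSV of sample annotations.
#' @return an `expression_matrix`.
#' @export
read_expression_tsv <- function(matrix_path, annotation_path) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE)
  ann <- utils::read.csv(annotation_path)
  stopifnot(all(c("sample", "class") %in% names(ann)))
  probe_id <- as.character(tab[[1]])
  gene_symbol <- if ("gene_symbol" %in% names(tab))
    as.character(tab$gene_symbol) else probe_id
  keep <- setdiff(names(tab), c(names(tab)[1], "gene_symbol"))
  x <- as.matrix(tab[, keep, drop = FALSE])
  rownames(x) <- probe_id
  miss <- setdiff(ann$sample, colnames(x))
  if (length(miss)) stop("annotated samples absent from matrix: ",
                         paste(miss, collapse = ", "))
  x <- x[, as.character(ann$sample), drop = FALSE]
  expression_matrix(x, data.frame(probe_id, gene_symbol),
                    classes = ann$class,
                    trait = if ("trait" %in% names(ann)) ann$trait else NULL)
}

#' Read a GEO series-matrix file
#'
#' Parses the `!series_matrix_table_begin` ... `!series_matrix_table_end`
#' block of a GEO series-matrix TSV into an `expression_matrix`; class
#' labels must be supplied (or default to a single class).
#'
#' @param path series-matrix file (plain text).
#' @param classes class label per sample column, or `NULL`.
#' @return an `expression_matrix`.
#' @export
read_series_matrix <- function(path, classes = NULL) {
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stop("no series-matrix table found in ", path)
  tab <- utils::read.delim(text = lines[(beg + 1L):(end - 1L)],
                           check.names = FALSE)
  probe_id <- as.character(tab[[1]])
  x <- as.matrix(tab[, -1, drop = FALSE])
  rownames(x) <- probe_id
  if (is.null(classes)) classes <- rep("all", ncol(x))
  expression_matrix(x, data.frame(probe_id, gene_symbol = probe_id),
                    classes = classes)
}
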