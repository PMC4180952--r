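#' Log2 fold change relative to each gene's mean
#'
#' Heat-map normalization: `out[g, j] = log2((v[g, j] + pc) / (mean_g + pc))`
#' where `mean_g` is the gene's row mean. With `pseudocount = 0` the per-row
#' mean of `2^out` is exactly 1. Scale-invariant per gene: doubling a row
#' leaves its output unchanged (when `pseudocount = 0`).
#'
#' @param matrix a linear-scale [time_series_matrix()].
#' @param pseudocount expression units added before the ratio, >= 0. Rows with
#'   zero mean require `pseudocount > 0`.
#' @return a [time_series_matrix()] with `scale = "log2rel"`.
#' @export
log2_relative_to_mean <- function(matrix, pseudocount = 0) {
  stopifnot(inherits(matrix, "time_series_matrix"), pseudocount >= 0)
  if (matrix$scale != "linear")
    stop("input error: matrix is already normalized")
  mu <- rowMeans(matrix$values)
  if (pseudocount == 0 && any(mu == 0))
    stop("normalization error: zero-mean row(s) with pseudocount 0: ",
         paste(matrix$gene_ids[mu == 0], collapse = ", "))
  out <- log2(sweep(matrix$values + pseudocount, 1, mu + pseudocount, `/`))
  time_series_matrix(out, matrix$gene_ids, matrix$times,
                     condition = matrix$condition,
                     replicate = matrix$replicate, scale = "log2rel")
}

#' Time at which half the population has budded
#'
#' First crossing of 0.5 in the budding-index curve, by linear interpolation
#' between the bracketing samples. This is the cross-condition temporal
#' anchor used to align arrest experiments.
#'
#' @param curve a [budding_curve()].
#' @return anchor time in minutes.
#' @export
t50_budded <- function(curve) {
  f <- curve$fraction_budded
  t <- curve$times
  i <- which(f >= 0.5)[1]
  if (is.na(i))
    stop("no-anchor error: budding curve never reaches 0.5")
  if (i == 1L) return(t[1])
  t[i - 1] + (0.5 - f[i - 1]) / (f[i] - f[i - 1]) * (t[i] - t[i - 1])
}

#' Align matrices at per-condition anchor times
#'
#' Shifts each matrix's time axis by its anchor (`times - anchor`); no
#' resampling is performed. The overlapping aligned range across all matrices
#' is attached as attribute `"aligned_range"`.
#'
#' @param matrices list of [time_series_matrix()].
#' @param anchors numeric vector of anchor times (minutes), one per matrix.
#' @return list of shifted matrices with attribute `aligned_range`.
#' @export
align_at_anchor <- function(matrices, anchors) {
  stopifnot(length(matrices) == length(anchors))
  out <- Map(function(m, a) {
    m$times <- m$times - a
    colnames(m$values) <- format_num(m$times)
    m
  }, matrices, anchors)
  lo <- max(vapply(out, function(m) min(m$times), numeric(1)))
  hi <- min(vapply(out, function(m) max(m$times), numeric(1)))
  attr(out, "aligned_range") <- c(lo, hi)
  out
}

#' Behavior-classification thresholds
#'
#' Config-exposed defaults validated by simulation (the reference study
#' classifies behaviors qualitatively from heat maps).
#'
#' @param alpha FDR level for the post-window rhythmicity call.
#' @param peak_ratio first-cycle max over series floor required to count a
#'   first-cycle pulse (fold change).
#' @param high late-mean ratio at or above which a non-oscillating gene with
#'   a non-negative late slope is `persistent_high`.
#' @param low late-mean ratio at or below which a pulsed gene is `repressed`.
#' @param window_start_frac start of the post-first-cycle window, as a
#'   multiple of the WT period.
#' @param late_frac fraction of time points forming the "late" window.
#' @param slope_tol relative change over the late window below which the late
#'   slope sign is 0 (default 0.2, above typical noise-driven drift).
#' @return named list of thresholds.
#' @export
behavior_thresholds <- function(alpha = 0.05, peak_ratio = 2, high = 0.6,
                                low = 0.3, window_start_frac = 1.25,
                                late_frac = 0.25, slope_tol = 0.2) {
  list(alpha = alpha, peak_ratio = peak_ratio, high = high, low = low,
       window_start_frac = window_start_frac, late_frac = late_frac,
       slope_tol = slope_tol)
}

## features + deterministic label rule shared by single-series and
## matrix-level classification; q is the post-window rhythmicity q-value
behavior_features <- function(series, times, wt_period, thresholds) {
  w0 <- thresholds$window_start_frac * wt_period
  if (max(times) < w0 + 2 * wt_period)
    stop("insufficient-window error: series must cover >= 2 periods past ",
         format_num(w0), " min")
  n <- length(series)
  n_late <- max(2L, ceiling(thresholds$late_frac * n))
  late <- seq(n - n_late + 1L, n)
  fc <- series[times <= w0]
  fc_max <- max(fc)
  base <- min(series)
  peak_ratio <- fc_max / max(base, 1e-8)
  late_mean_ratio <- mean(series[late]) / max(fc_max, 1e-8)
  sl <- stats::coef(stats::lm.fit(cbind(1, times[late]),
                                  series[late] / max(fc_max, 1e-8)))[2]
  rel_change <- sl * (times[late[n_late]] - times[late[1]])
  slope_sign <- if (abs(rel_change) < thresholds$slope_tol) 0L
                else as.integer(sign(rel_change))
  list(first_cycle_peak_ratio = unname(peak_ratio),
       late_mean_ratio = unname(late_mean_ratio),
       late_slope_sign = slope_sign)
}

behavior_label_from <- function(post_window_q, feats, thresholds) {
  if (is.finite(post_window_q) && post_window_q <= thresholds$alpha)
    return("oscillating")
  if (feats$first_cycle_peak_ratio < thresholds$peak_ratio)
    return("low_flat")
  if (feats$late_mean_ratio >= thresholds$high && feats$late_slope_sign >= 0)
    return("persistent_high")
  if (feats$late_mean_ratio <= thresholds$low)
    return("repressed")
  "damped"
}

#' Classify one gene's arrest behavior
#'
#' Assigns one of `oscillating`, `damped`, `persistent_high`, `repressed`,
#' `low_flat` from features computed on the post-first-cycle window
#' (`t > window_start_frac * wt_period`): a rhythmicity q-value on the
#' windowed series, the late-mean ratio (mean of the last quarter over the
#' first-cycle maximum), the late slope sign, and the first-cycle peak ratio
#' (first-cycle maximum over the series floor). The label is a deterministic
#' function of these features and the thresholds. For a single series the
#' rhythmicity q-value is the median of the three algorithms' permutation
#' p-values (two of three scorers must agree); matrix-level classification
#' with per-algorithm BH across genes is provided by [classify_matrix()].
#'
#' @param series_arrest numeric expression values under the arrest condition.
#' @param times sampling times in minutes.
#' @param wt_period reference WT cell-cycle period in minutes.
#' @param thresholds a [behavior_thresholds()] list.
#' @param post_window_q optional precomputed post-window rhythmicity q-value;
#'   when `NULL` it is computed from the three permutation p-values.
#' @param period_grid candidate periods for the windowed rhythmicity call;
#'   defaults to `wt_period * seq(0.6, 1.6, 0.1)` — the classifier asks
#'   whether the gene still oscillates at roughly the WT period, so the grid
#'   is targeted rather than exploratory.
#' @param n_perm,seed rhythmicity-call settings used when `post_window_q` is
#'   `NULL`.
#' @return An object of class `behavior_label`: list with `label` and
#'   `features`.
#' @export
classify_behavior <- function(series_arrest, times, wt_period,
                              thresholds = behavior_thresholds(),
                              post_window_q = NULL,
                              period_grid = wt_period * seq(0.6, 1.6, 0.1),
                              n_perm = 999L, seed = 1L) {
  feats <- behavior_features(series_arrest, times, wt_period, thresholds)
  if (is.null(post_window_q)) {
    w0 <- thresholds$window_start_frac * wt_period
    win <- times > w0
    m1 <- time_series_matrix(base::matrix(series_arrest[win], nrow = 1),
                             "g", times[win])
    res <- call_periodic(m1, period_grid, alpha = thresholds$alpha,
                         n_perm = n_perm, seed = seed)
    post_window_q <- stats::median(res$calls$p_value)
  }
  feats$post_window_q <- post_window_q
  structure(list(label = behavior_label_from(post_window_q, feats, thresholds),
                 features = feats),
            class = "behavior_label")
}

#' Classify arrest behaviors for every gene in a matrix
#'
#' Runs the three rhythmicity algorithms on the post-first-cycle window of
#' the whole matrix. The post-window rhythmicity value per gene is the
#' median of the three algorithms' raw permutation p-values: a gene counts
#' as still oscillating when at least two of the three scorers reject at
#' `alpha` individually. The classifier assigns a per-gene phenotype label,
#' so per-comparison calibration is the appropriate control here;
#' across-gene FDR control (BH plus strict three-way intersection) belongs
#' to the discovery call in [call_periodic()]. The deterministic label rule
#' of [classify_behavior()] is then applied per gene.
#'
#' @param matrix a linear-scale [time_series_matrix()] for one arrest
#'   condition.
#' @param wt_period reference WT period in minutes.
#' @param thresholds a [behavior_thresholds()] list.
#' @param period_grid candidate periods for the windowed call (default:
#'   `wt_period * seq(0.6, 1.6, 0.1)`, see [classify_behavior()]).
#' @param n_perm,seed settings for the windowed rhythmicity call.
#' @return data.frame: gene_id, condition, label, post_window_q,
#'   late_mean_ratio, late_slope_sign, first_cycle_peak_ratio.
#' @export
classify_matrix <- function(matrix, wt_period,
                            thresholds = behavior_thresholds(),
                            period_grid = wt_period * seq(0.6, 1.6, 0.1),
                            n_perm = 999L, seed = 1L) {
  stopifnot(inherits(matrix, "time_series_matrix"))
  w0 <- thresholds$window_start_frac * wt_period
  if (max(matrix$times) < w0 + 2 * wt_period)
    stop("insufficient-window error: need >= 2 periods past ",
         format_num(w0), " min")
  win <- matrix$times > w0
  wm <- time_series_matrix(matrix$values[, win, drop = FALSE],
                           matrix$gene_ids, matrix$times[win],
                           condition = matrix$condition,
                           replicate = matrix$replicate)
  res <- call_periodic(wm, period_grid, alpha = thresholds$alpha,
                       n_perm = n_perm, seed = seed)
  pmed <- tapply(res$calls$p_value, res$calls$gene_id, stats::median)
  rows <- lapply(seq_along(matrix$gene_ids), function(g) {
    id <- matrix$gene_ids[g]
    feats <- behavior_features(matrix$values[g, ], matrix$times, wt_period,
                               thresholds)
    q <- unname(pmed[[id]])
    data.frame(gene_id = id, condition = matrix$condition,
               label = behavior_label_from(q, feats, thresholds),
               post_window_q = q,
               late_mean_ratio = feats$late_mean_ratio,
               late_slope_sign = feats$late_slope_sign,
               first_cycle_peak_ratio = feats$first_cycle_peak_ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overlap between a reference gene set and a comparison set
#'
#' Reports set sizes, intersection count, and the fraction of the reference
#' set shared (`intersection / |set_a|`) — e.g. the fraction of WT-periodic
#' genes that continue to oscillate under an arrest.
#'
#' @param wt_set character vector, reference set (must be non-empty).
#' @param arrest_set character vector, comparison set.
#' @return An object of class `overlap_stat`: list with `set_a_size`,
#'   `set_b_size`, `intersection`, `fraction_of_a`.
#' @export
persistence_overlap <- function(wt_set, arrest_set) {
  wt_set <- unique(wt_set); arrest_set <- unique(arrest_set)
  if (length(wt_set) == 0)
    stop("empty-reference error: reference set is empty")
  k <- length(intersect(wt_set, arrest_set))
  structure(list(set_a_size = length(wt_set),
                 set_b_size = length(arrest_set),
                 intersection = k,
                 fraction_of_a = k / length(wt_set)),
            class = "overlap_stat")
}

#' @export
print.overlap_stat <- function(x, ...) {
  cat(sprintf("overlap: %d / %d of reference shared (%.1f%%); comparison set %d\n",
              x$intersection, x$set_a_size, 100 * x$fraction_of_a,
              x$set_b_size))
  invisible(x)
}

#' Replicate concordance (squared Pearson correlation)
#'
#' Flattens both matrices over all (gene, time) pairs on the log2 scale with a
#' pseudocount and reports the squared Pearson correlation. Gene sets must be
#' identical; time axes are matched by rank and truncated to the common
#' length.
#'
#' @param rep1,rep2 linear-scale [time_series_matrix()] replicates.
#' @param pseudocount expression units added before the log (variance
#'   stabilization), default 1.
#' @return r-squared in `[0, 1]`.
#' @export
replicate_concordance <- function(rep1, rep2, pseudocount = 1) {
  if (!setequal(rep1$gene_ids, rep2$gene_ids)) {
    d1 <- setdiff(rep1$gene_ids, rep2$gene_ids)
    d2 <- setdiff(rep2$gene_ids, rep1$gene_ids)
    stop("input error: gene sets differ; only in rep1: ",
         paste(d1, collapse = ","), "; only in rep2: ",
         paste(d2, collapse = ","))
  }
  v1 <- rep1$values
  v2 <- rep2$values[rep1$gene_ids, , drop = FALSE]
  k <- min(ncol(v1), ncol(v2))
  x <- log2(as.vector(v1[, seq_len(k)]) + pseudocount)
  y <- log2(as.vector(v2[, seq_len(k)]) + pseudocount)
  stats::cor(x, y)^2
}

#' Compare period estimates between two conditions
#'
#' Summary over genes shared by both estimate tables: per-condition median
#' period and the median absolute per-gene period difference. Medians are
#' robust to occasional estimator boundary failures.
#'
#' @param estimates_a,estimates_b data.frames with columns `gene_id`,
#'   `period` (as returned by [estimate_periods()]).
#' @return list with `median_a`, `median_b`, `median_abs_diff`, `n_shared`.
#' @export
compare_periods <- function(estimates_a, estimates_b) {
  shared <- intersect(estimates_a$gene_id, estimates_b$gene_id)
  if (length(shared) == 0)
    stop("empty-comparison error: no shared genes")
  pa <- estimates_a$period[match(shared, estimates_a$gene_id)]
  pb <- estimates_b$period[match(shared, estimates_b$gene_id)]
  list(median_a = stats::median(pa), median_b = stats::median(pb),
       median_abs_diff = stats::median(abs(pa - pb)),
       n_shared = length(shared))
}
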