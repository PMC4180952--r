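#' Default candidate-period grid
#'
#' 40 to 240 minutes in 10-minute steps: brackets both the free-running WT
#' cycle and the arrest-condition oscillations at 18-20 min sampling.
#'
#' @return numeric vector of periods in minutes.
#' @export
default_period_grid <- function() seq(40, 240, by = 10)

## precompute Lomb-Scargle design for fixed times and period grid:
## per-period tau-shifted cosine/sine bases and their sums of squares
ls_design <- function(times, periods) {
  n <- length(times)
  m <- length(periods)
  C <- matrix(0, n, m); S <- matrix(0, n, m)
  for (j in seq_len(m)) {
    w <- 2 * pi / periods[j]
    tau <- atan2(sum(sin(2 * w * times)), sum(cos(2 * w * times))) / (2 * w)
    C[, j] <- cos(w * (times - tau))
    S[, j] <- sin(w * (times - tau))
  }
  list(C = C, S = S, css = colSums(C^2), sss = colSums(S^2),
       periods = periods, n = n)
}

## normalized Lomb-Scargle power for one or more series (columns of Y)
ls_power_multi <- function(Y, design) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  s2 <- colSums(Yc^2) / (n - 1)
  A <- crossprod(design$C, Yc)   # m x k
  B <- crossprod(design$S, Yc)
  css <- ifelse(design$css > 1e-12, design$css, Inf)
  sss <- ifelse(design$sss > 1e-12, design$sss, Inf)
  P <- (A^2 / css + B^2 / sss) / 2
  P <- sweep(P, 2, ifelse(s2 > 1e-300, s2, Inf), `/`)
  P
}

#' Lomb-Scargle periodogram power
#'
#' Normalized Lomb-Scargle power at each candidate period. The estimator
#' works on the actual sampling times, so missing time points (uneven
#' sampling, `NA` values) are handled without imputation. A constant series
#' has zero power at every period.
#'
#' @param series numeric expression values (may contain `NA`).
#' @param times sampling times in minutes, same length.
#' @param period_grid candidate periods in minutes, within
#'   `[2 * min(diff(times)), diff(range(times))]`.
#' @return named numeric vector of powers, one per candidate period.
#' @export
periodogram_power <- function(series, times, period_grid = default_period_grid()) {
  keep <- is.finite(series)
  series <- series[keep]; times <- times[keep]
  if (length(series) < 8)
    stop("insufficient-data error: need >= 8 finite time points")
  dt <- min(diff(times)); span <- diff(range(times))
  if (any(period_grid < 2 * dt - 1e-9 | period_grid > span + 1e-9))
    stop("period_grid must lie within [2*dt, total span]")
  P <- drop(ls_power_multi(matrix(series, ncol = 1), ls_design(times, period_grid)))
  names(P) <- format_num(period_grid)
  P
}

#' Lagged autocorrelation score
#'
#' Pearson correlation of `series[1:(n-lag)]` with `series[(lag+1):n]`.
#' A zero-variance segment yields a score of 0. The periodicity statistic is
#' the maximum of this score over lags matching the candidate period grid
#' (see [call_periodic()]).
#'
#' @param series numeric values.
#' @param lag_points integer lag, `1 <= lag_points < length(series)`.
#' @return correlation in `[-1, 1]`.
#' @export
autocorr_score <- function(series, lag_points) {
  n <- length(series)
  if (lag_points < 1 || lag_points >= n)
    stop("lag_points must satisfy 1 <= lag < length(series)")
  x <- series[seq_len(n - lag_points)]
  y <- series[(lag_points + 1):n]
  if (stats::sd(x) < 1e-300 || stats::sd(y) < 1e-300) return(0)
  stats::cor(x, y)
}

## max autocorrelation over a set of lags, vectorized over columns of Y;
## lags with < 3 overlapping points are skipped
autocorr_max_multi <- function(Y, lags) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  lags <- lags[lags >= 1 & lags <= n - 3]
  if (!length(lags)) return(rep(0, ncol(Y)))
  best <- rep(-Inf, ncol(Y))
  for (L in lags) {
    nl <- n - L
    X <- Y[seq_len(nl), , drop = FALSE]
    Z <- Y[(L + 1):n, , drop = FALSE]
    mx <- colMeans(X); mz <- colMeans(Z)
    num <- colSums(X * Z) - nl * mx * mz
    den <- sqrt(pmax(colSums(X^2) - nl * mx^2, 0) *
                  pmax(colSums(Z^2) - nl * mz^2, 0))
    r <- ifelse(den > 1e-300, num / den, 0)
    best <- pmax(best, r)
  }
  best
}

## cosine templates over (period, phase) combinations: n x (m*p) matrix.
## Finite damping half-lives (in periods) add amplitude-decaying variants,
## matching the bulk signal of a desynchronizing synchronized population.
template_bank <- function(times, periods, phase_grid, damping = Inf) {
  grid <- expand.grid(phase = phase_grid, period = periods,
                      damping = damping)
  TM <- mapply(function(phi, per, dmp)
    cos(2 * pi * (times / per - phi)) *
      if (is.finite(dmp)) exp(-times * log(2) / (dmp * per)) else 1,
    grid$phase, grid$period, grid$damping)
  matrix(TM, nrow = length(times))
}

## index pairs i < j for an n-point series
pair_index <- function(n) {
  which(upper.tri(diag(n)), arr.ind = TRUE)
}

## exact Kendall tau-b between every column of Y and every column of TM:
## tau-b = (C - D) / sqrt((n0 - ties_y)(n0 - ties_t)) over the n0 = n(n-1)/2
## index pairs; C - D is a single sign-matrix cross product
kendall_tau_multi <- function(Y, TM, pairs = pair_index(nrow(Y))) {
  sy <- sign(Y[pairs[, 1], , drop = FALSE] - Y[pairs[, 2], , drop = FALSE])
  st <- sign(TM[pairs[, 1], , drop = FALSE] - TM[pairs[, 2], , drop = FALSE])
  n0 <- nrow(pairs)
  cd <- crossprod(sy, st)                      # C - D, columns x templates
  ny <- colSums(sy != 0)                       # n0 - ties in each series
  nt <- colSums(st != 0)
  den <- sqrt(outer(ny, nt))
  tau <- ifelse(den > 0, cd / den, 0)
  matrix(tau, nrow = ncol(Y))
}

## max Kendall tau against a template bank, vectorized over columns of Y
template_max_multi <- function(Y, TM) {
  Y <- as.matrix(Y)
  tau <- kendall_tau_multi(Y, TM)
  apply(tau, 1, max)
}

## template statistic used inside the permutation caller: max tau plus an
## infinitesimal continuous key (max Pearson r against the same bank) so
## that discrete tau ties between observed and permuted series are broken
## deterministically and the permutation p-value stays uniform under the
## null. The 1e-9 weight never reorders distinct tau values.
template_stat_multi <- function(Y, TM) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  tau_max <- template_max_multi(Y, TM)
  Yc <- sweep(Y, 2, colMeans(Y))
  sy <- sqrt(colSums(Yc^2))
  TMc <- sweep(TM, 2, colMeans(TM))
  st <- sqrt(colSums(TMc^2))
  R <- crossprod(Yc, TMc) / (pmax(sy, 1e-300) %o% pmax(st, 1e-300))
  tau_max + 1e-9 * apply(R, 1, max)
}

#' Rank-based template-matching score
#'
#' Maximum over a phase grid of Kendall's tau (tau-b, ties handled) between
#' the series and a cosine template `cos(2*pi*(t/period - phi))`. Rank-based,
#' hence robust to monotone distortions of the expression scale; the antiphase
#' template makes a negated oscillation score +1 when the phase grid contains
#' the opposite phase.
#'
#' @param series numeric values (>= 8 points).
#' @param times sampling times in minutes.
#' @param period template period in minutes.
#' @param phase_grid template peak phases as cycle fractions in `[0, 1)`.
#' @return score in `[-1, 1]`; an all-tied series scores 0.
#' @export
template_rank_score <- function(series, times, period,
                                phase_grid = seq(0, 15 / 16, by = 1 / 16)) {
  if (length(series) < 8)
    stop("insufficient-data error: need >= 8 time points")
  TM <- template_bank(times, period, phase_grid)
  template_max_multi(matrix(series, ncol = 1), TM)
}

## all permutations of 1..n (n <= 8), deterministic lexicographic order
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    for (j in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- c(i, rest[sub[j, ]])
    }
  }
  out
}

## derive a per-gene permutation seed from the global seed; stays < 2^31
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 7919) %% 2147483629 + 1)
}

#' Permutation p-value for a periodicity statistic
#'
#' Shuffles time-point order with a seeded generator and reports the add-one
#' permutation p-value `(1 + #[stat_perm >= stat_obs]) / (n_perm + 1)`, which
#' is never 0 and never below `1/(n_perm + 1)`. With `exact = TRUE` (series of
#' length <= 8) all `n!` orderings are enumerated instead and the p-value is
#' the exact null fraction `#[stat >= obs] / n!` (the identity ordering is
#' included, so p >= 1/n!).
#'
#' @param statistic function of `(series, times)` returning a scalar score in
#'   which larger means more periodic.
#' @param series numeric values.
#' @param times sampling times.
#' @param n_perm number of permutations (>= 99); ignored when `exact = TRUE`.
#' @param seed integer seed.
#' @param exact enumerate all orderings instead of sampling.
#' @return p-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(statistic, series, times, n_perm = 999L,
                               seed = 1L, exact = FALSE) {
  obs <- statistic(series, times)
  if (exact) {
    n <- length(series)
    if (n > 8) stop("exact enumeration limited to series of length <= 8")
    P <- all_perms(n)
    stats_all <- apply(P, 1, function(idx) statistic(series[idx], times))
    return(sum(stats_all >= obs - 1e-12) / nrow(P))
  }
  if (n_perm < 99) stop("n_perm must be >= 99")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- length(series)
  count <- 0L
  for (i in seq_len(n_perm)) {
    s <- statistic(series[sample.int(n)], times)
    if (s >= obs - 1e-12) count <- count + 1L
  }
  (1 + count) / (n_perm + 1)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment `q(i) = min_{j >= i} p_(j) * m / j`, returned in the
#' input order.
#'
#' @param p_values numeric p-values in `(0, 1]`.
#' @return q-values in `(0, 1]`, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  o <- order(p_values, decreasing = TRUE)
  q <- pmin(1, cummin(p_values[o] * m / seq(m, 1)))
  q[order(o)]
}

#' Consensus set of periodic genes
#'
#' @param per_algorithm named list mapping algorithm name to the character
#'   vector of significant gene ids.
#' @param alpha per-algorithm FDR level used for the calls.
#' @return An object of class `consensus_set` with fields `gene_ids`
#'   (the intersection), `per_algorithm`, and `alpha`. Construction asserts
#'   that `gene_ids` is contained in every per-algorithm set.
#' @export
consensus_set <- function(per_algorithm, alpha) {
  ids <- Reduce(intersect, per_algorithm)
  ids <- sort(ids)
  stopifnot(all(vapply(per_algorithm,
                       function(s) all(ids %in% s), logical(1))))
  structure(list(gene_ids = ids, per_algorithm = per_algorithm,
                 alpha = alpha),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("consensus_set: %d genes (alpha = %g; per algorithm: %s)\n",
              length(x$gene_ids), x$alpha,
              paste(sprintf("%s=%d", names(x$per_algorithm),
                            lengths(x$per_algorithm)), collapse = ", ")))
  invisible(x)
}

#' Call high-confidence periodic genes by multi-algorithm consensus
#'
#' Scores every gene with three independent rhythmicity statistics
#' (Lomb-Scargle maximum power, maximum lagged autocorrelation, maximum
#' rank-template concordance), calibrates each with a shared stream of seeded
#' time-order permutations (add-one p-values), applies Benjamini-Hochberg FDR
#' per algorithm, and intersects the per-algorithm significant sets. The
#' intersection is deliberately conservative: a gene must convince all three
#' scorers.
#'
#' @param matrix a [time_series_matrix()].
#' @param period_grid candidate periods in minutes; silently clipped to the
#'   feasible range `[2*dt, span]` of the sampling grid.
#' @param alpha per-algorithm FDR level in `(0, 1)`.
#' @param n_perm permutations per gene (>= 99).
#' @param seed global seed; per-gene permutation seeds are derived from
#'   `(seed, gene index)`.
#' @param phase_grid template peak phases for the rank-template statistic.
#' @return list with `calls` (data.frame: gene_id, algorithm, score, p_value,
#'   q_value, significant), `consensus` (a [consensus_set()]), and
#'   `not_called` (gene ids skipped for insufficient data).
#' @export
call_periodic <- function(matrix, period_grid = default_period_grid(),
                          alpha = 0.05, n_perm = 999L, seed = 1L,
                          phase_grid = seq(0, 15 / 16, by = 1 / 16)) {
  stopifnot(inherits(matrix, "time_series_matrix"),
            alpha >= 0, alpha < 1, n_perm >= 99)
  times <- matrix$times
  dt <- min(diff(times)); span <- diff(range(times))
  grid <- period_grid[period_grid >= 2 * dt - 1e-9 &
                        period_grid <= span + 1e-9]
  if (!length(grid))
    stop("period_grid has no entries within [2*dt, span]")
  n <- length(times)
  if (n < 8) stop("insufficient-data error: need >= 8 time points")
  design <- ls_design(times, grid)
  ## the caller's template bank pairs every sustained template with a
  ## damped variant (half-life 1.5 periods): synchronized populations lose
  ## synchrony, so the late cycles of a genuine oscillation shrink
  TM <- template_bank(times, grid, phase_grid, damping = c(Inf, 1.5))
  ## lags capped at n/2 so every correlation uses at least half the series;
  ## longer lags have too few overlapping points and inflate the null
  lags <- sort(unique(pmax(1L, round(grid / stats::median(diff(times))))))
  lags <- lags[lags <= floor(n / 2)]
  algs <- c("periodogram", "autocorr", "template_rank")
  G <- length(matrix$gene_ids)
  scores <- p_raw <- sapply(algs, function(a) rep(NA_real_, G),
                            simplify = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  for (g in seq_len(G)) {
    y <- matrix$values[g, ]
    set.seed(derive_seed(seed, g))
    perms <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
    Y <- cbind(y, base::matrix(y[perms], nrow = n))
    st <- list(
      periodogram = apply(ls_power_multi(Y, design), 2, max),
      autocorr = autocorr_max_multi(Y, lags),
      template_rank = template_stat_multi(Y, TM))
    for (a in algs) {
      obs <- st[[a]][1]
      scores[[a]][g] <- obs
      p_raw[[a]][g] <- (1 + sum(st[[a]][-1] >= obs - 1e-12)) / (n_perm + 1)
    }
  }
  calls <- do.call(rbind, lapply(algs, function(a) {
    q <- bh_fdr(p_raw[[a]])
    data.frame(gene_id = matrix$gene_ids, algorithm = a,
               score = scores[[a]], p_value = p_raw[[a]], q_value = q,
               significant = q <= alpha, stringsAsFactors = FALSE)
  }))
  rownames(calls) <- NULL
  per_alg <- lapply(stats::setNames(algs, algs), function(a) {
    sub <- calls[calls$algorithm == a & calls$significant, ]
    sort(sub$gene_id)
  })
  list(calls = calls, consensus = consensus_set(per_alg, alpha),
       not_called = character(0))
}

#' Estimate period and peak time for one series
#'
#' Finds the grid argmax of Lomb-Scargle power (ties broken toward the
#' shorter period), refines the period continuously over the bracketing grid
#' interval, then fits a cosine at the refined period by least squares to
#' locate the first peak time in `[0, period)`. An argmax on the grid
#' boundary is returned unrefined with `boundary = TRUE`.
#'
#' @param series numeric expression values.
#' @param times sampling times in minutes.
#' @param period_grid candidate periods in minutes.
#' @return An object of class `period_phase_estimate`: list with `period`,
#'   `peak_time`, `power`, `boundary`.
#' @export
estimate_period_phase <- function(series, times,
                                  period_grid = default_period_grid()) {
  P <- periodogram_power(series, times, period_grid)
  i <- which.max(P)           # first maximum = shortest period on ties
  boundary <- i == 1L || i == length(period_grid)
  if (boundary) {
    period <- period_grid[i]
    power <- P[[i]]
  } else {
    keep <- is.finite(series)
    y <- series[keep]; tt <- times[keep]
    f <- function(per) drop(ls_power_multi(base::matrix(y, ncol = 1),
                                           ls_design(tt, per)))
    opt <- stats::optimize(f, lower = period_grid[i - 1],
                           upper = period_grid[i + 1], maximum = TRUE,
                           tol = 1e-6)
    period <- opt$maximum
    power <- opt$objective
  }
  w <- 2 * pi / period
  keep <- is.finite(series)
  y <- series[keep]; tt <- times[keep]
  X <- cbind(1, cos(w * tt), sin(w * tt))
  beta <- stats::lm.fit(X, y)$coefficients
  peak_time <- (atan2(beta[3], beta[2]) / (2 * pi) * period) %% period
  structure(list(period = unname(period), peak_time = unname(peak_time),
                 power = unname(power), boundary = boundary),
            class = "period_phase_estimate")
}

#' Estimate periods and peak times for a set of genes
#'
#' @param matrix a [time_series_matrix()].
#' @param gene_ids genes to estimate (default: all).
#' @param period_grid candidate periods in minutes.
#' @return data.frame with columns gene_id, period, peak_time, power,
#'   boundary.
#' @export
estimate_periods <- function(matrix, gene_ids = matrix$gene_ids,
                             period_grid = default_period_grid()) {
  stopifnot(all(gene_ids %in% matrix$gene_ids))
  rows <- lapply(gene_ids, function(g) {
    e <- estimate_period_phase(matrix$values[g, ], matrix$times, period_grid)
    data.frame(gene_id = g, period = e$period, peak_time = e$peak_time,
               power = e$power, boundary = e$boundary,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
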