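CONDITIONS <- c("WT", "CDK_ON", "CDK_OFF", "REP_CHECKPOINT",
                "SPINDLE_CHECKPOINT", "REP_CHECKPOINT_RAD53OFF")
REGULONS <- c("SBF", "MBF", "SFF", "SWI5_ACE2", "OTHER")
PROGRAMS <- c("continue", "repress_after_first_peak", "persistent_high",
              "off", "one_cycle_then_repress")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Single-gene generative model
#'
#' Describes one gene's single-cell expression profile over the cell cycle and
#' its per-condition arrest program. The single-cell profile is a von
#' Mises-shaped pulse \eqn{b + a\,e^{\kappa(\cos 2\pi(\theta-\phi) - 1)}} of a
#' gene peaking at cell-cycle position \eqn{\phi}; `concentration`
#' (\eqn{\kappa}) sets pulse sharpness (0 = flat).
#'
#' @param gene_id character scalar, unique gene identifier.
#' @param baseline basal expression level `b` (expression units, >= 0).
#' @param amplitude peak height above baseline `a` (expression units, >= 0);
#'   `a = 0` makes the gene constitutive.
#' @param peak_phase cell-cycle fraction in `[0, 1)` at which the single-cell
#'   profile peaks.
#' @param concentration dimensionless sharpness `kappa >= 0`.
#' @param regulon one of `"SBF"`, `"MBF"`, `"SFF"`, `"SWI5_ACE2"`, `"OTHER"`.
#' @param programs named list mapping condition labels to arrest program
#'   labels (see [apply_arrest_program()]).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, baseline, amplitude, peak_phase,
                       concentration, regulon = "OTHER", programs = list()) {
  if (!is.character(gene_id) || length(gene_id) != 1L || !nzchar(gene_id))
    stop("invalid model: gene_id must be a non-empty string")
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("invalid model: ", nm, " must be a finite number (gene ", gene_id, ")")
    as.numeric(x)
  }
  baseline <- num1(baseline, "baseline")
  amplitude <- num1(amplitude, "amplitude")
  peak_phase <- num1(peak_phase, "peak_phase")
  concentration <- num1(concentration, "concentration")
  if (baseline < 0 || amplitude < 0 || concentration < 0)
    stop("invalid model: baseline, amplitude, concentration must be >= 0 (gene ",
         gene_id, ")")
  if (peak_phase < 0 || peak_phase >= 1)
    stop("invalid model: peak_phase must lie in [0, 1) (gene ", gene_id, ")")
  regulon <- match.arg(regulon, REGULONS)
  if (length(programs)) {
    bad <- setdiff(unlist(programs), PROGRAMS)
    if (length(bad))
      stop("configuration error: unknown program label(s): ",
           paste(bad, collapse = ", "))
  }
  structure(list(gene_id = gene_id, baseline = baseline,
                 amplitude = amplitude, peak_phase = peak_phase,
                 concentration = concentration, regulon = regulon,
                 programs = programs),
            class = "gene_model")
}

#' Population synchrony model
#'
#' An elutriation-synchronized population starts with a tight cell-cycle phase
#' distribution and desynchronizes as cells progress: phase is wrapped normal
#' with mean \eqn{\theta_0 + t/p} and standard deviation
#' \eqn{\sigma(t) = \sqrt{\sigma_0^2 + (c\,t/p)^2}} (cycle fractions).
#' Growing \eqn{\sigma(t)} damps bulk oscillation amplitude.
#'
#' @param initial_phase starting mean phase `theta0` (cycle fraction).
#' @param initial_sd starting phase sd `sigma0 >= 0` (cycle fraction).
#' @param period cell-cycle period in minutes, > 0.
#' @param dispersion_rate phase-sd growth per elapsed cycle, `c >= 0`.
#' @param bud_phase cycle fraction in `(0, 1)` at which a cell buds.
#' @return An object of class `synchrony_model`.
#' @export
synchrony_model <- function(initial_phase = 0, initial_sd = 0.05,
                            period = 100, dispersion_rate = 0.08,
                            bud_phase = 0.25) {
  vals <- c(initial_phase, initial_sd, period, dispersion_rate, bud_phase)
  if (!all(is.finite(vals)))
    stop("invalid model: synchrony parameters must be finite")
  if (initial_sd < 0 || dispersion_rate < 0)
    stop("invalid model: initial_sd and dispersion_rate must be >= 0")
  if (period <= 0) stop("invalid model: period must be > 0")
  if (bud_phase <= 0 || bud_phase >= 1)
    stop("invalid model: bud_phase must lie in (0, 1)")
  structure(list(initial_phase = initial_phase, initial_sd = initial_sd,
                 period = period, dispersion_rate = dispersion_rate,
                 bud_phase = bud_phase),
            class = "synchrony_model")
}

#' Phase standard deviation at time t
#'
#' @param sync a [synchrony_model()].
#' @param t time(s) in minutes.
#' @return sd of the population phase distribution (cycle fractions),
#'   non-decreasing in `t`.
#' @export
phase_sd <- function(sync, t) {
  sqrt(sync$initial_sd^2 + (sync$dispersion_rate * t / sync$period)^2)
}

#' Experiment design
#'
#' @param condition one of the supported condition labels.
#' @param dt sampling interval in minutes (> 0); defaults mirror the
#'   experimental designs (20- or 18-min sampling).
#' @param total_time total duration in minutes (>= dt); 300 or 360 in the
#'   reference designs.
#' @param noise_cv multiplicative measurement noise coefficient of variation,
#'   >= 0.
#' @param seed integer RNG seed.
#' @param replicate replicate index, >= 1.
#' @return An object of class `experiment_design` with a `times` field holding
#'   `floor(total_time/dt) + 1` sampling times.
#' @export
experiment_design <- function(condition = "WT", dt = 20, total_time = 360,
                              noise_cv = 0.1, seed = 1L, replicate = 1L) {
  condition <- match.arg(condition, CONDITIONS)
  if (!is.finite(dt) || dt <= 0) stop("invalid design: dt must be > 0")
  if (!is.finite(total_time) || total_time < dt)
    stop("invalid design: total_time must be >= dt")
  if (!is.finite(noise_cv) || noise_cv < 0)
    stop("invalid design: noise_cv must be >= 0")
  if (replicate < 1) stop("invalid design: replicate must be >= 1")
  times <- seq(0, by = dt, length.out = floor(total_time / dt) + 1L)
  structure(list(condition = condition, dt = dt, total_time = total_time,
                 noise_cv = noise_cv, seed = as.integer(seed),
                 replicate = as.integer(replicate), times = times),
            class = "experiment_design")
}

#' Gene-by-time expression matrix
#'
#' The central data container: one condition/replicate's bulk expression time
#' course, genes in rows, time points in columns, linear-scale arbitrary
#' expression units.
#'
#' @param values numeric matrix, genes x times.
#' @param gene_ids unique character vector, one per row.
#' @param times strictly increasing numeric vector of minutes, one per column.
#' @param condition condition label.
#' @param replicate replicate index.
#' @param scale `"linear"` (values must be finite and >= 0) or `"log2rel"`
#'   (normalized log2 ratios; sign-free).
#' @return An object of class `time_series_matrix`.
#' @export
time_series_matrix <- function(values, gene_ids, times, condition = "WT",
                               replicate = 1L, scale = c("linear", "log2rel")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (anyDuplicated(gene_ids))
    stop("input error: duplicate gene_ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (nrow(values) != length(gene_ids))
    stop("input error: row count != number of gene_ids")
  if (ncol(values) != length(times))
    stop("input error: column count != number of times")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("input error: times must be strictly increasing")
  if (!all(is.finite(values)))
    stop("input error: all values must be finite")
  if (scale == "linear" && any(values < 0))
    stop("input error: linear-scale values must be >= 0")
  dimnames(values) <- list(gene_ids, format_num(times))
  structure(list(values = values, gene_ids = as.character(gene_ids),
                 times = as.numeric(times), condition = condition,
                 replicate = as.integer(replicate), scale = scale),
            class = "time_series_matrix")
}

#' @export
print.time_series_matrix <- function(x, ...) {
  cat(sprintf("time_series_matrix: %d genes x %d time points [%s, rep %d, %s]\n",
              nrow(x$values), ncol(x$values), x$condition, x$replicate,
              x$scale))
  invisible(x)
}

#' Budding-index curve
#'
#' @param times strictly increasing minutes.
#' @param fraction_budded fraction of cells with a bud, values in `[0, 1]`.
#' @return An object of class `budding_curve`.
#' @export
budding_curve <- function(times, fraction_budded) {
  if (length(times) != length(fraction_budded))
    stop("input error: times and fraction_budded lengths differ")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("input error: times must be strictly increasing")
  if (any(fraction_budded < -1e-12 | fraction_budded > 1 + 1e-12))
    stop("input error: fraction_budded must lie in [0, 1]")
  structure(list(times = as.numeric(times),
                 fraction_budded = pmin(1, pmax(0, fraction_budded))),
            class = "budding_curve")
}

## wrapped-normal weights at quadrature nodes; mean reduced mod 1,
## 11 integer wraps cover +/- ~5 sd for sigma <= 1
wrapped_normal_weights <- function(nodes, mu, sd) {
  mu <- mu %% 1
  w <- numeric(length(nodes))
  for (k in -5:5) w <- w + stats::dnorm(nodes + k, mean = mu, sd = sd)
  w / sum(w)
}

## single-cell profile at phase theta
cell_profile <- function(theta, b, a, kappa, phi) {
  b + a * exp(kappa * (cos(2 * pi * (theta - phi)) - 1))
}

#' Population-mean expression trajectory
#'
#' Bulk signal of a desynchronizing population: the single-cell profile
#' averaged over the wrapped-normal phase distribution at each time,
#' \eqn{b + a\,E[f(\Theta_t)]}, evaluated by deterministic quadrature.
#' With perfect synchrony (`initial_sd = dispersion_rate = 0`) this equals the
#' single-cell profile at the deterministic phase; with growing phase sd the
#' bulk amplitude damps cycle by cycle.
#'
#' @param model a [gene_model()].
#' @param sync a [synchrony_model()].
#' @param t time(s) in minutes, >= 0.
#' @param nodes number of quadrature nodes over `[0, 1)` (>= 256 recommended).
#' @return numeric vector of expression values, one per element of `t`.
#' @export
mean_profile <- function(model, sync, t, nodes = 256L) {
  if (!inherits(model, "gene_model")) stop("invalid model: not a gene_model")
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  b <- model$baseline; a <- model$amplitude
  kappa <- model$concentration; phi <- model$peak_phase
  if (a == 0) return(rep(b, length(t)))
  if (kappa == 0) return(rep(b + a, length(t)))
  mu <- sync$initial_phase + t / sync$period
  sd <- phase_sd(sync, t)
  th <- (seq_len(nodes) - 0.5) / nodes
  f <- exp(kappa * (cos(2 * pi * (th - phi)) - 1))
  out <- numeric(length(t))
  for (j in seq_along(t)) {
    if (sd[j] < 1e-10) {
      out[j] <- cell_profile(mu[j], b, a, kappa, phi)
    } else {
      w <- wrapped_normal_weights(th, mu[j], sd[j])
      out[j] <- b + a * sum(w * f)
    }
  }
  out
}

## time (minutes) at which the population mean phase first hits the gene's
## peak phase; arrest onsets are defined relative to this first peak
first_peak_time <- function(model, sync) {
  ((model$peak_phase - sync$initial_phase) %% 1) * sync$period
}

#' Apply a per-condition arrest program to a gene's trajectory
#'
#' Arrest programs encode the qualitative regulon behaviors observed under CDK
#' and checkpoint arrests: `continue` (free-running oscillation),
#' `repress_after_first_peak` (one pulse, then exponential repression to
#' baseline with half-life `period/4`), `persistent_high` (one rise, then held
#' at the full single-cell peak level `b + a`), `off` (never induced, flat at
#' baseline), and `one_cycle_then_repress` (one extra full cycle before
#' repression).
#'
#' @inheritParams mean_profile
#' @param condition condition label; must have an entry in `model$programs`.
#' @return numeric vector of noiseless expression values at `t`.
#' @export
apply_arrest_program <- function(model, condition, sync, t, nodes = 256L) {
  program <- model$programs[[condition]]
  if (is.null(program))
    stop("configuration error: gene ", model$gene_id,
         " has no program for condition ", condition)
  if (!program %in% PROGRAMS)
    stop("configuration error: unknown program label: ", program)
  b <- model$baseline; a <- model$amplitude
  p <- sync$period
  t_peak <- first_peak_time(model, sync)
  t1 <- t_peak + 0.25 * p          # repression onset, quarter-cycle past peak
  half_life <- p / 4
  decay_to_b <- function(tt, t_on) {
    v_on <- mean_profile(model, sync, t_on, nodes)
    b + (v_on - b) * 2^(-(tt - t_on) / half_life)
  }
  switch(program,
    continue = mean_profile(model, sync, t, nodes),
    off = rep(b, length(t)),
    persistent_high = {
      out <- mean_profile(model, sync, t, nodes)
      out[t > t_peak] <- b + a
      out
    },
    repress_after_first_peak = {
      out <- mean_profile(model, sync, t, nodes)
      late <- t > t1
      if (any(late)) out[late] <- decay_to_b(t[late], t1)
      out
    },
    one_cycle_then_repress = {
      t2 <- t1 + p
      out <- mean_profile(model, sync, t, nodes)
      late <- t > t2
      if (any(late)) out[late] <- decay_to_b(t[late], t2)
      out
    })
}

#' Simulate one synchronized-population expression time course
#'
#' Evaluates every gene's arrest-program trajectory on the design's sampling
#' grid and applies multiplicative lognormal measurement noise with mean 1:
#' `value = trajectory * exp(eps)`, `eps ~ N(-noise_cv^2/2, noise_cv)`, drawn
#' in a fixed gene-major order from a generator seeded by
#' `(design$seed, design$replicate)` so runs are reproducible bit for bit.
#'
#' @param models list of [gene_model()] with unique ids.
#' @param sync a [synchrony_model()].
#' @param design an [experiment_design()].
#' @param nodes quadrature nodes for [mean_profile()].
#' @return A [time_series_matrix()].
#' @export
simulate_experiment <- function(models, sync, design, nodes = 256L) {
  ids <- vapply(models, function(m) m$gene_id, character(1))
  if (anyDuplicated(ids))
    stop("input error: duplicate gene_ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  times <- design$times
  traj <- t(vapply(models, function(m)
    apply_arrest_program(m, design$condition, sync, times, nodes),
    numeric(length(times))))
  if (design$noise_cv > 0) {
    cv <- design$noise_cv
    noise_seed <- as.integer((as.numeric(design$seed) + 7919 *
                                design$replicate) %% 2147483647)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(noise_seed)
    eps <- matrix(stats::rnorm(length(ids) * length(times),
                               mean = -cv^2 / 2, sd = cv),
                  nrow = length(ids), byrow = TRUE)
    traj <- traj * exp(eps)
  }
  time_series_matrix(traj, ids, times, condition = design$condition,
                     replicate = design$replicate)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a budding-index curve
#'
#' Within the first cycle the fraction budded is
#' \eqn{\Phi((\theta_0 + t/p - \theta_{bud})/\sigma(t))}. For arrest
#' conditions the curve is held at its running maximum (arrested cells keep
#' their bud); for WT the population keeps cycling, so the budded fraction is
#' the wrapped-normal probability of phase (mod 1) lying in
#' `[bud_phase, 1)` — cells divide at phase 1 and lose the bud.
#'
#' @param sync a [synchrony_model()].
#' @param design an [experiment_design()]; `design$condition == "WT"` selects
#'   the cycling variant.
#' @return A [budding_curve()].
#' @export
simulate_budding <- function(sync, design) {
  times <- design$times
  mu <- sync$initial_phase + times / sync$period
  sd <- phase_sd(sync, times)
  tb <- sync$bud_phase
  if (design$condition == "WT") {
    frac <- vapply(seq_along(times), function(j) {
      if (sd[j] < 1e-10) return(as.numeric((mu[j] %% 1) >= tb))
      k <- seq(floor(mu[j]) - 5, floor(mu[j]) + 5)
      sum(stats::pnorm((k + 1 - mu[j]) / sd[j]) -
            stats::pnorm((k + tb - mu[j]) / sd[j]))
    }, numeric(1))
    frac <- pmin(1, pmax(0, frac))
  } else {
    frac <- ifelse(sd < 1e-10, as.numeric(mu >= tb),
                   stats::pnorm((mu - tb) / pmax(sd, 1e-10)))
    frac <- cummax(pmin(1, pmax(0, frac)))
  }
  budding_curve(times, frac)
}

## regulon -> condition -> arrest program; encodes the qualitative behaviors
## of each transcription-factor regulon under each arrest
regulon_programs <- function() {
  list(
    SBF = list(WT = "continue", CDK_ON = "repress_after_first_peak",
               CDK_OFF = "continue",
               REP_CHECKPOINT = "repress_after_first_peak",
               SPINDLE_CHECKPOINT = "repress_after_first_peak",
               REP_CHECKPOINT_RAD53OFF = "continue"),
    MBF = list(WT = "continue", CDK_ON = "continue", CDK_OFF = "continue",
               REP_CHECKPOINT = "persistent_high",
               SPINDLE_CHECKPOINT = "one_cycle_then_repress",
               REP_CHECKPOINT_RAD53OFF = "continue"),
    SFF = list(WT = "continue", CDK_ON = "persistent_high",
               CDK_OFF = "continue", REP_CHECKPOINT = "persistent_high",
               SPINDLE_CHECKPOINT = "persistent_high",
               REP_CHECKPOINT_RAD53OFF = "persistent_high"),
    SWI5_ACE2 = list(WT = "continue", CDK_ON = "off", CDK_OFF = "continue",
                     REP_CHECKPOINT = "off", SPINDLE_CHECKPOINT = "off",
                     REP_CHECKPOINT_RAD53OFF = "off"),
    OTHER = list(WT = "continue", CDK_ON = "continue", CDK_OFF = "continue",
                 REP_CHECKPOINT = "continue", SPINDLE_CHECKPOINT = "continue",
                 REP_CHECKPOINT_RAD53OFF = "continue"))
}

## typical peak phases: SBF/MBF at G1/S, SFF at G2/M, Swi5-Ace2 at M/G1
regulon_phases <- c(SBF = 0.15, MBF = 0.20, SFF = 0.55, SWI5_ACE2 = 0.80)

#' Build a default scenario gene panel
#'
#' Draws a panel of gene models with regulon-typical peak phases and arrest
#' programs. Proportions default to 20% SBF, 20% MBF, 20% SFF, 10% Swi5/Ace2
#' and 30% constitutive (aperiodic) genes. Baselines and amplitudes are
#' lognormal; periodic genes swing several-fold over the cycle.
#'
#' @param n_genes number of genes.
#' @param proportions named numeric vector over the five regulon classes,
#'   summing to 1.
#' @param seed integer seed for the parameter draws.
#' @return list of [gene_model()] objects.
#' @export
scenario_gene_models <- function(n_genes = 500L,
                                 proportions = c(SBF = 0.2, MBF = 0.2,
                                                 SFF = 0.2, SWI5_ACE2 = 0.1,
                                                 OTHER = 0.3),
                                 seed = 1L) {
  stopifnot(abs(sum(proportions) - 1) < 1e-8,
            all(names(proportions) %in% REGULONS))
  counts <- floor(proportions * n_genes)
  rem <- n_genes - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  regs <- rep(names(counts), counts)
  programs <- regulon_programs()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  models <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    reg <- regs[i]
    if (reg == "OTHER") {
      models[[i]] <- gene_model(
        gene_id = sprintf("g%04d_OTHER", i),
        baseline = stats::rlnorm(1, meanlog = log(2), sdlog = 0.6),
        amplitude = 0, peak_phase = 0, concentration = 0,
        regulon = "OTHER", programs = programs$OTHER)
    } else {
      phi <- (regulon_phases[[reg]] + stats::runif(1, -0.05, 0.05)) %% 1
      models[[i]] <- gene_model(
        gene_id = sprintf("g%04d_%s", i, reg),
        baseline = stats::rlnorm(1, meanlog = log(0.5), sdlog = 0.4),
        amplitude = stats::rlnorm(1, meanlog = log(4), sdlog = 0.4),
        peak_phase = phi,
        concentration = stats::runif(1, 2, 6),
        regulon = reg, programs = programs[[reg]])
    }
  }
  models
}

## expected behavior label implied by each (program, amplitude) pair;
## ground truth for label-recovery tests
expected_label <- function(model, condition) {
  program <- model$programs[[condition]]
  if (model$amplitude == 0) return("low_flat")
  switch(program,
         continue = "oscillating",
         off = "low_flat",
         persistent_high = "persistent_high",
         repress_after_first_peak = "repressed",
         one_cycle_then_repress = "repressed")
}
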