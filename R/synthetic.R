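#' Default cohort prediction equations for synthetic subjects
#'
#' The synthetic cohort generator predicts each subject's 2-back sensitivity
#' (d') from task-state network efficiency and response speed using one linear
#' equation per age cohort. The defaults encode the study conditions this
#' package emulates: d' falls with local efficiency and with slower responding
#' in both cohorts, while global efficiency strongly helps the young cohort
#' and slightly hurts the older one.
#'
#' @return A list with elements `young` and `old`, each a named numeric vector
#'   with components `intercept`, `e_local` (per unit local efficiency),
#'   `e_global` (per unit global efficiency) and `rt` (per millisecond of mean
#'   correct RT).
#' @export
#' @examples
#' default_cohort_equations()$young
default_cohort_equations <- function() {
  list(
    young = c(intercept = 3.6708, e_local = -9.4607,
              e_global = 20.2928, rt = -0.0034),
    old   = c(intercept = 9.2047, e_local = -9.4607,
              e_global = -2.7517, rt = -0.0034)
  )
}

default_covariate_ranges <- function() {
  list(e_local_task = c(0.35, 0.50),
       e_global_task = c(0.15, 0.35),
       mean_rt = c(400, 1500),
       n_volumes_removed = c(0, 5))
}

set_seed_if_given <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop("'seed' must be a single finite number or NULL")
    }
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

#' Specification of a block-modular correlated time-series simulation
#'
#' Nodes are partitioned into `n_blocks` contiguous blocks and each node's
#' series is a weighted sum of a global latent signal, its block's latent
#' signal and independent noise:
#' `x_i = a*g + b*f_block(i) + c*eps_i` with `a^2 + b^2 + c^2 = 1`.
#' Solving `a^2 = rho_between` and `a^2 + b^2 = rho_within` makes the expected
#' pairwise Pearson correlation exactly `rho_within` inside a block and
#' `rho_between` across blocks. A constant baseline offset (arbitrary BOLD-like
#' units) gives the series a realistic nonzero mean level.
#'
#' @param n_nodes number of nodes (>= 1).
#' @param n_blocks number of modules (1 <= n_blocks <= n_nodes).
#' @param rho_within target within-block correlation, in `[0, 1)`.
#' @param rho_between target between-block correlation, `0 <= rho_between <=
#'   rho_within`.
#' @param n_frames number of frames (>= 3).
#' @param tr seconds per frame.
#' @param baseline mean signal level added to every node (arbitrary units).
#' @param seed RNG seed, or `NULL` to use the current RNG state.
#' @return An object of class `modular_series_spec`.
#' @export
modular_series_spec <- function(n_nodes, n_blocks, rho_within, rho_between,
                                n_frames, tr = 2, baseline = 1000,
                                seed = NULL) {
  if (n_nodes < 1L) stop("'n_nodes' must be >= 1")
  if (n_blocks < 1L || n_blocks > n_nodes) {
    stop("'n_blocks' must satisfy 1 <= n_blocks <= n_nodes")
  }
  if (n_frames < 3L) stop("'n_frames' must be >= 3")
  if (tr <= 0) stop("'tr' must be positive")
  if (rho_within < 0 || rho_within >= 1 || rho_between < 0) {
    stop("correlations must satisfy 0 <= rho_between <= rho_within < 1")
  }
  if (rho_between > rho_within) {
    stop("infeasible correlation pair: no factor weights give ",
         "rho_between > rho_within")
  }
  structure(list(n_nodes = as.integer(n_nodes), n_blocks = as.integer(n_blocks),
                 rho_within = rho_within, rho_between = rho_between,
                 n_frames = as.integer(n_frames), tr = tr,
                 baseline = baseline, seed = seed),
            class = "modular_series_spec")
}

#' Generate block-modular correlated time series
#'
#' Draws a `timeseries_matrix` under the latent-factor model described in
#' [modular_series_spec()]. The block assignment of each node is attached as
#' attribute `"block"` on the returned object.
#'
#' @param spec a [modular_series_spec()].
#' @return A [timeseries_matrix()] of dimension `n_nodes x n_frames`.
#' @export
#' @examples
#' ts <- generate_modular_timeseries(
#'   modular_series_spec(n_nodes = 12, n_blocks = 3, rho_within = 0.6,
#'                       rho_between = 0.1, n_frames = 200, seed = 1))
generate_modular_timeseries <- function(spec) {
  stopifnot(inherits(spec, "modular_series_spec"))
  set_seed_if_given(spec$seed)
  a <- sqrt(spec$rho_between)
  b <- sqrt(spec$rho_within - spec$rho_between)
  cw <- sqrt(1 - spec$rho_within)
  nf <- spec$n_frames
  g <- stats::rnorm(nf)
  blk_sig <- matrix(stats::rnorm(spec$n_blocks * nf), spec$n_blocks, nf)
  block <- sort(rep_len(seq_len(spec$n_blocks), spec$n_nodes))
  eps <- matrix(stats::rnorm(spec$n_nodes * nf), spec$n_nodes, nf)
  vals <- spec$baseline +
    a * matrix(g, spec$n_nodes, nf, byrow = TRUE) +
    b * blk_sig[block, , drop = FALSE] +
    cw * eps
  ts <- timeseries_matrix(vals, tr = spec$tr)
  attr(ts, "block") <- block
  ts
}

#' Generate a rigid-body motion-parameter trace
#'
#' Produces a 6-column motion table (3 translations in mm, 3 rotations in
#' radians), one row per frame, whose framewise displacement stays below
#' 0.1 mm at every transition except exactly at `spike_frames`, where a single
#' x-translation step of `spike_fd` mm is injected (and the baseline jitter of
#' that transition suppressed), so FD equals `spike_fd` there.
#'
#' A spike at frame `t` means the transition into frame `t`; valid spike
#' frames are `2..n_frames`.
#'
#' @param n_frames number of frames (>= 2).
#' @param spike_frames integer vector of frames receiving a motion spike.
#' @param spike_fd FD magnitude of each spike, in mm (>= 0).
#' @param seed RNG seed, or `NULL`.
#' @return A data frame with columns `trans_x`, `trans_y`, `trans_z` (mm) and
#'   `rot_x`, `rot_y`, `rot_z` (radians).
#' @export
#' @examples
#' m <- generate_motion_trace(60, spike_frames = c(10, 50), spike_fd = 1, seed = 1)
#' which(compute_fd(m) >= 1) + 1L   # frames 10 and 50
generate_motion_trace <- function(n_frames, spike_frames = integer(),
                                  spike_fd = 1, seed = NULL) {
  if (n_frames < 2L) stop("'n_frames' must be >= 2")
  spike_frames <- as.integer(spike_frames)
  if (length(spike_frames) &&
      (any(spike_frames < 2L) || any(spike_frames > n_frames))) {
    stop("'spike_frames' must lie in 2..n_frames ",
         "(a spike is the transition into that frame)")
  }
  if (spike_fd < 0) stop("'spike_fd' must be >= 0")
  set_seed_if_given(seed)
  nt <- n_frames - 1L
  # jitter budget: 3 * 0.005 mm + 50 mm * 3 * 1e-4 rad = 0.03 mm FD, << 0.1 mm
  deltas <- cbind(matrix(stats::runif(nt * 3, -0.005, 0.005), nt, 3),
                  matrix(stats::runif(nt * 3, -1e-4, 1e-4), nt, 3))
  if (length(spike_frames)) {
    deltas[spike_frames - 1L, ] <- 0
    deltas[spike_frames - 1L, 1L] <- spike_fd
  }
  pos <- rbind(0, apply(deltas, 2, cumsum))
  colnames(pos) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")
  as.data.frame(pos)
}

#' Specification of a simulated 2-back session
#'
#' Letters are drawn uniformly from a 20-consonant alphabet; on each scoreable
#' trial (the third onwards) a 2-back match is forced with probability
#' `target_rate`. Responses are Bernoulli: "match" with probability `hit_rate`
#' on targets and `fa_rate` on non-targets, "nonmatch" otherwise; reaction
#' times on responded trials are log-normal with the requested mean/SD in ms.
#' The first two trials can never be scored and carry no response.
#'
#' @param n_trials number of letters presented (>= 3).
#' @param target_rate fraction of scoreable trials that are 2-back matches.
#' @param hit_rate probability of a "match" response on a target trial.
#' @param fa_rate probability of a "match" response on a non-target trial.
#' @param rt_mean,rt_sd reaction-time mean and SD in milliseconds.
#' @param seed RNG seed, or `NULL`.
#' @return An object of class `nback_session_spec`.
#' @export
nback_session_spec <- function(n_trials = 100, target_rate = 0.3,
                               hit_rate = 0.9, fa_rate = 0.1,
                               rt_mean = 700, rt_sd = 150, seed = NULL) {
  rates <- c(target_rate, hit_rate, fa_rate)
  if (any(rates < 0) || any(rates > 1)) stop("rates must lie in [0, 1]")
  if (n_trials < 3L) stop("'n_trials' must be >= 3")
  if (rt_mean <= 0 || rt_sd < 0) stop("'rt_mean' must be > 0 and 'rt_sd' >= 0")
  structure(list(n_trials = as.integer(n_trials), target_rate = target_rate,
                 hit_rate = hit_rate, fa_rate = fa_rate,
                 rt_mean = rt_mean, rt_sd = rt_sd, seed = seed),
            class = "nback_session_spec")
}

nback_alphabet <- function() setdiff(LETTERS, c("A", "E", "I", "O", "U", "Y"))

#' Generate a 2-back trial log
#'
#' @param spec an [nback_session_spec()].
#' @return A data frame of trial records with columns `index`, `letter`,
#'   `is_target`, `response` (`"match"`, `"nonmatch"` or `"none"`) and `rt_ms`
#'   (`NA` when no response was given).
#' @export
#' @examples
#' trials <- generate_nback_session(nback_session_spec(n_trials = 20, seed = 1))
#' classify_trials(trials)
generate_nback_session <- function(spec) {
  stopifnot(inherits(spec, "nback_session_spec"))
  set_seed_if_given(spec$seed)
  ab <- nback_alphabet()
  n <- spec$n_trials
  letter <- character(n)
  is_target <- logical(n)
  response <- rep("none", n)
  rt <- rep(NA_real_, n)
  # log-normal parameters matched to the requested arithmetic mean/SD
  sig2 <- log(1 + (spec$rt_sd / spec$rt_mean)^2)
  mulog <- log(spec$rt_mean) - sig2 / 2
  letter[1:2] <- sample(ab, 2, replace = TRUE)
  for (t in 3:n) {
    is_target[t] <- stats::runif(1) < spec$target_rate
    letter[t] <- if (is_target[t]) letter[t - 2L] else
      sample(setdiff(ab, letter[t - 2L]), 1)
    p_match <- if (is_target[t]) spec$hit_rate else spec$fa_rate
    response[t] <- if (stats::runif(1) < p_match) "match" else "nonmatch"
    rt[t] <- stats::rlnorm(1, mulog, sqrt(sig2))
  }
  data.frame(index = seq_len(n), letter = letter, is_target = is_target,
             response = response, rt_ms = rt)
}

#' Specification of a synthetic subject cohort
#'
#' Each subject gets task-state local/global efficiency, mean correct RT and a
#' motion covariate (volumes removed), drawn within `covariate_ranges`; d' is
#' computed from the age-appropriate cohort equation plus Gaussian noise with
#' SD `noise_sd`. With `noise_sd = 0` the covariates are laid out on a
#' deterministic grid (a truncated factorial over efficiency and RT levels,
#' with the motion covariate cycling through its range) so that a refit of the
#' generating model recovers its coefficients exactly and by construction
#' avoids collinearity.
#'
#' @param n_young,n_old subjects per cohort (each >= 1). Defaults match a
#'   typical two-cohort fMRI study of 14 young and 15 older adults.
#' @param noise_sd SD of the d' noise, in d' units (>= 0).
#' @param covariate_ranges named list of `c(low, high)` bounds for
#'   `e_local_task`, `e_global_task`, `mean_rt`, `n_volumes_removed`.
#' @param equations per-cohort prediction equations, as
#'   [default_cohort_equations()].
#' @param seed RNG seed, or `NULL`.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_young = 14, n_old = 15, noise_sd = 0.3,
                        covariate_ranges = default_covariate_ranges(),
                        equations = default_cohort_equations(),
                        seed = NULL) {
  if (n_young < 1L || n_old < 1L) {
    stop("cohort must contain at least one subject per age group")
  }
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  needed <- c("e_local_task", "e_global_task", "mean_rt", "n_volumes_removed")
  if (!all(needed %in% names(covariate_ranges))) {
    stop("'covariate_ranges' must name: ", paste(needed, collapse = ", "))
  }
  for (nm in needed) {
    r <- covariate_ranges[[nm]]
    if (length(r) != 2L || r[1] >= r[2]) {
      stop("covariate range for '", nm, "' must be c(low, high) with low < high")
    }
  }
  structure(list(n_young = as.integer(n_young), n_old = as.integer(n_old),
                 noise_sd = noise_sd, covariate_ranges = covariate_ranges,
                 equations = equations, seed = seed),
            class = "cohort_spec")
}

# van der Corput radical-inverse sequence in the given prime base
radical_inverse <- function(n, base) {
  vapply(seq_len(n), function(i) {
    f <- 1
    r <- 0
    while (i > 0) {
      f <- f / base
      r <- r + f * (i %% base)
      i <- i %/% base
    }
    r
  }, numeric(1))
}

grid_covariates <- function(n, ranges) {
  # deterministic Halton layout (prime bases 2, 3, 5, 7): every covariate
  # sweeps its full range even for small n, and the columns -- including
  # their products and squares -- are not linearly dependent, so the
  # expanded candidate design stays full rank without any RNG
  span <- function(r, u) r[1] + (r[2] - r[1]) * u
  vr <- ranges$n_volumes_removed
  vol_levels <- seq(ceiling(vr[1]), floor(vr[2]))
  data.frame(
    e_local_task = span(ranges$e_local_task, radical_inverse(n, 2)),
    e_global_task = span(ranges$e_global_task, radical_inverse(n, 3)),
    mean_rt = span(ranges$mean_rt, radical_inverse(n, 5)),
    n_volumes_removed = vol_levels[
      pmin(floor(radical_inverse(n, 7) * length(vol_levels)) + 1L,
           length(vol_levels))])
}

random_covariates <- function(n, ranges) {
  draw <- function(r) stats::runif(n, r[1], r[2])
  vr <- ranges$n_volumes_removed
  data.frame(e_local_task = draw(ranges$e_local_task),
             e_global_task = draw(ranges$e_global_task),
             mean_rt = draw(ranges$mean_rt),
             n_volumes_removed = sample(seq(ceiling(vr[1]), floor(vr[2])),
                                        n, replace = TRUE))
}

#' Generate a synthetic subject cohort
#'
#' @param spec a [cohort_spec()].
#' @return A data frame with one row per subject: `subject_id`, `age_group`
#'   (0 = young, 1 = old), `e_local_task`, `e_global_task`, `mean_rt` (ms),
#'   `n_volumes_removed` and `dprime`.
#' @export
#' @examples
#' cohort <- generate_subject_cohort(cohort_spec(noise_sd = 0, seed = 1))
#' head(cohort)
generate_subject_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set_seed_if_given(spec$seed)
  one_group <- function(n, group) {
    cov <- if (spec$noise_sd == 0) grid_covariates(n, spec$covariate_ranges)
           else random_covariates(n, spec$covariate_ranges)
    eq <- spec$equations[[if (group == 0L) "young" else "old"]]
    mu <- eq[["intercept"]] + eq[["e_local"]] * cov$e_local_task +
      eq[["e_global"]] * cov$e_global_task + eq[["rt"]] * cov$mean_rt
    noise <- if (spec$noise_sd > 0) stats::rnorm(n, 0, spec$noise_sd) else 0
    cbind(data.frame(age_group = group), cov, dprime = mu + noise)
  }
  out <- rbind(one_group(spec$n_young, 0L), one_group(spec$n_old, 1L))
  out <- cbind(subject_id = sprintf("S%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}
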