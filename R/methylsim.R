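#' Langmuir hybridization parameters
#'
#' Parameters of the saturating hybridization model used by the array
#' simulator. The noiseless signal for target concentration c is
#' `baseline + saturation * c / (c + affinity)`: `baseline` is the optical
#' background (fluorescence units), `saturation` the maximum specific
#' signal above baseline, and `affinity` the half-saturation concentration
#' (same units as the concentration; with the default
#' `total_molecules = 1` in [simulate_arrays()], concentrations live on
#' the methylation-proportion scale).
#'
#' @param baseline Optical background intensity (>= 0; default 500).
#' @param saturation Maximum specific signal (>= 0; default 20000).
#' @param affinity Half-saturation concentration (> 0; default 0.5).
#' @param noise_sd SD of multiplicative log-normal probe-level noise, log
#'   scale (default 0.1).
#' @param sample_scale_sd SD of per-sample, per-channel log-normal scale
#'   factors (default 0.05). This is the "level of technical variation"
#'   knob: the two channels draw independent factors, emulating dye and
#'   scanner effects that shift a whole sample's intensity distribution.
#' @return Object of class `"langmuir_params"`.
#' @export
langmuir_params <- function(baseline = 500, saturation = 20000,
                            affinity = 0.5, noise_sd = 0.1,
                            sample_scale_sd = 0.05) {
  stopifnot(baseline >= 0, saturation >= 0, affinity > 0,
            noise_sd >= 0, sample_scale_sd >= 0)
  structure(list(baseline = baseline, saturation = saturation,
                 affinity = affinity, noise_sd = noise_sd,
                 sample_scale_sd = sample_scale_sd),
            class = "langmuir_params")
}

#' Langmuir-model hybridization intensity
#'
#' Maps target concentration to fluorescence intensity through the
#' Langmuir adsorption isotherm with optional multiplicative noise:
#' `(baseline + saturation * c / (c + affinity)) * exp(noise)`. Monotone
#' non-decreasing in the concentration at fixed noise.
#'
#' @param concentration Non-negative concentration(s).
#' @param params A [langmuir_params()].
#' @param noise Log-scale noise draw(s), default 0 (noiseless mean).
#' @return Positive intensity vector.
#' @examples
#' p <- langmuir_params()
#' langmuir_intensity(0, p)            # baseline
#' langmuir_intensity(p$affinity, p)   # baseline + saturation / 2
#' @export
langmuir_intensity <- function(concentration, params = langmuir_params(),
                               noise = 0) {
  if (any(concentration < 0)) {
    stop("concentration must be non-negative", call. = FALSE)
  }
  mu <- params$baseline +
    params$saturation * concentration / (concentration + params$affinity)
  mu * exp(noise)
}

#' Simulate ground-truth methylation for a two-group comparison
#'
#' Draws per-CpG baseline methylation proportions from a three-component
#' mixture emulating the characteristic hypo-/hemi-/hyper-methylated modes
#' of methylation arrays, then makes a uniformly chosen fraction `pi_dm`
#' of CpGs differentially methylated by shifting the second group's mean
#' by a random-signed effect.
#'
#' @param n_cpgs Number of CpG sites (>= 1).
#' @param pi_dm Proportion of differentially methylated CpGs in [0, 1];
#'   `ceiling(pi_dm * n_cpgs)` sites are shifted.
#' @param delta_range Range of the absolute effect |delta|, drawn
#'   uniformly (default c(0.2, 0.4) on the proportion scale).
#' @param modes,mode_weights,mode_sd Mixture means (default 0.1, 0.5,
#'   0.9), weights (0.4, 0.2, 0.4) and within-mode SD (0.05).
#' @param clip Truth proportions are clipped into this open interval
#'   (default c(0.02, 0.98)) so neither channel concentration vanishes.
#' @param seed Integer seed (optional; draws use the current RNG state
#'   when `NULL`).
#' @return Object of class `"methyl_truth"`: `true_beta` (n_cpgs x 2,
#'   columns = groups), `dm_mask`, `dm_delta` (achieved group-2 minus
#'   group-1 difference, 0 where not DM), `pi_dm`, `cpg_ids`.
#' @export
simulate_truth <- function(n_cpgs, pi_dm, delta_range = c(0.2, 0.4),
                           modes = c(0.1, 0.5, 0.9),
                           mode_weights = c(0.4, 0.2, 0.4),
                           mode_sd = 0.05, clip = c(0.02, 0.98),
                           seed = NULL) {
  if (n_cpgs < 1L) stop("n_cpgs must be >= 1", call. = FALSE)
  if (!is.numeric(pi_dm) || pi_dm < 0 || pi_dm > 1) {
    stop("pi_dm must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(length(modes), n_cpgs, replace = TRUE,
                     prob = mode_weights)
  base <- pmin(pmax(modes[comp] + stats::rnorm(n_cpgs, 0, mode_sd),
                    clip[1L]), clip[2L])
  beta2 <- base
  n_dm <- as.integer(ceiling(pi_dm * n_cpgs))
  dm_mask <- rep(FALSE, n_cpgs)
  if (n_dm > 0L) {
    dm_idx <- sample.int(n_cpgs, n_dm)
    dm_mask[dm_idx] <- TRUE
    delta <- stats::runif(n_dm, delta_range[1L], delta_range[2L]) *
      sample(c(-1, 1), n_dm, replace = TRUE)
    beta2[dm_idx] <- pmin(pmax(base[dm_idx] + delta, clip[1L]), clip[2L])
  }
  true_beta <- cbind(group1 = base, group2 = beta2)
  structure(
    list(true_beta = true_beta, dm_mask = dm_mask,
         dm_delta = beta2 - base, pi_dm = pi_dm,
         cpg_ids = sprintf("cpg_%d", seq_len(n_cpgs))),
    class = "methyl_truth")
}

#' Beta values from channel intensities
#'
#' Illumina-style methylation proportion estimate
#' `meth / (meth + unmeth + offset)`; the platform-default offset of 100
#' keeps the denominator positive and shrinks low-intensity estimates.
#'
#' @param meth,unmeth Positive intensity matrices or vectors.
#' @param offset Non-negative offset (default 100).
#' @return Values in [0, 1).
#' @export
beta_values <- function(meth, unmeth, offset = 100) {
  meth / (meth + unmeth + offset)
}

#' Simulate two-group methylation microarrays
#'
#' Hybridizes ground-truth methylation through the Langmuir model. Per
#' sample, each CpG's methylated-channel concentration is
#' `total_molecules * beta` and the unmethylated channel gets the
#' complement, where `beta` adds per-sample biological jitter around the
#' group truth. Both channels pass through [langmuir_intensity()] with a
#' per-sample per-channel log-normal scale factor
#' (`sd = sample_scale_sd`) and probe-level log-normal noise
#' (`sd = noise_sd`); observed beta values use [beta_values()] with the
#' default offset 100.
#'
#' @param truth A [simulate_truth()] result.
#' @param n_per_group Samples per group (default 5, i.e. 2 x 5 = 10
#'   arrays).
#' @param total_molecules Total target molecules per CpG (concentration
#'   units; default 1, putting concentrations on the proportion scale).
#' @param params A [langmuir_params()].
#' @param bio_sd SD of per-sample biological jitter on the proportion
#'   scale (default 0.01).
#' @param seed Integer seed (optional).
#' @return Object of class `"sim_array_set"`: `meth`, `unmeth`,
#'   `beta_observed` (n_cpgs x n_T matrices), `groups` (factor), `truth`,
#'   `params`, `offset`, `seed`.
#' @export
simulate_arrays <- function(truth, n_per_group = 5L, total_molecules = 1,
                            params = langmuir_params(), bio_sd = 0.01,
                            seed = NULL) {
  stopifnot(inherits(truth, "methyl_truth"), inherits(params, "langmuir_params"))
  if (n_per_group < 2L) stop("n_per_group must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth$true_beta)
  k <- ncol(truth$true_beta)
  n_t <- k * n_per_group
  groups <- factor(rep(colnames(truth$true_beta), each = n_per_group))
  meth <- unmeth <- matrix(NA_real_, n, n_t)
  for (j in seq_len(n_t)) {
    g <- as.integer(groups)[j]
    beta_j <- truth$true_beta[, g]
    if (bio_sd > 0) {
      beta_j <- pmin(pmax(beta_j + stats::rnorm(n, 0, bio_sd), 0), 1)
    }
    scale_m <- stats::rnorm(1, 0, params$sample_scale_sd)
    scale_u <- stats::rnorm(1, 0, params$sample_scale_sd)
    noise_m <- if (params$noise_sd > 0) stats::rnorm(n, 0, params$noise_sd) else 0
    noise_u <- if (params$noise_sd > 0) stats::rnorm(n, 0, params$noise_sd) else 0
    meth[, j] <- langmuir_intensity(total_molecules * beta_j, params,
                                    noise = noise_m + scale_m)
    unmeth[, j] <- langmuir_intensity(total_molecules * (1 - beta_j), params,
                                      noise = noise_u + scale_u)
  }
  ids <- sprintf("%s_s%d", groups, rep(seq_len(n_per_group), times = k))
  dimnames(meth) <- dimnames(unmeth) <- list(truth$cpg_ids, ids)
  structure(
    list(meth = meth, unmeth = unmeth,
         beta_observed = beta_values(meth, unmeth),
         groups = groups, truth = truth, params = params,
         offset = 100, seed = seed),
    class = "sim_array_set")
}

#' @export
print.sim_array_set <- function(x, ...) {
  cat(sprintf(
    "sim_array_set: %d CpGs x %d samples (%d per group), pi_dm = %g\n",
    nrow(x$beta_observed), ncol(x$beta_observed),
    ncol(x$beta_observed) / nlevels(x$groups), x$truth$pi_dm))
  invisible(x)
}
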