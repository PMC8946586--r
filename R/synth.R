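#' Configuration for the synthetic two-group cohort generator
#'
#' The generator emulates the statistical structure the downstream
#' analysis consumes: per-subject regions x timepoints BOLD-like
#' signals whose band-wise Pearson correlation structure is fully
#' controllable. Each region is a sum over frequency bands of a shared
#' band-limited module signal (white noise filtered into the band,
#' standardized, and scaled by that band's coupling) plus broadband
#' white noise. No hemodynamic, head-motion, or scanner-noise modelling
#' is attempted: the analysis only reads band-wise correlations.
#'
#' The default cohort matches the reference study design: 90 regions,
#' 142 retained volumes at TR = 2 s, 69 controls (TD) and 50 patients
#' (SCHZ). Patient symptom scores default to SAPS mean 30.92 (SD 21.04)
#' and SANS mean 35.9 (SD 19.21), truncated at zero.
#'
#' Planted group effects act on `effect_nodes` in patients only:
#'
#' * `degree_rebalance`: at baseline (controls, and patients at
#'   `effect_size = 0`) an effect node shares module signal only in its
#'   "home" bands (the lower half of the band list), concentrating its
#'   links there and depressing its EMD; in patients the coupling of
#'   the remaining bands is restored in proportion to `effect_size`, so
#'   links spread evenly over layers and expected EMD rises.
#'   `effect_size = 1` is the documented strong setting (full
#'   rebalance); 0.5 is moderate.
#' * `coupling_shift`: patient coupling amplitudes at the effect nodes
#'   are multiplied by `1 + effect_size` in every band.
#'
#' Per-patient effect heterogeneity (a multiplier drawn uniformly from
#' \[0.4, 1\]) scales the planted effect, and symptom scores are drawn
#' as `baseline + score_coupling * (effect_size * multiplier) + noise`,
#' so score--metric correlation recovery is testable.
#'
#' @param n_regions number of parcellated regions (default 90).
#' @param n_timepoints retained volumes per subject (default 142).
#' @param tr_seconds repetition time in seconds (default 2).
#' @param n_controls,n_patients group sizes (defaults 69 and 50).
#' @param bands band table (default [multiplex_bands()], lowest first).
#' @param band_communities list of per-band integer membership vectors
#'   of length `n_regions` (module id, or 0 for a singleton region with
#'   no shared signal in that band); default
#'   [default_band_communities()].
#' @param within_module_coupling per-band amplitude of the shared
#'   module signal (recycled; default 1).
#' @param noise_sd standard deviation of the broadband white noise
#'   added to every region (default 1).
#' @param effect_nodes integer region indices receiving the planted
#'   group effect (default none).
#' @param effect_type `"degree_rebalance"` or `"coupling_shift"`.
#' @param effect_size unitless effect magnitude (default 0; 1 = strong).
#' @param score_coupling slope linking the planted effect proxy to the
#'   symptom scores (default 0).
#' @param score_noise_sd standard deviation of symptom-score noise; a
#'   single value used for both scores, or `NULL` (default) for the
#'   reference SDs (SANS 19.21, SAPS 21.04).
#' @param seed integer RNG seed for cohort generation.
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_regions = 90L, n_timepoints = 142L, tr_seconds = 2,
                         n_controls = 69L, n_patients = 50L,
                         bands = multiplex_bands(),
                         band_communities = NULL,
                         within_module_coupling = 1,
                         noise_sd = 1,
                         effect_nodes = integer(0),
                         effect_type = c("degree_rebalance", "coupling_shift"),
                         effect_size = 0,
                         score_coupling = 0,
                         score_noise_sd = NULL,
                         seed = 1L) {
  effect_type <- match.arg(effect_type)
  if (n_regions < 3) stop("n_regions must be at least 3")
  if (n_timepoints < 30) stop("n_timepoints must be at least 30")
  if (length(effect_nodes) && any(effect_nodes > n_regions | effect_nodes < 1)) {
    stop("effect_nodes must be region indices in 1..n_regions")
  }
  m <- nrow(bands)
  if (is.null(band_communities)) {
    band_communities <- default_band_communities(n_regions, n_bands = m)
  }
  if (length(band_communities) != m) {
    stop("band_communities must supply one partition per band (",
         m, " bands, got ", length(band_communities), ")")
  }
  for (b in seq_len(m)) {
    part <- band_communities[[b]]
    if (length(part) != n_regions || anyNA(part) || any(part < 0) ||
        any(part != floor(part))) {
      stop("band ", bands$name[b], ": partition must assign every region ",
           "exactly one nonnegative integer module id")
    }
  }
  # the slowest band must fit at least 2 cycles of its low edge
  min_low <- min(bands$low_hz)
  if (n_timepoints * tr_seconds < 2 / min_low) {
    stop(sprintf(
      "n_timepoints = %d at TR = %gs spans %.0fs < 2 cycles (%.0fs) of the lowest band edge %g Hz",
      n_timepoints, tr_seconds, n_timepoints * tr_seconds, 2 / min_low, min_low))
  }
  within_module_coupling <- rep_len(within_module_coupling, m)
  if (is.null(score_noise_sd)) {
    score_noise_sd <- c(sans = 19.21, saps = 21.04)
  } else {
    score_noise_sd <- c(sans = score_noise_sd[[1]],
                        saps = score_noise_sd[[length(score_noise_sd)]])
  }
  structure(
    list(n_regions = as.integer(n_regions),
         n_timepoints = as.integer(n_timepoints),
         tr_seconds = tr_seconds,
         n_controls = as.integer(n_controls),
         n_patients = as.integer(n_patients),
         bands = bands,
         band_communities = band_communities,
         within_module_coupling = within_module_coupling,
         noise_sd = noise_sd,
         effect_nodes = as.integer(effect_nodes),
         effect_type = effect_type,
         effect_size = effect_size,
         score_coupling = score_coupling,
         score_noise_sd = score_noise_sd,
         score_baseline = c(sans = 35.9, saps = 30.92),
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Default per-band module partitions
#'
#' Splits the regions into contiguous modules of roughly `module_size`
#' regions, cyclically shifting the block boundaries from band to band
#' so that no two bands share the same partition. Every region belongs
#' to exactly one module in every band.
#'
#' @param n_regions number of regions.
#' @param n_bands number of bands (default 4).
#' @param module_size target module size (default 15, giving six
#'   modules for 90 regions).
#' @return List of integer membership vectors, one per band.
#' @export
default_band_communities <- function(n_regions, n_bands = 4L, module_size = 15L) {
  n_modules <- max(2L, round(n_regions / module_size))
  shift_step <- max(1L, floor(n_regions / (n_modules * n_bands)))
  lapply(seq_len(n_bands), function(b) {
    shifted <- (seq_len(n_regions) - 1 + (b - 1) * shift_step) %% n_regions
    shifted %/% ceiling(n_regions / n_modules) + 1L
  })
}

#' Synthesize one subject's time series
#'
#' Draws one regions x timepoints matrix under a [synth_config()]. For
#' each band, each module's latent signal is white noise filtered into
#' the band and standardized; a region's series is the coupling-weighted
#' sum of its module latents across bands plus broadband white noise.
#' Patients (`group = "SCHZ"`) receive the configured planted effect at
#' the effect nodes, scaled by `effect_multiplier`.
#'
#' The draw consumes the current R RNG stream; pass `seed` for a
#' self-contained deterministic draw.
#'
#' @param config a `synth_config`.
#' @param group `"TD"` or `"SCHZ"`.
#' @param effect_multiplier per-subject effect heterogeneity (default 1).
#' @param seed optional integer seed.
#' @return regions x timepoints numeric matrix with region row names.
#' @export
synthesize_subject <- function(config, group = c("TD", "SCHZ"),
                               effect_multiplier = 1, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  group <- match.arg(group)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_regions
  tp <- config$n_timepoints
  m <- nrow(config$bands)
  coupling <- coupling_matrix(config, group, effect_multiplier)

  x <- matrix(0, n, tp, dimnames = list(sprintf("R%03d", seq_len(n)), NULL))
  for (b in seq_len(m)) {
    memb <- config$band_communities[[b]]
    for (k in sort(unique(memb[memb > 0]))) {
      latent <- bandpass(stats::rnorm(tp), config$bands$low_hz[b],
                         config$bands$high_hz[b], config$tr_seconds)
      s <- stats::sd(latent)
      if (s > 0) latent <- latent / s
      members <- which(memb == k)
      active <- members[coupling[members, b] != 0]
      for (r in active) x[r, ] <- x[r, ] + coupling[r, b] * latent
    }
  }
  x + config$noise_sd * matrix(stats::rnorm(n * tp), n, tp)
}

# Per-region, per-band coupling amplitudes, with the planted effect
# carved in. Effect nodes keep shared signal only in the lower half of
# the bands at baseline; degree_rebalance restores the upper half for
# patients in proportion to effect_size * effect_multiplier.
coupling_matrix <- function(config, group, effect_multiplier) {
  n <- config$n_regions
  m <- nrow(config$bands)
  coupling <- matrix(rep(config$within_module_coupling, each = n), n, m)
  for (b in seq_len(m)) coupling[config$band_communities[[b]] == 0, b] <- 0
  eff <- config$effect_nodes
  if (!length(eff)) return(coupling)
  if (config$effect_type == "degree_rebalance") {
    home <- seq_len(ceiling(m / 2))
    away <- setdiff(seq_len(m), home)
    if (group == "TD") {
      coupling[eff, away] <- 0
    } else {
      scale <- min(1, config$effect_size * effect_multiplier)
      coupling[eff, away] <- coupling[eff, away] * scale
    }
  } else if (group == "SCHZ") {
    coupling[eff, ] <- coupling[eff, ] * (1 + config$effect_size * effect_multiplier)
  }
  coupling
}

#' Synthesize a two-group cohort
#'
#' Generates `n_controls + n_patients` subjects (controls first),
#' reproducibly from `config$seed`. Patient symptom scores (SANS,
#' SAPS) are drawn around the configured baselines with slope
#' `score_coupling` on the planted effect proxy
#' (`effect_size * multiplier`) and truncated at zero; controls carry
#' no scores (`NA`).
#'
#' @param config a `synth_config`.
#' @return Object of class `synth_cohort`: list with `config`,
#'   `manifest` (data.frame: `subject_id`, `group`, `sans`, `saps`),
#'   and `series` (named list of regions x timepoints matrices).
#' @export
synthesize_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n_sub <- config$n_controls + config$n_patients
  groups <- rep(c("TD", "SCHZ"), c(config$n_controls, config$n_patients))
  ids <- sprintf("sub-%03d", seq_len(n_sub))
  subject_seeds <- sample.int(.Machine$integer.max, n_sub)
  mult <- stats::runif(n_sub, 0.4, 1.0)
  proxy <- ifelse(groups == "SCHZ", config$effect_size * mult, NA_real_)
  sans <- saps <- rep(NA_real_, n_sub)
  is_p <- groups == "SCHZ"
  sans[is_p] <- pmax(0, config$score_baseline[["sans"]] +
                       config$score_coupling * proxy[is_p] +
                       stats::rnorm(sum(is_p), 0, config$score_noise_sd[["sans"]]))
  saps[is_p] <- pmax(0, config$score_baseline[["saps"]] +
                       config$score_coupling * proxy[is_p] +
                       stats::rnorm(sum(is_p), 0, config$score_noise_sd[["saps"]]))
  series <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    series[[i]] <- synthesize_subject(config, groups[i],
                                      effect_multiplier = mult[i],
                                      seed = subject_seeds[i])
  }
  names(series) <- ids
  manifest <- data.frame(subject_id = ids, group = groups,
                         sans = sans, saps = saps,
                         stringsAsFactors = FALSE)
  structure(list(config = config, manifest = manifest, series = series),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("synth_cohort: %d subjects (%d TD, %d SCHZ), %d regions x %d timepoints, TR %gs\n",
              nrow(x$manifest), sum(x$manifest$group == "TD"),
              sum(x$manifest$group == "SCHZ"),
              x$config$n_regions, x$config$n_timepoints, x$config$tr_seconds))
  invisible(x)
}
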