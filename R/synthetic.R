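# Ground-truth-known simulator for factorial cultivation experiments:
# lag + logistic biomass rise to a peak followed by exponential decline,
# sigmoidal lipid accumulation, a Gaussian fucoxanthin bump, multiplicative
# replicate noise, and exact inverses for the analysis chain (absorbance
# records, target-ADU fatty-acid profiles).

# Evaluate a seeded expression without disturbing the caller's RNG stream.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

#' Configuration of a synthetic cultivation experiment
#'
#' Ground-truth parameters for [simulate_culture_experiment()]. Defaults
#' emulate a two-condition diatom batch-cultivation study: triplicates
#' sampled on days 0, 2, 4, 6, 8, 10; a 2-day lag; a logistic rise peaking
#' on day 8 followed by a 2 %/day decline; and 5 % relative measurement
#' noise. The default treatments contrast a control F/2-style culture
#' (carrying capacity 0.86 g/L) with an optimized medium (1.6 g/L), with
#' lipid plateaus of 252.8 vs 539.25 mg/g DW and fucoxanthin peaks of 4.04
#' vs 20.44 mg/g DW.
#'
#' @param treatments Data frame with columns `label`, `K` (carrying
#'   capacity, g/L), `r` (logistic steepness, /day), `lag` (days),
#'   `peak_day` (day the trajectory attains `K`), `decline_rate` (/day,
#'   post-peak exponential decay), `lipid_baseline`, `lipid_plateau` (mg/g
#'   DW), `lipid_midpoint` (day), `fx_peak` (mg/g DW), `fx_peak_day` (day),
#'   `fx_width` (days).
#' @param inoculum Starting biomass, g/L.
#' @param replicates Replicates per treatment.
#' @param sampling_days Days sampled.
#' @param noise Named relative SDs of the multiplicative log-normal
#'   measurement noise for `od750`, `dw`, `lipid`, `fx` (0 = noiseless).
#' @param od_per_g Dry weight (g/L) per OD750 unit, used only to derive the
#'   OD channel from biomass.
#' @param seed Integer seed; the whole experiment is reproducible from it.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(treatments = NULL,
                       inoculum = 0.1,
                       replicates = 3,
                       sampling_days = c(0, 2, 4, 6, 8, 10),
                       noise = c(od750 = 0.05, dw = 0.05, lipid = 0.05,
                                 fx = 0.05),
                       od_per_g = 0.5,
                       seed = 1L) {
  if (is.null(treatments)) {
    treatments <- data.frame(
      label = c("control", "optimized"),
      K = c(0.86, 1.6), r = c(1.0, 1.0), lag = c(2, 2),
      peak_day = c(8, 8), decline_rate = c(0.02, 0.02),
      lipid_baseline = c(120, 120), lipid_plateau = c(252.8, 539.25),
      lipid_midpoint = c(5, 5),
      fx_peak = c(4.04, 20.44), fx_peak_day = c(8, 8), fx_width = c(3, 3),
      stringsAsFactors = FALSE)
  }
  problems <- character(0)
  need <- c("label", "K", "r", "lag", "peak_day", "decline_rate",
            "lipid_baseline", "lipid_plateau", "lipid_midpoint",
            "fx_peak", "fx_peak_day", "fx_width")
  absent <- setdiff(need, names(treatments))
  if (length(absent)) {
    problems <- c(problems, paste("treatments missing columns:",
                                  paste(absent, collapse = ", ")))
  } else {
    if (any(treatments$K <= inoculum)) {
      problems <- c(problems, "every K must exceed the inoculum")
    }
    if (any(treatments$peak_day <= treatments$lag)) {
      problems <- c(problems, "peak_day must exceed lag")
    }
    if (any(treatments$decline_rate < 0) || any(treatments$fx_width <= 0)) {
      problems <- c(problems, "decline_rate >= 0 and fx_width > 0 required")
    }
  }
  if (replicates < 1) problems <- c(problems, "replicates must be >= 1")
  if (any(sampling_days < 0) || is.unsorted(sampling_days, strictly = TRUE)) {
    problems <- c(problems,
                  "sampling_days must be non-negative and strictly increasing")
  }
  if (any(noise < 0)) problems <- c(problems, "noise SDs must be >= 0")
  if (!all(c("od750", "dw", "lipid", "fx") %in% names(noise))) {
    problems <- c(problems, "noise needs elements od750, dw, lipid, fx")
  }
  if (inoculum <= 0) problems <- c(problems, "inoculum must be positive")
  if (length(problems)) {
    stop("invalid simulation config:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  structure(list(treatments = treatments, inoculum = inoculum,
                 replicates = as.integer(replicates),
                 sampling_days = as.numeric(sampling_days),
                 noise = noise, od_per_g = od_per_g,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Noiseless trajectories for one treatment row at times t.
.true_biomass <- function(t, tr, inoculum) {
  logis <- function(tt) stats::plogis(tr$r * (tt - (tr$lag + tr$peak_day) / 2))
  l0 <- logis(tr$lag); l1 <- logis(tr$peak_day)
  out <- numeric(length(t))
  pre <- t <= tr$lag
  rise <- t > tr$lag & t <= tr$peak_day
  post <- t > tr$peak_day
  out[pre] <- inoculum
  out[rise] <- inoculum + (tr$K - inoculum) * (logis(t[rise]) - l0) / (l1 - l0)
  out[post] <- tr$K * exp(-tr$decline_rate * (t[post] - tr$peak_day))
  out
}

.true_lipid <- function(t, tr) {
  tr$lipid_baseline + (tr$lipid_plateau - tr$lipid_baseline) *
    stats::plogis(1.2 * (t - tr$lipid_midpoint))
}

.true_fx <- function(t, tr) {
  tr$fx_peak * exp(-(t - tr$fx_peak_day)^2 / (2 * tr$fx_width^2))
}

#' Simulate a factorial cultivation experiment
#'
#' Generates replicate-level culture time series from the ground truth of a
#' [sim_config()]: biomass follows an inoculum-anchored lag phase, a
#' logistic rise that attains the carrying capacity exactly on the peak day,
#' then exponential decline; lipid content follows a sigmoid in time;
#' fucoxanthin follows a Gaussian bump centred on its peak day. Measurement
#' noise is multiplicative log-normal (`x * exp(rnorm(., 0, sd))`), applied
#' independently per observation, so all channels stay positive and
#' replicate scatter scales with the mean. The same config and seed always
#' regenerate identical data.
#'
#' @param config A [sim_config()].
#' @return A list with `data` (a [culture_ts()]) and `truth`: the noiseless
#'   `trajectories` per treatment/day, and `productivity` -- the true
#'   biomass productivity (mg/L/day) of each treatment over
#'   (first sampling day, peak day).
#' @examples
#' sim <- simulate_culture_experiment(sim_config(seed = 42))
#' head(sim$data)
#' sim$truth$productivity
#' @export
simulate_culture_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  days <- config$sampling_days
  trs <- config$treatments
  truth_traj <- do.call(rbind, lapply(seq_len(nrow(trs)), function(i) {
    tr <- trs[i, ]
    data.frame(treatment = tr$label, day = days,
               dw_g_per_l = .true_biomass(days, tr, config$inoculum),
               lipid_mg_per_g = .true_lipid(days, tr),
               fx_mg_per_g = .true_fx(days, tr),
               stringsAsFactors = FALSE)
  }))
  truth_traj$od750 <- truth_traj$dw_g_per_l / config$od_per_g

  true_prod <- vapply(seq_len(nrow(trs)), function(i) {
    tr <- trs[i, ]
    b <- .true_biomass(c(min(days), tr$peak_day), tr, config$inoculum)
    (b[2] - b[1]) * 1000 / (tr$peak_day - min(days))
  }, 0)
  names(true_prod) <- trs$label

  data <- .with_seed(config$seed, {
    rows <- list()
    for (i in seq_len(nrow(trs))) {
      tr_label <- trs$label[i]
      base <- truth_traj[truth_traj$treatment == tr_label, ]
      for (rep_i in seq_len(config$replicates)) {
        jitter <- function(x, sd) {
          if (sd == 0) x else x * exp(stats::rnorm(length(x), 0, sd))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          treatment = tr_label, replicate = paste0("R", rep_i),
          day = base$day,
          od750 = jitter(base$od750, config$noise[["od750"]]),
          dw_g_per_l = jitter(base$dw_g_per_l, config$noise[["dw"]]),
          lipid_mg_per_g = jitter(base$lipid_mg_per_g, config$noise[["lipid"]]),
          fx_mg_per_g = jitter(base$fx_mg_per_g, config$noise[["fx"]]),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  rownames(data) <- NULL
  list(data = culture_ts(data),
       truth = list(trajectories = truth_traj, productivity = true_prod,
                    config = config))
}

#' Simulate a fatty-acid profile with an exact target ADU
#'
#' Draws a random composition on the simplex over an acid pool (Dirichlet
#' via normalised gamma draws), scaled to a configurable identified total,
#' then mixes it linearly with the extreme composition concentrated on the
#' pool's least- or most-unsaturated acid so the mass-weighted double-bond
#' count equals `target_adu` exactly (ADU is linear in composition).
#'
#' @param condition Label for the generated profile.
#' @param target_adu Desired average degree of unsaturation.
#' @param acid_pool Character vector of shorthand codes (default: the acids
#'   of the packaged reference table).
#' @param identified_total Sum of percentages, default 95 (GC-MS tables
#'   rarely identify 100 % of the signal).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return An [fa_profile()] whose [adu()] equals `target_adu` to 1e-9.
#' @export
simulate_fa_profile <- function(condition, target_adu,
                                acid_pool = c("C14:0", "C16:0", "C18:0",
                                              "C20:0", "C16:1t", "C18:1(n-9)",
                                              "C18:2(n-6)", "C18:3(n-6)",
                                              "C20:5n3", "C20:3n3", "C18:3n3"),
                                identified_total = 95, seed = NULL) {
  stopifnot(identified_total > 0, identified_total <= 100)
  db <- vapply(lapply(acid_pool, parse_fatty_acid), `[[`, 0L, "double_bonds")
  total_frac <- identified_total / 100
  lo <- min(db) * total_frac
  hi <- max(db) * total_frac
  if (target_adu < lo - 1e-12 || target_adu > hi + 1e-12) {
    stop(sprintf("target ADU %.4g infeasible for this pool: achievable range [%.4g, %.4g]",
                 target_adu, lo, hi))
  }
  pct <- .with_seed(seed, {
    w <- stats::rgamma(length(acid_pool), shape = 1)
    w <- w / sum(w)
    p <- w * identified_total
    a0 <- sum(db * p) / 100
    if (abs(a0 - target_adu) > 1e-15) {
      extreme_idx <- if (target_adu > a0) which.max(db) else which.min(db)
      p_ext <- numeric(length(p))
      p_ext[extreme_idx] <- identified_total
      a_ext <- db[extreme_idx] * total_frac
      lambda <- (target_adu - a0) / (a_ext - a0)
      p <- (1 - lambda) * p + lambda * p_ext
    }
    p
  })
  fa_profile(sample_id = condition, condition = condition,
             fatty_acid = acid_pool, percent = pct)
}

#' Simulate an absorbance record for a known fucoxanthin content
#'
#' Inverts the dual-wavelength quantification: given the true content, the
#' extracted mass, the extract volume and a chlorophyll absorbance, solves
#' `A445 = (fx * m / V + 5.18 A663) / 6.39` and adds optional Gaussian
#' noise. At zero noise, [fucoxanthin_content()] applied to the record
#' returns `true_fx` exactly.
#'
#' @param true_fx True fucoxanthin content, mg/g DW.
#' @param biomass_g Dry mass extracted, g.
#' @param extract_volume_l Extract volume, L.
#' @param a663 Chlorophyll absorbance at 663 nm.
#' @param noise_sd Additive SD on A445 (absorbance units).
#' @param seed Integer seed, or `NULL`.
#' @return A list of class `"extract_reading"`: `a445`, `a663`,
#'   `biomass_g`, `extract_volume_l`.
#' @export
simulate_absorbance <- function(true_fx, biomass_g, extract_volume_l, a663,
                                noise_sd = 0, seed = NULL) {
  stopifnot(true_fx >= 0, biomass_g > 0, extract_volume_l > 0, a663 >= 0,
            noise_sd >= 0)
  a445 <- (true_fx * biomass_g / extract_volume_l + 5.18 * a663) / 6.39
  a445 <- .with_seed(seed, a445 + if (noise_sd > 0) {
    stats::rnorm(1, 0, noise_sd)
  } else 0)
  if (a445 < 0) {
    stop("infeasible: generated A445 would be negative")
  }
  structure(list(a445 = a445, a663 = a663, biomass_g = biomass_g,
                 extract_volume_l = extract_volume_l),
            class = "extract_reading")
}

#' @export
print.extract_reading <- function(x, ...) {
  cat(sprintf("<extract_reading> A445 %.4f  A663 %.4f  (%.4g g DW in %.4g L)\n",
              x$a445, x$a663, x$biomass_g, x$extract_volume_l))
  invisible(x)
}
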