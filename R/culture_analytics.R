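# Analytics for cultivation experiments: fucoxanthin quantification from
# extract absorbances, volumetric productivities, growth-curve features, and
# treatment comparison (ANOVA / Welch t-test with Tukey HSD letters).

#' Fucoxanthin content from dual-wavelength extract absorbances
#'
#' Fucoxanthin in an ethanol extract is quantified from the absorbance at
#' 445 nm (fucoxanthin maximum) corrected for chlorophyll interference at
#' 663 nm: the concentration term `6.39 A445 - 5.18 A663` is interpreted as
#' mg fucoxanthin per litre of extract (1 cm path), multiplied by the
#' extract volume and divided by the dry mass extracted to give mg per g DW.
#' A negative concentration term (chlorophyll-dominated extract) is clamped
#' to zero with a warning.
#'
#' The extract volume must be given explicitly, either in litres or via the
#' extraction ratio actually used at the bench (`ml_per_mg`, millilitres of
#' solvent per milligram of biomass; a 1:4 mg:mL extraction is
#' `ml_per_mg = 4`).
#'
#' @param a445,a663 Absorbances at 445 and 663 nm (>= 0).
#' @param biomass_g Dry mass extracted, g (> 0).
#' @param extract_volume_l Extract volume, L.
#' @param ml_per_mg Alternative to `extract_volume_l`: solvent-to-biomass
#'   ratio, mL per mg DW.
#' @return Fucoxanthin content, mg per g DW.
#' @examples
#' fucoxanthin_content(1.0, 0.5, biomass_g = 0.010, extract_volume_l = 0.004)
#' @export
fucoxanthin_content <- function(a445, a663, biomass_g,
                                extract_volume_l = NULL, ml_per_mg = NULL) {
  if (any(a445 < 0) || any(a663 < 0)) stop("absorbances must be non-negative")
  if (any(biomass_g <= 0)) stop("'biomass_g' must be positive")
  if (is.null(extract_volume_l)) {
    if (is.null(ml_per_mg)) {
      stop("give the extract volume: 'extract_volume_l' or 'ml_per_mg'")
    }
    extract_volume_l <- biomass_g * 1000 * ml_per_mg / 1000
  }
  if (any(extract_volume_l <= 0)) stop("extract volume must be positive")
  conc <- 6.39 * a445 - 5.18 * a663   # mg/L of extract
  if (any(conc < 0)) {
    warning("negative fucoxanthin concentration term clamped to 0 ",
            "(chlorophyll-dominated extract)")
    conc <- pmax(conc, 0)
  }
  conc * extract_volume_l / biomass_g
}

#' Volumetric productivity over a cultivation window
#'
#' `P = (C2 - C1) / (t2 - t1)` in mg/L/day. The sign is kept: a declining
#' culture yields a negative rate.
#'
#' @param c1,c2 Concentrations at the window ends, mg/L.
#' @param t1,t2 Window ends, days; `t2 > t1`.
#' @return An object of class `"productivity"`: the rate (mg/L/day) with the
#'   window as attributes.
#' @examples
#' productivity(c1 = 100, c2 = 1600, t1 = 0, t2 = 8)  # 187.5 mg/L/day
#' @export
productivity <- function(c1, c2, t1, t2) {
  if (any(t2 <= t1)) stop("'t2' must be greater than 't1'")
  structure((c2 - c1) / (t2 - t1), class = "productivity",
            window = c(t1 = t1, t2 = t2))
}

#' @export
print.productivity <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("%.4g mg/L/day over days %g-%g\n", unclass(x), w["t1"], w["t2"]))
  invisible(x)
}

#' Construct a culture time series
#'
#' Replicate-level cultivation measurements: per treatment, replicate and
#' sampling day, optical density at 750 nm, dry weight (g/L), lipid content
#' (mg/g DW) and fucoxanthin content (mg/g DW). Any measurement may be
#' missing on a given day.
#'
#' @param data A data frame with columns `treatment`, `replicate`, `day`,
#'   and any of `od750`, `dw_g_per_l`, `lipid_mg_per_g`, `fx_mg_per_g`.
#' @return The validated data frame, classed `"culture_ts"`.
#' @export
culture_ts <- function(data) {
  data <- as.data.frame(data)
  required <- c("treatment", "replicate", "day")
  if (!all(required %in% names(data))) {
    stop("need columns: ", paste(setdiff(required, names(data)), collapse = ", "))
  }
  measures <- intersect(
    c("od750", "dw_g_per_l", "lipid_mg_per_g", "fx_mg_per_g"), names(data))
  if (!length(measures)) stop("no measurement columns present")
  if (any(data$day < 0, na.rm = TRUE)) stop("days must be non-negative")
  for (m in measures) {
    if (any(data[[m]] < 0, na.rm = TRUE)) stop("negative values in ", m)
  }
  split_key <- interaction(data$treatment, data$replicate, drop = TRUE)
  for (grp in split(data$day, split_key)) {
    if (is.unsorted(grp, strictly = TRUE)) {
      stop("days must be strictly increasing within each replicate")
    }
  }
  class(data) <- c("culture_ts", "data.frame")
  data
}

#' Read a culture time series from CSV
#'
#' Schema `treatment,replicate,day,od750,dw_g_per_l,lipid_mg_per_g,
#' fx_mg_per_g`; blank cells are missing values.
#'
#' @param path Path to a CSV file.
#' @return A [culture_ts()].
#' @export
read_culture_ts <- function(path) {
  culture_ts(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @export
plot.culture_ts <- function(x, quantity = "dw_g_per_l", ...) {
  agg <- stats::aggregate(x[[quantity]],
                          list(treatment = x$treatment, day = x$day),
                          mean, na.rm = TRUE)
  treatments <- unique(agg$treatment)
  graphics::plot(range(agg$day), range(agg$x, na.rm = TRUE), type = "n",
                 xlab = "day", ylab = quantity, ...)
  for (i in seq_along(treatments)) {
    sub <- agg[agg$treatment == treatments[i], ]
    graphics::lines(sub$day, sub$x, col = i, type = "b", pch = 16)
  }
  graphics::legend("topleft", legend = treatments, col = seq_along(treatments),
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}

# Volumetric series (mg/L) for one replicate's chosen quantity. Per-mass
# quantities (mg/g DW) are converted via same-day dry weight; a missing
# dry weight on a sampled day is linearly interpolated from flanking days.
.volumetric_series <- function(days, values, quantity, dw = NULL,
                               quiet = FALSE) {
  if (quantity == "biomass") return(values * 1000)  # g/L -> mg/L
  if (is.null(dw)) stop("dry weight needed to convert mg/g to mg/L")
  if (anyNA(dw)) {
    known <- !is.na(dw)
    if (sum(known) < 2L) stop("too few dry-weight values to interpolate")
    dw_f <- stats::approx(days[known], dw[known], xout = days, rule = 2)$y
    if (!quiet) {
      message(sprintf("interpolated dry weight on day(s) %s",
                      paste(days[!known], collapse = ", ")))
    }
    dw <- dw_f
  }
  values * dw  # mg/g * g/L = mg/L
}

#' Productivity of a quantity from a culture time series
#'
#' Computes, per replicate, the volumetric productivity of biomass, lipid or
#' fucoxanthin over a window. Per-mass contents (mg/g DW) are first
#' converted to volumetric concentrations (mg/L) using the same-day dry
#' weight (linearly interpolated when missing, with a note). The default
#' window runs from the first sampled day to the day of peak (replicate-mean)
#' concentration, the convention under which cultivation studies report
#' their headline rates.
#'
#' @param ts A [culture_ts()].
#' @param quantity `"biomass"`, `"lipid"` or `"fucoxanthin"`.
#' @param window Length-2 numeric `(t1, t2)` in days, or `NULL` for
#'   first-day-to-peak.
#' @param quiet Suppress interpolation notes.
#' @return A data frame with one row per treatment x replicate:
#'   `treatment`, `replicate`, `t1`, `t2`, `productivity_mg_per_l_day`.
#' @export
series_productivity <- function(ts, quantity = c("biomass", "lipid", "fucoxanthin"),
                                window = NULL, quiet = FALSE) {
  stopifnot(inherits(ts, "culture_ts"))
  quantity <- match.arg(quantity)
  col <- switch(quantity, biomass = "dw_g_per_l", lipid = "lipid_mg_per_g",
                fucoxanthin = "fx_mg_per_g")
  if (!col %in% names(ts)) stop("column '", col, "' absent from time series")
  out <- list()
  for (tr in unique(ts$treatment)) {
    sub_t <- ts[ts$treatment == tr, ]
    # peak day from the replicate-mean volumetric concentration
    if (is.null(window)) {
      reps <- split(sub_t, sub_t$replicate)
      vol_all <- lapply(reps, function(r) {
        data.frame(day = r$day,
                   conc = .volumetric_series(r$day, r[[col]], quantity,
                                             r$dw_g_per_l, quiet = quiet))
      })
      means <- stats::aggregate(conc ~ day, do.call(rbind, vol_all), mean)
      t1 <- min(means$day)
      t2 <- means$day[which.max(means$conc)]
      if (t2 <= t1) stop("peak at the first sampled day: give a window")
      win <- c(t1, t2)
    } else {
      win <- window
    }
    for (rep_id in unique(sub_t$replicate)) {
      r <- sub_t[sub_t$replicate == rep_id, ]
      conc <- .volumetric_series(r$day, r[[col]], quantity, r$dw_g_per_l,
                                 quiet = quiet)
      i1 <- match(win[1], r$day); i2 <- match(win[2], r$day)
      if (is.na(i1) || is.na(i2)) {
        stop(sprintf("window days (%g, %g) not sampled in %s/%s",
                     win[1], win[2], tr, rep_id))
      }
      out[[length(out) + 1L]] <- data.frame(
        treatment = tr, replicate = rep_id, t1 = win[1], t2 = win[2],
        productivity_mg_per_l_day =
          as.numeric(productivity(conc[i1], conc[i2], win[1], win[2])),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Growth-curve features of one series
#'
#' Peak value, peak day, and a decline flag set when the final observation
#' sits more than `decline_frac` below the peak -- the "slight decline after
#' the peak" seen in batch cultures entering stationary or death phase.
#'
#' @param day Sampling days.
#' @param value Measurements (at least 2 non-missing).
#' @param decline_frac Relative drop from peak that counts as decline
#'   (default 0.02).
#' @return A list: `peak_value`, `peak_day`, `declined`.
#' @export
growth_features <- function(day, value, decline_frac = 0.02) {
  keep <- !is.na(value)
  if (sum(keep) < 2L) stop("need at least two observations")
  day <- day[keep]; value <- value[keep]
  i <- which.max(value)
  list(peak_value = value[i], peak_day = day[i],
       declined = value[length(value)] < value[i] * (1 - decline_frac))
}

# Compact letter display: maximal cliques of the graph whose edges join
# pairs NOT significantly different, ordered by descending group mean.
# Groups sharing no letter are significantly different on every pair.
.letter_display <- function(groups, ns_matrix, means) {
  k <- length(groups)
  adj <- ns_matrix
  diag(adj) <- FALSE  # no self-loops: neighbourhoods must exclude the vertex
  cliques <- list()
  # Bron-Kerbosch without pivoting; k is small (treatment counts)
  bk <- function(r, p, x) {
    if (!length(p) && !length(x)) {
      cliques[[length(cliques) + 1L]] <<- r
      return(invisible())
    }
    for (v in p) {
      nb <- which(adj[v, ])
      bk(c(r, v), intersect(p, nb), intersect(x, nb))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  bk(integer(0), seq_len(k), integer(0))
  ord <- order(vapply(cliques, function(cl) max(means[cl]), 0),
               decreasing = TRUE)
  cliques <- cliques[ord]
  letters_out <- rep("", k)
  for (j in seq_along(cliques)) {
    letters_out[cliques[[j]]] <- paste0(letters_out[cliques[[j]]],
                                        letters[j])
  }
  stats::setNames(letters_out, groups)
}

#' Compare treatment groups (ANOVA / Welch t-test with Tukey letters)
#'
#' With three or more groups: one-way ANOVA; when the ANOVA rejects at
#' `alpha`, all-pairs Tukey HSD feeds a compact letter display in which
#' groups sharing a letter are not significantly different. With exactly two
#' groups: Welch's t-test. Degenerate data with zero variance everywhere
#' (all observations identical) is reported as F = 0, p = 1, all groups
#' lettered `"a"`.
#'
#' @param values Numeric response values.
#' @param groups Group labels, same length; every group needs >= 2 values.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `"treatment_comparison"`: a list with
#'   `method`, `statistic` (F or t), `p_value`, `alpha`, `means`, `letters`,
#'   and for the ANOVA path `tukey` (the matrix from [stats::TukeyHSD()]).
#' @examples
#' compare_treatments(c(10, 11, 10, 20, 21, 20, 30, 29, 31),
#'                    rep(c("a", "b", "c"), each = 3))
#' @export
compare_treatments <- function(values, groups, alpha = 0.05) {
  stopifnot(length(values) == length(groups), alpha > 0, alpha < 1)
  groups <- as.character(groups)
  counts <- table(groups)
  if (length(counts) < 2L) stop("need at least two groups")
  if (any(counts < 2L)) {
    stop("every group needs at least 2 replicates; short: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  g_levels <- unique(groups)
  means <- vapply(split(values, factor(groups, levels = g_levels)), mean, 0)
  k <- length(g_levels)

  if (stats::var(values) == 0) {
    return(structure(list(method = "one-way ANOVA", statistic = 0,
                          p_value = 1, alpha = alpha, means = means,
                          letters = stats::setNames(rep("a", k), g_levels),
                          tukey = NULL),
                     class = "treatment_comparison"))
  }

  if (k == 2L) {
    tt <- stats::t.test(values[groups == g_levels[1L]],
                        values[groups == g_levels[2L]])
    letters_out <- if (tt$p.value < alpha) c("a", "b") else c("a", "a")
    if (means[2L] > means[1L]) letters_out <- rev(letters_out)
    return(structure(list(method = "Welch two-sample t-test",
                          statistic = unname(tt$statistic),
                          p_value = tt$p.value, alpha = alpha, means = means,
                          letters = stats::setNames(letters_out, g_levels),
                          tukey = NULL),
                     class = "treatment_comparison"))
  }

  df <- data.frame(y = values, g = factor(groups, levels = g_levels))
  fit <- stats::aov(y ~ g, data = df)
  tab <- summary(fit)[[1L]]
  f_stat <- tab[["F value"]][1L]
  p_val <- tab[["Pr(>F)"]][1L]
  tukey <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  if (p_val < alpha) {
    ns <- matrix(TRUE, k, k, dimnames = list(g_levels, g_levels))
    for (row in rownames(tukey)) {
      pair <- strsplit(row, "-", fixed = TRUE)[[1L]]
      ns[pair[1L], pair[2L]] <- ns[pair[2L], pair[1L]] <-
        tukey[row, "p adj"] >= alpha
    }
    letters_out <- .letter_display(g_levels, ns, means)
  } else {
    letters_out <- stats::setNames(rep("a", k), g_levels)
  }
  structure(list(method = "one-way ANOVA", statistic = f_stat,
                 p_value = p_val, alpha = alpha, means = means,
                 letters = letters_out, tukey = tukey),
            class = "treatment_comparison")
}

#' @export
print.treatment_comparison <- function(x, ...) {
  cat(sprintf("<treatment_comparison> %s: statistic = %.4g, p = %.4g (alpha %.2g)\n",
              x$method, x$statistic, x$p_value, x$alpha))
  print(data.frame(group = names(x$means), mean = unname(x$means),
                   letters = unname(x$letters[names(x$means)])),
        row.names = FALSE)
  invisible(x)
}
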