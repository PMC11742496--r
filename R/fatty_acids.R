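#' Parse fatty-acid shorthand nomenclature
#'
#' Parses a lipid shorthand code such as `"C16:0"`, `"C20:5n3"`,
#' `"C18:2(n-6)"` or `"C18:1t"` into its components: chain length, number of
#' carbon-carbon double bonds, omega (n-z) class, and cis/trans geometry.
#' Both the `"n3"` and `"(n-3)"` omega dialects are accepted, the leading
#' `"C"` is optional and case-insensitive, and a trailing `"t"` marks a trans
#' isomer.
#'
#' @param shorthand Character scalar, the shorthand code.
#' @return An object of class `"fatty_acid"`: a list with elements
#'   `shorthand` (canonical form), `carbons`, `double_bonds`, `omega_class`
#'   (`NA` when unstated), and `geometry` (`"cis"`, `"trans"` or
#'   `"unspecified"`).
#' @details Geometry is `"trans"` iff a `t` designator is present, `"cis"`
#'   when an omega class is given without `t` (GC-MS tables write the cis
#'   isomer as e.g. `C18:1(n-9)`), and `"unspecified"` otherwise.
#' @examples
#' parse_fatty_acid("C20:5n3")   # EPA: 20 carbons, 5 double bonds, omega-3
#' parse_fatty_acid("C18:1t")    # elaidic acid, trans
#' @export
parse_fatty_acid <- function(shorthand) {
  if (!is.character(shorthand) || length(shorthand) != 1L ||
      is.na(shorthand) || !nzchar(trimws(shorthand))) {
    stop("'shorthand' must be a single non-empty character string")
  }
  code <- trimws(shorthand)
  m <- regmatches(
    code,
    regexec("^[Cc]?([0-9]+):([0-9]+)(?:\\(n-([0-9]+)\\)|n-?([0-9]+))?([tT])?$",
            code)
  )[[1L]]
  if (length(m) == 0L) {
    stop(sprintf("malformed fatty-acid shorthand: '%s'", code))
  }
  carbons <- as.integer(m[2L])
  db <- as.integer(m[3L])
  omega <- if (nzchar(m[4L])) as.integer(m[4L])
           else if (nzchar(m[5L])) as.integer(m[5L]) else NA_integer_
  trans <- nzchar(m[6L])
  if (carbons < 1L) stop(sprintf("'%s': carbon count must be positive", code))
  if (db > carbons / 2) {
    stop(sprintf("'%s': %d double bonds impossible on %d carbons", code, db, carbons))
  }
  if (!is.na(omega) && omega > carbons) {
    stop(sprintf("'%s': omega class n-%d exceeds chain length", code, omega))
  }
  geometry <- if (trans) "trans" else if (!is.na(omega)) "cis" else "unspecified"
  canonical <- paste0(
    "C", carbons, ":", db,
    if (!is.na(omega)) paste0("n", omega) else "",
    if (trans) "t" else ""
  )
  structure(
    list(shorthand = canonical, carbons = carbons, double_bonds = db,
         omega_class = omega, geometry = geometry),
    class = "fatty_acid"
  )
}

#' @export
print.fatty_acid <- function(x, ...) {
  cat(sprintf("<fatty_acid> %s: %d C, %d double bond%s, %s%s\n",
              x$shorthand, x$carbons, x$double_bonds,
              if (x$double_bonds == 1L) "" else "s",
              x$geometry,
              if (!is.na(x$omega_class)) paste0(", omega-", x$omega_class) else ""))
  invisible(x)
}

#' Construct a fatty-acid composition profile
#'
#' A profile is one sample's GC-MS fatty acid composition: shorthand codes
#' with their mass percentages of total fatty acids. Percentages may sum to
#' less than 100 (the unidentified fraction).
#'
#' @param sample_id,condition Character scalars labelling the sample.
#' @param fatty_acid Character vector of shorthand codes (see
#'   [parse_fatty_acid()]).
#' @param percent Numeric vector of mass percentages (0-100), same length.
#' @param reported_class_totals Optional named numeric vector with elements
#'   `sfa`, `mufa`, `pufa`: class totals as printed in a source table, kept
#'   for cross-checking (see [verify_class_totals()]) but never used in
#'   computation.
#' @return An object of class `"fa_profile"`.
#' @export
fa_profile <- function(sample_id, condition = "", fatty_acid, percent,
                       reported_class_totals = NULL) {
  stopifnot(length(fatty_acid) == length(percent))
  percent <- as.numeric(percent)
  if (anyNA(percent) || any(percent < 0)) {
    stop("percentages must be non-negative and non-missing (code ND as 0)")
  }
  specs <- lapply(as.character(fatty_acid), parse_fatty_acid)
  keys <- vapply(specs, `[[`, "", "shorthand")
  if (anyDuplicated(keys)) {
    stop(sprintf("duplicate fatty acid in profile '%s': %s", sample_id,
                 paste(unique(keys[duplicated(keys)]), collapse = ", ")))
  }
  if (sum(percent) > 100 + 0.5) {
    stop(sprintf("profile '%s': percentages sum to %.2f > 100", sample_id,
                 sum(percent)))
  }
  structure(
    list(sample_id = as.character(sample_id),
         condition = as.character(condition),
         specs = specs, percent = percent,
         reported_class_totals = reported_class_totals),
    class = "fa_profile"
  )
}

#' @export
print.fa_profile <- function(x, ...) {
  cat(sprintf("<fa_profile> %s (%s): %d acids, %.2f%% identified\n",
              x$sample_id, x$condition, length(x$specs), sum(x$percent)))
  df <- as.data.frame(x)
  print(df[df$percent > 0, , drop = FALSE], row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.fa_profile <- function(x, ...) {
  data.frame(
    sample_id = x$sample_id,
    condition = x$condition,
    fatty_acid = vapply(x$specs, `[[`, "", "shorthand"),
    double_bonds = vapply(x$specs, `[[`, 0L, "double_bonds"),
    percent = x$percent,
    stringsAsFactors = FALSE
  )
}

#' Saturation class totals of a profile
#'
#' Assigns every entry to exactly one saturation class by its double-bond
#' count -- saturated (0), monounsaturated (1), polyunsaturated (>= 2) --
#' and sums the mass percentages per class.
#'
#' @param profile An [fa_profile()].
#' @return A list of class `"class_totals"` with `sfa_pct`, `mufa_pct`,
#'   `pufa_pct` and `identified_total_pct` (their sum).
#' @export
class_totals <- function(profile) {
  stopifnot(inherits(profile, "fa_profile"))
  db <- vapply(profile$specs, `[[`, 0L, "double_bonds")
  sfa <- sum(profile$percent[db == 0L])
  mufa <- sum(profile$percent[db == 1L])
  pufa <- sum(profile$percent[db >= 2L])
  structure(
    list(sfa_pct = sfa, mufa_pct = mufa, pufa_pct = pufa,
         identified_total_pct = sfa + mufa + pufa),
    class = "class_totals"
  )
}

#' @export
print.class_totals <- function(x, ...) {
  cat(sprintf("SFA %.2f%%  MUFA %.2f%%  PUFA %.2f%%  (identified %.2f%%)\n",
              x$sfa_pct, x$mufa_pct, x$pufa_pct, x$identified_total_pct))
  invisible(x)
}

#' Compare computed class totals against totals printed in a source table
#'
#' GC-MS publication tables print class totals alongside the per-acid rows;
#' the two occasionally disagree (a dropped cell, input rounding). This
#' reports, per class, the computed component sum, the reported total, and
#' the discrepancy.
#'
#' @param profile An [fa_profile()] carrying `reported_class_totals`.
#' @param tolerance Absolute discrepancy treated as agreement (default 0.02,
#'   the rounding granularity of 2-dp tables).
#' @return A data frame with columns `class`, `computed`, `reported`,
#'   `discrepancy`, `consistent`.
#' @export
verify_class_totals <- function(profile, tolerance = 0.02) {
  stopifnot(inherits(profile, "fa_profile"))
  rep_tot <- profile$reported_class_totals
  if (is.null(rep_tot)) stop("profile carries no reported_class_totals")
  ct <- class_totals(profile)
  computed <- c(sfa = ct$sfa_pct, mufa = ct$mufa_pct, pufa = ct$pufa_pct)
  reported <- c(sfa = rep_tot[["sfa"]], mufa = rep_tot[["mufa"]],
                pufa = rep_tot[["pufa"]])
  data.frame(
    class = c("SFA", "MUFA", "PUFA"),
    computed = unname(computed),
    reported = unname(reported),
    discrepancy = unname(computed - reported),
    consistent = unname(abs(computed - reported) <= tolerance + 1e-9),
    row.names = NULL
  )
}

#' Average degree of unsaturation (ADU)
#'
#' The mass-fraction-weighted mean number of carbon-carbon double bonds of a
#' fatty-acid profile: `ADU = sum_i N_i * Mf_i`, where `N_i` is the
#' double-bond count of acid *i* and `Mf_i` its mass fraction. By default the
#' mass fraction is the printed percentage divided by 100, i.e. taken over
#' *total* fatty acids including any unidentified fraction; with
#' `renormalize = TRUE` it is taken over the identified total instead.
#'
#' @param profile An [fa_profile()].
#' @param renormalize Logical; divide by the identified total rather than
#'   by 100. Default `FALSE` -- the convention under which published
#'   downstream property values are reproduced from published tables.
#' @return Numeric scalar, dimensionless (typical algal oils fall around
#'   0.5-1.5).
#' @export
adu <- function(profile, renormalize = FALSE) {
  stopifnot(inherits(profile, "fa_profile"))
  db <- vapply(profile$specs, `[[`, 0L, "double_bonds")
  denom <- if (renormalize) sum(profile$percent) else 100
  if (renormalize && denom == 0) {
    stop("cannot renormalize: identified total is zero")
  }
  sum(db * profile$percent) / denom
}

#' Read fatty-acid profiles from CSV
#'
#' Expects columns `sample_id,condition,fatty_acid,percent` (header
#' required). Percent cells reading `"ND"` (not detected) or left blank are
#' taken as 0, each substitution reported via [message()]. Rows are grouped
#' into one profile per `sample_id`, preserving file order.
#'
#' @param path Path to a CSV file.
#' @param quiet Suppress the ND-substitution notes.
#' @return A named list of [fa_profile()] objects.
#' @export
read_fa_profiles <- function(path, quiet = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", strip.white = TRUE)
  required <- c("sample_id", "condition", "fatty_acid", "percent")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s) in '%s': %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    stop(sprintf("unknown column(s) in '%s': %s", path,
                 paste(extra, collapse = ", ")))
  }
  pct <- numeric(nrow(df))
  for (i in seq_len(nrow(df))) {
    cell <- df$percent[i]
    if (is.na(cell) || !nzchar(cell) || toupper(cell) == "ND") {
      pct[i] <- 0
      if (!quiet) {
        message(sprintf("row %d (%s, %s): '%s' treated as 0",
                        i, df$sample_id[i], df$fatty_acid[i],
                        if (is.na(cell) || !nzchar(cell)) "blank" else cell))
      }
    } else {
      val <- suppressWarnings(as.numeric(cell))
      if (is.na(val)) stop(sprintf("row %d: unparsable percent '%s'", i, cell))
      if (val < 0) stop(sprintf("row %d: negative percent %s", i, cell))
      pct[i] <- val
    }
  }
  ids <- unique(df$sample_id)
  profiles <- lapply(ids, function(id) {
    rows <- df$sample_id == id
    fa_profile(sample_id = id, condition = df$condition[rows][1L],
               fatty_acid = df$fatty_acid[rows], percent = pct[rows])
  })
  names(profiles) <- ids
  profiles
}

#' Write fatty-acid profiles to CSV
#'
#' Emits the canonical column order `sample_id,condition,fatty_acid,percent`
#' with percentages formatted to 2 decimal places, so that a written file
#' read back with [read_fa_profiles()] and written again is byte-identical.
#'
#' @param profiles A list of [fa_profile()] objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fa_profiles <- function(profiles, path) {
  if (inherits(profiles, "fa_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    data.frame(sample_id = p$sample_id, condition = p$condition,
               fatty_acid = vapply(p$specs, `[[`, "", "shorthand"),
               percent = sprintf("%.2f", p$percent),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Path to the packaged reference fatty-acid profile table
#'
#' The packaged fixture holds the GC-MS fatty-acid composition of
#' *Phaeodactylum tricornutum* under a control F/2 medium and under an
#' optimized medium (reduced N, raised P, no Si, glycerol, low blue light),
#' in the long CSV schema of [read_fa_profiles()].
#'
#' @return Path to the CSV inside the installed package.
#' @export
fameprops_example_profiles <- function() {
  system.file("extdata", "phaeodactylum_fa_profiles.csv",
              package = "fameprops", mustWork = TRUE)
}
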