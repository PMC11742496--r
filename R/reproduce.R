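# End-to-end reproduction of the published reference analysis from the
# packaged fatty-acid table, and deterministic report writing.

# Published values the packaged table is compared against: per-condition
# class totals and the biodiesel property panel of the reference study.
# Two printed cells are known-discrepant with the table's own components
# (flagged below) and are excluded from the pass/fail verdict.
.reference_values <- function() {
  ref <- rbind(
    data.frame(quantity = "sfa_pct", condition = c("control", "optimized"),
               published = c(32.19, 48.72), flagged = FALSE),
    data.frame(quantity = "mufa_pct", condition = c("control", "optimized"),
               published = c(36.12, 20.59),
               # control MUFA prints 36.12 but its listed components sum to
               # 32.09 (one cell is blank in the source); discrepancy flagged
               flagged = c(TRUE, FALSE)),
    data.frame(quantity = "pufa_pct", condition = c("control", "optimized"),
               published = c(11.68, 14.71), flagged = FALSE),
    data.frame(quantity = "adu", condition = c("control", "optimized"),
               published = c(0.79, 0.70), flagged = FALSE),
    data.frame(quantity = "cn", condition = c("control", "optimized"),
               published = c(57.64, 58.24), flagged = FALSE),
    data.frame(quantity = "iv", condition = c("control", "optimized"),
               published = c(71.12, 64.40), flagged = FALSE),
    data.frame(quantity = "cp", condition = c("control", "optimized"),
               published = c(9.51, 10.71), flagged = FALSE),
    data.frame(quantity = "hhv", condition = c("control", "optimized"),
               published = c(39.92, 39.76), flagged = FALSE)
  )
  ref
}

#' Recompute the published reference analysis from the packaged table
#'
#' Runs the full chain on the packaged fatty-acid composition table --
#' parsing, class totals, ADU, and the biodiesel property panel -- and
#' compares every computed value side by side with the published one at a
#' stated tolerance. Cells whose published values are known to disagree
#' with the published table's own components (see the methods vignette) are
#' flagged and excluded from the overall verdict.
#'
#' @param cp_variant Cloud-point coefficient set (see [cloud_point()]).
#'   The published cloud points are only reproduced by the default
#'   `"reconstructed"` set.
#' @param renormalize Passed to [adu()]; the published values are only
#'   reproduced with the default `FALSE`.
#' @param tolerance Absolute tolerance for all comparisons (default 0.02,
#'   the input-rounding granularity of a 2-dp composition table).
#' @return An object of class `"repro_report"`: a data frame with columns
#'   `quantity`, `condition`, `computed`, `published`, `tolerance`, `pass`,
#'   `flagged`, plus attributes recording the variants used.
#' @examples
#' rep <- reproduce_reference_analysis()
#' rep
#' @export
reproduce_reference_analysis <- function(cp_variant = c("reconstructed", "printed"),
                                         renormalize = FALSE,
                                         tolerance = 0.02) {
  cp_variant <- match.arg(cp_variant)
  profiles <- read_fa_profiles(fameprops_example_profiles(), quiet = TRUE)
  computed <- list()
  for (id in names(profiles)) {
    ct <- class_totals(profiles[[id]])
    panel <- fuel_panel(profiles[[id]], cp_variant = cp_variant,
                        renormalize = renormalize)
    computed[[id]] <- c(sfa_pct = ct$sfa_pct, mufa_pct = ct$mufa_pct,
                        pufa_pct = ct$pufa_pct, adu = panel$adu,
                        cn = panel$cn, iv = panel$iv, cp = panel$cp,
                        hhv = panel$hhv)
  }
  ref <- .reference_values()
  ref$computed <- mapply(function(q, cond) computed[[cond]][[q]],
                         ref$quantity, ref$condition)
  ref$tolerance <- tolerance
  # ADU is published at 2 dp; compare the rounded value
  adu_rows <- ref$quantity == "adu"
  cmp_val <- ifelse(adu_rows, round(ref$computed, 2), ref$computed)
  ref$pass <- abs(cmp_val - ref$published) <= ref$tolerance + 1e-12
  out <- ref[, c("quantity", "condition", "computed", "published",
                 "tolerance", "pass", "flagged")]
  rownames(out) <- NULL
  attr(out, "cp_variant") <- cp_variant
  attr(out, "renormalize") <- renormalize
  class(out) <- c("repro_report", "data.frame")
  out
}

#' @export
print.repro_report <- function(x, ...) {
  cat(sprintf("<repro_report> cp_variant=%s, renormalize=%s\n",
              attr(x, "cp_variant"), attr(x, "renormalize")))
  shown <- data.frame(quantity = x$quantity, condition = x$condition,
                      computed = round(x$computed, 4),
                      published = x$published,
                      status = ifelse(x$flagged, "FLAGGED (known discrepancy)",
                                      ifelse(x$pass, "pass", "FAIL")))
  print.data.frame(shown, row.names = FALSE)
  n_checked <- sum(!x$flagged)
  cat(sprintf("%d/%d checks pass (%d flagged cell%s excluded)\n",
              sum(x$pass & !x$flagged), n_checked, sum(x$flagged),
              if (sum(x$flagged) == 1L) "" else "s"))
  invisible(x)
}

#' Write analysis results as deterministic JSON and text reports
#'
#' Serialises any combination of panels, compliance reports, comparison or
#' reproduction results into `report.json` (stable field order, full
#' precision) and `report.txt` (the objects' printed form) inside `dir`.
#' Rerunning on identical inputs yields byte-identical files.
#'
#' @param results A named list of package result objects (or plain
#'   lists/data frames). An empty list produces a valid empty-report
#'   skeleton.
#' @param dir Output directory, created if needed.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_report <- function(results = list(), dir) {
  stopifnot(is.list(results))
  if (length(results) && is.null(names(results))) {
    stop("'results' must be a named list")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  strip <- function(x) {
    if (is.data.frame(x)) {
      attrs <- setdiff(names(attributes(x)), c("names", "row.names", "class"))
      for (a in attrs) attr(x, a) <- NULL
      class(x) <- "data.frame"
      x
    } else if (is.list(x)) {
      lapply(unclass(x), strip)
    } else x
  }
  payload <- list(package = "fameprops",
                  version = as.character(utils::packageVersion("fameprops")),
                  results = lapply(results, strip))
  json_path <- file.path(dir, "report.json")
  txt_path <- file.path(dir, "report.txt")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  txt <- utils::capture.output({
    cat("fameprops report\n")
    for (nm in names(results)) {
      cat("\n== ", nm, " ==\n", sep = "")
      print(results[[nm]])
    }
    if (!length(results)) cat("\n(no results)\n")
  })
  writeLines(txt, txt_path)
  invisible(c(json = json_path, txt = txt_path))
}
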