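# Fucoxanthin quantification, productivities, growth features, statistics.

test_that("fucoxanthin quantification evaluates the dual-wavelength formula", {
  expect_equal(fucoxanthin_content(0, 0, biomass_g = 0.01,
                                   extract_volume_l = 0.004), 0)
  expect_equal(
    fucoxanthin_content(1.0, 0.5, biomass_g = 0.010, extract_volume_l = 0.004),
    (6.39 - 2.59) * 0.004 / 0.010)  # 1.52 mg/g
})

test_that("chlorophyll-dominated extracts clamp to zero with a warning", {
  expect_warning(
    out <- fucoxanthin_content(0, 1.0, biomass_g = 0.01,
                               extract_volume_l = 0.004),
    "clamped")
  expect_equal(out, 0)
})

test_that("fucoxanthin output is homogeneous in the absorbances (pre-clamp)", {
  base <- fucoxanthin_content(0.8, 0.3, 0.01, 0.004)
  doubled <- fucoxanthin_content(1.6, 0.6, 0.01, 0.004)
  expect_equal(doubled, 2 * base)
})

test_that("extract volume is never silently defaulted; the bench ratio works", {
  expect_error(fucoxanthin_content(1, 0.5, biomass_g = 0.01), "volume")
  expect_error(fucoxanthin_content(1, 0.5, biomass_g = 0), "positive")
  # 10 mg extracted at 4 mL solvent per mg = 0.04 L
  expect_equal(fucoxanthin_content(1, 0.5, biomass_g = 0.010, ml_per_mg = 4),
               fucoxanthin_content(1, 0.5, biomass_g = 0.010,
                                   extract_volume_l = 0.04))
})

test_that("productivity is the signed rate over the window", {
  expect_equal(as.numeric(productivity(100, 1600, 0, 8)), 187.5)
  expect_equal(as.numeric(productivity(500, 500, 0, 8)), 0)
  expect_lt(as.numeric(productivity(1600, 1500, 8, 10)), 0)
  expect_error(productivity(1, 2, 5, 5), "t2")
})

test_that("productivity is linear in c2 and scales as 1/(t2-t1)", {
  p1 <- as.numeric(productivity(0, 300, 0, 4))
  expect_equal(as.numeric(productivity(0, 600, 0, 4)), 2 * p1)
  expect_equal(as.numeric(productivity(0, 300, 0, 8)), p1 / 2)
})

test_that("series productivity converts per-mass contents via dry weight", {
  ts <- culture_ts(data.frame(
    treatment = "T", replicate = "R1", day = c(0, 4, 8),
    dw_g_per_l = c(0.1, 0.8, 1.6),
    lipid_mg_per_g = c(100, 200, 400)))
  bp <- series_productivity(ts, "biomass", window = c(0, 8))
  expect_equal(bp$productivity_mg_per_l_day, (1600 - 100) / 8)
  lp <- series_productivity(ts, "lipid", window = c(0, 8))
  # lipid mg/L: 100*0.1 = 10 at day 0; 400*1.6 = 640 at day 8
  expect_equal(lp$productivity_mg_per_l_day, (640 - 10) / 8)
})

test_that("missing dry weight is interpolated from flanking days, with a note", {
  ts <- culture_ts(data.frame(
    treatment = "T", replicate = "R1", day = c(0, 4, 8),
    dw_g_per_l = c(0.2, NA, 1.0),
    lipid_mg_per_g = c(100, 200, 400)))
  expect_message(
    lp <- series_productivity(ts, "lipid", window = c(0, 8)),
    "interpolated")
  expect_equal(lp$productivity_mg_per_l_day, (400 * 1.0 - 100 * 0.2) / 8)
})

test_that("the default window runs from the first day to the peak day", {
  ts <- culture_ts(data.frame(
    treatment = "T", replicate = "R1", day = c(0, 2, 4, 6, 8, 10),
    dw_g_per_l = c(0.1, 0.2, 0.7, 1.3, 1.6, 1.55)))
  bp <- series_productivity(ts, "biomass")
  expect_equal(bp$t1, 0)
  expect_equal(bp$t2, 8)
  expect_equal(bp$productivity_mg_per_l_day, (1600 - 100) / 8)
})

test_that("growth features find the peak and flag the post-peak decline", {
  mono <- growth_features(day = c(0, 2, 4), value = c(1, 2, 3))
  expect_equal(mono$peak_day, 4)
  expect_false(mono$declined)
  peaked <- growth_features(day = c(0, 4, 8, 10), value = c(0.1, 1.0, 1.6, 1.5))
  expect_equal(peaked$peak_day, 8)
  expect_equal(peaked$peak_value, 1.6)
  expect_true(peaked$declined)
  # 1% drop is inside the default 2% dead band
  flat <- growth_features(day = c(0, 8, 10), value = c(0.1, 1.0, 0.99))
  expect_false(flat$declined)
  expect_error(growth_features(day = 1, value = 5), "two observations")
})

test_that("identical groups give F = 0 and a shared letter", {
  cmp <- compare_treatments(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)
  expect_true(all(cmp$letters == "a"))
})

test_that("well-separated groups earn distinct letters, agreeing with multcomp", {
  set.seed(101)
  values <- rep(c(10, 20, 30), each = 3) + stats::rnorm(9, 0, 0.1)
  groups <- rep(c("g1", "g2", "g3"), each = 3)
  cmp <- compare_treatments(values, groups)
  expect_lt(cmp$p_value, 0.05)
  expect_length(unique(cmp$letters), 3)

  skip_if_not_installed("multcomp")
  fit <- stats::aov(y ~ g, data = data.frame(y = values, g = factor(groups)))
  mc <- multcomp::cld(multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey")))
  same_partition <- function(l1, l2) {
    identical(outer(l1, l1, `==`), outer(l2, l2, `==`))
  }
  expect_true(same_partition(unname(cmp$letters[groups]),
                             unname(mc$mcletters$Letters[groups])))
})

test_that("groups with disjoint letter sets are pairwise significant", {
  set.seed(55)
  for (i in 1:20) {
    k <- sample(3:5, 1)
    centers <- stats::runif(k, 0, 30)
    values <- rep(centers, each = 3) + stats::rnorm(3 * k, 0, 2)
    groups <- rep(paste0("g", seq_len(k)), each = 3)
    cmp <- compare_treatments(values, groups)
    if (is.null(cmp$tukey)) next
    for (a in seq_len(k - 1)) for (b in seq((a + 1), k)) {
      la <- strsplit(cmp$letters[[a]], "")[[1]]
      lb <- strsplit(cmp$letters[[b]], "")[[1]]
      if (!length(intersect(la, lb))) {
        pair <- rownames(cmp$tukey)
        hit <- grepl(paste0("^g", b, "-g", a, "$"), pair) |
          grepl(paste0("^g", a, "-g", b, "$"), pair)
        expect_lt(cmp$tukey[hit, "p adj"], cmp$alpha)
      }
    }
  }
})

test_that("the p-value is invariant to location shifts and relabeling", {
  set.seed(9)
  values <- stats::rnorm(12, rep(c(0, 1, 3, 5), each = 3))
  groups <- rep(c("w", "x", "y", "z"), each = 3)
  p0 <- compare_treatments(values, groups)$p_value
  expect_equal(compare_treatments(values + 100, groups)$p_value, p0)
  relabel <- c(w = "G4", x = "G3", y = "G2", z = "G1")
  expect_equal(compare_treatments(values, relabel[groups])$p_value, p0)
})

test_that("two-group comparisons use Welch's t-test", {
  cmp <- compare_treatments(c(1.0, 1.1, 0.9, 2.0, 2.1, 1.9),
                            rep(c("ctl", "trt"), each = 3))
  expect_match(cmp$method, "Welch")
  expect_lt(cmp$p_value, 0.05)
  expect_setequal(unname(cmp$letters), c("a", "b"))
  expect_equal(unname(cmp$letters["trt"]), "a")  # higher mean gets "a"
})

test_that("underpowered groups are rejected up front", {
  expect_error(compare_treatments(c(1, 2, 3), c("a", "a", "b")), "b")
  expect_error(compare_treatments(c(1, 2), c("a", "a")), "two groups")
})
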