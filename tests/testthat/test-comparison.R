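fake_fit <- function(a, se_a, b = -20, se_b = 2, x0 = 900, se_x0 = 5,
                     n = 16L) {
  structure(list(params = c(a = a, b = b, x0 = x0),
                 se = c(a = se_a, b = se_b, x0 = se_x0),
                 df_resid = n - 3L, n_points = n),
            class = "logistic_fit")
}

test_that("param_ttest combines SEs in quadrature", {
  # strongly different asymptotes (faba bean vs lentil T1-style values)
  f1 <- fake_fit(0.7769, 0.0170)
  f2 <- fake_fit(0.6618, 0.0098)
  for (rule in c("pooled_resid", "welch", "normal")) {
    cmp <- param_ttest(f1, f2, "a", df_rule = rule)
    expect_equal(cmp$se_diff, sqrt(0.0170^2 + 0.0098^2))
    expect_equal(cmp$t, 5.87, tolerance = 1e-3)
    expect_equal(cmp$class, "***")
  }
  # near-identical asymptotes (faba bean vs grass pea T1-style values)
  f3 <- fake_fit(0.7941, 0.0109)
  for (rule in c("pooled_resid", "welch", "normal")) {
    cmp <- param_ttest(f1, f3, "a", df_rule = rule)
    expect_equal(cmp$t, -0.85, tolerance = 1e-2)
    expect_equal(cmp$class, "ns")
  }
  # identical fits
  cmp0 <- param_ttest(f1, f1, "a")
  expect_equal(cmp0$t, 0)
  expect_equal(cmp0$p, 1)
  expect_equal(cmp0$class, "ns")
  bad <- f1; bad$se[["a"]] <- 0
  expect_error(param_ttest(bad, f2, "a"), "positive")
})

test_that("swapping the pair negates t and preserves p and class", {
  set.seed(91)
  for (i in 1:20) {
    f1 <- fake_fit(runif(1, 0.3, 1), runif(1, 0.005, 0.1))
    f2 <- fake_fit(runif(1, 0.3, 1), runif(1, 0.005, 0.1))
    c12 <- param_ttest(f1, f2, "a")
    c21 <- param_ttest(f2, f1, "a")
    expect_equal(c12$t, -c21$t)
    expect_equal(c12$p, c21$p)
    expect_identical(c12$class, c21$class)
  }
})

test_that("p decreases monotonically in |t| at fixed df", {
  ts <- seq(0.1, 8, by = 0.3)
  ps <- 2 * pt(-abs(ts), 26)
  expect_true(all(diff(ps) < 0))
})

test_that("classify_significance applies the 5/1/0.1 percent cutpoints", {
  expect_equal(classify_significance(0.0005), "***")
  expect_equal(classify_significance(0.0243), "*")
  expect_equal(classify_significance(0.3989), "ns")
  expect_equal(classify_significance(c(0.001, 0.01, 0.05, 0.051)),
               c("***", "**", "*", "ns"))
  expect_error(classify_significance(0), "within")
  expect_error(classify_significance(1.5), "within")
})

test_that("compare_all enumerates pairs and marks missing fits", {
  fits <- list()
  for (crop in c("faba_bean", "grass_pea", "lentil")) {
    fits[[fit_key(crop, "T1", "2007")]] <- fake_fit(runif(1, 0.5, 0.9),
                                                    0.01)
  }
  tab <- compare_all(fits)
  expect_equal(nrow(tab), 9L)  # 3 pairs x 3 parameters
  expect_true(all(!is.na(tab$t)))

  # lentil lacking T6: T6 rows exist only as explicit gaps for its pairs
  fits[[fit_key("faba_bean", "T6", "2007")]] <- fake_fit(0.4, 0.09)
  fits[[fit_key("grass_pea", "T6", "2007")]] <- fake_fit(0.32, 0.02)
  tab2 <- compare_all(fits)
  t6 <- tab2[tab2$stage == "T6", ]
  expect_equal(nrow(t6), 9L)
  expect_true(all(!is.na(t6$t[t6$pair == "faba_bean-grass_pea"])))
  expect_true(all(is.na(t6$t[grepl("lentil", t6$pair)])))

  expect_equal(nrow(compare_all(list())), 0L)
})

test_that("published comparison classes are reproduced where df-invariant", {
  # build pseudo-fits from the reference coefficient tables and rerun the
  # SE-based t test; classes that do not depend on df (|t| > 6 or < 1.4)
  # must match the published ones under every df rule
  refs <- reference_comparisons()
  checked <- 0L
  for (season in c("2007", "2008")) {
    fits <- reference_fits(reference_coefficients(season), season)
    for (i in which(refs$season == season)) {
      r <- refs[i, ]
      crops <- strsplit(r$pair, "-", fixed = TRUE)[[1]]
      k1 <- fit_key(crops[1], r$stage, season)
      k2 <- fit_key(crops[2], r$stage, season)
      if (is.null(fits[[k1]]) || is.null(fits[[k2]])) next
      cmp <- param_ttest(fits[[k1]], fits[[k2]], r$parameter)
      if (abs(cmp$t) <= 6 && abs(cmp$t) >= 1.4) next
      for (rule in c("pooled_resid", "welch", "normal")) {
        got <- param_ttest(fits[[k1]], fits[[k2]], r$parameter,
                           df_rule = rule)
        expect_identical(got$class, r$class,
                         label = sprintf("%s %s %s %s [%s]", season,
                                         r$stage, r$pair, r$parameter,
                                         rule))
      }
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 30L)
})

test_that("species-by-year ANOVA detects simulated interactions", {
  # replicate-level season-aggregated counts derived from the reference
  # curves over the weekly sampling window; crop-by-year x0 shifts (larger
  # for grass pea than the others) create the interaction
  coefs <- reference_coefficients("both")
  visit_gdd <- seq(600, 1200, by = 60)  # weekly visits through the log phase
  make_data <- function(seed, interaction = TRUE) {
    set.seed(seed)
    rows <- list()
    for (i in seq_len(nrow(coefs))) {
      r <- coefs[i, ]
      if (r$stage != "T1") next
      if (!interaction) {  # remove year structure: use season-2007 curve
        r <- coefs[coefs$season == "2007" & coefs$crop == r$crop &
                     coefs$stage == "T1", ]
      }
      mu <- pmax(10^logistic_eval(c(a = r$a, b = r$b, x0 = r$x0),
                                  visit_gdd) - 1, 1e-6)
      for (rep in 1:4) {
        eff <- rlnorm(1, -0.08^2 / 2, 0.08)
        # mean attachments per plant per visit, 5 plants per visit,
        # aggregated over the season
        per_visit <- rpois(length(mu), 5 * mu * eff) / 5
        rows[[length(rows) + 1L]] <- data.frame(
          species = coefs$crop[i], year = coefs$season[i],
          replicate = rep, stage = "T1", count = mean(per_visit))
      }
    }
    do.call(rbind, rows)
  }
  hits <- 0L
  n_seeds <- 25L
  for (s in seq_len(n_seeds)) {
    res <- anova_species_year(make_data(1000 + s))
    p_int <- res$p[res$term == "species:year"]
    if (is.finite(p_int) && p_int < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / n_seeds, 0.8)

  # species main effect is detected when only species differ
  res0 <- anova_species_year(make_data(1, interaction = FALSE))
  expect_lt(res0$p[res0$term == "species"], 0.01)

  expect_error(anova_species_year(data.frame(
    species = "a", year = c(1, 2), replicate = 1, stage = "T1",
    count = 1)), "two levels")
})

test_that("degenerate all-equal responses are flagged, not crashed", {
  d <- expand.grid(species = c("a", "b"), year = c("1", "2"),
                   replicate = 1:3)
  d$stage <- "T1"; d$count <- 4
  res <- anova_species_year(d)
  expect_true(all(res$degenerate))
  expect_true(all(is.na(res$F)))
})
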