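test_that("letter rule matches the published tillering-stage example", {
  tab <- load_table2_fixture()
  ts <- dplyr::filter(tab, variety == "Zhongjiazao 17", stage == "TS")
  res <- classify_letters(ts)
  lab <- setNames(res$labels$label, res$labels$n_rate)
  expect_identical(lab[["225"]], "non_limited")
  expect_identical(unname(lab[c("0", "75", "150")]),
                   rep("limited", 3))
  expect_true(res$usable)
})

test_that("letter rule handles shared letters, odd top letters and ties", {
  base <- tibble::tibble(
    variety = "V", season = "late", year = 1L, stage = "BS",
    n_rate = c(90, 180, 270), replicate = NA_integer_,
    ldm = c(2.0, 2.5, 3.0), pnc = c(1.5, 1.6, 1.7),
    ldm_se = NA_real_, pnc_se = NA_real_, yield = NA_real_,
    sig_letter = c("a", "a", "b")
  )
  # the max-LDM treatment carries "b": only it is non-limited
  lab <- setNames(classify_letters(base)$labels$label,
                  classify_letters(base)$labels$n_rate)
  expect_identical(unname(lab), c("limited", "limited", "non_limited"))

  # multi-letter labels share membership with the top group
  base$sig_letter <- c("c", "ab", "a")
  lab <- setNames(classify_letters(base)$labels$label,
                  classify_letters(base)$labels$n_rate)
  expect_identical(unname(lab), c("limited", "non_limited", "non_limited"))

  # all letters equal: no contrast, unusable
  base$sig_letter <- "a"
  res <- classify_letters(base)
  expect_true(all(res$labels$label == "non_limited"))
  expect_false(res$usable)

  # exact LDM ties at the top are all non-limited
  base$ldm <- c(2.0, 3.0, 3.0)
  base$sig_letter <- c("b", "a", "a")
  res <- classify_letters(base)
  expect_identical(res$labels$label[res$labels$n_rate %in% c(180, 270)],
                   rep("non_limited", 2))
})

test_that("missing letters direct the caller to the ANOVA route", {
  tab <- load_table2_fixture()
  ts <- dplyr::filter(tab, variety == "Fumeizhan", stage == "TS")
  ts$sig_letter <- NA_character_
  expect_error(classify_letters(ts), "classify_anova")
})

test_that("ANOVA route separates a plateau from limited treatments", {
  d <- make_date(means = c(1, 2, 3, 3))
  res <- classify_anova(d, alpha = 0.05)
  lab <- setNames(res$labels$label, res$labels$n_rate)
  expect_identical(unname(lab[c("0", "75")]), rep("limited", 2))
  expect_identical(unname(lab[c("150", "225")]), rep("non_limited", 2))
  expect_true(res$usable)

  # brute-force pairwise t-tests against the top treatment agree here
  top <- d$ldm[d$n_rate == 225]
  for (r in c(0, 75, 150)) {
    p <- t.test(d$ldm[d$n_rate == r], top)$p.value
    expect_identical(unname(lab[as.character(r)]),
                     if (p < 0.05) "limited" else "non_limited")
  }
})

test_that("a no-signal date is unusable with every treatment non-limited", {
  d <- make_date(means = c(2, 2, 2, 2), jitter = 0.01)
  res <- classify_anova(d)
  expect_false(res$usable)
  expect_true(all(res$labels$label == "non_limited"))
  # even exactly identical values (zero-variance ANOVA) degrade gracefully
  d$ldm <- 2
  res <- classify_anova(d)
  expect_false(res$usable)
  expect_true(all(res$labels$label == "non_limited"))
})

test_that("classification is invariant to row order", {
  d <- make_date(means = c(1, 1.6, 2.4, 2.45))
  res1 <- classify_anova(d)
  res2 <- classify_anova(d[rev(seq_len(nrow(d))), ])
  expect_identical(res1$labels, res2$labels)

  tab <- dplyr::filter(load_table2_fixture(), variety == "Changliangyou 173",
                       stage == "JS")
  expect_identical(classify_letters(tab)$labels,
                   classify_letters(tab[sample(4), ])$labels)
})

test_that("raising alpha never un-limits a treatment", {
  alphas <- c(0.01, 0.05, 0.1, 0.2)
  for (seed in 1:10) {
    sim <- simulate_experiment(synthetic_config(seed = seed))
    for (s in c("TS", "HS")) {
      d <- dplyr::filter(sim$table, stage == s)
      prev <- character(0)
      for (a in alphas) {
        lab <- classify_anova(d, alpha = a)$labels
        lim <- lab$n_rate[lab$label == "limited"]
        expect_true(all(prev %in% lim))
        prev <- lim
      }
    }
  }
})

test_that("replicate-poor or rate-poor inputs are refused", {
  d <- make_date(means = c(1, 2, 3, 3))
  expect_error(classify_anova(d[d$replicate == 1, ]), "replicates")
  expect_error(classify_anova(d[d$n_rate %in% c(0, 225), ]), "3 N-rate")
  expect_error(classify_anova(load_table2_fixture()[1:4, ]),
               "replicate-level")
})

test_that("ANOVA labels match a first-principles Tukey oracle", {
  mismatches <- 0L; dates <- 0L
  for (seed in 1:20) {
    sim <- simulate_experiment(synthetic_config(seed = seed))
    for (s in stage_levels()) {
      d <- dplyr::filter(sim$table, stage == s)
      got <- classify_anova(d)$labels
      want <- oracle_tukey_labels(d$ldm, d$n_rate)
      dates <- dates + 1L
      if (!identical(unname(want[as.character(got$n_rate)]), got$label)) {
        mismatches <- mismatches + 1L
      }
    }
  }
  expect_equal(mismatches, 0L)
  expect_equal(dates, 100L)
})

test_that("ANOVA labels and independently derived letters agree", {
  skip_if_not_installed("multcomp")
  agree <- 0L; total <- 0L
  for (seed in 1:15) {
    sim <- simulate_experiment(synthetic_config(seed = seed,
                                                noise_cv = 0.08))
    for (s in stage_levels()) {
      d <- dplyr::filter(sim$table, stage == s)
      d$rate <- factor(d$n_rate)
      fit <- aov(ldm ~ rate, data = d)
      if (summary(fit)[[1]][["Pr(>F)"]][1] >= 0.05) next
      cld <- multcomp::cld(multcomp::glht(
        fit, linfct = multcomp::mcp(rate = "Tukey")))
      means <- dplyr::summarise(dplyr::group_by(d, n_rate),
                                ldm = mean(ldm), pnc = mean(pnc),
                                .groups = "drop")
      means$variety <- "V"; means$season <- "early"; means$year <- 1L
      means$stage <- s; means$replicate <- NA_integer_
      means$sig_letter <- unname(
        cld$mcletters$Letters[as.character(means$n_rate)])
      lab_letters <- classify_letters(means)$labels
      lab_anova <- classify_anova(d)$labels
      total <- total + nrow(lab_anova)
      agree <- agree +
        sum(lab_letters$label[order(lab_letters$n_rate)] ==
              lab_anova$label[order(lab_anova$n_rate)])
    }
  }
  expect_gt(total, 0L)
  expect_gte(agree / total, 0.99)
})
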