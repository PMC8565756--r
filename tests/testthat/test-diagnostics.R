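test_that("NNI is the ratio of measured to critical N with banded status", {
  rec <- compute_nni(c(1.5, 1.2, 0.6), c(1.5, 0.8, 1.2))
  expect_equal(rec$nni, c(1, 1.5, 0.5), tolerance = 1e-12)
  expect_identical(rec$status, c("optimal", "surplus", "deficient"))
  # strict rule
  strict <- compute_nni(c(1.5, 1.500001), c(1.5, 1.5), band = c(1, 1))
  expect_identical(strict$status, c("optimal", "surplus"))
  expect_error(compute_nni(-1, 1), "positive")
  expect_error(compute_nni(1, 0), "positive")
})

test_that("RMSE and n-RMSE match hand arithmetic", {
  expect_equal(rmse(c(2, 4), c(2, 4)), 0)
  expect_equal(rmse(c(2, 4), c(1, 2)), sqrt(5 / 2), tolerance = 1e-12)
  expect_equal(rmse(3, 5), 2)
  expect_error(rmse(1:3, 1:2), "length")
  expect_error(rmse(numeric(0), numeric(0)), "empty")

  expect_equal(n_rmse(c(2, 4), c(2, 4)), 0)
  expect_equal(n_rmse(c(2, 4), c(1, 2)), 100 * sqrt(5 / 2) / 3,
               tolerance = 1e-12)
  expect_error(n_rmse(c(-2, 0), c(1, 1)), "positive")
})

test_that("n-RMSE is invariant to a common rescaling", {
  o <- c(2.1, 3.7, 1.4); p <- c(2.0, 3.9, 1.2)
  for (k in c(0.01, 1, 250)) {
    expect_equal(n_rmse(k * o, k * p), n_rmse(o, p), tolerance = 1e-12)
  }
})

test_that("stability classes cover [0, Inf) with half-open boundaries", {
  expect_identical(stability_class(c(0, 9.99, 10, 10.78, 19.99, 20,
                                     29.99, 30, 1e6)),
                   c("excellent", "excellent", "good", "good", "good",
                     "moderate", "moderate", "poor", "poor"))
  grid <- seq(0, 60, by = 0.25)
  cls <- stability_class(grid)
  expect_false(anyNA(cls))
  expect_setequal(unique(cls), c("excellent", "good", "moderate", "poor"))
  expect_error(stability_class(-1), ">= 0")
})

test_that("relative yield maps the best treatment to 1", {
  expect_equal(relative_yield(c(4, 5)), c(0.8, 1))
  expect_equal(relative_yield(6.2), 1)
  y <- c(3.5, 5.1, 4.8, 4.2)
  perm <- c(3, 1, 4, 2)
  expect_equal(relative_yield(y[perm]), relative_yield(y)[perm])
  expect_error(relative_yield(numeric(0)), "empty")
  expect_error(relative_yield(c(1, -2)), "positive")
})

test_that("the quadratic yield response recovers an exact vertex", {
  nni <- seq(0.5, 1.5, by = 0.1)
  yr <- fit_yield_response(nni, 1 - (nni - 1)^2)
  expect_equal(yr$c0, 0, tolerance = 1e-9)
  expect_equal(yr$c1, 2, tolerance = 1e-9)
  expect_equal(yr$c2, -1, tolerance = 1e-9)
  expect_equal(yr$nni_opt, 1, tolerance = 1e-9)
  expect_equal(yr$ry_max, 1, tolerance = 1e-9)
  expect_equal(yr$r2, 1, tolerance = 1e-12)
  expect_false(yr$convex)
})

test_that("the fitted vertex equals a fine-grid argmax", {
  set.seed(12)
  nni <- runif(15, 0.4, 1.6)
  ry <- 0.95 - 0.9 * (nni - 1.05)^2 + rnorm(15, 0, 0.02)
  yr <- fit_yield_response(nni, ry)
  want <- oracle_quad_argmax(yr$c0, yr$c1, yr$c2, min(nni), max(nni))
  expect_equal(yr$nni_opt, want, tolerance = 1e-4)
  # strict maximum: any step off the vertex loses yield
  for (eps in c(1e-3, 0.05, 0.2)) {
    at <- function(x) yr$c0 + yr$c1 * x + yr$c2 * x^2
    expect_lt(at(yr$nni_opt + eps), yr$ry_max)
    expect_lt(at(yr$nni_opt - eps), yr$ry_max)
  }
})

test_that("an upward-opening response is flagged as a minimum", {
  nni <- seq(0.5, 1.5, by = 0.25)
  expect_warning(yr <- fit_yield_response(nni, (nni - 1)^2), "minimum")
  expect_true(yr$convex)
  expect_error(fit_yield_response(rep(1, 5), 1:5), "rank-deficient")
  expect_error(fit_yield_response(1:3, 1:3), "4")
})

test_that("validating on points from the curve itself is error-free", {
  cv <- dilution_curve(2.66, 0.79)
  ldm <- c(0.9, 1.5, 2.2, 3.0)
  rep <- validate_curve(cv, data.frame(ldm_max = ldm,
                                       nc = 2.66 * ldm^(-0.79)))
  expect_equal(rep$rmse, 0)
  expect_equal(rep$n_rmse, 0)
  expect_identical(rep$stability, "excellent")
  expect_error(validate_curve(cv, data.frame(ldm_max = 1, nc = 2.66)),
               "2 hold-out")
})

test_that("mild hold-out noise keeps validation in the excellent class", {
  cv <- dilution_curve(3, 0.5)
  hits <- sum(vapply(1:200, function(seed) {
    pts <- withr::with_seed(seed, {
      ldm <- exp(runif(8, log(0.6), log(3)))
      data.frame(ldm_max = ldm,
                 nc = 3 * ldm^(-0.5) * exp(rnorm(8, 0, 0.05)))
    })
    validate_curve(cv, pts)$n_rmse < 10
  }, logical(1)))
  expect_gte(hits / 200, 0.9)
})

test_that("observations generated on the curve have NNI exactly 1", {
  cv <- dilution_curve(3, 0.5)
  tab <- tibble::tibble(
    variety = "V", season = "early", year = 1L,
    stage = c("TS", "JS", "BS", "HS"), n_rate = c(0, 75, 150, 225),
    replicate = NA_integer_, ldm = c(0.8, 1.4, 2.1, 2.6), pnc = NA_real_
  )
  tab$pnc <- evaluate_nc(cv, tab$ldm)
  out <- nni_table(tab, cv)
  expect_equal(out$nni, rep(1, 4), tolerance = 1e-12)
  expect_true(all(out$status == "optimal"))
})

test_that("plateau-based NNI uses the date's maximum LDM", {
  tab <- dplyr::filter(load_table2_fixture(), season == "early")
  pts <- extract_critical_points(tab)
  cv <- fit_curve(pts)
  own <- nni_table(tab, cv)
  plat <- nni_table(tab, cv, ldm_basis = "plateau", points = pts)
  key <- paste(plat$variety, plat$stage)
  expect_equal(plat$nc,
               suppressWarnings(
                 evaluate_nc(cv, pts$ldm_max[match(
                   key, paste(pts$variety, pts$stage))])))
  expect_false(isTRUE(all.equal(own$nni, plat$nni)))
})
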