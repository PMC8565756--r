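#' Configuration of a synthetic N-rate trial
#'
#' Assembles and validates the parameters of the synthetic trial generator.
#' The generator emulates the statistical structure the dilution-curve
#' analysis assumes: a true power-law critical curve
#' `Nc% = a_true * LDM^-b_true`, a biomass response that saturates with N
#' rate, N-limited treatments lying below the curve, multiplicative
#' replicate noise, and a quadratic relative-yield response to NNI.
#'
#' Biomass: at stage `s` and rate `r`, mean LDM is
#' `potential_ldm[s] * r_eff(r)` with the saturating (Mitscherlich)
#' availability `r_eff(r) = 1 - 2^-((soil_n + r) / biomass_halfsat)`;
#' `soil_n` (kg/ha) is the baseline soil N supply that lets the zero-N
#' control grow, `biomass_halfsat` the rate scale over which half of the
#' remaining gap to the potential closes, and `r_eff` tends to 1 as the
#' rate grows. Treatments with
#' `r_eff >= 0.95` are non-N-limited; their mean PNC sits on (or, with
#' `luxury_margin > 1`, above) the true curve. Limited treatments sit
#' strictly below it, either on the date's true oblique line
#' (`limited_relation = "linear"`, the geometry the Justes construction
#' assumes, with positive slope `sub_slope_factor * nc / ldm_max`) or
#' scaled down in proportion to N availability
#' (`limited_relation = "proportional"`, PNC multiplied by `r_eff / 0.95`).
#'
#' @param seed Integer seed; required, every stochastic element derives
#'   from it.
#' @param a_true,b_true True curve parameters (`a_true` = critical N % at
#'   LDM = 1 t/ha; `b_true` = dilution exponent); both > 0.
#' @param n_rates N rates in kg/ha, at least 3 levels including 0.
#' @param potential_ldm Named vector of per-stage potential (non-limited)
#'   LDM in t/ha; names are the stage codes, in order.
#' @param soil_n Baseline soil N supply, kg/ha.
#' @param biomass_halfsat Rate scale (kg/ha) of the saturating biomass
#'   response: each additional `biomass_halfsat` of available N closes half
#'   of the remaining gap to the potential LDM.
#' @param luxury_margin Multiplicative PNC surplus of non-limited
#'   treatments; >= 1.
#' @param limited_relation How limited-treatment mean PNC relates to LDM
#'   (see Details).
#' @param sub_slope_factor Slope of the true oblique line in units of
#'   `nc / ldm_max` (linear mode only).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   replicate noise, in `[0, 0.3]`.
#' @param replicates Replicates per treatment, >= 2.
#' @param ry_coeffs Quadratic coefficients `c(c0, c1, c2)` of relative
#'   yield on NNI; `c2 < 0`. The default places the optimum at NNI 1.04
#'   with maximal relative yield 0.96.
#' @param max_yield Yield (t/ha) corresponding to relative yield 1.
#' @param yield_stage Stage whose NNI drives the yield response.
#' @param variety,season,year Labels stamped on the generated records.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed,
                             a_true = 3.0,
                             b_true = 0.5,
                             n_rates = c(0, 75, 150, 225),
                             potential_ldm = c(TS = 0.8, JS = 1.5, BS = 2.2,
                                               HS = 2.6, FHS = 2.4),
                             soil_n = 60,
                             biomass_halfsat = 65,
                             luxury_margin = 1.05,
                             limited_relation = c("linear", "proportional"),
                             sub_slope_factor = 0.5,
                             noise_cv = 0.05,
                             replicates = 3,
                             ry_coeffs = c(-0.1216, 2.08, -1),
                             max_yield = 7,
                             yield_stage = "HS",
                             variety = "SIM",
                             season = "early",
                             year = 1L) {
  limited_relation <- match.arg(limited_relation)
  chk <- function(ok, field, what) {
    if (!ok) stop("invalid synthetic_config field `", field, "`: ", what,
                  call. = FALSE)
  }
  chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
      "seed", "must be a single integer")
  chk(is.numeric(a_true) && a_true > 0, "a_true", "must be > 0")
  chk(is.numeric(b_true) && b_true > 0, "b_true", "must be > 0")
  chk(length(n_rates) >= 3 && all(n_rates >= 0) && 0 %in% n_rates &&
        !anyDuplicated(n_rates),
      "n_rates", "need >= 3 distinct non-negative rates including 0")
  chk(length(potential_ldm) >= 1 && all(potential_ldm > 0) &&
        !is.null(names(potential_ldm)) &&
        all(names(potential_ldm) %in% stage_levels()),
      "potential_ldm", "named per-stage positive LDM, names in stage_levels()")
  chk(soil_n > 0, "soil_n", "must be > 0")
  chk(biomass_halfsat > 0, "biomass_halfsat", "must be > 0")
  chk(luxury_margin >= 1, "luxury_margin", "must be >= 1")
  chk(sub_slope_factor > 0, "sub_slope_factor", "must be > 0")
  chk(noise_cv >= 0 && noise_cv <= 0.3, "noise_cv", "must be in [0, 0.3]")
  chk(replicates >= 2 && replicates == round(replicates),
      "replicates", "must be an integer >= 2")
  chk(length(ry_coeffs) == 3 && ry_coeffs[3] < 0,
      "ry_coeffs", "need c(c0, c1, c2) with c2 < 0")
  chk(max_yield > 0, "max_yield", "must be > 0")
  chk(yield_stage %in% names(potential_ldm),
      "yield_stage", "must be one of the configured stages")
  r_eff <- 1 - 2^(-(soil_n + n_rates) / biomass_halfsat)
  chk(any(r_eff >= 0.95), "n_rates",
      "no rate reaches 95% of potential biomass; raise the top rate or lower biomass_halfsat")
  chk(any(r_eff < 0.95), "n_rates",
      "every rate is non-limited; lower soil_n or raise biomass_halfsat")
  structure(
    list(seed = as.integer(seed), a_true = a_true, b_true = b_true,
         n_rates = sort(n_rates), potential_ldm = potential_ldm,
         soil_n = soil_n, biomass_halfsat = biomass_halfsat,
         luxury_margin = luxury_margin, limited_relation = limited_relation,
         sub_slope_factor = sub_slope_factor, noise_cv = noise_cv,
         replicates = as.integer(replicates), ry_coeffs = ry_coeffs,
         max_yield = max_yield, yield_stage = yield_stage,
         variety = variety, season = season, year = year),
    class = "synthetic_config"
  )
}

# lognormal multiplier with mean exactly 1 and the requested CV
lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a replicate-level synthetic N-rate trial
#'
#' Draws one synthetic experiment under a [synthetic_config()] and returns
#' both the observation table (same format as [read_observations()]) and
#' the ground truth every downstream stage can be checked against. Two
#' calls with the same config are identical; the caller's RNG state is
#' left untouched.
#'
#' Grain yield is attached to the replicates of `yield_stage` only (one
#' harvest per treatment): relative yield is the configured quadratic
#' evaluated at the treatment's true NNI, scaled by `max_yield`, with the
#' same multiplicative noise model as the other traits.
#'
#' @param config A `synthetic_config`.
#' @return A list with elements `table` (tibble of replicate-level
#'   observations) and `truth` (`synthetic_truth`: the config, a
#'   `treatment` tibble with per-(stage, rate) true means, limitation
#'   status and true NNI, and a `stage` tibble with the true critical
#'   point of each date).
#' @examples
#' sim <- simulate_experiment(synthetic_config(seed = 1))
#' head(sim$table)
#' sim$truth$stage
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop("`config` must come from synthetic_config()", call. = FALSE)
  }
  cf <- config
  stages <- names(cf$potential_ldm)
  treat <- expand.grid(stage = stages, n_rate = cf$n_rates,
                       stringsAsFactors = FALSE)
  treat$potential <- cf$potential_ldm[treat$stage]
  treat$r_eff <- 1 - 2^(-(cf$soil_n + treat$n_rate) / cf$biomass_halfsat)
  treat$limited <- treat$r_eff < 0.95
  treat$ldm_true <- treat$potential * treat$r_eff

  curve_nc <- function(ldm) cf$a_true * ldm^(-cf$b_true)
  stage_truth <- do.call(rbind, lapply(stages, function(s) {
    i <- treat$stage == s
    ldm_star <- mean(treat$ldm_true[i & !treat$limited])
    data.frame(stage = s, ldm_max = ldm_star, nc = curve_nc(ldm_star))
  }))

  treat <- dplyr::left_join(treat, stage_truth, by = "stage")
  treat$pnc_true <- ifelse(
    treat$limited,
    switch(cf$limited_relation,
      linear = treat$nc + cf$sub_slope_factor * treat$nc / treat$ldm_max *
        (treat$ldm_true - treat$ldm_max),
      proportional = (treat$r_eff / 0.95) * curve_nc(treat$ldm_true)
    ),
    cf$luxury_margin * curve_nc(treat$ldm_true)
  )
  if (any(treat$pnc_true <= 0)) {
    stop("configuration yields non-positive limited-treatment PNC; ",
         "reduce sub_slope_factor or the rate spread", call. = FALSE)
  }
  treat$nni_true <- treat$pnc_true / curve_nc(treat$ldm_true)

  ry_at <- function(nni) {
    cf$ry_coeffs[1] + cf$ry_coeffs[2] * nni + cf$ry_coeffs[3] * nni^2
  }
  yield_nni <- treat$nni_true[match(
    paste(cf$yield_stage, treat$n_rate), paste(treat$stage, treat$n_rate))]
  treat$ry_true <- pmax(ry_at(yield_nni), 0.05)
  treat$yield_true <- treat$ry_true * cf$max_yield

  tab <- withr::with_seed(cf$seed, {
    rows <- treat[rep(seq_len(nrow(treat)), each = cf$replicates), ]
    rows$replicate <- rep(seq_len(cf$replicates), times = nrow(treat))
    n <- nrow(rows)
    rows$ldm <- rows$ldm_true * lnorm_noise(n, cf$noise_cv)
    rows$pnc <- rows$pnc_true * lnorm_noise(n, cf$noise_cv)
    rows$yield <- ifelse(rows$stage == cf$yield_stage,
                         rows$yield_true * lnorm_noise(n, cf$noise_cv),
                         NA_real_)
    rows
  })

  table <- tibble::tibble(
    variety = cf$variety, season = cf$season, year = cf$year,
    stage = tab$stage, n_rate = tab$n_rate, replicate = tab$replicate,
    ldm = tab$ldm, pnc = tab$pnc, yield = tab$yield,
    ldm_se = NA_real_, pnc_se = NA_real_, sig_letter = NA_character_
  )
  table <- validate_observations(table)

  truth <- structure(
    list(
      config = cf,
      treatment = tibble::tibble(
        stage = treat$stage, n_rate = treat$n_rate,
        ldm_true = treat$ldm_true, pnc_true = treat$pnc_true,
        limited = treat$limited, nni_true = treat$nni_true,
        ry_true = treat$ry_true, yield_true = treat$yield_true
      ),
      stage = tibble::as_tibble(stage_truth)
    ),
    class = "synthetic_truth"
  )
  list(table = table, truth = truth)
}

#' Write the ground truth of a synthetic trial as plain text
#'
#' Emits a key-value sidecar: one `key = value` line per scalar config
#' field, then one line per (stage, rate) truth quantity, so a run can be
#' audited without R.
#'
#' @param truth A `synthetic_truth` from [simulate_experiment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cf <- truth$config
  fmt <- function(x) paste(format(x, digits = 15, trim = TRUE), collapse = ",")
  lines <- c(
    vapply(setdiff(names(cf), "potential_ldm"),
           function(k) paste0(k, " = ", fmt(cf[[k]])), character(1)),
    paste0("potential_ldm = ",
           paste(names(cf$potential_ldm), cf$potential_ldm,
                 sep = ":", collapse = ",")),
    unlist(lapply(seq_len(nrow(truth$treatment)), function(i) {
      r <- truth$treatment[i, ]
      pre <- paste0("treatment[", r$stage, ",", r$n_rate, "].")
      paste0(pre, c("ldm_true", "pnc_true", "limited", "nni_true"), " = ",
             c(fmt(r$ldm_true), fmt(r$pnc_true), fmt(r$limited),
               fmt(r$nni_true)))
    }))
  )
  writeLines(lines, path)
  invisible(path)
}
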