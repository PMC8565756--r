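#' Treatment means of the Jiangxi double-cropped rice N-rate trial
#'
#' Loads the packaged transcription of the published treatment-mean table:
#' leaf dry matter (LDM, t/ha) and plant N concentration (PNC, % of dry
#' weight) for two early-rice varieties ('Zhongjiazao 17',
#' 'Changliangyou 173'; N rates 0/75/150/225 kg/ha) and two late-rice
#' varieties ('Fumeizhan', 'Taiyouhang 1573'; N rates 0/90/180/270 kg/ha)
#' at the five sampling stages TS/JS/BS/HS/FHS. Records are mean-level
#' (no `replicate`), with standard errors (`ldm_se`, `pnc_se`) and the
#' P < 0.05 post-hoc grouping letters of both traits (`sig_letter` for LDM
#' — the column the limitation classification uses — and `pnc_sig_letter`
#' for PNC). The source table does not state which trial year the means
#' represent, so `year` is left missing.
#'
#' @return A tibble of 80 mean-level observations
#'   (2 seasons x 2 varieties x 5 stages x 4 N rates).
#' @examples
#' tab <- load_table2_fixture()
#' dplyr::count(tab, season, variety)
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_rice.csv", package = "ndilute",
                      mustWork = TRUE)
  read_observations(path)
}

#' Published validation summaries of the fixed rice dilution curves
#'
#' Inert reference constants: RMSE (% N) and n-RMSE (%) of the fixed early-
#' and late-rice dilution curves evaluated against an independent trial,
#' one value per validation variety, as printed in the source study. These
#' are comparison values only; nothing in the package computes them (the
#' underlying plot-level validation data are unpublished).
#'
#' @return A tibble with columns `variety`, `season`, `rmse`, `n_rmse`.
#' @export
validation_reference <- function() {
  tibble::tibble(
    variety = c("Zaoxian 618", "Ganxin 203", "Taiyou 398", "Wufengyou T025"),
    season  = c("early", "early", "late", "late"),
    rmse    = c(0.59, 0.54, 0.24, 0.41),
    n_rmse  = c(19.45, 19.25, 10.78, 19.49)
  )
}

#' Published critical N dilution curves from other rice regions
#'
#' Inert reference constants for context: power-law parameters of critical
#' N dilution curves reported for other Chinese rice regions (whole-plant
#' dry matter based). Useful when discussing how leaf-based parameters
#' differ from plant-based ones; not used in any computation.
#'
#' @return A tibble with columns `region`, `season`, `a`, `b`, `accuracy`.
#' @export
literature_curves <- function() {
  tibble::tibble(
    region = c("Northern rice growing area, China",
               "Double-cropped rice area, China",
               "Double-cropped rice area, China",
               "Rice-wheat rotation area, Central China"),
    season = c(NA, "early", "late", NA),
    a = c(1.96, 3.37, 3.69, 3.33),
    b = c(0.56, 0.44, 0.34, 0.26),
    accuracy = c(0.87, 0.82, 0.78, 0.86)
  )
}
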