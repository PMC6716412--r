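#' Outcome definitions
#'
#' The eleven smoking and cancer-screening outcomes the estimation pipeline
#' targets.  Each outcome is a prevalence among a denominator defined by a
#' sex filter and a minimum age: current smoking (overall / men / women,
#' adults 18+), ever smoking (overall / men / women, 18+), mammography in the
#' past 2 years (women 40+), Papanicolaou test in the past 3 years (women
#' 18+), home fecal occult blood test in the past 2 years (adults 50+),
#' colorectal endoscopy ever (50+), and any colorectal screening (50+).
#'
#' @return A data frame with one row per outcome and columns `name`,
#'   `sex_filter` (`"all"`, `"male"` or `"female"`), `min_age` (years) and
#'   `description`.
#' @examples
#' outcome_definitions()
#' @export
outcome_definitions <- function() {
  out <- data.frame(
    name = c(
      "current_smoking_all", "current_smoking_male", "current_smoking_female",
      "ever_smoking_all", "ever_smoking_male", "ever_smoking_female",
      "mammography", "pap_test", "hfobt", "crc_endoscopy", "crc_screening"
    ),
    sex_filter = c(
      "all", "male", "female",
      "all", "male", "female",
      "female", "female", "all", "all", "all"
    ),
    min_age = c(18L, 18L, 18L, 18L, 18L, 18L, 40L, 18L, 50L, 50L, 50L),
    description = c(
      "Currently smokes, smoked >= 100 cigarettes lifetime, adults 18+",
      "Current smoker, men 18+",
      "Current smoker, women 18+",
      "Smoked >= 100 cigarettes lifetime, adults 18+",
      "Ever smoker, men 18+",
      "Ever smoker, women 18+",
      "Mammogram within past 2 years, women 40+",
      "Papanicolaou test within past 3 years, women 18+",
      "Home fecal occult blood test within past 2 years, adults 50+",
      "Colorectal endoscopy ever, adults 50+",
      "HFOBT within 2 years or endoscopy ever, adults 50+"
    ),
    stringsAsFactors = FALSE
  )
  class(out) <- c("outcome_definitions", "data.frame")
  out
}

#' Look up a single outcome definition
#'
#' @param name Outcome name; one of `outcome_definitions()$name`.
#' @return One-row data frame with the outcome's denominator filters.
#' @examples
#' outcome_definition("mammography")
#' @export
outcome_definition <- function(name) {
  defs <- outcome_definitions()
  hit <- defs[defs$name == name, , drop = FALSE]
  if (nrow(hit) != 1L) {
    stop("unknown outcome '", name, "'; see outcome_definitions()",
         call. = FALSE)
  }
  hit
}

# Restrict respondent rows to an outcome's denominator.  Rows lacking age or
# sex columns are kept (filters only apply when the information is present).
filter_denominator <- function(rows, outcome) {
  if (is.null(outcome)) return(rows)
  if (is.character(outcome)) outcome <- outcome_definition(outcome)
  keep <- rep(TRUE, nrow(rows))
  if (!is.null(rows$age)) keep <- keep & rows$age >= outcome$min_age
  if (!is.null(rows$sex) && outcome$sex_filter != "all") {
    keep <- keep & rows$sex == outcome$sex_filter
  }
  rows[keep, , drop = FALSE]
}
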