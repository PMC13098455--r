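#' Attribute set for a best-worst scaling study
#'
#' An attribute set binds short attribute codes (used in survey files and
#' model output) to human-readable labels. Codes must be unique; the order
#' given here is the order used for design binding and reporting.
#'
#' @param codes Character vector of unique short codes.
#' @param labels Character vector of labels, same length as `codes`.
#' @return An object of class `bws_attributes`: a data frame with columns
#'   `code` and `label`.
#' @seealso [nurse_sow_attributes()] for the bundled seven-attribute set.
#' @export
attribute_set <- function(codes, labels = codes) {
  codes <- as.character(codes)
  labels <- as.character(labels)
  if (length(codes) != length(labels)) {
    stop("`codes` and `labels` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(codes)) {
    stop("attribute codes must be unique", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("attribute labels must be unique", call. = FALSE)
  }
  structure(
    data.frame(code = codes, label = labels, stringsAsFactors = FALSE),
    class = c("bws_attributes", "data.frame")
  )
}

#' Nurse-sow selection attributes
#'
#' The seven candidate attributes a farrow-wean farm manager weighs when
#' picking a recently weaned sow to nurse surplus piglets: the health and
#' size of the litter the sow currently has, her body condition, functional
#' teat count, lactation stage, behaviour, and parity.
#'
#' @return A [attribute_set()] of the seven attributes, in reporting order:
#'   SCLH, BCS, SCLS, STN, LS, SB, P.
#' @export
nurse_sow_attributes <- function() {
  attribute_set(
    codes = c("SCLH", "BCS", "SCLS", "STN", "LS", "SB", "P"),
    labels = c(
      "Sow's Current Litter Health",
      "Body Condition Score",
      "Sow's Current Litter Size",
      "Sow's Teat Number",
      "Lactation Stage",
      "Sow Behavior",
      "Parity"
    )
  )
}

#' Demographic strata of the surveyed manager cohort
#'
#' Marginal category proportions for the five demographic variables recorded
#' in the survey (gender, age band, years of pig-farming experience,
#' education, and sow herd size managed), expressed as fractions of the
#' 51-manager cohort. These are the default strata for
#' [simulate_respondents()].
#'
#' @return Named list; each element is a named two-element probability
#'   vector summing to 1.
#' @export
study_strata <- function() {
  list(
    gender          = c(female = 18 / 51, male = 33 / 51),
    age_band        = c("18-40" = 24 / 51, ">40" = 27 / 51),
    experience_band = c("<=10yr" = 26 / 51, ">10yr" = 25 / 51),
    education       = c(college = 15 / 51, professional = 36 / 51),
    herd_band       = c("<=5000" = 19 / 51, ">5000" = 32 / 51)
  )
}

#' Illustrative latent utility profile for the nurse-sow attributes
#'
#' A plausible generating utility vector for simulation scenarios, taken
#' from the pooled conditional-logit estimates of the survey (reference
#' attribute Parity fixed at 0). These are illustrative simulation inputs,
#' not ground truth for any real population.
#'
#' @return Named numeric vector of length 7 with `P = 0`.
#' @export
default_utilities <- function() {
  c(SCLH = 1.744, BCS = 1.455, SCLS = 0.811, STN = 0.697,
    LS = 0.485, SB = 0.431, P = 0)
}
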