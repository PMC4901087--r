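# Harmonised lifestyle covariate categorisations and the joint
# favourable/unfavourable lifestyle profiles.

#' Body-mass-index category
#'
#' BMI = weight / height^2 (kg/m^2), categorised with each upper category
#' closed on the left: underweight < 18.5, normal 18.5 to <25, overweight
#' 25 to <30, obese >= 30.
#'
#' @param height Height in metres (> 0).
#' @param weight Weight in kilograms (>= 0).
#' @return Character vector of categories.
#' @examples
#' bmi_category(1.70, 72.2)   # BMI 24.98 -> "normal"
#' bmi_category(1.70, 72.25)  # BMI 25.0  -> "overweight"
#' @export
bmi_category <- function(height, weight) {
  if (any(!is.finite(height)) || any(height <= 0))
    stop("height must be positive (metres)", call. = FALSE)
  if (any(!is.finite(weight)) || any(weight < 0))
    stop("weight must be nonnegative (kg)", call. = FALSE)
  bmi <- weight / height^2
  cuts <- c(-Inf, 18.5, 25, 30, Inf)
  labs <- c("underweight", "normal", "overweight", "obese")
  labs[findInterval(bmi, cuts, left.open = FALSE)]
}

#' Alcohol intake category
#'
#' Sex-specific daily alcohol categories: abstainer (0 g daily);
#' light/moderate (men >0 and <60 g, women >0 and <40 g); heavy closed at
#' the threshold (men >= 60 g, women >= 40 g).
#'
#' @param daily_grams Daily alcohol intake in grams (>= 0).
#' @param sex `"male"` or `"female"` (recycled).
#' @return Character vector of categories.
#' @export
alcohol_category <- function(daily_grams, sex) {
  if (any(!is.finite(daily_grams)) || any(daily_grams < 0))
    stop("daily alcohol intake must be nonnegative (g/day)", call. = FALSE)
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'", call. = FALSE)
  n <- max(length(daily_grams), length(sex))
  daily_grams <- rep_len(daily_grams, n)
  thr <- ifelse(rep_len(sex, n) == "male", 60, 40)
  ifelse(daily_grams == 0, "abstainer",
         ifelse(daily_grams >= thr, "heavy", "light_moderate"))
}

#' Joint lifestyle profile
#'
#' Builds the joint lifestyle evaluation profiles: both kinds are
#' overweight (not obese) light/moderate drinkers; the favourable profile
#' is additionally a non-smoker who partakes in vigorous physical activity,
#' the unfavourable profile a smoker who does not.  The profiles therefore
#' differ in exactly two fields (smoking and vigorous physical activity).
#'
#' @param kind `"favourable"` or `"unfavourable"`.
#' @param sex `"male"` or `"female"`.
#' @param background A profile (or named list) supplying the remaining
#'   covariates, at least `diabetes`, `hypertension` and `tc_hdl_ratio`
#'   (typically the [cohort_mean_profile()]).
#' @param nonsmoker How "non-smoker" is coded in the favourable profile:
#'   `"never"` (default) or `"never_former"` (never and former smokers
#'   pooled with equal weight).
#' @return A [covariate_profile()].
#' @export
lifestyle_profile <- function(kind = c("favourable", "unfavourable"),
                              sex = c("male", "female"), background,
                              nonsmoker = c("never", "never_former")) {
  kind <- match.arg(kind)
  sex <- match.arg(sex)
  nonsmoker <- match.arg(nonsmoker)
  bg <- unclass(background)
  need <- c("diabetes", "hypertension", "tc_hdl_ratio")
  miss <- setdiff(need, names(bg))
  if (length(miss))
    stop("background profile must supply: ",
         paste(miss, collapse = ", "), call. = FALSE)
  bg$sex <- sex
  bg$bmi_cat <- "overweight"
  bg$alcohol_cat <- "light_moderate"
  if (kind == "favourable") {
    bg$smoking <- if (nonsmoker == "never") "never" else
      c(never = 0.5, former = 0.5, current = 0)
    bg$vigorous_pa <- "yes"
  } else {
    bg$smoking <- "current"
    bg$vigorous_pa <- "no"
  }
  do.call(covariate_profile, bg)
}

#' Derive analysis-ready covariate categories from raw measurements
#'
#' Adds `bmi_cat` (from `height` and `weight`) and `alcohol_cat` (from
#' `daily_alcohol` and `sex`) columns to a raw covariate table.  Smoking,
#' physical activity, diabetes and hypertension are accepted pre-coded and
#' validated only.
#'
#' @param data Data frame with columns `sex`, `height` (m), `weight` (kg),
#'   `daily_alcohol` (g/day) plus any pre-coded covariate columns.
#' @return `data` with `bmi_cat` and `alcohol_cat` columns added.
#' @export
code_covariates <- function(data) {
  for (col in c("sex", "height", "weight", "daily_alcohol"))
    if (is.null(data[[col]]))
      stop("data lacks column '", col, "'", call. = FALSE)
  data$bmi_cat <- bmi_category(data$height, data$weight)
  data$alcohol_cat <- alcohol_category(data$daily_alcohol, data$sex)
  for (col in intersect(names(.cvd_covariate_catalogue), names(data))) {
    info <- .cvd_covariate_catalogue[[col]]
    if (info$type == "factor") {
      bad <- !is.na(data[[col]]) & !(data[[col]] %in% info$levels)
      if (any(bad))
        stop("invalid values in '", col, "': ",
             paste(unique(data[[col]][bad]), collapse = ", "),
             call. = FALSE)
    }
  }
  data
}

#' Carry covariate values forward within subject
#'
#' Fills missing covariate cells with the most recent available value for
#' the same subject (last observation carried forward), the
#' repeated-measures rule used when an event occurs between contacts.
#'
#' @param data Long-format observation data ordered within subject by age.
#' @param covariates Columns to fill; defaults to every catalogue covariate
#'   present.
#' @return `data` with covariate cells filled.
#' @export
carry_forward <- function(data,
                          covariates = intersect(
                            names(.cvd_covariate_catalogue), names(data))) {
  data <- data[order(data$subject_id, data$age), , drop = FALSE]
  for (col in covariates) {
    v <- data[[col]]
    filled <- !is.na(v)
    idx <- cumsum(filled)
    # reset the carry at subject boundaries: a subject's first record may
    # not inherit the previous subject's value
    first_filled <- stats::ave(filled, data$subject_id, FUN = cumsum)
    v_f <- v[filled][pmax(idx, 1L)]
    v_f[idx == 0L | first_filled == 0L] <- NA
    data[[col]] <- v_f
  }
  data
}
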