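# Orchestration of the two analyses the package reports: per-risk-factor
# life-expectancy tables (one fitted model per tabulated lifestyle factor,
# adjusted for age, sex, the other lifestyle factors, diabetes,
# hypertension and the cholesterol ratio; life expectancy per category at
# the starting age with the other covariates at cohort means), and the
# joint favourable-versus-unfavourable lifestyle comparison.

.lifestyle_factors <- c("smoking", "vigorous_pa", "bmi_cat", "alcohol_cat")

#' Analysis configuration
#'
#' @param factors Lifestyle risk factors to tabulate.
#' @param adjusters Additional adjustment covariates applied to every model
#'   (sex and age are always included; each tabulated factor's model also
#'   adjusts for the other lifestyle factors).
#' @param sexes Sexes to evaluate.
#' @param grid A [le_grid()].
#' @param n_draws Parameter draws for percentile intervals.
#' @param seed Base RNG seed; per-factor seeds are derived from it.
#' @param step Age-discretisation step (years) used in fitting.
#' @param single_model If `TRUE`, fit one model containing all four
#'   lifestyle factors and tabulate every factor from it (off by default;
#'   the default refits per tabulated factor).
#' @param nonsmoker Coding of "non-smoker" in the favourable joint profile
#'   (see [lifestyle_profile()]).
#' @param level Interval level.
#' @return An object of class `cvd_analysis_config`.
#' @export
analysis_config <- function(factors = .lifestyle_factors,
                            adjusters = c("diabetes", "hypertension",
                                          "tc_hdl_ratio"),
                            sexes = c("male", "female"),
                            grid = le_grid(), n_draws = 1000L, seed = 1L,
                            step = 0.5, single_model = FALSE,
                            nonsmoker = "never", level = 0.95) {
  stopifnot(all(factors %in% .lifestyle_factors))
  structure(list(factors = factors, adjusters = adjusters, sexes = sexes,
                 grid = .as_le_grid(grid), n_draws = as.integer(n_draws),
                 seed = seed, step = step, single_model = single_model,
                 nonsmoker = nonsmoker, level = level),
            class = "cvd_analysis_config")
}

.as_records <- function(data) {
  if (inherits(data, "cvd_cohort")) data$data else data
}

# Component draws and point estimates for a named list of profiles, all on
# the same parameter draws (so between-profile differences are paired).
.profile_le_draws <- function(fit, profiles, grid, n_draws, seed) {
  draws <- .fit_draws(fit, n_draws, seed)
  out <- list()
  for (nm in names(profiles)) {
    dl <- .draws_lp(draws, fit$spec, profiles[[nm]])
    r <- .occ_le(dl$lp12, dl$lp13, dl$lp23, dl$b12, dl$b13, dl$b23,
                 dl$age_center, grid)
    pt <- life_expectancy(fit$estimates, profiles[[nm]], grid)
    out[[nm]] <- list(free = r$le_free, with = r$le_with, point = pt)
  }
  out
}

.pct <- function(v, level) {
  a <- (1 - level) / 2
  unname(stats::quantile(v, c(a, 1 - a)))
}

# One output row: point estimates with percentile intervals, plus paired
# differences against a reference profile's draws (NULL for the reference
# row itself).
.le_row <- function(ld, ref_ld, level) {
  pt <- ld$point
  row <- data.frame(
    le_total = pt$le_total, le_free = pt$le_free, le_with = pt$le_with)
  tot <- ld$free + ld$with
  ci <- rbind(.pct(tot, level), .pct(ld$free, level), .pct(ld$with, level))
  row[c("total_lo", "total_hi")] <- ci[1L, ]
  row[c("free_lo", "free_hi")] <- ci[2L, ]
  row[c("with_lo", "with_hi")] <- ci[3L, ]
  if (is.null(ref_ld)) {
    row[c("dif_total", "dif_total_lo", "dif_total_hi",
          "dif_free", "dif_free_lo", "dif_free_hi",
          "dif_with", "dif_with_lo", "dif_with_hi")] <- NA_real_
  } else {
    rpt <- ref_ld$point
    d_free <- ld$free - ref_ld$free
    d_with <- ld$with - ref_ld$with
    row$dif_free <- pt$le_free - rpt$le_free
    row$dif_with <- pt$le_with - rpt$le_with
    row$dif_total <- row$dif_free + row$dif_with
    row[c("dif_total_lo", "dif_total_hi")] <- .pct(d_free + d_with, level)
    row[c("dif_free_lo", "dif_free_hi")] <- .pct(d_free, level)
    row[c("dif_with_lo", "dif_with_hi")] <- .pct(d_with, level)
  }
  row
}

#' Per-risk-factor life-expectancy analysis
#'
#' For each tabulated lifestyle factor, fits the illness-death model
#' (exposure plus adjusters), then evaluates total, disease-free and
#' with-disease life expectancy at `grid$start_age` for each category
#' level and each sex, with the other covariates fixed at the baseline
#' cohort means, and paired differences against the factor's reference
#' level.  Category levels with no baseline subjects of that sex are
#' omitted with a warning.
#'
#' @param data Long-format observation data or a [simulate_cohort()]
#'   result.
#' @param config An [analysis_config()].
#' @return An object of class `cvd_le_tables`: `table` (one row per sex x
#'   factor x level), `fits` (per factor), `n_subjects`, `exclusions`,
#'   `config`.
#' @export
run_risk_factor_analysis <- function(data, config = analysis_config()) {
  stopifnot(inherits(config, "cvd_analysis_config"))
  data <- apply_exclusions(.as_records(data))
  excl <- attr(data, "exclusions")
  validate_histories(data)
  baseline <- data[!duplicated(data$subject_id), , drop = FALSE]
  means <- cohort_mean_profile(data)
  fits <- list()
  rows <- list()
  shared_fit <- NULL
  if (config$single_model) {
    spec <- model_spec(covariates = unique(c(.lifestyle_factors, "sex",
                                             config$adjusters)))
    shared_fit <- fit_model(data, spec,
                            options = list(step = config$step))
  }
  for (fi in seq_along(config$factors)) {
    f <- config$factors[[fi]]
    fit <- if (config$single_model) shared_fit else {
      covs <- unique(c(f, setdiff(.lifestyle_factors, f), "sex",
                       config$adjusters))
      fit_model(data, model_spec(covariates = covs),
                options = list(step = config$step))
    }
    fits[[f]] <- fit
    levels <- .cvd_covariate_catalogue[[f]]$levels
    ref <- .cvd_covariate_catalogue[[f]]$ref
    for (sex in config$sexes) {
      counts <- vapply(levels, function(lv)
        sum(baseline$sex == sex & baseline[[f]] == lv), integer(1))
      present <- levels[counts > 0]
      if (length(absent <- setdiff(levels, present)))
        warning(sprintf(
          "factor %s, sex %s: omitting level(s) with no baseline ",
          f, sex), "subjects: ", paste(absent, collapse = ", "),
          call. = FALSE)
      profiles <- lapply(stats::setNames(nm = present), function(lv) {
        p <- set_profile(means, sex = sex)
        args <- list(p); args[[f]] <- lv
        do.call(set_profile, args)
      })
      ld <- .profile_le_draws(fit, profiles, config$grid, config$n_draws,
                              seed = config$seed + 1000L * fi +
                                match(sex, config$sexes))
      for (lv in present) {
        row <- .le_row(ld[[lv]],
                       if (lv == ref || !(ref %in% present)) NULL
                       else ld[[ref]],
                       config$level)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(factor = f, sex = sex, level = lv,
                     is_ref = lv == ref, n_baseline = counts[[lv]],
                     stringsAsFactors = FALSE), row)
      }
    }
  }
  structure(list(table = do.call(rbind, rows), fits = fits,
                 n_subjects = length(unique(data$subject_id)),
                 exclusions = excl, means = means, config = config),
            class = "cvd_le_tables")
}

#' Joint favourable-versus-unfavourable lifestyle analysis
#'
#' Fits one model containing all four lifestyle factors plus adjusters and
#' evaluates life expectancy for the joint favourable and unfavourable
#' lifestyle profiles per sex (unfavourable is the reference), together
#' with the count of baseline subjects matching each profile's four
#' lifestyle fields.
#'
#' @inheritParams run_risk_factor_analysis
#' @return An object of class `cvd_joint_table`.
#' @export
run_joint_analysis <- function(data, config = analysis_config()) {
  stopifnot(inherits(config, "cvd_analysis_config"))
  data <- apply_exclusions(.as_records(data))
  excl <- attr(data, "exclusions")
  validate_histories(data)
  baseline <- data[!duplicated(data$subject_id), , drop = FALSE]
  means <- cohort_mean_profile(data)
  smk_ok <- function(kind) {
    if (kind == "favourable") {
      if (config$nonsmoker == "never") baseline$smoking == "never"
      else baseline$smoking %in% c("never", "former")
    } else baseline$smoking == "current"
  }
  pa_target <- c(favourable = "yes", unfavourable = "no")
  # baseline cell counts first: sparse joint cells are a data problem and
  # should be reported before any model is fitted
  counts <- list()
  for (sex in config$sexes) {
    counts[[sex]] <- sapply(c("favourable", "unfavourable"),
                            function(kind)
      sum(baseline$sex == sex & smk_ok(kind) &
            baseline$vigorous_pa == pa_target[[kind]] &
            baseline$bmi_cat == "overweight" &
            baseline$alcohol_cat == "light_moderate"))
    for (kind in names(counts[[sex]]))
      if (counts[[sex]][[kind]] == 0)
        stop("no baseline subjects match the ", kind, " profile for ",
             sex, "s; joint cells are too sparse - use a larger ",
             "(synthetic) cohort", call. = FALSE)
  }
  spec <- model_spec(covariates = unique(c(.lifestyle_factors, "sex",
                                           config$adjusters)))
  fit <- fit_model(data, spec, options = list(step = config$step))
  rows <- list()
  for (sex in config$sexes) {
    profiles <- lapply(
      stats::setNames(nm = c("favourable", "unfavourable")),
      function(kind) lifestyle_profile(kind, sex, means,
                                       nonsmoker = config$nonsmoker))
    ld <- .profile_le_draws(fit, profiles, config$grid, config$n_draws,
                            seed = config$seed + 9000L +
                              match(sex, config$sexes))
    for (kind in c("favourable", "unfavourable")) {
      row <- .le_row(ld[[kind]],
                     if (kind == "favourable") ld[["unfavourable"]]
                     else NULL, config$level)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(sex = sex, profile = kind,
                   is_ref = kind == "unfavourable",
                   n_baseline = counts[[sex]][[kind]],
                   stringsAsFactors = FALSE),
        row)
    }
  }
  structure(list(table = do.call(rbind, rows), fit = fit,
                 n_subjects = length(unique(data$subject_id)),
                 exclusions = excl, means = means, config = config),
            class = "cvd_joint_table")
}

# ---- rendering -----------------------------------------------------------

.fmt_ci <- function(x, lo, hi, digits) {
  sprintf(paste0("%.", digits, "f (%.", digits, "f; %.", digits, "f)"),
          x, lo, hi)
}

# Character matrix of the six tabulated columns; rounding happens only
# here, at render time.
.render_rows <- function(tab, digits = 1) {
  dif <- function(v, lo, hi, ref)
    ifelse(ref, "Ref", .fmt_ci(v, lo, hi, digits))
  cbind(
    `Total LE (years)` = .fmt_ci(tab$le_total, tab$total_lo, tab$total_hi,
                                 digits),
    `Dif total LE (years)` = dif(tab$dif_total, tab$dif_total_lo,
                                 tab$dif_total_hi, tab$is_ref),
    `LE free of CVD (years)` = .fmt_ci(tab$le_free, tab$free_lo,
                                       tab$free_hi, digits),
    `Dif LE free of CVD (years)` = dif(tab$dif_free, tab$dif_free_lo,
                                       tab$dif_free_hi, tab$is_ref),
    `LE with CVD (years)` = .fmt_ci(tab$le_with, tab$with_lo, tab$with_hi,
                                    digits),
    `Dif LE with CVD (years)` = dif(tab$dif_with, tab$dif_with_lo,
                                    tab$dif_with_hi, tab$is_ref))
}

#' Render a life-expectancy table as aligned text
#'
#' Mirrors the published layout: one block per sex, rows per category
#' level (reference rows printed "Ref" in the difference columns), values
#' rounded to `digits` decimals only at render time.
#'
#' @param x A `cvd_le_tables` or `cvd_joint_table` result.
#' @param digits Decimals (default 1).
#' @return Character vector of lines, invisibly printed by the print
#'   methods.
#' @export
format_le_table <- function(x, digits = 1) {
  tab <- x$table
  joint <- inherits(x, "cvd_joint_table")
  cells <- .render_rows(tab, digits)
  label <- if (joint) {
    sprintf("  %-14s n=%-5d", tab$profile, tab$n_baseline)
  } else sprintf("  %-12s %-15s", tab$factor, tab$level)
  lines <- character(0)
  for (sex in unique(tab$sex)) {
    lines <- c(lines, sprintf("*%s*",
                              paste0(toupper(substring(sex, 1, 1)),
                                     substring(sex, 2))))
    sel <- which(tab$sex == sex)
    block <- cbind(label[sel], cells[sel, , drop = FALSE])
    widths <- apply(nchar(rbind(c("", colnames(cells)), block)), 2, max)
    hdr <- paste(mapply(formatC, c("", colnames(cells)), width = widths,
                        MoreArgs = list(flag = "-")), collapse = "  ")
    body <- apply(block, 1, function(r)
      paste(mapply(formatC, r, width = widths,
                   MoreArgs = list(flag = "-")), collapse = "  "))
    lines <- c(lines, hdr, body)
  }
  lines
}

#' @export
print.cvd_le_tables <- function(x, digits = 1, ...) {
  cat(sprintf(
    "Life expectancy at age %g by risk factor (%d subjects)\n",
    x$config$grid$start_age, x$n_subjects))
  cat(format_le_table(x, digits), sep = "\n")
  invisible(x)
}

#' @export
print.cvd_joint_table <- function(x, digits = 1, ...) {
  cat(sprintf(
    "Joint lifestyle analysis at age %g (%d subjects)\n",
    x$config$grid$start_age, x$n_subjects))
  cat(format_le_table(x, digits), sep = "\n")
  invisible(x)
}

#' Write analysis outputs
#'
#' Writes the results table as CSV, the rendered text table, and a run
#' manifest (seed, settings, subject counts at each exclusion step) into a
#' directory.
#'
#' @param x A `cvd_le_tables` or `cvd_joint_table`.
#' @param path Output directory.
#' @param stem File-name stem (default derived from the class).
#' @export
write_le_tables <- function(x, path, stem = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  stem <- stem %||%
    if (inherits(x, "cvd_joint_table")) "joint" else "risk_factors"
  utils::write.csv(x$table, file.path(path, paste0(stem, ".csv")),
                   row.names = FALSE, quote = FALSE)
  writeLines(format_le_table(x), file.path(path, paste0(stem, ".txt")))
  cfg <- x$config
  jsonlite::write_json(
    list(seed = cfg$seed, n_draws = cfg$n_draws, step = cfg$step,
         grid = unclass(cfg$grid), factors = cfg$factors,
         adjusters = cfg$adjusters,
         n_subjects = x$n_subjects,
         exclusions = as.list(x$exclusions),
         r_version = as.character(getRversion())),
    file.path(path, paste0(stem, "_manifest.json")),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}
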