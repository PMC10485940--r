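#' Configuration for a full study run
#'
#' Collects the tunables of [run_study()] in one validated list.
#'
#' @param radix Life-table radix (default 100,000).
#' @param smooth_order Graduation window for `qx` (odd; `NULL` to skip).
#' @param extension_families Candidate old-age families (default: all nine).
#' @param fit_window Ages used to fit the old-age extension, default
#'   `c(65, 84)`; large populations with reliable oldest-old data may prefer
#'   `c(75, 94)`.
#' @param splice_age First age replaced by the extension model (`NULL`: one
#'   past the fit window).
#' @param blend_width Log-linear ramp width at the splice (ages).
#' @param max_age Oldest age of the extended tables (default 100).
#' @param family_overrides Named list `group_id -> family` forcing a family
#'   for specific groups (e.g. a conventional family for the general
#'   population) instead of criterion-based selection.
#' @param report_ages Group-start ages of the abridged report.
#' @param hale_definitions Prevalence definitions to compute HALE for
#'   (`NULL`: every definition present in the prevalence input).
#' @param prevalence_variance Add the binomial prevalence term to HALE
#'   intervals (requires denominators).
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(radix = 1e5, smooth_order = 9,
                         extension_families = all_families(),
                         fit_window = c(65L, 84L), splice_age = NULL,
                         blend_width = 5L, max_age = 100L,
                         family_overrides = list(),
                         report_ages = seq(0L, 85L, 5L),
                         hale_definitions = NULL,
                         prevalence_variance = FALSE) {
  structure(
    list(
      radix = radix, smooth_order = smooth_order,
      extension_families = extension_families, fit_window = as.integer(fit_window),
      splice_age = splice_age, blend_width = blend_width, max_age = as.integer(max_age),
      family_overrides = family_overrides, report_ages = as.integer(report_ages),
      hale_definitions = hale_definitions, prevalence_variance = prevalence_variance
    ),
    class = "study_config"
  )
}

#' Names of all registered extension families
#'
#' Convenience accessor equal to `names(extension_families())`.
#' @export
all_families <- function() names(extension_families())

#' Run the full estimation chain
#'
#' For every sex present: builds the standard (all-subgroup) and reference
#' complete life tables with old-age extension and graduation; imputes gapped
#' subgroup rates through the logit link to the standard table; extends and
#' tabulates every subgroup; computes Sullivan HALE under each requested
#' prevalence definition; abridges to the report ages; and derives
#' between-group differences against the reference. Deterministic: re-running
#' with the same inputs reproduces every output exactly.
#'
#' @param mortality A tibble of mortality schedules for all groups (columns
#'   `group_id, sex, age, person_years, deaths`).
#' @param reference_group Group id differences are measured against (e.g. the
#'   non-disabled population).
#' @param standard_group Group id of the standard table used for imputing
#'   sparse subgroups (e.g. all disabled combined).
#' @param prevalence Optional tibble of grouped prevalence schedules
#'   (columns `definition, sex, group_id, age_lo, age_hi, pi[, denom]`).
#' @param config A [study_config()].
#' @return A list of class `"lifehale_study"` with elements `tables` (named
#'   `sex.group_id`, complete life tables), `abridged` (one tibble),
#'   `differences` (reference minus group per report age and metric),
#'   `extension` (per-group selection diagnostics), `config`.
#' @export
run_study <- function(mortality, reference_group, standard_group,
                      prevalence = NULL, config = study_config()) {
  mortality <- tibble::as_tibble(mortality)
  known <- unique(mortality$group_id)
  for (g in c(reference_group, standard_group)) {
    if (!g %in% known) {
      rlang::abort(sprintf("group '%s' not present in the mortality input", g),
        class = "lifehale_validation_error"
      )
    }
  }
  definitions <- config$hale_definitions
  if (is.null(definitions) && !is.null(prevalence)) {
    definitions <- unique(prevalence$definition)
  }
  tables <- list()
  extension_log <- list()
  abridged <- list()
  for (sx in unique(mortality$sex)) {
    mort_sx <- dplyr::filter(mortality, .data$sex == sx)
    groups <- unique(mort_sx$group_id)
    build <- function(group, standard_table = NULL) {
      sched <- mortality_schedule(dplyr::filter(mort_sx, .data$group_id == group))
      sched <- compute_mx(sched)
      if (anyNA(sched$mx)) {
        if (is.null(standard_table)) {
          rlang::abort(
            sprintf("stage imputation: group '%s' (%s) has gaps but no standard table", group, sx),
            class = "lifehale_stage_error"
          )
        }
        sched <- impute_rates(sched, standard_table)
      }
      forced <- config$family_overrides[[group]]
      fit <- tryCatch(
        if (is.null(forced)) {
          select_extension(sched, config$fit_window, families = config$extension_families)
        } else {
          fit_extension(sched, forced, config$fit_window)
        },
        error = function(e) {
          rlang::abort(
            sprintf("stage extension failed for group '%s' (%s): %s", group, sx, conditionMessage(e)),
            class = "lifehale_stage_error"
          )
        }
      )
      splice <- if (is.null(config$splice_age)) config$fit_window[2] + 1L else config$splice_age
      ext <- extend_mortality(sched, fit,
        splice_age = splice, max_age = config$max_age,
        blend_width = config$blend_width
      )
      lt <- life_table(ext,
        radix = config$radix, smooth_order = config$smooth_order, quiet = TRUE
      )
      if (!is.null(prevalence) && length(definitions) > 0) {
        for (def in definitions) {
          prev <- dplyr::filter(
            prevalence,
            .data$definition == def, .data$sex == sx, .data$group_id == group
          )
          if (nrow(prev) == 0) next
          withme <- sullivan_hale(lt, prev,
            definition = def,
            prevalence_variance = config$prevalence_variance, quiet = TRUE
          )
          keep <- c("hale", "se_hale", "hale_lo95", "hale_hi95")
          for (k in keep) lt[[paste0(k, "_", def)]] <- withme[[k]]
        }
      }
      list(table = lt, fit = fit)
    }
    std <- build(standard_group)
    for (group in groups) {
      res <- if (group == standard_group) std else build(group, standard_table = std$table)
      key <- paste(sx, group, sep = ".")
      tables[[key]] <- res$table
      extension_log[[key]] <- dplyr::mutate(
        if (!is.null(res$fit$selection)) res$fit$selection else glance(res$fit),
        group_id = group, sex = sx, chosen = .data$family == res$fit$family
      )
      abridged[[key]] <- abridge_life_table(res$table, config$report_ages) |>
        dplyr::mutate(group_id = group, sex = sx, .before = 1)
    }
  }
  abridged_tbl <- purrr::list_rbind(abridged)
  diffs <- difference_report(
    dplyr::rename(abridged_tbl, age = "age_start"),
    reference = reference_group
  )
  structure(
    list(
      tables = tables,
      abridged = abridged_tbl,
      differences = diffs,
      extension = purrr::list_rbind(extension_log),
      config = config
    ),
    class = "lifehale_study"
  )
}

#' @export
print.lifehale_study <- function(x, ...) {
  cat(sprintf(
    "<lifehale_study> %d complete tables, %d abridged rows, %d difference rows\n",
    length(x$tables), nrow(x$abridged), nrow(x$differences)
  ))
  invisible(x)
}

#' Between-group differences in LE and HALE
#'
#' Computes reference-minus-group differences for life expectancy and every
#' HALE column present, at each requested age, on full-precision values. A
#' `diff_printed` column repeats the computation on values rounded to two
#' decimals — the precision of published report tables — so printed-table
#' concordance can be checked without feeding rounded values into anything
#' downstream.
#'
#' @param data A tibble with columns `group_id, sex, age, ex` and optionally
#'   `hale*` columns — typically the `abridged` element of a study, but any
#'   keyed table of expectancies works (published values included).
#' @param reference Group id to difference against.
#' @param ages Optional ages to retain (default: all shared ages).
#' @return A tibble `group_id, sex, age, metric, reference_value,
#'   group_value, diff, diff_printed`.
#' @export
difference_report <- function(data, reference, ages = NULL) {
  tbl <- tibble::as_tibble(data)
  if (!"age" %in% names(tbl) && "age_start" %in% names(tbl)) {
    tbl <- dplyr::rename(tbl, age = "age_start")
  }
  metrics <- c("ex", grep("^hale(_[A-Za-z]+)?$", names(tbl), value = TRUE))
  if (!reference %in% tbl$group_id) {
    rlang::abort(sprintf("reference group '%s' absent from the table", reference),
      class = "lifehale_validation_error"
    )
  }
  long <- tbl |>
    dplyr::select(dplyr::all_of(c("group_id", "sex", "age", metrics))) |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric", values_to = "value")
  ref <- long |>
    dplyr::filter(.data$group_id == reference) |>
    dplyr::select("sex", "age", "metric", reference_value = "value")
  out <- long |>
    dplyr::inner_join(ref, by = c("sex", "age", "metric")) |>
    dplyr::mutate(
      group_value = .data$value,
      diff = .data$reference_value - .data$group_value,
      diff_printed = round(.data$reference_value, 2) - round(.data$group_value, 2)
    ) |>
    dplyr::select(
      "group_id", "sex", "age", "metric",
      "reference_value", "group_value", "diff", "diff_printed"
    )
  if (!is.null(ages)) {
    missing_ages <- setdiff(ages, unique(out$age))
    if (length(missing_ages) > 0) {
      rlang::abort(
        paste0("ages absent from the table: ", paste(missing_ages, collapse = ", ")),
        class = "lifehale_validation_error"
      )
    }
    out <- dplyr::filter(out, .data$age %in% ages)
  }
  dplyr::arrange(out, .data$sex, .data$metric, .data$group_id, .data$age)
}
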