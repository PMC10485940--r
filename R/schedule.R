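#' Validate a mortality schedule
#'
#' A mortality schedule is a tidy data frame with one row per single year of
#' age for one group and sex, carrying person-years of exposure and death
#' counts. It is the raw input of the whole pipeline: central death rates,
#' graduation, old-age extension and the life-table recursion all start here.
#'
#' Ages must be contiguous (step 1); gaps in the underlying registry are
#' encoded as `NA` in `person_years`/`deaths`, never as absent ages, so that
#' sparse subgroups can be carried through to [impute_rates()].
#'
#' @param data A data frame with columns `group_id`, `sex`
#'   (`"male"`/`"female"`), `age` (integer years), `person_years`, `deaths`.
#' @return The input as a validated tibble (invisibly classed
#'   `"mortality_schedule"`), rows ordered by age.
#' @examples
#' sched <- tibble::tibble(
#'   group_id = "demo", sex = "male", age = 0:3,
#'   person_years = c(1000, 990, 985, 980), deaths = c(8, 1, 1, 2)
#' )
#' mortality_schedule(sched)
#' @export
mortality_schedule <- function(data) {
  required <- c("group_id", "sex", "age", "person_years", "deaths")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("mortality schedule lacks columns: ", paste(missing_cols, collapse = ", ")),
      class = "lifehale_validation_error"
    )
  }
  out <- dplyr::arrange(tibble::as_tibble(data), .data$age)
  if (dplyr::n_distinct(out$group_id) != 1L || dplyr::n_distinct(out$sex) != 1L) {
    rlang::abort("a mortality schedule holds exactly one group and one sex",
      class = "lifehale_validation_error"
    )
  }
  if (!out$sex[1] %in% c("male", "female")) {
    rlang::abort(sprintf("unknown sex label '%s'", out$sex[1]),
      class = "lifehale_validation_error"
    )
  }
  if (any(diff(out$age) != 1L)) {
    rlang::abort("ages must be contiguous single years (encode gaps as NA exposure/deaths)",
      class = "lifehale_validation_error"
    )
  }
  if (out$age[1] < 0) {
    rlang::abort("first age must be >= 0", class = "lifehale_validation_error")
  }
  obs <- !is.na(out$person_years) & !is.na(out$deaths)
  if (any(out$person_years[obs] < 0) || any(out$deaths[obs] < 0)) {
    rlang::abort("person_years and deaths must be non-negative",
      class = "lifehale_validation_error"
    )
  }
  bad <- obs & out$person_years == 0 & out$deaths > 0
  if (any(bad)) {
    rlang::abort(
      sprintf(
        "deaths recorded with zero exposure at age(s) %s",
        paste(out$age[bad], collapse = ", ")
      ),
      class = "lifehale_validation_error"
    )
  }
  class(out) <- c("mortality_schedule", class(out))
  out
}

#' Central death rates from a schedule
#'
#' Computes the age-specific central death rate `mx = deaths / person_years`.
#' Ages with zero or missing exposure are flagged missing (`NA`), never zero:
#' absence of exposure is absence of information, and downstream imputation
#' treats it as such.
#'
#' @param data A mortality schedule (see [mortality_schedule()]).
#' @return The schedule with an `mx` column appended.
#' @export
compute_mx <- function(data) {
  sched <- mortality_schedule(data)
  dplyr::mutate(
    sched,
    mx = dplyr::if_else(
      !is.na(.data$person_years) & .data$person_years > 0,
      .data$deaths / .data$person_years,
      NA_real_
    )
  )
}

#' Read and write mortality schedules as CSV
#'
#' The on-disk format is a plain UTF-8 CSV with header
#' `group_id, sex, age, person_years, deaths`, one row per single year of age.
#' Sparse subgroups leave `person_years`/`deaths` empty at unobserved ages.
#'
#' @param path File path.
#' @return `read_mortality_csv()` returns a tibble with one validated schedule
#'   per group and sex, bound row-wise.
#' @export
read_mortality_csv <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      group_id = readr::col_character(),
      sex = readr::col_character(),
      age = readr::col_integer(),
      person_years = readr::col_double(),
      deaths = readr::col_double()
    )
  )
  raw |>
    dplyr::group_by(.data$group_id, .data$sex) |>
    dplyr::group_split() |>
    purrr::map(mortality_schedule) |>
    purrr::list_rbind()
}

#' @rdname read_mortality_csv
#' @param data A data frame of schedules.
#' @export
write_mortality_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Read grouped prevalence schedules as CSV
#'
#' Columns: `definition` (e.g. `DF`, `PH`, `NHIS`), `sex`, `group_id`,
#' `age_lo`, `age_hi`, `pi` (proportion unhealthy in `[0, 1]`) and an optional
#' `denom` (respondents at risk, used only for the optional prevalence
#' variance term).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_prevalence_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("definition", "sex", "group_id", "age_lo", "age_hi", "pi")
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("prevalence file lacks columns: ", paste(missing_cols, collapse = ", ")),
      class = "lifehale_validation_error"
    )
  }
  if (!"denom" %in% names(out)) out$denom <- NA_real_
  if (any(out$pi < 0 | out$pi > 1, na.rm = TRUE)) {
    rlang::abort("prevalence pi must lie in [0, 1]", class = "lifehale_validation_error")
  }
  out
}
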