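#' Plot a life table's expectancy profile
#'
#' Remaining life expectancy by age with its 95% band; any HALE columns
#' present are overlaid as dashed lines, one per prevalence definition.
#'
#' @param object A `lifetable` tibble.
#' @param ... Unused.
#' @method autoplot lifetable
#' @export
autoplot.lifetable <- function(object, ...) {
  lt <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(lt, ggplot2::aes(x = .data$age))
  if (all(c("lo95", "hi95") %in% names(lt))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
      fill = "grey80"
    )
  }
  p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$ex))
  hale_cols <- grep("^hale(_[A-Za-z]+)?$", names(lt), value = TRUE)
  if (length(hale_cols) > 0) {
    long <- lt |>
      dplyr::select("age", dplyr::all_of(hale_cols)) |>
      tidyr::pivot_longer(-"age", names_to = "definition", values_to = "hale") |>
      dplyr::mutate(definition = sub("^hale_?", "", .data$definition))
    p <- p + ggplot2::geom_line(
      data = long,
      ggplot2::aes(y = .data$hale, colour = .data$definition),
      linetype = "dashed"
    )
  }
  p + ggplot2::labs(
    x = "age", y = "remaining expectation (years)",
    colour = "HALE definition",
    title = sprintf(
      "%s (%s)", attr(object, "group_id") %||% "life table",
      attr(object, "sex") %||% ""
    )
  )
}

#' Plot between-group expectancy differences
#'
#' One panel per metric, reference minus group by age.
#'
#' @param differences The `differences` tibble of a [run_study()] result (or
#'   any [difference_report()] output).
#' @return A ggplot.
#' @export
plot_differences <- function(differences) {
  ggplot2::ggplot(
    differences,
    ggplot2::aes(
      x = .data$age, y = .data$diff,
      colour = .data$group_id, linetype = .data$sex
    )
  ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = "age", y = "reference minus group (years)",
      colour = "group", linetype = "sex"
    )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
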