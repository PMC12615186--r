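#' Round half away from zero
#'
#' Unlike [base::round()] (banker's rounding), ties go away from zero:
#' 66.75 rounds to 66.8 at one decimal, 98.5 to 99 at integer precision.
#' This is the convention sequencing reports typically use.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Host vs. microbial read-fraction report
#'
#' The clamp-efficiency bookkeeping: for each experimental condition,
#' sums host components (chloroplast, mitochondrial, nuclear) and
#' microbial counts and reports the microbial percentage at full
#' precision plus one-decimal and integer rounding (half away from zero).
#'
#' @param counts Tibble with columns `condition`, `component`, `count`.
#'   Components beginning with `"host"` count as host; everything else
#'   (`"microbial"`, `"taxon:<name>"`, ...) counts as microbial.
#' @return A `fraction_report` tibble: `condition`, `host_reads`,
#'   `microbial_reads`, `total_reads`, `microbial_percent`,
#'   `microbial_percent_1dp`, `microbial_percent_int`, `host_percent`.
#' @examples
#' read_fraction_report(tibble::tibble(
#'   condition = "PNA_V5V7",
#'   component = c("host_chloroplast", "host_mitochondrial", "microbial"),
#'   count = c(2, 229, 104078)
#' ))
#' @export
read_fraction_report <- function(counts) {
  stopifnot(all(c("condition", "component", "count") %in% names(counts)))
  if (any(counts$count < 0)) abort("counts must be non-negative")
  out <- counts |>
    mutate(is_host = startsWith(.data$component, "host")) |>
    group_by(.data$condition) |>
    summarise(
      host_reads = sum(.data$count[.data$is_host]),
      microbial_reads = sum(.data$count[!.data$is_host]),
      .groups = "drop"
    ) |>
    mutate(
      total_reads = .data$host_reads + .data$microbial_reads,
      microbial_percent = 100 * .data$microbial_reads / .data$total_reads,
      microbial_percent_1dp = round_half_away(.data$microbial_percent, 1L),
      microbial_percent_int = round_half_away(.data$microbial_percent, 0L),
      host_percent = 100 - .data$microbial_percent
    )
  zero <- out$condition[out$total_reads == 0]
  if (length(zero)) {
    abort(sprintf("condition '%s' has all-zero counts", zero[1]))
  }
  # preserve input condition order
  out <- out[match(unique(counts$condition), out$condition), ]
  class(out) <- c("fraction_report", class(out))
  out
}

#' Extremes of microbial percentage across conditions
#'
#' @param report A [read_fraction_report()] result.
#' @param rounding Which percentage column the extremes are taken from:
#'   `"int"`, `"1dp"`, or `"full"`.
#' @return One-row tibble with `min_percent`, `min_condition`,
#'   `max_percent`, `max_condition`; ties resolve to the first condition
#'   in input order.
#' @export
condition_summary <- function(report, rounding = c("int", "1dp", "full")) {
  rounding <- match.arg(rounding)
  stopifnot(nrow(report) >= 1L)
  col <- switch(rounding, int = "microbial_percent_int",
                `1dp` = "microbial_percent_1dp", full = "microbial_percent")
  v <- report[[col]]
  tibble(
    min_percent = min(v),
    min_condition = report$condition[which.min(v)],
    max_percent = max(v),
    max_condition = report$condition[which.max(v)]
  )
}

#' @method tidy fraction_report
#' @export
tidy.fraction_report <- function(x, ...) as_tibble(x)

#' @method glance fraction_report
#' @export
glance.fraction_report <- function(x, ...) {
  tibble(
    n_conditions = nrow(x),
    min_microbial_percent = min(x$microbial_percent),
    max_microbial_percent = max(x$microbial_percent),
    total_reads = sum(x$total_reads)
  )
}

#' @rdname autoplot.fraction_report
#' @export
plot_fraction_report <- function(object, ...) {
  autoplot.fraction_report(object, ...)
}

#' Stacked-bar plot of host vs. microbial read percentages
#'
#' @param object A [read_fraction_report()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fraction_report
#' @export
autoplot.fraction_report <- function(object, ...) {
  df <- as_tibble(object) |>
    select("condition", host = "host_percent",
           microbial = "microbial_percent") |>
    tidyr::pivot_longer(-"condition", names_to = "origin",
                        values_to = "percent") |>
    mutate(condition = factor(.data$condition,
                              levels = unique(object$condition)))
  ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$percent,
                                   fill = .data$origin)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of reads", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
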