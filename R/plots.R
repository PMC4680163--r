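#' Box plots of measured volumes by visual size category
#'
#' The measured volume distributions of each method, split by the
#' ground-truth visual size category - the divergence of the modified
#' ABC/2 method grows with category while ABC/2 and SAS track each other.
#'
#' @param report A `study_report` from [run_study()].
#' @param observer,session Which reading to plot.
#' @return A ggplot object.
#' @export
plot_volumes_by_size <- function(report, observer = 1L, session = 1L) {
  stopifnot(inherits(report, "study_report"))
  dat <- dplyr::inner_join(
    dplyr::filter(report$measurements,
                  observer == !!observer, session == !!session),
    report$manifest[, c("scan_id", "size_category")],
    by = "scan_id"
  )
  dat$size_category <- factor(dat$size_category,
                              levels = c("<3", "3-4.9", "5-8", ">8"))
  ggplot2::ggplot(dat, ggplot2::aes(x = size_category, y = volume_cm3,
                                    fill = method)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::labs(x = "Visual size category (cm)",
                  y = expression(Volume ~ (cm^3)), fill = "Method") +
    ggplot2::theme_minimal()
}

#' Box plots of measured volumes by haematoma shape class
#'
#' @inheritParams plot_volumes_by_size
#' @return A ggplot object.
#' @export
plot_volumes_by_shape <- function(report, observer = 1L, session = 1L) {
  stopifnot(inherits(report, "study_report"))
  dat <- dplyr::inner_join(
    dplyr::filter(report$measurements,
                  observer == !!observer, session == !!session),
    report$manifest[, c("scan_id", "shape_class")],
    by = "scan_id"
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = shape_class, y = volume_cm3,
                                    fill = method)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::labs(x = "Shape class", y = expression(Volume ~ (cm^3)),
                  fill = "Method") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot for a method pair of a study report
#'
#' @param report A `study_report`.
#' @param method_1,method_2 Methods to compare (`method_1` is plotted
#'   against `method_2` as reference).
#' @param observer,session Which reading to use.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(report, method_1 = "modified_abc2",
                              method_2 = "abc2", observer = 1L,
                              session = 1L) {
  stopifnot(inherits(report, "study_report"))
  wide <- wide_methods(report$measurements, observer, session)
  autoplot(bland_altman(wide[[method_1]], wide[[method_2]])) +
    ggplot2::labs(subtitle = sprintf("%s vs %s", method_1, method_2))
}
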