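#' Membership bar chart for an admixture fit
#'
#' The classic stacked-bar representation: one thin vertical segment
#' per accession, coloured by proportional membership, accessions
#' ordered by primary population then primary membership.
#'
#' @param object A `structure_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.structure_fit <- function(object, ...) {
  long <- tidy(object)
  ord <- assign_populations(object$Q)
  ord <- ord[order(ord$primary_pop, -ord$membership), ]
  long$accession_id <- factor(long$accession_id, levels = ord$accession_id)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$accession_id,
                                     y = .data$membership,
                                     fill = .data$population)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_y_continuous(expand = c(0, 0)) +
    ggplot2::labs(x = NULL, y = "proportional membership",
                  title = sprintf("Admixture memberships, K = %d", object$k)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' K-selection diagnostics plot
#'
#' Log evidence and its rate of change against K, the two curves whose
#' plateaus guide the choice of K.
#'
#' @param report Tibble with columns `K`, `lnP_est` and `delta` (as in
#'   the pipeline's K-selection report).
#' @return A ggplot.
#' @export
plot_k_selection <- function(report) {
  long <- dplyr::bind_rows(
    tibble::tibble(K = report$K, value = report$lnP_est, panel = "lnP(X|K)"),
    tibble::tibble(K = report$K, value = report$delta, panel = "rate of change")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$K, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(y = NULL) +
    ggplot2::theme_minimal()
}

#' Map of accessions with population standard-deviation ellipses
#'
#' @param coordinates Tibble `(accession_id, latitude, longitude)`.
#' @param assignments Tibble from [assign_populations()].
#' @return A ggplot.
#' @export
plot_population_map <- function(coordinates, assignments) {
  merged <- dplyr::inner_join(coordinates, assignments, by = "accession_id")
  summ <- population_geo_summaries(coordinates, assignments)
  ellipses <- purrr::pmap_dfr(summ, function(population, n, centre_lat,
                                             centre_lon, standard_distance_km,
                                             ellipse_major_km, ellipse_minor_km,
                                             ellipse_rotation_deg, ...) {
    if (is.na(ellipse_major_km)) return(NULL)
    th <- seq(0, 2 * pi, length.out = 120)
    rot <- ellipse_rotation_deg * pi / 180
    x <- ellipse_major_km * cos(th) * cos(rot) -
      ellipse_minor_km * sin(th) * sin(rot)
    y <- ellipse_major_km * cos(th) * sin(rot) +
      ellipse_minor_km * sin(th) * cos(rot)
    tibble::tibble(
      population = population,
      latitude = centre_lat + y / KM_PER_DEG,
      longitude = centre_lon + x / (KM_PER_DEG * cos(centre_lat * pi / 180))
    )
  })
  ggplot2::ggplot(merged, ggplot2::aes(.data$longitude, .data$latitude,
                                       colour = factor(.data$primary_pop))) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$strong), alpha = 0.7) +
    ggplot2::geom_path(
      data = ellipses,
      ggplot2::aes(group = factor(.data$population),
                   colour = factor(.data$population))
    ) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(colour = "population", shape = "membership ≥ 0.9") +
    ggplot2::theme_minimal()
}

#' Monthly climate F-ratio plot
#'
#' @param anova_by_month Tibble from [climate_anova_by_month()] (a
#'   `habit` column, if present, is mapped to colour).
#' @return A ggplot.
#' @export
plot_climate_f <- function(anova_by_month) {
  aes <- if ("habit" %in% names(anova_by_month)) {
    ggplot2::aes(.data$month, .data$F, colour = .data$habit)
  } else {
    ggplot2::aes(.data$month, .data$F)
  }
  ggplot2::ggplot(anova_by_month, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_x_continuous(breaks = 1:12, labels = month.abb) +
    ggplot2::labs(y = "between- / within-population variance (F)") +
    ggplot2::theme_minimal()
}
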