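#' @method autoplot lineweaver_burk
#' @export
autoplot.lineweaver_burk <- function(object, ...) {
  d <- dplyr::mutate(
    object$data,
    inv_S = 1 / .data$S, inv_v = 1 / .data$v,
    I_level = factor(.data$I)
  )
  lines <- dplyr::mutate(object$per_level, I_level = factor(.data$I))
  ggplot2::ggplot(d, ggplot2::aes(.data$inv_S, .data$inv_v, colour = .data$I_level)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept, colour = .data$I_level)
    ) +
    ggplot2::labs(
      x = "1 / [S] (1/mM)", y = "1 / v",
      colour = "[I] (mM)",
      title = "Lineweaver-Burk (double-reciprocal) plot"
    ) +
    ggplot2::theme_minimal()
}

#' Secondary (replot) diagnostics of a Lineweaver-Burk analysis
#'
#' Plots the per-inhibitor-level slopes and intercepts against inhibitor
#' concentration with their fitted replot lines; the x-intercepts estimate
#' -Ki (slope replot, competitive component) and -Ki' (intercept replot,
#' uncompetitive component).
#'
#' @param lb A `lineweaver_burk` object.
#' @return A ggplot.
#' @export
plot_lb_replots <- function(lb) {
  d <- tidyr::pivot_longer(
    lb$per_level, c("slope", "intercept"),
    names_to = "quantity", values_to = "value"
  )
  fits <- tibble::tibble(
    quantity = c("slope", "intercept"),
    intercept = c(lb$slope_replot$intercept, lb$intercept_replot$intercept),
    slope = c(lb$slope_replot$slope, lb$intercept_replot$slope)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$I, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = fits,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope)
    ) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(
      x = "[I] (mM)", y = NULL,
      title = "Secondary plots (LB slopes and intercepts vs [I])"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot mechanism_fit
#' @export
autoplot.mechanism_fit <- function(object, ...) {
  d <- dplyr::mutate(object$data, I_level = factor(.data$I))
  s_seq <- seq(min(object$data$S), max(object$data$S), length.out = 80)
  curves <- tidyr::expand_grid(S = s_seq, I = sort(unique(object$data$I)))
  curves$v <- rate_law(
    curves$S, curves$I, object$mechanism,
    object$Km, object$Vmax, object$Ki,
    if (object$mechanism == "mixed") object$Kip else NULL
  )
  curves$I_level <- factor(curves$I)
  ggplot2::ggplot(d, ggplot2::aes(.data$S, .data$v, colour = .data$I_level)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curves) +
    ggplot2::labs(
      x = "[S] (mM)", y = "v",
      colour = "[I] (mM)",
      title = paste0("Global fit: ", object$mechanism,
                     sprintf(" (Ki = %.3g mM)", object$Ki))
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot conformation_assessment
#' @export
autoplot.conformation_assessment <- function(object, ...) {
  boxes <- ramachandran_boxes()
  rects <- dplyr::bind_rows(lapply(names(boxes), function(cls) {
    b <- boxes[[cls]]
    dplyr::bind_rows(lapply(b$psi, function(pr) {
      tibble::tibble(
        class = cls,
        xmin = b$phi[1], xmax = b$phi[2], ymin = pr[1], ymax = pr[2]
      )
    }))
  }))
  d <- dplyr::filter(object$residues, !is.na(.data$phi), !is.na(.data$psi))
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = rects,
      ggplot2::aes(
        xmin = .data$xmin, xmax = .data$xmax,
        ymin = .data$ymin, ymax = .data$ymax, fill = .data$class
      ),
      alpha = 0.15
    ) +
    ggplot2::geom_point(data = d, ggplot2::aes(.data$phi, .data$psi, colour = .data$class)) +
    ggplot2::coord_cartesian(xlim = c(-180, 180), ylim = c(-180, 180)) +
    ggplot2::labs(
      x = expression(phi ~ "(degrees)"), y = expression(psi ~ "(degrees)"),
      title = "Ramachandran classification"
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of enrichment results
#'
#' @param enrichment Tibble from [term_enrichment()].
#' @param top_n Number of top terms (by p) to show.
#' @return A ggplot of -log10 adjusted p-values.
#' @export
plot_enrichment <- function(enrichment, top_n = 10L) {
  d <- utils::head(dplyr::arrange(enrichment, .data$p), top_n)
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(-log10(.data$p_adj), .data$term)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = expression(-log[10] ~ "BH-adjusted p"), y = NULL,
      title = "Annotation-term enrichment"
    ) +
    ggplot2::theme_minimal()
}
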