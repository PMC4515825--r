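#' @method tidy hyperbolic_fit
#' @export
tidy.hyperbolic_fit <- function(x, ...) {
  tibble::tibble(
    term = "Ki_app",
    estimate = x$Ki_app,
    std.error = x$se
  )
}

#' @method glance hyperbolic_fit
#' @export
glance.hyperbolic_fit <- function(x, ...) {
  tibble::tibble(
    Ki_app = x$Ki_app,
    floor = x$floor,
    sigma = x$sigma,
    n = x$n_points
  )
}

#' @method tidy mechanism_fit
#' @export
tidy.mechanism_fit <- function(x, ...) {
  est <- coef(x$fit)
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(x$se[names(est)])
  )
}

#' @method glance mechanism_fit
#' @export
glance.mechanism_fit <- function(x, ...) {
  ranked <- x$aic_table[order(x$aic_table$aicc), ]
  tibble::tibble(
    mechanism = x$mechanism,
    Ki = x$Ki,
    Kip = x$Kip,
    Km = x$Km,
    Vmax = x$Vmax,
    aicc = ranked$aicc[1],
    delta_next = ranked$aicc[2] - ranked$aicc[1],
    ambiguous = x$ambiguous,
    n = x$n
  )
}

#' @method tidy lineweaver_burk
#' @export
tidy.lineweaver_burk <- function(x, ...) {
  x$per_level
}

#' @method glance lineweaver_burk
#' @export
glance.lineweaver_burk <- function(x, ...) {
  tibble::tibble(
    Vmax = x$estimates$Vmax,
    Km = x$estimates$Km,
    Ki_slope = x$estimates$Ki_slope,
    Ki_intercept = x$estimates$Ki_intercept,
    n_levels = nrow(x$per_level)
  )
}

#' @method tidy conformation_assessment
#' @export
tidy.conformation_assessment <- function(x, ...) {
  x$residues
}

#' @method glance conformation_assessment
#' @export
glance.conformation_assessment <- function(x, ...) {
  fr <- as.list(x$class_fractions)
  tibble::tibble(
    chain = x$segment$chain,
    start = x$segment$start,
    end = x$segment$end,
    majority_class = x$majority_class,
    frac_helix = fr$helix,
    frac_strand = fr$strand,
    frac_loop = fr$loop
  )
}
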