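# ggplot2 views of scan results. The figure of interest in a flux-sum study
# is the production-vs-k profile: guaranteed target production (and growth)
# as the perturbation level moves from the weakest constraint toward the
# flux-sum extremum.

#' Plot production profiles of an FSA scan
#'
#' One panel per (metabolite, direction) pair, guaranteed production against
#' the perturbation level k, with the wild-type production as a dashed
#' reference line. By default only classified targets are shown.
#'
#' @param object an `fsa_scan`.
#' @param metabolites metabolite ids to show; default the classified
#'   targets (all scanned metabolites if there are none).
#' @param show_growth overlay the growth profile as a dotted line.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fsa_scan <- function(object, metabolites = NULL,
                              show_growth = FALSE, ...) {
  pts <- object$points[object$points$growth_status == "optimal", ]
  if (is.null(metabolites)) {
    metabolites <- unique(object$targets$metabolite)
    if (length(metabolites) == 0) metabolites <- unique(pts$metabolite)
  }
  pts <- pts[pts$metabolite %in% metabolites, ]
  pts$panel <- paste(pts$metabolite, pts$direction)
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$k, y = .data$production)) +
    ggplot2::geom_hline(yintercept = object$reference$wt_production,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(
      x = "perturbation level k",
      y = sprintf("guaranteed %s flux (mmol/gDCW-hr)",
                  object$reference$target),
      title = sprintf("Flux-sum scan: %s %s", object$reference$goal,
                      object$reference$target))
  if (show_growth) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$growth),
                                linetype = "dotted")
  }
  p
}

#' Plot one production/growth profile
#'
#' @param scan an `fsa_scan`.
#' @param metabolite metabolite id.
#' @param direction `"attenuation"` or `"intensification"`.
#' @return a ggplot object with production and growth against k.
#' @export
plot_production_profile <- function(scan, metabolite,
                                    direction = c("attenuation",
                                                  "intensification")) {
  direction <- match.arg(direction)
  prof <- production_profile(scan, metabolite, direction)
  long <- tidyr::pivot_longer(prof, c("growth", "production"),
                              names_to = "quantity", values_to = "flux")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$flux,
                                     linetype = .data$quantity)) +
    ggplot2::geom_hline(yintercept = scan$reference$wt_production,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "perturbation level k", y = "flux (mmol/gDCW-hr)",
                  title = sprintf("%s flux-sum %s", metabolite, direction))
}
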