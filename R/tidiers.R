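# Broom-style accessors and plots for fitted refinement objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a refinement trajectory
#'
#' @param x A `fold_refinement` from [run_refinement()].
#' @param ... Unused.
#' @return The per-iteration history tibble (trace, phase, iteration, LLG,
#'   restraint, loss, R factors, RMSD to the reference).
#' @method tidy fold_refinement
#' @export
tidy.fold_refinement <- function(x, ...) {
  x$history
}

#' One-row summary of a refinement
#'
#' @inheritParams tidy.fold_refinement
#' @return Tibble with initial/final LLG, the LLG gain, final R factors,
#'   final RMSD to the reference, iteration counts and the selected
#'   phase-1 trace.
#' @method glance fold_refinement
#' @export
glance.fold_refinement <- function(x, ...) {
  h2 <- x$history[x$history$phase == 2, ]
  last <- if (nrow(h2)) h2[nrow(h2), ] else x$history[nrow(x$history), ]
  tibble::tibble(
    llg_initial = x$initial$llg,
    llg_final = x$best$llg,
    llg_gain = x$best$llg - x$initial$llg,
    r_work = last$r_work, r_free = last$r_free,
    rmsd_ref = last$rmsd_ref,
    n_iter = nrow(x$history),
    n_iter_phase2 = nrow(h2),
    selected_trace = x$selected_trace
  )
}

#' Plot a refinement trajectory
#'
#' LLG (and, when available, R factors) against iteration, faceted by
#' phase, with phase-1 traces distinguished by color.
#'
#' @param object A `fold_refinement`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fold_refinement
#' @export
autoplot.fold_refinement <- function(object, ...) {
  h <- object$history
  h$trace <- factor(h$trace)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$iter, y = .data$llg,
                                  color = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~phase, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "iteration", y = "log-likelihood gain (work set)",
                  color = "trace") +
    ggplot2::theme_minimal()
}

#' Plot per-bin sigmaA
#'
#' @param object A `sigma_a_bins` tibble.
#' @param ... Unused.
#' @return A ggplot of sigmaA against mean bin resolution.
#' @method autoplot sigma_a_bins
#' @export
autoplot.sigma_a_bins <- function(object, ...) {
  d_mid <- (object$d_min + object$d_max) / 2
  ggplot2::ggplot(tibble::tibble(d = d_mid, sigma_a = object$sigma_a),
                  ggplot2::aes(x = .data$d, y = .data$sigma_a)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "resolution (A)", y = expression(sigma[A])) +
    ggplot2::theme_minimal()
}
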