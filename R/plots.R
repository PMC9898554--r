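# Lightweight ggplot2 helpers for the tabular results (ggplot2 is a
# suggested dependency; the functions error informatively without it).

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    .stopf("ggplot2 is required for plotting")
}

#' Plot a radial or angular distribution function
#'
#' @param x A data.frame from [rdf()] or [adf()].
#' @return A ggplot object.
#' @export
plot_rdf <- function(x) {
  .need_ggplot()
  ggplot2::ggplot(x, ggplot2::aes(x = r, y = g)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 3) +
    ggplot2::labs(x = "r [Å]", y = "g(r)")
}

#' @rdname plot_rdf
#' @export
plot_adf <- function(x) {
  .need_ggplot()
  ggplot2::ggplot(x, ggplot2::aes(x = angle, y = density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "angle [deg]", y = "probability density [1/deg]")
}

#' Plot a training log
#'
#' Validation energy and force mean absolute errors per epoch, on a log
#' scale.
#'
#' @param log The `log` data.frame returned by [train()].
#' @return A ggplot object.
#' @export
plot_training_log <- function(log) {
  .need_ggplot()
  d <- rbind(data.frame(epoch = log$epoch, value = log$val_e_mae,
                        metric = "energy MAE [eV/atom]"),
             data.frame(epoch = log$epoch, value = log$val_f_mae,
                        metric = "force MAE [eV/Å]"))
  ggplot2::ggplot(d, ggplot2::aes(x = epoch, y = value)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}
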