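# broom-style accessors and plots for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-epoch training history of a DTA model
#'
#' @param x A `dta_model`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_loss`, `valid_mse`, `valid_ci`.
#' @export
tidy.dta_model <- function(x, ...) x$history

#' One-row summary of a DTA model
#'
#' @param x A `dta_model`.
#' @param ... Unused.
#' @return Tibble with the best epoch and test metrics.
#' @export
glance.dta_model <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    valid_mse = min(x$history$valid_mse),
    test_mse = x$metrics$mse,
    test_ci = x$metrics$ci,
    frozen_protein = x$freeze_protein
  )
}

#' Per-step pretraining history
#'
#' @param x A `protein_pretrain`.
#' @param ... Unused.
#' @return Tibble with `step`, `mlm_loss`, `cpc_loss`, `cpc_accuracy`.
#' @export
tidy.protein_pretrain <- function(x, ...) x$history

#' One-row summary of a pretraining run
#'
#' @param x A `protein_pretrain`.
#' @param ... Unused.
#' @return Tibble with final losses and contrastive accuracy.
#' @export
glance.protein_pretrain <- function(x, ...) {
  h <- x$history
  last <- function(v) { v <- v[!is.na(v)]; if (length(v)) v[length(v)] else NA_real_ }
  tibble::tibble(
    steps = nrow(h),
    final_mlm_loss = last(h$mlm_loss),
    final_cpc_loss = last(h$cpc_loss),
    final_cpc_accuracy = last(h$cpc_accuracy)
  )
}

#' Plot the training history of a DTA model
#'
#' @param object A `dta_model`.
#' @param ... Unused.
#' @return A ggplot of training loss and validation MSE against epoch.
#' @export
autoplot.dta_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "valid_mse"),
                           names_to = "series", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(x = "epoch", y = "loss / MSE", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot pretraining losses
#'
#' @param object A `protein_pretrain`.
#' @param ... Unused.
#' @return A ggplot of both objective losses against step.
#' @export
autoplot.protein_pretrain <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("mlm_loss", "cpc_loss"),
                           names_to = "objective", values_to = "loss")
  h <- h[!is.na(h$loss), , drop = FALSE]
  ggplot2::ggplot(h, ggplot2::aes(x = .data$step, y = .data$loss,
                                  colour = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "step", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}
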