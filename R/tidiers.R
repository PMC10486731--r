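# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evaluation report
#'
#' @param x An `octa_eval` from [evaluate_model()].
#' @param ... Unused.
#' @return Tibble with one row per metric (`kappa`, `auc0`..`auc3`).
#' @export
tidy.octa_eval <- function(x, ...) {
  tibble::tibble(metric = c("kappa", names(x$auc)),
                 value = c(x$kappa, unname(x$auc)))
}

#' @rdname tidy.octa_eval
#' @export
glance.octa_eval <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, auc0 = x$auc[[1]], auc1 = x$auc[[2]],
                 auc2 = x$auc[[3]], auc3 = x$auc[[4]],
                 mean_auc = mean(x$auc, na.rm = TRUE), n_eyes = x$n_eyes)
}

#' Plot an evaluation report
#'
#' Bar chart of the four cumulative-task AUCs with kappa in the subtitle.
#'
#' @param object An `octa_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.octa_eval <- function(object, ...) {
  df <- tibble::tibble(task = factor(names(object$auc), levels = names(object$auc)),
                       auc = unname(object$auc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$task, y = .data$auc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(title = "Cumulative-task AUC",
                  subtitle = sprintf("Cohen's kappa = %.3f (n = %d eyes)",
                                     object$kappa, object$n_eyes),
                  x = NULL, y = "AUC") +
    ggplot2::theme_minimal()
}

#' Tidy a training run
#'
#' @param x An `octa_fit` from [train_model()].
#' @param ... Unused.
#' @return The per-epoch history tibble.
#' @export
tidy.octa_fit <- function(x, ...) x$history

#' @rdname tidy.octa_fit
#' @export
glance.octa_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = max(h$epoch), final_loss = h$loss[nrow(h)],
                 best_epoch = x$best_epoch,
                 best_val_metric = x$val_metric %||% NA_real_)
}

#' Plot a training run
#'
#' @param object An `octa_fit`.
#' @param ... Unused.
#' @return A ggplot object with the loss (and validation metric) curves.
#' @export
autoplot.octa_fit <- function(object, ...) {
  h <- object$history
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "epoch", y = "training loss") +
    ggplot2::theme_minimal()
  if (any(!is.na(h$val_metric)))
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$val_metric),
                                color = "darkorange", linetype = 2)
  p
}

#' Tidy a split plan
#'
#' @param x An `octa_split_plan`.
#' @param ... Unused.
#' @return Tibble with `patient_id`, `role` (`test`/`trainval`) and `fold`.
#' @export
tidy.octa_split_plan <- function(x, ...) {
  rbind(tibble::tibble(patient_id = x$test_patient_ids, role = "test",
                       fold = NA_integer_),
        tibble::tibble(patient_id = names(x$fold_assignments), role = "trainval",
                       fold = unname(x$fold_assignments)))
}

#' @importFrom rlang .data
NULL
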