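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

#' Tidy a trained model
#'
#' @param x a `cgardp_model`.
#' @param ... unused.
#' @return Tibble of the training trajectory: `epoch`, `loss`.
#' @method tidy cgardp_model
#' @export
tidy.cgardp_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' @rdname tidy.cgardp_model
#' @method glance cgardp_model
#' @export
glance.cgardp_model <- function(x, ...) {
  n_par <- sum(vapply(param_leaves(x$params), length, integer(1)))
  tibble::tibble(
    n_drugs = x$n_drugs, n_diseases = x$n_diseases,
    n_parameters = n_par, alpha1 = x$train_cfg$alpha1,
    epochs = length(x$loss_history),
    final_loss = utils::tail(x$loss_history, 1)
  )
}

#' @rdname tidy.cgardp_model
#' @param object a `cgardp_model`.
#' @method autoplot cgardp_model
#' @export
autoplot.cgardp_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(epoch, loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean training loss") +
    ggplot2::theme_minimal()
}

#' Tidy a cross-validation report
#'
#' @param x a `cgardp_cv`.
#' @param ... unused.
#' @return The per-drug metric table: `fold`, `drug`, `n_pos`, `n_neg`,
#'   `auc`, `aupr`.
#' @method tidy cgardp_cv
#' @export
tidy.cgardp_cv <- function(x, ...) x$per_drug

#' @rdname tidy.cgardp_cv
#' @method glance cgardp_cv
#' @export
glance.cgardp_cv <- function(x, ...) {
  tibble::tibble(
    n_folds = x$n_folds, n_rankings = nrow(x$per_drug),
    macro_auc = x$macro_auc, macro_aupr = x$macro_aupr,
    alpha1 = x$alpha1, seed = x$seed
  )
}

#' @rdname tidy.cgardp_cv
#' @param object a `cgardp_cv`.
#' @param type `"recall"` for the averaged top-k recall curve, `"auc"` for
#'   per-drug AUC distributions by fold.
#' @method autoplot cgardp_cv
#' @export
autoplot.cgardp_cv <- function(object, type = c("recall", "auc"), ...) {
  type <- match.arg(type)
  if (type == "recall") {
    ggplot2::ggplot(object$recall_curve, ggplot2::aes(k, recall)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::ylim(0, 1) +
      ggplot2::labs(x = "top-k cutoff", y = "mean recall over drugs") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$per_drug,
                    ggplot2::aes(factor(fold), auc)) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(x = "fold", y = "per-drug AUC") +
      ggplot2::theme_minimal()
  }
}

utils::globalVariables(c("epoch", "loss", "k", "recall", "fold", "auc",
                         "aupr", "drug", "disease", "label", "score",
                         "disease_id", "drug_id"))
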