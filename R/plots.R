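#' Plot one sample's pathway image
#' @param object a `pathway_image_set`.
#' @param sample_id sample to display (default: first).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pathway_image_set
#' @export
autoplot.pathway_image_set <- function(object, sample_id = object$sample_ids[1], ...) {
  m <- sample_image(object, sample_id)
  df <- tibble::tibble(
    pathway = factor(rep(rownames(m), ncol(m)), levels = rev(rownames(m))),
    pixel = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    value = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pixel, y = .data$pathway, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "PC score") +
    ggplot2::labs(title = paste("Pathway image:", sample_id), x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Heatmap of -log10 adjusted p-values over image pixels
#' @param object a `pixel_test_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pixel_test_result
#' @export
autoplot.pixel_test_result <- function(object, ...) {
  tb <- tidy(object)
  tb$neglog <- -log10(pmax(tb$adjusted_p, 1e-16))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$pixel, y = .data$row, fill = .data$neglog)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10] ~ p[adj])) +
    ggplot2::labs(x = NULL, y = "pathway row") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Distribution of cross-validation AUCs
#' @param object a `pathcnn_cv` result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pathcnn_cv
#' @export
autoplot.pathcnn_cv <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = factor(.data$repeat_id), y = .data$auc)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = object$mean_auc, linetype = 2) +
    ggplot2::labs(x = "repeat", y = "test AUC") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Kaplan-Meier curves for a median-split result
#' @param object a `km_split` result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot km_split
#' @export
autoplot.km_split <- function(object, ...) {
  fit <- object$fit
  strata <- rep(names(fit$strata), fit$strata)
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, surv = 1, group = names(fit$strata)),
    tibble::tibble(time = fit$time, surv = fit$surv, group = strata)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv, color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "years", y = "survival probability",
                  subtitle = sprintf("log-rank p = %.4g", object$p_value)) +
    ggplot2::theme_minimal(base_size = 9)
}
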