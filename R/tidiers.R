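#' Tidy the replicate table of a fit
#'
#' @param x an `sfs_fit`.
#' @param kya convert time parameters to kya using the model's generation
#'   time.
#' @param ... unused.
#' @return tibble with one row per replicate run.
#' @export
tidy.sfs_fit <- function(x, kya = FALSE, ...) {
  out <- x$replicates
  if (kya) {
    for (pname in x$space$name)
      if (param_kind(x$model, pname) == "time")
        out[[pname]] <- generations_to_kya(out[[pname]], x$model$gen_time)
  }
  mutate(out, is_ml = .data$replicate == x$ml_replicate)
}

#' One-row fit summary
#'
#' @param x an `sfs_fit`.
#' @param ... unused.
#' @return tibble with the ML likelihood, replicate counts and flags.
#' @export
glance.sfs_fit <- function(x, ...) {
  ml <- x$replicates[x$replicates$replicate == x$ml_replicate, ]
  tibble(n_replicates = nrow(x$replicates),
         n_failed = sum(x$replicates$failed),
         ml_replicate = x$ml_replicate,
         loglik = ml$loglik,
         boundary = ml$boundary,
         rescaling_factor = x$rescaling_factor,
         reestimated_mean = if (is.null(x$reestimated)) NA_real_
                            else mean(x$reestimated))
}

#' @export
tidy.model_selection <- function(x, ...) x$comparisons

#' @export
glance.model_selection <- function(x, ...) {
  tibble(best = x$best, decisive = x$decisive, threshold = x$threshold)
}

#' @export
tidy.boot_ci <- function(x, ...) x$ci

# ---- plots --------------------------------------------------------------

#' Plot marginal site frequency spectra of a joint SFS
#'
#' One panel per population, derived-allele count against site count.
#'
#' @param object a `joint_sfs`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.joint_sfs <- function(object, ...) {
  dat <- purrr::map_dfr(object$panel$pop, function(p)
    tibble(pop = p, derived = seq_along(marginal_sfs(object, p)) - 1L,
           count = marginal_sfs(object, p)))
  dat <- filter(dat, .data$derived > 0)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$derived, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~pop, scales = "free_x") +
    ggplot2::labs(x = "derived-allele count", y = "sites") +
    ggplot2::theme_minimal()
}

#' Plot replicate likelihoods and estimates of a fit
#'
#' Parameter estimates per replicate against their composite
#' log10-likelihood, highlighting the maximum-likelihood run.
#'
#' @param object an `sfs_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sfs_fit <- function(object, ...) {
  dat <- tidy(object) |>
    tidyr::pivot_longer(dplyr::all_of(object$space$name),
                        names_to = "param", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$value, y = .data$loglik,
                                    colour = .data$is_ml)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~param, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "estimate (generations)", y = "log10 CL") +
    ggplot2::theme_minimal()
}

#' Plot qpAdm admixture weights with jackknife error bars
#'
#' @param object a `qpadm_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.qpadm_result <- function(object, ...) {
  ggplot2::ggplot(object$weights,
                  ggplot2::aes(x = .data$source, y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$weight - 2 * .data$se,
                                        ymax = .data$weight + 2 * .data$se),
                           width = 0.2) +
    ggplot2::labs(title = paste("qpAdm:", object$target),
                  y = "admixture weight") +
    ggplot2::theme_minimal()
}
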