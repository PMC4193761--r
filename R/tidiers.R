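# broom-style tidiers for the fitted / measured result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.separatrix_fit <- function(x, ...) {
  cf <- stats::coef(x$fit)
  tibble::tibble(term = names(cf), estimate = unname(cf),
                 std.error = unname(sqrt(diag(stats::vcov(x$fit)))))
}

#' @export
glance.separatrix_fit <- function(x, ...) {
  s <- x$samples
  tibble::tibble(width = x$width, degree = x$degree, n = nrow(s),
                 n_success = sum(s$success), n_failure = sum(!s$success),
                 sigma_min = x$sigma_range[1], sigma_max = x$sigma_range[2])
}

#' @export
tidy.gain_function <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.gain_function <- function(x, ...) {
  fp <- tryCatch(self_consistent_rate(x), error = function(e) NA_real_)
  tibble::tibble(fixed_point = fp, k_exc = attr(x, "k_exc"),
                 k_inh = attr(x, "k_inh"), p_loss = attr(x, "p"),
                 n_grid = nrow(x))
}

#' @export
tidy.iterative_compensation <- function(x, ...) {
  x$trace
}

#' @export
glance.iterative_compensation <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  tibble::tibble(n_iter = nrow(x$trace), rate = last$rate,
                 cv_rates = last$cv_rates, nu_target = x$nu_target,
                 alpha = x$alpha, converged = x$converged,
                 rel_rate_error = abs(last$rate - x$nu_target) / x$nu_target)
}

#' @export
tidy.attractor_episodes <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.attractor_episodes <- function(x, ...) {
  tibble::tibble(n_episodes = nrow(x),
                 mean_dwell = if (nrow(x)) mean(x$dwell) else NA_real_,
                 competition_time = attr(x, "competition_time"),
                 duration = attr(x, "duration"))
}
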