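# broom-style tidiers for the package's result objects.

#' @export
tidy.mantel_result <- function(x, ...) {
  tibble(estimate = x$r, p.value = x$p, n.perm = x$n_perm,
         alternative = x$alternative)
}

#' @export
glance.mantel_result <- function(x, ...) tidy(x)

#' @export
tidy.permanova_result <- function(x, ...) {
  tibble(term = c("group", "residual"),
         statistic = c(x$pseudo_F, NA_real_),
         R2 = c(x$R2, 1 - x$R2),
         p.value = c(x$p, NA_real_))
}

#' @export
glance.permanova_result <- function(x, ...) {
  tibble(statistic = x$pseudo_F, R2 = x$R2, p.value = x$p, n.perm = x$n_perm)
}

#' @export
tidy.cca_model <- function(x, ...) {
  if (!is.null(x$selected) && nrow(x$selected) > 0) {
    x$selected
  } else {
    tibble(axis = seq_along(x$eigenvalues), eigenvalue = x$eigenvalues)
  }
}

#' @export
glance.cca_model <- function(x, ...) {
  tibble(total.inertia = x$total_inertia,
         constrained.inertia = x$constrained_inertia,
         prop.constrained = x$constrained_inertia / x$total_inertia,
         n.variables = length(x$variables))
}

#' @export
tidy.log_fit <- function(x, ...) {
  tibble(term = c("ln(n)", "(Intercept)"), estimate = c(x$a, x$b))
}

#' @export
glance.log_fit <- function(x, ...) {
  tibble(a = x$a, b = x$b, rmse = x$rmse, n.points = x$n_points)
}
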