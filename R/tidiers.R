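# broom-style tidiers for the package's fitted/result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.free_energy_profile <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.free_energy_profile <- function(x, ...) {
  tibble::tibble(n_bias = nrow(x$table),
                 max_beta_phi = max(x$table$beta_phi),
                 ref_beta_phi = x$ref_beta_phi,
                 F_dewet_kT = x$F_dewet,
                 beta = x$beta)
}

#' @exportS3Method generics::tidy
tidy.pmf_profile <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.pmf_profile <- function(x, ...) {
  tibble::tibble(n_bins = nrow(x$table),
                 z_min = min(x$table$z), z_max = max(x$table$z),
                 W_min = min(x$table$W),
                 plateau_lo = x$plateau_range[1], plateau_hi = x$plateau_range[2],
                 RT = x$RT, iterations = x$iterations,
                 n_boot = x$n_boot %||% NA_integer_)
}

#' @exportS3Method generics::tidy
tidy.binding_result <- function(x, ...) {
  tibble::tibble(term = c("dG", "z1", "z2", "z3", "z4"),
                 estimate = c(x$dG,
                              x$bound_range %||% c(NA_real_, NA_real_),
                              x$unbound_range))
}

#' @exportS3Method generics::glance
glance.binding_result <- function(x, ...) {
  tibble::tibble(dG = x$dG, has_minimum = x$has_minimum, RT = x$RT,
                 bound_width = if (x$has_minimum) diff(x$bound_range) else NA_real_,
                 unbound_width = diff(x$unbound_range))
}
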