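#' Parameter transforms between physical and sampling scales
#'
#' Bounded physical parameters are mapped to an unconstrained sampling scale so
#' the Hamiltonian dynamics never has to stop at a hard boundary: positive
#' parameters by a logarithm, interval-bounded ones by a logit, unbounded ones
#' by the identity. The change of variables carries a Jacobian term which
#' [potential_energy()] adds to the potential, so the sampled density on the
#' physical scale is exactly the likelihood.
#'
#' @param kind Character vector, one of `"identity"`, `"log"`, `"logit"` per
#'   parameter. Recycled to `length(names)`.
#' @param names Parameter names.
#' @param lower,upper Bounds, used by `"logit"` only.
#' @return A tibble of class `param_transform` with one row per parameter.
#' @examples
#' tr <- param_transform(c("log", "identity"), names = c("radius", "offset"))
#' z <- to_sampling(c(radius = 10, offset = -2), tr)
#' to_physical(z, tr)
#' @export
param_transform <- function(kind, names, lower = -Inf, upper = Inf) {
  kind <- match.arg(kind, c("identity", "log", "logit"), several.ok = TRUE)
  n <- length(names)
  out <- tibble::tibble(
    name  = names,
    kind  = rep_len(kind, n),
    lower = rep_len(lower, n),
    upper = rep_len(upper, n)
  )
  bad <- out$kind == "logit" & (!is.finite(out$lower) | !is.finite(out$upper))
  if (any(bad)) stop("logit transform requires finite lower and upper bounds")
  class(out) <- c("param_transform", class(out))
  out
}

#' @rdname param_transform
#' @param phys Named or ordered numeric vector on the physical scale.
#' @param transform A `param_transform`.
#' @export
to_sampling <- function(phys, transform) {
  z <- phys
  for (i in seq_len(nrow(transform))) {
    z[i] <- switch(transform$kind[i],
      identity = phys[i],
      log      = log(phys[i]),
      logit    = stats::qlogis((phys[i] - transform$lower[i]) /
                               (transform$upper[i] - transform$lower[i]))
    )
  }
  unname(z)
}

#' @rdname param_transform
#' @param z Numeric vector on the sampling (unconstrained) scale.
#' @export
to_physical <- function(z, transform) {
  x <- z
  for (i in seq_len(nrow(transform))) {
    x[i] <- switch(transform$kind[i],
      identity = z[i],
      log      = exp(z[i]),
      logit    = transform$lower[i] +
        (transform$upper[i] - transform$lower[i]) * stats::plogis(z[i])
    )
  }
  unname(x)
}

#' @rdname param_transform
#' @details `transform_log_jacobian()` returns `sum(log |d phys / d z|)`, the
#'   log absolute Jacobian determinant of the (diagonal) untransform.
#' @export
transform_log_jacobian <- function(z, transform) {
  lj <- 0
  for (i in seq_len(nrow(transform))) {
    lj <- lj + switch(transform$kind[i],
      identity = 0,
      log      = z[i],
      logit    = log(transform$upper[i] - transform$lower[i]) +
        stats::plogis(z[i], log.p = TRUE) +
        stats::plogis(-z[i], log.p = TRUE)
    )
  }
  lj
}
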