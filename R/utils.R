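#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select bind_rows bind_cols group_by
#'   summarise ungroup left_join distinct row_number n across desc pull rename
#' @importFrom purrr map map_dbl map_int map2 pmap imap
#' @importFrom stats rnorm runif rbinom rbeta rgamma rchisq qnorm pnorm dnorm
#'   quantile median sd var cor optimize rexp setNames mad complete.cases
#'   pchisq qchisq p.adjust predict ecdf
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# internal: stop with a classed condition so tests can assert on class
ta_stop <- function(msg, class = "traitarch_error") {
  abort(msg, class = class)
}

check_fraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    ta_stop(sprintf("`%s` must be a single finite number", name))
  }
  lo_ok <- if (lo_open) x > lo else x >= lo
  hi_ok <- if (hi_open) x < hi else x <= hi
  if (!lo_ok || !hi_ok) {
    ta_stop(sprintf(
      "`%s` must lie in %s%s, %s%s (got %g)", name,
      if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]", x
    ))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < min) {
    ta_stop(sprintf("`%s` must be an integer >= %d", name, min))
  }
  as.integer(x)
}

#' Derive a reproducible per-stage seed from one global seed
#'
#' Deterministic hash of a parent seed and a stage label; every derived
#' value stays inside the 32-bit signed-integer range, so one global seed
#' can drive every source of randomness in a pipeline run.
#'
#' @param seed Integer parent seed.
#' @param label Character stage label.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
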