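#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a comparison report
#' @param x A `cav_comparison`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.cav_comparison <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cav_comparison")
  out
}

#' One-row summary of a comparison report
#' @param x A `cav_comparison`.
#' @param ... Unused.
#' @return Tibble with the headline deltas that are present.
#' @export
glance.cav_comparison <- function(x, ...) {
  pick <- function(q) if (q %in% x$quantity) x$delta[x$quantity == q] else NA_real_
  tibble(delta_e_tot = pick("e_tot"),
         delta_e_tot_per_water = pick("e_tot_per_water"),
         delta_hb_sw = pick("hb_sw"),
         delta_n_water = pick("n_water"))
}
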