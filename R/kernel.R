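#' Distance-dependent rejoining kernel
#'
#' Probability weight for rejoining two chromosome-fragment free ends at
#' initial Euclidean distance r: \eqn{P(r) = \exp(-r/r_0)}.  `c_free` is the
#' dimensionless weight for an end remaining permanently unrejoined, entering
#' the same categorical draw as the pairwise weights.
#'
#' @param r0_um Characteristic rejoining distance in micrometres (> 0);
#'   default 0.8, the value established for human lymphocytes.
#' @param c_free Non-negative weight for staying free; default 0.1.
#' @return Object of class `rejoining_kernel`.
#' @examples
#' k <- rejoining_kernel()
#' kernel_prob(k, 0.8)  # exp(-1)
#' @export
rejoining_kernel <- function(r0_um = 0.8, c_free = 0.1) {
  if (!is.numeric(r0_um) || length(r0_um) != 1L || r0_um <= 0)
    stop("r0_um must be a single positive number", call. = FALSE)
  if (!is.numeric(c_free) || length(c_free) != 1L || c_free < 0)
    stop("c_free must be a single non-negative number", call. = FALSE)
  structure(list(r0_um = r0_um, c_free = c_free), class = "rejoining_kernel")
}

#' @rdname rejoining_kernel
#' @param kernel A `rejoining_kernel`.
#' @param r Distance(s) in micrometres, >= 0.
#' @export
kernel_prob <- function(kernel, r) {
  stopifnot(inherits(kernel, "rejoining_kernel"), all(r >= 0))
  exp(-r / kernel$r0_um)
}
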