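#' Burial sigmoid parameters
#'
#' Slopes (S) and offsets (O) of the two logistic functions of heavy-atom
#' neighbour counts within 6 and 12 A. All-atom: S = 0.15 and 0.5, O = 20
#' and 475; centroid: S = 0.15 and 5, O = 20 and 220 (6 and 12 A radii
#' respectively). Fixed by inspection of burial in polytopic membrane
#' proteins of known structure; not refit here.
#'
#' @param mode `"fullatom"` or `"centroid"`
#' @return object of class `burial_params`
#' @export
burial_params <- function(mode = c("fullatom", "centroid")) {
  mode <- match.arg(mode)
  p <- if (mode == "fullatom")
    list(s6 = 0.15, o6 = 20, s12 = 0.5, o12 = 475)
  else
    list(s6 = 0.15, o6 = 20, s12 = 5, o12 = 220)
  p$mode <- mode
  class(p) <- "burial_params"
  p
}

#' Burial/exposure weight from neighbour counts
#'
#' Product of two decreasing logistic functions of the 6 A and 12 A
#' heavy-atom neighbour counts:
#' \deqn{w = \frac{1}{1 + e^{S_6 (N_6 - O_6)}} \times
#'           \frac{1}{1 + e^{S_{12} (N_{12} - O_{12})}}}
#' The weight runs from 0 (completely buried in protein) to 1 (completely
#' lipid/solvent exposed). Counts may be non-integer (centroid
#' pseudo-counts); the function is continuous and differentiable.
#'
#' @param n6,n12 neighbour counts within 6 and 12 A (vectorised)
#' @param params a [burial_params()]
#' @return weights in (0, 1)
#' @export
burial_weight <- function(n6, n12, params = burial_params("fullatom")) {
  stopifnot(inherits(params, "burial_params"))
  if (any(n6 < 0) || any(n12 < 0))
    stop("neighbour counts must be non-negative", call. = FALSE)
  f6 <- 1 / (1 + exp(params$s6 * (n6 - params$o6)))
  f12 <- 1 / (1 + exp(params$s12 * (n12 - params$o12)))
  f6 * f12
}
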