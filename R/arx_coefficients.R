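#' ARX coefficient set
#'
#' Container for the coefficients of the order-5 autoregressive model with
#' three exogenous binary message inputs that the package fits to 15-minute
#' epoch step counts:
#' \deqn{y(k) = a_0 + \sum_{i=1}^{5} a_i\, y(k-i)
#'   + \sum_{j=1}^{3}\sum_{i=0}^{5} b_{ji}\, u_j(k-i) + \varepsilon(k)}
#' where \eqn{u_j} indicates delivery of a message from library \eqn{j}
#' (affective, social-cognitive, inspirational quote) in epoch \eqn{k-i}.
#'
#' @param a0 intercept (steps per epoch at rest enters through this term).
#' @param a numeric vector of 5 output-lag coefficients \eqn{a_1..a_5}.
#' @param b 3 x 6 numeric matrix of input coefficients; rows are message
#'   types in the order affective, social_cognitive, quote; columns are input
#'   lags 0..5. A vector of length 18 is reshaped row-wise.
#' @return An object of class `arx_coefficients`.
#' @examples
#' co <- arx_coefficients(a0 = 0, a = c(0.5, 0, 0, 0, 0),
#'                        b = rbind(c(10, 0, 0, 0, 0, 0),
#'                                  matrix(0, 2, 6)))
#' arx_spectral_radius(co)
#' @export
arx_coefficients <- function(a0 = 0, a = numeric(ARX_ORDER),
                             b = matrix(0, 3L, ARX_ORDER + 1L)) {
  stopifnot(is.numeric(a0), length(a0) == 1L, is.finite(a0))
  a <- as.numeric(a)
  if (length(a) != ARX_ORDER)
    stop("`a` must hold exactly ", ARX_ORDER, " output-lag coefficients")
  if (is.null(dim(b))) b <- matrix(as.numeric(b), 3L, ARX_ORDER + 1L,
                                   byrow = TRUE)
  b <- as.matrix(b)
  if (!all(dim(b) == c(3L, ARX_ORDER + 1L)))
    stop("`b` must be a 3 x ", ARX_ORDER + 1L, " matrix")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("coefficients must be finite")
  dimnames(b) <- list(MESSAGE_TYPES, paste0("lag", 0:ARX_ORDER))
  structure(list(a0 = a0, a = a, b = b, order = ARX_ORDER, d = EPOCH_MIN),
            class = "arx_coefficients")
}

#' Spectral radius of the output-lag companion matrix
#'
#' The autoregressive part of an ARX model is stable (impulse responses decay)
#' iff this radius is strictly below 1.
#'
#' @param coeffs an [arx_coefficients] object or a numeric vector of
#'   output-lag coefficients.
#' @return largest modulus among companion-matrix eigenvalues.
#' @export
arx_spectral_radius <- function(coeffs) {
  a <- if (inherits(coeffs, "arx_coefficients")) coeffs$a else as.numeric(coeffs)
  p <- length(a)
  if (all(a == 0)) return(0)
  comp <- rbind(a, cbind(diag(p - 1L), 0))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' @export
print.arx_coefficients <- function(x, ...) {
  cat("ARX coefficients (order ", x$order, ", d = ", x$d, " min)\n", sep = "")
  cat("  a0:", format(x$a0, digits = 4), "\n")
  cat("  a: ", paste(format(x$a, digits = 4), collapse = " "), "\n")
  cat("  spectral radius:", format(arx_spectral_radius(x), digits = 4), "\n")
  cat("  b:\n")
  print(round(x$b, 4))
  invisible(x)
}

# flatten to the 22-vector used by the regression design
# layout: intercept, y lags 1..5, then per channel u lags 0..5
coef_to_vector <- function(coeffs) {
  c(coeffs$a0, coeffs$a, as.vector(t(coeffs$b)))
}

coef_from_vector <- function(beta) {
  stopifnot(length(beta) == N_COEF)
  arx_coefficients(a0 = beta[1L],
                   a = beta[2:(ARX_ORDER + 1L)],
                   b = matrix(beta[(ARX_ORDER + 2L):N_COEF], nrow = 3L,
                              byrow = TRUE))
}

design_colnames <- function() {
  c("intercept", paste0("y_lag", 1:ARX_ORDER),
    unlist(lapply(MESSAGE_TYPES,
                  function(ch) paste0(ch, "_lag", 0:ARX_ORDER))))
}
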