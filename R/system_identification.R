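#' Build the ARX regression design from epoch series
#'
#' For every valid target epoch whose five preceding epochs within the same
#' day are also valid, emits one regression row
#' `[1, y(k-1)..y(k-5), u_j(k)..u_j(k-5) for the 3 channels]` (22 columns).
#' Rows from all supplied days are stacked; days never share lags because
#' message effects are not modeled across days.
#'
#' @param series list of `epoch_series` (one participant, one day type).
#' @param order number of lags (fixed at 5 in this analysis).
#' @return object of class `regression_design`: list with matrix `X`,
#'   vector `y_target`, and `n_rows`.
#' @export
build_design <- function(series, order = ARX_ORDER) {
  if (inherits(series, "epoch_series")) series <- list(series)
  rows <- vector("list", length(series))
  for (s in seq_along(series)) {
    es <- series[[s]]
    n <- length(es$y)
    if (n <= order) next
    ok <- which(vapply((order + 1L):n, function(k)
      all(es$valid[(k - order):k]), logical(1L)))
    if (!length(ok)) next
    ks <- ok + order
    X <- matrix(0, length(ks), N_COEF)
    X[, 1L] <- 1
    for (i in seq_len(order)) X[, 1L + i] <- es$y[ks - i]
    col <- order + 1L
    for (j in 1:3) for (i in 0:order) {
      col <- col + 1L
      X[, col] <- es$u[ks - i, j]
    }
    rows[[s]] <- list(X = X, y = es$y[ks])
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) stop("insufficient data: no eligible regression rows")
  X <- do.call(rbind, lapply(rows, `[[`, "X"))
  colnames(X) <- design_colnames()
  structure(list(X = X, y_target = unlist(lapply(rows, `[[`, "y")),
                 n_rows = nrow(X), order = order),
            class = "regression_design")
}

#' Fit the ARX model by least squares
#'
#' Solves the least-squares problem via QR factorisation (no explicit
#' normal-equations inverse for the solution). If the design is rank
#' deficient — typically a message type never delivered on that day type —
#' the unidentifiable columns are dropped, their coefficients set to zero,
#' and the model flagged; alternatively a ridge penalty can be supplied.
#'
#' @param design a `regression_design`.
#' @param ridge nonnegative ridge penalty added as `sqrt(ridge)` pseudo-rows
#'   (0 = plain least squares, the default and the analysis in this
#'   package).
#' @return object of class `arx_model`: `coeffs` ([arx_coefficients]),
#'   `sigma2` (RSS / (n - rank)), `cov` (22 x 22 coefficient covariance,
#'   zero rows/columns for dropped coefficients), `n_rows`, `rank`,
#'   `fit_rmse`, `dropped` (dropped column names), `flags`.
#' @export
fit_least_squares <- function(design, ridge = 0) {
  stopifnot(inherits(design, "regression_design"))
  X <- design$X
  y <- design$y_target
  n <- nrow(X)
  p <- ncol(X)
  if (n < p) stop("fewer rows (", n, ") than coefficients (", p, ")")
  if (ridge > 0) {
    X <- rbind(X, diag(sqrt(ridge), p))
    y <- c(y, numeric(p))
  }
  qx <- qr(X)
  rank <- qx$rank
  beta <- numeric(p)
  dropped <- character(0)
  keep <- sort(qx$pivot[seq_len(rank)])
  if (rank < p) {
    dropped <- colnames(design$X)[setdiff(seq_len(p), keep)]
    qx <- qr(X[, keep, drop = FALSE])
  }
  beta[keep] <- qr.coef(qx, y)
  fitted <- design$X %*% beta
  res <- design$y_target - fitted
  rss <- sum(res^2)
  dof <- design$n_rows - rank
  sigma2 <- if (dof > 0) rss / dof else NA_real_
  covb <- matrix(0, p, p, dimnames = list(colnames(design$X),
                                          colnames(design$X)))
  if (is.finite(sigma2))
    covb[keep, keep] <- sigma2 *
      chol2inv(chol(crossprod(design$X[, keep, drop = FALSE])))
  flags <- character(0)
  if (length(dropped)) flags <- c(flags, "rank_deficient")
  coeffs <- coef_from_vector(beta)
  if (arx_spectral_radius(coeffs) >= 1) flags <- c(flags, "unstable")
  structure(list(coeffs = coeffs, beta = setNames(beta, colnames(design$X)),
                 sigma2 = sigma2, cov = covb, n_rows = design$n_rows,
                 rank = rank, fit_rmse = sqrt(mean(res^2)),
                 dropped = dropped, flags = flags),
            class = "arx_model")
}

#' @export
print.arx_model <- function(x, ...) {
  cat("ARX model: ", x$n_rows, " rows, rank ", x$rank, ", RMSE ",
      format(x$fit_rmse, digits = 4), sep = "")
  if (length(x$flags)) cat(" [", paste(x$flags, collapse = ", "), "]",
                           sep = "")
  cat("\n")
  print(x$coeffs)
  invisible(x)
}

#' Predict epoch step sums from a fitted model
#'
#' @param object an `arx_model`.
#' @param design a `regression_design` with matching columns.
#' @param ... unused.
#' @return list with `fitted` and `residuals`.
#' @export
predict.arx_model <- function(object, design, ...) {
  stopifnot(inherits(design, "regression_design"))
  fitted <- drop(design$X %*% object$beta)
  list(fitted = fitted, residuals = design$y_target - fitted)
}

#' Fit switched weekday/weekend models for one participant
#'
#' @param series list of `epoch_series` across days.
#' @param ridge passed to [fit_least_squares].
#' @return list with `weekday` and `weekend` `arx_model`s (either may be
#'   `NULL` with a warning when no eligible rows exist).
#' @export
fit_switched_models <- function(series, ridge = 0) {
  halves <- split_day_type(series)
  fit_one <- function(ss, label) {
    if (!length(ss)) return(NULL)
    tryCatch(fit_least_squares(build_design(ss), ridge = ridge),
             error = function(e) {
               warning("could not fit ", label, " model: ",
                       conditionMessage(e))
               NULL
             })
  }
  list(weekday = fit_one(halves$weekday, "weekday"),
       weekend = fit_one(halves$weekend, "weekend"))
}

#' Serialise a fitted model to JSON
#' @param model an `arx_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_arx_model <- function(model, path) {
  jsonlite::write_json(
    list(beta = as.list(model$beta), sigma2 = model$sigma2,
         cov = model$cov, n_rows = model$n_rows, rank = model$rank,
         fit_rmse = model$fit_rmse, dropped = model$dropped,
         flags = model$flags),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted model from JSON
#' @param path file written by [write_arx_model].
#' @return an `arx_model`.
#' @export
read_arx_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- unlist(m$beta)
  covb <- matrix(unlist(m$cov), N_COEF, N_COEF,
                 dimnames = list(names(beta), names(beta)))
  structure(list(coeffs = coef_from_vector(unname(beta)), beta = beta,
                 sigma2 = m$sigma2, cov = covb, n_rows = m$n_rows,
                 rank = m$rank, fit_rmse = m$fit_rmse,
                 dropped = as.character(m$dropped %||% character(0)),
                 flags = as.character(m$flags %||% character(0))),
            class = "arx_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
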