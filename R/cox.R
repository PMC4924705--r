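#' Cox proportional-hazards fit for a single gene
#'
#' Maximizes the Cox partial likelihood (Breslow tie handling) by
#' Newton-Raphson for a gene-expression covariate, optionally adjusted for
#' clinical covariates. Convergence requires the score norm to fall below
#' `tol` within `max_iter` iterations; fits drifting to `|beta| > 20`
#' (complete separation) are flagged non-converged. A constant expression
#' vector yields the degenerate convention `beta = 0`, `p = 1`.
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicators (1 = event, 0 = censored); >= 2 events
#'   required.
#' @param x Numeric expression vector (the covariate of interest).
#' @param covariates Optional data frame or matrix of adjustment covariates;
#'   character/factor columns are expanded to reference-level indicators.
#' @param tol Convergence tolerance on the score norm (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 50).
#' @return An object of class `"cox_fit"`: list with `beta` (log hazard ratio
#'   per unit expression), `hr`, `se`, `z`, `p_value`, `coefficients` (all
#'   fitted coefficients), `loglik`, `n_used`, `n_events`, `iter`,
#'   `converged`, `degenerate`.
#' @export
fit_cox <- function(time, event, x, covariates = NULL,
                    tol = 1e-8, max_iter = 50L) {
  n <- length(time)
  if (length(event) != n || length(x) != n)
    stop("time, event and x must have equal length", call. = FALSE)
  if (!all(is.finite(time)) || !all(is.finite(x)))
    stop("time and x must be finite", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  if (sum(event) < 2) stop("need >= 2 events", call. = FALSE)

  X <- cbind(x = x)
  if (!is.null(covariates)) {
    cf <- as.data.frame(covariates)
    mm <- stats::model.matrix(~ ., data = cf)[, -1L, drop = FALSE]
    X <- cbind(X, mm)
    if (qr(X)$rank < ncol(X))
      stop("covariate matrix is rank-deficient after encoding", call. = FALSE)
  }
  degenerate <- stats::sd(x) == 0
  p <- ncol(X)
  centers <- colMeans(X)
  Xc <- sweep(X, 2L, centers)

  # sort by decreasing time; risk set of observation i = positions 1..ri
  ord <- order(-time)
  t_s <- time[ord]
  e_s <- event[ord]
  Xs <- Xc[ord, , drop = FALSE]
  r <- rle(t_s)
  ri <- rep(cumsum(r$lengths), r$lengths)
  ev <- which(e_s == 1)

  # cross-product columns for the information matrix
  pairs <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  Xprod <- Xs[, pairs[, 1L], drop = FALSE] * Xs[, pairs[, 2L], drop = FALSE]

  partial <- function(beta) {
    eta <- drop(Xs %*% beta)
    w <- exp(eta)
    S0 <- cumsum(w)[ri]
    S1 <- apply(Xs * w, 2L, cumsum)[ri, , drop = FALSE]
    S2 <- apply(Xprod * w, 2L, cumsum)[ri, , drop = FALSE]
    ll <- sum(eta[ev]) - sum(log(S0[ev]))
    xbar <- S1[ev, , drop = FALSE] / S0[ev]
    U <- colSums(Xs[ev, , drop = FALSE] - xbar)
    Imat <- matrix(0, p, p)
    s2e <- colSums(S2[ev, , drop = FALSE] / S0[ev])
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      Imat[i, j] <- Imat[j, i] <- s2e[k] - sum(xbar[, i] * xbar[, j])
    }
    list(ll = ll, U = U, I = Imat)
  }

  beta <- rep(0, p)
  if (degenerate) {
    fit_p <- partial(beta)
    return(structure(list(beta = 0, hr = 1, se = NA_real_, z = NA_real_,
                          p_value = 1, coefficients = stats::setNames(beta, colnames(X)),
                          loglik = fit_p$ll, n_used = n, n_events = sum(event),
                          iter = 0L, converged = TRUE, degenerate = TRUE),
                     class = "cox_fit"))
  }

  cur <- partial(beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(cur$I, cur$U), error = function(e) NULL)
    if (is.null(step)) break
    new_beta <- beta + step
    new <- partial(new_beta)
    halved <- 0L
    while ((!is.finite(new$ll) || new$ll < cur$ll - 1e-12) && halved < 20L) {
      step <- step / 2
      new_beta <- beta + step
      new <- partial(new_beta)
      halved <- halved + 1L
    }
    beta <- new_beta
    cur <- new
    if (max(abs(cur$U)) < tol) { converged <- TRUE; break }
    if (any(abs(beta) > 20)) break
  }
  if (any(abs(beta) > 20)) converged <- FALSE

  vcov_ <- tryCatch(solve(cur$I), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(vcov_))
  z <- beta / se
  structure(list(beta = unname(beta[1L]), hr = exp(unname(beta[1L])),
                 se = unname(se[1L]), z = unname(z[1L]),
                 p_value = unname(2 * stats::pnorm(-abs(z[1L]))),
                 coefficients = stats::setNames(beta, colnames(X)),
                 loglik = cur$ll, n_used = n, n_events = sum(event),
                 iter = iter, converged = converged, degenerate = FALSE),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(paste0("Cox proportional-hazards fit (Breslow ties)\n",
                     "  beta = %.4f  HR = %.4f  se = %.4f  p = %.3g\n",
                     "  n = %d, events = %d, %s%s\n"),
              x$beta, x$hr, x$se, x$p_value, x$n_used, x$n_events,
              if (x$converged) "converged" else "NOT converged",
              if (x$degenerate) " (degenerate: constant covariate)" else ""))
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
summary.cox_fit <- function(object, ...) {
  out <- data.frame(beta = object$beta, hr = object$hr, se = object$se,
                    z = object$z, p_value = object$p_value,
                    n = object$n_used, events = object$n_events,
                    converged = object$converged)
  rownames(out) <- names(object$coefficients)[1L]
  out
}

#' Per-gene univariate Cox screen
#'
#' Fits [fit_cox()] for every requested gene against the cohort's survival
#' endpoint, optionally adjusting each fit for clinical covariates.
#'
#' @param expr An [expression_matrix()] (genes x patients).
#' @param clinical A [clinical_table()] whose `sample_id`s appear in
#'   `colnames(expr)`.
#' @param genes Genes to screen (default all rows of `expr`).
#' @param covariates Optional character vector of clinical column names to
#'   adjust for (e.g. `c("age", "gender", "race")`).
#' @return Data frame of class `"cox_screen"`: one row per gene with `gene`,
#'   `beta`, `hr`, `se`, `z`, `p_value`, `n_used`, `n_events`, `converged`,
#'   `degenerate`.
#' @export
cox_screen <- function(expr, clinical, genes = rownames(expr),
                       covariates = NULL) {
  missing_genes <- setdiff(genes, rownames(expr))
  if (length(missing_genes) > 0L)
    stop("genes absent from expression matrix: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  idx <- match(clinical$sample_id, colnames(expr))
  if (anyNA(idx))
    stop("clinical samples missing from expression matrix", call. = FALSE)
  cov_df <- if (!is.null(covariates)) clinical[, covariates, drop = FALSE]
  rows <- lapply(genes, function(g) {
    fit <- fit_cox(clinical$time, clinical$event, expr[g, idx],
                   covariates = cov_df)
    data.frame(gene = g, beta = fit$beta, hr = fit$hr, se = fit$se,
               z = fit$z, p_value = fit$p_value, n_used = fit$n_used,
               n_events = fit$n_events, converged = fit$converged,
               degenerate = fit$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cox_screen", "data.frame")
  out
}
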