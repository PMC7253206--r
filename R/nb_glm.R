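#' Negative-binomial (NB2) log-likelihood
#'
#' Exact log-likelihood of counts under the NB2 parameterization with mean
#' `mu` and dispersion `phi`, i.e. variance = mu + phi * mu^2. `phi = 0`
#' evaluates the Poisson limit.
#'
#' @param counts Nonnegative integer vector of observed counts.
#' @param mu Positive vector of means, recycled against `counts`.
#' @param phi Single nonnegative dispersion.
#' @return Total log-likelihood (scalar).
#' @examples
#' nb_loglik(3, 3, 0)       # log Poisson pmf(3; 3)
#' nb_loglik(c(4, 6), 5, 0.1)
#' @export
nb_loglik <- function(counts, mu, phi) {
  if (length(phi) != 1L || is.na(phi) || phi < 0) {
    abort("`phi` must be a single nonnegative dispersion.")
  }
  if (any(mu <= 0)) abort("`mu` must be strictly positive.")
  mu <- rep_len(mu, length(counts))
  if (phi < 1e-10) {
    sum(dpois(counts, lambda = mu, log = TRUE))
  } else {
    sum(dnbinom(counts, size = 1 / phi, mu = mu, log = TRUE))
  }
}

# IRLS (Fisher scoring) fit of an NB2 GLM with log link, fixed dispersion and
# fixed offset. Small dense designs only; returns the pieces the LRT and the
# Cox-Reid adjustment need.
nb_irls <- function(y, X, offset, phi, beta_init = NULL, max_iter = 100L, tol = 1e-10) {
  p <- ncol(X)
  beta <- beta_init %||% qr.solve(qr(X), log(pmax(y, 0.5)) - offset)
  ll_old <- -Inf
  XtWX <- NULL
  for (iter in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtWX <- crossprod(X, X * w)
    beta_new <- tryCatch(
      drop(solve(XtWX, crossprod(X, w * z))),
      error = function(e) drop(qr.coef(qr(X * sqrt(w)), sqrt(w) * z))
    )
    beta_new[is.na(beta_new)] <- 0
    mu_new <- exp(pmin(pmax(drop(X %*% beta_new) + offset, -30), 30))
    ll <- nb_loglik(y, mu_new, phi)
    if (!is.finite(ll)) break
    beta <- beta_new
    if (abs(ll - ll_old) < tol) {
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  list(beta = beta, mu = mu, ll = nb_loglik(y, mu, phi), XtWX = XtWX)
}

# Cox-Reid adjusted profile log-likelihood of the dispersion under the full
# design: ll(beta_hat(phi); phi) - 0.5 * log det(X' W X). The adjustment
# removes most of the downward bias of the dispersion MLE at small replicate
# numbers.
nb_adjusted_profile_ll <- function(log_phi, y, X, offset) {
  phi <- exp(log_phi)
  fit <- nb_irls(y, X, offset, phi)
  d <- determinant(fit$XtWX, logarithm = TRUE)
  adj <- if (d$sign > 0) 0.5 * as.numeric(d$modulus) else 0
  fit$ll - adj
}

#' Estimate a gene-wise NB dispersion by adjusted profile likelihood
#'
#' Maximizes the Cox-Reid adjusted profile likelihood of the NB2 dispersion
#' under the supplied design, the standard small-sample correction for
#' GLM-based RNA-seq testing. Falls back to a method-of-moments estimate if
#' the optimization fails.
#'
#' @param y Count vector.
#' @param X Design (model) matrix of the full model.
#' @param offset Per-observation log offset (log size factors).
#' @return A single nonnegative dispersion estimate.
#' @export
estimate_dispersion <- function(y, X, offset = rep(0, length(y))) {
  mom <- local({
    m <- mean(y)
    v <- stats::var(y)
    if (!is.finite(v) || m <= 0) 0 else max((v - m) / m^2, 0)
  })
  opt <- tryCatch(
    optimize(nb_adjusted_profile_ll,
      interval = log(c(1e-8, 50)),
      y = y, X = X, offset = offset, maximum = TRUE, tol = 1e-4
    ),
    error = function(e) NULL
  )
  if (is.null(opt) || !is.finite(opt$objective)) {
    return(mom)
  }
  phi <- exp(opt$maximum)
  if (phi < 2e-8) 0 else phi
}

# Reference distribution for the LRT statistic. With a known (supplied)
# dispersion the usual chi-squared applies. When the dispersion is estimated
# from the same few observations, the chi-squared is anticonservative, so the
# statistic is instead scaled by the Pearson dispersion under the full model
# and referred to an F distribution (the quasi-likelihood F-test construction
# used for small-sample GLM count testing), which accounts for the
# uncertainty of the per-gene dispersion estimate.
lrt_pvalue <- function(stat, df, y, mu_full, phi, df_resid, estimated) {
  if (!estimated || df_resid < 1) {
    return(max(pchisq(stat, df = df, lower.tail = FALSE), 1e-300))
  }
  s2 <- sum((y - mu_full)^2 / (mu_full + phi * mu_full^2)) / df_resid
  f_stat <- (stat / df) / max(s2, 1e-8)
  max(stats::pf(f_stat, df, df_resid, lower.tail = FALSE), 1e-300)
}

check_nested <- function(X_full, X_reduced) {
  q1 <- qr(X_full)
  q2 <- qr(cbind(X_full, X_reduced))
  if (q2$rank > q1$rank) {
    abort("`design_reduced` is not nested within `design_full`.")
  }
  invisible(TRUE)
}

resolve_design <- function(design, data) {
  if (inherits(design, "formula")) {
    if (is.null(data)) abort("Formula designs need `data` with sample covariates.")
    model.matrix(design, data = data)
  } else {
    as.matrix(design)
  }
}

#' Negative-binomial GLM likelihood-ratio test
#'
#' Fits nested NB2 GLMs (log link, log size factors as fixed offsets) to one
#' gene's counts and compares them with a likelihood-ratio test against a
#' chi-squared reference. The gene-wise dispersion is estimated under the
#' full model by Cox-Reid adjusted profile likelihood and held fixed for both
#' fits, unless supplied.
#'
#' @param counts Count vector for one gene (one entry per sample).
#' @param design_full,design_reduced Model matrices, or formulas resolved
#'   against `data`. The reduced design must be nested in the full design.
#' @param size_factors Positive per-sample scaling factors (default 1).
#' @param data Optional tibble of per-sample covariates for formula designs.
#' @param dispersion Optional fixed NB2 dispersion; estimated when `NULL`.
#' @return An object of class `nb_lrt`: a list with the test statistic,
#'   degrees of freedom, p-value, dispersion used, log-likelihoods and fitted
#'   coefficients. `tidy()` returns it as a one-row tibble.
#' @examples
#' x <- data.frame(group = rep(c("A", "B"), each = 3))
#' y <- c(100, 110, 90, 10, 9, 11)
#' fit <- nb_glm_lrt(y, ~group, ~1, data = x, dispersion = 0.1)
#' tidy(fit)
#' @export
nb_glm_lrt <- function(counts, design_full, design_reduced,
                       size_factors = NULL, data = NULL, dispersion = NULL) {
  X_full <- resolve_design(design_full, data)
  X_reduced <- resolve_design(design_reduced, data)
  n <- length(counts)
  if (nrow(X_full) != n || nrow(X_reduced) != n) {
    abort("Design rows must match the number of count observations.")
  }
  size_factors <- size_factors %||% rep(1, n)
  if (any(size_factors <= 0)) abort("`size_factors` must be positive.")
  check_nested(X_full, X_reduced)
  offset <- log(size_factors)

  df <- qr(X_full)$rank - qr(X_reduced)$rank
  if (all(counts == 0)) {
    out <- list(
      lrt_stat = 0, df = df, pvalue = 1, dispersion = dispersion %||% 0,
      ll_full = 0, ll_reduced = 0, beta_full = rep(0, ncol(X_full)),
      degenerate = TRUE
    )
    class(out) <- "nb_lrt"
    return(out)
  }
  phi <- dispersion %||% estimate_dispersion(counts, X_full, offset)
  fit_full <- nb_irls(counts, X_full, offset, phi)
  fit_red <- nb_irls(counts, X_reduced, offset, phi)
  stat <- max(0, 2 * (fit_full$ll - fit_red$ll))
  p <- lrt_pvalue(
    stat, df, counts, fit_full$mu, phi,
    df_resid = n - qr(X_full)$rank, estimated = is.null(dispersion)
  )
  out <- list(
    lrt_stat = stat, df = df, pvalue = p, dispersion = phi,
    ll_full = fit_full$ll, ll_reduced = fit_red$ll,
    beta_full = fit_full$beta, degenerate = FALSE
  )
  class(out) <- "nb_lrt"
  out
}

#' @export
print.nb_lrt <- function(x, ...) {
  cat(sprintf(
    "NB GLM LRT: stat = %.4g on %d df, p = %.3g (dispersion %.4g)%s\n",
    x$lrt_stat, x$df, x$pvalue, x$dispersion,
    if (x$degenerate) " [degenerate: all-zero counts]" else ""
  ))
  invisible(x)
}

#' @rdname nb_glm_lrt
#' @param x An `nb_lrt` object.
#' @param ... Unused.
#' @method tidy nb_lrt
#' @export
tidy.nb_lrt <- function(x, ...) {
  tibble(
    lrt_stat = x$lrt_stat, df = x$df, pvalue = x$pvalue,
    dispersion = x$dispersion, degenerate = x$degenerate
  )
}

# Fast path: the same LRT applied to every row of a genes x samples count
# matrix under shared designs. Returns plain columns, no per-gene objects.
nb_lrt_matrix <- function(mat, X_full, X_reduced, size_factors, dispersion = NULL) {
  offset <- log(size_factors)
  rank_full <- qr(X_full)$rank
  df <- rank_full - qr(X_reduced)$rank
  df_resid <- ncol(mat) - rank_full
  ngene <- nrow(mat)
  stat <- numeric(ngene)
  pval <- numeric(ngene)
  phis <- numeric(ngene)
  degen <- logical(ngene)
  for (i in seq_len(ngene)) {
    y <- mat[i, ]
    if (all(y == 0)) {
      stat[i] <- 0
      pval[i] <- 1
      phis[i] <- dispersion %||% 0
      degen[i] <- TRUE
      next
    }
    phi <- dispersion %||% estimate_dispersion(y, X_full, offset)
    fit_f <- nb_irls(y, X_full, offset, phi)
    ll_r <- nb_irls(y, X_reduced, offset, phi)$ll
    stat[i] <- max(0, 2 * (fit_f$ll - ll_r))
    pval[i] <- lrt_pvalue(
      stat[i], df, y, fit_f$mu, phi,
      df_resid = df_resid, estimated = is.null(dispersion)
    )
    phis[i] <- phi
  }
  list(lrt_stat = stat, df = df, pvalue = pval, dispersion = phis, degenerate = degen)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR-adjusted p-values: `q_(i) = min_{j >= i} p_(j) * m / j`,
#' capped at 1. `NA` values are propagated and excluded from the ranking.
#'
#' @param p Vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted q-values in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(q)
  o <- order(p[ok])
  adj <- rev(cummin(rev(p[ok][o] * m / seq_len(m))))
  q[ok[o]] <- pmin(adj, 1)
  q
}
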