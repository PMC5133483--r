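#' Eigendecomposition of the structured covariance
#'
#' Decomposes K = 2 * Phi once per sample set so that every subsequent REML
#' fit on those samples reduces to a one-dimensional profile optimisation in
#' the rotated basis (the "rotation trick"). Reuse the returned object
#' across probes, SNPs and permutations.
#'
#' @param kinship a \code{"kinship_matrix"}, or a symmetric PSD matrix.
#' @return list with \code{U} (eigenvectors), \code{d} (eigenvalues),
#'   \code{sample_ids}; class \code{"kinship_eigen"}.
#' @export
kinship_eigen <- function(kinship) {
  K <- if (inherits(kinship, "kinship_matrix")) additive_relationship(kinship)
       else as.matrix(kinship)
  if (!isSymmetric(unname(K), tol = 1e-8))
    stop("covariance matrix is not symmetric")
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values)))
    stop("covariance matrix is not positive semidefinite (min eigenvalue ",
         format(min(e$values)), ")")
  structure(list(U = e$vectors, d = pmax(e$values, 0),
                 sample_ids = rownames(K)),
            class = "kinship_eigen")
}

#' REML fit of the kinship linear mixed model
#'
#' Fits y ~ N(X beta, sigma_g^2 K + sigma_e^2 I) by restricted maximum
#' likelihood, where K = 2 * Phi is the expected additive relationship
#' matrix. The restricted likelihood is profiled down to the variance ratio
#' lambda = sigma_g^2 / sigma_e^2 and maximised over log(lambda) on
#' [1e-6, 1e6] by a grid-guarded golden-section search (tolerance 1e-8);
#' beta is the generalized least squares estimate at the optimum.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (full column rank).
#' @param K a \code{"kinship_eigen"} (preferred: computed once and reused),
#'   a \code{"kinship_matrix"}, or a raw PSD matrix.
#' @param lambda_range search range for the variance ratio.
#' @param tol golden-section tolerance on log(lambda).
#' @return object of class \code{"lmmkin"} with elements \code{beta},
#'   \code{se}, \code{sigma_g2}, \code{sigma_e2}, \code{h2},
#'   \code{loglik_reml}, \code{converged}, \code{boundary}.
#' @export
reml_fit <- function(y, X, K, lambda_range = c(1e-6, 1e6), tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n) stop("nrow(X) must match length(y)")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  ke <- if (inherits(K, "kinship_eigen")) K else kinship_eigen(K)
  if (nrow(ke$U) != n) stop("kinship dimension must match length(y)")
  ytil <- crossprod(ke$U, y)
  Xtil <- crossprod(ke$U, X)
  fit <- cpp_reml_fit(ytil, Xtil, ke$d, lambda_range[1], lambda_range[2],
                      tol, 33L)
  beta <- drop(fit$beta); names(beta) <- colnames(X)
  se <- drop(fit$se); names(se) <- colnames(X)
  sg2 <- if (fit$at_lower) 0 else fit$sigma_g2
  structure(list(beta = beta, se = se,
                 sigma_g2 = sg2, sigma_e2 = fit$sigma_e2,
                 lambda = fit$lambda,
                 h2 = sg2 / (sg2 + fit$sigma_e2),
                 loglik_reml = fit$loglik_reml,
                 converged = isTRUE(fit$converged),
                 boundary = isTRUE(fit$boundary),
                 n = n, df_residual = n - ncol(X)),
            class = "lmmkin")
}

#' Kinship mixed model with a formula interface
#'
#' Formula front end to \code{\link{reml_fit}}. Rows of \code{data} are
#' matched to the kinship matrix by the \code{id} column (or row names).
#'
#' @param formula model formula for the fixed effects.
#' @param data data frame of response and covariates.
#' @param kinship a \code{"kinship_matrix"} covering the samples.
#' @param id column of \code{data} holding sample ids; defaults to row names.
#' @param ... passed to \code{\link{reml_fit}}.
#' @export
lmmkin <- function(formula, data, kinship, id = NULL, ...) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  dropped <- nrow(data) - nrow(mf)
  if (dropped > 0)
    message("lmmkin: dropped ", dropped, " rows with missing values")
  all_ids <- if (!is.null(id)) as.character(data[[id]]) else rownames(data)
  ids <- all_ids[match(rownames(mf), rownames(data))]
  kb <- block_view(kinship, ids)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  fit <- reml_fit(y, X, kinship_eigen(kb), ...)
  fit$call <- match.call()
  fit$formula <- formula
  fit$sample_ids <- ids
  fit$y <- y
  fit$X <- X
  fit$kinship <- kb
  fit
}

#' Wald test for one coefficient of a kinship mixed model
#'
#' Two-sided p-value from (beta/se)^2 against the chi-square distribution
#' with 1 degree of freedom.
#'
#' @param fit an \code{"lmmkin"} object.
#' @param coefficient coefficient name.
#' @return p-value; \code{NA} if the fit did not converge.
#' @export
wald_p <- function(fit, coefficient) {
  if (!coefficient %in% names(fit$beta))
    stop("no coefficient named '", coefficient, "'")
  if (!isTRUE(fit$converged)) return(NA_real_)
  z2 <- (fit$beta[[coefficient]] / fit$se[[coefficient]])^2
  stats::pchisq(z2, df = 1, lower.tail = FALSE)
}

#' Narrow-sense heritability of a trait from the SNP-free model
#'
#' Fits the covariates-only mixed model and returns
#' h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2).
#'
#' @inheritParams reml_fit
#' @param X_null covariate design (no SNP column).
#' @export
estimate_h2 <- function(y, X_null, K, ...) {
  fit <- reml_fit(y, X_null, K, ...)
  fit$h2
}

#' Expression principal components for batch adjustment
#'
#' Sample scores of the top-k principal components of the probes x samples
#' expression matrix after per-probe centering. The sign of each component
#' is fixed by making its largest-magnitude probe loading positive.
#'
#' @param expr numeric matrix, probes in rows, samples in columns.
#' @param k number of components (default 2: Pc1, Pc2).
#' @return samples x k matrix of scores, columns \code{Pc1}, \code{Pc2}, ...
#' @export
pca_covariates <- function(expr, k = 2) {
  expr <- as.matrix(expr)
  if (ncol(expr) < k + 1) stop("need at least k+1 samples")
  cx <- expr - rowMeans(expr)
  if (all(abs(cx) < 1e-12)) stop("expression matrix is constant")
  s <- svd(t(cx), nu = k, nv = k)     # samples x probes
  flip <- vapply(seq_len(k), function(j) {
    v <- s$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(s$u[, seq_len(k), drop = FALSE] %*%
                    diag(s$d[seq_len(k)], k), 2, flip, `*`)
  dimnames(scores) <- list(colnames(expr), paste0("Pc", seq_len(k)))
  scores
}

#' Shapiro-Wilk normality scan over expression probes
#'
#' Runs the Shapiro-Wilk test on every probe and flags probes significant
#' after Bonferroni correction (p < 0.05 / number of testable probes).
#' Constant probes are marked non-testable and excluded from the
#' denominator.
#'
#' @param expr probes x samples matrix.
#' @param alpha family-wise level before correction.
#' @return data frame (probe_id, p, testable, flagged) with attribute
#'   \code{"fraction_flagged"}.
#' @export
normality_scan <- function(expr, alpha = 0.05) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) stop("Shapiro-Wilk needs at least 3 samples")
  p <- apply(expr, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(unique(v)) < 3) return(NA_real_)
    stats::shapiro.test(v)$p.value
  })
  testable <- !is.na(p)
  thr <- alpha / sum(testable)
  out <- data.frame(probe_id = rownames(expr), p = p, testable = testable,
                    flagged = testable & p < thr, row.names = NULL)
  attr(out, "bonferroni_threshold") <- thr
  attr(out, "fraction_flagged") <- mean(out$flagged[testable])
  out
}

# ---- S3 methods for lmmkin ------------------------------------------------

#' @export
print.lmmkin <- function(x, ...) {
  cat("Kinship linear mixed model (REML)\n")
  if (!is.null(x$call)) cat("  call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  n = %d, sigma_g2 = %.4g, sigma_e2 = %.4g, h2 = %.3f\n",
              x$n, x$sigma_g2, x$sigma_e2, x$h2))
  cat(sprintf("  REML log-likelihood: %.4f%s\n", x$loglik_reml,
              if (x$boundary) " (variance ratio at search boundary)" else ""))
  cat("Coefficients:\n")
  print(x$beta)
  invisible(x)
}

#' @export
coef.lmmkin <- function(object, ...) object$beta

#' @export
vcov.lmmkin <- function(object, ...) {
  # diagonal reconstruction is enough for Wald tests; full vcov needs X
  if (is.null(object$X)) return(diag(object$se^2))
  ke <- kinship_eigen(object$kinship)
  w <- 1 / (object$lambda * ke$d + 1)
  Xt <- crossprod(ke$U, object$X)
  object$sigma_e2 * solve(crossprod(Xt, Xt * w))
}

#' @export
logLik.lmmkin <- function(object, ...) {
  structure(object$loglik_reml, df = length(object$beta) + 2,
            class = "logLik")
}

#' @export
summary.lmmkin <- function(object, ...) {
  z <- object$beta / object$se
  tab <- cbind(Estimate = object$beta, `Std. Error` = object$se,
               `z value` = z,
               `Pr(>|z|)` = stats::pchisq(z^2, 1, lower.tail = FALSE))
  structure(list(fit = object, coefficients = tab), class = "summary.lmmkin")
}

#' @export
print.summary.lmmkin <- function(x, ...) {
  print(x$fit)
  cat("\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
fitted.lmmkin <- function(object, ...) {
  if (is.null(object$X)) stop("fit carries no design (use lmmkin())")
  drop(object$X %*% object$beta)
}

#' @export
residuals.lmmkin <- function(object, ...) {
  if (is.null(object$y)) stop("fit carries no response (use lmmkin())")
  object$y - fitted(object)
}

#' @export
predict.lmmkin <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  X <- stats::model.matrix(stats::delete.response(stats::terms(object$formula)),
                           newdata)
  drop(X %*% object$beta[colnames(X)])
}

#' @export
simulate.lmmkin <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(object$kinship)) stop("fit carries no kinship (use lmmkin())")
  K <- additive_relationship(object$kinship)
  L <- chol(object$sigma_g2 * K +
              diag(object$sigma_e2, nrow(K)) + diag(1e-10, nrow(K)))
  mu <- fitted(object)
  out <- as.data.frame(replicate(nsim, mu + drop(crossprod(L, stats::rnorm(nrow(K))))))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.lmmkin <- function(x, ...) {
  r <- residuals(x)
  stats::qqnorm(r, main = "Marginal residuals", ...)
  stats::qqline(r)
  invisible(x)
}
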