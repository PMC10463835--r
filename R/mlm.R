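#' Fit the null mixed model (no SNP)
#'
#' Single-variance-component REML in the EMMA parameterization: with
#' kinship K eigendecomposed once, the variance ratio
#' `lambda = sigma2_g / sigma2_e` is profiled out by one-dimensional
#' optimization of the REML log-likelihood over `log(lambda)` in
#' \[-10, 10\]. K is bent to the nearest positive-semidefinite matrix
#' (eigenvalues floored at 1e-6) when needed.
#'
#' @param y Numeric phenotype vector (typically per-accession BLUEs).
#' @param S Covariate matrix including an intercept column (e.g. cbind(1,
#'   top PCs)); must have full column rank.
#' @param K Kinship matrix matching the order of `y`.
#' @return Object of class `mlm_null`: list with `lambda`, `sigma2_e`,
#'   `sigma2_g`, `loglik`, `beta` (covariate GLS estimates), `eigen`
#'   (values/vectors of K), `y`, `S`.
#' @export
fit_null_mlm <- function(y, S, K) {
  n <- length(y)
  if (any(!is.finite(y))) abort("y must be finite")
  S <- as.matrix(S)
  if (nrow(S) != n || nrow(K) != n) abort("dimension mismatch")
  if (qr(S)$rank < ncol(S)) abort("covariate matrix S is rank deficient")
  K <- bend_psd(unclass(K))
  ee <- eigen(K, symmetric = TRUE)
  ystar <- crossprod(ee$vectors, y)
  Sstar <- crossprod(ee$vectors, S)
  p <- ncol(S)
  ldet_sts <- determinant(crossprod(S), logarithm = TRUE)$modulus

  reml_ll <- function(log_lambda) {
    w <- exp(log_lambda) * ee$values + 1
    sw <- sqrt(w)
    yt <- ystar / sw
    St <- Sstar / sw
    qrS <- qr(St)
    res <- qr.resid(qrS, yt)
    rss <- sum(res^2)
    s2 <- rss / (n - p)
    ldet_xvx <- determinant(crossprod(St), logarithm = TRUE)$modulus
    -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + sum(log(w)) +
              ldet_xvx - ldet_sts)
  }
  opt <- optimize(reml_ll, interval = c(-10, 10), maximum = TRUE, tol = 1e-6)
  lambda <- exp(opt$maximum)
  w <- lambda * ee$values + 1
  sw <- sqrt(w)
  yt <- ystar / sw
  St <- Sstar / sw
  qrS <- qr(St)
  beta <- qr.coef(qrS, yt)
  rss <- sum(qr.resid(qrS, yt)^2)
  s2e <- rss / (n - p)
  structure(list(
    lambda = lambda, sigma2_e = s2e, sigma2_g = lambda * s2e,
    loglik = opt$objective, beta = as.numeric(beta),
    eigen = ee, y = y, S = S, reml_ll = reml_ll
  ), class = "mlm_null")
}

#' @export
print.mlm_null <- function(x, ...) {
  cat(sprintf(
    "<mlm_null> lambda = %.4g (sigma2_g = %.4g, sigma2_e = %.4g), REML LL = %.2f\n",
    x$lambda, x$sigma2_g, x$sigma2_e, x$loglik
  ))
  invisible(x)
}

#' Mixed-model association scan
#'
#' Tests every SNP for association with `y` under the mixed model
#' y = g * alpha + S * beta + u + e with cov(u) proportional to K. In
#' `approx` mode (P3D/EMMAX) the variance ratio is fixed at the null-model
#' estimate and each SNP is tested by generalized least squares on the
#' eigen-rotated, rescaled data; `exact` mode re-optimizes the variance
#' ratio per SNP (the per-SNP REML of GEMMA-style scans). Missing dosages
#' are mean-imputed per SNP inside the test only; SNPs monomorphic in the
#' tested accessions are skipped (NA statistics, counted in attribute
#' `"n_skipped"`). The test is a Wald t-test on alpha.
#'
#' @param gm A [genotype_matrix()] whose accessions match `y`.
#' @param y Phenotype vector (one value per accession of `gm`).
#' @param S Covariate matrix with intercept.
#' @param K Kinship matrix.
#' @param mode `"approx"` (default) or `"exact"`.
#' @param null_fit Optional pre-computed [fit_null_mlm()] result.
#' @param trait Trait name stored in the result.
#' @return Tibble of class `assoc_scan` (`snp`, `chrom`, `pos`, `beta`,
#'   `se`, `statistic`, `p`, `neglog10p`, `trait`).
#' @export
association_scan <- function(gm, y, S, K, mode = c("approx", "exact"),
                             null_fit = NULL, trait = "trait") {
  mode <- match.arg(mode)
  n <- length(y)
  stopifnot(nrow(gm$dosages) == n)
  S <- as.matrix(S)
  if (is.null(null_fit)) null_fit <- fit_null_mlm(y, S, K)

  G <- gm$dosages
  cm <- colMeans(G, na.rm = TRUE)
  na_idx <- which(is.na(G))
  if (length(na_idx) > 0) {
    G[na_idx] <- cm[((na_idx - 1) %/% n) + 1]
  }
  mono <- apply(G, 2, function(g) var(g) < 1e-12)

  if (mode == "approx") {
    ee <- null_fit$eigen
    w <- null_fit$lambda * ee$values + 1
    sw <- sqrt(w)
    yt <- as.numeric(crossprod(ee$vectors, y)) / sw
    St <- crossprod(ee$vectors, S) / sw
    Gt <- crossprod(ee$vectors, G) / sw
    qrS <- qr(St)
    yr <- qr.resid(qrS, yt)
    Gr <- qr.resid(qrS, Gt)
    gg <- unname(colSums(Gr^2))
    gy <- unname(colSums(Gr * yr))
    beta <- gy / gg
    df <- n - ncol(S) - 1
    rss <- pmax(sum(yr^2) - beta * gy, 0)
    se <- sqrt(rss / df / gg)
    stat <- beta / se
    p <- 2 * pt(-abs(stat), df)
  } else {
    m <- ncol(G)
    beta <- se <- stat <- p <- rep(NA_real_, m)
    for (j in seq_len(m)) {
      if (mono[j]) next
      fit <- fit_null_mlm(y, cbind(S, snp = G[, j]), K)
      ee <- fit$eigen
      w <- fit$lambda * ee$values + 1
      sw <- sqrt(w)
      yt <- as.numeric(crossprod(ee$vectors, y)) / sw
      Xt <- crossprod(ee$vectors, cbind(S, G[, j])) / sw
      XtX_inv <- solve(crossprod(Xt))
      b <- XtX_inv %*% crossprod(Xt, yt)
      k <- ncol(Xt)
      res <- yt - Xt %*% b
      s2 <- sum(res^2) / (n - k)
      beta[j] <- b[k]
      se[j] <- sqrt(s2 * XtX_inv[k, k])
      stat[j] <- beta[j] / se[j]
      p[j] <- 2 * pt(-abs(stat[j]), n - k)
    }
  }
  beta[mono] <- se[mono] <- stat[mono] <- p[mono] <- NA_real_
  if (any(mono)) {
    inform(sprintf("skipped %d monomorphic SNP(s)", sum(mono)))
  }
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  out <- tibble(
    snp = gm$variants$id, chrom = gm$variants$chrom, pos = gm$variants$pos,
    beta = beta, se = se, statistic = stat, p = p,
    neglog10p = -log10(p), trait = trait
  )
  attr(out, "n_skipped") <- sum(mono)
  attr(out, "lambda") <- null_fit$lambda
  class(out) <- c("assoc_scan", class(out))
  out
}
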