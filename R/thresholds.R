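#' Bonferroni genome-wide threshold
#'
#' `p = alpha / n_independent`, where `n_independent` is the LD-pruned
#' marker count (see [ld_prune()]). Also returns the -log10 threshold and
#' both rounded for display (3 significant digits / 2 decimals).
#'
#' @param n_independent Number of independent markers (>= 1).
#' @param alpha Family-wise error rate, default 0.05.
#' @return List with `p`, `neglog10p`, `p_display`, `neglog10p_display`,
#'   `n_independent`, `alpha`.
#' @export
bonferroni_threshold <- function(n_independent, alpha = 0.05) {
  stopifnot(n_independent >= 1, alpha > 0, alpha < 1)
  p <- alpha / n_independent
  list(
    p = p, neglog10p = -log10(p),
    p_display = signif(p, 3), neglog10p_display = round(-log10(p), 2),
    n_independent = n_independent, alpha = alpha
  )
}

#' Permutation-based genome-wide threshold
#'
#' Shuffles the phenotype across accessions (keeping S and K fixed so the
#' structure correction behaves as in the real scan), reruns the approx
#' mixed-model scan per permutation, records each genome-wide minimum
#' p-value, and returns the requested empirical quantile of those minima
#' (type-1 empirical quantile).
#'
#' @param gm A [genotype_matrix()].
#' @param y Phenotype vector.
#' @param S Covariate matrix with intercept.
#' @param K Kinship matrix.
#' @param n_perm Number of permutations (>= 20).
#' @param prob Quantile of the minimum-p distribution, default 0.05.
#' @param seed Optional integer seed for the shuffles.
#' @return List with `p_threshold`, `neglog10p`, `min_p` (all recorded
#'   minima), `n_perm`.
#' @export
permutation_threshold <- function(gm, y, S, K, n_perm = 100, prob = 0.05,
                                  seed = NULL) {
  if (n_perm < 20) abort("n_perm must be >= 20 for a stable quantile")
  n <- length(y)
  S <- as.matrix(S)
  null_fit <- fit_null_mlm(y, S, K)
  ee <- null_fit$eigen
  w <- null_fit$lambda * ee$values + 1
  sw <- sqrt(w)
  G <- gm$dosages
  cm <- colMeans(G, na.rm = TRUE)
  na_idx <- which(is.na(G))
  if (length(na_idx) > 0) G[na_idx] <- cm[((na_idx - 1) %/% n) + 1]
  mono <- apply(G, 2, function(g) var(g) < 1e-12)
  G <- G[, !mono, drop = FALSE]
  St <- crossprod(ee$vectors, S) / sw
  Gt <- crossprod(ee$vectors, G) / sw
  qrS <- qr(St)
  Gr <- qr.resid(qrS, Gt)
  gg <- colSums(Gr^2)
  df <- n - ncol(S) - 1
  Ut <- t(ee$vectors)

  run_perm <- function() {
    yp <- y[sample.int(n)]
    yt <- as.numeric(Ut %*% yp) / sw
    yr <- qr.resid(qrS, yt)
    gy <- colSums(Gr * yr)
    beta <- gy / gg
    rss <- pmax(sum(yr^2) - beta * gy, 0)
    stat <- beta / sqrt(rss / df / gg)
    min(2 * pt(-abs(stat), df))
  }
  min_p <- if (is.null(seed)) {
    replicate(n_perm, run_perm())
  } else {
    withr::with_seed(as.integer(seed), replicate(n_perm, run_perm()))
  }
  thr <- as.numeric(quantile(min_p, prob, type = 1))
  list(p_threshold = thr, neglog10p = -log10(thr), min_p = min_p,
       n_perm = n_perm)
}

#' Bundle the thresholds a scan is judged against
#'
#' @param n_independent LD-pruned marker count for Bonferroni.
#' @param perm Optional [permutation_threshold()] result.
#' @param working_neglog10p Working threshold for peak calling, default 5.
#' @param alpha Family-wise error rate.
#' @return List of class `threshold_set` with `bonferroni`, `permutation`,
#'   `working_neglog10p`.
#' @export
threshold_set <- function(n_independent, perm = NULL,
                          working_neglog10p = 5, alpha = 0.05) {
  structure(list(
    bonferroni = bonferroni_threshold(n_independent, alpha),
    permutation = perm,
    working_neglog10p = working_neglog10p
  ), class = "threshold_set")
}
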