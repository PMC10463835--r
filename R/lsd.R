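#' LSD multiple comparisons with compact letter display
#'
#' One-way ANOVA followed by Fisher's least-significant-difference test:
#' two groups differ when `|mean_i - mean_j|` exceeds
#' `t(1 - alpha/2, df_error) * sqrt(MSE * (1/n_i + 1/n_j))`. Groups sharing
#' a letter are not significantly different (insert-and-absorb letter
#' assignment). Groups with fewer than 2 observations are excluded with a
#' warning.
#'
#' @param values Numeric observations.
#' @param group Group labels, same length as `values`.
#' @param alpha Significance level, default 0.05.
#' @return Tibble (`group`, `n`, `mean`, `letters`), sorted by descending
#'   mean, with attributes `"mse"`, `"df_error"`, `"lsd"` (the equal-n LSD
#'   value when group sizes are equal).
#' @export
lsd_groups <- function(values, group, alpha = 0.05) {
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]
  group <- as.character(group)[ok]
  sizes <- table(group)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warn(paste0("excluding group(s) with < 2 observations: ",
                paste(small, collapse = ", ")))
    keep <- !(group %in% small)
    values <- values[keep]
    group <- group[keep]
  }
  groups <- sort(unique(group))
  if (length(groups) < 2) abort("need >= 2 groups with >= 2 observations")

  fit <- aov(values ~ factor(group))
  s <- summary(fit)[[1]]
  mse <- s$`Mean Sq`[2]
  dfe <- s$Df[2]
  tcrit <- qt(1 - alpha / 2, dfe)

  means <- tapply(values, group, mean)
  ns <- tapply(values, group, length)
  ord <- order(-means)
  groups <- names(means)[ord]
  means <- means[ord]
  ns <- ns[ord]
  k <- length(groups)
  sig <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      lsd_ij <- tcrit * sqrt(mse * (1 / ns[i] + 1 / ns[j]))
      sig[i, j] <- sig[j, i] <- abs(means[i] - means[j]) > lsd_ij
    }
  }
  letters_vec <- cld_insert_absorb(sig)
  out <- tibble(group = groups, n = as.integer(ns),
                mean = as.numeric(means), letters = letters_vec)
  attr(out, "mse") <- mse
  attr(out, "df_error") <- dfe
  if (length(unique(ns)) == 1) {
    attr(out, "lsd") <- tcrit * sqrt(2 * mse / ns[1])
  }
  out
}

# Compact letter display by insert-and-absorb: start from one column holding
# every group; for each significantly different pair split any column that
# contains both; drop columns that are subsets of others; letter columns in
# order of their highest-mean member.
cld_insert_absorb <- function(sig) {
  k <- nrow(sig)
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!sig[i, j]) next
      new_cols <- list()
      for (col in cols) {
        if (col[i] && col[j]) {
          c1 <- col; c1[i] <- FALSE
          c2 <- col; c2[j] <- FALSE
          new_cols <- c(new_cols, list(c1, c2))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb subsets
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a != b && keep[b] &&
              all(new_cols[[a]] <= new_cols[[b]]) &&
              !identical(new_cols[[a]], new_cols[[b]])) {
            keep[a] <- FALSE
            break
          }
        }
      }
      cols <- unique(new_cols[keep])
    }
  }
  first <- vapply(cols, function(col) which(col)[1], numeric(1))
  cols <- cols[order(first)]
  vapply(seq_len(k), function(g) {
    paste0(letters[which(vapply(cols, `[`, logical(1), g))], collapse = "")
  }, character(1))
}
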