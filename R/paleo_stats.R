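#' Linearly interpolate a proxy series onto sample ages
#'
#' Piecewise-linear interpolation, exact at knots; target ages outside
#' the series support return NA (no extrapolation — samples outside a
#' proxy's record are dropped from analyses involving it).
#'
#' @param series data.frame with columns `age_calBP` and `value` (any
#'   order; sorted internally; duplicate ages are an error).
#' @param target_ages ages (cal yr BP) at which to evaluate.
#' @return numeric vector of interpolated values (NA outside support).
#' @export
interpolate_proxy <- function(series, target_ages) {
  stopifnot(all(c("age_calBP", "value") %in% names(series)))
  s <- series[order(series$age_calBP), ]
  if (anyDuplicated(s$age_calBP)) stop("proxy series has duplicate ages")
  if (nrow(s) < 2L) stop("proxy series needs at least two points")
  stats::approx(s$age_calBP, s$value, xout = target_ages, rule = 1)$y
}

#' Z-standardize a vector
#'
#' Centers to mean 0 and scales to sample standard deviation 1 (n - 1
#' denominator) over non-missing entries.
#'
#' @param x numeric vector (>= 2 non-missing values).
#' @param name label used in the zero-variance error message.
#' @return z-scores (NAs preserved).
#' @export
standardize <- function(x, name = deparse(substitute(x))) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("standardize needs >= 2 non-missing values: ", name)
  s <- stats::sd(x[ok])
  if (s == 0) stop("zero variance, cannot standardize: ", name)
  (x - mean(x[ok])) / s
}

#' Join detections with interpolated, standardized proxies
#'
#' Builds the integrated sample-by-variable table: taxon abundance columns
#' from a detection matrix plus one standardized column per proxy series
#' interpolated to each sample's median age.
#'
#' @param detections samples-by-taxa matrix (see [detection_matrix()]).
#' @param sample_ages data.frame `sample_id`, `age_median`.
#' @param proxies named list of proxy series data.frames (`age_calBP`,
#'   `value`).
#' @return data.frame with `sample_id`, `age_median`, the taxon columns
#'   and one standardized column per proxy (NA where a sample's age falls
#'   outside the proxy's support).
#' @export
integrate_table <- function(detections, sample_ages, proxies) {
  stopifnot(all(c("sample_id", "age_median") %in% names(sample_ages)))
  idx <- match(sample_ages$sample_id, rownames(detections))
  taxa <- detections[idx, , drop = FALSE]
  taxa[is.na(idx), ] <- 0
  out <- data.frame(sample_id = sample_ages$sample_id,
                    age_median = sample_ages$age_median,
                    taxa, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (p in names(proxies)) {
    v <- interpolate_proxy(proxies[[p]], sample_ages$age_median)
    out[[p]] <- standardize(v, name = p)
  }
  rownames(out) <- NULL
  out
}

# Spearman p-value from the t-approximation with n - 2 df (two-sided)
spearman_p <- function(rs, n) {
  if (is.na(rs) || n < 3) return(NA_real_)
  if (abs(rs) >= 1) return(0)
  t <- rs * sqrt((n - 2) / (1 - rs^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Pairwise Spearman correlation matrix with significance filter
#'
#' Spearman's rank correlation with average ranks for ties, computed on
#' pairwise-complete observations; two-sided p-values from the
#' t-approximation with n - 2 degrees of freedom. Pairs with fewer than
#' `min_n` complete observations are flagged and their p set missing.
#'
#' @param table numeric data.frame or matrix (columns = variables; a
#'   `sample_id` column, if present, is dropped).
#' @param alpha significance level for the `kept` flag (default 0.05).
#' @param min_n minimum pairwise-complete n for a p-value (default 5).
#' @return class `correlation_result`: list with matrices `rs`, `p`, `n`
#'   and a long data.frame `table` (`var_a`, `var_b`, `rs`, `p`, `n`,
#'   `kept`) over unordered pairs.
#' @export
spearman_matrix <- function(table, alpha = 0.05, min_n = 5) {
  x <- as.data.frame(table)
  x <- x[vapply(x, is.numeric, logical(1))]
  m <- ncol(x)
  if (m < 2L) stop("need at least two numeric columns")
  vars <- names(x)
  rs <- p <- nmat <- matrix(NA_real_, m, m, dimnames = list(vars, vars))
  diag(rs) <- 1; diag(p) <- 0
  diag(nmat) <- colSums(!is.na(x))
  rows <- list()
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      ok <- !is.na(x[[i]]) & !is.na(x[[j]])
      n <- sum(ok)
      r <- if (n >= 3) stats::cor(x[[i]][ok], x[[j]][ok],
                                  method = "spearman") else NA_real_
      pv <- if (n >= min_n) spearman_p(r, n) else NA_real_
      rs[i, j] <- rs[j, i] <- r
      p[i, j] <- p[j, i] <- pv
      nmat[i, j] <- nmat[j, i] <- n
      rows[[length(rows) + 1L]] <- data.frame(
        var_a = vars[i], var_b = vars[j], rs = r, p = pv, n = n,
        kept = !is.na(pv) && pv < alpha, stringsAsFactors = FALSE)
    }
  }
  structure(list(rs = rs, p = p, n = nmat,
                 table = do.call(rbind, rows), alpha = alpha),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("correlation_result:", ncol(x$rs), "variables;",
      sum(x$table$kept), "of", nrow(x$table),
      sprintf("pairs significant at p < %.2g\n", x$alpha))
  invisible(x)
}

#' Redundancy analysis with an ANOVA-like permutation test
#'
#' RDA: multivariate least squares of the (column-centered) response
#' matrix on the (standardized) explanatory matrix; the constrained
#' variance is the total variance of the fitted values, and its
#' eigenstructure gives the constrained ordination axes. Each explanatory
#' term is tested marginally (given all other terms) with a
#' pseudo-F = (marginal SS / df_term) / (residual SS / df_resid), and its
#' significance assessed by Freedman-Lane permutation: rows of the
#' reduced-model residuals are permuted, added back to the reduced-model
#' fit, and the statistic recomputed; `p = (1 + #{F* >= F_obs}) /
#' (n_perm + 1)`.
#'
#' @param Y response matrix (samples x taxa), columns centered
#'   internally.
#' @param X explanatory matrix/data.frame (samples x terms), columns
#'   standardized internally.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return class `rda_result`: list with `total_variance`,
#'   `constrained_fraction`, `residual_fraction`, `eigenvalues`
#'   (constrained axes), `terms` (data.frame `term`, `fraction` — marginal
#'   SS over total SS —, `F`, `p`), `n_perm`, `seed`, `df_resid`.
#' @export
rda <- function(Y, X, n_perm = 999, seed = NULL) {
  Y <- as.matrix(Y)
  X <- as.matrix(as.data.frame(X))
  storage.mode(Y) <- "double"; storage.mode(X) <- "double"
  n <- nrow(Y); p <- ncol(X)
  stopifnot(nrow(X) == n)
  if (n <= p + 1) stop("need more samples than explanatory terms + 1")
  if (anyNA(Y) || anyNA(X)) stop("RDA inputs must be complete (no NA)")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xz <- scale(X)
  qrx <- qr(Xz)
  if (qrx$rank < p) {
    dropped <- colnames(X)[-qrx$pivot[seq_len(qrx$rank)]]
    stop("explanatory matrix is rank-deficient; collinear terms: ",
         paste(dropped, collapse = ", "))
  }
  hat <- function(M) M %*% solve(crossprod(M), t(M))
  H_full <- hat(Xz)
  fitted <- H_full %*% Yc
  ss_tot <- sum(Yc^2)
  ss_fit <- sum(fitted^2)
  ss_res <- sum((Yc - fitted)^2)
  df_resid <- n - p - 1L
  ev <- eigen(crossprod(fitted) / (n - 1), symmetric = TRUE,
              only.values = TRUE)$values
  ev <- ev[seq_len(min(p, ncol(Y)))]

  terms <- colnames(X)
  if (is.null(terms)) terms <- paste0("X", seq_len(p))
  set_seed_if(seed)
  res <- lapply(seq_len(p), function(j) {
    H_red <- if (p == 1L) matrix(0, n, n) else hat(Xz[, -j, drop = FALSE])
    fit_red <- H_red %*% Yc
    resid_red <- Yc - fit_red
    ss_j <- ss_fit - sum(fit_red^2)
    F_obs <- (ss_j / 1) / (ss_res / df_resid)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      Ystar <- fit_red + resid_red[sample.int(n), , drop = FALSE]
      fit_star <- H_full %*% Ystar
      ss_fit_star <- sum(fit_star^2)
      ss_j_star <- ss_fit_star - sum((H_red %*% Ystar)^2)
      ss_res_star <- sum((Ystar - fit_star)^2)
      F_star <- ss_j_star / (ss_res_star / df_resid)
      if (F_star >= F_obs) exceed <- exceed + 1L
    }
    data.frame(term = terms[j], fraction = ss_j / ss_tot, F = F_obs,
               p = (1 + exceed) / (n_perm + 1), stringsAsFactors = FALSE)
  })
  structure(list(
    total_variance = ss_tot / (n - 1),
    constrained_fraction = ss_fit / ss_tot,
    residual_fraction = ss_res / ss_tot,
    eigenvalues = ev,
    terms = do.call(rbind, res),
    n_perm = as.integer(n_perm), seed = seed,
    df_resid = df_resid), class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("rda_result: constrained %.1f%% of variance (%d permutations)\n",
              100 * x$constrained_fraction, x$n_perm))
  for (i in seq_len(nrow(x$terms))) {
    cat(sprintf("  %s: F = %.2f; Pr(>F) = %.3g; %.1f%% of variance\n",
                x$terms$term[i], x$terms$F[i], x$terms$p[i],
                100 * x$terms$fraction[i]))
  }
  invisible(x)
}
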