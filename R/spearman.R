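# caches: permutation matrices (n <= 7) and exact null S distributions
.st_cache <- new.env(parent = emptyenv())

all_perms <- function(n) {
  key <- paste0("perm", n)
  if (!is.null(.st_cache[[key]])) return(.st_cache[[key]])
  p <- if (n == 1) matrix(1L) else {
    q <- all_perms(n - 1)
    do.call(rbind, lapply(1:n, function(k) {
      cbind(k, q + (q >= k))
    }))
  }
  storage.mode(p) <- "integer"
  .st_cache[[key]] <- p
  p
}

# Exact null distribution of Spearman's S = sum (i - p(i))^2 over all n!
# permutations of untied ranks, by dynamic programming over subsets:
# counts[s + 1] = number of permutations with S = s. Equivalent to full
# enumeration (n! grows, the DP is 2^n * n * maxS) and verified against it.
spearman_null_counts <- function(n) {
  key <- paste0("null", n)
  if (!is.null(.st_cache[[key]])) return(.st_cache[[key]])
  max_s <- sum((1:n - n:1)^2)
  f <- vector("list", 2^n)
  f[[1]] <- c(1, numeric(max_s))
  bits <- 2^(0:(n - 1))
  for (mask in 1:(2^n - 1)) {
    i <- sum(bitwAnd(mask, bits) > 0)  # rank position being assigned
    acc <- numeric(max_s + 1)
    for (j in 1:n) {
      if (bitwAnd(mask, bits[j])) {
        prev <- f[[bitwXor(mask, bits[j]) + 1]]
        d2 <- (i - j)^2
        if (d2 == 0) acc <- acc + prev
        else acc[(d2 + 1):(max_s + 1)] <-
            acc[(d2 + 1):(max_s + 1)] + prev[1:(max_s + 1 - d2)]
      }
    }
    f[[mask + 1]] <- acc
  }
  .st_cache[[key]] <- f[[2^n]]
  f[[2^n]]
}

rho_from_ranks <- function(rx, ry) {
  n <- length(rx)
  sx <- stats::sd(rx); sy <- stats::sd(ry)
  if (sx == 0 || sy == 0)
    st_stop("st_undefined_correlation",
            "correlation undefined for a constant vector")
  sum((rx - mean(rx)) * (ry - mean(ry))) / ((n - 1) * sx * sy)
}

#' Spearman rank correlation with exact small-sample p-values
#'
#' The correlation coefficient is the Pearson correlation of mid-ranks,
#' which is the ties-adjusted Spearman rho. The two-sided p-value is the
#' permutation probability `P(|rho*| >= |rho|)` under random pairing,
#' computed by:
#' \itemize{
#'   \item full enumeration of all `n!` pairings for `n <= 7` (ties or not);
#'   \item an exact dynamic program over the permutation distribution of
#'     `S = sum d^2` for untied data with `7 < n <= exact_n_max`
#'     (equivalent to full enumeration; at the default `exact_n_max = 10`
#'     this is the exact probability over all 3,628,800 pairings);
#'   \item seeded Monte-Carlo permutation (`n_perm` draws) for tied data
#'     with `7 < n <= exact_n_max`;
#'   \item the t approximation `t = rho sqrt((n-2)/(1-rho^2))` above
#'     `exact_n_max`.
#' }
#'
#' @param x,y paired numeric vectors, `n >= 3` after removing incomplete
#'   pairs.
#' @param exact_n_max largest n for which exact/permutation p-values are
#'   used (default 10, matching exact probabilities for ten accessions).
#' @param n_perm Monte-Carlo permutation count for tied mid-size samples.
#' @param seed seed for the Monte-Carlo branch (ignored elsewhere).
#' @return A list of class `spearman_cor`: `rho`, `p`, `n`, `method`
#'   (`"exact"`, `"permutation"` or `"t_approx"`).
#' @examples
#' spearman(1:5, c(2, 4, 6, 8, 10))       # rho = 1
#' spearman(1:3, 3:1)$p                   # exact: 2/6
#' @export
spearman <- function(x, y, exact_n_max = 10, n_perm = 99999, seed = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3)
    st_stop("st_insufficient_data", "need >= 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  rho <- rho_from_ranks(rx, ry)
  tied <- anyDuplicated(rx) > 0 || anyDuplicated(ry) > 0
  eps <- 1e-12

  if (n <= 7) {
    P <- all_perms(n)
    # permutation rho via the cross-product term only
    cps <- as.vector(matrix(rx[P], nrow(P), n) %*% ry)
    denom <- (n - 1) * stats::sd(rx) * stats::sd(ry)
    rhos <- (cps - n * mean(rx) * mean(ry)) / denom
    p <- mean(abs(rhos) >= abs(rho) - eps)
    method <- "exact"
  } else if (n <= exact_n_max && !tied) {
    cnt <- spearman_null_counts(n)
    m <- n * (n^2 - 1)
    rhos <- 1 - 6 * (seq_along(cnt) - 1) / m
    p <- sum(cnt[abs(rhos) >= abs(rho) - eps]) / sum(cnt)
    method <- "exact"
  } else if (n <= exact_n_max) {
    p <- with_seed(seed %||% 1L, {
      cnt <- 0L
      for (b in seq_len(n_perm))
        if (abs(rho_from_ranks(rx, sample(ry))) >= abs(rho) - eps)
          cnt <- cnt + 1L
      (cnt + 1) / (n_perm + 1)
    })
    method <- "permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), n - 2)
    method <- "t_approx"
  }
  structure(list(rho = rho, p = min(p, 1), n = n, method = method),
            class = "spearman_cor")
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf("<spearman_cor> rho = %.4f, p = %.4g (n = %d, %s)\n",
              x$rho, x$p, x$n, x$method))
  invisible(x)
}
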