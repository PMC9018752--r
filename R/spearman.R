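#' Spearman rank correlation with reproducible p-values
#'
#' Spearman's rho computed as the Pearson correlation of average ranks
#' (ties receive the mean of the ranks they span). The two-sided p-value
#' uses the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2`
#' degrees of freedom for `n >= 10`, and the exact permutation distribution
#' of rho for `n < 10` (all `n!` permutations enumerated), so small-sample
#' p-values are exact and platform-independent.
#'
#' @param x,y Numeric vectors of equal length, `n >= 4`.
#' @return An object of class `cox2_cor`: list with `rho`, `p_value`, `n`,
#'   `method`. Has [tidy()] and [glance()] methods.
#' @export
#' @examples
#' spearman_cor(1:4, c(10, 20, 30, 40))$rho   # 1
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort("spearman_cor: x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) abort("spearman_cor: need n >= 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("spearman_cor: rho undefined for a constant vector")
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- cor(rx, ry)

  if (n >= 10) {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tval), df = n - 2)
    }
    method <- "t_approximation"
  } else {
    # exact permutation null: rho for every reordering of y, vectorized as
    # cov(perm(ry), rx) / (sd(rx) sd(ry)); permuting preserves sd and mean
    perms <- .permutations(n)
    rx0 <- rx - mean(rx)
    ymat <- matrix(ry[perms], nrow(perms), n)
    rhos <- as.vector(ymat %*% rx0) / ((n - 1) * sd(rx) * sd(ry))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  }
  structure(list(rho = rho, p_value = p, n = n, method = method),
            class = "cox2_cor")
}

# all permutations of 1..n (n <= 9): element i first, then permutations of rest
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

#' @export
print.cox2_cor <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f, p = %.3g, n = %d (%s)\n",
              x$rho, x$p_value, x$n, x$method))
  invisible(x)
}

#' @rdname spearman_cor
#' @param x A `cox2_cor` object.
#' @param ... Unused.
#' @export
tidy.cox2_cor <- function(x, ...) {
  tibble(estimate = x$rho, p.value = x$p_value,
         method = paste0("spearman_", x$method))
}

#' @rdname spearman_cor
#' @export
glance.cox2_cor <- function(x, ...) {
  tibble(rho = x$rho, p.value = x$p_value, n = x$n, method = x$method)
}
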