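#' Kernel specification
#'
#' @param name `"rbf"` or `"linear"`.
#' @param sigma bandwidth of the Gaussian kernel
#'   \eqn{k(x,z) = \exp(-\|x-z\|^2 / (2\sigma^2))}; ignored for the linear
#'   kernel. Note that conventions differ across software: here `sigma` is
#'   the bandwidth in the denominator `2*sigma^2`, so `sigma = 1` equals
#'   `gamma = 1/2` in the `exp(-gamma*||x-z||^2)` parameterization.
#' @return an object of class `kernel_spec`.
#' @export
kernel_spec <- function(name = c("rbf", "linear"), sigma = 1) {
  name <- match.arg(name)
  if (name == "rbf") {
    if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) ||
        sigma <= 0) {
      stop("rbf kernel requires a single positive 'sigma'")
    }
  }
  structure(list(name = name, sigma = as.numeric(sigma)),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  if (x$name == "rbf") cat("rbf kernel, sigma =", x$sigma, "\n")
  else cat("linear kernel\n")
  invisible(x)
}

#' Gram matrix between two sets of points
#'
#' Entry (i, j) is `<x_i, z_j>` for the linear kernel and
#' `exp(-||x_i - z_j||^2 / (2*sigma^2))` for the Gaussian kernel. With
#' `Z = X` the result is symmetric positive semidefinite.
#'
#' @param X,Z numeric matrices with the same number of columns.
#' @param kernel a [kernel_spec()].
#' @return `nrow(X)` x `nrow(Z)` numeric matrix.
#' @export
gram_matrix <- function(X, Z, kernel = kernel_spec()) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  if (ncol(X) != ncol(Z)) {
    stop("feature dimension mismatch: ncol(X) = ", ncol(X),
         ", ncol(Z) = ", ncol(Z))
  }
  if (kernel$name == "linear") return(X %*% t(Z))
  d2 <- outer(rowSums(X^2), rep(1, nrow(Z))) +
    outer(rep(1, nrow(X)), rowSums(Z^2)) - 2 * X %*% t(Z)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * kernel$sigma^2))
}
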