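#' Exact small-scale mixed model
#'
#' Container for the exact model `y = Xb + Za + e` with
#' `var(a) = sigma_a2 * A`, `var(e) = sigma_e2 * I`, so
#' `var(y) = V = sigma_a2 Z A Z' + sigma_e2 I`.  Dense algebra limits it
#' to small n; it is a test instrument certifying the AGLS approximation,
#' not a production path.
#'
#' @param y response vector.
#' @param X fixed-effect design matrix (e.g. genotype-class indicators).
#' @param Z random-effect incidence matrix (default identity: one record
#'   per individual).
#' @param A relationship matrix (invertible).
#' @param sigma_a2,sigma_e2 variance components.
#' @param n_cap guard on problem size (dense algebra).
#' @return Object of class `exact_model`.
#' @export
exact_model <- function(y, X, Z = NULL, A = NULL, sigma_a2, sigma_e2,
                        n_cap = 2000L) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (n > n_cap) stop("oracle model capped at n = ", n_cap)
  if (is.null(Z)) Z <- diag(n)
  if (is.null(A)) A <- diag(ncol(Z))
  stopifnot(nrow(X) == n, nrow(Z) == n, nrow(A) == ncol(Z),
            sigma_a2 >= 0, sigma_e2 > 0)
  structure(list(y = y, X = X, Z = as.matrix(Z), A = as.matrix(A),
                 sigma_a2 = sigma_a2, sigma_e2 = sigma_e2),
            class = "exact_model")
}

#' Genotype-class indicator design
#'
#' Cell-means design matrix: one indicator column per genotype class
#' present in `codes` (columns named g11/g12/g22).
#'
#' @param codes genotype codes 0/1/2 (no NAs).
#' @return n x k indicator matrix.
#' @export
design_cell_means <- function(codes) {
  classes <- sort(unique(codes))
  X <- sapply(classes, function(cl) as.numeric(codes == cl))
  colnames(X) <- c("g11", "g12", "g22")[classes + 1L]
  X
}

.V_matrix <- function(model) {
  model$sigma_a2 * model$Z %*% model$A %*% t(model$Z) +
    model$sigma_e2 * diag(length(model$y))
}

#' Exact GLS fixed-effect estimate (BLUE)
#'
#' `b = (X' V^-1 X)^- X' V^-1 y` with the explicit V inverse and a
#' generalized inverse for the crossproduct.
#'
#' @param model an [exact_model].
#' @return Named vector `b_hat`.
#' @export
gls_blue <- function(model) {
  V <- .V_matrix(model)
  Vi <- tryCatch(solve(V), error = function(e) stop("singular V"))
  XtVi <- crossprod(model$X, Vi)
  b <- MASS::ginv(XtVi %*% model$X) %*% (XtVi %*% model$y)
  stats::setNames(as.numeric(b), colnames(model$X))
}

#' Mixed-model-equation solve: BLUE and BLUP
#'
#' Henderson's equations
#' `[X'X, X'Z; Z'X, Z'Z + lambda A^-1] [b; a] = [X'y; Z'y]`,
#' `lambda = sigma_e2/sigma_a2`, giving the fixed-effect BLUE `b_hat` and
#' the polygenic BLUP `a_hat`; `b_hat` is also reconstructed as
#' `(X'X)^- X'(y - Z a_hat)` (the least-squares-on-adjusted-phenotypes
#' identity AGLS approximates).  At `sigma_a2 = 0` the BLUP vanishes and
#' the BLUE reduces to ordinary least squares.
#'
#' @param model an [exact_model].
#' @return List: `b_hat`, `a_hat`, `b_hat_adjusted` (the reconstruction).
#' @export
mme_blue <- function(model) {
  X <- model$X; Z <- model$Z; y <- model$y
  XtX <- crossprod(X)
  if (model$sigma_a2 <= 0) {
    b <- MASS::ginv(XtX) %*% crossprod(X, y)
    b <- stats::setNames(as.numeric(b), colnames(X))
    return(list(b_hat = b, a_hat = rep(0, ncol(Z)), b_hat_adjusted = b))
  }
  lambda <- model$sigma_e2 / model$sigma_a2
  Ai <- tryCatch(solve(model$A),
                 error = function(e) stop("singular A"))
  C <- rbind(cbind(XtX, crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lambda * Ai))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- tryCatch(as.numeric(MASS::ginv(C) %*% rhs),
                  error = function(e) stop("singular coefficient matrix"))
  p <- ncol(X)
  b <- stats::setNames(sol[seq_len(p)], colnames(X))
  a_hat <- sol[-seq_len(p)]
  b_adj <- stats::setNames(
    as.numeric(MASS::ginv(XtX) %*% crossprod(X, y - Z %*% a_hat)),
    colnames(X))
  list(b_hat = b, a_hat = a_hat, b_hat_adjusted = b_adj)
}

#' Exact GLS contrast t-statistic
#'
#' `t = |c'b| / sqrt(c' (X' V^-1 X)^- c)` for an estimable contrast `c`;
#' the reference statistic against which the AGLS least-squares t is
#' calibrated.
#'
#' @param model an [exact_model].
#' @param contrast coefficient vector over the columns of `X`.
#' @return Non-negative t value.
#' @export
exact_contrast_t <- function(model, contrast) {
  contrast <- as.numeric(contrast)
  XtX <- crossprod(model$X)
  proj <- XtX %*% MASS::ginv(XtX) %*% contrast
  if (max(abs(proj - contrast)) > 1e-8 * max(1, max(abs(contrast))))
    stop("contrast not estimable")
  V <- .V_matrix(model)
  Vi <- solve(V)
  M <- MASS::ginv(crossprod(model$X, Vi) %*% model$X)
  b <- gls_blue(model)
  se <- sqrt(as.numeric(t(contrast) %*% M %*% contrast))
  abs(sum(contrast * b)) / se
}
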