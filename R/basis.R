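#' Declare a penalized smooth term
#'
#' Smooths are cubic B-spline bases with a squared-second-difference
#' penalty on the coefficients (penalty order 2). The `"cyclic"` basis
#' wraps the B-splines and the difference penalty around the declared
#' period, so the fitted smooth and its first and second derivatives match
#' at the period endpoints — appropriate for hour of day (period 24) and
#' month (period 12). The `"cubic"` basis is the open-interval analogue;
#' its penalty null space contains constant and linear functions, so a
#' fully penalized smooth shrinks to a straight line rather than to zero.
#'
#' @param var Covariate name.
#' @param bs Basis type, `"cubic"` (default) or `"cyclic"`.
#' @param k Number of basis functions (>= 4, default 10).
#' @param period Required for the cyclic basis (e.g. 24 for hours,
#'   12 for months).
#' @return An object of class `sm_spec`.
#' @export
sm <- function(var, bs = c("cubic", "cyclic"), k = 10, period = NULL) {
  bs <- match.arg(bs)
  k <- as.integer(k)
  if (k < 4L) stop("smooth basis needs k >= 4", call. = FALSE)
  if (bs == "cyclic" && is.null(period)) {
    stop("cyclic basis requires a declared period", call. = FALSE)
  }
  structure(list(var = var, bs = bs, k = k, period = period),
            class = "sm_spec")
}

#' Build a smooth basis on data
#'
#' Constructs the (identifiability-constrained) design block and penalty
#' matrix for a smooth term. The coefficient direction confounded with the
#' intercept is removed by reparametrisation, so the block has `k - 1`
#' columns; the penalty is the squared second difference mapped through the
#' same reparametrisation (circular differences for the cyclic basis).
#'
#' @param spec An [sm()] specification.
#' @param x Covariate vector (cyclic values are reduced modulo the period,
#'   so evaluation at 0 and at the period gives identical rows).
#' @return A list of class `sm_basis`: `X` (n x (k-1) design block), `S`
#'   ((k-1) square penalty), and the knot/range information needed to
#'   evaluate the basis on new data via [eval_basis()].
#' @export
build_basis <- function(spec, x) {
  stopifnot(inherits(spec, "sm_spec"))
  if (anyNA(x)) stop("smooth covariate contains NA", call. = FALSE)
  k <- spec$k
  if (k > length(unique(x))) {
    stop("n_basis exceeds the number of distinct covariate values",
         call. = FALSE)
  }
  if (spec$bs == "cyclic") {
    P <- spec$period
    h <- P / k
    knots <- seq(-3 * h, P + 3 * h, by = h)
    D <- matrix(0, k, k)
    for (i in seq_len(k)) {
      D[i, i] <- 1
      D[i, (i %% k) + 1L] <- -2
      D[i, ((i + 1L) %% k) + 1L] <- 1
    }
    xr <- c(0, P)
  } else {
    xr <- range(x)
    if (diff(xr) <= 0) stop("smooth covariate is constant", call. = FALSE)
    h <- diff(xr) / (k - 3)
    knots <- seq(xr[1] - 3 * h, xr[2] + 3 * h, by = h)
    D <- diff(diag(k), differences = 2)
  }
  Z <- qr.Q(qr(matrix(1, k, 1)), complete = TRUE)[, -1, drop = FALSE]
  S_full <- crossprod(D)
  b <- list(spec = spec, knots = knots, xrange = xr, Z = Z,
            S = crossprod(Z, S_full %*% Z))
  class(b) <- "sm_basis"
  b$X <- eval_basis(b, x)
  b
}

#' Evaluate a smooth basis on new covariate values
#'
#' @param basis An `sm_basis` from [build_basis()].
#' @param x New covariate values; cyclic values are wrapped, open-interval
#'   values clamped to the training range.
#' @return An n x (k-1) design block.
#' @export
eval_basis <- function(basis, x) {
  spec <- basis$spec
  k <- spec$k
  if (spec$bs == "cyclic") {
    x <- x %% spec$period
    B <- splines::splineDesign(basis$knots, x, ord = 4, outer.ok = TRUE)
    # fold the 3 trailing wrapped copies back onto the leading functions
    Bp <- B[, seq_len(k), drop = FALSE]
    Bp[, 1:3] <- Bp[, 1:3] + B[, k + 1:3, drop = FALSE]
    B <- Bp
  } else {
    x <- pmin(pmax(x, basis$xrange[1]), basis$xrange[2])
    B <- splines::splineDesign(basis$knots, x, ord = 4, outer.ok = TRUE)
  }
  B %*% basis$Z
}
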