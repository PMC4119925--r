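#' B-spline basis with equidistant knots
#'
#' Builds the evaluation matrix of a B-spline basis on the range of `x`,
#' using `num_basis - degree` equal-width segments with `degree` padding
#' knots beyond each boundary (the standard P-spline knot rule). Rows sum to
#' one on `[min(x), max(x)]` (partition of unity). If `x` has fewer distinct
#' values than `num_basis`, the basis dimension is reduced to the number of
#' distinct values (never below `degree + 1`) with a warning.
#'
#' @param x Numeric vector of evaluation points; must contain at least two
#'   distinct finite values unless `num_basis == 1`.
#' @param num_basis Number of basis functions (default 8).
#' @param degree Spline degree (default 3, cubic).
#' @return An object of class `"bspline_basis"`: a list with the evaluation
#'   matrix `B` (length(x) x num_basis), the full `knots` vector, `degree`,
#'   `num_basis` and the data range `xmin`, `xmax`.
#' @seealso [eval_basis()], [difference_penalty()]
#' @export
bspline_basis <- function(x, num_basis = 8, degree = 3) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (num_basis < degree + 1) {
    stop("num_basis must be at least degree + 1", call. = FALSE)
  }
  n_distinct <- length(unique(x))
  xmin <- min(x)
  xmax <- max(x)
  if (num_basis > 1 && xmax <= xmin) {
    stop("x must contain at least two distinct values", call. = FALSE)
  }
  if (n_distinct < num_basis) {
    num_basis <- max(degree + 1, n_distinct)
    warning(sprintf("fewer distinct x values than basis functions; num_basis reduced to %d",
                    num_basis), call. = FALSE)
  }
  if (num_basis == 1 && degree == 0) {
    basis <- structure(list(B = matrix(1, length(x), 1),
                            knots = c(xmin, xmax), degree = 0L,
                            num_basis = 1L, xmin = xmin, xmax = xmax),
                       class = "bspline_basis")
    return(basis)
  }
  nseg <- num_basis - degree
  h <- (xmax - xmin) / nseg
  knots <- xmin + h * seq(-degree, nseg + degree)
  basis <- structure(list(B = NULL, knots = knots, degree = as.integer(degree),
                          num_basis = as.integer(num_basis),
                          xmin = xmin, xmax = xmax),
                     class = "bspline_basis")
  basis$B <- eval_basis(basis, x)
  basis
}

#' Evaluate a B-spline basis at new points
#'
#' Points must lie within the (padded) knot span; prediction beyond the data
#' range is handled upstream by linear extension of the linear predictor, not
#' by extrapolating the basis itself.
#'
#' @param basis A `"bspline_basis"` object.
#' @param x Numeric vector of evaluation points.
#' @param deriv Derivative order (0 = function values).
#' @return A `length(x) x num_basis` matrix.
#' @export
eval_basis <- function(basis, x, deriv = 0) {
  if (length(x) == 0) return(matrix(0, 0, basis$num_basis))
  if (basis$num_basis == 1 && basis$degree == 0) {
    if (deriv > 0) return(matrix(0, length(x), 1))
    return(matrix(1, length(x), 1))
  }
  ord <- basis$degree + 1
  # clamp within the numerically safe evaluation span
  eps <- 1e-10 * max(1, abs(basis$xmax))
  xe <- pmin(pmax(x, basis$xmin), basis$xmax - 0 * eps)
  splines::splineDesign(knots = basis$knots, x = xe, ord = ord,
                        derivs = rep(deriv, length(xe)), outer.ok = TRUE)
}

#' Difference penalty matrix for P-splines
#'
#' Returns \eqn{D^\top D} where `D` is the `order`-th difference operator on
#' `num_basis` coefficients. The quadratic form `t(c) %*% P %*% c` equals the
#' sum of squared `order`-th differences of `c`; its null space is spanned by
#' polynomial sequences of degree `< order` in the coefficient index.
#'
#' @param num_basis Number of spline coefficients.
#' @param order Difference order (default 2).
#' @return A `num_basis x num_basis` positive semi-definite matrix.
#' @export
difference_penalty <- function(num_basis, order = 2) {
  if (order >= num_basis) {
    stop("penalty order must be smaller than num_basis", call. = FALSE)
  }
  if (order == 0) return(diag(num_basis))
  D <- diff(diag(num_basis), differences = order)
  crossprod(D)
}

# ---------------------------------------------------------------------------
# Design construction for the per-strain smooth NB model.
#
# Linear predictor: intercept + strain main effect (reference coding)
#   + experiment-within-strain effect (reference coding per strain)
#   + f_s(sqrt(dose)) for the row's strain,
# where each f_s uses a sum-to-zero-constrained B-spline basis on that
# strain's observed sqrt-dose range.  The constraint (colSums of the basis
# over the strain's rows annihilated via a QR null-space reparameterisation)
# makes the smooth orthogonal to the intercept, so strain level differences
# live entirely in the parametric part.

build_design <- function(data, num_basis = 8, degree = 3, penalty_order = 2) {
  strain <- as.character(data$strain)
  experiment <- as.character(data$experiment)
  x <- sqrt(data$dose)
  strains <- sort(unique(strain))
  n <- length(x)

  cols <- list(`(Intercept)` = rep(1, n))
  for (s in strains[-1]) {
    cols[[paste0("strain", s)]] <- as.numeric(strain == s)
  }
  exp_levels <- list()
  for (s in strains) {
    levs <- sort(unique(experiment[strain == s]))
    exp_levels[[s]] <- levs
    for (e in levs[-1]) {
      cols[[paste0("strain", s, ":exp", e)]] <-
        as.numeric(strain == s & experiment == e)
    }
  }
  Xpar <- do.call(cbind, cols)
  colnames(Xpar) <- names(cols)
  n_par <- ncol(Xpar)

  smooths <- list()
  Xs <- list()
  blocks <- matrix(0L, length(strains), 2)
  col_cursor <- n_par
  for (si in seq_along(strains)) {
    s <- strains[si]
    rows <- which(strain == s)
    basis <- bspline_basis(x[rows], num_basis = num_basis, degree = degree)
    K <- basis$num_basis
    ord <- min(penalty_order, K - 1L)
    if (ord < penalty_order) {
      warning(sprintf("penalty order reduced to %d for strain %s (basis dimension %d)",
                      ord, s, K), call. = FALSE)
    }
    B <- basis$B
    # sum-to-zero constraint over the strain's observed rows
    C <- matrix(colSums(B), ncol = 1)
    Z <- qr.Q(qr(C), complete = TRUE)[, -1, drop = FALSE]
    P <- t(Z) %*% difference_penalty(K, ord) %*% Z
    Xblock <- matrix(0, n, K - 1)
    Xblock[rows, ] <- B %*% Z
    colnames(Xblock) <- paste0("s(", s, ").", seq_len(K - 1))
    Xs[[si]] <- Xblock
    blocks[si, ] <- c(col_cursor, col_cursor + K - 2L)  # 0-based inclusive
    col_cursor <- col_cursor + K - 1L
    smooths[[s]] <- list(basis = basis, Z = Z, penalty = P,
                         cols = (blocks[si, 1] + 1L):(blocks[si, 2] + 1L),
                         penalty_order = ord)
  }
  X <- cbind(Xpar, do.call(cbind, Xs))
  p <- ncol(X)
  Slist <- lapply(seq_along(strains), function(si) {
    S <- matrix(0, p, p)
    idx <- smooths[[strains[si]]]$cols
    S[idx, idx] <- smooths[[strains[si]]]$penalty
    S
  })
  list(X = X, Slist = Slist, blocks = blocks, smooths = smooths,
       strains = strains, exp_levels = exp_levels, n_par = n_par,
       col_names = colnames(X))
}

# Linear-form rows for the smooth f_s at sqrt-dose points: returns a
# length(x) x (K-1) matrix M with f_s(x) = M %*% b_s.  Beyond the observed
# range the linear predictor is extended linearly from the boundary (raw
# B-spline extrapolation is numerically unstable), which keeps the map
# linear in the coefficients.
smooth_rows <- function(design, strain, x) {
  sm <- design$smooths[[strain]]
  if (is.null(sm)) stop("unknown strain: ", strain, call. = FALSE)
  basis <- sm$basis
  M <- matrix(0, length(x), ncol(sm$Z))
  inside <- x >= basis$xmin & x <= basis$xmax
  if (any(inside)) M[inside, ] <- eval_basis(basis, x[inside]) %*% sm$Z
  extend <- function(idx, xb) {
    rb <- drop(eval_basis(basis, xb) %*% sm$Z)
    db <- drop(eval_basis(basis, xb, deriv = 1) %*% sm$Z)
    M[idx, ] <<- rep(1, sum(idx)) %o% rb + (x[idx] - xb) %o% db
  }
  if (any(x < basis$xmin)) extend(x < basis$xmin, basis$xmin)
  if (any(x > basis$xmax)) extend(x > basis$xmax, basis$xmax)
  M
}

# Smooth contribution f_s evaluated at sqrt-dose points.
smooth_value <- function(design, beta, strain, x) {
  sm <- design$smooths[[strain]]
  if (is.null(sm)) stop("unknown strain: ", strain, call. = FALSE)
  drop(smooth_rows(design, strain, x) %*% beta[sm$cols])
}

# Parametric part of the linear predictor for a (strain, experiment) pair.
parametric_value <- function(design, beta, strain, experiment) {
  if (!strain %in% design$strains) {
    stop("unknown strain: ", strain, call. = FALSE)
  }
  levs <- design$exp_levels[[strain]]
  if (!experiment %in% levs) {
    stop(sprintf("unknown experiment '%s' for strain '%s'", experiment, strain),
         call. = FALSE)
  }
  nm <- design$col_names
  val <- beta[match("(Intercept)", nm)]
  sc <- match(paste0("strain", strain), nm)
  if (!is.na(sc)) val <- val + beta[sc]
  ec <- match(paste0("strain", strain, ":exp", experiment), nm)
  if (!is.na(ec)) val <- val + beta[ec]
  unname(val)
}
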