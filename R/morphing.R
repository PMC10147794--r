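#' Fit a dual-kriging transform
#'
#' Solves, per output coordinate, the (n + 4) dual-kriging system with a
#' radial kernel and full linear drift:
#' \deqn{f(x) = a_0 + a^T x + \sum_i b_i K(\|x - s_i\|)}
#' subject to the orthogonality side conditions `sum(b) = 0` and
#' `sum(b_i s_i) = 0`. The transform interpolates every control pair
#' exactly and reproduces affine maps exactly (zero dual coefficients).
#'
#' @param src n x 3 matrix of source control points (n >= 4, not
#'   coplanar, pairwise distinct).
#' @param dst n x 3 matrix of target control points.
#' @param kernel radial kernel: `"h"` (default, K(h) = h) or `"h3"`
#'   (K(h) = h^3).
#' @param ridge optional non-negative ridge (nugget) added to the kernel
#'   diagonal for ill-conditioned control sets. Default 0 (exact
#'   interpolation).
#' @return Object of class `kriging_transform`.
#' @export
fit_kriging <- function(src, dst, kernel = c("h", "h3"), ridge = 0) {
  kernel <- match.arg(kernel)
  src <- as.matrix(src); dst <- as.matrix(dst)
  n <- nrow(src)
  if (n < 4) stop("kriging needs at least 4 control points")
  if (nrow(dst) != n) stop("src and dst must pair up")
  D <- as.matrix(stats::dist(src))
  if (any(D[upper.tri(D)] < 1e-9)) stop("duplicate source control points")
  K <- kernel_eval(D, kernel)
  if (ridge > 0) diag(K) <- diag(K) + ridge
  P <- cbind(1, src)                      # n x 4 drift basis
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  # coplanar controls make the drift block rank-deficient
  qrA <- qr(A)
  if (qrA$rank < n + 4) stop("singular kriging system (coplanar or degenerate controls)")
  cn <- kappa(A, exact = FALSE)
  if (is.finite(cn) && cn > 1e12) {
    warning(sprintf("ill-conditioned kriging system (condition number %.2e)", cn))
  }
  rhs <- rbind(dst, matrix(0, 4, 3))
  coef <- solve(qrA, rhs)
  structure(list(src = src, dual = coef[1:n, , drop = FALSE],
                 drift = coef[(n + 1):(n + 4), , drop = FALSE],
                 kernel = kernel, ridge = ridge),
            class = "kriging_transform")
}

kernel_eval <- function(h, kernel) {
  switch(kernel, h = h, h3 = h^3)
}

#' Apply a fitted kriging transform to points
#'
#' @param t a `kriging_transform` from [fit_kriging()].
#' @param points m x 3 matrix (or length-3 vector) of points.
#' @return m x 3 matrix of mapped points.
#' @export
apply_kriging <- function(t, points) {
  stopifnot(inherits(t, "kriging_transform"))
  x <- if (is.null(dim(points))) matrix(points, 1) else as.matrix(points)
  # pairwise distances x (m) vs src (n)
  m <- nrow(x); n <- nrow(t$src)
  d2 <- outer(rowSums(x^2), rep(1, n)) + outer(rep(1, m), rowSums(t$src^2)) -
    2 * x %*% t(t$src)
  H <- sqrt(pmax(d2, 0))
  drift <- cbind(1, x) %*% t$drift
  drift + kernel_eval(H, t$kernel) %*% t$dual
}

#' @export
print.kriging_transform <- function(x, ...) {
  cat(sprintf("<kriging_transform> %d controls, kernel K(h)=%s, ridge %g\n",
              nrow(x$src), x$kernel, x$ridge))
  invisible(x)
}

#' Morph a template model to patient geometry
#'
#' Fits a dual-kriging transform from the template's mesh-borne landmarks
#' (see [mesh_landmarks()]) to the patient's 3D landmark set and passes
#' every template node through it. Element labels, springs, constraints
#' and the corner-node map are preserved. Mesh quality is evaluated after
#' morphing; fractions below `floor` raise a warning (not an error).
#'
#' @param template a `hex_mesh` (typically [build_template()]).
#' @param patient a complete `landmark_set` (153 points).
#' @param kernel,ridge passed to [fit_kriging()].
#' @param floor quality pass-fraction floor for the post-morph warning.
#' @return The morphed `hex_mesh`, with the quality check stored in
#'   attribute `"quality"`.
#' @export
morph_model <- function(template, patient, kernel = "h", ridge = 0,
                        floor = 0.97) {
  stopifnot(inherits(template, "hex_mesh"), inherits(patient, "landmark_set"))
  miss <- missing_landmarks(patient)
  if (length(miss)) stop("patient landmark set incomplete; missing: ",
                         paste(utils::head(miss, 5), collapse = "; "))
  src_lm <- mesh_landmarks(template)
  key <- paste(src_lm$level, src_lm$id)
  pat_key <- paste(patient$level, patient$id)
  dst <- landmark_matrix(patient)[match(key, pat_key), , drop = FALSE]
  tr <- fit_kriging(landmark_matrix(src_lm), dst, kernel = kernel, ridge = ridge)
  out <- template
  out$nodes <- apply_kriging(tr, template$nodes)
  q <- check_quality(mesh_quality(out), floor = floor)
  if (!q$overall) {
    warning("post-morph mesh quality below floor: ",
            paste(sprintf("%s=%.3f", names(q$fractions), q$fractions),
                  collapse = ", "))
  }
  attr(out, "quality") <- q
  attr(out, "kriging") <- tr
  out
}
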