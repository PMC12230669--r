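# Least-squares rigid superposition (Kabsch, SVD form) with reflection
# correction.

#' Optimal rigid superposition of two point sets
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' paired points, so that `P %*% t(rotation) + translation` best matches
#' `Q`. Reflections are corrected so `det(rotation) = +1`.
#'
#' @param P,Q n x 3 matrices of paired coordinates (n >= 3,
#'   non-collinear).
#' @return list with `rotation` (3x3), `translation` (length 3) and
#'   `rmsd` (Angstrom).
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) stop("point sets differ in size")
  if (nrow(P) < 3L) stop("degenerate input: need at least 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  sv_p <- svd(Pc)$d
  if (sv_p[2L] < 1e-8 * max(sv_p[1L], 1e-12))
    stop("degenerate input: points are collinear")
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  Pr <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pr - Qc)^2)))
  list(rotation = R, translation = as.numeric(cq - R %*% cp), rmsd = rmsd)
}

# RMSD of paired points after optimal superposition; NA-safe guard for
# tiny sets (falls back to direct RMSD when superposition is degenerate)
fitted_rmsd <- function(P, Q) {
  res <- try(kabsch(P, Q), silent = TRUE)
  if (inherits(res, "try-error")) {
    sqrt(mean(rowSums((as.matrix(P) - as.matrix(Q))^2)))
  } else res$rmsd
}

# apply a kabsch result to coordinates
apply_fit <- function(fit, X) {
  sweep(as.matrix(X) %*% t(fit$rotation), 2L, fit$translation, "+")
}
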