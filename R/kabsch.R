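#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) least-squares deviation between two paired coordinate sets,
#' via SVD of the covariance matrix with reflection correction, and
#' reports the residual RMSD. The transform maps `coords_b` onto
#' `coords_a`: `fitted = coords_b %*% t(rotation) + translation`.
#'
#' @param coords_a,coords_b N x 3 matrices of paired coordinates (N >= 3,
#'   not all collinear).
#' @param weights Optional non-negative weight per point.
#' @return List of class `afm_superposition`: `rotation` (3 x 3, proper
#'   orthonormal), `translation` (length-3), `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(coords_a, coords_b, weights = NULL) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (ncol(a) != 3 || ncol(b) != 3) abort("coordinate matrices must be N x 3")
  n <- nrow(a)
  if (nrow(b) != n) abort("coordinate sets must have equal length")
  if (n < 3) abort("need at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0) {
    abort("weights must be non-negative with positive sum")
  }
  w <- weights / sum(weights)
  cen_a <- colSums(a * w)
  cen_b <- colSums(b * w)
  ac <- sweep(a, 2, cen_a)
  bc <- sweep(b, 2, cen_b)
  # covariance of b against a; rank < 2 means the points carry no plane
  h <- t(bc * w) %*% ac
  sv <- svd(h)
  if (sum(sv$d > max(sv$d) * 1e-10) < 2) abort("degenerate (collinear) point set")
  d_sign <- sign(det(sv$v %*% t(sv$u)))
  if (d_sign == 0) d_sign <- 1
  rot <- sv$v %*% diag(c(1, 1, d_sign)) %*% t(sv$u)
  fitted <- bc %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((fitted - ac)^2)))
  structure(list(
    rotation = rot,
    translation = as.numeric(cen_a - rot %*% cen_b),
    rmsd = rmsd
  ), class = "afm_superposition")
}

#' @export
print.afm_superposition <- function(x, ...) {
  cat("<afm_superposition> rmsd ", format(x$rmsd, digits = 6), " A\n", sep = "")
  invisible(x)
}

#' Apply a superposition transform to coordinates
#'
#' @param sup An `afm_superposition` from [kabsch_superpose()].
#' @param coords N x 3 matrix (in the frame of `coords_b`).
#' @return Transformed N x 3 matrix.
#' @export
apply_superposition <- function(sup, coords) {
  sweep(as.matrix(coords) %*% t(sup$rotation), 2, sup$translation, "+")
}

#' C-alpha RMSD between two models after superposition
#'
#' Pairs residues across the two models by (chain role, residue index),
#' extracts C-alpha coordinates, and reports the Kabsch-superposed RMSD.
#' The designs-versus-prediction validation gate in triage uses this with
#' its 1.5 Angstrom default threshold.
#'
#' @param model_a,model_b [afm_structure()] objects with roles assigned
#'   (or identical chain ids, used as a fallback when roles are all
#'   unassigned).
#' @param selection `"all"` or a tibble with `chain`, `resno` (in
#'   `model_a`'s chain ids) restricting the residues compared.
#' @return RMSD in Angstrom (scalar).
#' @export
ca_rmsd <- function(model_a, model_b, selection = "all") {
  key_tbl <- function(s) {
    a <- as_tibble(s)
    a <- a[a$atom == "CA", c("chain", "resno", "role", "x", "y", "z")]
    a$pair_key <- ifelse(a$role == "unassigned",
                         paste(a$chain, a$resno),
                         paste(a$role, a$resno))
    a
  }
  ta <- key_tbl(model_a)
  tb <- key_tbl(model_b)
  if (is.data.frame(selection)) {
    keep <- paste(ta$chain, ta$resno) %in% paste(selection$chain, selection$resno)
    ta <- ta[keep, , drop = FALSE]
  } else if (!identical(selection, "all")) {
    abort("selection must be 'all' or a tibble with chain, resno")
  }
  idx <- match(ta$pair_key, tb$pair_key)
  if (any(is.na(idx))) {
    bad <- ta$pair_key[is.na(idx)]
    abort(paste0("unpaired residue(s) or missing C-alpha: ", paste(head(bad, 5), collapse = ", ")))
  }
  kabsch_superpose(
    as.matrix(ta[, c("x", "y", "z")]),
    as.matrix(tb[idx, c("x", "y", "z")])
  )$rmsd
}
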