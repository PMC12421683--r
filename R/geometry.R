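#' Minimum-image distance under an orthorhombic box
#'
#' @param a,b Numeric length-3 positions, or `n x 3` matrices of positions
#'   (paired row-wise; one of the two may be a single position).
#' @param box Orthorhombic box lengths, Angstrom.
#' @return Distance(s) in Angstrom; never exceeds half the box diagonal.
#' @export
minimum_image_distance <- function(a, b, box) {
  if (any(box <= 0)) abort("box lengths must be > 0")
  a <- if (is.null(dim(a))) matrix(a, ncol = 3) else as.matrix(a)
  b <- if (is.null(dim(b))) matrix(b, ncol = 3) else as.matrix(b)
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
  d <- a - b
  d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  sqrt(rowSums(d * d))
}

# minimum-image displacement vectors a - b (matrices n x 3)
minimum_image_vec <- function(a, b, box) {
  d <- a - b
  d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
}

# Kabsch: rotation + translation mapping `moving` onto `fixed` (n x 3 each)
kabsch <- function(moving, fixed) {
  cm <- colMeans(moving); cf <- colMeans(fixed)
  P <- sweep(moving, 2, cm); Q <- sweep(fixed, 2, cf)
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  list(rotation = R, translation = cf - as.vector(R %*% cm))
}

#' Superpose frames onto a reference structure
#'
#' Least-squares (Kabsch) rigid superposition of each frame onto reference
#' coordinates using a selection of atoms; the fitted rotation + translation
#' is applied to all atoms of the frame, so internal distances are preserved.
#'
#' @param trajectory A `cav_trajectory` (or a single `n x 3` matrix).
#' @param reference `m x 3` matrix of reference coordinates, ordered as
#'   `atom_selection`.
#' @param atom_selection Integer atom rows (1-based) used for the fit; at
#'   least 3 non-collinear atoms.
#' @return The transformed trajectory (or matrix), plus an attribute
#'   `selection_rmsd` with the post-fit RMSD per frame.
#' @export
superpose <- function(trajectory, reference, atom_selection) {
  reference <- as.matrix(reference)
  if (length(atom_selection) < 3 || nrow(reference) != length(atom_selection)) {
    abort("selection must list >= 3 atoms matching the reference rows")
  }
  if (is_collinear(reference)) abort("reference selection is collinear")
  single <- is.matrix(trajectory)
  coords <- if (single) array(trajectory, c(dim(trajectory), 1)) else trajectory$coords
  nf <- dim(coords)[3]
  rmsd <- numeric(nf)
  for (f in seq_len(nf)) {
    X <- coords[, , f]
    sel <- X[atom_selection, , drop = FALSE]
    if (is_collinear(sel)) abort("frame selection is collinear")
    tr <- kabsch(sel, reference)
    Xn <- X %*% t(tr$rotation)
    Xn <- sweep(Xn, 2, tr$translation, "+")
    coords[, , f] <- Xn
    d <- Xn[atom_selection, , drop = FALSE] - reference
    rmsd[f] <- sqrt(mean(rowSums(d * d)))
  }
  out <- if (single) coords[, , 1] else {
    trajectory$coords <- coords
    trajectory
  }
  attr(out, "selection_rmsd") <- rmsd
  out
}

is_collinear <- function(X, tol = 1e-8) {
  if (nrow(X) < 3) return(TRUE)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = 0)$d
  sv[2] < tol * max(sv[1], 1)
}
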