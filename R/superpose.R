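# Horn closed-form quaternion superposition and tetraloop-anchored
# transformation of protein interfaces into a common frame.

#' Apply a rigid transform to points
#'
#' @param transform list with `rotation` (3x3) and `translation` (length 3).
#' @param points n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, points) {
  points <- matrix(points, ncol = 3,
                   dimnames = list(rownames(points), NULL))
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

quaternion_to_rotation <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
         nrow = 3, byrow = TRUE)
}

#' Horn quaternion absolute-orientation superposition
#'
#' Closed-form least-squares rigid superposition of corresponding point
#' sets: the optimal rotation is obtained from the eigenvector of the
#' largest eigenvalue of the 4x4 symmetric quaternion matrix built from the
#' cross-covariance of the centered sets; the translation follows from the
#' centroids. The solution is a proper rotation (det +1): reflections are
#' never produced.
#'
#' @param moving,target n x 3 coordinate matrices, n >= 3, in
#'   correspondence row by row; the moving set must not be collinear.
#' @return a `SuperpositionResult`: list with `transform` (list
#'   `rotation`, `translation`), `rmsd` (A) at the optimum, and `n_points`.
#' @export
horn_superpose <- function(moving, target) {
  moving <- as.matrix(moving); target <- as.matrix(target)
  if (!all(dim(moving) == dim(target)))
    stop("point sets differ in size: ", nrow(moving), " vs ", nrow(target))
  if (nrow(moving) < 3) stop("need at least 3 points, got ", nrow(moving))
  cm <- colMeans(moving); ct <- colMeans(target)
  m0 <- sweep(moving, 2, cm); t0 <- sweep(target, 2, ct)
  sv <- svd(m0)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate geometry: moving point set is collinear")
  S <- t(m0) %*% t0
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    nrow = 4, byrow = TRUE)
  eig <- eigen(N, symmetric = TRUE)
  q <- eig$vectors[, 1]
  R <- quaternion_to_rotation(q / sqrt(sum(q^2)))
  tr <- ct - as.vector(R %*% cm)
  moved <- sweep(moving %*% t(R), 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((moved - target)^2)))
  structure(list(transform = list(rotation = R, translation = tr),
                 rmsd = rmsd, n_points = nrow(moving)),
            class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat("SuperpositionResult:", x$n_points, "points, rmsd",
      format(x$rmsd, digits = 4), "A\n")
  invisible(x)
}

#' Superpose tetraloop-anchored interfaces onto a reference
#'
#' Superposes each tetraloop backbone onto the reference tetraloop by
#' [horn_superpose()] over the named backbone atoms common to both
#' (correspondence by rowname, e.g. `"2_C4'"` = nucleotide position 2,
#' atom C4'; missing atoms dropped pairwise), then carries each tetraloop's
#' interface atoms through its rigid transform. The reference maps to
#' itself with rmsd 0.
#'
#' @param tetraloops list; each element a list with `backbone` (n x 3
#'   matrix, rownames `"<position>_<atom>"`) and `interface` (m x 3 matrix,
#'   possibly 0-row).
#' @param ref_index index of the reference tetraloop (default 1).
#' @return list, one element per tetraloop: `result`
#'   (`SuperpositionResult`), `backbone` and `interface` (transformed
#'   coordinates).
#' @export
superpose_interfaces <- function(tetraloops, ref_index = 1) {
  stopifnot(length(tetraloops) >= 1, ref_index >= 1,
            ref_index <= length(tetraloops))
  ref <- tetraloops[[ref_index]]$backbone
  lapply(seq_along(tetraloops), function(k) {
    bb <- tetraloops[[k]]$backbone
    common <- intersect(rownames(ref), rownames(bb))
    if (length(common) < 3)
      stop("tetraloop ", k, ": fewer than 3 backbone atoms in common with",
           " the reference after pairwise dropping")
    res <- horn_superpose(bb[common, , drop = FALSE],
                          ref[common, , drop = FALSE])
    intf <- tetraloops[[k]]$interface
    list(result = res,
         backbone = apply_transform(res$transform, bb),
         interface = if (is.null(intf) || nrow(intf) == 0) intf else
           apply_transform(res$transform, intf))
  })
}
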