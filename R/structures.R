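#' Protein structure as an ordered set of C-alpha coordinates
#'
#' A protein structure is an ordered sequence of labelled points in 3-space,
#' one per residue (conventionally the C-alpha atom). Order is meaningful:
#' index i of a model corresponds to index i of its target.
#'
#' @param xyz numeric n x 3 matrix of coordinates in Angstrom (a length-3
#'   vector is accepted for a single residue).
#' @param labels optional character vector of per-residue identifiers
#'   (e.g. "A:42"); defaults to the row index.
#' @return An object of class `protein_structure` with elements `xyz` and
#'   `labels`.
#' @export
protein_structure <- function(xyz, labels = NULL) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L) stop("coordinates must have 3 columns")
  if (nrow(xyz) < 1L) stop("empty structure")
  if (!all(is.finite(xyz))) stop("non-finite coordinate")
  if (is.null(labels)) labels <- as.character(seq_len(nrow(xyz)))
  labels <- as.character(labels)
  if (length(labels) != nrow(xyz)) stop("labels length must match points")
  structure(list(xyz = xyz, labels = labels), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("protein_structure: %d residues\n", nrow(x$xyz)))
  invisible(x)
}

#' @export
length.protein_structure <- function(x) nrow(x$xyz)

#' Pair a target structure with a model
#'
#' Builds the equal-length target/model pair on which all GDT quantities are
#' defined. With `mode = "by_index"` the structures must have identical
#' length and residue i of the model corresponds to residue i of the target.
#' With `mode = "by_label"` the label sets are intersected (target order is
#' preserved) and unmatched residues are dropped with a message.
#'
#' @param target,model `protein_structure` objects.
#' @param mode correspondence rule, `"by_index"` (default) or `"by_label"`.
#' @return An object of class `structure_pair` with elements `target`,
#'   `model` and `n`.
#' @export
pair_structures <- function(target, model, mode = c("by_index", "by_label")) {
  mode <- match.arg(mode)
  stopifnot(inherits(target, "protein_structure"),
            inherits(model, "protein_structure"))
  if (mode == "by_index") {
    if (length(target) != length(model))
      stop("by_index pairing requires equal lengths (",
           length(target), " vs ", length(model), ")")
  } else {
    common <- intersect(target$labels, model$labels)
    if (length(common) == 0L) stop("no common labels between structures")
    dropped <- (length(target) - length(common)) +
      (length(model) - length(common))
    if (dropped > 0L)
      message(sprintf("pair_structures: dropped %d unmatched residues", dropped))
    ti <- match(common, target$labels)
    ti <- ti[order(ti)]            # preserve target order
    keep <- target$labels[ti]
    mi <- match(keep, model$labels)
    target <- protein_structure(target$xyz[ti, , drop = FALSE], keep)
    model <- protein_structure(model$xyz[mi, , drop = FALSE], keep)
  }
  structure(list(target = target, model = model, n = length(target)),
            class = "structure_pair")
}

#' @export
print.structure_pair <- function(x, ...) {
  cat(sprintf("structure_pair: n = %d residues\n", x$n))
  invisible(x)
}

#' Rigid-body transformation
#'
#' A rotation followed by a translation, `x -> R x + t`. The rotation matrix
#' must be proper orthogonal (det +1).
#'
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation length-3 numeric vector (Angstrom).
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (abs(det(rotation) - 1) > 1e-9 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation must be proper orthogonal (det +1)")
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$R)) - 1) / 2)))
  cat(sprintf("rigid_transform: rotation %.2f rad, translation (%.3f, %.3f, %.3f)\n",
              ang, x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

#' @rdname rigid_transform
#' @export
transform_identity <- function() rigid_transform()

#' Compose two rigid transforms
#'
#' Returns the transform applying `second` after `first`,
#' i.e. `x -> second(first(x))`.
#' @param first,second `rigid_transform` objects.
#' @export
transform_compose <- function(second, first) {
  rigid_transform(second$R %*% first$R,
                  as.numeric(second$R %*% first$t) + second$t)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @export
transform_inverse <- function(transform) {
  rigid_transform(t(transform$R), as.numeric(-t(transform$R) %*% transform$t))
}

#' Apply a rigid transform to a structure or coordinate matrix
#'
#' @param transform a `rigid_transform`.
#' @param s a `protein_structure` or an n x 3 coordinate matrix.
#' @return Object of the same type as `s`, pointwise transformed.
#' @export
apply_transform <- function(transform, s) {
  if (inherits(s, "protein_structure")) {
    protein_structure(apply_transform(transform, s$xyz), s$labels)
  } else {
    xyz <- as.matrix(s)
    sweep(xyz %*% t(transform$R), 2L, transform$t, "+")
  }
}

#' Rotation about an arbitrary axis
#'
#' Rigid transform rotating by `angle` radians about the line through
#' `point` with (unit) direction `direction`; points on the axis are fixed.
#'
#' @param point a point on the axis.
#' @param direction axis direction (normalized internally).
#' @param angle rotation angle in radians.
#' @export
rotation_about_axis <- function(point, direction, angle) {
  u <- direction / sqrt(sum(direction^2))
  R <- rotation_from_axis_angle(u * angle)
  rigid_transform(R, as.numeric(point - R %*% point))
}

# Rodrigues formula; rv is axis*angle.
rotation_from_axis_angle <- function(rv) {
  th <- sqrt(sum(rv^2))
  if (th < 1e-12) return(diag(3))
  u <- rv / th
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Least-squares (Kabsch) superposition
#'
#' RMSD-optimal rigid fit of `model_xyz` onto `target_xyz`. This is a
#' utility for warm starts and test oracles only: the GDT criterion is
#' count-under-cutoff, not least squares, and the scoring path never relies
#' on this fit for its guarantees.
#'
#' @param target_xyz,model_xyz n x 3 coordinate matrices (n >= 1).
#' @return A `rigid_transform` mapping the model onto the target.
#' @export
kabsch_transform <- function(target_xyz, model_xyz) {
  target_xyz <- as.matrix(target_xyz)
  model_xyz <- as.matrix(model_xyz)
  stopifnot(nrow(target_xyz) == nrow(model_xyz))
  ca <- colMeans(target_xyz)
  cb <- colMeans(model_xyz)
  A <- sweep(target_xyz, 2L, ca)
  B <- sweep(model_xyz, 2L, cb)
  H <- crossprod(B, A)           # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, as.numeric(ca - R %*% cb))
}
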