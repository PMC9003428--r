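#' Sparse dictionary of labelled training atoms
#'
#' A dictionary `A = [a_1 ... a_k]` of training signals (columns),
#' unit-normalised at construction so reconstruction residuals are
#' comparable across atoms, with a class label per atom. A test signal is
#' modelled as a sparse linear combination of atoms plus an error term;
#' classification assigns the class whose atoms explain the signal best.
#'
#' @param atoms numeric matrix, signal dimension x k (k >= 2). Columns are
#'   rescaled to unit Euclidean norm.
#' @param atom_classes vector of class labels, one per atom; each declared
#'   class must contribute at least one atom.
#' @param noise_tolerance documented error-term bound epsilon (>= 0); kept
#'   as metadata, the coding itself is penalty-parameterised (see
#'   [src_code()]).
#' @return an object of class `sparse_dictionary`.
#' @export
sparse_dictionary <- function(atoms, atom_classes, noise_tolerance = 0) {
  atoms <- as.matrix(atoms)
  if (ncol(atoms) < 2L) stop("dictionary needs at least 2 atoms")
  if (!all(is.finite(atoms))) stop("non-finite atom values")
  if (length(atom_classes) != ncol(atoms))
    stop("one class label per atom required")
  if (noise_tolerance < 0) stop("`noise_tolerance` must be >= 0")
  nrm <- sqrt(colSums(atoms^2))
  if (any(nrm == 0)) stop("zero-norm atom(s)")
  atoms <- sweep(atoms, 2, nrm, "/")
  structure(list(atoms = atoms,
                 atom_classes = as.character(atom_classes),
                 classes = unique(as.character(atom_classes)),
                 noise_tolerance = noise_tolerance),
            class = "sparse_dictionary")
}

#' Sparse coding of a test signal
#'
#' Encodes signal `b` as a sparse coefficient vector over the dictionary
#' atoms by solving the l1-penalised least-squares problem with the
#' homotopy solver and reading the path off at penalty `lam`. Atoms are
#' used as-is (no centring/standardisation — they are unit-normalised).
#'
#' @param dict a [sparse_dictionary()].
#' @param b test signal (length = atom dimension).
#' @param lam penalty at which to read the solution (relative sparsity
#'   knob; smaller values give denser codes).
#' @return sparse coefficient vector of length k.
#' @export
src_code <- function(dict, b, lam) {
  stopifnot(inherits(dict, "sparse_dictionary"))
  b <- as.numeric(b)
  if (length(b) != nrow(dict$atoms))
    stop("signal dimension must equal atom dimension")
  if (all(b == 0)) return(numeric(ncol(dict$atoms)))
  lmax <- max(abs(crossprod(dict$atoms, b))) / length(b)
  if (lmax == 0) return(numeric(ncol(dict$atoms)))
  # trace the path at least down to the requested penalty
  ratio <- max(min(1e-4, lam / (2 * lmax)), 1e-12)
  prob <- lasso_problem(dict$atoms, b, standardize = FALSE,
                        lambda_min_ratio = ratio)
  suppressWarnings(solution_at(solve_path(prob), lam))
}

#' Residual-rule sparse-representation classification
#'
#' Codes `b` over the dictionary, then computes the class-wise
#' reconstruction residual `r_c = ||b - A d_c(x)||_2`, where `d_c` keeps
#' only the coefficients of class-`c` atoms. The predicted class is the
#' residual minimiser (ties broken toward the class declared first); when
#' the code is identically zero every class reconstructs nothing and the
#' prediction is the sentinel `"abstain"`.
#'
#' @param dict a [sparse_dictionary()].
#' @param b test signal.
#' @param lam coding penalty, as in [src_code()].
#' @return list with `class` (predicted label or `"abstain"`), `residuals`
#'   (named per-class residuals) and `code` (the sparse coefficients).
#' @export
src_classify <- function(dict, b, lam) {
  x <- src_code(dict, b, lam)
  b <- as.numeric(b)
  res <- vapply(dict$classes, function(cl) {
    xi <- ifelse(dict$atom_classes == cl, x, 0)
    sqrt(sum((b - dict$atoms %*% xi)^2))
  }, numeric(1))
  names(res) <- dict$classes
  if (all(abs(x) <= 1e-12)) {
    return(list(class = "abstain", residuals = res, code = x))
  }
  list(class = dict$classes[which.min(res)], residuals = res, code = x)
}
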