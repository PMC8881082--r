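#' Superpose a model onto a target by matched C-alpha atoms
#'
#' Least-squares rigid superposition (closed-form Kabsch rotation via SVD) of
#' the model's C-alpha atoms onto the target's, using the residue
#' correspondence given by matching chain / residue-number / insertion-code
#' identifiers. The fitted rigid motion is applied to all model atoms. This is
#' the optional pre-orientation step; models are otherwise assumed to be
#' pre-oriented.
#'
#' @param model,target `mr_model` objects sharing residue numbering.
#' @return the transformed model.
#' @export
superpose <- function(model, target) {
  mk <- paste(residue_key(model), model$atoms$name)
  tk <- paste(residue_key(target), target$atoms$name)
  ca_m <- which(trimws(model$atoms$name) == "CA")
  m2t <- match(mk[ca_m], tk)
  ok <- !is.na(m2t)
  if (sum(ok) < 3)
    stop_rellg("fewer than 3 matched C-alpha pairs between model and target",
               "correspondence")
  X <- model_xyz(model)[ca_m[ok], , drop = FALSE]
  Y <- model_xyz(target)[m2t[ok], , drop = FALSE]
  fit <- kabsch(X, Y)
  xyz <- sweep(model_xyz(model), 2, fit$cx) %*% fit$R
  xyz <- sweep(xyz, 2, fit$cy, `+`)
  set_model_xyz(model, xyz)
}

# Kabsch: rotation R (row-vector convention) and centroids minimizing
# || (Y - cy) - (X - cx) R ||_F
kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sv <- svd(crossprod(Xc, Yc))
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  rmsd <- sqrt(mean(rowSums((Yc - Xc %*% R)^2)))
  list(R = R, cx = cx, cy = cy, rmsd = rmsd)
}
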