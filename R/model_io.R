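#' Read a coordinate model from a PDB file
#'
#' Parses ATOM/HETATM records (via \pkg{bio3d}), drops hydrogens, waters and
#' all but the first alternate location, and records how the B-factor column
#' is to be interpreted: as a true isotropic B (Angstrom^2) or as a per-atom
#' RMS coordinate-error estimate (Angstrom), the convention used for CASP
#' model submissions.
#'
#' Negative B-field values are clamped to zero. In error-estimate mode,
#' values above `error_cap` (implausible as RMS displacements) are clamped to
#' the cap rather than rejected: atoms with huge error estimates are
#' effectively downweighted to nothing downstream, and a fully downweighted
#' model scores zero instead of raising an error.
#'
#' @param path path to a PDB-format coordinate file.
#' @param bfield_mode `"b_factor"` or `"rms_error"`: interpretation of the
#'   B-factor column.
#' @param error_cap clamp for implausible error estimates (Angstrom), applied
#'   only in `"rms_error"` mode.
#' @param keep_hetero keep non-water HETATM records (default drops them).
#' @return an object of class `mr_model`: a list with `atoms` (data frame with
#'   columns `element`, `name`, `resid`, `chain`, `resseq`, `icode`, `x`, `y`,
#'   `z`, `occ`, `bfield`), `bfield_mode`, and `center` (unweighted centroid).
#' @seealso [write_model()], [apply_error_weighting()], [prune_by_rmsd()]
#' @export
read_model <- function(path, bfield_mode = c("b_factor", "rms_error"),
                       error_cap = 100, keep_hetero = FALSE) {
  bfield_mode <- match.arg(bfield_mode)
  if (!file.exists(path)) stop_rellg(paste0("cannot read '", path, "'"), "input")
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                  error = function(e) stop_rellg(
                    paste0("unparseable PDB file '", path, "': ", conditionMessage(e)),
                    "input"))
  a <- pdb$atom
  atoms <- data.frame(
    element = ifelse(is.na(a$elesy) | trimws(a$elesy) == "",
                     guess_element(a$elety), toupper(trimws(a$elesy))),
    name = a$elety, resid = a$resid, chain = a$chain,
    resseq = a$resno, icode = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o), bfield = ifelse(is.na(a$b), 0, a$b),
    alt = ifelse(is.na(a$alt), "", a$alt), type = a$type,
    stringsAsFactors = FALSE)
  atoms <- atoms[atoms$element != "H" & atoms$element != "D", , drop = FALSE]
  atoms <- atoms[!(atoms$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (!keep_hetero) atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  # first alternate location only
  atoms <- atoms[atoms$alt %in% c("", "A", "1"), , drop = FALSE]
  atoms$alt <- NULL; atoms$type <- NULL
  new_model(atoms, bfield_mode, error_cap = error_cap)
}

# construct and validate an mr_model from an atom table
new_model <- function(atoms, bfield_mode, error_cap = 100) {
  if (nrow(atoms) == 0)
    stop_rellg("no atoms remain after filtering", "empty_model")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop_rellg("non-finite coordinates", "input")
  atoms$occ <- pmin(pmax(atoms$occ, 0), 1)
  atoms$bfield <- pmax(atoms$bfield, 0)
  if (bfield_mode == "rms_error") atoms$bfield <- pmin(atoms$bfield, error_cap)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, bfield_mode = bfield_mode,
                 center = c(mean(atoms$x), mean(atoms$y), mean(atoms$z))),
            class = "mr_model")
}

#' @export
print.mr_model <- function(x, ...) {
  cat(sprintf("mr_model: %d atoms, %d residues, B-field = %s\n",
              nrow(x$atoms), length(unique(residue_key(x))), x$bfield_mode))
  cat(sprintf("  center (%.2f, %.2f, %.2f) A, span %.1f x %.1f x %.1f A\n",
              x$center[1], x$center[2], x$center[3],
              diff(range(x$atoms$x)), diff(range(x$atoms$y)), diff(range(x$atoms$z))))
  invisible(x)
}

# n x 3 coordinate matrix
model_xyz <- function(model) cbind(model$atoms$x, model$atoms$y, model$atoms$z)

# replace coordinates, recomputing the centroid
set_model_xyz <- function(model, xyz) {
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model$center <- colMeans(xyz)
  model
}

residue_key <- function(model)
  paste(model$atoms$chain, model$atoms$resseq, model$atoms$icode, sep = "|")

#' Write a model to a PDB file
#'
#' The B-field column is written as-is (whatever its current interpretation).
#'
#' @param model an `mr_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  a <- model$atoms
  bio3d::write.pdb(file = path, xyz = as.numeric(t(model_xyz(model))),
                   type = rep("ATOM", nrow(a)), resno = a$resseq,
                   resid = a$resid, chain = ifelse(is.na(a$chain), "A", a$chain),
                   insert = ifelse(a$icode == "", NA, a$icode),
                   elety = a$name, o = a$occ, b = a$bfield,
                   elesy = a$element)
  invisible(path)
}

#' Convert RMS coordinate error to an isotropic B-factor (and back)
#'
#' `rmsd_to_bfactor()` returns the isotropic displacement parameter that
#' smears an atom's density over a 3D Gaussian distribution of true positions
#' with radial RMS error `sigma_r`: B = 8 pi^2 / 3 * sigma_r^2.
#' `bfactor_to_rmsd()` is its inverse.
#'
#' @param sigma_r radial RMS positional error (Angstrom), non-negative.
#' @param b isotropic B-factor (Angstrom^2), non-negative.
#' @return B-factor in Angstrom^2 (or error in Angstrom for the inverse).
#' @examples
#' rmsd_to_bfactor(1.0)           # 26.319
#' bfactor_to_rmsd(rmsd_to_bfactor(0.4))
#' @export
rmsd_to_bfactor <- function(sigma_r) {
  if (any(!is.finite(sigma_r)) || any(sigma_r < 0))
    stop_rellg("sigma_r must be finite and >= 0", "domain")
  8 * pi^2 / 3 * sigma_r^2
}

#' @rdname rmsd_to_bfactor
#' @export
bfactor_to_rmsd <- function(b) {
  if (any(!is.finite(b)) || any(b < 0))
    stop_rellg("b must be finite and >= 0", "domain")
  sqrt(3 * b / (8 * pi^2))
}

#' Apply coordinate-error weighting to a model's B-field
#'
#' In `"error"` mode each atom's RMS-error estimate is converted to the
#' equivalent B-factor via [rmsd_to_bfactor()], so that each atom's density is
#' smeared over its positional uncertainty -- the weighting that optimizes the
#' electron-density overlap with the target. In `"constant"` mode every atom
#' receives the same B (default 25 Angstrom^2); because scoring uses
#' normalized structure factors the particular constant is immaterial.
#'
#' @param model an `mr_model`.
#' @param mode `"error"` (requires `bfield_mode == "rms_error"`) or
#'   `"constant"`.
#' @param constant_b the constant B value (Angstrom^2) for `"constant"` mode.
#' @return the model with `bfield` transformed and `bfield_mode` set to
#'   `"b_factor"`.
#' @export
apply_error_weighting <- function(model, mode = c("error", "constant"),
                                  constant_b = 25) {
  mode <- match.arg(mode)
  if (mode == "error") {
    if (model$bfield_mode != "rms_error")
      stop_rellg("mode = 'error' requires a model whose B-field holds RMS error estimates",
                 "mode_mismatch")
    model$atoms$bfield <- rmsd_to_bfactor(model$atoms$bfield)
  } else {
    model$atoms$bfield <- rep(constant_b, nrow(model$atoms))
  }
  model$bfield_mode <- "b_factor"
  model
}

#' Prune residues with large coordinate-error estimates
#'
#' Removes, at whole-residue granularity, every residue whose maximum per-atom
#' RMS-error estimate exceeds `threshold`.
#'
#' @param model an `mr_model` with `bfield_mode == "rms_error"`.
#' @param threshold error threshold (Angstrom).
#' @return the pruned model.
#' @export
prune_by_rmsd <- function(model, threshold) {
  if (model$bfield_mode != "rms_error")
    stop_rellg("pruning requires B-field in RMS-error mode", "mode_mismatch")
  key <- residue_key(model)
  res_max <- tapply(model$atoms$bfield, key, max)
  keep <- key %in% names(res_max)[res_max <= threshold]
  if (!any(keep)) stop_rellg("pruning removed every residue", "empty_model")
  new_model(model$atoms[keep, , drop = FALSE], model$bfield_mode)
}
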