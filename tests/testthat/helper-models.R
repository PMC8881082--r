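# Hand-written fixed-width PDB text, independent of write_model(), so that
# read_model() is tested against the wire format rather than a round trip.
pdb_line <- function(serial, name, resid, chain, resseq, x, y, z,
                     occ = 1, b = 0, element = substr(name, 1, 1),
                     record = "ATOM") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %-4s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, resid, chain, resseq, x, y, z, occ, b, element)
}

write_pdb_text <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# a tiny in-memory model without touching the file system
tiny_model <- function(xyz, bfield = 0, bfield_mode = "b_factor",
                       element = "C", name = "CA", occ = 1) {
  n <- nrow(xyz)
  rellg:::new_model(data.frame(
    element = rep(element, length.out = n), name = rep(name, length.out = n),
    resid = "ALA", chain = "A", resseq = seq_len(n), icode = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = rep(occ, length.out = n), bfield = rep(bfield, length.out = n),
    stringsAsFactors = FALSE), bfield_mode)
}

model_xyz <- rellg:::model_xyz

# net residual rigid motion between two same-shape coordinate sets:
# rotation angle (degrees) and centroid shift (Angstrom)
residual_motion <- function(a, b) {
  K <- rellg:::kabsch(model_xyz(a), model_xyz(b))
  list(angle_deg = acos(min(1, (sum(diag(K$R)) - 1) / 2)) * 180 / pi,
       shift = sqrt(sum((K$cy - K$cx)^2)), rmsd = K$rmsd)
}
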