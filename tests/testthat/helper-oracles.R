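# Independent oracles used across the suite.

# Kabsch/SVD rigid superposition (reference for Horn's quaternion solution).
kabsch_superpose <- function(moving, target, allow_reflection = FALSE) {
  cm <- colMeans(moving); ct <- colMeans(target)
  s <- svd(t(sweep(moving, 2, cm)) %*% sweep(target, 2, ct))
  d <- if (allow_reflection) 1 else sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- ct - as.vector(R %*% cm)
  moved <- sweep(moving %*% t(R), 2, tr, "+")
  list(rotation = R, translation = tr,
       rmsd = sqrt(mean(rowSums((moved - target)^2))))
}

# All-pairs brute-force cross neighbour search.
brute_pairs <- function(A, B, cutoff) {
  out <- list()
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- sqrt(sum((A[i, ] - B[j, ])^2))
    if (d <= cutoff) out[[length(out) + 1]] <- c(i, j, d)
  }
  if (length(out) == 0)
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2], dist = m[, 3])
}

# Exposed area of each of two equal spheres of radius R at distance d
# (spherical-cap formula).
two_sphere_exposed <- function(R, d) {
  if (d >= 2 * R) return(4 * pi * R^2)
  2 * pi * R^2 * (1 + d / (2 * R))
}

# Brute-force reference for choose_step: largest candidate under which all
# atoms of every interface land on distinct cells.
brute_choose_step <- function(interfaces, candidates) {
  ok_steps <- candidates[vapply(candidates, function(step) {
    all(vapply(interfaces, function(p) {
      i <- floor(p$theta / step); j <- floor((p$phi + pi) / step)
      !anyDuplicated(paste(i, j))
    }, logical(1)))
  }, logical(1))]
  if (length(ok_steps) == 0) return(min(candidates))
  max(ok_steps)
}

# Minimal in-memory StructureModel from an atom table (test scaffolding).
toy_model <- function(atoms, id = "toy") {
  atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  atoms$kind <- ribomotif::residue_kind(atoms$resid)
  ribomotif:::new_structure_model(id, atoms)
}

# Convenience: atom row constructor.
atom_row <- function(name, element, x, y, z, chain, resno, resid) {
  data.frame(name = name, element = element, x = x, y = y, z = z,
             chain = chain, resno = resno, resid = resid,
             stringsAsFactors = FALSE)
}
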