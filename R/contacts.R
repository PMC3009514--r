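# Contact-surface extraction and per-nucleotide P-R-B contact counts.
#
# Contacts are defined by transparent distance rules rather than the original
# extraction tool's (undocumented) parameterization: a contact is any RNA/
# protein heavy-atom pair within `contact_dist`; a hydrogen bond additionally
# requires both atoms to be N or O within `hbond_dist`.

#' Contact extraction parameters
#'
#' @param contact_dist heavy-atom contact cutoff, A (default 4.5).
#' @param hbond_dist donor-acceptor cutoff for the hydrogen-bond class, A
#'   (default 3.5); must not exceed `contact_dist`.
#' @param min_pairs_per_surface minimum number of contact pairs for a protein
#'   chain to yield a contact surface.
#' @return a list of class `ContactParams`.
#' @export
contact_params <- function(contact_dist = 4.5, hbond_dist = 3.5,
                           min_pairs_per_surface = 1) {
  stopifnot(contact_dist > 0, hbond_dist <= contact_dist,
            min_pairs_per_surface >= 1)
  structure(list(contact_dist = contact_dist, hbond_dist = hbond_dist,
                 min_pairs_per_surface = as.integer(min_pairs_per_surface)),
            class = "ContactParams")
}

# Grid-based cross neighbour search: all pairs (i in A, j in B) with
# distance <= cutoff. Expected O(n) with bounded density.
neighbor_pairs <- function(A, B, cutoff) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) == 0 || nrow(B) == 0)
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  cell <- cutoff
  keyA <- floor(A / cell)
  idxA <- split(seq_len(nrow(A)),
                paste(keyA[, 1], keyA[, 2], keyA[, 3], sep = "_"))
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  keyB <- floor(B / cell)
  res_i <- vector("list", nrow(B))
  res_d <- vector("list", nrow(B))
  for (j in seq_len(nrow(B))) {
    ks <- sweep(off, 2, keyB[j, ], "+")
    keys <- paste(ks[, 1], ks[, 2], ks[, 3], sep = "_")
    cand <- unlist(idxA[keys], use.names = FALSE)
    if (is.null(cand) || length(cand) == 0) next
    d <- sqrt((A[cand, 1] - B[j, 1])^2 + (A[cand, 2] - B[j, 2])^2 +
                (A[cand, 3] - B[j, 3])^2)
    keep <- d <= cutoff
    if (any(keep)) {
      res_i[[j]] <- cand[keep]
      res_d[[j]] <- d[keep]
    }
  }
  lens <- lengths(res_i)
  data.frame(i = unlist(res_i, use.names = FALSE),
             j = rep(seq_len(nrow(B)), lens),
             dist = unlist(res_d, use.names = FALSE))
}

#' Find protein-RNA contact surfaces
#'
#' Extracts, for each protein chain, the paired contact surfaces against the
#' (merged) RNA chains: the RNA-side atom set (R-CS), the protein-side atom
#' set (P-CS), and the list of contact pairs with their interaction class.
#'
#' @param model a `StructureModel` with at least one RNA and one protein
#'   chain.
#' @param params a [contact_params()] list.
#' @return list of `ContactSurface` objects (one per protein chain with at
#'   least `min_pairs_per_surface` pairs), each a list with `protein_chain`,
#'   `pairs` (data frame: `rna_atom`, `protein_atom` row indices into
#'   `model$atoms`, `distance`, `klass`), `rcs_atoms`, `pcs_atoms`.
#' @export
find_contacts <- function(model, params = contact_params()) {
  at <- model$atoms
  rna_chains <- model$chains$chain[model$chains$polymer_class == "rna"]
  prot_chains <- model$chains$chain[model$chains$polymer_class == "protein"]
  if (length(rna_chains) == 0 || length(prot_chains) == 0)
    stop("not a protein-RNA complex: need at least one RNA and one protein chain")
  rna_idx <- which(at$chain %in% rna_chains & at$kind == "nucleotide")
  surfaces <- list()
  for (ch in prot_chains) {
    prot_idx <- which(at$chain == ch & at$kind == "amino_acid")
    if (length(prot_idx) == 0) next
    np <- neighbor_pairs(at[rna_idx, c("x", "y", "z")],
                         at[prot_idx, c("x", "y", "z")],
                         params$contact_dist)
    if (nrow(np) < params$min_pairs_per_surface) next
    pairs <- data.frame(rna_atom = rna_idx[np$i],
                        protein_atom = prot_idx[np$j],
                        distance = np$dist)
    both_no <- at$element[pairs$rna_atom] %in% c("N", "O") &
      at$element[pairs$protein_atom] %in% c("N", "O")
    pairs$klass <- ifelse(both_no & pairs$distance <= params$hbond_dist,
                          "hbond", "vdw")
    ord <- order(at$serial[pairs$rna_atom], at$serial[pairs$protein_atom])
    pairs <- pairs[ord, , drop = FALSE]
    rownames(pairs) <- NULL
    surfaces[[length(surfaces) + 1]] <- structure(
      list(protein_chain = ch,
           pairs = pairs,
           rcs_atoms = sort(unique(pairs$rna_atom)),
           pcs_atoms = sort(unique(pairs$protein_atom))),
      class = "ContactSurface")
  }
  surfaces
}

#' @export
print.ContactSurface <- function(x, ...) {
  cat("ContactSurface protein chain", x$protein_chain, "-",
      nrow(x$pairs), "pairs,", length(x$rcs_atoms), "R-CS atoms,",
      length(x$pcs_atoms), "P-CS atoms\n")
  invisible(x)
}

#' Per-nucleotide phosphate/ribose/base contact counts
#'
#' Partitions the contact pairs of a surface by the chemical group of the
#' RNA-side atom and tallies them per contacted nucleotide. The three counts
#' of a nucleotide sum to its total number of contact pairs.
#'
#' @param surface a `ContactSurface`.
#' @param model the `StructureModel` the surface was computed on.
#' @return data frame ordered by (chain, seq number): `chain`, `resno`,
#'   `insert`, `base` (residue name), `p`, `r`, `b`.
#' @export
prb_counts <- function(surface, model) {
  at <- model$atoms
  pr <- surface$pairs
  if (nrow(pr) == 0) stop("empty contact surface")
  grp <- rna_atom_group(at$name[pr$rna_atom])
  key <- residue_key(at[pr$rna_atom, ])
  keys <- sort(unique(key))
  tab <- data.frame(key = keys,
                    p = tapply(grp == "phosphate", key, sum)[keys],
                    r = tapply(grp == "ribose", key, sum)[keys],
                    b = tapply(grp == "base", key, sum)[keys],
                    stringsAsFactors = FALSE)
  parts <- strsplit(tab$key, "|", fixed = TRUE)
  tab$chain <- vapply(parts, `[`, "", 1)
  tab$resno <- as.integer(vapply(parts, `[`, "", 2))
  tab$insert <- vapply(parts, function(p) if (length(p) >= 3) p[[3]] else "",
                       "")
  first <- at[pr$rna_atom, ][match(tab$key, key), ]
  tab$base <- first$resid
  tab <- tab[order(tab$chain, tab$resno, tab$insert),
             c("chain", "resno", "insert", "base", "p", "r", "b")]
  rownames(tab) <- NULL
  tab
}

#' Contact-surface area
#'
#' Approximates the area of a contact patch as the summed solvent-accessible
#' area of its atoms computed in the whole-molecule context. This is an
#' approximation to a rolled-probe contact surface: adequate for comparing
#' patch sizes, not for absolute areas.
#'
#' @param atom_rows integer atom row indices (e.g. `rcs_atoms`).
#' @param model the `StructureModel`.
#' @param params a [surface_params()] list.
#' @param sasa optional precomputed [compute_sasa()] vector.
#' @return area in A^2 (0 for an empty set).
#' @export
contact_area <- function(atom_rows, model, params = surface_params(),
                         sasa = NULL) {
  if (length(atom_rows) == 0) return(0)
  if (is.null(sasa)) sasa <- compute_sasa(model, params)
  sum(sasa[atom_rows])
}
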