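# Tripod binding-site search: convex knobs on protein contact surfaces,
# knob-triplet enumeration around contacted nucleotides, geometric
# fingerprint matching and the P-R-B contact filter.

#' Tripod geometric fingerprint
#'
#' The query triangle for the tripod search. The canonical triangle is
#' equilateral with the given side (midpoint of the admissible side range),
#' placed in the z = 0 plane; candidate triplets must have all sides within
#' `side_range` and all angles within `angle_range` (open intervals) and a
#' best-permutation rigid-superposition RMSD to this triangle of at most
#' `rmsd_max`.
#'
#' @param side canonical equilateral side (A), default 8.5.
#' @param side_range open interval of admissible sides (A), default (7, 10).
#' @param angle_range open interval of admissible angles (deg),
#'   default (40, 70).
#' @param rmsd_max RMSD acceptance threshold (A), default 1.5.
#' @return a `TripodFingerprint` list with `points` (3 x 3 matrix).
#' @export
tripod_fingerprint <- function(side = 8.5, side_range = c(7, 10),
                               angle_range = c(40, 70), rmsd_max = 1.5) {
  stopifnot(side > side_range[1], side < side_range[2], rmsd_max > 0)
  points <- rbind(c(0, 0, 0),
                  c(side, 0, 0),
                  c(side / 2, side * sqrt(3) / 2, 0))
  fp <- structure(list(points = points, side_range = side_range,
                       angle_range = angle_range, rmsd_max = rmsd_max),
                  class = "TripodFingerprint")
  geom <- triangle_geometry(points[1, ], points[2, ], points[3, ])
  stopifnot(all(geom$sides > side_range[1]), all(geom$sides < side_range[2]),
            all(geom$angles > angle_range[1]),
            all(geom$angles < angle_range[2]))
  fp
}

#' Sides and angles of a triangle
#'
#' Euclidean side lengths and law-of-cosines angles; `angles[k]` is the
#' angle at vertex `k` (opposite `sides[k]`). Angles sum to 180 degrees.
#'
#' @param p1,p2,p3 distinct 3-vectors.
#' @return list with `sides` (A; `sides[k]` opposite vertex k) and `angles`
#'   (degrees).
#' @export
triangle_geometry <- function(p1, p2, p3) {
  l1 <- sqrt(sum((p2 - p3)^2))  # opposite p1
  l2 <- sqrt(sum((p1 - p3)^2))
  l3 <- sqrt(sum((p1 - p2)^2))
  if (min(l1, l2, l3) < 1e-9) stop("coincident points in triangle")
  ang <- function(opp, a, b) {
    c_ <- (a^2 + b^2 - opp^2) / (2 * a * b)
    acos(pmin(1, pmax(-1, c_))) * 180 / pi
  }
  list(sides = c(l1, l2, l3),
       angles = c(ang(l1, l2, l3), ang(l2, l1, l3), ang(l3, l1, l2)))
}

#' Knob detection parameters
#'
#' @param neigh_radius radius (A) of the local neighbourhood whose heavy-atom
#'   centroid the candidate is compared against (default 6).
#' @param out_radius radius (A) of the protein-atom shell whose centroid
#'   defines the local outward direction (default 10).
#' @param convexity_min minimum convexity score (A) for a knob (default
#'   0.75).
#' @return a list of class `KnobParams`.
#' @export
knob_params <- function(neigh_radius = 6, out_radius = 10,
                        convexity_min = 0.75) {
  stopifnot(neigh_radius > 0, out_radius >= neigh_radius, convexity_min >= 0)
  structure(list(neigh_radius = neigh_radius, out_radius = out_radius,
                 convexity_min = convexity_min),
            class = "KnobParams")
}

#' Detect knobs on a protein contact surface
#'
#' Scores every contact-surface (P-CS) atom with a local-centroid convexity
#' heuristic: for atom position `a`, `m` is the centroid of all heavy atoms
#' within `neigh_radius`, `u` the unit vector from the centroid of
#' same-chain protein atoms within `out_radius` to `a` (a local outward
#' direction), and the convexity is `||a - m||` signed by `sign((a - m) . u)`
#' -- positive for atoms protruding from the surface, negative for atoms
#' pressed into concave contact pits. A knob is retained per amino acid:
#' its maximum-convexity atom among solvent-exposed atoms with convexity
#' above the threshold.
#'
#' @param surface a `ContactSurface`.
#' @param model the `StructureModel`.
#' @param sasa per-atom areas from [compute_sasa()] (required: knob apexes
#'   must be exposed).
#' @param params a [knob_params()] list.
#' @return data frame, one knob per amino acid: `chain`, `resno`, `insert`,
#'   `resid`, `apex_row`, `x`, `y`, `z`, `convexity`. May have zero rows.
#' @export
detect_knobs <- function(surface, model, sasa, params = knob_params()) {
  at <- model$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  cand <- surface$pcs_atoms[sasa[surface$pcs_atoms] > 0]
  empty <- data.frame(chain = character(0), resno = integer(0),
                      insert = character(0), resid = character(0),
                      apex_row = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), convexity = numeric(0))
  if (length(cand) == 0) return(empty)
  chain_rows <- which(at$chain == surface$protein_chain &
                        at$kind == "amino_acid")
  nb_all <- neighbor_pairs(xyz, xyz[cand, , drop = FALSE],
                           params$neigh_radius)
  nb_out <- neighbor_pairs(xyz[chain_rows, , drop = FALSE],
                           xyz[cand, , drop = FALSE], params$out_radius)
  conv <- vapply(seq_along(cand), function(k) {
    a <- xyz[cand[k], ]
    ns <- nb_all$i[nb_all$j == k]
    ns <- ns[ns != cand[k]]
    os <- chain_rows[nb_out$i[nb_out$j == k]]
    os <- os[os != cand[k]]
    if (length(ns) == 0 || length(os) == 0) return(0)
    m <- colMeans(xyz[ns, , drop = FALSE])
    cc <- colMeans(xyz[os, , drop = FALSE])
    u <- a - cc
    nu <- sqrt(sum(u^2))
    if (nu < 1e-9) return(0)
    disp <- a - m
    sign(sum(disp * u) / nu) * sqrt(sum(disp^2))
  }, numeric(1))
  keep <- conv > params$convexity_min
  if (!any(keep)) return(empty)
  cand <- cand[keep]; conv <- conv[keep]
  rkey <- residue_key(at[cand, ])
  best <- vapply(split(seq_along(cand), rkey),
                 function(ii) ii[which.max(conv[ii])], integer(1))
  rows <- cand[best]
  out <- data.frame(chain = at$chain[rows], resno = at$resno[rows],
                    insert = at$insert[rows], resid = at$resid[rows],
                    apex_row = rows,
                    x = at$x[rows], y = at$y[rows], z = at$z[rows],
                    convexity = conv[best], stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$resno, out$insert), ]
  rownames(out) <- NULL
  out
}

#' Enumerate candidate knob triplets per contacted nucleotide
#'
#' For each nucleotide contacted by the surface, forms every 3-subset of
#' the knobs whose amino acids contact that nucleotide (one knob per amino
#' acid, amino acids pairwise distinct). Deterministic order.
#'
#' @param knobs data frame from [detect_knobs()].
#' @param surface the `ContactSurface`.
#' @param model the `StructureModel`.
#' @return list of candidates: each a list with `nt` (list: chain, resno,
#'   insert, base), `knobs` (3-row slice of `knobs`), `coords` (3 x 3).
#' @export
enumerate_candidates <- function(knobs, surface, model) {
  if (nrow(knobs) < 3) return(list())
  at <- model$atoms
  pr <- surface$pairs
  nt_key <- residue_key(at[pr$rna_atom, ])
  aa_key <- residue_key(at[pr$protein_atom, ])
  knob_key <- paste(knobs$chain, knobs$resno, knobs$insert, sep = "|")
  out <- list()
  for (nk in sort(unique(nt_key))) {
    aas <- sort(unique(aa_key[nt_key == nk]))
    krows <- which(knob_key %in% aas)
    if (length(krows) < 3) next
    first <- pr$rna_atom[nt_key == nk][1]
    nt <- list(chain = at$chain[first], resno = at$resno[first],
               insert = at$insert[first], base = at$resid[first])
    combs <- utils::combn(krows, 3)
    for (c_ in seq_len(ncol(combs))) {
      tri <- knobs[combs[, c_], , drop = FALSE]
      out[[length(out) + 1]] <- list(
        nt = nt, knobs = tri,
        coords = as.matrix(tri[, c("x", "y", "z")]))
    }
  }
  out
}

#' Match a knob triplet against the tripod fingerprint
#'
#' Two gates: (1) all triangle sides within the fingerprint's side range
#' and all angles within its angle range (open intervals); (2) the best
#' rigid-superposition RMSD onto the canonical triangle over the 6 vertex
#' permutations is at most `rmsd_max`. Acceptance is invariant under rigid
#' motion and vertex permutation of the triplet.
#'
#' @param coords 3 x 3 matrix of knob apex coordinates.
#' @param fingerprint a [tripod_fingerprint()].
#' @return list with `best_rmsd` (NA when degenerate), `accepted`,
#'   `reason` (`""` when accepted).
#' @export
match_fingerprint <- function(coords, fingerprint) {
  geom <- tryCatch(triangle_geometry(coords[1, ], coords[2, ], coords[3, ]),
                   error = function(e) NULL)
  if (is.null(geom))
    return(list(best_rmsd = NA_real_, accepted = FALSE,
                reason = "degenerate triplet"))
  sr <- fingerprint$side_range; ar <- fingerprint$angle_range
  if (!all(geom$sides > sr[1] & geom$sides < sr[2]))
    return(list(best_rmsd = NA_real_, accepted = FALSE,
                reason = sprintf("side out of range (%.2f-%.2f)",
                                 min(geom$sides), max(geom$sides))))
  if (!all(geom$angles > ar[1] & geom$angles < ar[2]))
    return(list(best_rmsd = NA_real_, accepted = FALSE,
                reason = sprintf("angle out of range (%.1f-%.1f)",
                                 min(geom$angles), max(geom$angles))))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  rmsds <- vapply(perms, function(p)
    horn_superpose(coords[p, , drop = FALSE], fingerprint$points)$rmsd,
    numeric(1))
  best <- min(rmsds)
  if (best > fingerprint$rmsd_max)
    return(list(best_rmsd = best, accepted = FALSE,
                reason = sprintf("rmsd %.2f above threshold", best)))
  list(best_rmsd = best, accepted = TRUE, reason = "")
}

#' P-R-B acceptance filter
#'
#' A candidate nucleotide's contact counts must satisfy `B >= R`, `R >= P`
#' and `B > P`: extruded bases bind mainly through the base, then ribose,
#' then phosphate.
#'
#' @param p,r,b non-negative contact-pair counts (vectorized).
#' @return logical.
#' @export
filter_prb <- function(p, r, b) {
  (b >= r) & (r >= p) & (b > p)
}

format_aa <- function(resid, resno) {
  nm <- paste0(substr(resid, 1, 1), tolower(substr(resid, 2, 3)))
  paste0(nm, "-", resno)
}

#' Search a structure for tripod binding sites
#'
#' Full pipeline over every protein contact surface: knob detection,
#' per-nucleotide knob-triplet enumeration, fingerprint matching, and the
#' P-R-B filter. When annotations are supplied, candidate nucleotides are
#' restricted to residues not labelled `helix` (single-stranded context);
#' otherwise all contacted nucleotides are candidates. A hit's hydrogen-bond
#' flag is set when at least one hydrogen-bond-class contact touches the
#' nucleotide's base atoms.
#'
#' @param model a `StructureModel`.
#' @param contacts optional precomputed [find_contacts()] list.
#' @param annotations optional list of `MotifAnnotation` for the
#'   single-stranded restriction.
#' @param fingerprint a [tripod_fingerprint()].
#' @param cparams,sparams,kparams contact / surface / knob parameter lists.
#' @param sasa optional precomputed [compute_sasa()] vector.
#' @return data frame of `TripodInstance` rows sorted by (protein chain,
#'   nucleotide): `structure`, `nt_chain`, `nt_resno`, `base`, `aa1`-`aa3`
#'   (as `"Arg-212"`), `protein_chain`, `p`, `r`, `b`, `prb` (dash string),
#'   `match_rmsd`, `hbond`. Attribute `stage_counts` records per-stage
#'   candidate counts (knobs, triplets, geometry passes, accepted).
#' @export
search_tripods <- function(model, contacts = NULL, annotations = NULL,
                           fingerprint = tripod_fingerprint(),
                           cparams = contact_params(),
                           sparams = surface_params(),
                           kparams = knob_params(),
                           sasa = NULL) {
  if (is.null(contacts)) contacts <- find_contacts(model, cparams)
  if (is.null(sasa)) sasa <- compute_sasa(model, sparams)
  at <- model$atoms
  allowed_nt <- NULL
  if (!is.null(annotations) && length(annotations) > 0) {
    labels <- label_atoms(model, annotations)
    rows <- as.integer(names(labels))
    keys <- residue_key(at[rows, ])
    allowed_nt <- unique(keys[labels != "helix"])
  }
  hits <- list()
  n_knobs <- 0L; n_triplets <- 0L; n_geom <- 0L
  for (surface in contacts) {
    knobs <- detect_knobs(surface, model, sasa, kparams)
    n_knobs <- n_knobs + nrow(knobs)
    prb <- prb_counts(surface, model)
    prb_key <- paste(prb$chain, prb$resno, prb$insert, sep = "|")
    cands <- enumerate_candidates(knobs, surface, model)
    if (!is.null(allowed_nt)) {
      cands <- Filter(function(cd)
        paste(cd$nt$chain, cd$nt$resno, cd$nt$insert, sep = "|") %in%
          allowed_nt, cands)
    }
    n_triplets <- n_triplets + length(cands)
    pr <- surface$pairs
    pair_nt <- residue_key(at[pr$rna_atom, ])
    pair_grp <- rna_atom_group(at$name[pr$rna_atom])
    for (cd in cands) {
      m <- match_fingerprint(cd$coords, fingerprint)
      if (!m$accepted) next
      n_geom <- n_geom + 1L
      key <- paste(cd$nt$chain, cd$nt$resno, cd$nt$insert, sep = "|")
      row <- prb[match(key, prb_key), ]
      if (!filter_prb(row$p, row$r, row$b)) next
      hb <- any(pr$klass == "hbond" & pair_nt == key & pair_grp == "base")
      hits[[length(hits) + 1]] <- data.frame(
        structure = model$id,
        nt_chain = cd$nt$chain, nt_resno = cd$nt$resno,
        base = cd$nt$base,
        aa1 = format_aa(cd$knobs$resid[1], cd$knobs$resno[1]),
        aa2 = format_aa(cd$knobs$resid[2], cd$knobs$resno[2]),
        aa3 = format_aa(cd$knobs$resid[3], cd$knobs$resno[3]),
        protein_chain = surface$protein_chain,
        p = row$p, r = row$r, b = row$b,
        prb = paste(row$p, row$r, row$b, sep = "-"),
        match_rmsd = m$best_rmsd, hbond = hb,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits) > 0) do.call(rbind, hits) else
    data.frame(structure = character(0), nt_chain = character(0),
               nt_resno = integer(0), base = character(0),
               aa1 = character(0), aa2 = character(0), aa3 = character(0),
               protein_chain = character(0), p = integer(0), r = integer(0),
               b = integer(0), prb = character(0), match_rmsd = numeric(0),
               hbond = logical(0), stringsAsFactors = FALSE)
  out <- out[order(out$protein_chain, out$nt_chain, out$nt_resno), ]
  rownames(out) <- NULL
  attr(out, "stage_counts") <- c(knobs = n_knobs, triplets = n_triplets,
                                 geometry_pass = n_geom,
                                 accepted = nrow(out))
  out
}
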