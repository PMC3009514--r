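# Ground-truthed synthetic protein-RNA scenes.
#
# Two generators: rigid tetraloop copies dressed with backbone-hugging
# protein interface clouds (exercising superposition and interaction maps),
# and tripod binding sites with engineered knob triangles and P-R-B contact
# counts plus decoys violating each acceptance gate.

PHOSPHATE_ATOMS <- c("P", "OP1", "OP2")
RIBOSE_ATOMS <- c("O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'",
                  "C1'")
BASE_ATOMS <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
  C = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
  U = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6"))

#' Synthetic-scene specification
#'
#' Parameters of the synthetic generators. Defaults emulate the study
#' conditions of the analyses this package implements: eleven tetraloop
#' interfaces with the published per-interface atom counts (capped at the
#' 24 backbone atoms of the idealized loop), coordinate jitter 0.2 A
#' (the regime in which all pairwise tetraloop RMSDs stay below 1 A),
#' interface amino-acid frequencies drawn from the reported tetraloop
#' contact-surface composition, and three planted tripods plus one decoy
#' per violation class.
#'
#' @param seed integer RNG seed (required).
#' @param noise_sigma Gaussian jitter (A, per coordinate) applied to every
#'   atom.
#' @param n_tetraloops number of tetraloop copies.
#' @param n_interface_atoms integer vector (recycled) of interface-cloud
#'   sizes per tetraloop; at most 24 each.
#' @param planted_tripods list of tripod blueprints (see
#'   [tripod_blueprints()]).
#' @param decoys character vector of decoy class tags.
#' @return a list of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(seed, noise_sigma = 0.2, n_tetraloops = 11,
                           n_interface_atoms = NULL,
                           planted_tripods = NULL,
                           decoys = c("side_violation", "angle_violation",
                                      "prb_violation", "two_aa_site",
                                      "buried_knob")) {
  stopifnot(!missing(seed), noise_sigma >= 0, n_tetraloops >= 0)
  if (is.null(n_interface_atoms)) {
    n_interface_atoms <- pmin(ribosome_tetraloops()$n_atoms, 24L)
  }
  stopifnot(all(n_interface_atoms >= 1), all(n_interface_atoms <= 24))
  if (is.null(planted_tripods)) planted_tripods <- tripod_blueprints()
  structure(list(seed = as.integer(seed), noise_sigma = noise_sigma,
                 n_tetraloops = as.integer(n_tetraloops),
                 n_interface_atoms = as.integer(n_interface_atoms),
                 planted_tripods = planted_tripods, decoys = decoys),
            class = "SyntheticSpec")
}

#' Default planted-tripod blueprints
#'
#' Three true tripod sites whose triangles sit inside the fingerprint
#' ranges and whose engineered P-R-B contact counts satisfy the acceptance
#' relations; shapes follow reported instances (e.g. counts 2-4-11).
#'
#' @return list of blueprints: `sides` (A), `prb`, `base`, `hbond`, `aa`.
#' @export
tripod_blueprints <- function() {
  list(
    list(tag = "true_eq", sides = c(8.5, 8.5, 8.5), prb = c(2, 4, 11),
         base = "G", hbond = TRUE, aa = c("ARG", "SER", "LEU")),
    list(tag = "true_near_eq", sides = c(8.0, 8.5, 9.0), prb = c(0, 2, 7),
         base = "A", hbond = TRUE, aa = c("GLN", "LYS", "GLU")),
    list(tag = "true_scalene", sides = c(7.8, 8.8, 8.2), prb = c(1, 5, 9),
         base = "G", hbond = TRUE, aa = c("ARG", "ALA", "THR")))
}

decoy_blueprint <- function(tag) {
  switch(tag,
    side_violation = list(tag = tag, sides = c(8.5, 8.5, 12), prb = c(1, 3, 8),
                          base = "A", hbond = FALSE,
                          aa = c("LYS", "VAL", "ASN")),
    angle_violation = list(tag = tag, sides = c(7.2, 7.2, 9.9), prb = c(1, 3, 8),
                           base = "A", hbond = FALSE,
                           aa = c("ARG", "THR", "GLY")),
    prb_violation = list(tag = tag, sides = c(8.5, 8.5, 8.5), prb = c(1, 10, 5),
                         base = "C", hbond = FALSE,
                         aa = c("ARG", "GLU", "VAL")),
    two_aa_site = list(tag = tag, sides = c(8.5, 8.5, 8.5), prb = c(1, 3, 8),
                       base = "U", hbond = FALSE, aa = c("LYS", "SER")),
    buried_knob = list(tag = tag, sides = c(8.5, 8.5, 8.5), prb = c(0, 0, 3),
                       base = "A", hbond = FALSE,
                       aa = c("LEU", "HIS", "ASP"), buried = TRUE),
    stop("unknown decoy class: ", tag))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  quaternion_to_rotation(q / sqrt(sum(q^2)))
}

#' Idealized tetraloop backbone template
#'
#' A rigid 4-nucleotide, 24-atom backbone (P, O5', C5', C4', C3', O3' per
#' nucleotide) laid out as a helix-capped semicircular sweep around the
#' origin: atom directions sweep monotonically in azimuth with a modulated
#' zenith and radius, giving a non-planar, non-collinear rigid shape whose
#' atoms occupy well-separated directions from the loop centroid. One base
#' nitrogen per nucleotide is placed radially inward of the sugar.
#'
#' @return list with `backbone` (24 x 3 matrix), `positions` (1..4),
#'   `atom_names`, `base` (4 x 3 matrix), `base_names`, `sequence`.
#' @export
tetraloop_template <- function() {
  k <- 0:23
  phi <- (-150 + 13 * k) * pi / 180
  theta <- (90 + 25 * sin(2 * pi * k * 1.5 / 23)) * pi / 180
  r <- 9 + 0.6 * sin(5 * k)
  backbone <- cbind(r * sin(theta) * cos(phi),
                    r * sin(theta) * sin(phi),
                    r * cos(theta))
  backbone <- sweep(backbone, 2, colMeans(backbone))
  positions <- rep(1:4, each = 6)
  atom_names <- rep(c("P", "O5'", "C5'", "C4'", "C3'", "O3'"), 4)
  rownames(backbone) <- paste(positions, atom_names, sep = "_")
  c4 <- backbone[atom_names == "C4'", , drop = FALSE]
  base <- c4 * 0.6
  rownames(base) <- paste(1:4, "N1", sep = "_")
  list(backbone = backbone, positions = positions, atom_names = atom_names,
       base = base, base_names = rep("N1", 4), sequence = "GAAA")
}

#' Generate a synthetic tetraloop scene
#'
#' Copies the idealized tetraloop template under random rigid motions plus
#' Gaussian jitter and dresses each copy with a protein interface cloud
#' hugging the backbone: each interface atom is anchored to a distinct
#' backbone atom and offset radially outward from the loop centroid by
#' 2.2-4.0 A with only a small tangential scatter, so that after
#' superposition the interface concentrates over the four backbone regions
#' of the interaction map. Interface residues are drawn from the reported
#' tetraloop contact-surface amino-acid frequencies. Copies are laid out on
#' a lattice 70 A apart; each copy's interface is its own protein chain.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `model` (`StructureModel`), `annotations` (tetraloop
#'   `MotifAnnotation`s) and `truth` (per-copy true transforms, anchor
#'   assignments and interface residues).
#' @export
make_tetraloop_scene <- function(spec) {
  tpl <- tetraloop_template()
  aa_tab <- ribosome_pcs_composition()
  aa_prob <- aa_tab$tl_pcs / sum(aa_tab$tl_pcs)
  seqs <- ribosome_tetraloops()$sequence
  n <- spec$n_tetraloops
  sizes <- rep_len(spec$n_interface_atoms, max(n, 1))
  rows <- list()
  annotations <- list()
  truth <- list()
  serial <- 0
  withr::with_seed(spec$seed, {
    for (cp in seq_len(n)) {
      R <- random_rotation()
      tr <- c(((cp - 1) %% 3) * 70, (((cp - 1) %/% 3) %% 3) * 70,
              ((cp - 1) %/% 9) * 70) + stats::runif(3, -5, 5)
      place <- function(pts) {
        out <- sweep(as.matrix(pts) %*% t(R), 2, tr, "+")
        out + matrix(stats::rnorm(length(out), 0, spec$noise_sigma),
                     ncol = 3)
      }
      seq4 <- strsplit(seqs[[(cp - 1) %% length(seqs) + 1]], "")[[1]]
      res0 <- 100 * cp
      bb <- place(tpl$backbone)
      base <- place(tpl$base)
      rna <- data.frame(
        serial = serial + seq_len(28),
        name = c(tpl$atom_names, tpl$base_names),
        element = element_from_name(c(tpl$atom_names, tpl$base_names)),
        x = c(bb[, 1], base[, 1]), y = c(bb[, 2], base[, 2]),
        z = c(bb[, 3], base[, 3]),
        chain = "A",
        resno = res0 + c(tpl$positions, 1:4),
        insert = "", resid = seq4[c(tpl$positions, 1:4)],
        occ = 1, b = 0, stringsAsFactors = FALSE)
      serial <- serial + 28
      m <- sizes[[cp]]
      anchors <- sort(sample.int(24, m))
      anchor_pts <- tpl$backbone[anchors, , drop = FALSE]
      rad <- sqrt(rowSums(anchor_pts^2))
      off <- stats::runif(m, 2.2, 4.0)
      cloud <- anchor_pts * (1 + off / rad) +
        matrix(stats::rnorm(3 * m, 0, 0.15), ncol = 3)
      cloud <- place(cloud)
      resid <- sample(aa_tab$resid, m, replace = TRUE, prob = aa_prob)
      prot <- data.frame(
        serial = serial + seq_len(m),
        name = "CB", element = "C",
        x = cloud[, 1], y = cloud[, 2], z = cloud[, 3],
        chain = LETTERS[cp + 1],
        resno = seq_len(m), insert = "", resid = resid,
        occ = 1, b = 0, stringsAsFactors = FALSE)
      serial <- serial + m
      rows[[length(rows) + 1]] <- rna
      rows[[length(rows) + 1]] <- prot
      ann <- new_motif_annotation(
        motif_id = paste0("TL", res0 + 1), klass = "tetraloop",
        ranges = list(list(chain = "A", start = res0 + 1, end = res0 + 4)),
        sequence = paste(seq4, collapse = ""))
      annotations[[length(annotations) + 1]] <- ann
      truth[[length(truth) + 1]] <- list(
        copy = cp, rotation = R, translation = tr, anchors = anchors,
        interface_resid = resid, resno_start = res0 + 1)
    }
  })
  atoms <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(serial = integer(0), name = character(0),
               element = character(0), x = numeric(0), y = numeric(0),
               z = numeric(0), chain = character(0), resno = integer(0),
               insert = character(0), resid = character(0),
               occ = numeric(0), b = numeric(0), stringsAsFactors = FALSE)
  atoms$kind <- residue_kind(atoms$resid)
  model <- new_structure_model("synthetic_tetraloops", atoms)
  list(model = model, annotations = annotations, truth = truth)
}

# --- tripod scene -----------------------------------------------------------

triangle_vertices <- function(sides) {
  d12 <- sides[1]; d13 <- sides[2]; d23 <- sides[3]
  x <- (d12^2 + d13^2 - d23^2) / (2 * d12)
  y2 <- d13^2 - x^2
  if (y2 <= 0) stop("impossible triangle sides: ",
                    paste(sides, collapse = ", "))
  v <- rbind(c(0, 0, 0), c(d12, 0, 0), c(x, sqrt(y2), 0))
  sweep(v, 2, colMeans(v))
}

# Each contacted RNA atom sits on a narrow cone directly above one apex
# (radius 1.8 A, height 3.2 A): within contact range (4.5 A) of that apex
# and of nothing else, so every slot atom contributes exactly one contact
# pair. Atoms that must contribute two pairs hover over a triangle-side
# midpoint at low elevation, in range of both flanking apexes only. An
# H-bond is realized by one N/O base atom on a tighter cone (3.3 A) over a
# nitrogen apex.
build_tripod_site <- function(bp, nt_resno, aa_resno0) {
  n_aa <- length(bp$aa)
  verts <- triangle_vertices(bp$sides)
  apex_xy <- verts[seq_len(n_aa), 1:2, drop = FALSE]
  buried <- isTRUE(bp$buried)
  hbond <- isTRUE(bp$hbond)
  p_req <- bp$prb[1]; r_req <- bp$prb[2]; b_req <- bp$prb[3]
  base_names <- BASE_ATOMS[[bp$base]]
  if (b_req < n_aa + as.integer(hbond))
    stop("blueprint '", bp$tag, "': base count too small for the apexes")
  designated <- base_names[seq_len(n_aa)]
  rest_base <- setdiff(base_names, designated)
  hb_name <- NULL
  if (hbond) {
    rest_base <- rest_base[order(!grepl("^[NO]", rest_base))]
    if (length(rest_base) < 1 || !grepl("^[NO]", rest_base[1]))
      stop("blueprint '", bp$tag, "': cannot realize an H-bond contact")
    hb_name <- rest_base[1]
    rest_base <- rest_base[-1]
  }
  b_extra <- b_req - n_aa - as.integer(hbond)
  alloc <- function(req, pool) {
    n_dbl <- max(0L, req - length(pool))
    n_sng <- req - 2L * n_dbl
    if (n_sng < 0)
      stop("blueprint '", bp$tag, "': requested counts unreachable")
    list(single = pool[seq_len(n_sng)],
         double = if (n_dbl > 0) pool[n_sng + seq_len(n_dbl)]
                  else character(0))
  }
  a_p <- alloc(p_req, PHOSPHATE_ATOMS)
  a_r <- alloc(r_req, RIBOSE_ATOMS)
  a_b <- alloc(b_extra, rest_base)
  singles <- c(a_p$single, a_r$single, a_b$single)
  doubles <- c(a_p$double, a_r$double, a_b$double)
  aa_pairs <- if (n_aa >= 2) utils::combn(n_aa, 2) else
    matrix(integer(0), nrow = 2)
  if (length(singles) > 6 * n_aa || length(doubles) > ncol(aa_pairs))
    stop("blueprint '", bp$tag, "': requested counts unreachable")

  rna <- data.frame(name = character(0), element = character(0),
                    x = numeric(0), y = numeric(0), z = numeric(0),
                    stringsAsFactors = FALSE)
  add_rna <- function(name, p) {
    rna[nrow(rna) + 1, ] <<- list(name, element_from_name(name),
                                  p[1], p[2], p[3])
  }
  prot <- list()
  add_aa_atom <- function(aa_idx, name, element, p) {
    prot[[length(prot) + 1]] <<- data.frame(
      aa = aa_idx, name = name, element = element,
      x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
  }
  for (k in seq_len(n_aa)) {
    apex <- c(apex_xy[k, ], 0)
    if (hbond && k == 1) add_aa_atom(k, "NZ", "N", apex)
    else add_aa_atom(k, "CB", "C", apex)
    if (!buried) {
      # 24-atom pedestal: four stacked rings below the apex
      radii <- c(1.1, 1.1, 0.8, 0.5)
      depth <- c(-2.0, -2.8, -3.6, -4.4)
      q <- 0
      for (ring in 1:4) {
        az <- seq(0, 2 * pi, length.out = 7)[-7] + 0.3 * ring
        for (a in az) {
          q <- q + 1
          add_aa_atom(k, sprintf("C%02d", q), "C",
                      apex + c(radii[ring] * cos(a), radii[ring] * sin(a),
                               depth[ring]))
        }
      }
    } else {
      # cage at apex level: no protrusion, convexity stays low
      az <- seq(0, 2 * pi, length.out = 5)[-5]
      for (q in seq_along(az))
        add_aa_atom(k, sprintf("C%02d", q), "C",
                    apex + c(1.5 * cos(az[q]), 1.5 * sin(az[q]), 0))
      for (q in seq_along(az))
        add_aa_atom(k, sprintf("C%02d", q + 4), "C",
                    apex + c(cos(az[q] + 0.7), sin(az[q] + 0.7), -1.5))
    }
    # designated base contact right above the apex (higher over a cage so
    # the cage atoms stay out of contact range)
    add_rna(designated[k], c(apex[1], apex[2], if (buried) 4.3 else 3.8))
  }
  if (hbond)
    add_rna(hb_name, c(apex_xy[1, ] + c(cos(0.5), sin(0.5)) * 1.0, 3.15))
  # single-pair slot atoms, round-robin over the apexes
  ring_used <- integer(n_aa)
  for (nm in singles) {
    k <- which.min(ring_used)
    ring_used[k] <- ring_used[k] + 1L
    az <- (ring_used[k] - 1) * pi / 3 + 0.25 + 0.7 * k
    add_rna(nm, c(apex_xy[k, ] + 1.8 * c(cos(az), sin(az)), 3.2))
  }
  # double-pair atoms over triangle-side midpoints
  for (d in seq_along(doubles)) {
    ij <- aa_pairs[, d]
    mid <- colMeans(apex_xy[ij, , drop = FALSE])
    add_rna(doubles[d], c(mid, 1.3))
  }
  # non-contacted nucleotide atoms, far above everything
  far <- setdiff(base_names, c(designated, hb_name))
  far <- c(setdiff(PHOSPHATE_ATOMS, a_p$single),
           setdiff(RIBOSE_ATOMS, c(a_r$single, a_r$double)),
           setdiff(far, c(a_b$single, a_b$double)))
  far <- setdiff(far, doubles)
  if (length(far) > 0) {
    az <- seq(0, 2 * pi, length.out = length(far) + 1)[seq_along(far)]
    for (q in seq_along(far))
      add_rna(far[q], c(3 * cos(az[q]), 3 * sin(az[q]), 10))
  }
  prot <- do.call(rbind, prot)
  # verify the realized contact counts against the request
  d <- sqrt(outer(rna$x, prot$x, "-")^2 + outer(rna$y, prot$y, "-")^2 +
              outer(rna$z, prot$z, "-")^2)
  pairs_per_atom <- rowSums(d <= 4.5)
  got <- c(sum(pairs_per_atom[rna_atom_group(rna$name) == "phosphate"]),
           sum(pairs_per_atom[rna_atom_group(rna$name) == "ribose"]),
           sum(pairs_per_atom[rna_atom_group(rna$name) == "base"]))
  if (!all(got == bp$prb))
    stop("blueprint '", bp$tag, "': realized P-R-B counts ",
         paste(got, collapse = "-"), " differ from requested ",
         paste(bp$prb, collapse = "-"))
  list(rna = rna, prot = prot, nt_resno = nt_resno,
       aa_resno = aa_resno0 + seq_len(n_aa), apex_xyz = cbind(apex_xy, 0))
}

#' Generate a synthetic tripod scene
#'
#' Plants tripod binding sites -- one extruded nucleotide cradled by three
#' single-residue amino acids whose convex apex atoms sit at the vertices
#' of a prescribed triangle -- with contact pairs engineered to realize the
#' requested P-R-B counts exactly, plus decoy sites violating one gate
#' each: a 12 A side, an 89.5 deg angle, an inverted P-R-B profile, a
#' two-amino-acid site, and non-protruding (buried) knobs. Sites are spaced
#' 50 A apart under independent random rigid motions; Gaussian jitter
#' `noise_sigma` is applied to all atoms.
#'
#' @param spec a [synthetic_spec()]; `spec$planted_tripods` and
#'   `spec$decoys` select the sites.
#' @return list with `model` (`StructureModel`) and `truth` (data frame per
#'   site: `tag`, `true`, `nt_resno`, `base`, `p`, `r`, `b`, `hbond`).
#' @export
make_tripod_scene <- function(spec) {
  bps <- c(spec$planted_tripods, lapply(spec$decoys, decoy_blueprint))
  rows <- list()
  truth <- list()
  serial <- 0
  withr::with_seed(spec$seed, {
    for (si in seq_along(bps)) {
      bp <- bps[[si]]
      site <- build_tripod_site(bp, nt_resno = 100 * si,
                                aa_resno0 = 10 * si)
      R <- random_rotation()
      tr <- c((si - 1) * 50, 0, 0)
      place <- function(m) {
        out <- sweep(as.matrix(m) %*% t(R), 2, tr, "+")
        out + matrix(stats::rnorm(length(out), 0, spec$noise_sigma),
                     ncol = 3)
      }
      rxyz <- place(site$rna[, c("x", "y", "z")])
      rows[[length(rows) + 1]] <- data.frame(
        serial = serial + seq_len(nrow(site$rna)),
        name = site$rna$name, element = site$rna$element,
        x = rxyz[, 1], y = rxyz[, 2], z = rxyz[, 3],
        chain = "R", resno = site$nt_resno, insert = "",
        resid = bp$base, occ = 1, b = 0, stringsAsFactors = FALSE)
      serial <- serial + nrow(site$rna)
      pxyz <- place(site$prot[, c("x", "y", "z")])
      rows[[length(rows) + 1]] <- data.frame(
        serial = serial + seq_len(nrow(site$prot)),
        name = site$prot$name, element = site$prot$element,
        x = pxyz[, 1], y = pxyz[, 2], z = pxyz[, 3],
        chain = "P", resno = site$aa_resno[site$prot$aa], insert = "",
        resid = bp$aa[site$prot$aa], occ = 1, b = 0,
        stringsAsFactors = FALSE)
      serial <- serial + nrow(site$prot)
      truth[[length(truth) + 1]] <- data.frame(
        tag = bp$tag, true = grepl("^true", bp$tag),
        nt_resno = site$nt_resno, base = bp$base,
        p = bp$prb[1], r = bp$prb[2], b = bp$prb[3],
        hbond = isTRUE(bp$hbond), stringsAsFactors = FALSE)
    }
  })
  atoms <- do.call(rbind, rows)
  atoms$kind <- residue_kind(atoms$resid)
  model <- new_structure_model("synthetic_tripods", atoms)
  list(model = model, truth = do.call(rbind, truth))
}

#' Write a synthetic fixture to disk
#'
#' Writes `scene.pdb`, `annotations.json` and `truth.json` into a
#' directory; [read_structure()] round-trips the PDB. Byte-deterministic
#' for a fixed-seed scene.
#'
#' @param model `StructureModel`.
#' @param annotations list of `MotifAnnotation` (may be empty/NULL).
#' @param truth any JSON-serializable ground-truth object.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_fixture <- function(model, annotations, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_structure(model, file.path(dir, "scene.pdb"))
  if (!is.null(annotations))
    write_annotations(annotations, file.path(dir, "annotations.json"))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
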