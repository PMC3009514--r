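# End-to-end analyses: composition tables, tetraloop interaction maps,
# tripod search.

BACKBONE_ORDER <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")

#' Extract tetraloop backbones and their protein interfaces
#'
#' For each tetraloop annotation, collects the loop's backbone atoms
#' (P, O5', C5', C4', C3', O3' per nucleotide, canonical order, rownames
#' `"<position>_<name>"`) and the protein atoms in contact with any of the
#' loop's residues (its interface), with per-atom residue metadata.
#'
#' @param model a `StructureModel`.
#' @param annotations list of `MotifAnnotation` (only tetraloops used).
#' @param contacts [find_contacts()] result.
#' @return list per tetraloop: `motif_id`, `backbone` (matrix), `positions`,
#'   `atom_names`, `interface` (matrix, may be 0-row), `interface_meta`
#'   (data frame `resid`, `class`, `chain`, `resno`).
#' @export
tetraloop_inputs <- function(model, annotations, contacts) {
  at <- model$atoms
  tls <- Filter(function(a) a$klass == "tetraloop", annotations)
  lapply(tls, function(a) {
    r <- a$ranges[[1]]
    resnos <- seq.int(r$start, r$end)
    bb_rows <- integer(0); positions <- integer(0); names_ <- character(0)
    for (pos in seq_along(resnos)) {
      res_rows <- which(at$chain == r$chain & at$resno == resnos[pos])
      for (nm in BACKBONE_ORDER) {
        hit <- res_rows[at$name[res_rows] == nm]
        if (length(hit) == 1) {
          bb_rows <- c(bb_rows, hit)
          positions <- c(positions, pos)
          names_ <- c(names_, nm)
        }
      }
    }
    backbone <- as.matrix(at[bb_rows, c("x", "y", "z")])
    rownames(backbone) <- paste(positions, names_, sep = "_")
    loop_rows <- which(at$chain == r$chain & at$resno %in% resnos)
    intf_rows <- integer(0)
    for (s in contacts) {
      hit <- s$pairs$protein_atom[s$pairs$rna_atom %in% loop_rows]
      intf_rows <- c(intf_rows, hit)
    }
    intf_rows <- sort(unique(intf_rows))
    list(motif_id = a$motif_id,
         backbone = backbone, positions = positions, atom_names = names_,
         interface = as.matrix(at[intf_rows, c("x", "y", "z")]),
         interface_meta = data.frame(resid = at$resid[intf_rows],
                                     class = aa_class(at$resid[intf_rows]),
                                     chain = at$chain[intf_rows],
                                     resno = at$resno[intf_rows],
                                     stringsAsFactors = FALSE))
  })
}

#' Interface composition analysis
#'
#' Computes the RNA-element frequency table (whole RNA / RNA surface /
#' RNA contact surface) when annotations are given, and the contact-surface
#' composition tables: RNA-side atom types with their
#' phosphate/ribose/base summary, and protein-side residues -- each for the
#' full contact surface and restricted to structural motifs and to
#' tetraloops -- with interface-level bootstrap standard errors.
#'
#' @param model a `StructureModel`.
#' @param annotations optional list of `MotifAnnotation`.
#' @param cparams,sparams contact and surface parameter lists.
#' @param boot a [bootstrap_params()] list (or NULL to skip SEs).
#' @param sasa optional precomputed SASA vector (computed when needed).
#' @return list with `element_frequencies` (or NULL), `rcs` tables
#'   (`atoms`, `prb`, `se`), `sm_rcs`, `tl_rcs`, `pcs`, `sm_pcs`, `tl_pcs`,
#'   and `surfaces` (the contact list).
#' @export
run_composition <- function(model, annotations = NULL,
                            cparams = contact_params(),
                            sparams = surface_params(),
                            boot = NULL, sasa = NULL) {
  contacts <- find_contacts(model, cparams)
  if (length(contacts) == 0) stop("no protein-RNA contacts found")
  at <- model$atoms
  labels <- NULL
  element_freq <- NULL
  if (!is.null(annotations) && length(annotations) > 0) {
    labels <- label_atoms(model, annotations)
    rna_rows <- as.integer(names(labels))
    if (is.null(sasa)) sasa <- compute_sasa(model, sparams)
    surf <- intersect(rna_rows, surface_atoms(sasa, sparams))
    rcs_rows <- sort(unique(unlist(lapply(contacts, `[[`, "rcs_atoms"))))
    lab_of <- function(rows) labels[as.character(rows)]
    element_freq <- list(
      whole = composition(lab_of(rna_rows)),
      surface = composition(lab_of(surf)),
      rcs = composition(lab_of(rcs_rows)))
  } else if (!is.null(annotations)) {
    warning("no annotations supplied; element-frequency section skipped")
  }
  motif_rows <- if (!is.null(labels))
    as.integer(names(labels))[labels == "motif"] else integer(0)
  tl_rows <- integer(0)
  if (!is.null(annotations)) {
    for (a in Filter(function(x) x$klass == "tetraloop", annotations)) {
      for (r in a$ranges)
        tl_rows <- c(tl_rows, which(at$chain == r$chain &
                                      at$resno >= r$start &
                                      at$resno <= r$end))
    }
  }
  side_tables <- function(restrict_rows = NULL) {
    rna_groups <- list(); prot_groups <- list()
    for (s in contacts) {
      rr <- s$rcs_atoms; pp <- s$pcs_atoms
      if (!is.null(restrict_rows)) {
        keep <- s$pairs$rna_atom %in% restrict_rows
        rr <- sort(unique(s$pairs$rna_atom[keep]))
        pp <- sort(unique(s$pairs$protein_atom[keep]))
      }
      if (length(rr) > 0) rna_groups[[length(rna_groups) + 1]] <- at$name[rr]
      if (length(pp) > 0)
        prot_groups[[length(prot_groups) + 1]] <- at$resid[pp]
    }
    if (length(rna_groups) == 0) return(NULL)
    rna_items <- unlist(rna_groups); prot_items <- unlist(prot_groups)
    atoms_tab <- composition(rna_items)
    res <- list(atoms = atoms_tab,
                prb = prb_summary(atoms_tab, complete = FALSE),
                residues = composition(prot_items))
    if (!is.null(boot)) {
      res$atoms_se <- bootstrap_se(rna_groups, boot)
      res$residues_se <- bootstrap_se(prot_groups, boot)
    }
    res
  }
  list(element_frequencies = element_freq,
       rcs = side_tables(),
       sm_rcs = if (length(motif_rows) > 0) side_tables(motif_rows),
       tl_rcs = if (length(tl_rows) > 0) side_tables(tl_rows),
       surfaces = contacts)
}

#' Tetraloop interaction-map analysis
#'
#' Superposes all annotated tetraloops onto a reference by their backbone
#' atoms, carries the protein interfaces through the transforms, projects
#' everything onto the reference sphere, chooses the quantization step,
#' and builds the density map, majority property map and the four backbone
#' regions with the in-region atom fraction.
#'
#' @param model a `StructureModel`.
#' @param annotations list of `MotifAnnotation` with >= 2 tetraloops having
#'   non-empty interfaces.
#' @param ref_index reference tetraloop (among those with interfaces).
#' @param exclude character vector of `motif_id`s to leave out.
#' @param cparams contact parameters.
#' @param step_candidates candidate steps for [choose_step()].
#' @return list with `rmsd` (named per tetraloop), `step`, `grid`,
#'   `properties`, `regions`, `coverage`, `frame`, `tetraloops`.
#' @export
run_map <- function(model, annotations, ref_index = 1, exclude = NULL,
                    cparams = contact_params(),
                    step_candidates = rev(seq(0.5, 30, by = 0.5)) * pi / 180) {
  contacts <- find_contacts(model, cparams)
  tls <- tetraloop_inputs(model, annotations, contacts)
  if (!is.null(exclude))
    tls <- Filter(function(t) !(t$motif_id %in% exclude), tls)
  tls <- Filter(function(t) nrow(t$interface) > 0, tls)
  if (length(tls) < 2)
    stop("need at least 2 tetraloops with non-empty interfaces, got ",
         length(tls))
  sup <- superpose_interfaces(tls, ref_index)
  rmsd <- vapply(sup, function(s) s$result$rmsd, numeric(1))
  names(rmsd) <- vapply(tls, `[[`, "", "motif_id")
  ref <- tls[[ref_index]]
  frame <- reference_frame(ref$backbone, ref$positions, ref$atom_names)
  interfaces <- lapply(seq_along(sup), function(k) {
    pr <- project_to_sphere(sup[[k]]$interface, frame)
    cbind(pr, tls[[k]]$interface_meta)
  })
  bb_proj <- do.call(rbind, lapply(seq_along(sup), function(k) {
    pr <- project_to_sphere(sup[[k]]$backbone, frame)
    pr$position <- tls[[k]]$positions
    pr
  }))
  step <- choose_step(interfaces, step_candidates)
  grid <- build_map(interfaces, step)
  regions <- mark_regions(bb_proj, step)
  list(rmsd = rmsd, step = step, grid = grid,
       properties = property_map(grid), regions = regions,
       coverage = region_coverage(grid, regions),
       frame = frame, tetraloops = tls)
}

#' Tripod search analysis
#'
#' Runs [search_tripods()] over all protein contact surfaces and reports
#' the instances together with the per-stage candidate counts.
#'
#' @inheritParams search_tripods
#' @return the instance data frame (see [search_tripods()]); stage counts
#'   in `attr(, "stage_counts")`.
#' @export
run_tripods <- function(model, annotations = NULL,
                        fingerprint = tripod_fingerprint(),
                        cparams = contact_params(),
                        sparams = surface_params(),
                        kparams = knob_params()) {
  search_tripods(model, contacts = NULL, annotations = annotations,
                 fingerprint = fingerprint, cparams = cparams,
                 sparams = sparams, kparams = kparams)
}
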