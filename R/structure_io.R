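# Structure reading, atom typing, solvent accessibility.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL", "MSE", "SEC", "PYL")

NT_RESID <- c("A", "U", "G", "C", "I", "DA", "DT", "DG", "DC", "DI",
              "RA", "RU", "RG", "RC", "+A", "+U", "+G", "+C")

SOLVENT_RESID <- c("HOH", "WAT", "DOD", "H2O", "SOL")

#' Residue kind from a residue name
#'
#' Classifies a residue name into `amino_acid`, `nucleotide` or `other`
#' using a fixed lookup of standard (and a few common modified) names.
#'
#' @param res_name character vector of PDB residue names.
#' @return character vector in `{"amino_acid", "nucleotide", "other"}`.
#' @export
residue_kind <- function(res_name) {
  rn <- toupper(trimws(res_name))
  out <- rep("other", length(rn))
  out[rn %in% AA3] <- "amino_acid"
  out[rn %in% NT_RESID] <- "nucleotide"
  out
}

#' Surface / SASA parameters
#'
#' @param probe_radius probe sphere radius in Angstrom. The default 1.5 A
#'   matches the probe used for the interface-area computations this package
#'   reproduces (rather than the more common 1.4 A).
#' @param n_sphere_points number of quadrature points per atom sphere
#'   (deterministic golden-spiral construction); at least 92.
#' @param surface_sasa_min area threshold (A^2) above which an atom is
#'   called a surface atom.
#' @return a list of class `SurfaceParams`.
#' @export
surface_params <- function(probe_radius = 1.5, n_sphere_points = 960,
                           surface_sasa_min = 0.1) {
  stopifnot(probe_radius > 0, n_sphere_points >= 92, surface_sasa_min >= 0)
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 surface_sasa_min = surface_sasa_min),
            class = "SurfaceParams")
}

# van der Waals radii (A); unknown elements fall back to carbon.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80)

vdw_radius <- function(element) {
  el <- toupper(trimws(element))
  r <- unname(VDW_RADII[el])
  bad <- is.na(r)
  if (any(bad)) {
    warning("unknown element(s) ", paste(unique(el[bad]), collapse = ", "),
            "; using 1.70 A")
    r[bad] <- 1.70
  }
  r
}

# Normalize legacy atom names: O1P/O2P -> OP1/OP2, '*' -> "'".
normalize_atom_name <- function(name) {
  nm <- gsub("*", "'", trimws(name), fixed = TRUE)
  nm[nm == "O1P"] <- "OP1"
  nm[nm == "O2P"] <- "OP2"
  nm
}

element_from_name <- function(name) {
  # first alphabetic character of the stripped atom name
  sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", name)
}

new_structure_model <- function(id, atoms) {
  rownames(atoms) <- NULL
  atoms$serial <- as.integer(atoms$serial)
  atoms$resno <- as.integer(atoms$resno)
  # per-chain polymer class by residue-kind vote
  chains <- unique(atoms$chain)
  pc <- vapply(chains, function(ch) {
    res <- unique(atoms[atoms$chain == ch,
                        c("resno", "insert", "resid", "kind")])
    tab <- table(res$kind)
    kinds <- names(tab)[tab == max(tab)]
    k <- kinds[[1]]
    switch(k, amino_acid = "protein", nucleotide = "rna", "other")
  }, character(1))
  structure(list(id = id,
                 atoms = atoms,
                 chains = data.frame(chain = chains,
                                     polymer_class = unname(pc),
                                     stringsAsFactors = FALSE)),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel", x$id, "-", nrow(x$atoms), "heavy atoms,",
      nrow(x$chains), "chains (",
      paste0(x$chains$chain, ":", x$chains$polymer_class, collapse = " "),
      ")\n")
  invisible(x)
}

residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
}

# Pre-validate ATOM/HETATM records of a PDB file so malformed lines are
# reported with their line number before bio3d sees the file.
validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(rec)
  for (i in idx) {
    ln <- lines[[i]]
    if (nchar(ln) < 54)
      stop("parse error in '", path, "' at line ", i,
           ": truncated ATOM/HETATM record", call. = FALSE)
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords))))
      stop("parse error in '", path, "' at line ", i,
           ": non-numeric coordinate field", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a protein-RNA complex structure
#'
#' Reads a PDB or mmCIF file into a `StructureModel`. Hydrogens and solvent
#' are dropped, alternate locations are resolved to the highest-occupancy
#' copy (ties: first in file), legacy atom names are normalized
#' (`O1P -> OP1`, `C1* -> C1'`), and each chain is classified as
#' `protein`/`rna`/`other` by a residue-kind vote. Only the first model of
#' multi-model files is used.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param id entry label; defaults to the file base name.
#' @return a `StructureModel`: a list with `id`, an `atoms` data frame
#'   (serial, name, element, x, y, z, chain, resno, insert, resid, kind,
#'   occ, b) and a `chains` data frame (chain, polymer_class).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "pdb") {
    validate_pdb_lines(path)
    pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                           verbose = FALSE)
  } else {
    # muffle bio3d's advisory warnings on its cif reader; real parse
    # failures still surface as errors
    pdb <- withCallingHandlers(
      bio3d::read.cif(path, verbose = FALSE),
      warning = function(w) {
        if (grepl("beta version|helix/sheet", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  at <- pdb$atom
  el <- trimws(at$elesy)
  noel <- is.na(el) | el == ""
  el[noel] <- element_from_name(at$elety[noel])
  el <- toupper(el)
  keep <- !(el %in% c("H", "D")) & !(toupper(at$resid) %in% SOLVENT_RESID)
  at <- at[keep, , drop = FALSE]
  el <- el[keep]
  if (nrow(at) == 0) stop("no heavy atoms in ", path)
  atoms <- data.frame(serial = at$eleno,
                      name = normalize_atom_name(at$elety),
                      element = el,
                      x = at$x, y = at$y, z = at$z,
                      chain = ifelse(is.na(at$chain), "", at$chain),
                      resno = at$resno,
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      resid = toupper(trimws(at$resid)),
                      occ = ifelse(is.na(at$o), 1, at$o),
                      b = ifelse(is.na(at$b), 0, at$b),
                      stringsAsFactors = FALSE)
  # altloc: keep highest occupancy per (chain, resno, insert, name)
  alt <- if (!is.null(at$alt)) ifelse(is.na(at$alt), "", at$alt) else ""
  if (any(alt != "")) {
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name)
    ord <- order(key, -atoms$occ, seq_len(nrow(atoms)))
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno,
                                     atoms$insert, atoms$name)), ,
                   drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }
  atoms$kind <- residue_kind(atoms$resid)
  new_structure_model(id, atoms)
}

#' Write a minimal PDB file
#'
#' Writes `ATOM`/`TER`/`END` records for a `StructureModel`; coordinates are
#' kept to three decimals. Intended for synthetic models and transformed
#' interfaces; it is not a general-purpose PDB writer.
#'
#' @param model a `StructureModel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  at <- model$atoms
  recs <- sprintf(
    "ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    at$serial %% 100000,
    ifelse(nchar(at$name) >= 4, at$name, paste0(" ", at$name)),
    " ", substr(at$resid, 1, 3), substr(at$chain, 1, 1), at$resno %% 10000,
    ifelse(at$insert == "", " ", substr(at$insert, 1, 1)),
    at$x, at$y, at$z, at$occ, at$b, at$element)
  # atoms kept in input order; TER wherever the chain changes
  n <- length(recs)
  lines <- character(0)
  if (n > 0) {
    breaks <- c(which(at$chain[-1] != at$chain[-n]), n)
    prev <- 0
    for (b in breaks) {
      lines <- c(lines, recs[(prev + 1):b], "TER")
      prev <- b
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Phosphate / ribose / base group of an RNA atom name
#'
#' Partitions nucleotide heavy-atom names into the three chemical groups
#' used throughout interface composition statistics: phosphate
#' `{P, OP1, OP2}`, ribose `{O5', C5', C4', O4', C3', O3', C2', O2', C1'}`,
#' and everything else (the base). Legacy `O1P`/`O2P` and `*`-primed names
#' are normalized first. Total on heavy-atom names.
#'
#' @param atom_name character vector of atom names.
#' @return character vector in `{"phosphate", "ribose", "base"}`.
#' @export
rna_atom_group <- function(atom_name) {
  nm <- normalize_atom_name(atom_name)
  phosphate <- c("P", "OP1", "OP2")
  ribose <- c("O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'")
  out <- rep("base", length(nm))
  out[nm %in% phosphate] <- "phosphate"
  out[nm %in% ribose] <- "ribose"
  out
}

# Deterministic golden-spiral points on the unit sphere.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA by rolling a probe sphere over the heavy atoms: each atom's
#' sphere of radius `r_vdw + probe` is sampled at `n_sphere_points`
#' deterministic golden-spiral points; a point is accessible when outside
#' every neighbouring expanded sphere. Deterministic for fixed parameters.
#'
#' @param model a `StructureModel`.
#' @param params a [surface_params()] list.
#' @return numeric vector of areas (A^2), one per atom row of `model$atoms`.
#' @export
compute_sasa <- function(model, params = surface_params()) {
  at <- model$atoms
  n <- nrow(at)
  if (n == 0) stop("empty model")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- vdw_radius(at$element) + params$probe_radius
  pts <- sphere_points(params$n_sphere_points)
  # neighbour candidates within the maximal contact distance of two spheres
  cutoff <- 2 * max(rad)
  nb <- neighbor_pairs(xyz, xyz, cutoff)
  nb <- nb[nb$i != nb$j, , drop = FALSE]
  # keep only true sphere overlaps
  nb <- nb[nb$dist < rad[nb$i] + rad[nb$j], , drop = FALSE]
  nb_list <- split(nb$j, factor(nb$i, levels = seq_len(n)))
  area <- numeric(n)
  for (i in seq_len(n)) {
    js <- nb_list[[i]]
    full <- 4 * pi * rad[i]^2
    if (length(js) == 0) {
      area[i] <- full
      next
    }
    p <- pts * rad[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    acc <- rep(TRUE, nrow(p))
    for (j in js) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & (d2 > rad[j]^2)
      if (!any(acc)) break
    }
    area[i] <- full * sum(acc) / nrow(p)
  }
  area
}

#' Surface atoms by SASA threshold
#'
#' @param sasa per-atom areas from [compute_sasa()].
#' @param params a [surface_params()] list; atoms with
#'   `sasa > surface_sasa_min` are surface atoms.
#' @return integer vector of atom row indices.
#' @export
surface_atoms <- function(sasa, params = surface_params()) {
  which(sasa > params$surface_sasa_min)
}
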