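# Polar interaction maps: project superposed interface atoms onto a sphere
# around the reference tetraloop, discretize in (zenith, azimuth), accumulate
# densities, mark the four nucleotide-backbone regions and color cells by
# majority physicochemical class.

#' Intrinsic reference frame of a tetraloop backbone
#'
#' Origin at the backbone centroid; axes are the principal axes of the
#' backbone coordinates with signs fixed deterministically: the first axis
#' points toward the P atom of nucleotide 1 (fallback: first atom of
#' position 1), the third axis toward the loop apex (centroid of positions
#' 2 and 3), and the second axis completes a right-handed orthonormal
#' triad. Equivariant under rigid motion of the backbone.
#'
#' @param backbone n x 3 matrix of backbone coordinates (n >= 3,
#'   non-collinear).
#' @param positions integer vector (1..4) giving the nucleotide position of
#'   each backbone row.
#' @param atom_names character vector of atom names per row.
#' @return list with `origin` (length 3) and `axes` (3x3 matrix, columns =
#'   axes 1..3, right-handed).
#' @export
reference_frame <- function(backbone, positions, atom_names) {
  backbone <- as.matrix(backbone)
  stopifnot(nrow(backbone) >= 3, length(positions) == nrow(backbone),
            length(atom_names) == nrow(backbone))
  origin <- colMeans(backbone)
  centered <- sweep(backbone, 2, origin)
  sv <- svd(centered)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate geometry: backbone is collinear")
  eg <- eigen(stats::cov(centered), symmetric = TRUE)
  e1 <- eg$vectors[, 1]; e3 <- eg$vectors[, 3]
  p1 <- which(positions == 1 & atom_names == "P")
  if (length(p1) == 0) p1 <- which(positions == 1)
  if (length(p1) == 0) p1 <- 1
  ref1 <- centered[p1[1], ]
  if (sum(e1 * ref1) < 0) e1 <- -e1
  apex_rows <- which(positions %in% c(2, 3))
  if (length(apex_rows) == 0) apex_rows <- seq_len(nrow(backbone))
  apex <- colMeans(centered[apex_rows, , drop = FALSE])
  if (sum(e3 * apex) < 0) e3 <- -e3
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  list(origin = origin, axes = cbind(e1, e2, e3, deparse.level = 0))
}

#' Project points onto the unit sphere of a frame
#'
#' Expresses points in the frame and keeps only their direction: zenith
#' `theta` in `[0, pi]` is the angle from the third axis, azimuth `phi` in
#' `[-pi, pi)` is `atan2` over the first two axes. The sphere radius is
#' irrelevant (angles only).
#'
#' @param points n x 3 matrix; no point may coincide with the frame origin.
#' @param frame a [reference_frame()] list.
#' @return data frame with `theta`, `phi` (radians).
#' @export
project_to_sphere <- function(points, frame) {
  points <- matrix(points, ncol = 3)
  local <- sweep(points, 2, frame$origin) %*% frame$axes
  r <- sqrt(rowSums(local^2))
  if (any(r < 1e-9))
    stop("point(s) at the frame origin cannot be projected: row ",
         paste(which(r < 1e-9), collapse = ", "))
  theta <- acos(pmin(1, pmax(-1, local[, 3] / r)))
  phi <- atan2(local[, 2], local[, 1])
  phi[phi >= pi - 1e-12] <- -pi  # [-pi, pi) convention
  data.frame(theta = theta, phi = phi)
}

map_cells <- function(theta, phi, step) {
  data.frame(i = floor(theta / step), j = floor((phi + pi) / step))
}

#' Choose the quantization step of the interaction map
#'
#' Returns the largest candidate step at which, within every single
#' interface, all atoms fall on distinct cells (cells are half-open
#' `[k*step, (k+1)*step)` in both angles, a single shared step). If no
#' candidate separates every interface, the smallest candidate is returned
#' with a warning.
#'
#' @param interfaces list of projected-point data frames (`theta`, `phi`),
#'   one per contact surface, each with at least one point.
#' @param candidates descending positive candidate steps in radians;
#'   default 30 deg down to 0.5 deg in 0.5 deg decrements.
#' @return chosen step (radians).
#' @export
choose_step <- function(interfaces,
                        candidates = rev(seq(0.5, 30, by = 0.5)) * pi / 180) {
  stopifnot(length(interfaces) >= 1, all(diff(candidates) < 0),
            all(candidates > 0))
  for (step in candidates) {
    ok <- all(vapply(interfaces, function(p) {
      cells <- map_cells(p$theta, p$phi, step)
      !anyDuplicated(paste(cells$i, cells$j))
    }, logical(1)))
    if (ok) return(step)
  }
  warning("no candidate step separates all atoms of every interface; ",
          "using the smallest candidate")
  candidates[[length(candidates)]]
}

#' Build the discretized interaction map
#'
#' Accumulates all interfaces' projected atoms on the grid: each stored
#' cell's count is the number of atoms (across interfaces) mapping into it.
#' Per-interface injectivity holds when `step` comes from [choose_step()].
#'
#' @param interfaces list of projected-point data frames (`theta`, `phi`,
#'   plus any per-atom metadata columns, carried through).
#' @param step quantization step (radians).
#' @return a `MapGrid`: list with `step`, `cells` (data frame `i`, `j`,
#'   `count`) and `atoms` (data frame with `interface`, `i`, `j` and the
#'   input metadata columns).
#' @export
build_map <- function(interfaces, step) {
  stopifnot(step > 0)
  if (length(interfaces) == 0) {
    return(structure(list(step = step,
                          cells = data.frame(i = integer(0), j = integer(0),
                                             count = integer(0)),
                          atoms = data.frame()),
                     class = "MapGrid"))
  }
  atoms <- do.call(rbind, lapply(seq_along(interfaces), function(k) {
    p <- interfaces[[k]]
    cbind(data.frame(interface = k), p, map_cells(p$theta, p$phi, step))
  }))
  rownames(atoms) <- NULL
  key <- paste(atoms$i, atoms$j)
  cnt <- table(key)
  ij <- do.call(rbind, strsplit(names(cnt), " ", fixed = TRUE))
  cells <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                      count = as.integer(cnt))
  cells <- cells[order(cells$i, cells$j), ]
  rownames(cells) <- NULL
  structure(list(step = step, cells = cells, atoms = atoms),
            class = "MapGrid")
}

#' Physicochemical class of an amino acid
#'
#' Fixed mapping used to color interaction maps: positive (Arg, Lys, His),
#' negative (Asp, Glu), aromatic (Phe, Trp, Tyr), proline (Pro), polar
#' (Ser, Thr, Asn, Gln, Cys), hydrophobic (Ala, Val, Leu, Ile, Met, Gly).
#' His is classed with the positives and Gly with the hydrophobics;
#' nonstandard residues return `"unknown"` and can only contribute to gap
#' cells.
#'
#' @param res_name character vector of 3-letter residue names.
#' @return character vector of classes.
#' @export
aa_class <- function(res_name) {
  map <- c(ARG = "positive", LYS = "positive", HIS = "positive",
           ASP = "negative", GLU = "negative",
           PHE = "aromatic", TRP = "aromatic", TYR = "aromatic",
           PRO = "proline",
           SER = "polar", THR = "polar", ASN = "polar", GLN = "polar",
           CYS = "polar",
           ALA = "hydrophobic", VAL = "hydrophobic", LEU = "hydrophobic",
           ILE = "hydrophobic", MET = "hydrophobic", GLY = "hydrophobic")
  out <- unname(map[toupper(trimws(res_name))])
  out[is.na(out)] <- "unknown"
  out
}

#' Majority physicochemical property map
#'
#' Assigns each populated cell the class held by a strict majority (more
#' than half) of its atoms; when no strict majority exists (including ties
#' and cells dominated by unknown residues) the cell is a gap.
#'
#' @param grid a `MapGrid` from [build_map()] whose `atoms` carry a
#'   `class` column (e.g. from [aa_class()] of the atom's residue).
#' @return data frame `i`, `j`, `class` (`"gap"` where no strict majority).
#' @export
property_map <- function(grid) {
  atoms <- grid$atoms
  stopifnot(!is.null(atoms$class))
  key <- paste(atoms$i, atoms$j)
  out <- lapply(split(seq_len(nrow(atoms)), key), function(rows) {
    cls <- atoms$class[rows]
    tab <- table(cls[cls != "unknown"])
    n <- length(cls)
    win <- names(tab)[tab > n / 2]
    data.frame(i = atoms$i[rows[1]], j = atoms$j[rows[1]],
               class = if (length(win) == 1) win else "gap",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$i, out$j), ]
  rownames(out) <- NULL
  out
}

# connected components of a cell set under 4-neighbor adjacency
n_components <- function(cells) {
  if (nrow(cells) == 0) return(0L)
  key <- paste(cells$i, cells$j)
  idx <- seq_len(nrow(cells))
  seen <- rep(FALSE, nrow(cells))
  comp <- 0L
  lookup <- stats::setNames(idx, key)
  for (s in idx) {
    if (seen[s]) next
    comp <- comp + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      nb <- paste(cells$i[cur] + c(-1, 1, 0, 0),
                  cells$j[cur] + c(0, 0, -1, 1))
      hits <- lookup[nb]
      hits <- hits[!is.na(hits)]
      hits <- hits[!seen[hits]]
      seen[hits] <- TRUE
      queue <- c(queue, hits)
    }
  }
  comp
}

#' Mark the four nucleotide-backbone regions
#'
#' A region is the set of cells containing at least one backbone-atom
#' projection of its nucleotide position (1..4), pooled over all superposed
#' tetraloops. Cells contested between positions are assigned to the
#' majority position (ties to the lower position), so the four regions are
#' pairwise disjoint.
#'
#' @param backbone_projections data frame with `theta`, `phi`, `position`
#'   (1..4) for the backbone atoms of all superposed tetraloops.
#' @param step quantization step (radians), same as the map's.
#' @return a `RegionSet`: data frame `i`, `j`, `region`, with attribute
#'   `components` (named integer: connected components per region under
#'   4-neighbour adjacency).
#' @export
mark_regions <- function(backbone_projections, step) {
  cells <- cbind(map_cells(backbone_projections$theta,
                           backbone_projections$phi, step),
                 position = backbone_projections$position)
  key <- paste(cells$i, cells$j)
  out <- lapply(split(seq_len(nrow(cells)), key), function(rows) {
    tab <- table(cells$position[rows])
    best <- as.integer(names(tab)[tab == max(tab)])
    data.frame(i = cells$i[rows[1]], j = cells$j[rows[1]],
               region = min(best))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$region, out$i, out$j), ]
  rownames(out) <- NULL
  comp <- vapply(sort(unique(out$region)), function(r)
    n_components(out[out$region == r, , drop = FALSE]), integer(1))
  names(comp) <- sort(unique(out$region))
  attr(out, "components") <- comp
  class(out) <- c("RegionSet", "data.frame")
  out
}

#' Fraction of map atoms inside the backbone regions
#'
#' @param grid a `MapGrid` of interface atoms.
#' @param regions a `RegionSet` from [mark_regions()].
#' @return fraction in `[0, 1]` of interface atoms whose cell belongs to
#'   any region.
#' @export
region_coverage <- function(grid, regions) {
  if (nrow(grid$atoms) == 0) return(NA_real_)
  in_region <- paste(grid$atoms$i, grid$atoms$j) %in%
    paste(regions$i, regions$j)
  mean(in_region)
}
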