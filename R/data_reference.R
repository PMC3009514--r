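# Curated reference tables from the published interface analysis of the
# three ribosome crystal structures (PDB 1S72, 2AWB, 1FJF). These are
# inputs for bookkeeping and for parameterizing the synthetic generator;
# they are not recomputed by this package.

#' Reported RNA-side contact-surface composition
#'
#' Atom-type composition (percent) of ribosomal RNA contact surfaces pooled
#' over the H. marismortui 50S, E. coli 50S and T. thermophilus 30S
#' structures: the twelve backbone atom names, for the full contact surface
#' (`rcs`), the surface restricted to structural motifs (`sm_rcs`) and to
#' tetraloops (`tl_rcs`). Base-atom shares are the remainders to 100.
#'
#' @return data frame with columns `atom`, `rcs`, `sm_rcs`, `tl_rcs`.
#' @export
ribosome_rcs_composition <- function() {
  data.frame(
    atom = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'",
             "C2'", "O2'", "C1'"),
    rcs = c(3.68, 9.56, 5.61, 3.20, 9.43, 8.55, 4.75, 6.80, 6.57,
            7.12, 7.46, 6.14),
    sm_rcs = c(3.73, 9.22, 5.79, 2.99, 8.95, 8.13, 4.05, 6.72, 6.42,
               6.64, 6.57, 5.32),
    tl_rcs = c(3.67, 8.28, 5.00, 2.92, 9.79, 8.86, 5.18, 6.95, 7.31,
               6.56, 7.35, 5.82),
    stringsAsFactors = FALSE)
}

#' Reported protein-side contact-surface composition
#'
#' Amino-acid composition (percent) of ribosomal protein contact surfaces:
#' full (`pcs`), restricted to structural motifs (`sm_pcs`) and to
#' tetraloops (`tl_pcs`; Cys was not observed there).
#'
#' @return data frame with columns `resid` (3-letter), `pcs`, `sm_pcs`,
#'   `tl_pcs`.
#' @export
ribosome_pcs_composition <- function() {
  data.frame(
    resid = c("ALA", "ARG", "ASN", "ASP", "CYS", "GLU", "GLN", "GLY",
              "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
              "THR", "TRP", "TYR", "VAL"),
    pcs = c(3.93, 21.92, 4.41, 2.58, 0.19, 3.11, 4.57, 6.61, 4.63, 2.17,
            3.71, 14.65, 2.00, 3.03, 3.84, 4.74, 4.67, 1.94, 3.69, 3.65),
    sm_pcs = c(5.02, 24.87, 3.40, 2.53, 0.16, 3.73, 2.94, 4.97, 4.81,
               1.63, 5.04, 13.91, 2.76, 3.69, 3.14, 5.90, 2.75, 2.46,
               3.05, 3.26),
    tl_pcs = c(2.70, 27.99, 3.07, 1.42, 0, 2.32, 1.06, 5.51, 5.20, 1.24,
               2.48, 10.03, 3.05, 10.77, 4.12, 5.67, 1.77, 3.56, 4.12,
               3.93),
    stringsAsFactors = FALSE)
}

#' Reported tetraloop contact surfaces (H. marismortui 50S)
#'
#' The eleven r-protein / standard-tetraloop contact surfaces with their
#' loop sequence, rolled-probe area and atom count.
#'
#' @return data frame with columns `protein`, `tetraloop`, `sequence`,
#'   `area`, `n_atoms`.
#' @export
ribosome_tetraloops <- function() {
  data.frame(
    protein = c("L2", "L15e", "L15", "L13", "L2", "L19e", "L37e", "L10e",
                "L15e", "L32e", "L18"),
    tetraloop = c("TL2249", "TL1863", "TL691", "TL1238", "TL2630",
                  "TL1794", "TL469", "TL1055", "TL1469", "TL1327",
                  "TL2412"),
    sequence = c("GGGA", "GCAA", "GAAA", "CGGG", "GUGA", "GGAA", "GUGA",
                 "GUAA", "CAAC", "GAAA", "GAAA"),
    area = c(117.5, 127.8, 139.5, 155.2, 174, 188, 257.25, 375.4, 401.9,
             552.5, 580.3),
    n_atoms = c(8L, 14L, 15L, 14L, 13L, 15L, 24L, 34L, 40L, 63L, 58L),
    stringsAsFactors = FALSE)
}

#' Reported tripod instances
#'
#' The published inventory of tripod binding sites found on r-protein
#' interfaces of the three ribosomes: nucleotide (author numbering), base,
#' the three amino acids, protein, P-R-B contact counts and whether the
#' site makes hydrogen bonds with the base.
#'
#' @return data frame with columns `structure`, `nt`, `base`, `aa1`, `aa2`,
#'   `aa3`, `protein`, `p`, `r`, `b`, `hbond`.
#' @export
ribosome_tripods <- function() {
  parse_row <- function(s) strsplit(s, ";")[[1]]
  rows <- c(
    "1S72;700;A;Gln-113;Arg-115;Glu-71;L15;2;4;11;TRUE",
    "1S72;2368;A;Arg-13;Asp-19;Leu-106;L18;2;2;10;FALSE",
    "1S72;2815;G;Arg-102;Lys-80;Tyr-104;L13;2;4;11;TRUE",
    "1S72;746;A;Glu-42;Asn-44;Leu-65;L18e;0;2;7;TRUE",
    "1S72;96;A;His-4;Glu-7;Gln-6;L29;0;2;7;TRUE",
    "1S72;659;A;Lys-63;Leu-65;Glu-42;L18e;3;6;12;TRUE",
    "1S72;1315;G;Arg-212;Ala-211;Glu-215;L32e;1;5;9;TRUE",
    "1S72;1359;U;Ala-68;Gly-66;His-69;L4;1;4;8;FALSE",
    "1S72;452;G;Gln-178;Arg-182;Ala-181;L4;0;2;5;TRUE",
    "1S72;327;A;Lys-149;Gln-151;Asn-206;L4;3;6;10;TRUE",
    "1S72;1356;A;Arg-130;Arg-138;Lys-136;L32e;2;5;8;TRUE",
    "1S72;308;U;Arg-97;Arg-52;Ser-94;L24;2;7;9;FALSE",
    "1S72;1150;A;Thr-65;Lys-16;Arg-69;L10;0;7;7;FALSE",
    "2AWB;144;A;Met-1;Arg-3;Glu-4;L23;0;11;12;FALSE",
    "2AWB;2286;G;Thr-23;Asn-25;Lys-36;L33;1;4;16;TRUE",
    "2AWB;1820;U;Arg-176;Ala-197;Met-200;L2;2;5;10;FALSE",
    "2AWB;2305;U;Met-37;Arg-132;Arg-149;L5;0;3;11;TRUE",
    "2AWB;636;G;Thr-74;Glu-76;Arg-126;L15;2;2;8;TRUE",
    "2AWB;2250;G;Val-80;Arg-81;Met-82;L16;0;3;12;FALSE",
    "2AWB;1156;A;Arg-47;Gln-51;Arg-54;L20;1;2;8;FALSE",
    "2AWB;1252;G;Tyr-31;Arg-32;Gln-36;L20;1;3;10;TRUE",
    "1FJF;7;G;Lys-92;Lys-121;Thr-120;S5;0;2;8;TRUE",
    "1FJF;1347;G;Arg-10;Lys-11;Arg-107;S9;1;4;16;TRUE",
    "1FJF;691;G;Asn-26;Gly-52;Lys-55;S11;2;3;6;TRUE",
    "1FJF;562;C;Arg-15;Glu-16;Val-18;S12;1;10;5;TRUE",
    "1FJF;1317;C;Phe-16;Arg-19;Val-18;S14;2;4;9;FALSE",
    "1FJF;958;A;Lys-55;Thr-77;Gly-54;S19;1;2;10;TRUE")
  parts <- lapply(rows, parse_row)
  data.frame(
    structure = vapply(parts, `[`, "", 1),
    nt = as.integer(vapply(parts, `[`, "", 2)),
    base = vapply(parts, `[`, "", 3),
    aa1 = vapply(parts, `[`, "", 4),
    aa2 = vapply(parts, `[`, "", 5),
    aa3 = vapply(parts, `[`, "", 6),
    protein = vapply(parts, `[`, "", 7),
    p = as.integer(vapply(parts, `[`, "", 8)),
    r = as.integer(vapply(parts, `[`, "", 9)),
    b = as.integer(vapply(parts, `[`, "", 10)),
    hbond = as.logical(vapply(parts, `[`, "", 11)),
    stringsAsFactors = FALSE)
}
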