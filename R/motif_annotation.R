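# Structural-element annotation of RNA atoms and tetraloop detection.

MOTIF_KLASSES <- c("tetraloop", "kink_turn", "other_motif", "helix", "junction")

new_motif_annotation <- function(motif_id, klass, ranges, sequence = NULL,
                                 n_helices = NULL) {
  if (!klass %in% MOTIF_KLASSES)
    stop("annotation '", motif_id, "': unknown klass '", klass, "'")
  if (length(ranges) == 0)
    stop("annotation '", motif_id, "': no ranges")
  for (r in ranges) {
    if (as.integer(r$start) > as.integer(r$end))
      stop("annotation '", motif_id, "': inverted range ",
           r$start, "-", r$end)
  }
  if (klass == "tetraloop") {
    span <- sum(vapply(ranges,
                       function(r) as.integer(r$end) - as.integer(r$start) + 1L,
                       integer(1)))
    if (span != 4)
      stop("annotation '", motif_id, "': tetraloop must span exactly 4 residues, got ",
           span)
  }
  structure(list(motif_id = motif_id, klass = klass, ranges = ranges,
                 sequence = sequence, n_helices = n_helices,
                 standard = NA),
            class = "MotifAnnotation")
}

#' Load RNA motif annotations
#'
#' Reads a sidecar annotation file describing RNA structural elements
#' (tetraloops, kink-turns, other motifs, helices, junctions) as residue
#' ranges in author numbering. Accepts JSON (an array of records with
#' `motif_id`, `klass`, `ranges` = list of `[chain, start, end]`, optional
#' `sequence`, `n_helices`) or 4-column TSV
#' (`motif_id  klass  chain  start-end[,start-end...]`).
#'
#' @param path file path (`.json` or `.tsv`).
#' @return list of `MotifAnnotation` objects (possibly empty).
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    lapply(recs, function(rec) {
      ranges <- lapply(rec$ranges, function(r)
        list(chain = as.character(r[[1]]), start = as.integer(r[[2]]),
             end = as.integer(r[[3]])))
      new_motif_annotation(rec$motif_id, rec$klass, ranges,
                           sequence = rec$sequence,
                           n_helices = rec$n_helices)
    })
  } else {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                             comment.char = "#",
                             col.names = c("motif_id", "klass", "chain",
                                           "ranges"))
    if (nrow(tab) == 0) return(list())
    lapply(seq_len(nrow(tab)), function(k) {
      spans <- strsplit(tab$ranges[k], ",", fixed = TRUE)[[1]]
      ranges <- lapply(spans, function(s) {
        se <- as.integer(strsplit(trimws(s), "-", fixed = TRUE)[[1]])
        if (length(se) != 2 || anyNA(se))
          stop("annotation '", tab$motif_id[k], "': bad range '", s, "'")
        list(chain = as.character(tab$chain[k]), start = se[1], end = se[2])
      })
      new_motif_annotation(tab$motif_id[k], tab$klass[k], ranges)
    })
  }
}

#' Write motif annotations as JSON
#'
#' @param annotations list of `MotifAnnotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  recs <- lapply(annotations, function(a) {
    rec <- list(motif_id = a$motif_id, klass = a$klass,
                ranges = lapply(a$ranges,
                                function(r) list(r$chain, r$start, r$end)))
    if (!is.null(a$sequence)) rec$sequence <- a$sequence
    rec
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# Stack-parse a dot-bracket string into a pair table (0 = unpaired).
parse_dotbracket <- function(dotbracket) {
  chars <- strsplit(dotbracket, "")[[1]]
  pair <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    c <- chars[[i]]
    if (c == "(") {
      stack <- c(stack, i)
    } else if (c == ")") {
      if (length(stack) == 0)
        stop("unbalanced dot-bracket: unmatched ')' at position ", i)
      j <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      pair[i] <- j
      pair[j] <- i
    } else if (c != ".") {
      stop("unbalanced dot-bracket: unexpected character '", c,
           "' at position ", i)
    }
  }
  if (length(stack) > 0)
    stop("unbalanced dot-bracket: unmatched '(' at position ",
         stack[[length(stack)]])
  pair
}

#' Detect tetraloops from sequence and secondary structure
#'
#' A tetraloop is a hairpin loop of exactly four unpaired residues closed by
#' a base pair. Every such loop is returned; the `standard` flag records
#' whether the loop sequence matches one of the consensus families GNRA,
#' UNCG or CUUG (N = any, R = G/A). Non-consensus tetraloops are reported
#' with `standard = FALSE`, not dropped, since non-consensus loops occur in
#' curated ribosomal inventories.
#'
#' @param sequence RNA sequence (A/C/G/U), same length as `dotbracket`.
#' @param dotbracket dot-bracket secondary structure.
#' @param chain chain id recorded in the annotation ranges (default `"A"`).
#' @param numbering integer residue numbers for the sequence positions
#'   (default `1:nchar(sequence)`).
#' @return list of tetraloop `MotifAnnotation`s with `standard` flags,
#'   detection being independent of flanking helix length and position.
#' @export
detect_tetraloops <- function(sequence, dotbracket, chain = "A",
                              numbering = NULL) {
  sequence <- toupper(sequence)
  if (nchar(sequence) != nchar(dotbracket))
    stop("sequence and dot-bracket lengths differ")
  if (is.null(numbering)) numbering <- seq_len(nchar(sequence))
  pair <- parse_dotbracket(dotbracket)
  out <- list()
  for (i in seq_along(pair)) {
    j <- pair[[i]]
    if (j > i && j - i == 5 && all(pair[(i + 1):(j - 1)] == 0)) {
      loop_start <- i + 1
      loop <- substr(sequence, loop_start, j - 1)
      ann <- new_motif_annotation(
        motif_id = paste0("TL", numbering[loop_start]),
        klass = "tetraloop",
        ranges = list(list(chain = chain, start = numbering[loop_start],
                           end = numbering[j - 1])),
        sequence = loop)
      ann$standard <- grepl("^(G[ACGU][GA]A|U[ACGU]CG|CUUG)$", loop)
      out[[length(out) + 1]] <- ann
    }
  }
  out
}

#' Label RNA atoms by structural element
#'
#' Assigns each RNA atom one of `motif`, `junction`, `helix`, `other` from a
#' set of (possibly overlapping) annotations. Precedence on overlap is
#' motif > junction > helix, so that e.g. the helical strands of a kink-turn
#' still count as motif; unannotated residues are `other`. The labels
#' partition the RNA atoms.
#'
#' @param model a `StructureModel`.
#' @param annotations list of `MotifAnnotation`.
#' @return character vector over RNA atom rows, named by row index into
#'   `model$atoms`.
#' @export
label_atoms <- function(model, annotations) {
  at <- model$atoms
  rna_rows <- which(at$kind == "nucleotide")
  labels <- rep("other", length(rna_rows))
  names(labels) <- rna_rows
  rank <- c(other = 0, helix = 1, junction = 2, motif = 3)
  res_rank <- numeric(0)  # residue key -> current rank
  rkey <- residue_key(at[rna_rows, ])
  cur <- rep(0, length(rna_rows))
  for (a in annotations) {
    lab <- switch(a$klass,
                  tetraloop = "motif", kink_turn = "motif",
                  other_motif = "motif", junction = "junction",
                  helix = "helix")
    for (r in a$ranges) {
      for (s in seq.int(r$start, r$end)) {
        hit <- which(at$chain[rna_rows] == r$chain &
                       at$resno[rna_rows] == s)
        if (length(hit) == 0) {
          warning("annotation '", a$motif_id, "': residue ", r$chain, ":",
                  s, " not in model; skipped")
          next
        }
        upd <- hit[rank[[lab]] > cur[hit]]
        labels[upd] <- lab
        cur[upd] <- rank[[lab]]
      }
    }
  }
  labels
}
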