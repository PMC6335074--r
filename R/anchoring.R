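#' Assign scaffolds to linkage groups and flag chimeras
#'
#' Each scaffold is assigned to the linkage group of its mapped markers.
#' Markers are ordered by scaffold position and collapsed into contiguous
#' same-LG blocks; blocks smaller than `min_split_support` are dismissed as
#' noise. A scaffold whose retained blocks span two or more linkage groups
#' is flagged chimeric (a misjoin to be split); a scaffold with no retained
#' block -- e.g. single conflicting markers on two groups -- is left
#' unassigned with a warning.
#'
#' @param markers data.frame with columns marker_id, lg, cM, scaffold_id,
#'   position (1-based bp on the scaffold)
#' @param min_split_support minimum markers per block (default 2)
#' @return data.frame with one row per scaffold: scaffold_id, lg (NA when
#'   unassigned), chimeric, n_markers, n_blocks
#' @export
assign_scaffolds <- function(markers, min_split_support = 2) {
  required <- c("marker_id", "lg", "cM", "scaffold_id", "position")
  if (!all(required %in% names(markers)))
    stop("markers must have columns ", paste(required, collapse = ", "))
  out <- lapply(split(markers, markers$scaffold_id), function(mk) {
    mk <- mk[order(mk$position), ]
    blocks <- marker_blocks(mk$lg, min_split_support)
    lgs <- unique(blocks$lg)
    if (length(lgs) == 0) {
      warning("scaffold ", mk$scaffold_id[1],
              ": conflicting or insufficient marker support, unassigned")
      lg <- NA_integer_; chimeric <- FALSE
    } else if (length(lgs) == 1) {
      lg <- lgs; chimeric <- FALSE
    } else {
      lg <- NA_integer_; chimeric <- TRUE
    }
    data.frame(scaffold_id = mk$scaffold_id[1], lg = lg,
               chimeric = chimeric, n_markers = nrow(mk),
               n_blocks = nrow(blocks))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$scaffold_id), ]
}

# Contiguous same-LG blocks along a scaffold, keeping only blocks with
# enough support. Returns a data.frame(lg, from, to) in marker indices.
marker_blocks <- function(lg_seq, min_support) {
  r <- rle(lg_seq)
  to <- cumsum(r$lengths)
  from <- to - r$lengths + 1L
  keep <- r$lengths >= min_support
  b <- data.frame(lg = r$values[keep], from = from[keep], to = to[keep])
  # merge adjacent retained blocks of the same LG (noise block removed
  # between them)
  if (nrow(b) > 1) {
    merged <- b[1, , drop = FALSE]
    for (i in 2:nrow(b)) {
      if (b$lg[i] == merged$lg[nrow(merged)]) {
        merged$to[nrow(merged)] <- b$to[i]
      } else merged <- rbind(merged, b[i, ])
    }
    b <- merged
  }
  b
}

#' Split a chimeric scaffold at marker-block boundaries
#'
#' Cuts at the midpoint of the gap between the last marker of one
#' linkage-group block and the first marker of the next; parts are suffixed
#' `a`, `b`, ... in position order, inherit their markers (with shifted
#' coordinates), and their lengths sum to the original scaffold length.
#' Interleaved blocks (a linkage group recurring in non-adjacent blocks)
#' are not separable and raise an error naming the scaffold.
#'
#' @param scaffold_seq the scaffold sequence (character or
#'   [Biostrings::DNAString])
#' @param markers markers on this scaffold (same columns as
#'   [assign_scaffolds()])
#' @param min_split_support minimum markers per block (default 2)
#' @return a list with `parts` (named character vector of sequences),
#'   `markers` (updated scaffold_id and position), and `cut_points`
#'   (1-based: part i ends at cut_points[i])
#' @export
split_chimeric <- function(scaffold_seq, markers, min_split_support = 2) {
  seq_chr <- as.character(scaffold_seq)
  mk <- markers[order(markers$position), ]
  id <- mk$scaffold_id[1]
  blocks <- marker_blocks(mk$lg, min_split_support)
  if (nrow(blocks) < 2)
    stop("scaffold ", id, " is not chimeric (needs >= 2 supported blocks)")
  if (anyDuplicated(blocks$lg))
    stop("scaffold ", id, ": interleaved linkage-group blocks, not separable")
  cuts <- integer(nrow(blocks) - 1L)
  for (i in seq_len(nrow(blocks) - 1L)) {
    last_pos <- mk$position[blocks$to[i]]
    first_pos <- mk$position[blocks$from[i + 1L]]
    cuts[i] <- floor((last_pos + first_pos) / 2)
  }
  bounds <- c(0L, cuts, nchar(seq_chr))
  parts <- setNames(
    vapply(seq_len(nrow(blocks)), function(i)
      substr(seq_chr, bounds[i] + 1L, bounds[i + 1L]), character(1)),
    paste0(id, letters[seq_len(nrow(blocks))]))
  part_of <- findInterval(mk$position, bounds + 1L)
  mk$scaffold_id <- names(parts)[part_of]
  mk$position <- mk$position - bounds[part_of]
  list(parts = parts, markers = mk, cut_points = cuts)
}

#' Order scaffolds within a chromosome by map position
#'
#' Sorts placements by median marker cM; ties are broken by marker count
#' (descending) then scaffold id (ascending), so the order is
#' deterministic.
#'
#' @param placements data.frame with columns scaffold_id, anchor_cM
#'   (median marker cM) and supporting_marker_count
#' @return the placements with an `order_index` column, sorted
#' @export
order_scaffolds <- function(placements) {
  o <- order(placements$anchor_cM, -placements$supporting_marker_count,
             placements$scaffold_id)
  placements <- placements[o, ]
  placements$order_index <- seq_len(nrow(placements))
  rownames(placements) <- NULL
  placements
}

#' Orient a scaffold by marker-pair majority vote
#'
#' Every pair of mapped markers votes: `+` when their scaffold-position
#' order agrees with their cM order, `-` when reversed; pairs tied on cM
#' abstain. The orientation is the majority vote; a tied vote, or fewer
#' than three markers, gives `?` (placed unoriented rather than guessed).
#'
#' @param markers markers on one scaffold (columns cM and position)
#' @return `"+"`, `"-"` or `"?"`
#' @export
orient_scaffold <- function(markers) {
  if (nrow(markers) < 3) return("?")
  votes <- 0L
  n <- nrow(markers)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dpos <- markers$position[j] - markers$position[i]
    dcm <- markers$cM[j] - markers$cM[i]
    if (dcm == 0 || dpos == 0) next
    votes <- votes + sign(dpos) * sign(dcm)
  }
  if (votes > 0) "+" else if (votes < 0) "-" else "?"
}

#' Anchor scaffolds to a genetic map
#'
#' Full placement flow: assign scaffolds to linkage groups
#' ([assign_scaffolds()]), split flagged chimeras ([split_chimeric()]),
#' order within each group by median cM ([order_scaffolds()]) and orient by
#' marker-pair majority ([orient_scaffold()]). Scaffolds without an
#' assignment are routed to chromosome 0.
#'
#' @param scaffolds [Biostrings::DNAStringSet] of scaffold sequences
#' @param markers mapped-marker table (marker_id, lg, cM, scaffold_id,
#'   position)
#' @param min_split_support minimum markers per linkage-group block
#' @return a list with `placements` (scaffold_id, chromosome, order_index,
#'   orientation, supporting_marker_count, anchor_cM), `scaffolds` (with
#'   chimeras replaced by their parts), and `unassigned` ids
#' @export
anchor_scaffolds <- function(scaffolds, markers, min_split_support = 2) {
  assign <- assign_scaffolds(markers, min_split_support)
  seqs <- setNames(as.character(scaffolds), names(scaffolds))
  mk <- markers
  for (id in assign$scaffold_id[assign$chimeric]) {
    sp <- split_chimeric(seqs[[id]], mk[mk$scaffold_id == id, ],
                         min_split_support)
    seqs <- c(seqs[setdiff(names(seqs), id)], sp$parts)
    mk <- rbind(mk[mk$scaffold_id != id, ], sp$markers)
  }
  assign <- assign_scaffolds(mk, min_split_support)
  anchored <- assign[!is.na(assign$lg), ]
  placements <- NULL
  for (i in seq_len(nrow(anchored))) {
    id <- anchored$scaffold_id[i]
    mrk <- mk[mk$scaffold_id == id & mk$lg == anchored$lg[i], ]
    placements <- rbind(placements, data.frame(
      scaffold_id = id, chromosome = anchored$lg[i],
      anchor_cM = median(mrk$cM),
      supporting_marker_count = nrow(mrk),
      orientation = orient_scaffold(mrk)))
  }
  ordered <- NULL
  if (!is.null(placements))
    for (ch in sort(unique(placements$chromosome)))
      ordered <- rbind(ordered,
                       order_scaffolds(placements[placements$chromosome == ch, ]))
  unassigned <- setdiff(names(seqs), ordered$scaffold_id)
  list(placements = ordered,
       scaffolds = Biostrings::DNAStringSet(seqs),
       unassigned = unassigned)
}

#' Build pseudomolecules and an AGP from ordered placements
#'
#' Concatenates each chromosome's scaffolds in order -- reverse-complementing
#' `-` placements, leaving `?` as-is -- with exactly 1000 `N` between
#' adjacent components. Scaffolds not placed on a chromosome are
#' concatenated in seeded-random order onto chromosome 0. Emits the FASTA
#' together with AGP v2.1 records that round-trip to it exactly.
#'
#' @param placements placement table from [anchor_scaffolds()]
#' @param scaffolds [Biostrings::DNAStringSet] holding every placed
#'   sequence
#' @param seed integer seed for the chromosome-0 shuffle
#' @param gap_bp spacer length between adjacent components (default 1000)
#' @return a list with `fasta` ([Biostrings::DNAStringSet] of
#'   pseudomolecules) and `agp` (data.frame of AGP v2.1 records)
#' @export
build_pseudomolecules <- function(placements, scaffolds, seed = 1,
                                  gap_bp = 1000) {
  seqs <- setNames(as.character(scaffolds), names(scaffolds))
  missing <- setdiff(placements$scaffold_id, names(seqs))
  if (length(missing))
    stop("missing sequence for placement: ", missing[1])
  unanchored <- setdiff(names(seqs), placements$scaffold_id)
  if (length(unanchored)) {
    set.seed(seed)
    unanchored <- sample(unanchored)
    placements <- rbind(placements, data.frame(
      scaffold_id = unanchored, chromosome = 0L,
      anchor_cM = NA_real_, supporting_marker_count = 0L,
      orientation = "?", order_index = seq_along(unanchored)))
  }
  fasta <- character(0)
  agp <- NULL
  for (ch in sort(unique(placements$chromosome))) {
    pl <- placements[placements$chromosome == ch, ]
    pl <- pl[order(pl$order_index), ]
    obj <- paste0("chr", ch)
    parts <- character(0)
    pos <- 0L; part_no <- 0L
    for (i in seq_len(nrow(pl))) {
      if (i > 1) {
        part_no <- part_no + 1L
        agp <- rbind(agp, data.frame(
          object = obj, object_beg = pos + 1L, object_end = pos + gap_bp,
          part_number = part_no, component_type = "N",
          component_id = as.character(gap_bp), component_beg = "scaffold",
          component_end = "yes", orientation = "map"))
        parts <- c(parts, strrep("N", gap_bp))
        pos <- pos + gap_bp
      }
      s <- seqs[[pl$scaffold_id[i]]]
      emitted <- if (pl$orientation[i] == "-")
        reverse_complement_chr(s) else s
      part_no <- part_no + 1L
      agp <- rbind(agp, data.frame(
        object = obj, object_beg = pos + 1L, object_end = pos + nchar(s),
        part_number = part_no, component_type = "W",
        component_id = pl$scaffold_id[i], component_beg = "1",
        component_end = as.character(nchar(s)),
        orientation = pl$orientation[i]))
      parts <- c(parts, emitted)
      pos <- pos + nchar(s)
    }
    fasta[obj] <- paste(parts, collapse = "")
  }
  list(fasta = Biostrings::DNAStringSet(fasta), agp = agp)
}

#' Rebuild pseudomolecule FASTA from an AGP and scaffold sequences
#'
#' The inverse of [build_pseudomolecules()]: W components are substrings of
#' the named scaffold (reverse-complemented when the orientation is `-`),
#' N/U components become runs of `N`.
#'
#' @param agp AGP data.frame (as emitted by [build_pseudomolecules()] or
#'   read by [read_agp()])
#' @param scaffolds [Biostrings::DNAStringSet] of component sequences
#' @return [Biostrings::DNAStringSet] of reconstructed objects
#' @export
agp_to_fasta <- function(agp, scaffolds) {
  seqs <- setNames(as.character(scaffolds), names(scaffolds))
  out <- character(0)
  for (obj in unique(agp$object)) {
    rec <- agp[agp$object == obj, ]
    rec <- rec[order(rec$part_number), ]
    parts <- vapply(seq_len(nrow(rec)), function(i) {
      r <- rec[i, ]
      if (r$component_type %in% c("N", "U"))
        return(strrep("N", as.integer(r$component_id)))
      s <- substr(seqs[[r$component_id]], as.integer(r$component_beg),
                  as.integer(r$component_end))
      if (r$orientation == "-") reverse_complement_chr(s) else s
    }, character(1))
    out[obj] <- paste(parts, collapse = "")
  }
  Biostrings::DNAStringSet(out)
}

#' Read and write AGP v2.1
#'
#' Nine-column tab-separated AGP with a `##agp-version 2.1` header line.
#'
#' @param agp AGP data.frame
#' @param path file path
#' @export
write_agp <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  write.table(agp, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_agp
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  tab <- read.table(text = lines, sep = "\t",
                    col.names = c("object", "object_beg", "object_end",
                                  "part_number", "component_type",
                                  "component_id", "component_beg",
                                  "component_end", "orientation"),
                    colClasses = "character")
  for (col in c("object_beg", "object_end", "part_number"))
    tab[[col]] <- as.integer(tab[[col]])
  tab
}
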