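#' Per-base depth track for a sequencing pool
#'
#' A dense per-base coverage vector for each reference sequence, plus the
#' pool's genome-wide mean depth (always recomputed from the vectors, never
#' trusted from input).
#'
#' @param depths named list of non-negative integer vectors, one per
#'   reference sequence
#' @return an object of class `depth_track`
#' @export
depth_track <- function(depths) {
  if (is.null(names(depths)) || any(!nzchar(names(depths))))
    stop("depth vectors must be named by reference sequence")
  depths <- lapply(depths, function(v) {
    if (any(v < 0)) stop("depths must be non-negative")
    as.integer(v)
  })
  structure(list(
    depths = depths,
    genome_mean_depth = sum(vapply(depths, function(v) sum(as.double(v)),
                                   numeric(1))) /
      sum(vapply(depths, length, integer(1)))
  ), class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat("depth_track:", length(x$depths), "reference(s),",
      format(sum(vapply(x$depths, length, integer(1))), big.mark = ","),
      "bp, mean depth", round(x$genome_mean_depth, 2), "\n")
  invisible(x)
}

#' Read and write three-column per-base depth text
#'
#' The on-disk format is tab-separated `reference  position  depth` with
#' 1-based positions; zero-depth positions are omitted by the writer and
#' filled in by the loader, so a write/load/write cycle is byte-identical.
#'
#' @param path file path
#' @param reference_lengths named integer vector giving the length of every
#'   reference sequence
#' @return for `load_depth_track`, a [depth_track()]
#' @export
load_depth_track <- function(path, reference_lengths) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("reference", "pos", "depth"),
                    colClasses = c("character", "numeric", "numeric"))
  if (any(tab$depth != floor(tab$depth)))
    stop("non-integer depth value in ", path)
  bad <- setdiff(unique(tab$reference), names(reference_lengths))
  if (length(bad)) stop("unknown reference id: ", bad[1])
  depths <- lapply(names(reference_lengths), function(rn) {
    v <- integer(reference_lengths[[rn]])
    rows <- tab$reference == rn
    if (any(tab$pos[rows] < 1 | tab$pos[rows] > reference_lengths[[rn]]))
      stop("position outside reference ", rn)
    v[tab$pos[rows]] <- as.integer(tab$depth[rows])
    v
  })
  names(depths) <- names(reference_lengths)
  depth_track(depths)
}

#' @rdname load_depth_track
#' @param track a [depth_track()]
#' @export
write_depth_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rn in names(track$depths)) {
    v <- track$depths[[rn]]
    nz <- which(v > 0L)
    if (length(nz))
      writeLines(paste(rn, nz, v[nz], sep = "\t"), con)
  }
  invisible(path)
}

#' Parameters of the sex-specific depth scan
#'
#' Thresholds follow the pooled-coverage scan used to map female-specific
#' insertions: a base qualifies when the target pool exceeds
#' `min_target_depth` (strict) while the other pool is at or below
#' `max_other_depth`; runs longer than `min_run_bp` (strict) are kept,
#' optionally merged across gaps of up to `merge_gap_bp`, and a merged
#' region is a candidate when its mean target depth reaches
#' `min_depth_fraction` of the target pool's genome-wide mean.
#' `noise_fraction_ceiling` is the depth fraction below which residual
#' contrasts on the opposite reference are dismissed as noise when calling
#' the sex system.
#'
#' @param min_run_bp minimum run length, strict `>` (default 100: a run
#'   qualifies at 101 bp)
#' @param min_target_depth minimum qualifying base depth, strict `>`
#'   (default 10: a base qualifies at depth 11)
#' @param max_other_depth maximum tolerated depth in the other pool
#'   (default 0, exact absence)
#' @param merge_gap_bp merge runs separated by at most this many bases
#'   (default 0: no merging)
#' @param min_depth_fraction candidate threshold on mean region depth as a
#'   fraction of the pool's genome mean (default 0.5)
#' @param noise_fraction_ceiling depth fraction regarded as background
#'   (default 0.4); must be below `min_depth_fraction`
#' @return an object of class `scan_params`
#' @export
scan_params <- function(min_run_bp = 100, min_target_depth = 10,
                        max_other_depth = 0, merge_gap_bp = 0,
                        min_depth_fraction = 0.5,
                        noise_fraction_ceiling = 0.4) {
  check_count(min_run_bp, "min_run_bp", positive = FALSE)
  check_count(min_target_depth, "min_target_depth", positive = FALSE)
  check_count(max_other_depth, "max_other_depth", positive = FALSE)
  check_count(merge_gap_bp, "merge_gap_bp", positive = FALSE)
  check_fraction(min_depth_fraction, "min_depth_fraction")
  check_fraction(noise_fraction_ceiling, "noise_fraction_ceiling")
  if (min_depth_fraction <= noise_fraction_ceiling)
    stop_field("min_depth_fraction",
               "must exceed noise_fraction_ceiling")
  structure(list(min_run_bp = as.integer(min_run_bp),
                 min_target_depth = as.integer(min_target_depth),
                 max_other_depth = as.integer(max_other_depth),
                 merge_gap_bp = as.integer(merge_gap_bp),
                 min_depth_fraction = min_depth_fraction,
                 noise_fraction_ceiling = noise_fraction_ceiling),
            class = "scan_params")
}

#' Find runs covered in one pool and absent in the other
#'
#' Scans both tracks base by base for the predicate
#' `target > min_target_depth & other <= max_other_depth` and returns the
#' maximal runs of consecutive qualifying bases longer than `min_run_bp`
#' (strict), sorted by (reference, start).
#'
#' @param target,other [depth_track()] objects over the same references
#' @param params a [scan_params()]
#' @return data.frame with columns reference_id, start, end (0-based
#'   half-open), length
#' @export
find_sex_specific_runs <- function(target, other, params = scan_params()) {
  if (!identical(sort(names(target$depths)), sort(names(other$depths))))
    stop("target and other tracks cover different reference sets")
  out <- list()
  for (rn in names(target$depths)) {
    tv <- target$depths[[rn]]; ov <- other$depths[[rn]]
    if (length(tv) != length(ov))
      stop("reference ", rn, " has different lengths in the two tracks")
    pred <- tv > params$min_target_depth & ov <= params$max_other_depth
    r <- rle(pred)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values & r$lengths > params$min_run_bp
    if (any(keep))
      out[[rn]] <- data.frame(reference_id = rn, start = starts[keep],
                              end = ends[keep],
                              length = r$lengths[keep])
  }
  if (!length(out))
    return(data.frame(reference_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$reference_id, res$start), ]
  rownames(res) <- NULL
  res
}

#' Merge nearby runs and apply the depth-fraction filter
#'
#' Runs separated by at most `merge_gap_bp` are merged; each merged region
#' is annotated with its qualifying-base count, mean target depth and depth
#' fraction (mean depth over the target pool's genome mean), and kept only
#' when the depth fraction reaches `min_depth_fraction`.
#'
#' @param runs output of [find_sex_specific_runs()]
#' @param target the target pool's [depth_track()]
#' @param params a [scan_params()]
#' @return data.frame of candidate regions (0-based half-open) with columns
#'   reference_id, start, end, qualifying_bases, mean_target_depth,
#'   depth_fraction, run_count
#' @export
merge_and_filter_candidates <- function(runs, target,
                                        params = scan_params()) {
  empty <- data.frame(reference_id = character(0), start = integer(0),
                      end = integer(0), qualifying_bases = integer(0),
                      mean_target_depth = numeric(0),
                      depth_fraction = numeric(0), run_count = integer(0))
  if (nrow(runs) == 0) return(empty)
  out <- list()
  for (rn in unique(runs$reference_id)) {
    rr <- runs[runs$reference_id == rn, ]
    ir <- IRanges::IRanges(start = rr$start + 1L, end = rr$end)
    merged <- IRanges::reduce(ir, min.gapwidth = params$merge_gap_bp + 1L)
    # each run lies in exactly one merged interval (merged is sorted)
    member_of <- findInterval(rr$start + 1L, IRanges::start(merged))
    tv <- target$depths[[rn]]
    rows <- lapply(seq_along(merged), function(i) {
      s1 <- IRanges::start(merged)[i]; e1 <- IRanges::end(merged)[i]
      members <- which(member_of == i)
      data.frame(reference_id = rn, start = s1 - 1L, end = e1,
                 qualifying_bases = sum(rr$length[members]),
                 mean_target_depth = mean(tv[s1:e1]),
                 run_count = length(members))
    })
    out[[rn]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  res$depth_fraction <- res$mean_target_depth / target$genome_mean_depth
  res <- res[res$depth_fraction >= params$min_depth_fraction, ]
  res <- res[order(res$reference_id, res$start),
             c("reference_id", "start", "end", "qualifying_bases",
               "mean_target_depth", "depth_fraction", "run_count")]
  rownames(res) <- NULL
  res
}

#' One-call sex-specific region scan
#'
#' Convenience wrapper: [find_sex_specific_runs()] followed by
#' [merge_and_filter_candidates()].
#'
#' @inheritParams find_sex_specific_runs
#' @return a list with `runs`, `candidates` and `params`
#' @export
scan_sex_specific_regions <- function(target, other,
                                      params = scan_params()) {
  runs <- find_sex_specific_runs(target, other, params)
  list(runs = runs,
       candidates = merge_and_filter_candidates(runs, target, params),
       params = params)
}

#' Classify the sex-determination system from two reference scans
#'
#' Takes the female-pool-specific scan on the female reference and the
#' male-pool-specific scan on the male reference. Surviving female-specific
#' candidates without male-specific ones call a ZW system (the
#' heterogametic female carries a region males lack); the mirror calls XY;
#' candidates on both sides are ambiguous; none on either side gives no
#' call. Sub-threshold contrasts (depth fraction under the candidate
#' threshold) are reported as background in the evidence summary.
#'
#' @param female_ref_scan scan of the female pool against the female
#'   reference (from [scan_sex_specific_regions()] with the male pool as
#'   `other`)
#' @param male_ref_scan scan of the male pool against the male reference
#' @param params a [scan_params()]
#' @return a list of class `sex_system_call` with `model` (one of "ZW",
#'   "XY", "ambiguous", "none"), `female_specific_regions`,
#'   `male_specific_regions`, and `evidence`
#' @export
classify_sex_system <- function(female_ref_scan, male_ref_scan,
                                params = scan_params()) {
  f_cand <- female_ref_scan$candidates
  m_cand <- male_ref_scan$candidates
  model <- if (nrow(f_cand) > 0 && nrow(m_cand) == 0) "ZW"
  else if (nrow(m_cand) > 0 && nrow(f_cand) == 0) "XY"
  else if (nrow(f_cand) > 0 && nrow(m_cand) > 0) "ambiguous"
  else "none"
  evidence <- sprintf(
    paste0("%d female-specific candidate region(s); %d male-specific; ",
           "background contrasts below a depth fraction of %.2f ignored"),
    nrow(f_cand), nrow(m_cand), params$noise_fraction_ceiling)
  structure(list(model = model, female_specific_regions = f_cand,
                 male_specific_regions = m_cand, evidence = evidence),
            class = "sex_system_call")
}

#' @export
print.sex_system_call <- function(x, ...) {
  cat("Sex system call:", x$model, "\n ", x$evidence, "\n")
  invisible(x)
}

#' Write candidate regions as BED
#'
#' 0-based half-open records; the score column carries the depth fraction
#' scaled to 0-1000 (capped).
#'
#' @param candidates candidate data.frame from
#'   [merge_and_filter_candidates()]
#' @param path output path
#' @export
candidates_to_bed <- function(candidates, path) {
  if (nrow(candidates) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- data.frame(
    chrom = candidates$reference_id, start = candidates$start,
    end = candidates$end,
    name = sprintf("candidate_%d", seq_len(nrow(candidates))),
    score = pmin(1000L, as.integer(round(candidates$depth_fraction * 1000))),
    strand = ".")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
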