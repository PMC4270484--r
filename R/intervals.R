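# Genomic intervals are plain tibbles with columns chrom, start, end
# (0-based, half-open, BED convention) and optionally strand. All
# overlap machinery below works in that coordinate system.

#' Construct a tibble of genomic intervals
#'
#' Intervals follow the BED convention: 0-based starts, half-open ends.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-like positions with `0 <= start < end`.
#' @param strand Optional strand (`"+"`, `"-"` or `"*"`); recycled.
#' @param ... Further columns passed to [tibble::tibble()].
#' @return A tibble with at least `chrom`, `start`, `end`.
#' @examples
#' genome_intervals("chr1", c(0, 100), c(50, 200))
#' @export
genome_intervals <- function(chrom, start, end, strand = "*", ...) {
  iv <- tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    ...
  )
  validate_intervals(iv)
  iv
}

#' Validate interval invariants
#'
#' Checks that `chrom` is non-empty, `start >= 0` and `start < end`.
#'
#' @param iv A tibble with `chrom`, `start`, `end`.
#' @param what Label used in error messages.
#' @return `iv`, invisibly.
#' @export
validate_intervals <- function(iv, what = "interval") {
  stopifnot(is.data.frame(iv), all(c("chrom", "start", "end") %in% names(iv)))
  bad <- which(is.na(iv$chrom) | iv$chrom == "" |
    is.na(iv$start) | is.na(iv$end) |
    iv$start < 0 | iv$start >= iv$end)
  if (length(bad)) {
    abort(sprintf(
      "%s %d violates interval invariants (need chrom != '', 0 <= start < end)",
      what, bad[1]
    ))
  }
  invisible(iv)
}

iranges_of <- function(iv) {
  IRanges::IRanges(start = iv$start + 1L, end = iv$end)
}

split_by_chrom <- function(iv) split(iv, iv$chrom)

#' Merge overlapping or bookended intervals
#'
#' @param iv Interval tibble.
#' @return Tibble of disjoint intervals sorted by (chrom, start).
#' @export
interval_union <- function(iv) {
  validate_intervals(iv)
  if (!nrow(iv)) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  purrr::map_dfr(split_by_chrom(iv), function(d) {
    r <- IRanges::reduce(iranges_of(d))
    tibble(
      chrom = d$chrom[1],
      start = IRanges::start(r) - 1L, end = IRanges::end(r)
    )
  }) %>% arrange(.data$chrom, .data$start)
}

#' Intersect two interval sets
#'
#' @param a,b Interval tibbles.
#' @return Tibble of intervals covering bases present in both sets.
#' @export
interval_intersect <- function(a, b) {
  validate_intervals(a)
  validate_intervals(b)
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  out <- purrr::map_dfr(chroms, function(ch) {
    r <- IRanges::intersect(
      iranges_of(a[a$chrom == ch, ]),
      iranges_of(b[b$chrom == ch, ])
    )
    tibble(chrom = ch, start = IRanges::start(r) - 1L, end = IRanges::end(r))
  })
  if (!nrow(out)) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  arrange(out, .data$chrom, .data$start)
}

#' Total bases shared by two interval sets
#'
#' @param a,b Interval tibbles.
#' @return Number of shared bases (double).
#' @export
interval_overlap_bp <- function(a, b) {
  x <- interval_intersect(a, b)
  sum(as.numeric(x$end - x$start))
}

#' Does each interval in `a` overlap anything in `b`?
#'
#' @param a,b Interval tibbles.
#' @param min_bp Minimum shared bases to count as overlap.
#' @return Logical vector along rows of `a`.
#' @export
interval_overlaps_any <- function(a, b, min_bp = 1L) {
  validate_intervals(a)
  if (!nrow(a)) return(logical())
  if (!nrow(b)) return(rep(FALSE, nrow(a)))
  out <- rep(FALSE, nrow(a))
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch)
    hits <- IRanges::findOverlaps(
      iranges_of(a[ia, , drop = FALSE]),
      iranges_of(b[b$chrom == ch, , drop = FALSE]),
      minoverlap = min_bp
    )
    out[ia[unique(IRanges::from(hits))]] <- TRUE
  }
  out
}

# cumulative "mass below x" step function over weighted intervals;
# returns a closure F with F(x) = sum over intervals of covered bases < x
# (weights multiply per-base contribution). Intervals may overlap.
step_prefix <- function(start, end, weight = 1) {
  if (!length(start)) {
    return(function(x) rep(0, length(x)))
  }
  weight <- rep_len(weight, length(start))
  pos <- c(start, end)
  delta <- c(weight, -weight)
  o <- order(pos)
  pos <- pos[o]
  cov <- cumsum(delta[o])
  # collapse duplicate positions
  keep <- c(pos[-1] != pos[-length(pos)], TRUE)
  pos <- pos[keep]
  cov <- cov[keep]
  mass <- cumsum(c(0, cov[-length(cov)] * diff(pos)))
  function(x) {
    j <- findInterval(x, pos)
    out <- numeric(length(x))
    inside <- j >= 1
    jj <- pmin(j[inside], length(pos))
    out[inside] <- mass[jj] +
      ifelse(j[inside] >= length(pos), 0, cov[jj]) * (x[inside] - pos[jj])
    out
  }
}
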