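# Tag-to-signal quantification. Tags (aligned read intervals) are
# extended to a fixed fragment length from their 5' end, piled up into
# fixed-width bins, normalized to reads-per-million, input-subtracted
# with a floor at zero, and summarized over strand-aware promoter
# windows or length-normalized metagene profiles. Stored bin values are
# mean per-base coverage over the bin.

new_signal_track <- function(values, bin, chrom_sizes, units = "raw") {
  structure(
    list(values = values, bin = as.integer(bin),
         chrom_sizes = chrom_sizes, units = units),
    class = "signal_track"
  )
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf(
    "signal_track: %d chromosome(s), bin %d bp, units %s\n",
    length(x$values), x$bin, x$units
  ))
  invisible(x)
}

#' Turn a signal track into a tibble
#' @param x A `signal_track`.
#' @param ... Unused.
#' @return Tibble `chrom, start, end, value`.
#' @export
tidy.signal_track <- function(x, ...) {
  purrr::map_dfr(names(x$values), function(ch) {
    v <- x$values[[ch]]
    start <- (seq_along(v) - 1L) * x$bin
    tibble(
      chrom = ch, start = start,
      end = pmin(start + x$bin, x$chrom_sizes[[ch]]), value = v
    )
  })
}

#' Extend tags to fragments and pile up coverage
#'
#' Each tag contributes `fragment_length` bases of coverage extending
#' 3'-ward from its 5' end ('+' tags from `start`, '-' tags leftward from
#' `end`), clipped at the chromosome bounds. Unstranded tags are treated
#' as '+' with a warning.
#'
#' @param tags Interval tibble with `strand`.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param fragment_length Fragment extension in bp (default 200).
#' @param bin Bin width in bp (default 25).
#' @return `signal_track` of raw mean per-base coverage per bin.
#' @export
extend_and_pileup <- function(tags, chrom_sizes, fragment_length = 200L,
                              bin = 25L) {
  validate_intervals(tags)
  if (!"strand" %in% names(tags)) tags$strand <- "*"
  unknown <- !(tags$strand %in% c("+", "-"))
  if (any(unknown)) {
    warn(sprintf("%d unstranded tag(s) treated as '+'", sum(unknown)))
    tags$strand[unknown] <- "+"
  }
  frag_start <- ifelse(tags$strand == "+", tags$start,
    tags$end - as.integer(fragment_length)
  )
  frag_end <- frag_start + as.integer(fragment_length)
  values <- lapply(names(chrom_sizes), function(ch) {
    size <- chrom_sizes[[ch]]
    n_bins <- ceiling(size / bin)
    sel <- tags$chrom == ch
    if (!any(sel)) {
      return(numeric(n_bins))
    }
    s <- pmax(0, frag_start[sel])
    e <- pmin(size, frag_end[sel])
    keep <- s < e
    if (!any(keep)) {
      return(numeric(n_bins))
    }
    pf <- step_prefix(s[keep], e[keep])
    edges <- c(seq(0, by = bin, length.out = n_bins), size)
    edges[n_bins + 1] <- size
    mass <- diff(pf(pmin(edges, size)))
    width <- diff(pmin(edges, size))
    ifelse(width > 0, mass / width, 0)
  })
  names(values) <- names(chrom_sizes)
  new_signal_track(values, bin, chrom_sizes, units = "raw")
}

#' Normalize to RPM and subtract input control
#'
#' Per bin: `max(0, treat * 1e6 / n_treat - input * 1e6 / n_input)`, i.e.
#' both tracks scaled to reads-per-million before subtraction, floored at
#' zero.
#'
#' @param treat,input_ctrl Raw `signal_track`s on the same grid.
#' @param n_treat,n_input Total mapped reads for each library.
#' @return `signal_track` in input-subtracted RPM.
#' @export
normalize_subtract <- function(treat, input_ctrl, n_treat, n_input) {
  stopifnot(
    n_treat > 0, n_input > 0, treat$bin == input_ctrl$bin,
    identical(names(treat$values), names(input_ctrl$values))
  )
  values <- purrr::map2(
    treat$values, input_ctrl$values,
    ~ pmax(0, .x * 1e6 / n_treat - .y * 1e6 / n_input)
  )
  new_signal_track(values, treat$bin, treat$chrom_sizes, units = "rpm")
}

# mean track value over arbitrary half-open windows (vectorized);
# cumulative bin mass is interpolated linearly inside bins, so at bin = 1
# this is exact per-base averaging
track_window_mean <- function(track, chrom, start, end) {
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    v <- track$values[[ch]]
    if (is.null(v)) {
      out[chrom == ch] <- 0
      next
    }
    size <- track$chrom_sizes[[ch]]
    bin <- track$bin
    edges <- c(seq(0, by = bin, length.out = length(v)), size)
    edges[length(v) + 1] <- size
    width <- diff(edges)
    cum <- c(0, cumsum(v * width))
    pf <- function(x) {
      x <- pmin(pmax(x, 0), size)
      j <- pmin(findInterval(x, edges), length(v))
      j <- pmax(j, 1L)
      cum[j] + v[j] * (x - edges[j])
    }
    sel <- chrom == ch
    s <- pmax(0, start[sel])
    e <- pmin(end[sel], size)
    w <- pmax(e - s, 0)
    out[sel] <- ifelse(w > 0, (pf(e) - pf(s)) / w, 0)
  }
  out
}

# strand-aware promoter windows [TSS - upstream, TSS + downstream)
promoter_windows <- function(genes, upstream = 2000L, downstream = 2000L) {
  minus <- genes$strand == "-"
  tibble(
    chrom = genes$chrom,
    start = pmax(0L, as.integer(ifelse(minus,
      genes$tss - downstream + 1L, genes$tss - upstream
    ))),
    end = as.integer(ifelse(minus,
      genes$tss + upstream + 1L, genes$tss + downstream
    ))
  )
}

#' Promoter signal matrix over a panel of marks
#'
#' For every gene and mark track, the mean input-subtracted RPM over the
#' strand-aware window `[TSS - upstream, TSS + downstream)` is recorded
#' as `log2(1 + mean)`.
#'
#' @param tracks Named list of `signal_track`s (one per mark/TF).
#' @param genes Gene tibble.
#' @param upstream,downstream Window extent around the TSS, in the
#'   direction of transcription.
#' @return Tibble with `gene_id` plus one column per mark.
#' @export
promoter_matrix <- function(tracks, genes, upstream = 2000L, downstream = 2000L) {
  stopifnot(length(names(tracks)) == length(tracks))
  w <- promoter_windows(genes, upstream, downstream)
  out <- tibble(gene_id = genes$gene_id)
  for (mk in names(tracks)) {
    out[[mk]] <- log2(1 + track_window_mean(tracks[[mk]], w$chrom, w$start, w$end))
  }
  out
}

#' Length-normalized metagene profile
#'
#' Averages signal across genes over a fixed layout: `flank` bp upstream
#' of the TSS at native bin resolution, the gene body resampled to
#' `body_bins` equal slices, and `flank` bp downstream of the TES. Minus
#' strand genes are reflected so all profiles run 5' to 3'.
#'
#' @param track A `signal_track`.
#' @param genes Gene tibble; genes with body length < `body_bins` bp are
#'   dropped.
#' @param flank Flank extent in bp.
#' @param body_bins Number of body slices.
#' @return Tibble `position` (slice index), `zone`
#'   (upstream/body/downstream), `value` (mean over genes). Profile
#'   length is `2 * flank / bin(track) + body_bins`.
#' @export
metagene_profile <- function(track, genes, flank = 2000L, body_bins = 100L) {
  bin <- track$bin
  n_flank <- as.integer(flank / bin)
  body_lo <- pmin(genes$tss, genes$tes)
  body_hi <- pmax(genes$tss, genes$tes) + 1L
  eligible <- (body_hi - body_lo) >= body_bins
  if (!any(eligible)) abort("no genes with body length >= body_bins")
  g <- genes[eligible, , drop = FALSE]
  body_lo <- body_lo[eligible]
  body_hi <- body_hi[eligible]
  n_slices <- 2L * n_flank + body_bins
  acc <- matrix(0, nrow = nrow(g), ncol = n_slices)
  for (i in seq_len(nrow(g))) {
    up_edges <- seq(body_lo[i] - flank, body_lo[i], length.out = n_flank + 1)
    body_edges <- seq(body_lo[i], body_hi[i], length.out = body_bins + 1)
    down_edges <- seq(body_hi[i], body_hi[i] + flank, length.out = n_flank + 1)
    edges <- c(up_edges, body_edges[-1], down_edges[-1])
    vals <- track_window_mean(
      track, rep(g$chrom[i], n_slices), head(edges, -1), edges[-1]
    )
    if (g$strand[i] == "-") vals <- rev(vals)
    acc[i, ] <- vals
  }
  tibble(
    position = seq_len(n_slices),
    zone = rep(c("upstream", "body", "downstream"), c(n_flank, body_bins, n_flank)),
    value = colMeans(acc)
  )
}

#' Classify promoters by H3K4me3/H3K27me3 state
#'
#' Thresholds are on the pre-log input-subtracted RPM scale (the promoter
#' matrix stores `log2(1 + rpm)`): active = H3K4me3 above threshold only,
#' repressed = H3K27me3 only, bivalent = both, neither otherwise.
#'
#' @param pm Promoter matrix containing `H3K4me3` and `H3K27me3` columns.
#' @param k4me3_min,k27me3_min RPM thresholds (defaults 1 and 0.5).
#' @return Tibble `gene_id, class`.
#' @export
promoter_mark_class <- function(pm, k4me3_min = 1.0, k27me3_min = 0.5) {
  for (col in c("H3K4me3", "H3K27me3")) {
    if (!col %in% names(pm)) abort(sprintf("promoter matrix lacks column %s", col))
  }
  k4 <- 2^pm$H3K4me3 - 1 >= k4me3_min
  k27 <- 2^pm$H3K27me3 - 1 >= k27me3_min
  tibble(
    gene_id = pm$gene_id,
    class = dplyr::case_when(
      k4 & k27 ~ "bivalent",
      k4 ~ "active",
      k27 ~ "repressed",
      TRUE ~ "neither"
    )
  )
}

#' Correlate promoter-matrix columns
#'
#' Pearson or Spearman correlation between mark columns of one or two
#' promoter matrices over shared genes. Zero-variance columns give NA
#' with a warning.
#'
#' @param a,b Promoter matrices (`b` defaults to `a`).
#' @param method `"pearson"` or `"spearman"`.
#' @return Tibble `mark_a, mark_b, r, n`.
#' @export
promoter_correlation <- function(a, b = NULL, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.null(b)) b <- a
  shared <- dplyr::inner_join(a, b, by = "gene_id", suffix = c(".a", ".b"))
  if (nrow(shared) < 3) abort("fewer than 3 shared genes")
  marks_a <- setdiff(names(a), "gene_id")
  marks_b <- setdiff(names(b), "gene_id")
  grid <- tidyr::expand_grid(mark_a = marks_a, mark_b = marks_b)
  grid$r <- purrr::map2_dbl(grid$mark_a, grid$mark_b, function(ma, mb) {
    x <- shared[[if (paste0(ma, ".a") %in% names(shared)) paste0(ma, ".a") else ma]]
    y <- shared[[if (paste0(mb, ".b") %in% names(shared)) paste0(mb, ".b") else mb]]
    if (sd(x) == 0 || sd(y) == 0) {
      warn(sprintf("zero variance in %s or %s; correlation undefined", ma, mb))
      return(NA_real_)
    }
    cor(x, y, method = method)
  })
  grid$n <- nrow(shared)
  grid
}
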