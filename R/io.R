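# Readers and writers for every standard flat format the pipeline touches.
# All coordinates are BED-style 0-based half-open; chain query coordinates
# on '-' strand chains are kept in the UCSC reverse-complement frame and
# only converted to forward-strand coordinates at the lifting boundary.

#' Read a peak file
#'
#' Supports ENCODE narrowPeak (10 columns; column 10 is the summit offset
#' from `start`, `-1` meaning "no summit") and BED6 plus a 7th column with
#' an absolute summit position. Peaks without a summit fall back to the
#' interval midpoint, with a warning.
#'
#' @param path Path to the peak file.
#' @param dialect `"narrowPeak"` (summit as offset) or `"bed6+summit"`
#'   (summit as absolute position in column 7).
#' @param factor,sample Optional TF/mark name and sample tag attached to
#'   every peak (defaults to the file's `name` column / `NA`).
#' @return A tibble with columns `chrom, start, end, name, score, strand,
#'   summit, factor, sample`. `score` is the total mapped-read count in
#'   the peak region.
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "bed6+summit"),
                       factor = NULL, sample = NA_character_) {
  dialect <- match.arg(dialect)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      name = character(), score = double(), strand = character(),
      summit = integer(), factor = character(), sample = character()
    ))
  }
  fields <- stringr::str_split(lines, "[ \t]+")
  ncols <- if (dialect == "narrowPeak") 10L else 7L
  nf <- lengths(fields)
  if (any(nf < ncols)) {
    abort(sprintf(
      "malformed %s line %d in %s: expected >= %d fields, got %d",
      dialect, which(nf < ncols)[1], path, ncols, nf[which(nf < ncols)[1]]
    ))
  }
  m <- do.call(rbind, fields)
  pk <- tibble(
    chrom = m[, 1],
    start = as.integer(m[, 2]),
    end = as.integer(m[, 3]),
    name = m[, 4],
    score = as.double(m[, 5]),
    strand = m[, 6]
  )
  validate_intervals(pk, what = sprintf("peak record in %s, line", path))
  if (dialect == "narrowPeak") {
    off <- as.integer(m[, 10])
    missing_summit <- off < 0
    summit <- pk$start + off
  } else {
    summit <- as.integer(m[, 7])
    missing_summit <- is.na(summit) | summit < 0
  }
  if (any(missing_summit)) {
    warn(sprintf(
      "%d peak(s) in %s lack a summit; using interval midpoints",
      sum(missing_summit), path
    ))
    summit[missing_summit] <-
      (pk$start[missing_summit] + pk$end[missing_summit]) %/% 2L
  }
  bad <- which(summit < pk$start | summit >= pk$end)
  if (length(bad)) {
    abort(sprintf(
      "peak record at line %d of %s: summit %d outside interval [%d, %d)",
      bad[1], path, summit[bad[1]], pk$start[bad[1]], pk$end[bad[1]]
    ))
  }
  if (any(pk$score < 0)) abort(sprintf("negative peak score in %s", path))
  pk$summit <- as.integer(summit)
  pk$factor <- if (is.null(factor)) pk$name else factor
  pk$sample <- sample
  pk
}

#' Write peaks as narrowPeak
#'
#' @param peaks Peak tibble as returned by [read_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%g\t%s\t0\t-1\t-1\t%d",
    peaks$chrom, peaks$start, peaks$end, peaks$name, peaks$score,
    peaks$strand, peaks$summit - peaks$start
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a UCSC chain file
#'
#' Each chain is one row; its alignment blocks live in the `blocks`
#' list-column as a tibble with `size`, `dt`, `dq` plus precomputed
#' absolute block starts `t_start`, `q_start` (chain frames). Block sums
#' are checked against the header spans.
#'
#' @param path Path to a chain file.
#' @return Tibble with the twelve UCSC header fields plus `blocks`.
#' @export
read_chain <- function(path) {
  lines <- readr::read_lines(path)
  lines <- stringr::str_trim(lines)
  i <- 1L
  out <- list()
  while (i <= length(lines)) {
    if (!nzchar(lines[i]) || startsWith(lines[i], "#")) {
      i <- i + 1L
      next
    }
    f <- stringr::str_split_1(lines[i], "[ \t]+")
    if (f[1] != "chain" || length(f) != 13) {
      abort(sprintf("expected chain header at line %d of %s", i, path))
    }
    hdr <- list(
      score = as.double(f[2]),
      t_name = f[3], t_size = as.integer(f[4]), t_strand = f[5],
      t_start = as.integer(f[6]), t_end = as.integer(f[7]),
      q_name = f[8], q_size = as.integer(f[9]), q_strand = f[10],
      q_start = as.integer(f[11]), q_end = as.integer(f[12]),
      id = f[13]
    )
    i <- i + 1L
    size <- integer()
    dt <- integer()
    dq <- integer()
    repeat {
      if (i > length(lines)) abort(sprintf("truncated chain %s in %s", hdr$id, path))
      if (!nzchar(lines[i])) {
        i <- i + 1L
        next
      }
      b <- suppressWarnings(as.integer(stringr::str_split_1(lines[i], "[ \t]+")))
      if (anyNA(b)) abort(sprintf("malformed block line %d in %s", i, path))
      i <- i + 1L
      if (length(b) == 1) {
        size <- c(size, b)
        dt <- c(dt, 0L)
        dq <- c(dq, 0L)
        break
      } else if (length(b) == 3) {
        size <- c(size, b[1])
        dt <- c(dt, b[2])
        dq <- c(dq, b[3])
      } else {
        abort(sprintf("malformed block line %d in %s", i, path))
      }
    }
    if (any(size <= 0) || any(dt < 0) || any(dq < 0)) {
      abort(sprintf("chain %s: block sizes must be > 0 and gaps >= 0", hdr$id))
    }
    t_span <- sum(size) + sum(dt)
    q_span <- sum(size) + sum(dq)
    if (t_span != hdr$t_end - hdr$t_start || q_span != hdr$q_end - hdr$q_start) {
      abort(sprintf(
        "chain %s: block sums (t %d, q %d) disagree with header spans (t %d, q %d)",
        hdr$id, t_span, q_span, hdr$t_end - hdr$t_start, hdr$q_end - hdr$q_start
      ))
    }
    blocks <- tibble(
      size = size, dt = dt, dq = dq,
      t_start = hdr$t_start + cumsum(c(0L, head(size + dt, -1))),
      q_start = hdr$q_start + cumsum(c(0L, head(size + dq, -1)))
    )
    out[[length(out) + 1L]] <- c(hdr, list(blocks = list(blocks)))
  }
  if (!length(out)) abort(sprintf("no chains found in %s", path))
  bind_rows(out)
}

#' Write chains in UCSC chain format
#'
#' @param chains Chain tibble from [read_chain()] or the simulator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chains, path) {
  txt <- purrr::map_chr(seq_len(nrow(chains)), function(i) {
    h <- chains[i, ]
    b <- h$blocks[[1]]
    hdr <- sprintf(
      "chain %g %s %d %s %d %d %s %d %s %d %d %s",
      h$score, h$t_name, h$t_size, h$t_strand, h$t_start, h$t_end,
      h$q_name, h$q_size, h$q_strand, h$q_start, h$q_end, h$id
    )
    n <- nrow(b)
    body <- if (n > 1) {
      c(sprintf("%d %d %d", b$size[-n], b$dt[-n], b$dq[-n]), sprintf("%d", b$size[n]))
    } else {
      sprintf("%d", b$size[1])
    }
    paste(c(hdr, body, ""), collapse = "\n")
  })
  readr::write_lines(txt, path)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-separated with header columns `gene_id, ortholog_id, chrom, start,
#' end, strand, tss, tes`. `ortholog_id` may be empty/NA for genes without
#' a one-to-one partner.
#'
#' @param path Path to the TSV.
#' @return Gene tibble; invariants (TSS/TES inside the gene body, minus
#'   strand genes with `tss >= tes`) enforced.
#' @export
read_gene_table <- function(path) {
  g <- readr::read_tsv(path,
    col_types = readr::cols(
      gene_id = "c", ortholog_id = "c", chrom = "c", start = "i",
      end = "i", strand = "c", tss = "i", tes = "i"
    )
  )
  validate_gene_table(g)
}

#' Validate gene-table invariants
#' @param g Gene tibble.
#' @return `g` invisibly-visibly (returned for piping).
#' @export
validate_gene_table <- function(g) {
  validate_intervals(g, what = "gene record")
  if (anyDuplicated(g$gene_id)) {
    abort(sprintf("duplicate gene_id: %s", g$gene_id[duplicated(g$gene_id)][1]))
  }
  inside <- g$tss >= g$start & g$tss < g$end & g$tes >= g$start & g$tes < g$end
  if (!all(inside)) abort(sprintf("gene %s: tss/tes outside gene body", g$gene_id[!inside][1]))
  bad_minus <- g$strand == "-" & g$tss < g$tes
  bad_plus <- g$strand == "+" & g$tss > g$tes
  if (any(bad_minus | bad_plus)) {
    abort(sprintf(
      "gene %s: tss/tes ordering inconsistent with strand",
      g$gene_id[bad_minus | bad_plus][1]
    ))
  }
  g
}

#' Write a gene table
#' @param genes Gene tibble.
#' @param path Output path.
#' @export
write_gene_table <- function(genes, path) {
  readr::write_tsv(
    genes[, c("gene_id", "ortholog_id", "chrom", "start", "end", "strand", "tss", "tes")],
    path
  )
  invisible(path)
}

#' Read a chromatin-state segmentation BED
#'
#' Four columns: chrom, start, end, state (integer `1..n_states`, possibly
#' prefixed "E" as ChromHMM writes it). Segments of one genome must not
#' overlap.
#'
#' @param path Path to segmentation BED.
#' @param n_states Number of states in the model; labels outside
#'   `1..n_states` are an error.
#' @return Tibble `chrom, start, end, state`.
#' @export
read_segmentation <- function(path, n_states = 15L) {
  s <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "state"),
    col_types = "ciic"
  )
  s$state <- as.integer(sub("^E", "", s$state))
  validate_segmentation(s, n_states)
}

#' Validate segmentation invariants (no overlap, states in range)
#' @param s Segmentation tibble.
#' @param n_states Declared number of states.
#' @export
validate_segmentation <- function(s, n_states = 15L) {
  validate_intervals(s, what = "state segment")
  if (any(is.na(s$state) | s$state < 1 | s$state > n_states)) {
    abort(sprintf("state label outside 1..%d in segmentation", n_states))
  }
  s <- arrange(s, .data$chrom, .data$start)
  same <- s$chrom[-1] == s$chrom[-nrow(s)]
  if (nrow(s) > 1 && any(same & s$start[-1] < s$end[-nrow(s)])) {
    abort("overlapping state segments")
  }
  s
}

#' Write a segmentation BED
#' @param seg Segmentation tibble.
#' @param path Output path.
#' @export
write_segmentation <- function(seg, path) {
  readr::write_tsv(seg[, c("chrom", "start", "end", "state")], path,
    col_names = FALSE
  )
  invisible(path)
}

#' Read an expression table
#'
#' TSV with header `gene_id, stage, replicate, fpkm` (FPKM: fragments per
#' kilobase of transcript per million mapped reads, non-negative).
#'
#' @param path Path to the TSV.
#' @return Expression tibble.
#' @export
read_expression <- function(path) {
  e <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", stage = "c", replicate = "i", fpkm = "d"
  ))
  validate_expression(e)
}

#' Validate expression-table invariants
#' @param e Expression tibble.
#' @export
validate_expression <- function(e) {
  if (any(is.na(e$fpkm) | e$fpkm < 0)) abort("FPKM must be non-negative")
  if (anyDuplicated(e[, c("gene_id", "stage", "replicate")])) {
    abort("duplicate (gene_id, stage, replicate) rows in expression table")
  }
  e
}

#' Write an expression table
#' @param expr Expression tibble.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr[, c("gene_id", "stage", "replicate", "fpkm")], path)
  invisible(path)
}

#' Drop genes whose ortholog is missing from the partner table
#'
#' Genes claiming an `ortholog_id` absent from the partner's `gene_id`
#' column are excluded (with a warning), as are genes with no ortholog.
#'
#' @param genes,partner Gene tibbles for the two species.
#' @return `genes` restricted to one-to-one pairs present in `partner`.
#' @export
paired_orthologs <- function(genes, partner) {
  has <- !is.na(genes$ortholog_id) & genes$ortholog_id %in% partner$gene_id
  dropped <- sum(!is.na(genes$ortholog_id) & !has)
  if (dropped > 0) {
    warn(sprintf("%d gene(s) have an ortholog_id absent from the partner table; excluded", dropped))
  }
  genes[has, , drop = FALSE]
}
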