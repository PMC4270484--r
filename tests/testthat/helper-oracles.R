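# Independent brute-force oracles used across the suite. These re-derive
# expected values per base / per placement, deliberately sharing no code
# with the implementation paths they check.

# map every base of [start, end) through the chain blocks independently;
# returns the per-base images (forward query strand) and aligned count
oracle_lift <- function(chain_row, start, end) {
  b <- chain_row$blocks[[1]]
  images <- c()
  for (pos in seq(start, end - 1)) {
    for (j in seq_len(nrow(b))) {
      tb <- b$t_start[j]
      if (pos >= tb && pos < tb + b$size[j]) {
        q <- b$q_start[j] + (pos - tb)
        if (chain_row$q_strand == "-") q <- chain_row$q_size - 1 - q
        images <- c(images, q)
      }
    }
  }
  if (!length(images)) {
    return(list(n = 0L, span = NULL))
  }
  list(
    n = length(images),
    span = c(min(images), max(images) + 1L)
  )
}

# random multi-block chain on one chromosome pair
random_chain <- function(id, t_name = "chrT", q_name = "chrQ",
                         q_strand = "+", n_blocks = sample(2:6, 1)) {
  size <- sample(20:120, n_blocks, replace = TRUE)
  dt <- c(sample(0:80, n_blocks - 1, replace = TRUE), 0L)
  dq <- c(sample(0:80, n_blocks - 1, replace = TRUE), 0L)
  t_start0 <- sample(0:200, 1)
  q_start0 <- sample(0:200, 1)
  t_span <- sum(size) + sum(dt)
  q_span <- sum(size) + sum(dq)
  tibble::tibble(
    score = sample(100:1000, 1),
    t_name = t_name, t_size = t_start0 + t_span + 500L, t_strand = "+",
    t_start = t_start0, t_end = t_start0 + t_span,
    q_name = q_name, q_size = q_start0 + q_span + 500L, q_strand = q_strand,
    q_start = q_start0, q_end = q_start0 + q_span, id = as.character(id),
    blocks = list(tibble::tibble(
      size = size, dt = dt, dq = dq,
      t_start = t_start0 + cumsum(c(0L, utils::head(size + dt, -1))),
      q_start = q_start0 + cumsum(c(0L, utils::head(size + dq, -1)))
    ))
  )
}

identity_chain <- function(len = 1000L, t_name = "chrT", q_name = "chrQ") {
  tibble::tibble(
    score = 1000, t_name = t_name, t_size = len, t_strand = "+",
    t_start = 0L, t_end = len, q_name = q_name, q_size = len,
    q_strand = "+", q_start = 0L, q_end = len, id = "1",
    blocks = list(tibble::tibble(
      size = len, dt = 0L, dq = 0L, t_start = 0L, q_start = 0L
    ))
  )
}

# per-base coverage oracle: counts fragments covering each base
oracle_pileup <- function(tags, chrom_size, fragment_length) {
  cov <- integer(chrom_size)
  for (i in seq_len(nrow(tags))) {
    s <- if (tags$strand[i] == "-") tags$end[i] - fragment_length else tags$start[i]
    e <- s + fragment_length
    s <- max(s, 0)
    e <- min(e, chrom_size)
    if (s < e) cov[(s + 1):e] <- cov[(s + 1):e] + 1L
  }
  cov
}

# per-base membership oracle for interval set operations
oracle_base_set <- function(iv, chrom, size) {
  covered <- logical(size)
  d <- iv[iv$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(d))) {
    s <- max(d$start[i], 0) + 1
    e <- min(d$end[i], size)
    if (s <= e) covered[s:e] <- TRUE
  }
  covered
}

# rank-then-average quantile normalization oracle (ties averaged)
oracle_quantile_normalize <- function(mat) {
  ref <- rowMeans(apply(mat, 2, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    r <- rank(mat[, j], ties.method = "average")
    out[, j] <- stats::approx(seq_len(nrow(mat)), ref, xout = r)$y
  }
  out
}

# tiny peak tibble builder
make_peaks <- function(chrom, summit, score = 100, factor = "TF",
                       half = 100L, sample = "s") {
  tibble::tibble(
    chrom = chrom, start = as.integer(summit - half),
    end = as.integer(summit + half),
    name = sprintf("p%03d", seq_along(summit)), score = as.double(score),
    strand = ".", summit = as.integer(summit), factor = factor,
    sample = sample
  )
}

# build a signal_track directly from a value vector (test fixture)
new_track_for_test <- function(values, bin, size, chrom = "chr1") {
  orthopeaks:::new_signal_track(
    setNames(list(values), chrom), bin,
    setNames(as.integer(size), chrom), units = "rpm"
  )
}
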