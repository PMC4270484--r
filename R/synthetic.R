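# Paired-species synthetic fixtures with planted ground truth. Species A
# ("mouse-like" source) and species B ("human-like" destination) are
# linked by a block/gap chain alignment; ortholog genes sit at
# chain-corresponding positions; TF peak sets carry planted conservation,
# compensatory and gain structure; promoter marks follow a planted linear
# model of expression; a chromatin-state segmentation plants active-state
# enrichment over conserved sites. Everything is deterministic under the
# config seed.

#' Simulation configuration
#'
#' Defaults are the desk-scale study conditions: two 200-Mb chromosomes
#' per species (chosen so peak density, about one destination peak per
#' 300 kb per TF, is of the same order as real ChIP-seq peak sets --
#' denser genomes would let random peaks fall inside the +/- 5 kb
#' compensatory windows and mask the planted rate), 2,000
#' ortholog-eligible genes, a four-TF panel with 2,000
#' source peaks each, planted conservation rates of 0.25 for the
#' master-regulator-like TFs and 0.60 for the KLF1-like TF, a
#' compensatory rate of 0.25 of lost sites, ten promoter marks with five
#' nonzero planted coefficients and noise set for a true R-squared of
#' 0.60, and a 15-state segmentation with 5-fold active-state enrichment
#' over conserved/strongly-gained sites.
#'
#' @param seed Integer seed; every stage derives its randomness from it.
#' @param n_chrom,chrom_length Chromosome count and length (species A).
#' @param unmappable_frac Fraction of species-A bases outside aligned
#'   chain blocks.
#' @param n_genes Number of genes per species.
#' @param ortholog_frac Fraction of genes with a one-to-one partner.
#' @param tf_panel Named numeric vector: planted conservation rate per TF.
#' @param n_peaks Source peaks per TF.
#' @param p_comp Fraction of lost sites with a compensatory partner.
#' @param n_gain Pure species-B gain peaks per TF.
#' @param score_slope Dependence of per-peak conservation probability on
#'   the score rank (mean stays at the TF's planted rate).
#' @param marks Mark/TF names for the promoter model.
#' @param beta_true Planted coefficient vector (same length as `marks`).
#' @param r2_true Planted variance explained; sets the noise SD via
#'   `sigma^2 = Var(X beta) (1 - R2) / R2`.
#' @param divergent_frac Fraction of ortholog genes with strong planted
#'   mark divergence (the species-specific set).
#' @param divergence_sd Per-mark SD of the between-species mark
#'   difference, `c(specific, background)`.
#' @param stages Expression stage names (first = ProE-like reference).
#' @param n_states,active_state,state_fold Segmentation model: number of
#'   states, the active state planted over conserved/strongly-gained
#'   sites, and its planted fold enrichment.
#' @param category_offsets Optional named vector of per-category
#'   expression offsets (planted into non-reference stages when given).
#' @param coocc_panel TF panel for the planted co-occupancy study.
#' @param coocc_n Regions per combinatorial tier (triple / each pair /
#'   each single).
#' @param coocc_retention Planted full-set retention per tier (triple
#'   regions transfer intact far more often than pairs or singles).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_length = 2e8,
                       unmappable_frac = 0.10,
                       n_genes = 2000L,
                       ortholog_frac = 0.90,
                       tf_panel = c(GATA1 = 0.25, TAL1 = 0.25, NFE2 = 0.25, KLF1 = 0.60),
                       n_peaks = 2000L,
                       p_comp = 0.25,
                       n_gain = 500L,
                       score_slope = 0.3,
                       marks = c(
                         "H3K9ac", "H3K4me3", "H3K27me3", "H3K36me3", "GATA1",
                         "H3K4me2", "H3K4me1", "TAL1", "KLF1", "NFE2"
                       ),
                       beta_true = c(3, 2, -1.5, 1, 0.5, 0, 0, 0, 0, 0),
                       r2_true = 0.60,
                       divergent_frac = 0.20,
                       divergence_sd = c(specific = 0.83, background = 0.44),
                       stages = c("ProE", "eBasoE", "BasoE", "lBasoE", "PolyE", "OrthE"),
                       n_states = 15L,
                       active_state = 5L,
                       state_fold = 5,
                       category_offsets = NULL,
                       coocc_panel = c("GATA1", "KLF1", "TAL1"),
                       coocc_n = c(triple = 400L, pair = 800L, single = 1600L),
                       coocc_retention = c(triple = 0.35, pair = 0.15, single = 0.05)) {
  stopifnot(
    length(beta_true) == length(marks),
    all(tf_panel >= 0 & tf_panel <= 1),
    p_comp >= 0, p_comp <= 1, unmappable_frac >= 0, unmappable_frac < 1,
    r2_true > 0, r2_true < 1, chrom_length > 0
  )
  structure(as.list(environment()), class = "sim_config")
}

# split RNG streams deterministically off the master seed
sub_seed <- function(seed, k) (as.integer(seed) * 1009L + k * 9973L) %% 2147483562L

#' Generate a paired genome: chain + two gene tables
#'
#' Aligned blocks (median ~100 kb) alternate with target-only gaps that
#' realize the configured unmappable fraction and small query insertions.
#' Ortholog genes are placed wholly inside aligned blocks so their
#' species-B coordinates follow from the chain; non-ortholog genes are
#' species-specific.
#'
#' @param cfg A `sim_config`.
#' @return List: `chains` (chain tibble, A -> B), `genes_a`, `genes_b`,
#'   `chrom_sizes_a`, `chrom_sizes_b`.
#' @export
generate_genome_pair <- function(cfg) {
  set.seed(sub_seed(cfg$seed, 1L))
  chains <- list()
  sizes_a <- integer()
  sizes_b <- integer()
  for (ci in seq_len(cfg$n_chrom)) {
    t_name <- sprintf("chrA%d", ci)
    q_name <- sprintf("chrB%d", ci)
    t_size <- as.integer(cfg$chrom_length)
    # alternate blocks and gaps until the chromosome is consumed
    size <- integer(); dt <- integer(); dq <- integer()
    pos <- 0L
    gap_scale <- cfg$unmappable_frac / max(1 - cfg$unmappable_frac, 1e-9)
    while (pos < t_size) {
      b <- as.integer(runif(1, 5e4, 1.5e5))
      b <- min(b, t_size - pos)
      size <- c(size, b)
      pos <- pos + b
      if (pos >= t_size) {
        dt <- c(dt, 0L); dq <- c(dq, 0L)
        break
      }
      g <- as.integer(runif(1, 0.5, 1.5) * b * gap_scale)
      g <- min(g, t_size - pos - 1L)
      ins <- as.integer(runif(1, 0, 5e3))
      dt <- c(dt, g); dq <- c(dq, ins)
      pos <- pos + g
    }
    n <- length(size)
    dt[n] <- 0L; dq[n] <- 0L
    q_span <- sum(size) + sum(dq)
    q_size <- as.integer(q_span)
    chains[[ci]] <- tibble(
      score = 1000, t_name = t_name, t_size = t_size, t_strand = "+",
      t_start = 0L, t_end = as.integer(sum(size) + sum(dt)),
      q_name = q_name, q_size = q_size, q_strand = "+",
      q_start = 0L, q_end = q_size, id = as.character(ci),
      blocks = list(tibble(
        size = size, dt = dt, dq = dq,
        t_start = cumsum(c(0L, head(size + dt, -1))),
        q_start = cumsum(c(0L, head(size + dq, -1)))
      ))
    )
    sizes_a[t_name] <- t_size
    sizes_b[q_name] <- q_size
  }
  chains <- bind_rows(chains)

  # genes inside aligned blocks, mapped through the chain
  n_orth <- round(cfg$n_genes * cfg$ortholog_frac)
  n_spec <- cfg$n_genes - n_orth
  blocks_all <- purrr::map_dfr(seq_len(nrow(chains)), function(i) {
    b <- chains$blocks[[i]]
    tibble(
      chrom_a = chains$t_name[i], chrom_b = chains$q_name[i],
      t_start = b$t_start, q_start = b$q_start, size = b$size
    )
  }) %>% filter(.data$size > 30000)
  gene_len <- as.integer(runif(n_orth, 3000, 15000))
  bi <- sample(nrow(blocks_all), n_orth, replace = TRUE, prob = blocks_all$size)
  off <- floor(runif(n_orth) * (blocks_all$size[bi] - gene_len - 100)) + 50
  strand <- sample(c("+", "-"), n_orth, replace = TRUE)
  mk_genes <- function(chrom, start, len, strand, ids, orth) {
    end <- start + len
    tibble(
      gene_id = ids, ortholog_id = orth, chrom = chrom,
      start = as.integer(start), end = as.integer(end), strand = strand,
      tss = as.integer(ifelse(strand == "+", start, end - 1L)),
      tes = as.integer(ifelse(strand == "+", end - 1L, start))
    )
  }
  ids <- sprintf("g%05d", seq_len(n_orth))
  genes_a <- mk_genes(
    blocks_all$chrom_a[bi], blocks_all$t_start[bi] + off, gene_len, strand,
    ids, ids
  )
  genes_b <- mk_genes(
    blocks_all$chrom_b[bi], blocks_all$q_start[bi] + off, gene_len, strand,
    ids, ids
  )
  add_specific <- function(genes, chrom_sizes, prefix) {
    if (n_spec <= 0) return(genes)
    len <- as.integer(runif(n_spec, 3000, 15000))
    ch <- sample(names(chrom_sizes), n_spec, replace = TRUE)
    st <- floor(runif(n_spec) * (unlist(chrom_sizes)[ch] - len - 100)) + 50
    sp <- mk_genes(
      ch, st, len, sample(c("+", "-"), n_spec, replace = TRUE),
      sprintf("%s%05d", prefix, seq_len(n_spec)), NA_character_
    )
    bind_rows(genes, sp)
  }
  genes_a <- add_specific(genes_a, sizes_a, "sa")
  genes_b <- add_specific(genes_b, sizes_b, "sb")
  list(
    chains = chains, genes_a = validate_gene_table(genes_a),
    genes_b = validate_gene_table(genes_b),
    chrom_sizes_a = sizes_a, chrom_sizes_b = sizes_b
  )
}

# exact A -> B map for positions inside aligned blocks (NA otherwise)
chain_map_position <- function(chains, chrom, pos) {
  out <- rep(NA_integer_, length(pos))
  chrom_b <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(chains))) {
    sel <- which(chrom == chains$t_name[i])
    if (!length(sel)) next
    b <- chains$blocks[[i]]
    j <- findInterval(pos[sel], b$t_start)
    ok <- j >= 1 & pos[sel] < b$t_start[pmax(j, 1)] + b$size[pmax(j, 1)]
    out[sel[ok]] <- b$q_start[j[ok]] + (pos[sel][ok] - b$t_start[j[ok]])
    chrom_b[sel[ok]] <- chains$q_name[i]
  }
  tibble(chrom = chrom_b, pos = out)
}

#' Generate planted-conservation peak sets
#'
#' Source peaks (species A) get summits inside aligned blocks; each is
#' planted conserved with a per-peak probability whose mean is the TF's
#' configured rate (optionally increasing with score rank). Conserved
#' peaks receive an overlapping species-B partner; a fraction `p_comp` of
#' lost peaks receive a nearby (within +/- 5 kb, non-overlapping)
#' compensatory partner. Pure gain peaks with heavy-tailed scores are
#' added on species B.
#'
#' @param cfg A `sim_config`.
#' @param gp Genome pair from [generate_genome_pair()].
#' @return List: `src`, `dst` (peak tibbles), `truth` (per source peak:
#'   planted category; per dst peak: planted origin).
#' @export
generate_peaks <- function(cfg, gp) {
  set.seed(sub_seed(cfg$seed, 2L))
  peak_half <- 100L
  src_list <- list()
  dst_list <- list()
  truth_list <- list()
  blocks_all <- purrr::map_dfr(seq_len(nrow(gp$chains)), function(i) {
    b <- gp$chains$blocks[[i]]
    tibble(chrom = gp$chains$t_name[i], t_start = b$t_start, size = b$size)
  }) %>% filter(.data$size > 2 * peak_half + 200)
  for (tf in names(cfg$tf_panel)) {
    p_cons <- cfg$tf_panel[[tf]]
    n <- cfg$n_peaks
    bi <- sample(nrow(blocks_all), n, replace = TRUE, prob = blocks_all$size)
    summit <- blocks_all$t_start[bi] + peak_half + 100L +
      floor(runif(n) * (blocks_all$size[bi] - 2 * (peak_half + 100L)))
    score <- round(rlnorm(n, meanlog = 5, sdlog = 1)) + 1
    # conservation probability tied to score rank; mean preserved and the
    # p(1-p) factor keeps degenerate rates (0, 1) exact
    rank01 <- (rank(score, ties.method = "first") - 0.5) / n
    p_i <- p_cons + 4 * cfg$score_slope * p_cons * (1 - p_cons) * (rank01 - 0.5)
    p_i <- pmin(pmax(p_i, 0), 1)
    conserved <- runif(n) < p_i
    comp <- !conserved & runif(n) < cfg$p_comp
    src <- tibble(
      chrom = blocks_all$chrom[bi],
      start = as.integer(summit - peak_half),
      end = as.integer(summit + peak_half),
      name = sprintf("%s_a_%04d", tf, seq_len(n)),
      score = as.double(score), strand = ".",
      summit = as.integer(summit), factor = tf, sample = "speciesA"
    )
    mapped <- chain_map_position(gp$chains, src$chrom, src$summit)
    mk_dst <- function(sel, offset, origin) {
      if (!any(sel)) return(NULL)
      s2 <- mapped$pos[sel] + offset[sel]
      tibble(
        chrom = mapped$chrom[sel],
        start = as.integer(s2 - peak_half), end = as.integer(s2 + peak_half),
        name = sprintf("%s_b_%s_%04d", tf, origin, which(sel)),
        score = round(rlnorm(sum(sel), 5, 1)) + 1, strand = ".",
        summit = as.integer(s2), factor = tf, sample = "speciesB",
        origin = origin, src_name = src$name[sel]
      )
    }
    zero <- integer(n)
    comp_off <- (sample(c(-1L, 1L), n, replace = TRUE)) *
      as.integer(runif(n, 500, 4500))
    dst_cons <- mk_dst(conserved, zero, "conserved_partner")
    dst_comp <- mk_dst(comp, comp_off, "compensatory_partner")
    # pure gains with heavy-tailed scores
    gb <- sample(names(gp$chrom_sizes_b), cfg$n_gain, replace = TRUE,
      prob = unlist(gp$chrom_sizes_b))
    gs <- peak_half + 100L +
      floor(runif(cfg$n_gain) * (unlist(gp$chrom_sizes_b)[gb] - 2 * (peak_half + 100L)))
    dst_gain <- tibble(
      chrom = gb, start = as.integer(gs - peak_half),
      end = as.integer(gs + peak_half),
      name = sprintf("%s_b_gain_%04d", tf, seq_len(cfg$n_gain)),
      score = round(rlnorm(cfg$n_gain, 5, 1.5)) + 1, strand = ".",
      summit = as.integer(gs), factor = tf, sample = "speciesB",
      origin = "gain", src_name = NA_character_
    )
    src_list[[tf]] <- src
    dst_list[[tf]] <- bind_rows(dst_cons, dst_comp, dst_gain)
    truth_list[[tf]] <- tibble(
      name = src$name, factor = tf,
      planted = dplyr::case_when(
        conserved ~ "conserved",
        comp ~ "lost_with_compensatory",
        TRUE ~ "lost"
      )
    )
  }
  dst <- bind_rows(dst_list)
  list(
    src = bind_rows(src_list),
    dst = dst %>% select(-"origin", -"src_name"),
    truth = list(
      source = bind_rows(truth_list),
      dst_origin = dst[, c("name", "factor", "origin", "src_name")]
    )
  )
}

#' Generate a co-occupancy study with planted group retention
#'
#' Plants source co-occupancy regions of chosen combinatorial groups at
#' well-separated mappable anchors; with the group's retention
#' probability the destination genome receives the full same TF set at
#' the chain-mapped anchor, otherwise nothing (the region maps but lands
#' "absent").
#'
#' @param gp Genome pair from [generate_genome_pair()].
#' @param n_by_group Named integer vector, names are "+"-joined sorted
#'   TF sets (e.g. `"GATA1+KLF1+TAL1"`).
#' @param retention_by_group Named numeric vector of planted full-set
#'   retention probabilities, same names.
#' @param seed Integer seed.
#' @param spread Max summit offset from the anchor within a region (bp).
#' @return List: `src`, `dst` peak tibbles, `truth` (per region:
#'   group, planted retained flag).
#' @export
generate_cooccupancy <- function(gp, n_by_group, retention_by_group, seed = 1L,
                                 spread = 400L) {
  stopifnot(setequal(names(n_by_group), names(retention_by_group)))
  set.seed(as.integer(seed))
  blocks_all <- purrr::map_dfr(seq_len(nrow(gp$chains)), function(i) {
    b <- gp$chains$blocks[[i]]
    tibble(chrom = gp$chains$t_name[i], t_start = b$t_start, size = b$size)
  }) %>% filter(.data$size > 20000)
  n_total <- sum(n_by_group)
  # anchor grid: one anchor per block segment of 20 kb, shuffled
  anchors <- purrr::map_dfr(seq_len(nrow(blocks_all)), function(i) {
    k <- floor(blocks_all$size[i] / 20000)
    tibble(
      chrom = blocks_all$chrom[i],
      pos = blocks_all$t_start[i] + 10000 + 20000 * (seq_len(k) - 1)
    )
  })
  if (nrow(anchors) < n_total) abort("genome too small for requested regions")
  anchors <- anchors[sample(nrow(anchors), n_total), ]
  group <- rep(names(n_by_group), n_by_group)
  retained <- runif(n_total) < retention_by_group[group]
  mapped <- chain_map_position(gp$chains, anchors$chrom, as.integer(anchors$pos))
  src_list <- list()
  dst_list <- list()
  for (i in seq_len(n_total)) {
    tfs <- strsplit(group[i], "+", fixed = TRUE)[[1]]
    off <- as.integer(round(runif(length(tfs), -spread, spread)))
    s <- as.integer(anchors$pos[i] + off)
    src_list[[i]] <- tibble(
      chrom = anchors$chrom[i], start = s - 100L, end = s + 100L,
      name = sprintf("r%04d_%s", i, tfs), score = 100, strand = ".",
      summit = s, factor = tfs, sample = "speciesA"
    )
    if (retained[i] && !is.na(mapped$pos[i])) {
      s2 <- as.integer(mapped$pos[i] + off)
      dst_list[[i]] <- tibble(
        chrom = mapped$chrom[i], start = s2 - 100L, end = s2 + 100L,
        name = sprintf("r%04d_%s_b", i, tfs), score = 100, strand = ".",
        summit = s2, factor = tfs, sample = "speciesB"
      )
    }
  }
  list(
    src = bind_rows(src_list), dst = bind_rows(dst_list),
    truth = tibble(
      region = seq_len(n_total), group = group, retained = retained
    )
  )
}

#' Generate promoter marks and expression from a planted linear model
#'
#' Ortholog genes share a latent mark profile; species divergence is
#' added per gene (larger for a planted species-specific subset).
#' Expression is `y = X beta + noise` with noise SD set by the planted
#' R-squared, exported as `FPKM = 2^y - 1` floored at zero, for every
#' configured stage (non-reference stages add small stage drift and,
#' when configured, per-category offsets).
#'
#' @param cfg A `sim_config`.
#' @param gp Genome pair.
#' @param gene_categories Optional tibble `gene_id, category` used with
#'   `cfg$category_offsets`.
#' @return List: `pm_a`, `pm_b` (planted promoter matrices, log2 scale),
#'   `expr_a`, `expr_b` (expression tibbles across stages), `truth`
#'   (beta, sigma, divergent gene ids).
#' @export
generate_marks_expression <- function(cfg, gp, gene_categories = NULL) {
  set.seed(sub_seed(cfg$seed, 3L))
  orth <- gp$genes_a$gene_id[!is.na(gp$genes_a$ortholog_id)]
  n <- length(orth)
  p <- length(cfg$marks)
  x0 <- matrix(rnorm(n * p, mean = 3, sd = 1), n, p,
    dimnames = list(orth, cfg$marks)
  )
  n_div <- round(cfg$divergent_frac * n)
  divergent <- sample(orth, n_div)
  sd_gene <- ifelse(orth %in% divergent,
    cfg$divergence_sd[["specific"]], cfg$divergence_sd[["background"]]
  )
  delta <- matrix(rnorm(n * p), n, p) * sd_gene
  xa <- x0 + delta / 2
  xb <- x0 - delta / 2
  beta <- cfg$beta_true
  # noise set so each species' true variance explained equals r2_true
  var_signal <- mean(c(var(xa %*% beta), var(xb %*% beta)))
  sigma <- sqrt(var_signal * (1 - cfg$r2_true) / cfg$r2_true)
  ya <- as.numeric(xa %*% beta) + rnorm(n, 0, sigma)
  yb <- as.numeric(xb %*% beta) + rnorm(n, 0, sigma)
  offsets <- rep(0, n)
  if (!is.null(cfg$category_offsets) && !is.null(gene_categories)) {
    m <- match(orth, gene_categories$gene_id)
    cat <- gene_categories$category[m]
    offs <- cfg$category_offsets[cat]
    offsets <- ifelse(is.na(offs), 0, offs)
  }
  mk_expr <- function(y) {
    purrr::map_dfr(seq_along(cfg$stages), function(si) {
      drift <- if (si == 1) 0 else rnorm(n, 0, 0.3)
      boost <- if (si == 1) 0 else offsets * (si - 1) / (length(cfg$stages) - 1)
      ys <- y + drift + boost
      purrr::map_dfr(1:2, function(rep_i) {
        tibble(
          gene_id = orth, stage = cfg$stages[si], replicate = rep_i,
          fpkm = pmax(2^(ys + rnorm(n, 0, 0.05)) - 1, 0)
        )
      })
    })
  }
  pm_a <- as_tibble(as.data.frame(xa)) %>% mutate(gene_id = orth, .before = 1)
  pm_b <- as_tibble(as.data.frame(xb)) %>% mutate(gene_id = orth, .before = 1)
  list(
    pm_a = pm_a, pm_b = pm_b,
    expr_a = mk_expr(ya), expr_b = mk_expr(yb),
    truth = list(
      beta = setNames(beta, cfg$marks), sigma = sigma,
      divergent_genes = divergent, y_a = setNames(ya, orth),
      y_b = setNames(yb, orth), x0 = x0, delta = delta
    )
  )
}

#' Emit tag files that recover a planted promoter matrix
#'
#' For each mark and gene, a Poisson number of treatment tags
#' (proportional to the planted pre-log intensity) is placed uniformly in
#' the promoter window; input tags are a uniform background. Quantifying
#' these through [extend_and_pileup()], [normalize_subtract()] and
#' [promoter_matrix()] recovers the planted matrix up to scale.
#'
#' @param cfg A `sim_config`.
#' @param gp Genome pair (species A side is used).
#' @param pm Planted promoter matrix (log2 scale).
#' @param reads_per_rpm Expected tags per planted RPM unit per gene.
#' @param read_length Tag length in bp.
#' @return List of per-mark lists: `tags`, `input`, `n_treat`, `n_input`.
#' @export
generate_tags <- function(cfg, gp, pm, reads_per_rpm = 20, read_length = 36L) {
  set.seed(sub_seed(cfg$seed, 4L))
  genes <- gp$genes_a[match(pm$gene_id, gp$genes_a$gene_id), ]
  w <- promoter_windows(genes)
  total_bp <- sum(unlist(gp$chrom_sizes_a))
  out <- list()
  for (mk in setdiff(names(pm), "gene_id")) {
    lambda <- reads_per_rpm * (2^pm[[mk]] - 1)
    n_tags <- rpois(nrow(genes), lambda)
    idx <- rep(seq_len(nrow(genes)), n_tags)
    tstart <- floor(w$start[idx] + runif(length(idx)) *
      pmax(w$end[idx] - w$start[idx] - 200L, 1))
    tags <- tibble(
      chrom = w$chrom[idx], start = as.integer(tstart),
      end = as.integer(tstart + read_length), strand = "+"
    )
    n_bg <- 2000L
    bg_ch <- sample(names(gp$chrom_sizes_a), n_bg, replace = TRUE,
      prob = unlist(gp$chrom_sizes_a))
    bg_st <- floor(runif(n_bg) * (unlist(gp$chrom_sizes_a)[bg_ch] - 300))
    input <- tibble(
      chrom = bg_ch, start = as.integer(bg_st),
      end = as.integer(bg_st + read_length), strand = "+"
    )
    out[[mk]] <- list(
      tags = bind_rows(tags, input[seq_len(min(500L, n_bg)), ]),
      input = input,
      n_treat = nrow(tags) + min(500L, n_bg), n_input = n_bg
    )
  }
  out
}

#' Generate a chromatin-state segmentation with planted enrichment
#'
#' 200-bp bins tile species B; bins overlapping conserved or
#' strongly-gained peak windows receive the active state with probability
#' `state_fold / n_states` (capped at 1), other bins draw states
#' uniformly. Adjacent equal-state bins are merged.
#'
#' @param cfg A `sim_config`.
#' @param chrom_sizes Named chromosome sizes for species B.
#' @param planted_sites Interval tibble of conserved/strongly-gained
#'   sites on species B.
#' @return Segmentation tibble `chrom, start, end, state`.
#' @export
generate_segmentation <- function(cfg, chrom_sizes, planted_sites) {
  set.seed(sub_seed(cfg$seed, 5L))
  bin <- 200L
  out <- purrr::map_dfr(names(chrom_sizes), function(ch) {
    size <- chrom_sizes[[ch]]
    n_bins <- ceiling(size / bin)
    start <- (seq_len(n_bins) - 1L) * bin
    end <- pmin(start + bin, size)
    state <- sample.int(cfg$n_states, n_bins, replace = TRUE)
    ps <- planted_sites[planted_sites$chrom == ch, , drop = FALSE]
    if (nrow(ps)) {
      hot <- interval_overlaps_any(tibble(chrom = ch, start = start, end = end), ps)
      p_active <- min(cfg$state_fold / cfg$n_states, 1)
      hot_active <- runif(sum(hot)) < p_active
      other <- sample(setdiff(seq_len(cfg$n_states), cfg$active_state),
        sum(hot), replace = TRUE)
      state[hot] <- ifelse(hot_active, cfg$active_state, other)
    }
    # merge runs of equal states
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- c(0L, head(ends, -1)) * bin
    tibble(
      chrom = ch, start = as.integer(starts),
      end = as.integer(pmin(ends * bin, size)), state = r$values
    )
  })
  validate_segmentation(out, cfg$n_states)
}

#' Run the full synthetic study
#'
#' Generates genomes, peaks, marks/expression and segmentation under one
#' seed and returns everything plus ground truth.
#'
#' @param cfg A `sim_config`.
#' @param tags Also emit tag files (slower; default FALSE).
#' @return List with `cfg, genomes, peaks, marks, segmentation`.
#' @export
simulate_study <- function(cfg = sim_config(), tags = FALSE) {
  gp <- generate_genome_pair(cfg)
  pk <- generate_peaks(cfg, gp)
  mx <- generate_marks_expression(cfg, gp)
  planted_cons <- pk$truth$dst_origin %>%
    filter(.data$origin == "conserved_partner")
  sites <- pk$dst %>%
    dplyr::semi_join(planted_cons, by = "name") %>%
    select("chrom", "start", "end")
  seg <- generate_segmentation(cfg, gp$chrom_sizes_b, sites)
  coocc <- generate_cooccupancy(
    gp,
    n_by_group = coocc_groups(cfg$coocc_panel, cfg$coocc_n),
    retention_by_group = coocc_groups(cfg$coocc_panel, cfg$coocc_retention),
    seed = sub_seed(cfg$seed, 6L)
  )
  out <- list(
    cfg = cfg, genomes = gp, peaks = pk, marks = mx, segmentation = seg,
    coocc = coocc
  )
  if (tags) out$tags <- generate_tags(cfg, gp, mx$pm_a)
  out
}

# expand tier settings (triple/pair/single) into named per-group vectors
coocc_groups <- function(panel, by_tier) {
  panel <- sort(panel)
  pairs <- utils::combn(panel, 2, paste, collapse = "+")
  vals <- c(
    setNames(rep(by_tier[["triple"]], 1), paste(panel, collapse = "+")),
    setNames(rep(by_tier[["pair"]], length(pairs)), pairs),
    setNames(rep(by_tier[["single"]], length(panel)), panel)
  )
  vals
}
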