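#' Configuration of the synthetic MNase-seq cohort generator
#'
#' Collects every parameter of the synthetic-data generator. The generator
#' emulates the statistical structure the downstream analysis assumes: a
#' hard-rod gas of nucleosomes at mean spacing `dbar` around a
#' nucleosome-free region per gene, a +1 nucleosome concentrated ~50 bp
#' downstream of the TSS, a dispersed -1 nucleosome, per-nucleosome Poisson
#' read sampling with positional jitter, a fraction of multi-mapped reads,
#' and heavy-tailed gene lengths (roughly a third longer than 2000 bp).
#'
#' Each gene is an ensemble of `cells_per_gene` independent gas
#' configurations ("cells") sharing the gene's boundary, so that the
#' alignment anchor (the called +1/-1 nucleosome) and the cell-to-cell
#' positional variability both exist, as in real chromatin data.
#'
#' @param seed Integer seed used by the generator.
#' @param n_genes Number of genes.
#' @param dbar Mean nucleosome center-to-center spacing, bp.
#' @param b Nucleosome footprint, bp (odd).
#' @param plus1_offset_mean,plus1_offset_sd TSS-to-+1 distance law, bp.
#' @param gap_mean Mean edge-to-edge gap between -1 and +1 (NFR width), bp.
#' @param minus1_dispersion Standard deviation of the gap, bp (disperses
#'   the -1 position relative to the TSS).
#' @param reads_per_nucleosome_mean Mean reads per nucleosome (Poisson).
#' @param read_jitter_sd Positional jitter of each read's inferred dyad, bp.
#' @param multimap_fraction Fraction of reads emitted as multi-mapped.
#' @param multimap_copies Alignment rows per multi-mapped read.
#' @param gene_length_meanlog,gene_length_sdlog Log-normal gene-length law.
#' @param cells_per_gene Configurations per gene.
#' @param plus1_cell_sd Cell-to-cell positional sd of a directly positioned
#'   +1 nucleosome, bp (0 = perfectly pinned).
#' @param scenario_plus,scenario_minus Boundary condition on each side of
#'   the NFR: `"direct"` (pinned anchor nucleosome) or `"indirect"`
#'   (repelling edge, first nucleosome free).
#' @param flank_extent Extent of the gas fill on each side of the NFR, bp.
#' @param chrom Name of the synthetic contig.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_genes = 2000L,
                             dbar = 177,
                             b = 147L,
                             plus1_offset_mean = 50,
                             plus1_offset_sd = 20,
                             gap_mean = 140,
                             minus1_dispersion = 60,
                             reads_per_nucleosome_mean = 6,
                             read_jitter_sd = 10,
                             multimap_fraction = 0.05,
                             multimap_copies = 5L,
                             gene_length_meanlog = log(1300),
                             gene_length_sdlog = 0.85,
                             cells_per_gene = 6L,
                             plus1_cell_sd = 0,
                             scenario_plus = c("direct", "indirect"),
                             scenario_minus = c("indirect", "direct"),
                             flank_extent = 2200L,
                             chrom = "chrSim") {
  scenario_plus <- match.arg(scenario_plus)
  scenario_minus <- match.arg(scenario_minus)
  sc <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
             dbar = dbar, b = as.integer(b),
             plus1_offset_mean = plus1_offset_mean,
             plus1_offset_sd = plus1_offset_sd,
             gap_mean = gap_mean, minus1_dispersion = minus1_dispersion,
             reads_per_nucleosome_mean = reads_per_nucleosome_mean,
             read_jitter_sd = read_jitter_sd,
             multimap_fraction = multimap_fraction,
             multimap_copies = as.integer(multimap_copies),
             gene_length_meanlog = gene_length_meanlog,
             gene_length_sdlog = gene_length_sdlog,
             cells_per_gene = as.integer(cells_per_gene),
             plus1_cell_sd = plus1_cell_sd,
             scenario_plus = scenario_plus, scenario_minus = scenario_minus,
             flank_extent = as.integer(flank_extent), chrom = chrom)
  scales <- c("dbar", "plus1_offset_sd", "gap_mean", "minus1_dispersion",
              "reads_per_nucleosome_mean", "flank_extent")
  for (f in scales)
    if (sc[[f]] <= 0) stop("'", f, "' must be positive", call. = FALSE)
  if (sc$read_jitter_sd < 0 || sc$plus1_cell_sd < 0)
    stop("jitter standard deviations must be >= 0", call. = FALSE)
  if (sc$multimap_fraction < 0 || sc$multimap_fraction > 1)
    stop("'multimap_fraction' must be in [0, 1]", call. = FALSE)
  if (sc$b %% 2L == 0L) stop("'b' must be odd", call. = FALSE)
  if (sc$dbar <= sc$b) stop("'dbar' must exceed 'b'", call. = FALSE)
  structure(sc, class = "synthetic_config")
}

# slot pitch: each gene owns [tss - flank - 400, tss + flank + 400]
slot_pitch <- function(sc) 2L * (sc$flank_extent + 400L)

#' Reads from one nucleosome configuration
#'
#' Per nucleosome, draws a Poisson number of reads; each read's inferred
#' dyad is the true dyad plus rounded Gaussian jitter, its strand a fair
#' coin, and its interval the `b`-bp window centred on the dyad (0-based
#' half-open). A `multimap_fraction` of reads is emitted as
#' `multimap_copies` alignment rows sharing one read identifier, the extra
#' copies at uniformly displaced positions.
#'
#' @param config A [sample_tonks()] configuration (or any list with
#'   `midpoints` and `b`).
#' @param sc A [synthetic_config()] (read-sampling fields are used).
#' @param chrom_length Contig length for placing displaced multi-map copies.
#' @param id_offset Integer offset for read identifiers.
#' @return data.frame with columns `chrom`, `start`, `end`, `read_id`,
#'   `score`, `strand` (BED6-like, 0-based half-open).
#' @export
generate_reads <- function(config, sc, chrom_length = NULL, id_offset = 0L) {
  stopifnot(inherits(sc, "synthetic_config"))
  dyads <- round(config$midpoints)
  counts <- stats::rpois(length(dyads), sc$reads_per_nucleosome_mean)
  rd <- rep(dyads, counts)
  n <- length(rd)
  if (n == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      read_id = character(), score = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  if (sc$read_jitter_sd > 0)
    rd <- rd + round(stats::rnorm(n, 0, sc$read_jitter_sd))
  ids <- sprintf("r%09d", id_offset + seq_len(n))
  if (is.null(chrom_length)) chrom_length <- max(rd) + 10L * sc$b
  reads_table(rd, ids, sc, chrom_length)
}

# assemble the BED6-like table from inferred dyads, adding multi-map copies
reads_table <- function(dyads, ids, sc, chrom_length) {
  n <- length(dyads)
  if (n == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), read_id = character(),
                      score = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  n_mm <- round(sc$multimap_fraction * n)
  if (n_mm > 0 && sc$multimap_copies > 1L) {
    pick <- sample.int(n, n_mm)
    extra_per <- sc$multimap_copies - 1L
    mm_dyads <- round(stats::runif(n_mm * extra_per, 5L * sc$b,
                                   chrom_length - 5L * sc$b))
    dyads <- c(dyads, mm_dyads)
    ids <- c(ids, rep(ids[pick], each = extra_per))
    strand <- c(strand, ifelse(stats::runif(n_mm * extra_per) < 0.5, "+", "-"))
  }
  h <- (sc$b - 1L) %/% 2L
  start <- as.integer(dyads - h)
  data.frame(chrom = sc$chrom, start = start, end = start + sc$b,
             read_id = ids, score = 1L, strand = strand,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic promoter cohort
#'
#' Builds the full synthetic dataset: a gene table, per-gene -1/+1
#' nucleosome calls, strand-resolved reads, and a truth record. Each gene
#' gets a TSS on its own slot of the synthetic contig, a +1 nucleosome
#' target ~`plus1_offset_mean` bp downstream of the TSS, a -1 target one
#' NFR gap upstream, and `cells_per_gene` independent hard-rod gas fills of
#' both flanks drawn from the exact thermodynamic-limit half-line law
#' ([sample_gas_halfline()]). Under the `direct` scenario the anchor
#' nucleosome is pinned (optionally with cell-to-cell sd `plus1_cell_sd`);
#' under the `indirect` scenario a repelling edge sits at the target and
#' the first nucleosome is free. The emitted call for an indirect anchor is
#' the NFR-proximal extreme of the first-nucleosome dyads over cells (the
#' mode of the exponential first-particle law sits at the wall); for a
#' direct anchor it is the pinned position. Call fuzziness is the empirical
#' standard deviation of that nucleosome's reads.
#'
#' @param sc A [synthetic_config()].
#' @return A list of class `synthetic_cohort` with elements `reads`,
#'   `calls`, `genes`, `truth` (data.frames) and `config`. The truth table
#'   is never consumed by the analysis; it exists for blind
#'   parameter-recovery tests.
#' @export
simulate_cohort <- function(sc) {
  stopifnot(inherits(sc, "synthetic_config"))
  set.seed(sc$seed)
  params <- tonks_params(b = sc$b, dbar = sc$dbar)
  pitch <- slot_pitch(sc)
  chrom_length <- as.integer(sc$n_genes) * pitch + 2L * pitch
  ext <- sc$flank_extent

  n <- sc$n_genes
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  s <- ifelse(strand == "+", 1L, -1L)
  tss <- pitch + (seq_len(n) - 1L) * pitch + pitch %/% 2L
  glen <- pmax(300, round(stats::rlnorm(n, sc$gene_length_meanlog,
                                        sc$gene_length_sdlog)))
  orf_end <- tss + s * glen
  # the +1 nucleosome is by definition at or downstream of the TSS, so the
  # offset law is a truncated Gaussian
  p1_target <- tss + s * pmax(0, round(stats::rnorm(n, sc$plus1_offset_mean,
                                                    sc$plus1_offset_sd)))
  gap <- pmax(20, round(stats::rnorm(n, sc$gap_mean, sc$minus1_dispersion)))
  m1_target <- p1_target - s * (sc$b + gap)

  read_dyads <- vector("list", n)
  p1_call <- m1_call <- integer(n)
  p1_fuzz <- m1_fuzz <- numeric(n)
  lambda <- sc$reads_per_nucleosome_mean / sc$cells_per_gene

  sample_side <- function(target, sign, scenario, cell_sd) {
    # one gene-side across cells; returns list(all_dyads, anchor_dyads, call)
    all_d <- vector("list", sc$cells_per_gene)
    first_d <- numeric(sc$cells_per_gene)
    for (cell in seq_len(sc$cells_per_gene)) {
      if (scenario == "direct") {
        anchor <- target + if (cell_sd > 0) round(stats::rnorm(1, 0, cell_sd)) else 0
        pos <- sample_gas_halfline(ext, params, "pinned")
        all_d[[cell]] <- c(anchor, anchor + sign * round(pos))
        first_d[cell] <- anchor
      } else {
        pos <- sample_gas_halfline(ext, params, "wall")
        all_d[[cell]] <- target + sign * round(pos)
        first_d[cell] <- all_d[[cell]][1]
      }
    }
    call <- if (scenario == "direct") target
            else if (sign > 0) min(first_d) else max(first_d)
    list(dyads = unlist(all_d), anchors = first_d, call = call)
  }

  for (g in seq_len(n)) {
    down <- sample_side(p1_target[g], s[g], sc$scenario_plus, sc$plus1_cell_sd)
    up <- sample_side(m1_target[g], -s[g], sc$scenario_minus, sc$plus1_cell_sd)
    p1_call[g] <- down$call
    m1_call[g] <- up$call
    dy <- c(down$dyads, up$dyads)
    cnt <- stats::rpois(length(dy), lambda)
    rd <- rep(dy, cnt)
    if (sc$read_jitter_sd > 0 && length(rd))
      rd <- rd + round(stats::rnorm(length(rd), 0, sc$read_jitter_sd))
    read_dyads[[g]] <- rd
    # fuzziness: sd of the anchor nucleosome's read positions across cells
    p1_fuzz[g] <- anchor_fuzz(down$anchors, lambda, sc)
    m1_fuzz[g] <- anchor_fuzz(up$anchors, lambda, sc)
  }

  all_rd <- unlist(read_dyads)
  ids <- sprintf("r%09d", seq_along(all_rd))
  reads <- reads_table(all_rd, ids, sc, chrom_length)

  feature_id <- sprintf("g%05d", seq_len(n))
  genes <- data.frame(feature_id = feature_id, chrom = rep(sc$chrom, n),
                      strand = strand, tss = tss, orf_end = orf_end,
                      stringsAsFactors = FALSE)
  calls <- data.frame(
    chrom = rep(sc$chrom, 2L * n),
    dyad = c(m1_call, p1_call),
    fuzziness = c(m1_fuzz, p1_fuzz),
    stringsAsFactors = FALSE)
  calls <- calls[order(calls$dyad), , drop = FALSE]
  rownames(calls) <- NULL
  truth <- data.frame(feature_id = feature_id, strand = strand, tss = tss,
                      p1_target = p1_target, m1_target = m1_target,
                      p1_call = p1_call, m1_call = m1_call,
                      gap = gap, gene_length = glen,
                      scenario_plus = rep(sc$scenario_plus, n),
                      scenario_minus = rep(sc$scenario_minus, n),
                      dbar_true = rep(sc$dbar, n), stringsAsFactors = FALSE)
  structure(list(reads = reads, calls = calls, genes = genes, truth = truth,
                 config = sc, chrom_length = chrom_length),
            class = "synthetic_cohort")
}

# empirical sd of an anchor's simulated read positions (jitter + cell spread)
anchor_fuzz <- function(anchors, lambda, sc) {
  cnt <- stats::rpois(length(anchors), lambda)
  rd <- rep(anchors, cnt)
  if (length(rd) >= 2) {
    if (sc$read_jitter_sd > 0)
      rd <- rd + round(stats::rnorm(length(rd), 0, sc$read_jitter_sd))
    stats::sd(rd)
  } else {
    sc$read_jitter_sd
  }
}

#' Synthetic cohort for the genic/intergenic density-ratio analysis
#'
#' Tiles a contig with alternating intergenic and genic segments, each
#' filled with an exact canonical hard-rod configuration at its own target
#' spacing, and emits reads, a gene table and the flanking -1/+1 calls per
#' junction. Because the segments tile the contig completely, the genic and
#' intergenic partitions of [density_ratio()] are both fully covered, and
#' the expected ratio of intergenic to genic density equals
#' `dbar_genic / dbar_intergenic`.
#'
#' @param n_units Number of intergenic+genic tiles.
#' @param dbar_genic,dbar_intergenic Target spacings, bp.
#' @param genic_length,intergenic_length Segment lengths, bp.
#' @param sc A [synthetic_config()] supplying `b`, read sampling and contig
#'   name; its `seed` seeds the generator.
#' @return A list with `reads`, `genes`, `calls`, `expected_ratio`.
#' @export
simulate_ratio_cohort <- function(n_units = 60,
                                  dbar_genic = 177, dbar_intergenic = 177,
                                  genic_length = 3400, intergenic_length = 4000,
                                  sc = synthetic_config()) {
  stopifnot(inherits(sc, "synthetic_config"))
  set.seed(sc$seed)
  b <- sc$b
  # snap segment lengths to whole rods at the target spacing so the mean
  # density of each segment is exactly 1/dbar (no round-off bias)
  n_g <- round(genic_length / dbar_genic)
  n_i <- round(intergenic_length / dbar_intergenic)
  genic_length <- round(n_g * dbar_genic)
  intergenic_length <- round(n_i * dbar_intergenic)
  pitch <- genic_length + intergenic_length
  # tiles cover the contig end to end so the genic/intergenic partition of
  # density_ratio() has (almost) no uncovered base pairs
  chrom_length <- n_units * pitch + 100L
  dyads <- numeric(0); tss <- orf_end <- integer(n_units)
  m1 <- p1 <- integer(n_units)
  for (u in seq_len(n_units)) {
    base <- (u - 1L) * pitch
    di <- base + round(sample_tonks(intergenic_length, n_i, b)$midpoints)
    dg <- base + intergenic_length +
      round(sample_tonks(genic_length, n_g, b)$midpoints)
    tss[u] <- base + intergenic_length
    orf_end[u] <- base + intergenic_length + genic_length
    m1[u] <- di[length(di)]
    p1[u] <- dg[1]
    dyads <- c(dyads, di, dg)
  }
  cnt <- stats::rpois(length(dyads), sc$reads_per_nucleosome_mean)
  rd <- rep(dyads, cnt)
  if (sc$read_jitter_sd > 0)
    rd <- rd + round(stats::rnorm(length(rd), 0, min(sc$read_jitter_sd, 10)))
  reads <- reads_table(rd, sprintf("r%09d", seq_along(rd)), sc, chrom_length)
  genes <- data.frame(feature_id = sprintf("u%04d", seq_len(n_units)),
                      chrom = sc$chrom, strand = "+",
                      tss = tss, orf_end = orf_end, stringsAsFactors = FALSE)
  calls <- data.frame(chrom = sc$chrom, dyad = sort(c(m1, p1)),
                      fuzziness = 5, stringsAsFactors = FALSE)
  list(reads = reads, genes = genes, calls = calls,
       expected_ratio = dbar_genic / dbar_intergenic,
       chrom_length = chrom_length)
}
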