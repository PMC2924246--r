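#' Identify the NFR-flanking nucleosomes of each gene
#'
#' In transcription coordinates, the +1 nucleosome is the call with the
#' smallest dyad at or downstream of the TSS and the -1 nucleosome the
#' first call strictly upstream. For Crick genes downstream means
#' decreasing genomic coordinate. Genes without a call on one side get
#' `NA` for that anchor and are excluded from the corresponding alignment.
#' With `anchor = "three_prime"` the same rule is applied at the ORF end
#' with the inclusive side swapped: the 3' -1 nucleosome is the call at or
#' upstream of the ORF end, the 3' +1 the first call downstream.
#'
#' @param genes data.frame with `feature_id`, `chrom`, `strand`, `tss`,
#'   `orf_end`.
#' @param calls data.frame with `chrom`, `dyad`.
#' @param anchor `"tss"` (default) or `"three_prime"`.
#' @return data.frame with `feature_id`, `chrom`, `strand`, `plus1`,
#'   `minus1` (dyad coordinates, `NA` when absent).
#' @export
find_flanking <- function(genes, calls, anchor = c("tss", "three_prime")) {
  anchor <- match.arg(anchor)
  ref <- if (anchor == "tss") genes$tss else genes$orf_end
  plus1 <- minus1 <- rep(NA_real_, nrow(genes))
  at <- function(dy, k) if (k >= 1L && k <= length(dy)) dy[k] else NA_real_
  for (cn in unique(genes$chrom)) {
    dy <- sort(calls$dyad[calls$chrom == cn])
    gi <- which(genes$chrom == cn)
    if (length(dy) == 0L) next
    for (i in gi) {
      r <- ref[i]
      fwd <- genes$strand[i] == "+"
      # dyads are integer coordinates: +-0.5 turns <=/< into clean counts
      if (anchor == "tss") {
        # +1 = first call at or downstream of the TSS, -1 = first upstream
        if (fwd) {
          k <- findInterval(r - 0.5, dy)      # calls strictly upstream
          plus1[i] <- at(dy, k + 1L); minus1[i] <- at(dy, k)
        } else {
          k <- findInterval(r + 0.5, dy)      # calls at or downstream
          plus1[i] <- at(dy, k); minus1[i] <- at(dy, k + 1L)
        }
      } else {
        # 3' end: -1 = call at or upstream of ORF end, +1 = first downstream
        if (fwd) {
          k <- findInterval(r + 0.5, dy)
          minus1[i] <- at(dy, k); plus1[i] <- at(dy, k + 1L)
        } else {
          k <- findInterval(r - 0.5, dy)
          minus1[i] <- at(dy, k + 1L); plus1[i] <- at(dy, k)
        }
      }
    }
  }
  data.frame(feature_id = genes$feature_id, chrom = genes$chrom,
             strand = genes$strand, plus1 = plus1, minus1 = minus1,
             stringsAsFactors = FALSE)
}

#' Align a density map to per-gene anchors and average over genes
#'
#' For each gene the density is extracted at `anchor + offset` (Watson) or
#' `anchor - offset` (Crick) for offsets in `[-window, window]`, so that
#' transcription always runs left to right, and averaged over genes with
#' equal weight per gene. Offsets falling outside the chromosome are
#' excluded from that offset's denominator.
#'
#' @param density A `density_map`.
#' @param anchors data.frame with `chrom`, `strand` and the anchor dyad in
#'   column `anchor` (rows with `NA` anchors are dropped).
#' @param window Half-width of the profile, bp (default 2000).
#' @param anchor_kind Label stored on the profile
#'   (`"plus1"`, `"minus1"`, `"plus1_3prime"`, `"minus1_3prime"`).
#' @return An object of class `aligned_profile`: data.frame with `offset`,
#'   `mean_weight`, `n_genes`.
#' @export
align_average <- function(density, anchors, window = 2000,
                          anchor_kind = "plus1") {
  stopifnot(inherits(density, "density_map"))
  if (window <= 0) stop("'window' must be positive", call. = FALSE)
  anchors <- anchors[!is.na(anchors$anchor), , drop = FALSE]
  if (nrow(anchors) == 0L) stop("no anchors to align to", call. = FALSE)
  offs <- seq.int(-window, window)
  acc <- numeric(length(offs))
  cnt <- integer(length(offs))
  for (i in seq_len(nrow(anchors))) {
    tr <- density$tracks[[anchors$chrom[i]]]
    if (is.null(tr)) next
    a <- anchors$anchor[i]
    pos <- if (anchors$strand[i] == "+") a + offs else a - offs
    ok <- pos >= 0 & pos <= length(tr) - 1
    acc[ok] <- acc[ok] + tr[pos[ok] + 1]
    cnt <- cnt + ok
  }
  if (all(cnt == 0L)) stop("no anchors overlapped the density map", call. = FALSE)
  prof <- data.frame(offset = offs,
                     mean_weight = ifelse(cnt > 0, acc / pmax(cnt, 1L), NA_real_),
                     n_genes = cnt)
  class(prof) <- c("aligned_profile", "data.frame")
  attr(prof, "anchor_kind") <- anchor_kind
  prof
}

#' Mirror an aligned profile at the origin
#'
#' Used for the -1 nucleosome alignments, which are fitted after mirroring
#' the data at the origin so that the upstream pattern runs in the positive
#' direction like the downstream one.
#'
#' @param profile An `aligned_profile`.
#' @return The mirrored `aligned_profile`.
#' @export
mirror_profile <- function(profile) {
  stopifnot(inherits(profile, "aligned_profile"))
  out <- profile[order(-profile$offset), , drop = FALSE]
  out$offset <- -out$offset
  rownames(out) <- NULL
  class(out) <- class(profile)
  attr(out, "anchor_kind") <- attr(profile, "anchor_kind")
  attr(out, "mirrored") <- TRUE
  out
}

#' Position and gap distributions of the NFR-flanking nucleosomes
#'
#' Computes, in transcription coordinates, the signed distance from the
#' TSS to the +1 and -1 dyads and the edge-to-edge gap between the two
#' nucleosomes, `(plus1 - minus1) - b`, and returns unit-mass histograms.
#'
#' @param genes,calls As in [find_flanking()].
#' @param b Nucleosome width, bp.
#' @param breaks Histogram bin width, bp (default 10).
#' @return List with `plus1_tss`, `minus1_tss`, `gap` (each a data.frame
#'   `mid`, `prob`) and the per-gene table `distances`.
#' @export
position_distributions <- function(genes, calls, b = 147, breaks = 10) {
  fl <- find_flanking(genes, calls)
  s <- ifelse(fl$strand == "+", 1, -1)
  d_plus <- s * (fl$plus1 - genes$tss)
  d_minus <- s * (fl$minus1 - genes$tss)
  gap <- s * (fl$plus1 - fl$minus1) - b
  hist1 <- function(x) {
    x <- x[!is.na(x)]
    br <- seq(floor(min(x) / breaks) * breaks,
              ceiling(max(x) / breaks) * breaks + breaks, by = breaks)
    h <- hist(x, breaks = br, plot = FALSE)
    data.frame(mid = h$mids, prob = h$counts / sum(h$counts))
  }
  list(plus1_tss = hist1(d_plus), minus1_tss = hist1(d_minus),
       gap = hist1(gap),
       distances = data.frame(feature_id = fl$feature_id,
                              plus1_tss = d_plus, minus1_tss = d_minus,
                              gap = gap, stringsAsFactors = FALSE))
}

#' Gene subsets used for robustness checks
#'
#' `long2000` keeps genes strictly longer than 2000 bp. `clean_upstream1000`
#' keeps genes with no other gene's TSS or ORF end within 1000 bp upstream
#' of the TSS (in transcription coordinates). `three_prime` returns the
#' gene table unchanged (anchors are re-derived at the ORF end via
#' [find_flanking()] with `anchor = "three_prime"`). `all` is the identity.
#'
#' @param genes Gene table.
#' @param mode One of `"all"`, `"long2000"`, `"clean_upstream1000"`,
#'   `"three_prime"`.
#' @return The subset of `genes`.
#' @export
subset_genes <- function(genes, mode = c("all", "long2000",
                                         "clean_upstream1000", "three_prime")) {
  mode <- match.arg(mode)
  if (mode == "all" || mode == "three_prime") return(genes)
  if (mode == "long2000")
    return(genes[abs(genes$orf_end - genes$tss) > 2000, , drop = FALSE])
  # clean_upstream1000: brute interval scan per gene
  keep <- logical(nrow(genes))
  ends <- data.frame(chrom = rep(genes$chrom, 2),
                     pos = c(genes$tss, genes$orf_end),
                     gene = rep(seq_len(nrow(genes)), 2))
  for (i in seq_len(nrow(genes))) {
    s <- if (genes$strand[i] == "+") 1 else -1
    lo <- genes$tss[i] - s * 1000
    rng <- sort(c(lo, genes$tss[i]))
    others <- ends$chrom == genes$chrom[i] & ends$gene != i
    hit <- others & ends$pos >= rng[1] & ends$pos <= rng[2]
    keep[i] <- !any(hit)
  }
  genes[keep, , drop = FALSE]
}
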