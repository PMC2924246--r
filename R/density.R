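#' Per-base-pair nucleosome density map
#'
#' A density map stores, per chromosome, a dense vector of nonnegative
#' weight per base pair (0-based coordinates: coordinate `c` is element
#' `c + 1`), together with the total weight. It is the common container for
#' the two experimental proxies of the physical nucleosome density: the
#' read-midpoint density and the Gaussian-per-call density.
#'
#' @param tracks Named list of numeric vectors (one per chromosome).
#' @return An object of class `density_map`.
#' @keywords internal
new_density_map <- function(tracks) {
  structure(list(tracks = tracks,
                 total_weight = sum(vapply(tracks, sum, numeric(1)))),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density_map: %d chromosome(s), total weight %.4f\n",
              length(x$tracks), x$total_weight))
  invisible(x)
}

#' Read-midpoint density map from aligned reads
#'
#' Assigns each read the putative midpoint of the original nucleosomal DNA
#' (`start + (b-1)/2` for Watson reads, `end - 1 - (b-1)/2` for Crick
#' reads, 0-based half-open coordinates) and accumulates weight
#' `1/n_alignments` at that coordinate, where `n_alignments` is the number
#' of alignment rows sharing the read identifier. Each read thus
#' contributes total weight 1 regardless of its mapping multiplicity, and
#' the map's total weight equals the number of distinct reads.
#'
#' @param reads data.frame with columns `chrom`, `start`, `end`,
#'   `read_id`, `strand` (0-based half-open).
#' @param b Nucleosome width, bp; must be odd (midpoint undefined
#'   otherwise).
#' @param chrom_sizes Optional named integer vector of chromosome sizes;
#'   inferred from the reads if omitted.
#' @return A `density_map`.
#' @export
reads_to_density <- function(reads, b = 147, chrom_sizes = NULL) {
  if (b %% 2 == 0) stop("'b' must be odd: midpoint undefined", call. = FALSE)
  need <- c("chrom", "start", "end", "read_id", "strand")
  if (!all(need %in% names(reads)))
    stop("reads table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  ok <- reads$strand %in% c("+", "-")
  if (!all(ok)) {
    warning(sum(!ok), " read row(s) with unknown strand rejected")
    reads <- reads[ok, , drop = FALSE]
  }
  h <- (b - 1) / 2
  mid <- ifelse(reads$strand == "+", reads$start + h, reads$end - 1 - h)
  idx <- match(reads$read_id, unique(reads$read_id))
  n_align <- tabulate(idx)[idx]
  w <- 1 / n_align
  if (is.null(chrom_sizes)) {
    chrom_sizes <- vapply(split(reads$end, reads$chrom), max, numeric(1)) + 1000
  }
  tracks <- lapply(names(chrom_sizes), function(cn) {
    tr <- numeric(chrom_sizes[[cn]])
    sel <- reads$chrom == cn
    if (any(sel)) {
      agg <- rowsum(w[sel], mid[sel])
      tr[as.numeric(rownames(agg)) + 1] <- agg[, 1]
    }
    tr
  })
  names(tracks) <- names(chrom_sizes)
  new_density_map(tracks)
}

#' Gaussian-per-call density map from a nucleosome-call table
#'
#' Represents each called nucleosome by a unit-mass discretized Gaussian
#' centred at its dyad, with standard deviation equal to the call's
#' fuzziness (its positional sd across cells), floored at `sd_floor`. The
#' Gaussian is truncated at +-6 sd and renormalized (mass loss < 1e-8
#' before renormalization); per-base masses are Gaussian probability mass
#' over each 1-bp interval. The map's total weight equals the number of
#' calls; calls whose mass would extend past a chromosome end are clipped
#' and renormalized with a warning.
#'
#' @param calls data.frame with columns `chrom`, `dyad`, `fuzziness`.
#' @param sd_floor Minimum Gaussian sd, bp (default 1).
#' @param chrom_sizes Named vector of chromosome sizes; inferred if omitted.
#' @return A `density_map`.
#' @export
calls_to_density <- function(calls, sd_floor = 1, chrom_sizes = NULL) {
  if (sd_floor < 0) stop("'sd_floor' must be >= 0", call. = FALSE)
  need <- c("chrom", "dyad", "fuzziness")
  if (!all(need %in% names(calls)))
    stop("calls table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(calls$fuzziness < 0)) stop("fuzziness must be >= 0", call. = FALSE)
  if (is.null(chrom_sizes))
    chrom_sizes <- vapply(split(calls$dyad, calls$chrom), max, numeric(1)) + 1000
  tracks <- lapply(chrom_sizes, numeric)
  names(tracks) <- names(chrom_sizes)
  clipped <- 0L
  for (i in seq_len(nrow(calls))) {
    cn <- calls$chrom[i]
    sz <- length(tracks[[cn]])
    s <- max(calls$fuzziness[i], sd_floor, 1e-3)
    d <- calls$dyad[i]
    r <- ceiling(6 * s)
    grid <- seq.int(d - r, d + r)
    mass <- stats::pnorm(grid + 0.5, d, s) - stats::pnorm(grid - 0.5, d, s)
    keep <- grid >= 0 & grid <= sz - 1
    if (!all(keep)) clipped <- clipped + 1L
    mass <- mass[keep] / sum(mass[keep])
    tracks[[cn]][grid[keep] + 1] <- tracks[[cn]][grid[keep] + 1] + mass
  }
  if (clipped > 0) warning(clipped, " call(s) clipped at a chromosome end ",
                           "and renormalized")
  new_density_map(tracks)
}

#' Genome-wide normalization factor between the two density proxies
#'
#' The read density has no absolute normalization (the mean number of
#' reads per nucleosome is unknown), so it is rescaled such that the
#' genome-wide weight of reads equals the genome-wide number of identified
#' nucleosomes: the factor is `call_map$total_weight / read_map$total_weight`.
#'
#' @param read_map,call_map `density_map` objects with positive totals.
#' @return The scale factor (scalar).
#' @export
cross_normalize <- function(read_map, call_map) {
  stopifnot(inherits(read_map, "density_map"),
            inherits(call_map, "density_map"))
  if (read_map$total_weight <= 0 || call_map$total_weight <= 0)
    stop("both maps must have positive total weight", call. = FALSE)
  call_map$total_weight / read_map$total_weight
}
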