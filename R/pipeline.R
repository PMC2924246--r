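#' Simulate a cohort and optionally write its tables
#'
#' Thin orchestration over [simulate_cohort()]: generates the synthetic
#' reads/calls/genes/truth tables and, when `out_dir` is given, writes
#' them as plain-text files (reads as headerless BED6-like TSV, the rest
#' as headered TSVs) stamped with the seed and a configuration hash. The
#' truth table is written separately and never read back by the analysis.
#'
#' @param sc A [synthetic_config()].
#' @param out_dir Optional output directory.
#' @return The `synthetic_cohort`, invisibly when writing.
#' @export
run_simulate <- function(sc, out_dir = NULL) {
  cohort <- simulate_cohort(sc)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- list(seed = sc$seed, hash = config_hash(unclass(sc)))
    write_tsv(cohort$reads, file.path(out_dir, "reads.bed"), stamp,
              col_names = FALSE)
    write_tsv(cohort$calls, file.path(out_dir, "calls.tsv"), stamp)
    write_tsv(cohort$genes, file.path(out_dir, "genes.tsv"), stamp)
    write_tsv(cohort$truth, file.path(out_dir, "truth.tsv"), stamp)
    write_tsv(data.frame(chrom = sc$chrom, size = cohort$chrom_length),
              file.path(out_dir, "chrom.sizes"), NULL, col_names = FALSE)
    return(invisible(cohort))
  }
  cohort
}

#' Run the full alignment-and-fitting analysis
#'
#' Chains the analysis stages: read-density map construction, -1/+1
#' anchor identification, metagene alignment on both NFR flanks, position
#' and gap distributions, the independent +1 fit (free basin), the
#' convolved +1 fit, the offset-only -1 fit, the simultaneous
#' four-scenario comparison, and the intergenic/genic density ratio.
#'
#' @param reads,calls,genes The input tables (as from [simulate_cohort()]
#'   or the `read_*` functions).
#' @param cfg A [fit_config()].
#' @param b Nucleosome width, bp.
#' @param window Alignment half-window, bp.
#' @param chrom_sizes Optional named chromosome sizes.
#' @param extra_range Optional second fit range (e.g. `c(200, 1200)`) for
#'   which the +1 fit is repeated.
#' @param out_dir Optional directory for profile/fit reports.
#' @return List with `density`, `flanking`, `profile_plus`,
#'   `profile_minus`, `distributions`, `fit_plus`, `fit_convolved`,
#'   `fit_minus`, `scenarios`, `ratio` and (optionally)
#'   `fit_plus_alt_range`.
#' @export
run_analyze <- function(reads, calls, genes, cfg = fit_config(), b = 147,
                        window = 2000, chrom_sizes = NULL,
                        extra_range = NULL, out_dir = NULL) {
  density <- reads_to_density(reads, b = b, chrom_sizes = chrom_sizes)
  fl <- find_flanking(genes, calls)
  n_missing <- sum(is.na(fl$plus1)) + sum(is.na(fl$minus1))
  if (n_missing > 0)
    message(n_missing, " gene-side(s) without a flanking call excluded")
  ap <- data.frame(chrom = fl$chrom, strand = fl$strand, anchor = fl$plus1)
  am <- data.frame(chrom = fl$chrom, strand = fl$strand, anchor = fl$minus1)
  profile_plus <- align_average(density, ap, window, "plus1")
  profile_minus <- align_average(density, am, window, "minus1")
  dist <- position_distributions(genes, calls, b = b)

  fit_plus <- fit_profile(profile_plus, cfg, basin = "free")
  fit_conv <- fit_convolved(profile_plus, cfg)
  fit_minus <- fit_minus_fixed(profile_minus, fit_plus$A, fit_plus$dbar, cfg)
  scen <- rank_scenarios(profile_plus, profile_minus, cfg)
  ratio <- density_ratio(density, genes, calls)

  out <- list(density = density, flanking = fl, profile_plus = profile_plus,
              profile_minus = profile_minus, distributions = dist,
              fit_plus = fit_plus, fit_convolved = fit_conv,
              fit_minus = fit_minus, scenarios = scen, ratio = ratio)
  if (!is.null(extra_range)) {
    cfg2 <- cfg; cfg2$fit_range <- extra_range
    out$fit_plus_alt_range <- fit_profile(profile_plus, cfg2, basin = "free")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- list(seed = cfg$seed, hash = config_hash(unclass(cfg)))
    write_tsv(as.data.frame(profile_plus),
              file.path(out_dir, "profile_plus1.tsv"), stamp)
    write_tsv(as.data.frame(profile_minus),
              file.path(out_dir, "profile_minus1.tsv"), stamp)
    write_tsv(dist$gap, file.path(out_dir, "gap_distribution.tsv"), stamp)
    write_tsv(dist$plus1_tss, file.path(out_dir, "plus1_tss_distribution.tsv"),
              stamp)
    write_tsv(dist$minus1_tss,
              file.path(out_dir, "minus1_tss_distribution.tsv"), stamp)
    write_tsv(scen$ranking, file.path(out_dir, "scenario_ranking.tsv"), stamp)
    write_fit_json(list(fit_plus = unclass(fit_plus),
                        fit_convolved = unclass(fit_conv),
                        fit_minus = unclass(fit_minus),
                        ratio = ratio, seed = cfg$seed),
                   file.path(out_dir, "fits.json"))
  }
  out
}

#' Compute the boundary-condition family of density patterns
#'
#' Wraps [boundary_family()]: one fugacity tuned to the target spacing,
#' then the barrier pattern for each boundary energy, written as a single
#' long-format TSV when `out_dir` is given.
#'
#' @param eps_values Boundary energies in kT (may include `Inf`).
#' @param L Lattice length, bp.
#' @param b Rod width, bp (odd).
#' @param well_width Attractive-well width, bp.
#' @param target_dbar Bulk spacing, bp.
#' @param out_dir Optional output directory.
#' @return The family data.frame (`eps`, `x`, `density`).
#' @export
run_boundary <- function(eps_values = c(-5, -2, 0, 2, 5, Inf), L = 12000,
                         b = 147, well_width = 20, target_dbar = 177,
                         out_dir = NULL) {
  gas <- lattice_gas(L, b)
  fam <- boundary_family(eps_values, gas, well_width, target_dbar)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(fam, file.path(out_dir, "boundary_family.tsv"))
  }
  fam
}
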