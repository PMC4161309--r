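#' Pipeline configuration
#'
#' Collects every numeric threshold used across the pipeline stages into one
#' validated object. Defaults follow the analysis conventions for single
#' amplified genome (SAG) curation: misassigned-read hunting against regions
#' above 5000x coverage, removal of foreign-mapped reads at pile-up depth
#' <= 20x, two mismatches per mapped read, 50%/50% identity/coverage gates for
#' ortholog hits, dS saturation at 3, 200/50 nt divergence windows, and
#' bootstrap support reported at the 80% level.
#'
#' @param random_seed integer seed controlling every stochastic step.
#' @param coverage_region_threshold read depth above which a contig counts as
#'   an ultra-high-coverage (hotspot) region.
#' @param read_removal_depth pile-up depth (x) at or below which a
#'   foreign-mapped read is removed.
#' @param mapper_max_mismatches maximum mismatches for the ungapped read
#'   mapper.
#' @param min_hit_identity,min_hit_coverage fractions in (0, 1] gating
#'   protein similarity hits.
#' @param mcl_inflation Markov clustering inflation (> 1).
#' @param ds_cap dS value at which saturated estimates are capped.
#' @param window_size,window_step sliding-window size and step (nt),
#'   `window_step <= window_size`.
#' @param gscale_set subset of `c(0, 1, 2)`: mismatch-penalty scales for the
#'   gene-conversion scan.
#' @param fragment_p_cutoff corrected p-value cutoff for fragments.
#' @param bootstrap_reps bootstrap replicates for tree support.
#' @param support_threshold bootstrap percentage regarded as supported.
#' @param min_rescue_identity identity fraction a high-pile-up read must reach
#'   against its own assembly to be rescued.
#' @param permutations permutations for the fragment null distribution.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(random_seed = 1L,
                            coverage_region_threshold = 5000,
                            read_removal_depth = 20,
                            mapper_max_mismatches = 2L,
                            min_hit_identity = 0.50,
                            min_hit_coverage = 0.50,
                            mcl_inflation = 1.5,
                            ds_cap = 3,
                            window_size = 200L,
                            window_step = 50L,
                            gscale_set = c(0L, 1L, 2L),
                            fragment_p_cutoff = 0.05,
                            bootstrap_reps = 100L,
                            support_threshold = 80,
                            min_rescue_identity = 0.90,
                            permutations = 10000L) {
  cfg <- list(
    random_seed = as.integer(random_seed),
    coverage_region_threshold = coverage_region_threshold,
    read_removal_depth = read_removal_depth,
    mapper_max_mismatches = as.integer(mapper_max_mismatches),
    min_hit_identity = min_hit_identity,
    min_hit_coverage = min_hit_coverage,
    mcl_inflation = mcl_inflation,
    ds_cap = ds_cap,
    window_size = as.integer(window_size),
    window_step = as.integer(window_step),
    gscale_set = sort(unique(as.integer(gscale_set))),
    fragment_p_cutoff = fragment_p_cutoff,
    bootstrap_reps = as.integer(bootstrap_reps),
    support_threshold = support_threshold,
    min_rescue_identity = min_rescue_identity,
    permutations = as.integer(permutations)
  )
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  pos <- c("coverage_region_threshold", "read_removal_depth", "mcl_inflation",
           "ds_cap", "window_size", "window_step", "fragment_p_cutoff",
           "bootstrap_reps", "support_threshold", "permutations")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      abort(paste0("config field `", f, "` must be a single positive number"))
    }
  }
  if (cfg$mapper_max_mismatches < 0) abort("mapper_max_mismatches must be >= 0")
  if (cfg$window_step > cfg$window_size) abort("window_step must be <= window_size")
  for (f in c("min_hit_identity", "min_hit_coverage", "min_rescue_identity")) {
    if (cfg[[f]] <= 0 || cfg[[f]] > 1) abort(paste0(f, " must lie in (0, 1]"))
  }
  if (cfg$mcl_inflation <= 1) abort("mcl_inflation must be > 1")
  if (!all(cfg$gscale_set %in% 0:2)) abort("gscale_set must be a subset of {0, 1, 2}")
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> hash", config_hash(x), "\n")
  for (f in names(x)) cat(" ", f, "=", paste(x[[f]], collapse = ","), "\n")
  invisible(x)
}
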