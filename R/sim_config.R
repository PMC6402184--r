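#' Simulation configuration for the synthetic two-condition study
#'
#' Bundles every knob of the synthetic-data generator: a two-condition
#' (case vs control) count experiment with negative-binomial noise and
#' planted fold changes, a toy genome that places lincRNAs at controlled
#' distances from coding genes, and transcript/miRNA sequences with planted
#' seed sites.  All randomness downstream of a config flows from its single
#' integer \code{seed}.
#'
#' @param seed Single integer seed; identical configs give byte-identical
#'   outputs.
#' @param n_lncrna,n_mirna,n_mrna Number of features per class (all >= 1).
#' @param n_samples_per_group Samples per condition (the study design this
#'   emulates sequenced five pooled libraries per condition).
#' @param de_fraction Proportion of features (per class) with a planted
#'   expression difference, in \code{[0, 1]}.
#' @param planted_log2fc Magnitude of the planted log2 fold change; signs
#'   alternate up/down across the selected features.
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   \code{mu + dispersion * mu^2}); 0 gives Poisson counts.
#' @param baseline_mean Baseline expected count per feature per sample (> 0).
#' @param module_specs Planted coexpression modules: a list of
#'   \code{list(size =, latent_correlation =)} entries.  Each module couples
#'   one lncRNA to \code{size} mRNAs through a shared latent Gaussian factor
#'   on the log scale, giving pairwise latent correlation
#'   \code{latent_correlation} between all members.
#' @param module_log_sd Marginal log-scale (natural log) standard deviation
#'   of module-member expression; larger values make the planted
#'   co-regulation dominate counting noise.
#' @param genome_length Length in bp of the single toy chromosome.
#' @param cis_pair_specs Planted lincRNA/coding-gene neighbourhoods: a list
#'   of \code{list(gap_bp =)} entries; \code{gap_bp} is the distance in bp
#'   between the lincRNA end and the gene start (0 = adjacent overlap-free
#'   is not representable; use >= 1, or negative values are rejected).
#' @param cis_window The cis window in bp used to mark planted pairs as
#'   positives (\code{gap_bp <= cis_window}) or negative controls.
#' @param n_background_genes,n_background_lincs Isolated features placed
#'   farther than \code{cis_window} from everything else.
#' @param site_specs Planted miRNA seed sites: a list of
#'   \code{list(mirna =, transcript =, site_type =, position = NULL,
#'   supplementary = FALSE, au_flank = FALSE)} entries.  \code{site_type}
#'   is one of \code{"8mer"}, \code{"7mer-m8"}, \code{"7mer-A1"},
#'   \code{"6mer"}; \code{position} is the 0-based start of the 8-nt site
#'   window (chosen at random when \code{NULL}).  \code{supplementary}
#'   additionally plants complementarity to miRNA positions 13-19 upstream
#'   of the seed window (emulating strong 3'-supplementary sites);
#'   \code{au_flank} makes the 30-nt flanks A/U-only (high-accessibility
#'   context).  Both extensions default to off.
#' @param transcript_length Length in nt of generated lncRNA/mRNA
#'   transcripts.
#' @param mirna_length Length in nt of generated miRNAs.
#' @param feature_length_bp Annotated feature length used for RPKM, per
#'   class (named numeric: lncRNA, miRNA, mRNA).
#' @param exclude_chance_sites Logical: after planting, resample background
#'   transcript positions until no unplanted window of any transcript
#'   classifies as a seed site (6mer or better) for any generated miRNA.
#'   This makes the truth manifest exhaustive — required when recovery
#'   checks assert that only planted sites/triads are found.  Planted
#'   constructs (window, supplementary span, A/U flanks) are never touched.
#' @param fixed_library_size Optional scalar: record this nominal total
#'   mapped-read depth per sample instead of the panel column sums.  A
#'   simulated feature panel is a small excerpt of a transcriptome-scale
#'   library; treating the panel sum as the library size lets a handful of
#'   strongly co-regulated features dominate the normalizer, which injects
#'   their shared signal into every other feature after RPKM scaling (a
#'   compositional artifact that cannot happen at genome scale).  Use a
#'   fixed depth for coexpression studies on small panels.
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_lncrna = 100L, n_mirna = 30L, n_mrna = 300L,
                       n_samples_per_group = 5L,
                       de_fraction = 0.1,
                       planted_log2fc = 2,
                       nb_dispersion = 0.1,
                       baseline_mean = 100,
                       module_specs = list(),
                       module_log_sd = 2,
                       genome_length = 1e6,
                       cis_pair_specs = list(),
                       cis_window = 10000,
                       n_background_genes = 5L,
                       n_background_lincs = 5L,
                       site_specs = list(),
                       transcript_length = 400L,
                       mirna_length = 22L,
                       feature_length_bp = c(lncRNA = 1000, miRNA = 22,
                                             mRNA = 1000),
                       fixed_library_size = NULL,
                       exclude_chance_sites = FALSE) {
  cfg <- list(seed = as.integer(seed),
              n_lncrna = as.integer(n_lncrna),
              n_mirna = as.integer(n_mirna),
              n_mrna = as.integer(n_mrna),
              n_samples_per_group = as.integer(n_samples_per_group),
              de_fraction = de_fraction,
              planted_log2fc = planted_log2fc,
              nb_dispersion = nb_dispersion,
              baseline_mean = baseline_mean,
              module_specs = module_specs,
              module_log_sd = module_log_sd,
              genome_length = genome_length,
              cis_pair_specs = cis_pair_specs,
              cis_window = cis_window,
              n_background_genes = as.integer(n_background_genes),
              n_background_lincs = as.integer(n_background_lincs),
              site_specs = site_specs,
              transcript_length = as.integer(transcript_length),
              mirna_length = as.integer(mirna_length),
              feature_length_bp = feature_length_bp,
              fixed_library_size = fixed_library_size,
              exclude_chance_sites = isTRUE(exclude_chance_sites))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (any(c(n_lncrna, n_mirna, n_mrna, n_samples_per_group) < 1))
      stop("configuration error: all feature and sample counts must be >= 1")
    if (de_fraction < 0 || de_fraction > 1)
      stop("configuration error: de_fraction must lie in [0, 1]")
    if (nb_dispersion < 0)
      stop("configuration error: nb_dispersion must be >= 0")
    if (baseline_mean <= 0)
      stop("configuration error: baseline_mean must be > 0")
    if (transcript_length < 8)
      stop("configuration error: transcript_length too short")
    if (!is.null(fixed_library_size) &&
        (length(fixed_library_size) != 1 || fixed_library_size <= 0))
      stop("configuration error: fixed_library_size must be a positive scalar")
    for (m in module_specs) {
      if (is.null(m$size) || m$size < 1)
        stop("configuration error: module size must be >= 1")
      if (is.null(m$latent_correlation) ||
          m$latent_correlation <= 0 || m$latent_correlation >= 1)
        stop("configuration error: latent_correlation must be in (0, 1)")
    }
    for (p in cis_pair_specs) {
      if (is.null(p$gap_bp) || p$gap_bp < 1)
        stop("configuration error: cis gap_bp must be >= 1")
    }
    for (s in site_specs) {
      if (is.null(s$site_type) ||
          !s$site_type %in% c("8mer", "7mer-m8", "7mer-A1", "6mer"))
        stop("configuration error: unknown site_type")
      if (is.null(s$mirna) || is.null(s$transcript))
        stop("configuration error: site_specs need mirna and transcript ids")
    }
  })
  invisible(cfg)
}

## Feature id vectors implied by a config, per class.
sim_feature_ids <- function(cfg) {
  list(lncRNA = sprintf("lnc_%04d", seq_len(cfg$n_lncrna)),
       miRNA  = sprintf("mir_%04d", seq_len(cfg$n_mirna)),
       mRNA   = sprintf("mrna_%04d", seq_len(cfg$n_mrna)))
}

#' Empty planted-truth manifest
#'
#' @return A \code{truth_manifest}: list of data frames (\code{de},
#'   \code{modules}, \code{cis_pairs}, \code{sites}) recording every planted
#'   signal.
#' @keywords internal
empty_manifest <- function() {
  m <- list(
    de = data.frame(feature_id = character(), class = character(),
                    log2fc = numeric(), stringsAsFactors = FALSE),
    modules = data.frame(module = integer(), feature_id = character(),
                         class = character(), stringsAsFactors = FALSE),
    cis_pairs = data.frame(linc_id = character(), gene_id = character(),
                           gap_bp = numeric(), planted_positive = logical(),
                           stringsAsFactors = FALSE),
    sites = data.frame(mirna = character(), transcript = character(),
                       position = integer(), site_type = character(),
                       supplementary = logical(), au_flank = logical(),
                       stringsAsFactors = FALSE))
  class(m) <- "truth_manifest"
  m
}

#' Write a truth manifest to YAML
#' @param manifest A \code{truth_manifest}.
#' @param path Output file.
#' @export
write_manifest_yaml <- function(manifest, path) {
  yaml::write_yaml(lapply(unclass(manifest), function(df)
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))),
    path)
  invisible(path)
}
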