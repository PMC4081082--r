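#' Pipeline configuration
#'
#' Assembles and validates the configuration of
#' [run_triplex_pipeline()]. Thresholds default to the published
#' workflow values: seed distance in [13, 35] nt, mirSVR <= -0.1,
#' population free-energy cutoff at Z = 3, and a triplex equilibrium
#' concentration above 50 nM.
#'
#' @param sites,utrs,mirnas Inputs: tibbles (from [read_site_table()],
#'   [read_fasta()], [read_mirna_fasta()]) or file paths.
#' @param d_min,d_max Seed-distance bounds (nt), both inclusive.
#' @param mirsvr_max mirSVR score threshold (kept when `<=`).
#' @param conserved_only Keep only sites of conserved miRNAs.
#' @param distance_metric `"gap"` or `"start_to_start"`.
#' @param flank Window padding in nt.
#' @param tfe_z Z for the population free-energy cutoff
#'   ([tfe_cutoff()]); `NA` disables the cutoff (appropriate for small
#'   candidate sets, where a population statistic is meaningless).
#' @param require_seed Require both seeds preserved in the MFE structure.
#' @param seed_min_paired Seed positions (of 2-8) that must pair into
#'   the designated site.
#' @param totals_nM Initial concentration per RNA species for the
#'   equilibrium step.
#' @param tec_threshold Triplex equilibrium concentration filter (nM,
#'   strict `>`).
#' @param stability Optional stability tibble or TSV path; when given,
#'   the MDS stability rule is applied to matching records.
#' @param stability_threshold_ps,stability_rule See [stability_pass()].
#' @param kinetics Run the kinetic model for surviving triplexes.
#' @param kinetic_cfg A [kinetic_config()].
#' @return A validated config list of class `triplex_config`.
#' @export
triplex_config <- function(sites = NULL, utrs = NULL, mirnas = NULL,
                           d_min = 13, d_max = 35,
                           mirsvr_max = -0.1, conserved_only = TRUE,
                           distance_metric = "gap", flank = 0,
                           tfe_z = 3, require_seed = TRUE,
                           seed_min_paired = 7,
                           totals_nM = 100, tec_threshold = 50,
                           stability = NULL,
                           stability_threshold_ps = 100,
                           stability_rule = "per_mirna",
                           kinetics = TRUE,
                           kinetic_cfg = kinetic_config()) {
  if (d_min < 0) abort("config error: d_min must be >= 0")
  if (d_max < d_min) abort("config error: d_max must be >= d_min")
  if (!is.na(tfe_z) && tfe_z < 0) abort("config error: tfe_z must be >= 0 (or NA)")
  if (!distance_metric %in% c("gap", "start_to_start")) {
    abort("config error: distance_metric must be 'gap' or 'start_to_start'")
  }
  if (totals_nM <= 0) abort("config error: totals_nM must be > 0")
  if (tec_threshold < 0) abort("config error: tec_threshold must be >= 0")
  if (!stability_rule %in% c("per_mirna", "min_duplex")) {
    abort("config error: stability_rule must be 'per_mirna' or 'min_duplex'")
  }
  if (seed_min_paired < 1 || seed_min_paired > 7) {
    abort("config error: seed_min_paired must be in [1, 7]")
  }
  structure(
    list(sites = sites, utrs = utrs, mirnas = mirnas,
         d_min = d_min, d_max = d_max, mirsvr_max = mirsvr_max,
         conserved_only = conserved_only, distance_metric = distance_metric,
         flank = flank, tfe_z = tfe_z, require_seed = require_seed,
         seed_min_paired = seed_min_paired,
         totals_nM = totals_nM, tec_threshold = tec_threshold,
         stability = stability,
         stability_threshold_ps = stability_threshold_ps,
         stability_rule = stability_rule,
         kinetics = kinetics, kinetic_cfg = kinetic_cfg),
    class = "triplex_config"
  )
}

#' Load a pipeline configuration from a key = value file
#'
#' Parses a plain-text configuration (one `key = value` per line; `#`
#' comments and blank lines ignored) and validates it through
#' [triplex_config()]. Unknown keys are rejected.
#'
#' @param path Path to the config file.
#' @return A `triplex_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  args <- list()
  known_num <- c("d_min", "d_max", "mirsvr_max", "flank", "tfe_z",
                 "seed_min_paired", "totals_nM", "tec_threshold",
                 "stability_threshold_ps")
  known_lgl <- c("conserved_only", "require_seed", "kinetics")
  known_chr <- c("sites", "utrs", "mirnas", "stability",
                 "distance_metric", "stability_rule")
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) abort(sprintf("config error: cannot parse line '%s'", ln))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (key %in% known_num) {
      args[[key]] <- if (toupper(val) %in% c("NA", "NONE")) NA_real_
                     else suppressWarnings(as.numeric(val))
      if (!toupper(val) %in% c("NA", "NONE") && is.na(args[[key]])) {
        abort(sprintf("config error: key '%s' needs a number, got '%s'", key, val))
      }
    } else if (key %in% known_lgl) {
      args[[key]] <- toupper(val) %in% c("TRUE", "YES", "1")
    } else if (key %in% known_chr) {
      args[[key]] <- val
    } else {
      abort(sprintf("config error: unknown key '%s'", key))
    }
  }
  do.call(triplex_config, args)
}

resolve_inputs <- function(config) {
  sites <- config$sites
  if (is.character(sites)) sites <- read_site_table(sites)
  utrs <- config$utrs
  if (is.character(utrs)) utrs <- read_fasta(utrs)
  mirnas <- config$mirnas
  if (is.character(mirnas)) mirnas <- read_mirna_fasta(mirnas)
  if (is.null(sites) || is.null(utrs) || is.null(mirnas)) {
    abort("config must name sites, utrs and mirnas inputs")
  }
  if (!"conserved" %in% names(mirnas)) mirnas$conserved <- TRUE
  stability <- config$stability
  if (is.character(stability)) stability <- read_stability_table(stability)
  list(sites = sites, utrs = utrs, mirnas = mirnas, stability = stability)
}

#' Run the full triplex identification workflow
#'
#' Executes the six-step workflow on a set of predicted target sites:
#' (I-II) site filtering and pairing under the seed-distance constraint,
#' (III) multi-strand MFE structure prediction with free-energy,
#' conformation and seed-preservation filters, (V) equilibrium
#' concentrations of all complexes with the triplex-concentration
#' filter, (IV, optional) the MDS stability rule on ingested stability
#' summaries, and (VI) the kinetic repression model with repression
#' gains and synergy calls. Each stage only ever removes candidates;
#' the returned funnel records the per-stage counts.
#'
#' @param config A [triplex_config()].
#' @param model An [energy_model()].
#' @return A list: `results` (one row per surviving triplex with
#'   energies, equilibrium concentrations, optional stability verdict,
#'   repression gains and synergy class) and `funnel`
#'   (stage, n_in, n_out).
#' @export
run_triplex_pipeline <- function(config, model = energy_model()) {
  inputs <- resolve_inputs(config)
  funnel <- list()
  note_stage <- function(stage, n_in, n_out) {
    funnel[[length(funnel) + 1]] <<- tibble(stage = stage,
                                            n_in = n_in, n_out = n_out)
  }

  # Steps I-II: filter and pair sites
  n0 <- nrow(inputs$sites)
  sites <- filter_sites(inputs$sites, mirsvr_max = config$mirsvr_max,
                        conserved_only = config$conserved_only,
                        mirnas = inputs$mirnas)
  note_stage("site_filter", n0, nrow(sites))
  cand <- pair_sites(sites, d_min = config$d_min, d_max = config$d_max,
                     utrs = inputs$utrs, metric = config$distance_metric,
                     flank = config$flank)
  note_stage("pairing", nrow(sites), nrow(cand))
  if (!nrow(cand)) {
    return(list(results = cand, funnel = bind_rows(funnel)))
  }

  # Step III: fold and filter on structure
  mir_seq <- function(id) inputs$mirnas$seq[match(id, inputs$mirnas$id)]
  energ <- purrr::map_dfr(seq_len(nrow(cand)), function(r) {
    triplex_energetics(cand[r, ], mir_seq(cand$mirna1_id[r]),
                       mir_seq(cand$mirna2_id[r]), model,
                       min_paired = config$seed_min_paired)
  })
  cand <- bind_cols(cand, energ)

  cutoff <- if (is.na(config$tfe_z)) Inf else {
    if (nrow(cand) >= 2) tfe_cutoff(cand$dg_triplex, z = config$tfe_z)
    else cand$dg_triplex
  }
  filt <- apply_structure_filters(cand, cutoff,
                                  require_seed = config$require_seed)
  note_stage("structure_filters", nrow(cand), nrow(filt$kept))
  cand <- filt$kept
  if (!nrow(cand)) {
    return(list(results = cand, funnel = bind_rows(funnel),
                dropped = filt$dropped))
  }

  # Step V: equilibrium concentrations and the TEC filter
  eq_cols <- purrr::map_dfr(seq_len(nrow(cand)), function(r) {
    ab <- mfe_complex(c(A = mir_seq(cand$mirna1_id[r]),
                        B = mir_seq(cand$mirna2_id[r])), model)
    st <- equilibrium_concentrations(
      c(MA = cand$dg_duplex1[r], MB = cand$dg_duplex2[r],
        AB = ab$dg, MAB = cand$dg_triplex[r]),
      totals = c(M = config$totals_nM, A = config$totals_nM,
                 B = config$totals_nM),
      temperature = model$temperature)
    tibble(
      conc_mrna = st$concentrations[["M"]],
      conc_duplex1 = st$concentrations[["MA"]],
      conc_duplex2 = st$concentrations[["MB"]],
      conc_triplex = st$concentrations[["MAB"]],
      tec_pass = triplex_filter(st, config$tec_threshold)
    )
  })
  cand <- bind_cols(cand, eq_cols)
  kept <- cand[cand$tec_pass, , drop = FALSE]
  note_stage("equilibrium", nrow(cand), nrow(kept))
  cand <- kept
  if (!nrow(cand)) {
    return(list(results = cand, funnel = bind_rows(funnel)))
  }

  # Step IV (optional): MDS stability rule on ingested summaries
  if (!is.null(inputs$stability)) {
    stab <- inputs$stability
    stab$stability_verdict <- stability_pass(stab, config$stability_threshold_ps,
                                             config$stability_rule)
    cand <- left_join(cand, stab[c("gene_id", "mirna1_id", "mirna2_id",
                                   "stability_verdict")],
                      by = c("gene_id", "mirna1_id", "mirna2_id"))
    kept <- cand[is.na(cand$stability_verdict) | cand$stability_verdict, ,
                 drop = FALSE]
    note_stage("mds_stability", nrow(cand), nrow(kept))
    cand <- kept
    if (!nrow(cand)) {
      return(list(results = cand, funnel = bind_rows(funnel)))
    }
  }

  # Step VI: kinetic repression model
  if (isTRUE(config$kinetics)) {
    kin <- purrr::map_dfr(seq_len(nrow(cand)), function(r) {
      km <- build_kinetic_model(cand[r, ], config = config$kinetic_cfg)
      repression_gain(km)[c("RG1", "RG2", "RG3", "synergy_class")]
    })
    cand <- bind_cols(cand, kin)
  }
  note_stage("final", nrow(cand), nrow(cand))

  results <- select(cand, -any_of(c("structure", "tec_pass")))
  list(results = results, funnel = bind_rows(funnel))
}
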