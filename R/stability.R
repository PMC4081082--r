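#' Triplex stability time from MDS summaries
#'
#' The stability time of a triplex during a molecular-dynamics
#' production run is the duration for which *both* miRNA strands stay
#' hydrogen-bonded to the mRNA, i.e. the minimum of the two per-miRNA
#' within-triplex times.
#'
#' @param records Stability tibble with columns `t1_ps`, `t2_ps`
#'   (see [read_stability_table()]).
#' @return Numeric vector of stability times in picoseconds.
#' @examples
#' triplex_stability_time(data.frame(t1_ps = 218, t2_ps = 449)) # 218
#' @export
triplex_stability_time <- function(records) {
  if (any(records$t1_ps < 0 | records$t2_ps < 0)) {
    abort("stability times must be >= 0")
  }
  pmin(records$t1_ps, records$t2_ps)
}

#' MDS stability decision rule
#'
#' Classifies triplexes as dynamically stable candidates of miRNA
#' cooperativity. Under the default `"per_mirna"` rule a record passes
#' when the triplex stability time ([triplex_stability_time()]) reaches
#' `threshold_ps` *and* at least one miRNA is held longer within the
#' triplex than in its corresponding duplex (`t1 > d1` or `t2 > d2`) -
#' i.e. triplex formation improved the binding of at least one partner.
#' The `"min_duplex"` variant instead compares the triplex stability
#' time against the smaller of the two duplex times
#' (`min(t1,t2) > min(d1,d2)`); it is provided for audit because the two
#' readings of the rule differ for borderline records.
#'
#' The time threshold is inclusive (`>= 100` ps by default), which is
#' decisive for records whose triplex stability time is exactly 100 ps.
#'
#' @param records Stability tibble (`d1_ps`, `d2_ps`, `t1_ps`, `t2_ps`).
#' @param threshold_ps Minimum triplex stability time (default 100 ps).
#' @param rule `"per_mirna"` (default) or `"min_duplex"`.
#' @return Logical vector, one element per record.
#' @export
stability_pass <- function(records, threshold_ps = 100,
                           rule = c("per_mirna", "min_duplex")) {
  rule <- match.arg(rule)
  st <- triplex_stability_time(records)
  time_ok <- st >= threshold_ps
  gain_ok <- if (rule == "per_mirna") {
    records$t1_ps > records$d1_ps | records$t2_ps > records$d2_ps
  } else {
    st > pmin(records$d1_ps, records$d2_ps)
  }
  time_ok & gain_ok
}

#' Count stability passes per selection group
#'
#' @param records Stability tibble with a `group_label` column.
#' @inheritParams stability_pass
#' @return Tibble with `group_label`, `n` (records) and `n_pass`.
#' @export
group_pass_counts <- function(records, threshold_ps = 100,
                              rule = c("per_mirna", "min_duplex")) {
  rule <- match.arg(rule)
  if (!nrow(records)) {
    return(tibble(group_label = character(), n = integer(), n_pass = integer()))
  }
  records$.pass <- stability_pass(records, threshold_ps, rule)
  records |>
    group_by(.data$group_label) |>
    summarise(n = n(), n_pass = sum(.data$.pass), .groups = "drop")
}

#' Packaged MDS benchmark triplexes
#'
#' Two small packaged tables describing 13 published human RNA
#' triplexes that were selected as extreme cases of triplex free energy
#' and free-energy gain, subjected to molecular-dynamics simulation,
#' plus the experimentally validated CDKN1A/miR-572/miR-93 control:
#'
#' * `"mds_selection"` - 12 triplexes with their triplex free energy
#'   (kcal/mol) and free-energy gain, grouped into `high_mfe`,
#'   `low_mfe`, `high_gain` and `low_gain`;
#' * `"mds_stability"` - duplex and within-triplex stability times
#'   (picoseconds) for all 13 complexes, the input for
#'   [stability_pass()].
#'
#' @param name `"mds_selection"` or `"mds_stability"`.
#' @return A tibble.
#' @examples
#' load_triplex_benchmark("mds_stability")
#' @export
load_triplex_benchmark <- function(name = c("mds_selection", "mds_stability")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"),
                      package = "triplexr", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}
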