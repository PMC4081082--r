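#' Free-energy profile of a triplex candidate
#'
#' Folds the candidate's mRNA window together with both miRNAs and with
#' each miRNA alone, and derives the quantities used to segregate
#' non-functional triplexes: the triplex free energy (TFE,
#' `dg_triplex`), both duplex energies, the free-energy gain
#' `ddg = dg_triplex - min(dg_duplex1, dg_duplex2)`, the structural
#' conformation class, and seed-preservation flags for both miRNAs.
#'
#' Because strand order matters in an ordered-complex fold, both strand
#' orders (window, miR1, miR2) and (window, miR2, miR1) are evaluated and
#' the lower-energy structure kept.
#'
#' @param candidate One-row candidate tibble from [pair_sites()] with
#'   `window_seq` and `window_offset`.
#' @param mir1_seq,mir2_seq Mature miRNA sequences (5'->3') of the
#'   upstream-site and downstream-site miRNA.
#' @param model An [energy_model()].
#' @param seed_positions,min_paired Seed definition forwarded to
#'   [seed_preserved()].
#' @return A one-row tibble: `dg_triplex`, `dg_duplex1`, `dg_duplex2`,
#'   `ddg`, `conformation`, `seed1_preserved`, `seed2_preserved`,
#'   `dot_bracket`, plus a `structure` list-column holding the winning
#'   `complex_structure`.
#' @export
triplex_energetics <- function(candidate, mir1_seq, mir2_seq,
                               model = energy_model(),
                               seed_positions = 2:8,
                               min_paired = length(seed_positions)) {
  window <- normalize_rna(candidate$window_seq, "mRNA window")
  mir1 <- normalize_rna(mir1_seq, "miRNA 1")
  mir2 <- normalize_rna(mir2_seq, "miRNA 2")
  id1 <- candidate$mirna1_id %||% "mir1"
  id2 <- candidate$mirna2_id %||% "mir2"

  d1 <- mfe_complex(setNames(c(window, mir1), c("mrna", id1)), model)
  d2 <- mfe_complex(setNames(c(window, mir2), c("mrna", id2)), model)

  t_a <- mfe_complex(setNames(c(window, mir1, mir2), c("mrna", id1, id2)), model)
  t_b <- mfe_complex(setNames(c(window, mir2, mir1), c("mrna", id2, id1)), model)
  tri <- if (t_a$dg <= t_b$dg) t_a else t_b

  dg_dup_min <- min(d1$dg, d2$dg)
  conf <- classify_conformation(tri)
  sp1 <- seed_preserved(tri, candidate, which_mirna = 1,
                        seed_positions = seed_positions, min_paired = min_paired)
  sp2 <- seed_preserved(tri, candidate, which_mirna = 2,
                        seed_positions = seed_positions, min_paired = min_paired)

  tibble(
    dg_triplex = tri$dg,
    dg_duplex1 = d1$dg,
    dg_duplex2 = d2$dg,
    ddg = tri$dg - dg_dup_min,
    conformation = conf,
    seed1_preserved = sp1,
    seed2_preserved = sp2,
    dot_bracket = tri$dot_bracket,
    structure = list(tri)
  )
}

#' Classify the conformation of a triplex structure
#'
#' Inspects the inter-strand pairing pattern of a three-strand MFE
#' structure (first strand = mRNA window):
#' * `duplex_plus_free_mirna` - one miRNA strand makes no inter-strand
#'   pair at all (the structure is really a duplex with an isolated
#'   miRNA);
#' * `mirna_mirna_hybrid` - the two miRNA strands pair with each other
#'   at least once (typically at the cost of seed binding);
#' * `canonical_triplex` - both miRNAs pair only with the mRNA, each
#'   with at least one pair;
#' * `other` - anything else.
#'
#' @param structure A 3-strand `complex_structure` whose first strand is
#'   the mRNA window.
#' @return A classification string.
#' @export
classify_conformation <- function(structure) {
  if (length(structure$strands) != 3) {
    abort("conformation classification needs exactly 3 strands (mRNA first)")
  }
  lens <- nchar(structure$strands)
  offs <- strand_offsets(lens)
  strand_of <- function(p) findInterval(p, offs + 1L)
  pr <- structure$pairs
  if (!nrow(pr)) return("duplex_plus_free_mirna")
  si <- strand_of(pr[, 1])
  sj <- strand_of(pr[, 2])
  inter <- si != sj
  mir_mrna <- function(k) sum(inter & ((si == 1 & sj == k) | (si == k & sj == 1)))
  mir_mir <- sum(inter & ((si == 2 & sj == 3) | (si == 3 & sj == 2)))
  # inter-strand pair counts per miRNA strand
  touches <- function(k) sum(inter & (si == k | sj == k))
  if (touches(2) == 0 || touches(3) == 0) return("duplex_plus_free_mirna")
  if (mir_mir >= 1) return("mirna_mirna_hybrid")
  if (mir_mrna(2) >= 1 && mir_mrna(3) >= 1) return("canonical_triplex")
  "other"
}

#' Is a miRNA's seed binding preserved in the triplex structure?
#'
#' A seed is preserved when at least `min_paired` of the miRNA's seed
#' nucleotides (positions 2-8 by the field's convention) are paired to
#' positions inside that miRNA's designated seed-match interval on the
#' mRNA window. Pairing the seed elsewhere (e.g. to the other site, or
#' to the other miRNA's 3' end) does not count.
#'
#' @param structure A 3-strand `complex_structure` (mRNA window first).
#' @param candidate The candidate row the structure was folded for
#'   (provides `window_offset` and the designated seed intervals).
#' @param which_mirna 1 for the upstream-site miRNA, 2 for the
#'   downstream-site miRNA.
#' @param seed_positions miRNA positions forming the seed (default 2:8).
#' @param min_paired Minimum number of seed positions that must pair
#'   into the designated interval (default: all of them).
#' @return `TRUE` or `FALSE`.
#' @export
seed_preserved <- function(structure, candidate, which_mirna,
                           seed_positions = 2:8,
                           min_paired = length(seed_positions)) {
  if (length(structure$strands) != 3) {
    abort("seed preservation check needs a 3-strand structure")
  }
  lens <- nchar(structure$strands)
  offs <- strand_offsets(lens)
  seed_start <- if (which_mirna == 1) candidate$seed1_start else candidate$seed2_start
  seed_end <- if (which_mirna == 1) candidate$seed1_end else candidate$seed2_end
  mir_id <- if (which_mirna == 1) candidate$mirna1_id else candidate$mirna2_id

  # designated seed interval in concatenation coordinates (window is strand 1)
  lo <- seed_start - candidate$window_offset + 1L
  hi <- seed_end - candidate$window_offset + 1L
  if (lo < 1 || hi > lens[1]) {
    abort("designated seed interval lies outside the folded window")
  }

  # candidate strands: those carrying the designated miRNA's id (both, for
  # homotypic pairs); fall back to position when ids are unavailable
  ids <- structure$strand_ids[2:3]
  strand_idx <- if (!is.null(mir_id) && any(ids == mir_id)) {
    which(ids == mir_id) + 1L
  } else {
    which_mirna + 1L
  }

  pr <- structure$pairs
  best <- 0L
  for (k in strand_idx) {
    pos <- offs[k] + seed_positions
    partner <- rep(NA_integer_, length(pos))
    if (nrow(pr)) {
      m1 <- match(pos, pr[, 1]); m2 <- match(pos, pr[, 2])
      partner <- ifelse(!is.na(m1), pr[m1, 2], ifelse(!is.na(m2), pr[m2, 1], NA))
    }
    hit <- sum(!is.na(partner) & partner >= lo & partner <= hi)
    best <- max(best, hit)
  }
  best >= min_paired
}

#' Population-relative triplex free-energy cutoff
#'
#' Returns `mean(dG) - z * sd(dG)` (sample standard deviation) over a
#' population of triplex free energies. With the default `z = 3` this is
#' the cutoff used to retain only the most stable triplexes of a large
#' prediction set: three standard deviations below the population mean.
#'
#' @param dg_population Numeric vector of triplex free energies
#'   (kcal/mol).
#' @param z Number of standard deviations below the mean (default 3,
#'   must be >= 0).
#' @return The cutoff in kcal/mol.
#' @examples
#' tfe_cutoff(c(-25, -15), z = 3) # mean -20, sd ~7.07
#' @export
tfe_cutoff <- function(dg_population, z = 3) {
  if (!length(dg_population)) abort("empty free-energy population")
  if (z < 0) abort("z must be >= 0")
  if (z > 0 && length(dg_population) < 2) {
    abort("population of >= 2 values needed for z > 0")
  }
  s <- if (length(dg_population) >= 2) sd(dg_population) else 0
  mean(dg_population) - z * s
}

#' Apply the structure-level triplex filters
#'
#' Applies, in order, the free-energy cutoff (`dg_triplex <= cutoff`,
#' boundary inclusive), the conformation filter (dropping structures
#' that are really a duplex plus a free miRNA, or miRNA-miRNA hybrids),
#' and the seed-preservation requirement for both miRNAs.
#'
#' @param energetics Tibble with columns `dg_triplex`, `conformation`,
#'   `seed1_preserved`, `seed2_preserved` (as from
#'   [triplex_energetics()], row-bound over candidates).
#' @param cutoff Free-energy cutoff in kcal/mol (use `Inf` to disable);
#'   typically [tfe_cutoff()] of the run's own population.
#' @param require_seed Require both seeds preserved (default `TRUE`).
#' @param drop_classes Conformation classes to discard.
#' @return A list: `kept` (surviving rows), `dropped` (discarded rows
#'   with a `reason` column: `"tfe"`, `"conformation"` or `"seed"`),
#'   and `funnel` (per-filter counts).
#' @export
apply_structure_filters <- function(energetics, cutoff,
                                    require_seed = TRUE,
                                    drop_classes = c("duplex_plus_free_mirna",
                                                     "mirna_mirna_hybrid")) {
  reason <- rep(NA_character_, nrow(energetics))
  fail_tfe <- energetics$dg_triplex > cutoff
  reason[fail_tfe] <- "tfe"
  fail_conf <- is.na(reason) & energetics$conformation %in% drop_classes
  reason[fail_conf] <- "conformation"
  if (require_seed) {
    fail_seed <- is.na(reason) &
      !(energetics$seed1_preserved & energetics$seed2_preserved)
    reason[fail_seed] <- "seed"
  }
  kept <- energetics[is.na(reason), , drop = FALSE]
  dropped <- energetics[!is.na(reason), , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- reason[!is.na(reason)]
  funnel <- tibble(
    filter = c("tfe", "conformation", "seed"),
    n_removed = c(sum(fail_tfe),
                  sum(fail_conf),
                  if (require_seed) sum(reason == "seed", na.rm = TRUE) else 0L)
  )
  list(kept = kept, dropped = dropped, funnel = funnel)
}
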