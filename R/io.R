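#' Read sequences from a FASTA file
#'
#' Reads a (possibly DNA) FASTA file and returns RNA sequences: records
#' are upper-cased and `T` is mapped to `U`; ids are taken up to the
#' first whitespace. A record containing symbols outside `{A,C,G,U,T}`
#' is an error naming the offending symbol, because every downstream
#' computation assumes an unambiguous RNA alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `seq`, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  first <- which(nzchar(trimws(lines)))[1]
  if (is.na(first)) abort(sprintf("%s: empty FASTA file", path))
  if (!startsWith(trimws(lines[first]), ">")) {
    abort(sprintf("%s: line %d: expected a '>' header before sequence data",
                  path, first))
  }
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) abort(sprintf("%s: no FASTA records", path))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (any(!nzchar(seqs))) {
    abort(sprintf("%s: empty record(s): %s", path,
                  paste(ids[!nzchar(seqs)], collapse = ", ")))
  }
  seqs <- vapply(seq_along(seqs), function(i) {
    normalize_rna(seqs[i], what = sprintf("record '%s'", ids[i]))
  }, character(1))
  tibble(id = ids, seq = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Tibble with columns `id` and `seq` (as from [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read miRNA sequences with conservation flags
#'
#' Convenience wrapper around [read_fasta()] for mature miRNA FASTA
#' files. miRNA sequences are checked against the expected mature-miRNA
#' length range (15-30 nt).
#'
#' @inheritParams read_fasta
#' @param conserved Either a logical scalar applied to all miRNAs or a
#'   character vector of conserved miRNA ids. miRNA conservation gates
#'   the `conserved_only` site filter in [filter_sites()].
#' @return Tibble with columns `id`, `seq`, `conserved`.
#' @export
read_mirna_fasta <- function(path, conserved = TRUE) {
  fa <- read_fasta(path)
  bad <- nchar(fa$seq) < 15 | nchar(fa$seq) > 30
  if (any(bad)) {
    abort(sprintf("mature miRNA length out of [15, 30] nt: %s",
                  paste(fa$id[bad], collapse = ", ")))
  }
  flag <- if (is.character(conserved)) fa$id %in% conserved else isTRUE(conserved)
  mutate(fa, conserved = flag)
}

site_required_cols <- c("gene_id", "transcript_id", "mirna_id",
                        "site_start", "site_end", "seed_start", "seed_end",
                        "mirsvr", "phastcons")

#' Read a miRanda-style target-site table
#'
#' Reads a tab-separated table of predicted miRNA binding sites on 3' UTRs.
#' The canonical dialect has mandatory columns `gene_id`, `transcript_id`,
#' `mirna_id`, `site_start`, `site_end`, `seed_start`, `seed_end`,
#' `mirsvr`, `phastcons`; extra columns are carried through untouched.
#' All coordinates are 1-based inclusive positions on the transcript's
#' 3' UTR (+ strand).
#'
#' Rows violating the site invariants (`site_start <= seed_start <=
#' seed_end <= site_end`, seed length 6-8 nt) are rejected, not silently
#' kept: the returned tibble carries a `rejections` attribute (tibble of
#' row number and reason), and a warning summarises the count.
#'
#' @param path Path to the TSV file.
#' @return Tibble of valid target sites, with attribute `rejections`.
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  missing <- setdiff(site_required_cols, names(raw))
  if (length(missing)) {
    abort(sprintf("site table %s is missing mandatory column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  checked <- validate_sites(raw)
  rej <- attr(checked, "rejections")
  if (nrow(rej)) {
    warn(sprintf("%d of %d site rows rejected (see attr(., 'rejections'))",
                 nrow(rej), nrow(raw)))
  }
  checked
}

# shared row-level invariant checks for target sites
validate_sites <- function(sites) {
  reason <- rep(NA_character_, nrow(sites))
  bad_coord <- with(sites, !(site_start <= seed_start & seed_start <= seed_end &
                               seed_end <= site_end))
  reason[bad_coord] <- "coordinates violate site_start <= seed_start <= seed_end <= site_end"
  seed_len <- sites$seed_end - sites$seed_start + 1
  bad_len <- is.na(reason) & (seed_len < 6 | seed_len > 8)
  reason[bad_len] <- sprintf("seed length %d outside [6, 8] nt", seed_len)[bad_len]
  ok <- is.na(reason)
  out <- as_tibble(sites[ok, , drop = FALSE])
  attr(out, "rejections") <- tibble(row = which(!ok), reason = reason[!ok])
  out
}

#' Read an MDS stability-time summary table
#'
#' Reads per-triplex stability times (picoseconds) from a molecular-
#' dynamics production run: `d1_ps`/`d2_ps` are the times each miRNA
#' stayed bonded to the mRNA in the isolated duplex, `t1_ps`/`t2_ps`
#' the corresponding times within the triplex. These summaries are
#' consumed, not produced, by this package; see [stability_pass()].
#'
#' @param path Path to a TSV with columns `gene_id`, `mirna1_id`,
#'   `mirna2_id`, `d1_ps`, `d2_ps`, `t1_ps`, `t2_ps` and optionally
#'   `group_label`, `potential_energy`.
#' @return Tibble of stability records.
#' @export
read_stability_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene_id", "mirna1_id", "mirna2_id", "d1_ps", "d2_ps", "t1_ps", "t2_ps")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    abort(sprintf("stability table %s is missing column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  times <- c("d1_ps", "d2_ps", "t1_ps", "t2_ps")
  if (any(as.matrix(raw[times]) < 0)) abort("stability times must be >= 0")
  if (!"group_label" %in% names(raw)) raw$group_label <- NA_character_
  as_tibble(raw)
}

#' Write and read triplex result tables
#'
#' Results are plain tabular records (one row per triplex); `tsv` and
#' `json` dialects round-trip losslessly through [read_triplex_results()].
#'
#' @param records A data frame of results sharing one schema.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_triplex_results <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(records, path)
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_triplex_results
#' @export
read_triplex_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::read_tsv(path, show_col_types = FALSE)
  } else {
    as_tibble(jsonlite::fromJSON(path))
  }
}

# ---- coordinate conventions -------------------------------------------
# On disk and in user-facing tibbles all coordinates are 1-based
# inclusive. Interval arithmetic inside the package uses 0-based
# half-open intervals; these two helpers are exact inverses.

to_halfopen <- function(start1, end1) list(start = start1 - 1L, end = end1)
to_onebased <- function(start0, end0) list(start = start0 + 1L, end = end0)
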