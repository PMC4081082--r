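#' Filter target sites by prediction score and miRNA conservation
#'
#' Keeps sites with a good miRanda/mirSVR score (`mirsvr <= mirsvr_max`,
#' boundary inclusive) and, optionally, only sites of conserved miRNAs.
#'
#' @param sites Tibble of target sites (see [read_site_table()]).
#' @param mirsvr_max Maximum (i.e. least negative) mirSVR score kept;
#'   default -0.1. mirSVR scores are more negative for stronger
#'   predicted repression.
#' @param conserved_only If `TRUE` (default) keep only sites whose miRNA
#'   is flagged conserved.
#' @param mirnas Optional miRNA tibble with columns `id`, `conserved`
#'   (see [read_mirna_fasta()]). If absent, a `conserved` column on
#'   `sites` is used; if neither exists all miRNAs count as conserved.
#' @return The filtered site tibble.
#' @export
filter_sites <- function(sites, mirsvr_max = -0.1, conserved_only = TRUE,
                         mirnas = NULL) {
  keep <- sites$mirsvr <= mirsvr_max
  if (conserved_only) {
    conserved <- if (!is.null(mirnas)) {
      sites$mirna_id %in% mirnas$id[mirnas$conserved]
    } else if ("conserved" %in% names(sites)) {
      sites$conserved
    } else {
      rep(TRUE, nrow(sites))
    }
    keep <- keep & conserved
  }
  sites[keep, , drop = FALSE]
}

#' Seed-site distance between two target sites
#'
#' Distance between the seed matches of two sites on the same transcript.
#' The default metric counts the nucleotides strictly between the two
#' seed-match intervals (`b$seed_start - a$seed_end - 1`); the
#' `"start_to_start"` metric returns `b$seed_start - a$seed_start`.
#' Cooperating miRNA pairs show optimal repression at seed distances of
#' 13-35 nt.
#'
#' @param a,b Single-row site tibbles (or lists) with `seed_start`,
#'   `seed_end`; `a` must be upstream (`a$seed_end < b$seed_start`).
#' @param metric `"gap"` (default) or `"start_to_start"`.
#' @return Integer distance in nucleotides.
#' @export
seed_distance <- function(a, b, metric = c("gap", "start_to_start")) {
  metric <- match.arg(metric)
  if (a$seed_end >= b$seed_start) {
    abort("sites are mis-ordered or their seeds overlap: need a$seed_end < b$seed_start")
  }
  if (metric == "gap") {
    as.integer(b$seed_start - a$seed_end - 1L)
  } else {
    as.integer(b$seed_start - a$seed_start)
  }
}

#' Pair target sites into triplex candidates
#'
#' Forms every ordered (upstream, downstream) pair of target sites on
#' the same transcript whose seed-site distance lies in
#' `[d_min, d_max]` (both bounds inclusive), the spacing at which two
#' miRNAs can co-occupy a 3' UTR and cooperate. Pairs of sites for the
#' same miRNA (homotypic triplexes) are allowed. When UTR sequences are
#' supplied, each candidate records the mRNA window enclosing both sites
#' (see [extract_window()]).
#'
#' @param sites Site tibble; pairing is done within each `transcript_id`.
#' @param d_min,d_max Seed-distance bounds in nt (defaults 13 and 35).
#' @param utrs Optional tibble of 3' UTR sequences (`id`, `seq`) keyed by
#'   `transcript_id`; enables window extraction.
#' @param metric Seed-distance metric, see [seed_distance()].
#' @param flank Extra nucleotides added on both sides of the window.
#' @return Tibble of candidates: gene/transcript ids, both miRNA ids,
#'   upstream and downstream site coordinates, `seed_dist`, and (with
#'   `utrs`) `window_seq` and 1-based `window_offset`.
#' @export
pair_sites <- function(sites, d_min = 13, d_max = 35, utrs = NULL,
                       metric = c("gap", "start_to_start"), flank = 0) {
  metric <- match.arg(metric)
  out <- list()
  for (tx in unique(sites$transcript_id)) {
    ss <- sites[sites$transcript_id == tx, , drop = FALSE]
    ss <- ss[order(ss$seed_start, ss$seed_end, ss$mirna_id), , drop = FALSE]
    k <- nrow(ss)
    if (k < 2) next
    for (u in seq_len(k - 1)) {
      for (v in seq(u + 1, k)) {
        a <- ss[u, ]
        b <- ss[v, ]
        if (a$seed_end >= b$seed_start) next # overlapping seeds cannot co-bind
        d <- seed_distance(a, b, metric)
        if (d < d_min || d > d_max) next
        out[[length(out) + 1]] <- tibble(
          gene_id = a$gene_id,
          transcript_id = tx,
          mirna1_id = a$mirna_id,
          mirna2_id = b$mirna_id,
          site1_start = a$site_start, site1_end = a$site_end,
          seed1_start = a$seed_start, seed1_end = a$seed_end,
          site2_start = b$site_start, site2_end = b$site_end,
          seed2_start = b$seed_start, seed2_end = b$seed_end,
          mirsvr1 = a$mirsvr, mirsvr2 = b$mirsvr,
          phastcons1 = a$phastcons, phastcons2 = b$phastcons,
          seed_dist = d
        )
      }
    }
  }
  cand <- if (length(out)) bind_rows(out) else tibble(
    gene_id = character(), transcript_id = character(),
    mirna1_id = character(), mirna2_id = character(),
    site1_start = integer(), site1_end = integer(),
    seed1_start = integer(), seed1_end = integer(),
    site2_start = integer(), site2_end = integer(),
    seed2_start = integer(), seed2_end = integer(),
    mirsvr1 = double(), mirsvr2 = double(),
    phastcons1 = double(), phastcons2 = double(),
    seed_dist = integer()
  )
  if (!is.null(utrs) && nrow(cand)) {
    win <- pmap(list(cand$transcript_id, cand$site1_start, cand$site1_end,
                     cand$site2_start, cand$site2_end),
                function(tx, s1, e1, s2, e2) {
                  utr <- utrs$seq[match(tx, utrs$id)]
                  if (is.na(utr)) {
                    abort(sprintf("no UTR sequence for transcript '%s'", tx))
                  }
                  extract_window(utr, min(s1, s2), max(e1, e2), flank = flank)
                })
    cand$window_seq <- map_chr(win, "seq")
    cand$window_offset <- map_int(win, "offset")
  }
  cand
}

#' Extract the mRNA window enclosing a pair of target sites
#'
#' Returns the UTR subsequence from the leftmost site start to the
#' rightmost site end, optionally padded by `flank` nt and clipped to the
#' UTR boundaries, together with the 1-based UTR position of the window
#' start. UTR position and window index are related by
#' `utr_pos = window_index + offset - 1`.
#'
#' @param utr_seq The 3' UTR sequence (RNA or DNA; normalised to RNA).
#' @param start,end 1-based inclusive span to enclose (typically
#'   `min(site starts)` and `max(site ends)`).
#' @param flank Padding in nt (default 0).
#' @return List with `seq` and `offset`.
#' @export
extract_window <- function(utr_seq, start, end, flank = 0) {
  utr_seq <- normalize_rna(utr_seq, what = "UTR sequence")
  L <- nchar(utr_seq)
  if (start < 1 || end > L || start > end) {
    abort(sprintf("site span [%d, %d] outside UTR of length %d", start, end, L))
  }
  a <- max(1L, as.integer(start - flank))
  b <- min(L, as.integer(end + flank))
  list(seq = substr(utr_seq, a, b), offset = a)
}
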