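#' Generate a synthetic triplex dataset with known ground truth
#'
#' Builds self-contained pipeline inputs - 3' UTR sequences, a mature
#' miRNA pool and a miRanda-style site table - in which RNA triplexes
#' with known seed distances are planted. For each planted triplex two
#' miRNAs from the pool receive perfect seed complements (miRNA
#' nucleotides 2-8 reverse-complemented into the UTR) at exactly the
#' requested seed-site distance; `complementarity_level` controls how
#' much additional 3'-end pairing (miRNA nucleotides 13 onwards) is
#' written. Background sequence is uniform over {A,C,G,U}, with
#' rejection sampling removing accidental occurrences of any pool
#' miRNA's seed complement so that the planted sites are the only true
#' sites.
#'
#' @param n_genes Number of genes; the first `length(planted)` genes
#'   carry one planted triplex each, the rest are pure background.
#' @param utr_len UTR length in nt (default 200).
#' @param mirna_pool_size Number of 22-nt miRNAs in the pool.
#' @param planted List of planted triplexes; each element is a list (or
#'   named vector) with `seed_distance` (nt between the two seed
#'   matches) and optionally `complementarity_level` (0-1, default 0.9).
#' @param rng_seed Integer seed; identical seeds give identical output.
#' @param mirsvr,phastcons Scores written for planted sites (defaults
#'   -0.5 and 0.9, comfortably passing the default filters).
#' @return A list of tibbles: `utrs` (`id`, `seq`), `mirnas` (`id`,
#'   `seq`, `conserved`), `sites` (canonical site-table dialect) and
#'   `truth` (one row per planted triplex: gene, transcript, both miRNA
#'   ids, seed distance).
#' @examples
#' toy <- generate_toy_dataset(n_genes = 2, planted = list(
#'   list(seed_distance = 20)), rng_seed = 1)
#' toy$truth
#' @export
generate_toy_dataset <- function(n_genes = length(planted),
                                 utr_len = 200,
                                 mirna_pool_size = 6,
                                 planted = list(),
                                 rng_seed = 1,
                                 mirsvr = -0.5,
                                 phastcons = 0.9) {
  if (n_genes < length(planted)) {
    abort("n_genes must be >= the number of planted triplexes")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(rng_seed)

  bases <- c("A", "C", "G", "U")
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  revcomp <- function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  rand_seq <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")

  mir_len <- 22L
  mirnas <- tibble(
    id = sprintf("syn-miR-%02d", seq_len(mirna_pool_size)),
    seq = vapply(seq_len(mirna_pool_size), function(i) rand_seq(mir_len),
                 character(1)),
    conserved = TRUE
  )
  # 7-mers whose presence in a UTR would create an unplanned seed match
  seed_complements <- vapply(mirnas$seq, function(s) revcomp(substr(s, 2, 8)),
                             character(1))

  utr_rows <- list()
  site_rows <- list()
  truth_rows <- list()

  for (g in seq_len(n_genes)) {
    gene <- sprintf("GENE%03d", g)
    tx <- paste0(gene, "-tx1")
    plan <- if (g <= length(planted)) planted[[g]] else NULL

    for (attempt in seq_len(200)) {
      chars <- strsplit(rand_seq(utr_len), "")[[1]]
      planted_spans <- integer(0)

      if (!is.null(plan)) {
        d <- as.integer(plan$seed_distance %||% plan[["seed_distance"]])
        if (is.na(d) || d < 0) abort("planted seed_distance must be >= 0")
        level <- plan$complementarity_level %||% 0.9
        idx <- sample.int(mirna_pool_size, 2)
        m1 <- mirnas$seq[idx[1]]
        m2 <- mirnas$seq[idx[2]]

        # miRNA nt k pairs UTR position e - k + 1 (antiparallel);
        # seed match (nts 2-8) occupies [e - 7, e - 1]
        e1 <- 50L
        e2 <- e1 + d + 7L
        if (e2 > utr_len - 30L) {
          abort("utr_len too small to host the planted triplex")
        }
        write_site <- function(chars, mir, e) {
          mseq <- strsplit(mir, "")[[1]]
          ks <- 1:8
          n_suppl <- round(level * 8)
          if (n_suppl > 0) ks <- c(ks, 12 + seq_len(n_suppl))
          for (k in ks) {
            pos <- e - k + 1L
            if (pos >= 1 && pos <= utr_len) chars[pos] <- comp[mseq[k]]
          }
          chars
        }
        chars <- write_site(chars, m1, e1)
        chars <- write_site(chars, m2, e2)
        planted_spans <- c((e1 - 7):(e1 - 1), (e2 - 7):(e2 - 1))

        s1_start <- max(1L, e1 - mir_len + 1L)
        s2_start <- max(1L, e2 - mir_len + 1L)
        site_rows[[length(site_rows) + 1]] <- tibble(
          gene_id = gene, transcript_id = tx,
          mirna_id = mirnas$id[c(idx[1], idx[2])],
          site_start = c(s1_start, s2_start),
          site_end = c(e1, e2),
          seed_start = c(e1 - 7L, e2 - 7L),
          seed_end = c(e1 - 1L, e2 - 1L),
          mirsvr = mirsvr, phastcons = phastcons
        )
        truth_rows[[length(truth_rows) + 1]] <- tibble(
          gene_id = gene, transcript_id = tx,
          mirna1_id = mirnas$id[idx[1]], mirna2_id = mirnas$id[idx[2]],
          seed_distance = d
        )
      }

      # reject backgrounds with accidental seed matches for any pool miRNA
      utr <- paste(chars, collapse = "")
      planned_starts <- if (length(planted_spans)) {
        c(planted_spans[1], planted_spans[8]) # the two seed-match starts
      } else integer(0)
      accidental <- FALSE
      for (sc in seed_complements) {
        hits <- gregexpr(sc, utr, fixed = TRUE)[[1]]
        hits <- hits[hits > 0]
        if (length(setdiff(hits, planned_starts))) {
          accidental <- TRUE
          break
        }
      }
      if (!accidental) {
        utr_rows[[length(utr_rows) + 1]] <- tibble(id = tx, seq = utr)
        break
      }
      if (attempt == 200) abort("could not place triplex without accidental seed matches")
      # resample: drop this gene's provisional site/truth rows and retry
      if (!is.null(plan)) {
        site_rows[[length(site_rows)]] <- NULL
        truth_rows[[length(truth_rows)]] <- NULL
      }
    }
  }

  list(
    utrs = bind_rows(utr_rows),
    mirnas = mirnas,
    sites = if (length(site_rows)) bind_rows(site_rows) else tibble(
      gene_id = character(), transcript_id = character(), mirna_id = character(),
      site_start = integer(), site_end = integer(), seed_start = integer(),
      seed_end = integer(), mirsvr = double(), phastcons = double()
    ),
    truth = if (length(truth_rows)) bind_rows(truth_rows) else tibble(
      gene_id = character(), transcript_id = character(),
      mirna1_id = character(), mirna2_id = character(), seed_distance = integer()
    )
  )
}

#' Write a toy dataset to a directory
#'
#' Serialises a [generate_toy_dataset()] result as `utrs.fa`,
#' `mirnas.fa`, `sites.tsv` and `truth.tsv`.
#'
#' @param toy A toy dataset list.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_toy_dataset <- function(toy, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(toy$utrs, file.path(dir, "utrs.fa"))
  write_fasta(toy$mirnas, file.path(dir, "mirnas.fa"))
  readr::write_tsv(toy$mirnas["id"] |> mutate(conserved = toy$mirnas$conserved),
                   file.path(dir, "conserved.tsv"))
  readr::write_tsv(toy$sites, file.path(dir, "sites.tsv"))
  readr::write_tsv(toy$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
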