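#' Predict the minimum-free-energy structure of an RNA complex
#'
#' Computes the minimum-free-energy (MFE) non-pseudoknotted secondary
#' structure of one to three RNA strands with a nick-aware Zuker-style
#' dynamic program. Base pairs are allowed within and between strands;
#' loops that span a strand nick carry no penalty and no minimum hairpin
#' size, so intermolecular helices are scored purely by their stacking
#' terms. Co-optimal structures are resolved by a fixed, deterministic
#' traceback order.
#'
#' @param strands Named character vector of RNA sequences (5'->3'), in
#'   complex order. `T` is tolerated and mapped to `U`.
#' @param model An [energy_model()].
#'
#' @return A `complex_structure`: strand ids and sequences, the base-pair
#'   map (1-based positions over the concatenation), the dot-bracket
#'   string with `&` strand separators, and the free energy `dG` in
#'   kcal/mol (0 for a structure with no pairs).
#' @examples
#' fold <- mfe_complex(c(g = "GGGGG", c = "CCCCC"))
#' fold$dot_bracket
#' fold$dg
#' @seealso [enumerate_structures()] for the exhaustive oracle on small
#'   inputs, [triplex_energetics()] for the duplex/triplex comparison.
#' @export
mfe_complex <- function(strands, model = energy_model()) {
  strands <- check_strands(strands, max_strands = 3)
  n_total <- sum(nchar(strands))
  if (n_total > 2000) abort("total strand length must be <= 2000 nt")

  codes <- strand_codes(strands)
  tabs <- loop_tables(model, n_total)
  res <- .mfe_fold_cpp(
    codes$codes, codes$nick_at,
    unname(model$pair_type), unname(model$stack_cc),
    tabs$hairpin, tabs$bulge, tabs$internal,
    tabs$ml_a, tabs$ml_b, tabs$ml_c
  )
  pairs <- res$pairs
  if (nrow(pairs)) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  new_complex_structure(strands, pairs, res$energy_cc / 100)
}

new_complex_structure <- function(strands, pairs, dg) {
  structure(
    list(
      strand_ids = names(strands),
      strands = unname(strands),
      pairs = pairs,
      dot_bracket = pairs_to_dotbracket(pairs, nchar(strands)),
      dg = dg
    ),
    class = "complex_structure"
  )
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("<complex_structure> ", paste(x$strand_ids, collapse = " + "), "\n", sep = "")
  cat("  ", paste(x$strands, collapse = "&"), "\n", sep = "")
  cat("  ", x$dot_bracket, "\n", sep = "")
  cat("  dG = ", sprintf("%.2f", x$dg), " kcal/mol, ",
      nrow(x$pairs), " base pairs\n", sep = "")
  invisible(x)
}

#' @export
tidy.complex_structure <- function(x, ...) {
  if (!nrow(x$pairs)) {
    return(tibble(pos_i = integer(), pos_j = integer(),
                  strand_i = character(), strand_j = character()))
  }
  offs <- strand_offsets(nchar(x$strands))
  which_strand <- function(p) findInterval(p, offs + 1L)
  tibble(
    pos_i = x$pairs[, 1], pos_j = x$pairs[, 2],
    strand_i = x$strand_ids[which_strand(x$pairs[, 1])],
    strand_j = x$strand_ids[which_strand(x$pairs[, 2])]
  )
}

#' @export
glance.complex_structure <- function(x, ...) {
  tibble(
    n_strands = length(x$strands),
    total_length = sum(nchar(x$strands)),
    n_pairs = nrow(x$pairs),
    dg = x$dg
  )
}

# ---- sequence utilities ------------------------------------------------

normalize_rna <- function(seq, what = "sequence") {
  seq <- toupper(seq)
  seq <- gsub("T", "U", seq, fixed = TRUE)
  bad <- unique(strsplit(gsub("[ACGU]", "", seq), "")[[1]])
  if (length(bad)) {
    abort(sprintf("%s contains invalid symbol(s): %s",
                  what, paste(bad, collapse = ", ")))
  }
  seq
}

check_strands <- function(strands, max_strands = 3) {
  if (is.list(strands)) strands <- unlist(strands)
  if (length(strands) < 1) abort("at least one strand is required")
  if (length(strands) > max_strands) {
    abort(sprintf("at most %d strands are supported", max_strands))
  }
  if (any(!nzchar(strands))) abort("empty strand")
  if (is.null(names(strands))) {
    names(strands) <- paste0("strand", seq_along(strands))
  }
  vapply(strands, normalize_rna, character(1))
}

# cumulative start offsets (0-based) of each strand in the concatenation
strand_offsets <- function(lengths) cumsum(c(0L, lengths))[seq_along(lengths)]

strand_codes <- function(strands) {
  lens <- nchar(strands)
  concat <- paste(strands, collapse = "")
  codes <- match(strsplit(concat, "")[[1]], c("A", "C", "G", "U")) - 1L
  n <- sum(lens)
  nick_at <- rep(FALSE, max(n - 1L, 0L))
  ends <- cumsum(lens)
  for (e in head(ends, -1)) nick_at[e] <- TRUE # nick between e and e+1 (1-based)
  list(codes = codes, nick_at = nick_at, lengths = lens)
}

# ---- dot-bracket <-> pair map -----------------------------------------

#' Convert a base-pair map to dot-bracket notation
#'
#' Multi-strand structures use `&` as the strand separator; positions in
#' the pair map index the plain concatenation (no separators).
#'
#' @param pairs Two-column integer matrix of paired positions (1-based,
#'   over the concatenation), `i < j` per row.
#' @param lengths Integer vector of strand lengths.
#' @return A dot-bracket string.
#' @export
pairs_to_dotbracket <- function(pairs, lengths) {
  n <- sum(lengths)
  chars <- rep(".", n)
  if (!is.null(pairs) && nrow(pairs)) {
    chars[pairs[, 1]] <- "("
    chars[pairs[, 2]] <- ")"
  }
  ends <- cumsum(lengths)
  out <- character(length(lengths))
  start <- 1L
  for (s in seq_along(lengths)) {
    out[s] <- paste(chars[start:ends[s]], collapse = "")
    start <- ends[s] + 1L
  }
  paste(out, collapse = "&")
}

#' Convert dot-bracket notation to a base-pair map
#'
#' @param db Dot-bracket string, `&` separating strands.
#' @return List with `pairs` (two-column matrix over the concatenation)
#'   and `lengths` (strand lengths).
#' @export
dotbracket_to_pairs <- function(db) {
  parts <- strsplit(db, "&", fixed = TRUE)[[1]]
  lengths <- nchar(parts)
  chars <- strsplit(paste(parts, collapse = ""), "")[[1]]
  if (!all(chars %in% c(".", "(", ")"))) {
    abort("dot-bracket may only contain '.', '(', ')' and '&'")
  }
  stack <- integer(0)
  pairs <- matrix(integer(0), 0, 2)
  for (p in seq_along(chars)) {
    if (chars[p] == "(") {
      stack <- c(stack, p)
    } else if (chars[p] == ")") {
      if (!length(stack)) abort("unbalanced dot-bracket string")
      pairs <- rbind(pairs, c(stack[length(stack)], p))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) abort("unbalanced dot-bracket string")
  if (nrow(pairs)) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  list(pairs = pairs, lengths = lengths)
}

# ---- reference scorer (loop decomposition, shared with the oracle) -----

# Scores an explicit structure with the identical integer tables used by
# the dynamic program. Returns energy in centi-kcal, or .INF_CC for a
# structure forbidden by the model (e.g. nick-free hairpin < 3 nt).
score_structure_cc <- function(pairs, strands, model,
                               tabs = NULL, codes = NULL) {
  info <- codes %||% strand_codes(strands)
  n <- length(info$codes)
  tabs <- tabs %||% loop_tables(model, n)
  nickat <- info$nick_at
  ptype <- model$pair_type
  base <- c("A", "C", "G", "U")[info$codes + 1]

  if (!nrow(pairs)) return(0L)
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  pt_of <- function(i, j) ptype[base[i], base[j]]
  if (any(apply(pairs, 1, function(p) pt_of(p[1], p[2]) == 0))) return(.INF_CC)

  # children of each closing pair (and of the exterior, idx 0)
  np <- nrow(pairs)
  parent <- integer(np)
  for (r in seq_len(np)) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    best <- 0L; best_span <- n + 1L
    for (q in seq_len(np)) {
      if (q == r) next
      qi <- pairs[q, 1]; qj <- pairs[q, 2]
      if (qi < i && j < qj && (qj - qi) < best_span) {
        best <- q; best_span <- qj - qi
      }
    }
    parent[r] <- best
  }

  nick_in <- function(a, b) a <= b && any(nickat[a:b])

  total <- 0L
  for (r in seq_len(np)) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    kids <- which(parent == r)
    kids <- kids[order(pairs[kids, 1])]
    # accessible gap ranges (nick positions between loop elements)
    prev_end <- i
    has_nick <- FALSE
    for (q in kids) {
      if (prev_end <= pairs[q, 1] - 1 && nick_in(prev_end, pairs[q, 1] - 1)) has_nick <- TRUE
      prev_end <- pairs[q, 2]
    }
    if (prev_end <= j - 1 && nick_in(prev_end, j - 1)) has_nick <- TRUE

    m <- length(kids)
    if (has_nick) next # exterior-like loop: zero penalty
    if (m == 0) {
      sz <- j - i - 1
      pen <- if (sz + 1 <= length(tabs$hairpin)) tabs$hairpin[sz + 1] else .INF_CC
      if (pen >= .INF_CC) return(.INF_CC)
      total <- total + pen
    } else if (m == 1) {
      k <- pairs[kids, 1]; l <- pairs[kids, 2]
      s1 <- k - i - 1; s2 <- j - l - 1
      pen <- if (s1 == 0 && s2 == 0) {
        model$stack_cc[pt_of(i, j), pt_of(k, l)]
      } else if (s1 == 0 || s2 == 0) {
        if (s1 + s2 + 1 <= length(tabs$bulge)) tabs$bulge[s1 + s2 + 1] else .INF_CC
      } else {
        if (s1 + s2 + 1 <= length(tabs$internal)) tabs$internal[s1 + s2 + 1] else .INF_CC
      }
      if (pen >= .INF_CC) return(.INF_CC)
      total <- total + pen
    } else {
      unpaired <- (j - i - 1) - sum(pairs[kids, 2] - pairs[kids, 1] + 1)
      total <- total + tabs$ml_a + tabs$ml_b * (m + 1L) + tabs$ml_c * unpaired
    }
  }
  as.integer(total)
}

#' Exhaustively enumerate secondary structures of a small complex
#'
#' Generates every valid non-pseudoknotted matching of a 1-3 strand
#' complex and scores each with exactly the scoring function behind
#' [mfe_complex()]. This is the package's independent verification
#' oracle: on any input within the length cap, the minimum over the
#' enumeration equals the dynamic-programming MFE exactly.
#'
#' @inheritParams mfe_complex
#' @param max_total_len Hard cap on the total length (default 30);
#'   longer inputs are refused because the structure count grows
#'   exponentially.
#' @return A tibble with one row per structure: `dot_bracket`, `n_pairs`,
#'   `energy` (kcal/mol), sorted by energy then dot-bracket.
#' @examples
#' enumerate_structures(c(a = "GC", b = "GC"))
#' @export
enumerate_structures <- function(strands, model = energy_model(),
                                 max_total_len = 30) {
  strands <- check_strands(strands, max_strands = 3)
  n <- sum(nchar(strands))
  if (n > max_total_len) {
    abort(sprintf("total length %d exceeds the enumeration cap (%d)",
                  n, max_total_len))
  }
  info <- strand_codes(strands)
  tabs <- loop_tables(model, n)
  base <- c("A", "C", "G", "U")[info$codes + 1]
  ptype <- model$pair_type
  min_hp <- model$loops$min_hairpin
  nickat <- info$nick_at
  nick_in <- function(a, b) a <= b && any(nickat[a:b])
  # a pair is a candidate if complementary and not a nick-free loop
  # smaller than the minimum hairpin size
  can <- function(i, j) {
    ptype[base[i], base[j]] != 0 &&
      (j - i - 1 >= min_hp || nick_in(i, j - 1))
  }

  memo <- new.env(parent = emptyenv())
  enum <- function(a, b) {
    if (a > b) return(list(matrix(integer(0), 0, 2)))
    key <- paste0(a, ":", b)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- lapply(enum(a + 1, b), identity) # a unpaired
    for (j in seq(a + 1, length.out = max(b - a, 0))) {
      if (!can(a, j)) next
      inner <- enum(a + 1, j - 1)
      outer <- enum(j + 1, b)
      for (s1 in inner) {
        for (s2 in outer) {
          out[[length(out) + 1]] <- rbind(c(a, j), s1, s2)
        }
      }
    }
    memo[[key]] <- out
    out
  }

  all_str <- enum(1L, n)
  energies <- vapply(all_str, function(p) {
    score_structure_cc(p, strands, model, tabs = tabs, codes = info)
  }, integer(1))
  keep <- energies < .INF_CC
  res <- tibble(
    dot_bracket = vapply(all_str[keep], pairs_to_dotbracket,
                         character(1), lengths = nchar(strands)),
    n_pairs = vapply(all_str[keep], nrow, integer(1)),
    energy = energies[keep] / 100
  )
  arrange(res, .data$energy, .data$dot_bracket)
}
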