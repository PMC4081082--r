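#' Reduced nearest-neighbor RNA energy model
#'
#' Builds the thermodynamic scoring model used by [mfe_complex()] and
#' [enumerate_structures()]. The model scores Watson-Crick and G.U wobble
#' base pairs with a symmetric stacking-energy table and penalises
#' hairpin, bulge, internal and multibranch loops with affine +
#' logarithmic terms. Loops whose accessible region spans a strand nick
#' are scored as exterior regions: no penalty and no minimum hairpin
#' size. Unstructured single strands are the zero point of the energy
#' scale, so every reported free energy is relative to fully dissociated,
#' unfolded monomers.
#'
#' Energies are handled internally as integer centi-kcal/mol so that the
#' dynamic program and the exhaustive enumeration oracle agree exactly.
#'
#' @param stacks_file,loops_file Paths to the parameter tables. Defaults
#'   to the tables packaged under `extdata` (stack free energies of
#'   Turner-like magnitude at 37 C; loop penalty coefficients).
#' @param temperature Temperature in Kelvin (default 310.15, i.e. 37 C).
#'   Used downstream to convert free energies into equilibrium and rate
#'   constants; the packaged stack parameters are 37 C values.
#'
#' @return An object of class `energy_model`: a list with the pair-type
#'   lookup, the stack table (centi-kcal), loop penalty coefficients and
#'   the temperature.
#' @examples
#' m <- energy_model()
#' m$stack_cc["GC", "GC"] # one G.C/G.C stack, centi-kcal/mol
#' @export
energy_model <- function(stacks_file = NULL, loops_file = NULL,
                         temperature = 310.15) {
  stacks_file <- stacks_file %||%
    system.file("extdata", "nn_stacks.tsv", package = "triplexr", mustWork = TRUE)
  loops_file <- loops_file %||%
    system.file("extdata", "nn_loops.tsv", package = "triplexr", mustWork = TRUE)

  st <- readr::read_tsv(stacks_file, show_col_types = FALSE)
  if (!all(c("pair1", "pair2", "dg_kcal") %in% names(st))) {
    abort("stack table must have columns pair1, pair2, dg_kcal")
  }
  ptypes <- c("AU", "UA", "CG", "GC", "GU", "UG")
  stack_cc <- matrix(NA_integer_, 6, 6, dimnames = list(ptypes, ptypes))
  for (r in seq_len(nrow(st))) {
    stack_cc[st$pair1[r], st$pair2[r]] <- as.integer(round(100 * st$dg_kcal[r]))
  }
  if (anyNA(stack_cc)) abort("stack table is incomplete")
  flip <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  for (p1 in ptypes) {
    for (p2 in ptypes) {
      if (stack_cc[p1, p2] != stack_cc[flip(p2), flip(p1)]) {
        abort("stack table violates strand-flip symmetry")
      }
    }
  }

  lp <- readr::read_tsv(loops_file, show_col_types = FALSE)
  loops <- setNames(lp$value, lp$parameter)
  needed <- c("hairpin_a", "hairpin_b", "bulge_a", "bulge_b", "internal_a",
              "internal_b", "ml_close", "ml_branch", "ml_unpaired",
              "min_hairpin", "max_interior")
  if (!all(needed %in% names(loops))) abort("loop table is incomplete")

  bases <- c("A", "C", "G", "U")
  # pair-type index per ordered base pair; 0 = not pairable
  pair_type <- matrix(0L, 4, 4, dimnames = list(bases, bases))
  pair_type["A", "U"] <- 1L; pair_type["U", "A"] <- 2L
  pair_type["C", "G"] <- 3L; pair_type["G", "C"] <- 4L
  pair_type["G", "U"] <- 5L; pair_type["U", "G"] <- 6L

  structure(
    list(
      bases = bases,
      pair_type = pair_type,
      stack_cc = stack_cc,
      loops = as.list(loops),
      temperature = temperature
    ),
    class = "energy_model"
  )
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model> reduced nearest-neighbor RNA model\n")
  cat("  pairs: Watson-Crick + G.U wobble;",
      sum(x$stack_cc < 0), "stabilising stack terms\n")
  cat("  min hairpin", x$loops$min_hairpin,
      "nt (waived across nicks); interior cap", x$loops$max_interior, "nt\n")
  cat("  temperature:", x$temperature, "K\n")
  invisible(x)
}

# Integer loop-penalty tables (centi-kcal), shared verbatim by the C++ DP
# and the R enumeration scorer. Index k holds the penalty for size k
# (1-based list positions k + 1 would be awkward; we return plain integer
# vectors indexed via `[size + 1]`).
loop_tables <- function(model, n) {
  lo <- model$loops
  sz <- 0:max(n, 3)
  hairpin <- rep(.INF_CC, length(sz))
  ok <- sz >= lo$min_hairpin
  hairpin[ok] <- as.integer(round(100 * (lo$hairpin_a +
    lo$hairpin_b * log(sz[ok] / lo$min_hairpin))))
  bulge <- rep(.INF_CC, length(sz))
  ok <- sz >= 1 & sz <= lo$max_interior
  bulge[ok] <- as.integer(round(100 * (lo$bulge_a + lo$bulge_b * log(sz[ok]))))
  internal <- rep(.INF_CC, length(sz))
  ok <- sz >= 2 & sz <= lo$max_interior
  internal[ok] <- as.integer(round(100 * (lo$internal_a +
    lo$internal_b * log(sz[ok] / 2))))
  list(
    hairpin = hairpin, bulge = bulge, internal = internal,
    ml_a = as.integer(round(100 * lo$ml_close)),
    ml_b = as.integer(round(100 * lo$ml_branch)),
    ml_c = as.integer(round(100 * lo$ml_unpaired))
  )
}

.INF_CC <- 100000000L

# RT in kcal/mol at the model temperature
model_rt <- function(model) .RGAS * model$temperature
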