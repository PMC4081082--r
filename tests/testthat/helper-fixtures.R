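# Shared fixtures built in code.

# one target-site row in the canonical dialect
make_site <- function(gene = "G1", tx = "G1-tx1", mirna = "miR-x",
                      site_start = 1L, site_end = 22L,
                      seed_start = 15L, seed_end = 21L,
                      mirsvr = -0.5, phastcons = 0.9) {
  tibble::tibble(
    gene_id = gene, transcript_id = tx, mirna_id = mirna,
    site_start = as.integer(site_start), site_end = as.integer(site_end),
    seed_start = as.integer(seed_start), seed_end = as.integer(seed_end),
    mirsvr = mirsvr, phastcons = phastcons
  )
}

# a site whose seed match ends at `seed_end` (site footprint 22 nt)
site_at <- function(seed_end, mirna = "miR-x", gene = "G1", tx = "G1-tx1",
                    mirsvr = -0.5) {
  make_site(gene = gene, tx = tx, mirna = mirna,
            site_start = seed_end - 20L, site_end = seed_end + 1L,
            seed_start = seed_end - 6L, seed_end = seed_end,
            mirsvr = mirsvr)
}

random_strand <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# random 1-3 strand instance with total length in [lo, hi]
random_instance <- function(lo = 8, hi = 16) {
  total <- sample(lo:hi, 1)
  ns <- sample(1:min(3, total %/% 3), 1)
  lens <- rep(total %/% ns, ns)
  lens[1] <- total - sum(lens[-1])
  strands <- vapply(lens, random_strand, character(1))
  names(strands) <- paste0("s", seq_along(strands))
  strands
}

# build a complex_structure by hand from a dot-bracket string
structure_from_db <- function(strands, db, dg = -1) {
  pm <- dotbracket_to_pairs(db)
  triplexr:::new_complex_structure(strands, pm$pairs, dg)
}

# a minimal candidate row matching a hand-built window geometry
make_candidate <- function(window_seq, window_offset = 1L,
                           seed1_start, seed1_end, seed2_start, seed2_end,
                           mirna1_id = "mirA", mirna2_id = "mirB") {
  tibble::tibble(
    gene_id = "G1", transcript_id = "G1-tx1",
    mirna1_id = mirna1_id, mirna2_id = mirna2_id,
    seed1_start = as.integer(seed1_start), seed1_end = as.integer(seed1_end),
    seed2_start = as.integer(seed2_start), seed2_end = as.integer(seed2_end),
    window_seq = window_seq, window_offset = as.integer(window_offset)
  )
}

# kinetic model straight from free energies
model_from_dg <- function(d1, d2, t, config = triplexr::kinetic_config()) {
  triplexr::build_kinetic_model(
    list(dg_duplex1 = d1, dg_duplex2 = d2, dg_triplex = t), config = config)
}

RT_BODY <- 1.9872e-3 * 310.15
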