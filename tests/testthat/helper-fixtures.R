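`%||%` <- function(x, y) if (is.null(x)) y else x

# Construct a variety_panel directly from a genotype matrix, so tests can
# plant exact pool compositions without going through the simulator.
make_panel <- function(geno, trait = NULL, chromosome = "1H",
                       pos = NULL, causal = NULL, effect = NULL) {
  if (is.null(rownames(geno))) {
    rownames(geno) <- sprintf("v%03d", seq_len(nrow(geno)))
  }
  if (is.null(colnames(geno))) {
    colnames(geno) <- sprintf("m%04d", seq_len(ncol(geno)))
  }
  m <- ncol(geno)
  markers <- tibble::tibble(
    marker_id = colnames(geno),
    chromosome = rep_len(chromosome, m),
    pos = pos %||% seq(1e6, by = 1e6, length.out = m),
    founder_raf = colMeans(geno == 2, na.rm = TRUE),
    causal = causal %||% rep(FALSE, m),
    effect = effect %||% rep(0, m)
  )
  structure(
    list(
      phenotypes = tibble::tibble(
        variety_id = rownames(geno),
        trait = trait %||% seq_len(nrow(geno))
      ),
      genotypes = geno,
      markers = markers
    ),
    class = "variety_panel"
  )
}

# A minimal pooled-variant tibble with sensible defaults.
make_variants <- function(n = 1, chromosome = "1H", pos = seq_len(n) * 1e6,
                          qual = 60, ro_high = 120, ao_high = 30,
                          ro_low = 30, ao_low = 120) {
  tibble::tibble(
    chromosome = rep_len(chromosome, n),
    pos = pos,
    marker_id = sprintf("m%04d", seq_len(n)),
    ref = rep_len("A", n),
    alt = rep_len("G", n),
    qual = rep_len(qual, n),
    ro_high = rep_len(ro_high, n),
    ao_high = rep_len(ao_high, n),
    ro_low = rep_len(ro_low, n),
    ao_low = rep_len(ao_low, n)
  )
}

# Independent re-implementation of the greedy distance-constrained
# selection, used as a brute-force oracle against select_contrasting_sets.
greedy_oracle <- function(ids, trait, dmat, tail, set_size, min_distance,
                          forced = character()) {
  ord <- ids[order(trait, decreasing = (tail == "high"))]
  picked <- forced
  for (v in setdiff(ord, forced)) {
    if (length(picked) >= set_size) break
    ok <- TRUE
    for (w in picked) if (dmat[v, w] < min_distance) ok <- FALSE
    if (ok) picked <- c(picked, v)
  }
  picked
}

# Exhaustive-partition oracle for the QTL independence rule on one
# chromosome: enumerates every partition of the sorted passing markers
# into contiguous blocks, keeps those in which all within-block adjacent
# separations are below the applicable gap and all between-block boundary
# separations are at or above it, and requires exactly one such partition.
partition_oracle <- function(pos, cent, gap_c, gap_o) {
  k <- length(pos)
  gap_at <- function(p1, p2) {
    centromeric <- nrow(cent) > 0 && p1 <= cent$cent_end[1] && p2 >= cent$cent_start[1]
    if (centromeric) gap_c else gap_o
  }
  if (k == 1) return(list(seq_len(1)))
  seps <- vapply(seq_len(k - 1), function(i) {
    (pos[i + 1] - pos[i]) >= gap_at(pos[i], pos[i + 1])
  }, logical(1))
  valid <- list()
  for (mask in 0:(2^(k - 1) - 1)) {
    cuts <- as.logical(bitwAnd(mask, 2^(seq_len(k - 1) - 1)) > 0)
    if (all(cuts == seps)) {
      valid[[length(valid) + 1]] <- split(seq_len(k), cumsum(c(0, cuts)))
    }
  }
  stopifnot(length(valid) == 1)
  valid[[1]]
}
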