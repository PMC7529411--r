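# Independent brute-force oracles used to validate the vectorised
# implementations. These are deliberately naive (per-pixel loops, exhaustive
# enumeration) and share no code with the package internals.

# Per-pixel ring assignment: loop over every pixel of the image, assign those
# within `radius` of `center` to ring round(distance) (half up), clamped to
# floor(radius).
oracle_ring_profile <- function(px, center, radius) {
  nring <- floor(radius)
  ring_sum <- numeric(nring + 1)
  ring_count <- integer(nring + 1)
  for (i in seq_len(nrow(px))) {
    for (j in seq_len(ncol(px))) {
      d <- sqrt((i - center[1])^2 + (j - center[2])^2)
      if (d <= radius) {
        r <- min(floor(d + 0.5), nring)
        ring_sum[r + 1] <- ring_sum[r + 1] + px[i, j]
        ring_count[r + 1] <- ring_count[r + 1] + 1L
      }
    }
  }
  list(ring_sum = ring_sum, ring_count = ring_count)
}

# Exhaustive Mann-Whitney: enumerate every assignment of the pooled values
# into groups of sizes n1/n2; two-sided p = fraction of assignments whose U
# is at least as extreme (as far from n1*n2/2) as the observed U.
oracle_mann_whitney <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pool <- c(a, b)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) u_of(pool[idx], pool[-idx]))
  center <- n1 * n2 / 2
  p <- mean(abs(us - center) >= abs(u_obs - center) - 1e-12)
  list(U = u_obs, p.value = p)
}

# Brute-force centroid and covering radius of a logical mask.
oracle_center_radius <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  best <- 0
  for (k in seq_len(nrow(idx))) {
    d <- sqrt((idx[k, 1] - ctr[1])^2 + (idx[k, 2] - ctr[2])^2)
    if (d > best) best <- d
  }
  list(center = unname(ctr), radius_px = unname(best))
}

# A filled digital disk as a plain intensity matrix.
make_disk_image <- function(n, center, radius, value = 100, background = 0) {
  px <- matrix(background, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if ((i - center[1])^2 + (j - center[2])^2 <= radius^2) px[i, j] <- value
    }
  }
  px
}

# Codon-walking translation oracle for the frameshift tests: translate from
# position 1, stop at the first stop codon, independent of Biostrings.
oracle_translate <- function(cds) {
  codon_table <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
    CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
    TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
    GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
    AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
    CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  out <- character()
  for (s in seq(1, nchar(cds) - 2, by = 3)) {
    aa <- codon_table[[substr(cds, s, s + 2)]]
    if (aa == "*") return(list(protein = paste(out, collapse = ""), stop_found = TRUE))
    out <- c(out, aa)
  }
  list(protein = paste(out, collapse = ""), stop_found = FALSE)
}

# Small random binned-profile table for round-trip tests.
random_profile_table <- function(n_nuclei, group = "reference", prefix = "img") {
  rows <- do.call(rbind, lapply(seq_len(n_nuclei), function(k) {
    vals <- runif(20)
    vals <- vals / max(vals)
    vals[sample(20, sample(0:2, 1))] <- NA
    data.frame(image_id = sprintf("%s%02d", prefix, k), nucleus = 1L,
               group = group, x = seq(5, 100, 5), value = vals,
               stringsAsFactors = FALSE)
  }))
  profile_table(rows)
}
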