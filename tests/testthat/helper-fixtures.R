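# Shared fixture builders. Everything is generated in code; no data files.

# quick geno_table from a dosage matrix (rows = sites)
toy_table <- function(geno, depth = NULL, chrom = NULL, pos = NULL,
                      samples = NULL, monomorphic = NULL,
                      ref = "A", alt = "C", rad = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (is.null(depth)) depth <- matrix(30L, n, ncol(geno))
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(geno)))
  if (is.null(monomorphic)) monomorphic <- radpopgen:::empty_monomorphic()
  if (is.null(rad)) rad <- seq_len(n)
  geno_table(
    variants = data.frame(chrom = chrom, pos = pos,
                          ref = rep_len(ref, n), alt = rep_len(alt, n),
                          rad_locus_id = rad, stringsAsFactors = FALSE),
    geno = geno, depth = depth, samples = samples,
    monomorphic = monomorphic)
}

toy_popmap <- function(samples, pops) {
  data.frame(sample = samples, pop = pops, stringsAsFactors = FALSE)
}

# a one-deme constant-size model with given sampled diploids
one_deme_model <- function(N = 5000, n_diploids = 2, free = TRUE) {
  dem_model("1pop",
            demes = data.frame(name = "A", size = "N",
                               n_diploids = n_diploids),
            events = list(),
            bindings = data.frame(param = "N", value = N, lower = 100,
                                  upper = 1e6, free = free, scale = "log"))
}

# two demes splitting at time T, no migration
two_deme_model <- function(N1 = 5000, N2 = 5000, NA_ = 5000, T_ = 2000,
                           n1 = 2, n2 = 2) {
  dem_model("2pop",
            demes = data.frame(name = c("A", "B", "Anc"),
                               size = c("N1", "N2", "NANC"),
                               n_diploids = c(n1, n2, 0)),
            events = list(
              list(kind = "split", time = "T", child = "A", parent = "Anc"),
              list(kind = "split", time = "T", child = "B", parent = "Anc")),
            bindings = rbind(
              data.frame(param = c("N1", "N2", "NANC"),
                         value = c(N1, N2, NA_), lower = 100, upper = 1e6,
                         free = TRUE, scale = "log"),
              data.frame(param = "T", value = T_, lower = 1, upper = 2e4,
                         free = TRUE, scale = "log")))
}

# quartet model for D-statistic simulations: ((P1,P2),P3),Out with an
# optional pulse P3 -> P2
quartet_model <- function(pulse_a = 0, N = 4000, t12 = 800, t123 = 2500,
                          t_out = 8000, t_pulse = 200, n_dip = 5) {
  ev <- list(
    list(kind = "split", time = t12, child = "P1", parent = "A12"),
    list(kind = "split", time = t12, child = "P2", parent = "A12"),
    list(kind = "split", time = t123, child = "A12", parent = "A123"),
    list(kind = "split", time = t123, child = "P3", parent = "A123"),
    list(kind = "split", time = t_out, child = "A123", parent = "Root"),
    list(kind = "split", time = t_out, child = "Out", parent = "Root"))
  b <- data.frame(param = "NC", value = N, lower = 100, upper = 1e6,
                  free = FALSE, scale = "log")
  if (pulse_a > 0)
    ev <- c(ev, list(list(kind = "pulse", time = t_pulse, source = "P3",
                          target = "P2", a = pulse_a)))
  dem_model(if (pulse_a > 0) "quartet_pulse" else "quartet_null",
            demes = data.frame(
              name = c("P1", "P2", "P3", "Out", "A12", "A123", "Root"),
              size = N,
              n_diploids = c(n_dip, n_dip, n_dip, n_dip, 0, 0, 0)),
            events = ev, bindings = b)
}

# diploid genotype table from a haplotype simulation
table_from_sim <- function(sim, locus_spacing = 1e5, locus_length = 200,
                           n_chrom = 4) {
  ca <- sim$carriers
  n_hap <- sim$n_hap
  n_ind <- sum(n_hap) / 2
  dos <- ca[, 2 * seq_len(n_ind) - 1, drop = FALSE] +
    ca[, 2 * seq_len(n_ind), drop = FALSE]
  seg <- rowSums(dos) > 0 & rowSums(dos) < 2 * n_ind
  loci <- sim$locus
  chrom <- paste0("chr", 1 + (loci - 1) %% n_chrom)
  start <- 1 + ((loci - 1) %/% n_chrom) * locus_spacing
  off <- integer(length(loci))
  for (l in unique(loci)) {
    i <- which(loci == l)
    off[i] <- sample(locus_length, length(i))
  }
  pos <- start + off - 1
  seg <- seg & !duplicated(paste(chrom, pos))
  pops <- rep(names(n_hap), n_hap / 2)
  samples <- paste0(pops, "_", unlist(lapply(n_hap / 2, seq_len)))
  list(table = toy_table(matrix(as.integer(dos[seg, , drop = FALSE]),
                                sum(seg)),
                         chrom = chrom[seg], pos = pos[seg],
                         samples = samples, rad = loci[seg]),
       popmap = toy_popmap(samples, pops))
}
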