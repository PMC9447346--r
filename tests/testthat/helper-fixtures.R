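# Shared fixture builders: everything is generated in code at test time.

region_df <- function(chrom, start, end, ...) {
  data.frame(chrom = chrom, start = start, end = end, ...,
             stringsAsFactors = FALSE)
}

# probe set with unit-ish spacing on one or more chromosomes
toy_probes <- function(n, chrom = "chr1", spacing = 100L) {
  probe_set(sprintf("%s_p%04d", chrom, seq_len(n)), rep(chrom, n),
            seq_len(n) * spacing)
}

# beta matrix with a group-mean shift at `shift_rows`
toy_beta <- function(n_probes, n1, n2, shift_rows = integer(), delta = 0.4,
                     sd = 0.05, seed = 1) {
  set.seed(seed)
  base <- runif(n_probes, 0.2, 0.6)
  m <- base + matrix(rnorm(n_probes * (n1 + n2), sd = sd), n_probes)
  m[shift_rows, seq_len(n1)] <- m[shift_rows, seq_len(n1)] + delta
  m <- pmax(pmin(m, 1), 0)
  dimnames(m) <- list(sprintf("p%04d", seq_len(n_probes)),
                      sprintf("S%02d", seq_len(n1 + n2)))
  m
}

toy_sheet <- function(n1, n2) {
  data.frame(sample_id = sprintf("S%02d", seq_len(n1 + n2)),
             group = rep(c("g1", "g2"), c(n1, n2)), stringsAsFactors = FALSE)
}

# significance track with chosen p-values on a toy probe set
toy_track <- function(probes, p) {
  precomputed_track(probes, p)
}

# small end-to-end simulation, sized for fast unit tests
small_sim <- function(seed = 3, n_probes = 4000, n_per_group = 4,
                      per_class = 2) {
  simulate_methylation(
    backbone_config(n_probes = n_probes, n_samples = 2 * n_per_group + 4),
    sim_config(n_per_group = n_per_group, n_dmrs_per_class = per_class),
    seed = seed)
}

top_layer_calls <- function(fit) {
  l <- as.data.frame(fit)
  l$p <- l$log10_p_region     # ordering column for PR machinery
  l
}
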