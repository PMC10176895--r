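# Hand-built tiny count matrix: counts are (site x sample) matrices, missing
# cells NA in both.
tiny_matrix <- function(chrom = c("chr1", "chr1", "chr2"),
                        pos = c(100L, 250L, 100L),
                        M = rbind(c(5, 0), c(10, 17), c(50, 80)),
                        Tt = rbind(c(10, 20), c(20, 17), c(100, 100)),
                        samples = c("s1", "s2")) {
  methylome_matrix(chrom, pos, M, Tt, samples)
}

# random valid matrix under a fixed seed; cover holes + missing cells
random_matrix <- function(n_sites = 50, n_samples = 8, seed = 1,
                          missing_rate = 0.15) {
  set.seed(seed)
  chrom <- sort(sample(c("chr1", "chr2", "chr3"), n_sites, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n_sites), chrom), function(ii)
    sort(sample.int(1e5, length(ii)))), use.names = FALSE)
  Tt <- matrix(sample(1:600, n_sites * n_samples, TRUE), n_sites)
  M <- matrix(rbinom(n_sites * n_samples, as.vector(Tt), 0.4), n_sites)
  drop <- matrix(runif(n_sites * n_samples) < missing_rate, n_sites)
  M[drop] <- NA; Tt[drop] <- NA
  methylome_matrix(chrom, pos, M, Tt, sprintf("s%02d", seq_len(n_samples)))
}

# minimal two-group sample sheet
tiny_sheet <- function(n_control = 4, n_case = 4) {
  n <- n_control + n_case
  data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    group = rep(c("control", "case"), c(n_control, n_case)),
    subgroup = "none",
    sex = rep_len(c("M", "F"), n),
    complications = FALSE,
    stringsAsFactors = FALSE)
}

# small, fast simulation configuration used across tests
small_sim_config <- function(...) {
  args <- list(...)
  defaults <- list(n_control = 10L, n_case = 10L, n_cpgs = 2000L,
                   markers_per_type = 10L, missing_rate = 0.01,
                   seed = 42L)
  do.call(simulation_config, utils::modifyList(defaults, args))
}

no_icr_blocks <- function() {
  data.frame(name = character(), n_sites = integer(), shift = numeric(),
             scope = character(), stringsAsFactors = FALSE)
}
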