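# Shared small simulated fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (!exists(name, envir = .fixtures)) assign(name, maker(), .fixtures)
  get(name, envir = .fixtures)
}

small_cfg <- function(seed = 42, ...) {
  demography_config(n_per_subpop = 6, L = 200000,
                    sweep_interval = c(80000, 100000), seed = seed, ...)
}

# small sweep dataset at the default 2x coverage
small_sim <- function() fixture("small_sim", function() {
  cfg <- small_cfg()
  h <- apply_sweep_introgression(simulate_haplotypes(cfg), cfg)
  pile <- simulate_reads(h, 2, 0.001, seed = 99)
  list(cfg = cfg, h = h, pile = pile)
})

# same demography at high coverage, for calibration-style checks
deep_sim <- function() fixture("deep_sim", function() {
  cfg <- small_cfg(seed = 43)
  h <- apply_sweep_introgression(simulate_haplotypes(cfg), cfg)
  pile <- simulate_reads(h, 30, 0.001, seed = 77)
  list(cfg = cfg, h = h, pile = pile)
})

# a bare haplotype_set with fully specified contents, for read-model tests
manual_haps <- function(hapm, positions, L, n_per_subpop = 1) {
  labels <- data.frame(id = sprintf("ind_%02d", seq_len(nrow(hapm) / 2)),
                       subpop = "OrII", status = "wild", deme = "OrII",
                       stringsAsFactors = FALSE)
  structure(list(haplotypes = hapm, positions = as.integer(positions),
                 labels = labels, L = as.integer(L),
                 cfg = NULL), class = "haplotype_set")
}
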