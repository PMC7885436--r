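# Shared fixture builders. All data is generated in code at test time.

# Single-CpG cohort with the given truth values; returns the phenotype
# vector and validated sheet alongside the full simulation.
sim_one_cpg <- function(n_mz, n_dz, seed, n_waves = 1, ...) {
  tr <- cpg_truth("cg_test", ...)
  cfg <- simulation_config(n_mz, n_dz, tr, n_waves = n_waves, seed = seed)
  sim <- simulate_cohort(cfg)
  list(y = sim$dataset$values[1, ], sheet = validate_sample_sheet(sim$sheet),
       sim = sim)
}

# Minimal hand-built sample sheet: n pairs per zygosity, one wave,
# constant age/sex (so twin models reduce to intercept-only means).
flat_sheet <- function(n_mz, n_dz, wave = 1) {
  zyg <- c(rep("MZ", n_mz), rep("DZ", n_dz))
  pid <- sprintf("%s%03d", zyg, c(seq_len(n_mz), seq_len(n_dz)))
  data.frame(sample_id = sprintf("%s_%d_w%d", rep(pid, each = 2), 1:2, wave),
             pair_id = rep(pid, each = 2), member = rep(1:2, n_mz + n_dz),
             zygosity = rep(zyg, each = 2), wave = wave, age = 75, sex = 0,
             stringsAsFactors = FALSE)
}

# Phenotype vector aligned to a flat_sheet from per-pair duples.
y_from_pairs <- function(pairs_mz, pairs_dz, sheet) {
  y <- numeric(nrow(sheet))
  names(y) <- sheet$sample_id
  all_pairs <- rbind(pairs_mz, pairs_dz)
  pid <- unique(sheet$pair_id)
  for (i in seq_along(pid)) {
    y[sheet$sample_id[sheet$pair_id == pid[i] & sheet$member == 1]] <- all_pairs[i, 1]
    y[sheet$sample_id[sheet$pair_id == pid[i] & sheet$member == 2]] <- all_pairs[i, 2]
  }
  y
}
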