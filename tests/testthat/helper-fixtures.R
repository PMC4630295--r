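# Shared, lazily computed fixtures. The noiseless phantom states are the
# expensive part; they are deterministic, so compute once per session.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

single_vein_states <- function() {
  memo("sv_states", {
    spec <- phantom_single_vein()
    phantom_signal(spec$grid, spec$veins, parenchyma = spec$parenchyma,
                   background_phase = spec$background_phase)
  })
}

two_vein_states <- function() {
  memo("tv_states", {
    spec <- phantom_two_vein()
    phantom_signal(spec$grid, spec$veins, parenchyma = spec$parenchyma,
                   background_phase = spec$background_phase)
  })
}

# preprocessed z-scored phantom run for a given seed
single_vein_pre <- function(seed) {
  memo(paste0("sv_pre_", seed), {
    spec <- phantom_single_vein()
    preprocess_series(synthesize_phantom(
      spec$grid, spec$veins, spec$design, noise_sd = spec$noise_sd,
      seed = seed, states = single_vein_states(),
      background_phase = spec$background_phase
    ))
  })
}

two_vein_pre <- function(seed) {
  memo(paste0("tv_pre_", seed), {
    spec <- phantom_two_vein()
    preprocess_series(synthesize_phantom(
      spec$grid, spec$veins, spec$design, noise_sd = spec$noise_sd,
      seed = seed, parenchyma = spec$parenchyma, states = two_vein_states(),
      background_phase = spec$background_phase
    ))
  })
}

# realized-fSNR statistics of PR/sPR-suppressed single-voxel simulations
# over a set of seeds, one regime
regime_stats <- function(mag_fsnr, phase_fsnr, n_seeds, base_seed = 1000) {
  design <- block_design()
  res <- t(vapply(seq_len(n_seeds), function(s) {
    tc <- simulate_voxel(mag_fsnr, phase_fsnr, design, seed = base_seed + s)
    Sm <- zscore(tc$magnitude)
    Sp <- zscore(tc$phase)
    pr <- apply_pr(Sm, Sp, fit_pr_chisq(Sm, Sp))
    spr <- apply_spr(Sm, Sp, cor(Sm, Sp))
    c(mag = realized_fsnr(Sm, design),
      phase = realized_fsnr(Sp, design),
      pr = realized_fsnr(pr, design),
      spr = realized_fsnr(spr, design),
      r = sign(cor(Sm, Sp)))
  }, numeric(5)))
  tibble::as_tibble(res)
}
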