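# Shared heavyweight fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# The clean end-to-end study: 5 training and 5 test phantoms (512 x 512,
# master seed 0), models trained with pipeline defaults, TSP traces of the
# test images.
e2e_suite <- function() {
  memo("e2e", function() {
    train_seeds <- mammotrace:::derive_seeds(0, 5, stream = 1L)
    test_seeds <- mammotrace:::derive_seeds(0, 5, stream = 2L)
    make <- function(s) generate_phantom(phantom_config(seed = s))
    train_ph <- lapply(train_seeds, make)
    test_ph <- lapply(test_seeds, make)
    models <- train_boundary_model(train_ph, seed = 42)
    cfg <- trace_config()
    traces <- lapply(test_ph, function(p) {
      trace_boundary(p$image, models$texture, models$smoothness, cfg)
    })
    list(train = train_ph, test = test_ph, models = models, config = cfg,
         traces = traces)
  })
}

# The noisy ablation study: 20 test phantoms at 256 x 256 with the
# boundary-band noise doubled, a model trained on 5 phantoms of the same
# kind, and T / TS / TSP traces of every test image.
noisy_suite <- function() {
  memo("noisy", function() {
    noisy_cfg <- function(s) {
      cfg <- phantom_config(size = c(256L, 256L), seed = s)
      cfg$band_noise_std <- cfg$band_noise_std * 2
      cfg
    }
    train_seeds <- mammotrace:::derive_seeds(7, 5, stream = 1L)
    test_seeds <- mammotrace:::derive_seeds(7, 20, stream = 2L)
    train_ph <- lapply(train_seeds, function(s) generate_phantom(noisy_cfg(s)))
    test_ph <- lapply(test_seeds, function(s) generate_phantom(noisy_cfg(s)))
    models <- train_boundary_model(train_ph, seed = 43)
    cfg <- trace_config()
    report <- run_ablation(lapply(test_ph, `[[`, "image"),
                           lapply(test_ph, `[[`, "gt_boundary"),
                           models$texture, models$smoothness, cfg)
    list(test = test_ph, models = models, config = cfg, report = report)
  })
}

# A small trained model on tiny phantoms for cheap tracer tests.
small_suite <- function() {
  memo("small", function() {
    seeds <- mammotrace:::derive_seeds(3, 3, stream = 1L)
    phs <- lapply(seeds, function(s) {
      generate_phantom(phantom_config(size = c(160L, 160L), seed = s))
    })
    models <- train_boundary_model(phs, seed = 44)
    test_ph <- generate_phantom(phantom_config(size = c(160L, 160L),
                                               seed = 987654))
    list(train = phs, models = models, test = test_ph)
  })
}
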