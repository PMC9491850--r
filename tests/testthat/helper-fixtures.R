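# Shared fixtures, built once per test run.

# evaluate expr under a local RNG seed without touching the session RNG
with_fixed_rng <- function(seed, expr) semgforce:::with_seed(seed, expr)

# short default-task recording (8 s keeps two full rest/effort cycles)
fixture_recording <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_recording(synth_config(duration = 8,
                                                                  seed = 1))
    cache
  }
})

# tiny deterministic windowed feature set for training tests
fixture_feature_task <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rec <- generate_recording(synth_config(duration = 40, seed = 42))
      ws <- build_windows(rec, 200, 100)
      fw <- featurize(ws, feature_spec("MAV"))
      arr <- semgforce:::windows_array(fw)
      y <- semgforce:::windows_targets(fw)
      n <- dim(arr)[1]
      i_tr <- seq_len(round(0.6 * n))
      i_vl <- (round(0.6 * n) + 1):round(0.8 * n)
      i_te <- (round(0.8 * n) + 1):n
      cache <<- list(
        x_train = arr[i_tr, , , drop = FALSE], y_train = y[i_tr],
        x_val = arr[i_vl, , , drop = FALSE], y_val = y[i_vl],
        x_test = arr[i_te, , , drop = FALSE], y_test = y[i_te]
      )
    }
    cache
  }
})
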