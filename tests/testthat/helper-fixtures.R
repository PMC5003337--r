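# Shared fixtures: all synthetic, built in code at test time.

# Minimal stimulus set: 1 model, 1 repetition, no targets -> 4 trials.
tiny_design_cfg <- function(n_targets = 0L, n_reps = 1L) {
  stimulus_set_config(n_models_female = 1L, n_models_male = 0L,
                      n_repetitions = n_reps, n_target_trials = n_targets)
}

# Epochs with known content: ntrial x nchan x nsamp filled from `fill`.
make_epochs <- function(ntrial = 4L, nchan = 1L, nsamp = 500L, fs = 1000,
                        t0 = -100, fill = function(n) rnorm(n),
                        events = NULL) {
  dat <- array(fill(ntrial * nchan * nsamp), c(ntrial, nchan, nsamp))
  hemis <- rep(c("left", "right"), length.out = nchan)
  ieeg_epochs(dat, fs_hz = fs, t0_ms = t0,
              channels = data.frame(label = paste0("CH", seq_len(nchan)),
                                    hemisphere = hemis,
                                    stringsAsFactors = FALSE),
              events = events)
}

# Balanced observation table covering all 8 design cells.
full_cell_obs <- function(n_per_cell = 4L, n_participants = 1L) {
  obs <- expand.grid(
    rep = seq_len(n_per_cell),
    stimulus_type = c("eyes", "mosaic"),
    first_direction = c("averted", "straight"),
    hemisphere = c("left", "right"),
    participant = sprintf("S%02d", seq_len(n_participants)),
    stringsAsFactors = FALSE)
  obs$second_direction <- ifelse(obs$first_direction == "averted",
                                 "straight", "averted")
  obs$trial_id <- seq_len(nrow(obs))   # unpaired observations
  obs$rep <- NULL
  obs
}

# Minimal two-cell (eyes vs mosaic) design object on the tf_design contract,
# for closed-form comparisons against the classical two-sample t statistic.
two_cell_design <- function(cell_of, obs) {
  n <- length(cell_of)
  X <- matrix(0, n, 2L, dimnames = list(NULL, c("eyes", "mosaic")))
  X[cbind(seq_len(n), cell_of)] <- 1
  structure(list(X = X,
                 cells = data.frame(label = c("eyes", "mosaic"),
                                    stringsAsFactors = FALSE),
                 cell_of = cell_of, n_per_cell = tabulate(cell_of, 2L),
                 obs = obs, pair = rep(NA_integer_, n)),
            class = "tf_design")
}

# Wrap a plain matrix (time x obs) as an erp_stack for GLM-level tests.
as_erp_stack <- function(values, times_ms, obs) {
  structure(list(values = values, times_ms = times_ms,
                 baseline_ms = c(-200, 0), obs = obs),
            class = "erp_stack")
}

# Wrap an array (time x freq x obs) as a raw tf_stack.
as_tf_stack <- function(power, times_ms, freqs_hz, obs = NULL,
                        stage = "raw_power") {
  structure(list(power = power, times_ms = times_ms, freqs_hz = freqs_hz,
                 obs = obs, stage = stage), class = "tf_stack")
}
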