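#' Analysis constants
#'
#' Single definition of every numeric gate and protocol size used across the
#' pipeline, so stage code never hard-codes them. Values follow the published
#' analysis conventions for high-gamma speech encoding work: 100 Hz frame
#' rate, 60-sample (0.6 s) TRF lag window, Bonferroni-corrected P < 0.01
#' timepoint tests, 0.1 s responsiveness / 50 ms discrimination contiguity,
#' R^2 > 0.1 weight-profile gate, model R^2 > 0.05 and delta R^2 > 0.001
#' unique-variance gates, 300 circular-shift permutations, 90% PCA variance,
#' and 20-fold decoder cross-validation.
#'
#' @return Named list of constants.
#' @export
trf_constants <- function() {
  list(
    fs_hfa          = 100,    # Hz, analysis frame rate
    n_lags          = 60,     # TRF lags (0 .. 0.59 s)
    baseline_s      = 0.5,    # silent prestimulus baseline per sentence
    resp_window_s   = 0.5,    # onset/offset responsiveness windows
    resp_alpha      = 0.01,   # timepoint test threshold (Bonferroni-corrected)
    resp_run_s      = 0.1,    # contiguous significance for responsiveness
    disc_run_s      = 0.05,   # contiguous significance for boundary effects
    r2_gate_profile = 0.1,    # model R^2 gate for weight-profile analyses
    r2_gate_uv      = 0.05,   # model R^2 gate for unique-variance summaries
    duv_gate        = 0.001,  # delta R^2 gate for unique-variance summaries
    n_perms_uv      = 300,    # circular-shift permutations per electrode
    pca_var         = 0.90,   # cumulative variance retained by decoder PCA
    n_folds_decode  = 20,     # decoder cross-validation folds
    n_profile_shuffles = 10,  # weight-profile permutations per electrode
    acoustic_window_s  = 0.1, # half-width of mel window around a boundary
    neural_window_s    = c(-0.2, 0.4), # neural decoding window
    n_mel_bands     = 80
  )
}

# frame index (1-based) of a time in seconds at the analysis rate,
# floor convention: t in [k/fs, (k+1)/fs) -> frame k+1
time_to_frame <- function(t, fs = 100) as.integer(floor(t * fs + 1e-9)) + 1L

`%||%` <- function(a, b) if (is.null(a)) b else a
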