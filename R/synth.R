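#' Markov state model for simulated smFRET traces
#'
#' Defines the hidden conformational-state process used by the trace
#' simulator: a set of true FRET efficiencies, initial-state weights, and a
#' single per-frame probability of leaving the current state (the landing
#' state is uniform over the remaining states when there are more than two).
#'
#' @param state_efficiencies Numeric vector of true FRET efficiencies,
#'   strictly inside (0, 1).
#' @param state_weights Initial-state probabilities; must sum to 1. Defaults
#'   to uniform.
#' @param transition_probability Per-frame probability of leaving the current
#'   state, in \[0, 1\].
#' @param frame_period Frame period in seconds (default 0.2, i.e. 200 ms).
#' @return An object of class `sim_state_model`.
#' @examples
#' # the fast two-state control condition
#' sim_state_model(c(0.3, 0.7), transition_probability = 0.95)
#' @export
sim_state_model <- function(state_efficiencies,
                            state_weights = NULL,
                            transition_probability = 0,
                            frame_period = 0.2) {
  if (length(state_efficiencies) < 1) abort("at least one state is required")
  if (any(!is.finite(state_efficiencies)) ||
      any(state_efficiencies <= 0) || any(state_efficiencies >= 1)) {
    abort("`state_efficiencies` must lie strictly inside (0, 1)")
  }
  k <- length(state_efficiencies)
  if (is.null(state_weights)) state_weights <- rep(1 / k, k)
  if (length(state_weights) != k) abort("one weight per state is required")
  assert_prob(state_weights, "state_weights")
  if (abs(sum(state_weights) - 1) > 1e-9) abort("`state_weights` must sum to 1")
  assert_prob(transition_probability, "transition_probability")
  assert_pos(frame_period, "frame_period")
  structure(
    list(state_efficiencies = as.numeric(state_efficiencies),
         state_weights = as.numeric(state_weights),
         transition_probability = as.numeric(transition_probability),
         frame_period = as.numeric(frame_period)),
    class = "sim_state_model"
  )
}

#' Photophysics configuration for trace rendering
#'
#' Distortion and noise parameters applied when a hidden state path is turned
#' into three-channel ALEX intensities: relative Gaussian intensity noise,
#' donor leakage (alpha), direct acceptor excitation (delta),
#' detection/quantum-yield imbalance (gamma), excitation normalisation (beta),
#' and per-frame single-step photobleach probabilities.
#'
#' @param total_intensity Mean detected photon count per frame in the FRET
#'   channels (arbitrary units).
#' @param noise_fraction Relative Gaussian noise applied to each channel
#'   (default 0.08, i.e. 8%).
#' @param alpha,delta Donor-leakage and direct-excitation fractions (>= 0).
#' @param gamma,beta Detection-ratio and excitation-normalisation factors
#'   (> 0); identity values of 1 leave apparent quantities undistorted.
#' @param donor_bleach_rate,acceptor_bleach_rate Per-frame probabilities of
#'   irreversible single-step photobleaching.
#' @return An object of class `photophysics_config`.
#' @export
photophysics_config <- function(total_intensity = 1000,
                                noise_fraction = 0.08,
                                alpha = 0, delta = 0,
                                gamma = 1, beta = 1,
                                donor_bleach_rate = 0,
                                acceptor_bleach_rate = 0) {
  assert_pos(total_intensity, "total_intensity")
  assert_pos(noise_fraction, "noise_fraction", strict = FALSE)
  assert_pos(alpha, "alpha", strict = FALSE)
  assert_pos(delta, "delta", strict = FALSE)
  assert_pos(gamma, "gamma")
  assert_pos(beta, "beta")
  assert_prob(donor_bleach_rate, "donor_bleach_rate")
  assert_prob(acceptor_bleach_rate, "acceptor_bleach_rate")
  structure(
    list(total_intensity = total_intensity, noise_fraction = noise_fraction,
         alpha = alpha, delta = delta, gamma = gamma, beta = beta,
         donor_bleach_rate = donor_bleach_rate,
         acceptor_bleach_rate = acceptor_bleach_rate),
    class = "photophysics_config"
  )
}

#' Simulate a hidden conformational-state path
#'
#' Draws the initial state from the model weights, then at every subsequent
#' frame leaves the current state with the model's transition probability
#' (uniformly over the other states when K > 2).
#'
#' @param model A [sim_state_model()].
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed; all randomness in this call derives from it.
#' @return Integer vector of state indices (1-based), length `n_frames`.
#' @export
simulate_state_sequence <- function(model, n_frames, seed) {
  stopifnot(inherits(model, "sim_state_model"))
  n_frames <- assert_count(n_frames, "n_frames")
  k <- length(model$state_efficiencies)
  with_seed(seed, {
    s0 <- sample.int(k, 1, prob = model$state_weights)
    if (n_frames == 1 || k == 1) return(rep(s0, n_frames))
    # offset representation: a switch adds a uniform offset in 1..K-1 (mod K),
    # which is uniform over the other states whatever the current state is
    switch_on <- runif(n_frames - 1) < model$transition_probability
    d <- integer(n_frames - 1)
    d[switch_on] <- sample.int(k - 1, sum(switch_on), replace = TRUE)
    as.integer((s0 - 1 + cumsum(c(0L, d))) %% k + 1)
  })
}

#' Render a state path into a three-channel ALEX trace
#'
#' Converts a hidden state path into per-frame donor-excitation donor
#' (`I_DD`), donor-excitation acceptor (`I_DA`) and acceptor-excitation
#' acceptor (`I_AA`) intensities under the ALEX detection model
#' \deqn{I_{DD} = (1-E)\,I_{tot}/\gamma, \quad
#'       I_{DA} = E\,I_{tot} + \alpha I_{DD} + \delta I_{AA}, \quad
#'       I_{AA} = \beta\,I_{tot},}
#' each signal term multiplied by `1 + eps` with
#' `eps ~ Normal(0, noise_fraction)`. Photobleaching is single-step and
#' irreversible: after acceptor bleach the FRET and acceptor-excitation
#' signals drop to noise and the donor recovers to its zero-FRET level; after
#' donor bleach both donor-excitation channels drop to noise.
#'
#' @param path Integer state path from [simulate_state_sequence()], or `NULL`
#'   to simulate one internally (requires `model`).
#' @param model A [sim_state_model()] supplying state efficiencies.
#' @param phys A [photophysics_config()].
#' @param seed Integer seed.
#' @param trace_id Identifier stored in the output.
#' @param species `"dual"` for a donor+acceptor molecule, `"donor_only"` or
#'   `"acceptor_only"` for single-fluorophore calibration species.
#' @param condition Optional condition label stored in metadata.
#' @return A tibble with columns `trace_id`, `frame` (0-based), `I_DD`,
#'   `I_DA`, `I_AA`, plus ground-truth columns `state` and `E_true`. Per-trace
#'   metadata (frame period, species, true bleach frames) is attached as the
#'   `"meta"` attribute, see [trace_meta()].
#' @export
render_alex_trace <- function(path, model, phys = photophysics_config(),
                              seed = 1, trace_id = "trace_1",
                              species = c("dual", "donor_only", "acceptor_only"),
                              condition = NA_character_) {
  stopifnot(inherits(model, "sim_state_model"),
            inherits(phys, "photophysics_config"))
  species <- match.arg(species)
  if (is.null(path)) path <- simulate_state_sequence(model, 200, seed)
  if (length(path) == 0) abort("`path` must be non-empty")
  n <- length(path)
  e_true <- model$state_efficiencies[path]

  with_seed(seed + 1L, {
    itot <- phys$total_intensity
    nf <- phys$noise_fraction
    eps <- function() rnorm(n, 0, nf)          # one relative-noise draw per channel
    noise_only <- function() rnorm(n, 0, nf * itot)

    # geometric single-step bleach times (0-based frame of first dark frame)
    draw_bleach <- function(rate) {
      if (rate <= 0) return(NA_integer_)
      b <- stats::rgeom(1, rate)               # frames survived before bleaching
      if (b >= n) NA_integer_ else as.integer(b)
    }
    don_b <- if (species != "acceptor_only") draw_bleach(phys$donor_bleach_rate) else NA_integer_
    acc_b <- if (species == "dual" || species == "acceptor_only")
      draw_bleach(phys$acceptor_bleach_rate) else NA_integer_

    has_donor <- species != "acceptor_only"
    has_acceptor <- species != "donor_only"

    frame <- seq_len(n) - 1L
    donor_alive <- has_donor & (is.na(don_b) | frame < don_b)
    acceptor_alive <- has_acceptor & (is.na(acc_b) | frame < acc_b)

    # effective FRET efficiency: zero without a live acceptor
    e_eff <- ifelse(acceptor_alive & donor_alive, e_true, 0)

    i_aa <- ifelse(acceptor_alive, phys$beta * itot * (1 + eps()), noise_only())
    i_dd <- ifelse(donor_alive,
                   (1 - e_eff) * itot / phys$gamma * (1 + eps()),
                   noise_only())
    fret <- ifelse(donor_alive & acceptor_alive, e_eff * itot * (1 + eps()), 0)
    i_da <- fret +
      ifelse(donor_alive, phys$alpha * i_dd, 0) +
      ifelse(acceptor_alive, phys$delta * i_aa, 0) +
      ifelse(donor_alive, 0, noise_only())

    out <- tibble(trace_id = trace_id, frame = frame,
                  I_DD = i_dd, I_DA = i_da, I_AA = i_aa,
                  state = as.integer(path), E_true = e_true)
    meta <- tibble(trace_id = trace_id, frame_period = model$frame_period,
                   condition = condition, species = species,
                   donor_bleach_frame = don_b, acceptor_bleach_frame = acc_b)
    set_trace_meta(out, meta)
  })
}

#' Simulate a set of ALEX traces
#'
#' Convenience wrapper drawing `n_traces` independent state paths and
#' rendering each with [render_alex_trace()].
#'
#' @inheritParams render_alex_trace
#' @param n_traces Number of traces.
#' @param n_frames Frames per trace.
#' @param id_prefix Prefix for generated trace ids.
#' @return A trace tibble covering all traces, with combined metadata.
#' @export
simulate_traces <- function(model, n_traces, n_frames,
                            phys = photophysics_config(), seed = 1,
                            species = "dual", id_prefix = "tr",
                            condition = NA_character_) {
  n_traces <- assert_count(n_traces, "n_traces")
  parts <- purrr::map(seq_len(n_traces), function(i) {
    s <- seed * 10000L + i
    path <- simulate_state_sequence(model, n_frames, s)
    render_alex_trace(path, model, phys, seed = s,
                      trace_id = sprintf("%s%04d", id_prefix, i),
                      species = species, condition = condition)
  })
  meta <- bind_rows(purrr::map(parts, trace_meta))
  set_trace_meta(bind_rows(parts), meta)
}

#' Bin a trace by averaging consecutive frames
#'
#' Each output frame is the mean of `frames_per_bin` consecutive input frames
#' in every channel; a trailing partial bin is dropped and the frame period is
#' multiplied by the bin size. Used to emulate coarser temporal resolution.
#'
#' @param traces A trace tibble (one or several traces).
#' @param frames_per_bin Integer >= 1.
#' @return The binned trace tibble.
#' @export
bin_intensities <- function(traces, frames_per_bin) {
  assert_traces(traces)
  frames_per_bin <- assert_count(frames_per_bin, "frames_per_bin")
  meta <- trace_meta(traces)
  num_cols <- intersect(c("I_DD", "I_DA", "I_AA", "E_true"), names(traces))
  parts <- purrr::map(split_traces(traces), function(tr) {
    nf <- nrow(tr)
    if (frames_per_bin > nf) {
      abort(sprintf("frames_per_bin (%d) exceeds trace length (%d) for %s",
                    frames_per_bin, nf, tr$trace_id[1]))
    }
    n_out <- nf %/% frames_per_bin
    idx <- rep(seq_len(n_out), each = frames_per_bin)
    tr <- tr[seq_len(n_out * frames_per_bin), ]
    out <- tibble(trace_id = tr$trace_id[1], frame = seq_len(n_out) - 1L)
    for (cl in num_cols) {
      out[[cl]] <- as.numeric(tapply(tr[[cl]], idx, mean))
    }
    out
  })
  out <- bind_rows(parts)
  if (!is.null(meta) && "frame_period" %in% names(meta)) {
    meta$frame_period <- meta$frame_period * frames_per_bin
  }
  set_trace_meta(out, meta)
}

#' Expected number of state transitions per bin
#'
#' For a per-frame switching probability `p_trans`, averaging `frames_per_bin`
#' frames into one bin hides on average `p_trans * frames_per_bin` transitions
#' inside every bin — 0.95 to 95 across the standard bin ladder
#' 1/5/10/20/50/100 at `p_trans = 0.95`.
#'
#' @param p_trans Per-frame transition probability.
#' @param frames_per_bin Bin size in frames.
#' @return Expected transitions per bin (numeric).
#' @export
expected_transitions_per_bin <- function(p_trans, frames_per_bin) {
  assert_prob(p_trans, "p_trans")
  assert_pos(frames_per_bin, "frames_per_bin")
  p_trans * frames_per_bin
}

#' Configuration for the fast-switching binning control
#'
#' The control condition: fast two-state switching (default per-frame
#' transition probability 0.95 between E = 0.3 and E = 0.7), 8% intensity
#' noise, binned at 1/5/10/20/50/100 frames per bin and cut to 200 frames
#' after binning with no bleaching.
#'
#' @param bin_sizes Integer bin ladder.
#' @param trace_length_after_binning Frames kept after binning.
#' @param n_traces Traces per bin size.
#' @param model State model; defaults to the two-state fast-switching control.
#' @param noise_fraction Relative intensity noise.
#' @param total_intensity Mean photons/frame.
#' @return An object of class `control_config`.
#' @export
control_config <- function(bin_sizes = c(1L, 5L, 10L, 20L, 50L, 100L),
                           trace_length_after_binning = 200L,
                           n_traces = 100L,
                           model = sim_state_model(c(0.3, 0.7),
                                                   transition_probability = 0.95),
                           noise_fraction = 0.08,
                           total_intensity = 1000) {
  if (any(bin_sizes < 1) || any(bin_sizes != round(bin_sizes))) {
    abort("`bin_sizes` must be integers >= 1")
  }
  trace_length_after_binning <- assert_count(trace_length_after_binning,
                                             "trace_length_after_binning")
  n_traces <- assert_count(n_traces, "n_traces")
  stopifnot(inherits(model, "sim_state_model"))
  assert_pos(noise_fraction, "noise_fraction", strict = FALSE)
  structure(
    list(bin_sizes = as.integer(bin_sizes),
         trace_length_after_binning = trace_length_after_binning,
         n_traces = n_traces, model = model,
         noise_fraction = noise_fraction, total_intensity = total_intensity),
    class = "control_config"
  )
}

#' Simulate the binning-control trace sets
#'
#' For every bin size, simulates `n_traces` bleach-free traces long enough
#' that after binning exactly `trace_length_after_binning` frames remain.
#' The relative Gaussian intensity noise models the measurement uncertainty
#' of the emulated recording, so it is applied to the binned intensities —
#' each bin size stands for an acquisition at that temporal resolution. (With
#' noise injected before binning instead, averaging would shrink the noise
#' and the hidden-state fluctuations at the same rate and the donor/acceptor
#' anti-correlation would never wash out, unlike the measured behaviour this
#' control reproduces.)
#'
#' @param config A [control_config()].
#' @param seed Integer seed.
#' @return A trace tibble with an extra `bin_size` column; metadata carries
#'   the per-bin frame period.
#' @export
simulate_control_traces <- function(config = control_config(), seed = 1) {
  stopifnot(inherits(config, "control_config"))
  phys <- photophysics_config(total_intensity = config$total_intensity,
                              noise_fraction = 0)
  parts <- purrr::map(seq_along(config$bin_sizes), function(bi) {
    b <- config$bin_sizes[bi]
    raw_len <- b * config$trace_length_after_binning
    traces <- simulate_traces(config$model, config$n_traces, raw_len,
                              phys = phys, seed = seed * 100L + bi,
                              id_prefix = sprintf("bin%03d_tr", b))
    binned <- bin_intensities(traces, b)
    if (config$noise_fraction > 0) {
      binned <- with_seed(seed * 100L + bi + 7919L, {
        n <- nrow(binned)
        for (cl in c("I_DD", "I_DA", "I_AA")) {
          binned[[cl]] <- binned[[cl]] * (1 + rnorm(n, 0, config$noise_fraction))
        }
        binned
      })
    }
    binned$bin_size <- b
    meta <- trace_meta(binned)
    meta$bin_size <- b
    set_trace_meta(binned, meta)
  })
  meta <- bind_rows(purrr::map(parts, trace_meta))
  set_trace_meta(bind_rows(parts), meta)
}

#' Native-condition five-state efficiency mixture
#'
#' The ligand-free conformational equilibrium of nanodisc-reconstituted
#' SbPOR2b: five states S1-S5 with inter-dye distances 76, 64, 57, 48 and
#' 44 Å (converted to efficiencies with the Cy3/Cy5 Förster radius) and
#' occupancies 17/25/16/27/14% (renormalised to sum to one).
#'
#' @param sigma Common state width in efficiency units (default 0.04).
#' @param r0 Förster radius in Å (default 56).
#' @return A list with `means`, `sigmas`, `weights`, `distances`.
#' @export
por_native_mixture <- function(sigma = 0.04, r0 = 56) {
  d <- c(76, 64, 57, 48, 44)
  w <- c(0.17, 0.25, 0.16, 0.27, 0.14)   # reported occupancies sum to 99%
  list(means = distance_to_efficiency(d, forster_calibration(r0)),
       sigmas = rep(sigma, 5),
       weights = w / sum(w),
       distances = d)
}

#' Rifampicin-condition five-state efficiency mixture
#'
#' Same state centres as [por_native_mixture()] but with the equilibrium
#' shifted towards the most extended state: S1 at 33%, S4 at 19%, S5 at 11%
#' (S2/S3 at 25%/12% completing the simplex).
#'
#' @inheritParams por_native_mixture
#' @return A list with `means`, `sigmas`, `weights`, `distances`.
#' @export
por_rifampicin_mixture <- function(sigma = 0.04, r0 = 56) {
  m <- por_native_mixture(sigma, r0)
  m$weights <- c(0.33, 0.25, 0.12, 0.19, 0.11)
  m
}

#' Sample efficiencies from a Gaussian mixture
#'
#' Draws component labels by weight, then values from the component normals.
#' Labels are retained so downstream state-inference can be checked against
#' ground truth.
#'
#' @param mixture A list with `means`, `sigmas`, `weights` (e.g.
#'   [por_native_mixture()]) or a fitted [fit_gmm()] object.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return A tibble with columns `component` (integer) and `e`.
#' @export
sample_mixture <- function(mixture, n, seed = 1) {
  if (inherits(mixture, "gmm_fit")) {
    mixture <- list(means = mixture$means, sigmas = mixture$sigmas,
                    weights = mixture$weights)
  }
  k <- length(mixture$means)
  stopifnot(length(mixture$sigmas) == k, length(mixture$weights) == k)
  if (abs(sum(mixture$weights) - 1) > 1e-9) abort("mixture weights must sum to 1")
  if (any(mixture$sigmas < 0)) abort("mixture sigmas must be >= 0")
  n <- assert_count(n, "n")
  with_seed(seed, {
    comp <- sample.int(k, n, replace = TRUE, prob = mixture$weights)
    tibble(component = as.integer(comp),
           e = rnorm(n, mixture$means[comp], mixture$sigmas[comp]))
  })
}

#' Configuration for synthetic dose-response tables
#'
#' Parameters of the four-parameter Hill model
#' `f(x) = A + (B - A) / (1 + (ic50/x)^n)` plus sampling noise, used to
#' generate replicate activity measurements in percent of control.
#'
#' @param A Baseline response at zero ligand (% of control).
#' @param B Plateau response at saturating ligand (% of control).
#' @param ic50 Half-effect concentration in uM (> 0).
#' @param hill_n Hill coefficient (>= 0).
#' @param concentrations Concentrations in uM.
#' @param noise_sd Gaussian replicate noise SD (% of control).
#' @param replicates Replicates per concentration (>= 1).
#' @return An object of class `dose_response_config`.
#' @export
dose_response_config <- function(A = 100, B = 156, ic50 = 21, hill_n = 1,
                                 concentrations = 10^seq(0, 2, length.out = 8),
                                 noise_sd = 5, replicates = 3) {
  assert_pos(ic50, "ic50")
  assert_pos(hill_n, "hill_n", strict = FALSE)
  assert_pos(concentrations, "concentrations")
  assert_pos(noise_sd, "noise_sd", strict = FALSE)
  replicates <- assert_count(replicates, "replicates")
  structure(
    list(A = A, B = B, ic50 = ic50, hill_n = hill_n,
         concentrations = as.numeric(concentrations),
         noise_sd = noise_sd, replicates = replicates),
    class = "dose_response_config"
  )
}

#' Simulate a replicate dose-response table
#'
#' Evaluates the Hill curve at each configured concentration and adds
#' independent Gaussian replicate noise.
#'
#' @param config A [dose_response_config()].
#' @param seed Integer seed.
#' @param ligand,acceptor Optional labels stored in the table.
#' @return A tibble with columns `ligand`, `acceptor`, `concentration_uM`,
#'   `replicate`, `response_pct`.
#' @export
simulate_dose_response <- function(config = dose_response_config(), seed = 1,
                                   ligand = "ligand", acceptor = "Cytc") {
  stopifnot(inherits(config, "dose_response_config"))
  with_seed(seed, {
    grid <- tidyr::expand_grid(concentration_uM = config$concentrations,
                               replicate = seq_len(config$replicates))
    f <- hill_response(grid$concentration_uM, config$A, config$B,
                       config$ic50, config$hill_n)
    tibble(ligand = ligand, acceptor = acceptor,
           concentration_uM = grid$concentration_uM,
           replicate = grid$replicate,
           response_pct = f + rnorm(nrow(grid), 0, config$noise_sd))
  })
}
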