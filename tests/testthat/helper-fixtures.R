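# Shared fixtures: small optical/camera setups and an independent oracle
# for joint cumulants computed from raw moments over all set partitions.

test_optics <- function() optical_config(600, 1.49, pixel_size = 105)
test_camera <- function(...) camera_config(...)

# noiseless camera: expectation only
quiet_camera <- function() {
  camera_config(quantum_efficiency = 0.9, em_gain = 100, read_noise_sd = 0,
                dark_current = 0, excess_noise_factor = 1)
}

# a single always-on emitter at `pos` (nm) rendered over a few frames
steady_emitter <- function(pos, i_on = 400, n_frames = 1, fov_px = 17) {
  kin <- photokinetics(activation_rate = 0, k_off = 0, k_on = 0,
                       bleach_rate = 0, i_on = i_on, p_preactivated = 1)
  es <- emitter_set(matrix(pos, 1, 2))
  es$traces <- simulate_traces(1, kin, n_frames)
  attr(es, "fov") <- fov_px * 105
  es
}

# all set partitions of the integer vector els (list of lists of blocks)
all_partitions <- function(els) {
  if (length(els) == 0) return(list(list()))
  out <- list()
  first <- els[1]
  rest <- els[-1]
  nr <- length(rest)
  subs <- lapply(0:(2^nr - 1), function(mask)
    rest[bitwAnd(mask, 2^(seq_len(nr) - 1)) > 0])
  for (s in subs) {
    blk <- c(first, s)
    for (p in all_partitions(setdiff(rest, s))) {
      out[[length(out) + 1]] <- c(list(blk), p)
    }
  }
  out
}

# joint cumulant of n trace vectors from the definition via raw moments:
# kappa = sum over partitions of (-1)^(m-1) (m-1)! prod_blocks E[prod x_i]
oracle_joint_cumulant <- function(traces) {
  n <- length(traces)
  total <- 0
  for (p in all_partitions(seq_len(n))) {
    term <- (-1)^(length(p) - 1) * factorial(length(p) - 1)
    for (blk in p) {
      pr <- rep(1, length(traces[[1]]))
      for (i in blk) pr <- pr * traces[[i]]
      term <- term * mean(pr)
    }
    total <- total + term
  }
  total
}

# strip cumulant_image attributes for value comparisons
as_plain <- function(m) {
  matrix(as.numeric(m), nrow(m), ncol(m))
}
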