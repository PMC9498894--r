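#' Build a sharp position weight matrix from a consensus string
#'
#' A convenience constructor for simulation motifs: at each position the
#' consensus base receives probability `dominant` and the remaining mass is
#' split over the other three bases in proportion to the background, so the
#' matrix has no zero entries and a well-defined log-likelihood ratio.
#'
#' @param consensus DNA string over A,C,G,T.
#' @param dominant probability of the consensus base, in (0.25, 1).
#' @param background a [background_distribution()].
#' @param name motif label.
#' @return a [motif()].
#' @export
consensus_motif <- function(consensus, dominant = 0.85,
                            background = background_distribution(),
                            name = consensus) {
  codes <- encode_codes(consensus)[1L, ]
  if (any(codes == 0L)) mc_stop("consensus may not contain N", "motifconv_input_error")
  if (!is_scalar_num(dominant) || dominant <= 0.25 || dominant >= 1) {
    mc_stop("dominant must be in (0.25, 1)", "motifconv_input_error")
  }
  b <- as_background(background)$probs
  probs <- t(vapply(codes, function(cd) {
    p <- b / sum(b[-cd]) * (1 - dominant)
    p[cd] <- dominant
    p
  }, numeric(4)))
  motif(probs, name = name)
}

# exact multinomial kernel with probs as given (softmax(1 * log p) = p)
kernel_from_motif <- function(m) {
  probs <- if (inherits(m, "motif")) m$probs else m
  if (any(probs <= 0)) {
    mc_stop("kernel probabilities must be strictly positive", "motifconv_input_error")
  }
  multinomial_transform(raw_convolution(log(probs)), alpha = 1)
}

#' Specification of a synthetic MPRA-style dataset
#'
#' Describes the generative world emulated by [simulate_mpra()]: fixed-length
#' sequences drawn i.i.d. per base from the background composition, with
#' motif instances planted at random non-overlapping positions on random
#' strands, and activity generated as a noisy linear function of each
#' motif's best (max over strands and positions) log-likelihood-ratio
#' score. Defaults mirror the scale of the real liver-enhancer study at
#' desk size: 2,000 sequences of length 150 with one planted activator
#' (weight +1) and one planted repressor (weight -1).
#'
#' @param n_sequences number of sequences.
#' @param seq_length sequence length in bases (>= longest planted motif).
#' @param background a [background_distribution()].
#' @param planted_motifs list of `list(motif = , weight = )` entries;
#'   motif probabilities must be strictly positive.
#' @param noise_sd Gaussian noise standard deviation added to the
#'   activities; `NULL` (default) uses 0.25 times the standard deviation of
#'   the noiseless activities.
#' @param plant_probability per-motif, per-sequence probability of planting
#'   an instance, in `[0, 1]`.
#' @param intercept baseline activity.
#' @param seed integer seed; the same seed reproduces the dataset exactly
#'   (and the same sequences regardless of `noise_sd`, which is drawn last).
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_sequences = 2000L,
                            seq_length = 150L,
                            background = background_distribution(),
                            planted_motifs = list(
                              list(motif = consensus_motif("TGACTCAGCAAT", name = "activator"),
                                   weight = 1),
                              list(motif = consensus_motif("GTCCAAAGGTCA", name = "repressor"),
                                   weight = -1)),
                            noise_sd = NULL,
                            plant_probability = 0.5,
                            intercept = 0,
                            seed = 1L) {
  if (!is_count(n_sequences)) mc_stop("n_sequences must be a count", "motifconv_spec_error")
  if (!is_count(seq_length)) mc_stop("seq_length must be a count", "motifconv_spec_error")
  background <- as_background(background)
  if (!is.list(planted_motifs)) mc_stop("planted_motifs must be a list", "motifconv_spec_error")
  for (pm in planted_motifs) {
    if (!inherits(pm$motif, "motif") || !is_scalar_num(pm$weight)) {
      mc_stop("each planted_motifs entry needs a motif and a weight", "motifconv_spec_error")
    }
    if (pm$motif$length > seq_length) {
      mc_stop(sprintf("motif '%s' is longer than seq_length", pm$motif$name),
              "motifconv_spec_error")
    }
    if (any(pm$motif$probs <= 0)) {
      mc_stop("planted motifs must have strictly positive probabilities",
              "motifconv_spec_error")
    }
  }
  if (!is.null(noise_sd) && (!is_scalar_num(noise_sd) || noise_sd < 0)) {
    mc_stop("noise_sd must be >= 0 or NULL", "motifconv_spec_error")
  }
  if (!is_scalar_num(plant_probability) || plant_probability < 0 || plant_probability > 1) {
    mc_stop("plant_probability must be in [0, 1]", "motifconv_spec_error")
  }
  structure(list(n_sequences = as.integer(n_sequences),
                 seq_length = as.integer(seq_length),
                 background = background, planted_motifs = planted_motifs,
                 noise_sd = noise_sd, plant_probability = plant_probability,
                 intercept = intercept, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Generate a synthetic MPRA-style dataset
#'
#' Draws sequences from the background, plants motif instances (sites
#' sampled from each motif's distribution, uniform random non-overlapping
#' positions, random strand), computes the noiseless activity
#' `intercept + sum_m weight_m * max-LLR_m(sequence)` with the package's
#' own scanning machinery, and finally adds Gaussian noise. With
#' `noise_sd = 0` the activities are an exact deterministic function of the
#' sequences, recomputable by [scan_llr()].
#'
#' @param spec a [simulation_spec()].
#' @return a list with `data` (an [mpra_dataset()]) and `truth`: the
#'   planted motifs and weights, a `plants` data frame (id, motif, 0-based
#'   position, strand), the noiseless activities and the noise sd used.
#' @export
simulate_mpra <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  n <- spec$n_sequences
  N <- spec$seq_length
  bg <- spec$background$probs
  codes <- matrix(sample.int(4L, n * N, replace = TRUE, prob = bg), n, N)

  plants <- list()
  for (s in seq_len(n)) {
    occupied <- rep(FALSE, N)
    for (pm in spec$planted_motifs) {
      if (stats::runif(1) > spec$plant_probability) next
      L <- pm$motif$length
      site <- vapply(seq_len(L), function(i) {
        sample.int(4L, 1L, prob = pm$motif$probs[i, ])
      }, 0L)
      minus <- stats::runif(1) < 0.5
      if (minus) site <- rev(5L - site)
      placed <- FALSE
      for (try in seq_len(100L)) {
        pos <- sample.int(N - L + 1L, 1L)
        span <- pos:(pos + L - 1L)
        if (!any(occupied[span])) {
          codes[s, span] <- site
          occupied[span] <- TRUE
          plants[[length(plants) + 1L]] <- data.frame(
            id = paste0("seq_", s), motif = pm$motif$name,
            position = pos - 1L, strand = if (minus) "-" else "+")
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        mc_stop("could not place a motif without overlap after 100 tries",
                "motifconv_placement_error")
      }
    }
  }

  # noiseless activity from best LLR per motif (both strands)
  signal <- rep(spec$intercept, n)
  for (pm in spec$planted_motifs) {
    k <- kernel_from_motif(pm$motif)
    signal <- signal + pm$weight * best_llr_scores(k, codes, spec$background)$score
  }
  noise_sd <- spec$noise_sd
  if (is.null(noise_sd)) noise_sd <- 0.25 * stats::sd(signal)
  activities <- signal + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0

  data <- mpra_dataset(codes_to_strings(codes), activities)
  plants_df <- if (length(plants)) do.call(rbind, plants) else
    data.frame(id = character(), motif = character(),
               position = integer(), strand = character())
  list(data = data,
       truth = list(motifs = lapply(spec$planted_motifs, `[[`, "motif"),
                    weights = vapply(spec$planted_motifs, `[[`, 0, "weight"),
                    intercept = spec$intercept, plants = plants_df,
                    noiseless_activities = signal, noise_sd = noise_sd,
                    spec = spec))
}

# best (max over both strands and all positions) LLR of one kernel across a
# code matrix; returns score, 0-based position and strand per sequence
best_llr_scores <- function(kernel, codes, background = background_distribution()) {
  L <- kernel$length
  n <- nrow(codes)
  nw <- ncol(codes) - L + 1L
  lr <- kernel_log_ratio(kernel, background)
  Wf <- as.vector(t(lr))                        # flat (i-1)*4+j order
  Z <- im2col_onehot(codes, L)
  s1 <- matrix(Z %*% Wf, nw, n)                 # window-minor rows
  s2 <- matrix(Z %*% Wf[rc_flat_perm(L)], nw, n)
  i1 <- max.col(t(s1), ties.method = "first")
  i2 <- max.col(t(s2), ties.method = "first")
  v1 <- s1[cbind(i1, seq_len(n))]
  v2 <- s2[cbind(i2, seq_len(n))]
  minus <- v2 > v1
  list(score = pmax(v1, v2),
       position = ifelse(minus, i2, i1) - 1L,
       strand = ifelse(minus, "-", "+"))
}

#' Score learned motifs against the planted ground truth
#'
#' For every true motif, finds the best-matching learned motif over all
#' sliding alignments and both strand orientations, scored by the Pearson
#' correlation of the flattened overlapping probability sub-matrices, and
#' reports whether the matched filter's dense-weight sign agrees with the
#' true regression weight's sign.
#'
#' @param truth the `truth` component of [simulate_mpra()] (or a list with
#'   `motifs` and `weights`).
#' @param learned_motifs list of learned [motif()] objects.
#' @param learned_weights optional numeric vector of dense weights; by
#'   default taken from the motifs' `dense_weight` fields.
#' @param min_overlap smallest alignment overlap considered.
#' @return a data frame with one row per true motif: `true_motif`,
#'   `true_weight`, `best_learned`, `correlation`, `offset`, `orientation`,
#'   `learned_weight`, `sign_match`.
#' @export
recovery_report <- function(truth, learned_motifs, learned_weights = NULL,
                            min_overlap = 5L) {
  true_motifs <- truth$motifs
  true_weights <- truth$weights
  if (length(true_motifs) < 1L || length(learned_motifs) < 1L) {
    mc_stop("need at least one true and one learned motif", "motifconv_data_error")
  }
  if (is.null(learned_weights)) {
    learned_weights <- vapply(learned_motifs, function(m) m$dense_weight %||% NA_real_, 0)
  }
  rows <- lapply(seq_along(true_motifs), function(ti) {
    tm <- true_motifs[[ti]]
    best <- list(cor = -Inf, learned = NA_integer_, offset = NA_integer_,
                 orientation = NA_character_)
    for (li in seq_along(learned_motifs)) {
      lm <- learned_motifs[[li]]
      for (ori in c("+", "-")) {
        lp <- if (ori == "+") lm$probs else rc_motif_probs(lm$probs)
        al <- best_alignment_cor(tm$probs, lp, min_overlap)
        if (is.finite(al$cor) && al$cor > best$cor) {
          best <- list(cor = al$cor, learned = li, offset = al$offset, orientation = ori)
        }
      }
    }
    if (!is.finite(best$cor)) {
      # every alignment was degenerate (zero-variance submatrices)
      return(data.frame(true_motif = tm$name, true_weight = true_weights[ti],
                        best_learned = NA_character_, correlation = NA_real_,
                        offset = NA_integer_, orientation = NA_character_,
                        learned_weight = NA_real_, sign_match = FALSE))
    }
    lw <- learned_weights[best$learned]
    data.frame(true_motif = tm$name, true_weight = true_weights[ti],
               best_learned = learned_motifs[[best$learned]]$name,
               correlation = best$cor, offset = best$offset,
               orientation = best$orientation, learned_weight = lw,
               sign_match = !is.na(lw) && sign(lw) == sign(true_weights[ti]))
  })
  do.call(rbind, rows)
}

# max Pearson correlation of flattened overlapping sub-matrices over all
# offsets of b relative to a (offset = start of b minus start of a)
best_alignment_cor <- function(a, b, min_overlap) {
  la <- nrow(a); lb <- nrow(b)
  mo <- min(min_overlap, la, lb)
  best <- list(cor = -Inf, offset = NA_integer_)
  for (off in (-(lb - mo)):(la - mo)) {
    sa <- max(1L, 1L + off); ea <- min(la, lb + off)
    if (ea - sa + 1L < mo) next
    va <- as.vector(a[sa:ea, , drop = FALSE])
    vb <- as.vector(b[(sa - off):(ea - off), , drop = FALSE])
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) next
    r <- stats::cor(va, vb)
    if (r > best$cor) best <- list(cor = r, offset = off)
  }
  best
}
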