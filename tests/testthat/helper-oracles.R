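# Independent scalar oracles and small fixture builders. These deliberately
# avoid the package's vectorized code paths: softmax by the bare formula,
# likelihoods as products over positions, windows by string enumeration.

oracle_softmax_row <- function(x, alpha) {
  e <- exp(alpha * x)
  e / sum(e)
}

# LLR of a window string under a probability matrix, as log of a product of
# per-position likelihood ratios
oracle_llr <- function(probs, window, bg = c(0.295, 0.205, 0.205, 0.295)) {
  idx <- match(strsplit(window, "")[[1]], c("A", "C", "G", "T"))
  log(prod(probs[cbind(seq_along(idx), idx)] / bg[idx]))
}

# all 4^L DNA strings of length L
all_kmers <- function(L) {
  grid <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), L))
  apply(grid, 1L, paste, collapse = "")
}

random_dna <- function(n, len, bg = c(0.295, 0.205, 0.205, 0.295)) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = bg), collapse = "")
  }, "")
}

random_motif_probs <- function(L) {
  m <- matrix(stats::runif(4 * L, 0.05, 1), L, 4)
  m / rowSums(m)
}

random_kernel <- function(L, alpha = 1) {
  multinomial_transform(raw_convolution(matrix(stats::rnorm(4 * L), L, 4)), alpha)
}

# kernel whose probability rows equal the background exactly
background_kernel <- function(L, bg = background_distribution(), alpha = 1) {
  w <- matrix(rep(log(bg$probs) / alpha, each = L), L, 4)
  multinomial_transform(raw_convolution(w), alpha)
}

# a fast throwaway training configuration; ... overrides the tiny defaults
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_filters = 2L, filter_length = 6L, max_epochs = 3L,
         batch_size = 16L, dropout_rate = 0, seed = 1L),
    list(...))
  do.call(model_config, args)
}

# small simulated dataset for pipeline tests
tiny_sim <- function(n = 80L, len = 40L, seed = 5L, ...) {
  simulate_mpra(simulation_spec(
    n_sequences = n, seq_length = len, seed = seed,
    planted_motifs = list(
      list(motif = consensus_motif("TGACTC", name = "act6"), weight = 1),
      list(motif = consensus_motif("GGGCAT", name = "rep6"), weight = -1)),
    ...))
}
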