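# Shared fixtures, built in code.

# a session with Gaussian responses and an optional shift of the relevant
# item on every measure (in the measure's expected direction)
random_session <- function(n_items = 5, n_reps = 5,
                           measures = cit_default_directions(),
                           relevant = 1, shift = 0, seed = NULL,
                           session_id = "test") {
  gen <- function() {
    responses <- lapply(seq_along(measures), function(k) {
      m <- matrix(rnorm(n_items * n_reps), n_items, n_reps)
      m[relevant, ] <- m[relevant, ] + measures[[k]] * shift
      m
    })
    names(responses) <- names(measures)
    cit_session(responses, relevant = relevant, directions = measures,
                session_id = session_id)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# independent brute-force oracle for the per-measure exhaustive
# randomization p: enumerates every subset by explicit loops over cell
# index vectors, recomputes each mean difference from scratch, and counts
# at-least-as-extreme differences directly
brute_force_exhaustive_p <- function(mat, relevant, direction) {
  n_items <- nrow(mat)
  n_reps <- ncol(mat)
  v <- as.vector(mat)
  n_cells <- length(v)
  rel_cells <- relevant + n_items * (seq_len(n_reps) - 1)
  real <- mean(v[rel_cells]) - mean(v[setdiff(seq_len(n_cells), rel_cells)])
  subsets <- utils::combn(n_cells, n_reps, simplify = FALSE)
  count <- 0L
  for (s in subsets) {
    g <- mean(v[s]) - mean(v[setdiff(seq_len(n_cells), s)])
    if (direction * g >= direction * real) count <- count + 1L
  }
  count / length(subsets)
}

# direct concordant-pair counting oracle for the AUC (ties count 1/2)
brute_force_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  pos <- scores[truth]
  neg <- scores[!truth]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}
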