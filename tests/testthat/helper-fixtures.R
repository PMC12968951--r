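# Shared fixtures and independent oracles ------------------------------------

# Worked 5-species x 4-trap incidence fixture used throughout:
# row sums (4, 2, 1, 1, 1), hence T = 4, S_obs = 5, U = 9, Q1 = 3, Q2 = 1.
m1_incidence <- function() {
  m <- rbind(sp1 = c(1, 1, 1, 1),
             sp2 = c(1, 1, 0, 0),
             sp3 = c(1, 0, 0, 0),
             sp4 = c(0, 1, 0, 0),
             sp5 = c(0, 0, 1, 0))
  colnames(m) <- paste0("t", 1:4)
  m
}

# small well-formed study tables for the data model tests
tiny_traps <- function() {
  data.frame(trap_id = c("t1", "t2", "t3"),
             landscape_id = c("L1", "L1", "L2"),
             tree_cover_250m = c(60, 30, 90),
             barrier_free_angle = c(80, 40, 95),
             stringsAsFactors = FALSE)
}

tiny_captures <- function() {
  data.frame(trap_id = c("t1", "t1", "t2"),
             species_id = c("sp1", "sp1", "sp2"),
             count = c(2, 3, 1),
             origin = c("native", "native", "non_native"),
             guild = c("bark", "bark", "ambrosia"),
             stringsAsFactors = FALSE)
}

# random binary incidence matrix with no all-zero species rows
random_incidence <- function(n_species, n_traps, p = 0.35) {
  repeat {
    m <- matrix(rbinom(n_species * n_traps, 1, p), nrow = n_species,
                dimnames = list(paste0("sp", seq_len(n_species)),
                                paste0("t", seq_len(n_traps))))
    if (all(rowSums(m) > 0)) return(m)
  }
}

# Exhaustive oracle: mean richness over all C(T, t) trap subsets.
enumerated_rarefied_richness <- function(incidence, t) {
  subs <- utils::combn(ncol(incidence), t)
  mean(apply(subs, 2, function(cols) {
    sum(rowSums(incidence[, cols, drop = FALSE]) > 0)
  }))
}

# Exhaustive oracle: mean % species loss at each k over all T! removal
# permutations (retained set = last k of the sequence; equivalent to mean
# over all subsets of size k).
enumerated_mean_loss <- function(incidence, k) {
  100 * (1 - enumerated_rarefied_richness(incidence, k) / nrow(incidence))
}

# all permutations of a (short) vector, as a list
.permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in .permutations_of(x[-i])) out[[length(out) + 1]] <- c(x[i], p)
  }
  out
}

# trap table whose per-trap richness decreases strictly with urbanization:
# used for the scenario-bracketing property
graded_fixture <- function(n_traps = 6) {
  traps <- data.frame(trap_id = sprintf("t%02d", seq_len(n_traps)),
                      landscape_id = "L1",
                      tree_cover_250m = seq(90, 10, length.out = n_traps),
                      barrier_free_angle = seq(90, 10, length.out = n_traps),
                      stringsAsFactors = FALSE)
  traps <- add_urbanization_index(traps)
  # trap j holds species sp1..sp(n_traps + 1 - j): nested, richer where less urban
  inc <- matrix(0L, nrow = n_traps, ncol = n_traps,
                dimnames = list(sprintf("sp%02d", seq_len(n_traps)),
                                traps$trap_id))
  for (j in seq_len(n_traps)) inc[seq_len(n_traps + 1 - j), j] <- 1L
  list(traps = traps, incidence = inc)
}
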