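# Incidence-based diversity estimation --------------------------------------
#
# All estimators work from the sufficient statistics of a binary species x
# trap (sampling-unit) matrix: T sampling units, per-species incidence
# frequencies Y_i (number of traps where species i was detected), U = sum(Y),
# and the counts of uniques Q1 (Y = 1) and duplicates Q2 (Y = 2).

#' Incidence frequency statistics
#'
#' Reduces a binary species-by-trap matrix to the sufficient statistics used
#' by all incidence-based estimators: the number of sampling units `T`,
#' observed richness `S_obs`, the incidence-frequency vector `Y` (one entry
#' per species, each in 1..T), their total `U`, and the number of uniques
#' `Q1` and duplicates `Q2`.
#'
#' @param incidence binary species-by-trap matrix (species in rows); all-zero
#'   species rows must have been removed at construction time (see
#'   [build_matrices()]).
#' @return an object of class `incidence_freq` with fields `T`, `S_obs`,
#'   `Y`, `U`, `Q1`, `Q2`.
#' @examples
#' m <- rbind(sp1 = c(1, 1, 1, 1), sp2 = c(1, 1, 0, 0),
#'            sp3 = c(1, 0, 0, 0), sp4 = c(0, 1, 0, 0), sp5 = c(0, 0, 1, 0))
#' incidence_freq(m)
#' @export
incidence_freq <- function(incidence) {
  incidence <- as.matrix(incidence)
  if (ncol(incidence) < 1L) stop("matrix has zero traps", call. = FALSE)
  if (!all(incidence %in% c(0, 1))) {
    stop("incidence matrix must be binary", call. = FALSE)
  }
  Y <- as.integer(rowSums(incidence))
  if (any(Y == 0L)) {
    stop("all-zero species rows must be dropped before computing frequencies",
         call. = FALSE)
  }
  structure(list(T = ncol(incidence), S_obs = nrow(incidence), Y = Y,
                 U = sum(Y), Q1 = sum(Y == 1L), Q2 = sum(Y == 2L)),
            class = "incidence_freq")
}

#' @export
print.incidence_freq <- function(x, ...) {
  cat(sprintf("Incidence frequencies: T = %d traps, S_obs = %d, U = %d, Q1 = %d, Q2 = %d\n",
              x$T, x$S_obs, x$U, x$Q1, x$Q2))
  invisible(x)
}

.as_freq <- function(x) {
  if (inherits(x, "incidence_freq")) return(x)
  if (is.matrix(x)) return(incidence_freq(x))
  stop("expected an incidence matrix or incidence_freq object", call. = FALSE)
}

#' Chao2 estimator of total species richness
#'
#' Nonparametric lower bound on the species richness of the assemblage
#' sampled by T incidence sampling units, with the (T-1)/T small-sample
#' correction in both branches:
#' \deqn{\hat S = S_{obs} + \frac{T-1}{T}\frac{Q_1^2}{2 Q_2}} when Q2 > 0,
#' and the bias-corrected form
#' \eqn{S_{obs} + \frac{T-1}{T} Q_1 (Q_1 - 1) / 2} when Q2 = 0.
#'
#' @param x an incidence matrix or [incidence_freq()] object.
#' @return the estimated richness (>= S_obs).
#' @export
chao2 <- function(x) {
  f <- .as_freq(x)
  if (f$T < 2L) stop("Chao2 is undefined for a single sampling unit",
                     call. = FALSE)
  k <- (f$T - 1) / f$T
  if (f$Q2 > 0L) {
    f$S_obs + k * f$Q1^2 / (2 * f$Q2)
  } else {
    f$S_obs + k * f$Q1 * (f$Q1 - 1) / 2
  }
}

#' Sample completeness (order q = 0)
#'
#' The proportion of the estimated total species richness that was observed:
#' `S_obs / chao2`. 1 when there are no uniques (no unseen richness is
#' inferred).
#'
#' @inheritParams chao2
#' @return a fraction in (0, 1\].
#' @export
sample_completeness <- function(x) {
  f <- .as_freq(x)
  f$S_obs / chao2(f)
}

# Coverage slope factor A-hat shared by the observed and extrapolated
# coverage estimators; the Q2 = 0 fallback substitutes (Q1 - 1).
.coverage_A <- function(f) {
  if (f$Q2 > 0L) {
    (f$T - 1) * f$Q1 / ((f$T - 1) * f$Q1 + 2 * f$Q2)
  } else if (f$Q1 > 0L) {
    (f$T - 1) * (f$Q1 - 1) / ((f$T - 1) * (f$Q1 - 1) + 2)
  } else {
    0
  }
}

#' Sample coverage of the observed incidence sample (order q = 1)
#'
#' The estimated probability that a new sampling unit (an additional trap)
#' contains only species already detected:
#' \eqn{\hat C = 1 - (Q_1/U)\,\hat A}, with
#' \eqn{\hat A = (T-1)Q_1 / ((T-1)Q_1 + 2Q_2)} when Q2 > 0 and the (Q1 - 1)
#' substitution when Q2 = 0. Coverage is 1 when there are no uniques.
#'
#' @inheritParams chao2
#' @return coverage in \[0, 1\].
#' @export
coverage_observed <- function(x) {
  f <- .as_freq(x)
  if (f$U < 1L) stop("no incidences: coverage undefined", call. = FALSE)
  if (f$T < 2L) stop("coverage requires at least 2 sampling units",
                     call. = FALSE)
  if (f$Q1 == 0L) return(1)
  1 - (f$Q1 / f$U) * .coverage_A(f)
}

# ratio C(n, t) / C(m, t) in log space; 0 when n < t
.choose_ratio <- function(n, t, m) {
  ifelse(n >= t, exp(lchoose(n, t) - lchoose(m, t)), 0)
}

#' Rarefied sample coverage at t < T sampling units
#'
#' The expected coverage of a random subsample of `t` of the `T` traps:
#' \deqn{\hat C(t) = 1 - \sum_i \frac{Y_i}{U}\binom{T-Y_i}{t}\Big/\binom{T-1}{t}}
#' with binomial coefficients zero when the upper index is smaller than `t`.
#' At t = T - 1 this reduces exactly to 1 - Q1/U.
#'
#' @inheritParams chao2
#' @param t number of sampling units, 1 <= t < T.
#' @return coverage in \[0, 1\].
#' @export
coverage_rarefied <- function(x, t) {
  f <- .as_freq(x)
  if (f$U < 1L) stop("no incidences: coverage undefined", call. = FALSE)
  if (length(t) != 1L || t < 1L || t >= f$T) {
    stop("t must satisfy 1 <= t < T", call. = FALSE)
  }
  1 - sum((f$Y / f$U) * .choose_ratio(f$T - f$Y, t, f$T - 1))
}

#' Extrapolated sample coverage beyond T sampling units
#'
#' Projects coverage to `T + t_star` sampling units via the coverage slope
#' factor: \eqn{\hat C(T + t^*) = 1 - (Q_1/U)\,\hat A^{t^*+1}}. At
#' `t_star = 0` it equals [coverage_observed()]; as `t_star` grows it
#' approaches 1 monotonically.
#'
#' @inheritParams chao2
#' @param t_star number of additional sampling units beyond T (>= 0).
#' @return coverage in \[0, 1\].
#' @export
coverage_extrapolated <- function(x, t_star) {
  f <- .as_freq(x)
  if (f$U < 1L) stop("no incidences: coverage undefined", call. = FALSE)
  if (length(t_star) != 1L || t_star < 0L) {
    stop("t_star must be >= 0", call. = FALSE)
  }
  if (f$Q1 == 0L) return(1)
  1 - (f$Q1 / f$U) * .coverage_A(f)^(t_star + 1)
}

#' Coverage profile by rarefaction and extrapolation
#'
#' Stitches the rarefied (t < T), observed (t = T) and extrapolated (t > T)
#' coverage estimates into one profile over a grid of sampling-unit counts.
#'
#' @inheritParams chao2
#' @param t_grid integer vector of sampling-unit counts (default 1..2T, the
#'   doubling range conventional for incidence extrapolation).
#' @return a data.frame with columns `t`, `coverage`, `method`
#'   (`rarefied`/`observed`/`extrapolated`).
#' @export
coverage_profile <- function(x, t_grid = NULL) {
  f <- .as_freq(x)
  if (is.null(t_grid)) t_grid <- seq_len(2L * f$T)
  t_grid <- as.integer(t_grid)
  cov <- vapply(t_grid, function(t) {
    if (t < f$T) coverage_rarefied(f, t)
    else if (t == f$T) coverage_observed(f)
    else coverage_extrapolated(f, t - f$T)
  }, numeric(1))
  method <- ifelse(t_grid < f$T, "rarefied",
                   ifelse(t_grid == f$T, "observed", "extrapolated"))
  data.frame(t = t_grid, coverage = cov, method = method,
             stringsAsFactors = FALSE)
}

#' Expected richness of a rarefied incidence sample
#'
#' The expected number of species detected in a uniformly random subset of
#' `t` of the `T` sampling units:
#' \deqn{S(t) = \sum_i \left[1 - \binom{T-Y_i}{t}\Big/\binom{T}{t}\right].}
#' At t = T it equals S_obs; at t = 1 it equals the mean per-trap richness
#' U/T. This is also the analytic expectation of retained richness under
#' random trap removal.
#'
#' @inheritParams chao2
#' @param t number of sampling units, 1 <= t <= T.
#' @return expected richness (real).
#' @export
rarefied_richness <- function(x, t) {
  f <- .as_freq(x)
  if (length(t) != 1L || t < 1L || t > f$T) {
    stop("t must satisfy 1 <= t <= T", call. = FALSE)
  }
  sum(1 - .choose_ratio(f$T - f$Y, t, f$T))
}

# Beta diversity: replacement (turnover) component ---------------------------

#' Pairwise replacement component of beta diversity
#'
#' For two traps with `a` shared species and `b`, `c` species unique to each,
#' the replacement (spatial turnover) component is
#' \eqn{\beta_{repl} = 2\min(b, c)/(a + b + c)} — twice the number of species
#' in one trap replaced by different species in the other, over the pooled
#' richness (Jaccard-family denominator). It is 0 when one trap's species are
#' nested in the other's and insensitive to pure richness differences.
#'
#' @param set_a,set_b character vectors of species present in each trap.
#' @return a list with `a`, `b`, `c` and `beta_repl`.
#' @export
pairwise_replacement <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  cc <- length(setdiff(set_b, set_a))
  if (a + b + cc == 0L) {
    stop("both species sets empty: replacement undefined", call. = FALSE)
  }
  list(a = a, b = b, c = cc, beta_repl = 2 * min(b, cc) / (a + b + cc))
}

#' Mean within-landscape species turnover
#'
#' Averages the pairwise replacement component over all unordered trap pairs
#' of one landscape's incidence matrix. Pairs in which both traps are empty
#' have an undefined ratio and are excluded from the mean; their count is
#' reported.
#'
#' @param incidence binary species-by-trap matrix for one landscape.
#' @return a list with `mean_turnover`, `n_pairs` (used) and
#'   `n_empty_pairs` (skipped).
#' @export
mean_turnover <- function(incidence) {
  incidence <- as.matrix(incidence)
  Tn <- ncol(incidence)
  if (Tn < 2L) stop("turnover requires at least 2 traps", call. = FALSE)
  sets <- lapply(seq_len(Tn), function(j) rownames(incidence)[incidence[, j] == 1])
  vals <- c()
  skipped <- 0L
  for (i in seq_len(Tn - 1L)) {
    for (j in seq.int(i + 1L, Tn)) {
      if (length(sets[[i]]) + length(sets[[j]]) == 0L) {
        skipped <- skipped + 1L
      } else {
        vals <- c(vals, pairwise_replacement(sets[[i]], sets[[j]])$beta_repl)
      }
    }
  }
  list(mean_turnover = if (length(vals)) mean(vals) else NA_real_,
       n_pairs = length(vals), n_empty_pairs = skipped)
}

#' Per-landscape diversity summary table
#'
#' Runs the full incidence-based battery for each landscape: observed and
#' Chao2 richness, sample completeness, observed coverage, coverage at a grid
#' of trap numbers (rarefied/extrapolated as needed) and mean turnover.
#'
#' @param traps trap table.
#' @param captures capture table.
#' @param coverage_t integer grid of trap numbers for standardized coverage
#'   (default `c(4, 8, 16, 32)`).
#' @return a data.frame with one row per landscape.
#' @export
diversity_table <- function(traps, captures, coverage_t = c(4, 8, 16, 32)) {
  traps <- validate_trap_table(traps)
  ids <- unique(traps$landscape_id)
  rows <- lapply(ids, function(lid) {
    m <- build_matrices(traps, captures, lid)
    f <- incidence_freq(m$incidence)
    covs <- vapply(coverage_t, function(t) {
      if (t < f$T) coverage_rarefied(f, t)
      else if (t == f$T) coverage_observed(f)
      else coverage_extrapolated(f, t - f$T)
    }, numeric(1))
    names(covs) <- paste0("coverage_t", coverage_t)
    tv <- mean_turnover(m$incidence)
    cbind(data.frame(landscape_id = lid, n_traps = f$T, S_obs = f$S_obs,
                     chao2 = chao2(f),
                     completeness = sample_completeness(f),
                     coverage_observed = coverage_observed(f),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(covs)),
          data.frame(mean_turnover = tv$mean_turnover))
  })
  do.call(rbind, rows)
}
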