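# Sampling-effort reduction by sequential trap removal -----------------------
#
# A removal scenario orders the traps of a landscape for sequential removal;
# reducing effort to k traps keeps the last k traps of the removal sequence.
# The outcome is percent species loss, 100 * (1 - S_retained / S_total),
# which normalizes out richness differences among landscapes.

.REMOVAL_POLICIES <- c("random", "most_urbanized_first", "least_urbanized_first")

#' Deterministic trap-removal order under an urbanization policy
#'
#' `most_urbanized_first` removes traps in descending order of the
#' urbanization index; `least_urbanized_first` in ascending order. Ties are
#' broken by lexicographic trap id, so ordered policies are fully
#' deterministic given the covariates.
#'
#' @param traps trap table for one landscape; must carry an
#'   `urbanization_index` column (see [add_urbanization_index()]).
#' @param policy `"most_urbanized_first"` or `"least_urbanized_first"`.
#' @return character vector of trap ids in removal order.
#' @export
removal_order <- function(traps, policy = c("most_urbanized_first",
                                            "least_urbanized_first")) {
  policy <- match.arg(policy)
  if (!"urbanization_index" %in% names(traps) ||
      anyNA(traps$urbanization_index)) {
    stop("traps must carry a complete urbanization_index", call. = FALSE)
  }
  idx <- traps$urbanization_index
  ord <- order(if (policy == "most_urbanized_first") -idx else idx,
               traps$trap_id, method = "radix")
  traps$trap_id[ord]
}

#' Species-loss curve along one removal sequence
#'
#' For each retained-trap count k from T down to 1, the retained set is the
#' last k traps of the removal sequence; the loss is the percentage of the
#' landscape's total species pool absent from the retained traps.
#'
#' @param incidence binary species-by-trap matrix.
#' @param sequence character vector: a permutation of the matrix's trap ids,
#'   in removal order.
#' @return a data.frame with columns `k` (retained traps, 1..T) and
#'   `loss_pct`.
#' @export
species_loss <- function(incidence, sequence) {
  incidence <- as.matrix(incidence)
  if (!setequal(sequence, colnames(incidence)) ||
      length(sequence) != ncol(incidence)) {
    stop("sequence must be a permutation of the matrix's trap ids",
         call. = FALSE)
  }
  Tn <- ncol(incidence)
  S_total <- nrow(incidence)
  loss <- vapply(seq_len(Tn), function(k) {
    retained <- sequence[seq.int(Tn - k + 1L, Tn)]
    S_ret <- sum(rowSums(incidence[, retained, drop = FALSE]) > 0)
    100 * (1 - S_ret / S_total)
  }, numeric(1))
  data.frame(k = seq_len(Tn), loss_pct = loss)
}

#' Mean species-loss curve under random trap removal
#'
#' Draws `n_randomizations` uniformly random full removal permutations
#' (sampling traps without replacement, i.e. one trap removed per step) and
#' averages the percent species loss at each retained-trap count k. Its
#' expectation has the closed form `100 * (1 - S(k)/S_obs)` with S(k) the
#' rarefied richness ([rarefied_richness()]).
#'
#' @param incidence binary species-by-trap matrix.
#' @param n_randomizations number of random permutations (study default 100).
#' @param seed integer seed; required for reproducibility.
#' @return a data.frame with columns `k`, `mean_loss_pct`, `sd_loss_pct`.
#' @export
random_mean_loss <- function(incidence, n_randomizations = 100, seed) {
  if (missing(seed)) stop("seed is required for the random policy",
                          call. = FALSE)
  if (n_randomizations < 1L) stop("n_randomizations must be >= 1",
                                  call. = FALSE)
  incidence <- as.matrix(incidence)
  ids <- colnames(incidence)
  rng <- .seeded_rng(seed)
  losses <- vapply(seq_len(n_randomizations), function(i) {
    species_loss(incidence, rng$shuffle(ids))$loss_pct
  }, numeric(ncol(incidence)))
  data.frame(k = seq_len(ncol(incidence)),
             mean_loss_pct = rowMeans(losses),
             sd_loss_pct = apply(losses, 1, stats::sd))
}

# local RNG so simulations never disturb the caller's .Random.seed
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    s
  })
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(shuffle = function(x) with_state(function() sample(x)),
       run = with_state)
}

#' Scenario table: mean loss per landscape, policy and retained-trap count
#'
#' @param traps trap table with `urbanization_index` for all landscapes.
#' @param captures capture table.
#' @param k_values retained-trap counts to report (default `c(8, 4)`, i.e.
#'   50% and 75% effort reduction from 16 traps).
#' @param policies subset of
#'   `c("random", "most_urbanized_first", "least_urbanized_first")`.
#' @param n_randomizations randomizations for the random policy.
#' @param seed integer seed for the random policy.
#' @return a data.frame with one row per (landscape, policy, k):
#'   `landscape_id`, `policy`, `k`, `mean_loss_pct`, `sd_loss_pct`,
#'   `n_randomizations`, `feasible` (FALSE when k exceeds the landscape's
#'   trap count; such rows are flagged, not dropped).
#' @export
scenario_table <- function(traps, captures, k_values = c(8, 4),
                           policies = .REMOVAL_POLICIES,
                           n_randomizations = 100, seed) {
  policies <- match.arg(policies, .REMOVAL_POLICIES, several.ok = TRUE)
  traps <- validate_trap_table(traps)
  ids <- unique(traps$landscape_id)
  rows <- list()
  for (lid in ids) {
    tr <- traps[traps$landscape_id == lid, , drop = FALSE]
    inc <- build_matrices(traps, captures, lid)$incidence
    curves <- list()
    for (pol in policies) {
      if (pol == "random") {
        curves[[pol]] <- random_mean_loss(inc, n_randomizations,
                                          seed = seed + match(lid, ids))
      } else {
        sl <- species_loss(inc, removal_order(tr, pol))
        curves[[pol]] <- data.frame(k = sl$k, mean_loss_pct = sl$loss_pct,
                                    sd_loss_pct = 0)
      }
    }
    for (pol in policies) for (k in k_values) {
      feasible <- k <= ncol(inc)
      cv <- curves[[pol]]
      rows[[length(rows) + 1L]] <- data.frame(
        landscape_id = lid, policy = pol, k = k,
        mean_loss_pct = if (feasible) cv$mean_loss_pct[cv$k == k] else NA_real_,
        sd_loss_pct = if (feasible) cv$sd_loss_pct[cv$k == k] else NA_real_,
        n_randomizations = if (pol == "random") n_randomizations else 1L,
        feasible = feasible, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Compare removal policies at one retained-trap count
#'
#' Landscape-paired comparison of mean percent species loss among policies:
#' an overall likelihood-ratio chi-square from a fixed-block linear model
#' (`loss ~ policy + landscape`) against the no-policy null, plus all
#' pairwise paired t-tests (raw p-values, no multiplicity correction).
#'
#' @param table a [scenario_table()] result.
#' @param k the retained-trap count to compare at.
#' @return a list with `chisq`, `df`, `p_value`, and a data.frame
#'   `contrasts` (policy pair, mean difference, t, p).
#' @export
compare_scenarios <- function(table, k) {
  tab <- table[table$k == k & table$feasible, , drop = FALSE]
  pols <- unique(tab$policy)
  if (length(pols) < 2L) stop("need at least 2 policies", call. = FALSE)
  if (length(unique(tab$landscape_id)) < 2L) {
    stop("need at least 2 landscapes", call. = FALSE)
  }
  tab$policy <- factor(tab$policy)
  tab$landscape_id <- factor(tab$landscape_id)
  full <- stats::lm(mean_loss_pct ~ policy + landscape_id, data = tab)
  null <- stats::lm(mean_loss_pct ~ landscape_id, data = tab)
  n <- nrow(tab)
  rss_full <- sum(stats::resid(full)^2)
  rss_null <- sum(stats::resid(null)^2)
  # guard against log-of-rounding-noise when both models fit (near) perfectly
  eps <- 1e-10 * (sum((tab$mean_loss_pct - mean(tab$mean_loss_pct))^2) + 1e-12)
  chisq <- if (rss_null - rss_full <= eps) 0 else
    as.numeric(n * (log(rss_null) - log(max(rss_full, eps))))
  df <- length(pols) - 1L
  pairs <- utils::combn(as.character(sort(unique(tab$policy))), 2)
  contrasts <- lapply(seq_len(ncol(pairs)), function(ci) {
    pr <- pairs[, ci]
    x <- tab$mean_loss_pct[tab$policy == pr[1]][
      order(tab$landscape_id[tab$policy == pr[1]])]
    y <- tab$mean_loss_pct[tab$policy == pr[2]][
      order(tab$landscape_id[tab$policy == pr[2]])]
    d <- x - y
    if (stats::sd(d) == 0) {
      tt <- list(estimate = mean(d), statistic = if (mean(d) == 0) 0 else Inf,
                 p.value = if (mean(d) == 0) 1 else 0)
    } else {
      tt <- stats::t.test(d)
    }
    data.frame(policy_a = pr[1], policy_b = pr[2],
               mean_diff = as.numeric(tt$estimate),
               t = as.numeric(tt$statistic),
               p = as.numeric(tt$p.value), stringsAsFactors = FALSE)
  })
  list(chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
       contrasts = do.call(rbind, contrasts))
}

#' Simple linear regression of a landscape summary on tree cover
#'
#' Ordinary least squares of a per-landscape response (mean percent species
#' loss, or standardized coverage) on landscape-scale tree cover, reporting
#' slope, intercept, F with (1, n-2) df, R-squared and the two-sided p.
#'
#' @param tree_cover numeric vector of landscape tree cover (%).
#' @param response numeric vector, same length.
#' @return a list: `slope`, `intercept`, `F`, `df`, `r_squared`, `p_value`,
#'   `n`.
#' @export
landscape_regression <- function(tree_cover, response) {
  if (length(tree_cover) != length(response)) {
    stop("tree_cover and response must have equal length", call. = FALSE)
  }
  if (length(tree_cover) < 3L) stop("need at least 3 landscapes", call. = FALSE)
  if (stats::sd(tree_cover) == 0) {
    stop("zero variance in tree cover: regression undefined", call. = FALSE)
  }
  fit <- stats::lm(response ~ tree_cover)
  n <- length(response)
  if (stats::sd(response) == 0) {
    # constant response: slope 0 by construction, no explainable variance
    return(list(slope = 0, intercept = response[1], F = 0,
                df = c(1, n - 2), r_squared = 0, p_value = 1, n = n))
  }
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       F = unname(fstat["value"]),
       df = c(unname(fstat["numdf"]), unname(fstat["dendf"])),
       r_squared = sm$r.squared,
       p_value = stats::pf(fstat["value"], fstat["numdf"], fstat["dendf"],
                           lower.tail = FALSE)[[1]],
       n = n)
}
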